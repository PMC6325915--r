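#' Pipeline configuration
#'
#' Describes one end-to-end analysis run: either a synthetic dataset (a
#' [synthetic_config()]) or real-data input paths, the gene subgroups to
#' analyse, the bootstrap settings, the hypothesis tests to run, the output
#' directory and the master seed.  The master seed drives every stochastic
#' stage (it replaces the synthetic config's own seed and, offset by one,
#' seeds the bootstrap), so a rerun with the same configuration reproduces
#' byte-identical numeric outputs.
#'
#' @param synthetic Optional [synthetic_config()]; mutually exclusive with
#'   the input paths.
#' @param expression_path,metadata_path,gene_map_path Input files for
#'   real-data mode (all three required); see [read_expression_matrix()],
#'   [read_sample_metadata()], [read_gene_map()].
#' @param par_list_path Optional PAR gene list ([read_par_list()]).
#' @param subgroups Gene subgroups to analyse, default all four.
#' @param rge_subgroup Subgroup for the per-autosome RGE table, default
#'   `"EXPRESSED"`.
#' @param expressed_threshold Expression cut-off in TPM, default 1.
#' @param bootstrap A [bootstrap_config()]; its seed is overridden by
#'   `seed + 1`.
#' @param comparisons List of `c(reference, alternative)` treatment pairs
#'   for differential expression and the diet test.
#' @param group_col Metadata column holding the DE grouping, default
#'   `"treatment"`.
#' @param tests Character subset of `c("sex_t_test", "diet_wilcoxon",
#'   "counts_anova")`.
#' @param out_dir Output directory for the result bundle.
#' @param seed Master seed (required).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL,
                            expression_path = NULL,
                            metadata_path = NULL,
                            gene_map_path = NULL,
                            par_list_path = NULL,
                            subgroups = SUBGROUP_NAMES,
                            rge_subgroup = "EXPRESSED",
                            expressed_threshold = 1,
                            bootstrap = bootstrap_config(),
                            comparisons = list(c("Con", "Over"), c("Con", "Res")),
                            group_col = "treatment",
                            tests = c("sex_t_test", "diet_wilcoxon", "counts_anova"),
                            out_dir = tempfile("xdosage_run_"),
                            seed = NULL) {
  if (is.null(seed)) abort("A master `seed` is required.")
  subgroups <- match.arg(subgroups, SUBGROUP_NAMES, several.ok = TRUE)
  rge_subgroup <- arg_match(rge_subgroup, SUBGROUP_NAMES)
  tests <- match.arg(tests,
    c("sex_t_test", "diet_wilcoxon", "counts_anova"),
    several.ok = TRUE
  )
  if (is.null(synthetic)) {
    missing_paths <- c(
      if (is.null(expression_path)) "expression_path",
      if (is.null(metadata_path)) "metadata_path",
      if (is.null(gene_map_path)) "gene_map_path"
    )
    if (length(missing_paths) > 0) {
      abort(paste0(
        "Real-data mode needs ", paste(missing_paths, collapse = ", "),
        " (or supply `synthetic`)."
      ))
    }
  } else if (!inherits(synthetic, "synthetic_config")) {
    abort("`synthetic` must be a synthetic_config object.")
  }
  structure(
    list(
      synthetic = synthetic,
      expression_path = expression_path,
      metadata_path = metadata_path,
      gene_map_path = gene_map_path,
      par_list_path = par_list_path,
      subgroups = subgroups,
      rge_subgroup = rge_subgroup,
      expressed_threshold = expressed_threshold,
      bootstrap = bootstrap,
      comparisons = comparisons,
      group_col = group_col,
      tests = tests,
      out_dir = out_dir,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full dosage-compensation analysis
#'
#' Executes the stages in fixed order — input (simulate or read), subgroup
#' RXE with compensation classification, per-autosome RGE, boxplot
#' summaries, bootstrap differential expression with the X-linked subset,
#' and the group hypothesis tests — writing a TSV/JSON result bundle and a
#' manifest (file MD5 hashes, seed, package version) to the output
#' directory.  A stage failure aborts with a message naming the stage.
#' Rerunning with the same configuration and seed reproduces byte-identical
#' numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages, default `FALSE`.
#' @return An object of class `xdosage_pipeline` with elements `rxe`, `rge`,
#'   `boxplots`, `degs` (list of [bootstrap_de()] objects), `x_degs`,
#'   `group_stats`, `expressed_counts`, `count_summary`, `correlation`,
#'   `manifest`, `config`, `out_dir`.  Use [tidy()] for the RXE table and
#'   [glance()] for a one-row run summary.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- paste0("[", stage, "] ", msg)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      say(stage, paste0("FAILED: ", conditionMessage(e)))
      writeLines(log_lines, log_path)
      abort(paste0("Pipeline stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }

  # -- input ----------------------------------------------------------------
  inputs <- run_stage("input", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      syn$seed <- config$seed
      ann <- generate_annotation(syn)
      list(
        annotation = ann,
        expr = generate_expression(ann, syn),
        samples = generate_design(syn),
        input_files = character(0)
      )
    } else {
      ann <- read_gene_map(config$gene_map_path)
      if (!is.null(config$par_list_path)) {
        ann <- read_par_list(ann, config$par_list_path)
      }
      list(
        annotation = ann,
        expr = read_expression_matrix(config$expression_path, config$metadata_path),
        samples = read_sample_metadata(config$metadata_path),
        input_files = c(
          config$expression_path, config$metadata_path,
          config$gene_map_path, config$par_list_path
        )
      )
    }
  })
  say("input", paste0(
    nrow(inputs$expr), " genes x ", ncol(inputs$expr) - 1, " samples"
  ))

  # -- chromosome-relative expression --------------------------------------
  rxe <- run_stage("rxe", compute_rxe(
    inputs$expr, inputs$annotation,
    subgroup = config$subgroups,
    expressed_threshold = config$expressed_threshold
  ))
  rge <- run_stage("rge", compute_rge(
    inputs$expr, inputs$annotation,
    subgroup = config$rge_subgroup,
    expressed_threshold = config$expressed_threshold
  ))
  say("rxe", paste0(nrow(rxe), " sample-by-subgroup RXE values"))

  boxplots <- run_stage("boxplots", {
    per_sample_rge <- rge %>%
      group_by(.data$sample_id) %>%
      dplyr::group_modify(~ summarize_group(.x, .data$rge, .data$chromosome)) %>%
      ungroup() %>%
      mutate(what = "rge_by_chromosome", .before = 1)
    rxe_box <- rxe %>%
      group_by(.data$subgroup) %>%
      dplyr::group_modify(~ summarize_group(.x, .data$rxe, .data$sample_id)) %>%
      ungroup() %>%
      mutate(what = "rxe_by_subgroup", .before = 1)
    list(rge = per_sample_rge, rxe = rxe_box)
  })

  # -- differential expression ----------------------------------------------
  boot_cfg <- config$bootstrap
  boot_cfg$seed <- config$seed + 1L
  degs <- run_stage("de", {
    purrr::map(config$comparisons, function(cmp) {
      bootstrap_de(inputs$expr, inputs$samples,
        group_col = config$group_col,
        reference = cmp[1], alternative = cmp[2],
        config = boot_cfg
      )
    })
  })
  x_degs <- purrr::map(degs, filter_x_linked, annotation = inputs$annotation)
  say("de", paste0(
    sum(purrr::map_int(degs, ~ sum(.x$results$significant))),
    " significant genes across ", length(degs), " comparison(s)"
  ))

  # -- group statistics -----------------------------------------------------
  stat_subgroup <- if ("EXPRESSED" %in% config$subgroups) "EXPRESSED" else config$subgroups[1]
  rxe_for_tests <- filter(rxe, .data$subgroup == stat_subgroup)
  group_stats <- run_stage("stats", {
    pieces <- list()
    if ("sex_t_test" %in% config$tests) {
      pieces$sex <- compare_rxe_by_sex(rxe_for_tests, inputs$samples)
    }
    if ("diet_wilcoxon" %in% config$tests) {
      pieces$diet <- bind_rows(purrr::map(config$comparisons, function(cmp) {
        compare_rxe_by_diet(rxe_for_tests, inputs$samples,
          reference = cmp[1], alternative = cmp[2]
        ) %>% mutate(stratum = paste(cmp[1], "vs", cmp[2]))
      }))
    }
    counts <- count_expressed_x_genes(inputs$expr, inputs$annotation,
                                      threshold = config$expressed_threshold)
    if ("counts_anova" %in% config$tests) {
      pieces$anova <- anova_expressed_counts(counts, inputs$samples)
    }
    list(tests = bind_rows(pieces), counts = counts)
  })
  expressed_counts <- group_stats$counts
  count_summary <- summarize_expressed_counts(expressed_counts, inputs$samples)

  correlation <- run_stage("correlation", {
    m <- expr_to_matrix(inputs$expr)
    chrom <- inputs$annotation$chromosome[
      match(rownames(m), inputs$annotation$gene_id)
    ]
    per_chrom <- tibble(
      chromosome = chrom,
      n_expressed = rowSums(m >= config$expressed_threshold) > 0
    ) %>%
      filter(is_autosome(.data$chromosome)) %>%
      group_by(.data$chromosome) %>%
      summarise(n_expressed = sum(.data$n_expressed), .groups = "drop")
    activity_gene_count_correlation(rge, per_chrom)
  })

  # -- report bundle --------------------------------------------------------
  files <- run_stage("report", {
    paths <- c(
      rxe = file.path(out_dir, "rxe.tsv"),
      rge = file.path(out_dir, "rge.tsv"),
      boxplots = file.path(out_dir, "boxplot_summaries.json"),
      degs = file.path(out_dir, "degs.tsv"),
      x_degs = file.path(out_dir, "x_degs.tsv"),
      group_stats = file.path(out_dir, "group_stats.tsv"),
      expressed_counts = file.path(out_dir, "expressed_x_counts.tsv"),
      summary = file.path(out_dir, "summary.json")
    )
    readr::write_tsv(rxe, paths[["rxe"]], progress = FALSE)
    readr::write_tsv(rge, paths[["rge"]], progress = FALSE)
    jsonlite::write_json(
      list(
        rge_by_chromosome = boxplot_json(boxplots$rge),
        rxe_by_subgroup = boxplot_json(boxplots$rxe)
      ),
      paths[["boxplots"]],
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_deg_table(bind_rows(purrr::map(degs, tidy)), paths[["degs"]])
    write_deg_table(bind_rows(purrr::map(x_degs, tidy)), paths[["x_degs"]])
    readr::write_tsv(group_stats$tests, paths[["group_stats"]], progress = FALSE)
    readr::write_tsv(
      inner_join(expressed_counts, inputs$samples, by = "sample_id"),
      paths[["expressed_counts"]], progress = FALSE
    )
    jsonlite::write_json(
      list(
        seed = config$seed,
        activity_gene_count_correlation = correlation,
        n_genes = nrow(inputs$expr),
        n_samples = ncol(inputs$expr) - 1,
        count_summary = count_summary
      ),
      paths[["summary"]],
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    paths
  })

  manifest <- tibble(
    name = names(files),
    path = unname(files),
    md5 = unname(tools::md5sum(unname(files)))
  )
  manifest_meta <- list(
    package = "xdosage",
    version = as.character(packageVersion("xdosage")),
    seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_files = as.list(setNames(
      unname(tools::md5sum(inputs$input_files)), inputs$input_files
    )),
    outputs = manifest
  )
  jsonlite::write_json(manifest_meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report", paste0("bundle written to ", out_dir))
  writeLines(log_lines, log_path)

  structure(
    list(
      rxe = rxe, rge = rge, boxplots = boxplots,
      degs = degs, x_degs = x_degs,
      group_stats = group_stats$tests,
      expressed_counts = expressed_counts,
      count_summary = count_summary,
      correlation = correlation,
      manifest = manifest,
      config = config,
      out_dir = out_dir
    ),
    class = "xdosage_pipeline"
  )
}

# Serialize boxplot-summary rows (with outlier list-columns) for JSON.
boxplot_json <- function(tbl) {
  purrr::pmap(tbl, function(...) {
    row <- list(...)
    row$outliers <- as.data.frame(row$outliers)
    row
  })
}

#' @export
print.xdosage_pipeline <- function(x, ...) {
  cat("xdosage pipeline run (seed ", x$config$seed, ")\n",
      "  RXE rows: ", nrow(x$rxe), " | RGE rows: ", nrow(x$rge), "\n",
      "  comparisons: ", length(x$degs),
      " | output: ", x$out_dir, "\n", sep = "")
  invisible(x)
}

#' Tidy a pipeline run
#'
#' @param x An `xdosage_pipeline` object.
#' @param ... Unused.
#' @return The per-sample, per-subgroup RXE tibble.
#' @export
tidy.xdosage_pipeline <- function(x, ...) x$rxe

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.xdosage_pipeline
#' @return A one-row tibble with run dimensions, the mean RXE per the first
#'   subgroup, significant DE gene counts and the activity/gene-count
#'   correlation.
#' @export
glance.xdosage_pipeline <- function(x, ...) {
  sg <- x$config$subgroups[1]
  tibble(
    seed = x$config$seed,
    n_samples = length(unique(x$rxe$sample_id)),
    n_subgroups = length(unique(x$rxe$subgroup)),
    mean_rxe = mean(x$rxe$rxe[x$rxe$subgroup == sg]),
    n_significant_degs = sum(purrr::map_int(x$degs, ~ sum(.x$results$significant))),
    n_significant_x_degs = sum(purrr::map_int(x$x_degs, ~ sum(.x$results$significant))),
    activity_gene_count_correlation = x$correlation
  )
}
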