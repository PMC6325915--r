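#' Configuration for the synthetic expression-data generator
#'
#' Describes a simulated dosage-compensation study: a chromosome-partitioned
#' gene universe, a log-normal baseline expression distribution, a planted
#' per-copy X-upregulation factor, pseudoautosomal (PAR) genes escaping X
#' inactivation, a tissue-by-treatment sampling design, and planted
#' diet-responsive differential effects.  Defaults emulate a sheep-like
#' study: 26 autosomes carrying 19,291 genes plus 1,228 X-linked genes (20
#' of them PAR) for 20,519 genes in total, and tissues brain/kidney/lung
#' sampled from control (n = 7), overfed (n = 4) and restricted (n = 4)
#' pregnancies.
#'
#' The expression model is multiplicative: each gene has a log-normal
#' baseline per-copy rate; autosomal genes contribute two copies, non-PAR
#' X-linked genes one active copy scaled by `upregulation_factor_u`, and PAR
#' genes two copies (both sex chromosomes express them).  Under this model
#' the population RXE is analytically `log2(u) - 1`, which is the surface
#' used for parameter-recovery checks.  Per-sample log-normal noise is
#' applied gene-wise, planted effects multiply designated genes in
#' designated treatment groups, a fraction of genes is silenced to zero, and
#' every sample column is renormalized to TPM.
#'
#' @param genes_per_chromosome Named integer vector, chromosome label ->
#'   gene count.  Default: sheep-like counts described above.
#' @param n_par Number of PAR genes to flag on X, default 20.
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD (log2 units) of
#'   the per-gene baseline rate distribution; defaults 3 and 1.5.
#' @param sample_noise_log2_sd SD (log2 units) of per-sample multiplicative
#'   noise, default 0.25.
#' @param upregulation_factor_u Per-copy transcription multiplier of the
#'   single active X, default 1.8 (population RXE about -0.152, i.e.
#'   partial compensation).
#' @param silent_fraction Fraction of genes forced to zero expression,
#'   default 0.3.
#' @param design Tibble with columns `tissue`, `treatment`, `sex`,
#'   `n_samples`; default mirrors the brain/kidney/lung x Con(7)/Over(4)/
#'   Res(4) layout with mixed sexes.
#' @param planted_degs Tibble with columns `gene_id`, `treatment`,
#'   `log2_effect`; `gene_id = NA` rows are assigned to distinct non-PAR
#'   X-linked genes at generation time.  Default plants 8 X-linked genes
#'   with effects of magnitude 3.2-4.6 split between the Over and Res
#'   groups.
#' @param seed Integer seed driving every random draw.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(genes_per_chromosome = NULL,
                             n_par = 20,
                             baseline_log2_mean = 3,
                             baseline_log2_sd = 1.5,
                             sample_noise_log2_sd = 0.25,
                             upregulation_factor_u = 1.8,
                             silent_fraction = 0.3,
                             design = NULL,
                             planted_degs = NULL,
                             seed = 1) {
  if (is.null(genes_per_chromosome)) {
    genes_per_chromosome <- default_gene_counts()
  }
  if (is.null(names(genes_per_chromosome)) ||
      any(genes_per_chromosome < 1)) {
    abort("`genes_per_chromosome` must be a named vector of positive counts.")
  }
  if (!"X" %in% names(genes_per_chromosome)) {
    abort("`genes_per_chromosome` must include an X chromosome.")
  }
  if (upregulation_factor_u <= 0) abort("`upregulation_factor_u` must be > 0.")
  if (silent_fraction < 0 || silent_fraction >= 1) {
    abort("`silent_fraction` must be in [0, 1).")
  }
  if (baseline_log2_sd < 0 || sample_noise_log2_sd < 0) {
    abort("Spread parameters must be nonnegative.")
  }
  if (n_par < 0 || n_par > genes_per_chromosome[["X"]]) {
    abort("`n_par` must be between 0 and the X gene count.")
  }
  if (is.null(design)) design <- default_design()
  needed <- c("tissue", "treatment", "sex", "n_samples")
  if (!all(needed %in% names(design))) {
    abort("`design` needs columns tissue, treatment, sex, n_samples.")
  }
  if (sum(design$n_samples) < 1) abort("Design must include at least one sample.")
  available_x <- genes_per_chromosome[["X"]] - n_par
  if (is.null(planted_degs)) {
    # adaptive default: never plant more effects than there are non-PAR
    # X-linked genes to carry them
    planted_degs <- head(default_planted_degs(), max(available_x, 0))
  }
  if (nrow(planted_degs) > 0 &&
      !all(c("gene_id", "treatment", "log2_effect") %in% names(planted_degs))) {
    abort("`planted_degs` needs columns gene_id, treatment, log2_effect.")
  }
  if (sum(is.na(planted_degs$gene_id)) > available_x) {
    abort("Not enough non-PAR X-linked genes to place planted effects.")
  }
  structure(
    list(
      genes_per_chromosome = genes_per_chromosome,
      n_par = as.integer(n_par),
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      sample_noise_log2_sd = sample_noise_log2_sd,
      upregulation_factor_u = upregulation_factor_u,
      silent_fraction = silent_fraction,
      design = as_tibble(design),
      planted_degs = as_tibble(planted_degs),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Sheep-like default: 19,291 autosomal genes spread over 26 autosomes with a
# decreasing size gradient, plus 1,228 X-linked genes (20,519 total).
default_gene_counts <- function() {
  w <- (27 - 1:26)
  cuts <- round(cumsum(w / sum(w)) * 19291)
  counts <- diff(c(0L, cuts))
  setNames(c(as.integer(counts), 1228L), c(as.character(1:26), "X"))
}

default_design <- function() {
  tidyr::expand_grid(
    tissue = c("brain", "kidney", "lung"),
    tibble(
      treatment = c("Con", "Con", "Over", "Over", "Res", "Res"),
      sex = rep(c("female", "male"), 3),
      n_samples = c(4L, 3L, 2L, 2L, 2L, 2L)
    )
  )
}

default_planted_degs <- function() {
  # both signs within each treatment, so planted effects perturb RXE in both
  # directions rather than biasing one diet group upward
  tibble(
    gene_id = NA_character_,
    treatment = rep(c("Over", "Res"), 4),
    log2_effect = c(3.2, -3.4, -3.6, 3.8, 4.0, -4.2, -4.4, 4.6)
  )
}

# All seed-dependent bookkeeping draws, in fixed order, WITHOUT seeding (the
# caller wraps in withr::with_seed) so annotation, truth table and
# expression stay mutually consistent: lengths, PAR selection, baselines,
# planted-gene resolution, silent mask.
synth_draws <- function(config) {
  counts <- config$genes_per_chromosome
  chrom <- rep(names(counts), counts)
  n <- length(chrom)
  gene_id <- sprintf("g%05d", seq_len(n))
  length_bp <- pmax(200L, as.integer(round(rlnorm(n, log(1500), 0.6))))
  x_idx <- which(chrom == "X")
  par_idx <- if (config$n_par > 0) sort(sample(x_idx, config$n_par)) else integer(0)
  is_par <- seq_len(n) %in% par_idx
  baseline_rate <- 2^rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  planted <- config$planted_degs
  if (nrow(planted) > 0 && any(is.na(planted$gene_id))) {
    candidates <- setdiff(which(chrom == "X" & !is_par), integer(0))
    need <- sum(is.na(planted$gene_id))
    if (need > length(candidates)) {
      abort("Not enough non-PAR X-linked genes to place planted effects.")
    }
    picked <- sample(candidates, need)
    planted$gene_id[is.na(planted$gene_id)] <- gene_id[picked]
  }
  if (nrow(planted) > 0 && !all(planted$gene_id %in% gene_id)) {
    abort("planted_degs reference gene_ids absent from the generated annotation.")
  }

  n_silent <- round(config$silent_fraction * n)
  eligible <- setdiff(seq_len(n), match(planted$gene_id, gene_id))
  silent_idx <- if (n_silent > 0) sort(sample(eligible, min(n_silent, length(eligible)))) else integer(0)
  is_silent <- seq_len(n) %in% silent_idx

  copies <- ifelse(chrom == "X",
    ifelse(is_par, 2, config$upregulation_factor_u),
    2
  )
  list(
    annotation = tibble(
      gene_id = gene_id, chromosome = chrom,
      length_bp = length_bp, is_par = is_par
    ),
    baseline_rate = baseline_rate,
    copies = copies,
    is_silent = is_silent,
    planted = planted
  )
}

#' Generate a synthetic gene annotation
#'
#' Deterministic under the config seed: gene identifiers laid out chromosome
#' by chromosome, log-normal gene lengths, and exactly `n_par` genes flagged
#' pseudoautosomal on X.
#'
#' @param config A [synthetic_config()].
#' @return An annotation tibble (`gene_id`, `chromosome`, `length_bp`,
#'   `is_par`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, synth_draws(config))$annotation
}

#' Expand the sampling design into per-sample metadata
#'
#' Deterministic (no random draws): one row per sample with identifiers of
#' the form `tissue_treatment_NN`.
#'
#' @param config A [synthetic_config()].
#' @return A sample-metadata tibble (`sample_id`, `tissue`, `sex`,
#'   `treatment`, `dataset`).
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  d <- config$design
  samples <- tidyr::uncount(d, .data$n_samples)
  samples %>%
    group_by(.data$tissue, .data$treatment) %>%
    mutate(sample_id = sprintf("%s_%s_%02d", .data$tissue, .data$treatment,
                               row_number())) %>%
    ungroup() %>%
    mutate(dataset = "synthetic") %>%
    select(all_of(c("sample_id", "tissue", "sex", "treatment", "dataset")))
}

#' Generate a synthetic TPM expression matrix
#'
#' Applies the generative model described in [synthetic_config()]: baseline
#' per-copy rates times copy numbers (with the X-upregulation factor on the
#' single active X and two copies for PAR genes), per-sample multiplicative
#' log-normal noise, planted treatment effects, silencing, and TPM
#' renormalization of every sample column to 1e6.
#'
#' @param annotation The annotation from [generate_annotation()] with the
#'   same config (checked).
#' @param config A [synthetic_config()].
#' @return An expression tibble (`gene_id` plus one column per sample).
#' @export
generate_expression <- function(annotation, config) {
  stopifnot(inherits(config, "synthetic_config"))
  samples <- generate_design(config)
  withr::with_seed(config$seed, {
    st <- synth_draws(config)
    if (!identical(st$annotation$gene_id, annotation$gene_id) ||
        !identical(st$annotation$chromosome, annotation$chromosome)) {
      abort("`annotation` does not match the one generated by this config/seed.")
    }
    n_genes <- nrow(st$annotation)
    n_samp <- nrow(samples)
    base <- st$baseline_rate * st$copies
    base[st$is_silent] <- 0
    noise <- if (config$sample_noise_log2_sd > 0) {
      matrix(2^rnorm(n_genes * n_samp, 0, config$sample_noise_log2_sd),
             n_genes, n_samp)
    } else {
      matrix(1, n_genes, n_samp)
    }
    m <- base * noise
    colnames(m) <- samples$sample_id
    rownames(m) <- st$annotation$gene_id
    if (nrow(st$planted) > 0) {
      for (k in seq_len(nrow(st$planted))) {
        g <- match(st$planted$gene_id[k], rownames(m))
        cols <- samples$treatment == st$planted$treatment[k]
        m[g, cols] <- m[g, cols] * 2^st$planted$log2_effect[k]
      }
    }
    totals <- colSums(m)
    if (any(totals == 0)) abort("A generated sample has zero total expression.")
    m <- sweep(m, 2, totals, "/") * 1e6
    bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
  })
}

#' Per-gene ground truth for a synthetic dataset
#'
#' The bookkeeping oracle for recovery tests: baseline rate, copy-number
#' multiplier (including the X-upregulation factor), silencing flag, and
#' planted differential effects.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with one row per gene: `gene_id`, `chromosome`,
#'   `is_par`, `baseline_rate`, `copies`, `is_silent`, `is_planted_deg`,
#'   `planted_treatment`, `log2_effect`.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  st <- withr::with_seed(config$seed, synth_draws(config))
  planted <- st$planted
  truth <- st$annotation %>%
    select(all_of(c("gene_id", "chromosome", "is_par"))) %>%
    mutate(
      baseline_rate = st$baseline_rate,
      copies = st$copies,
      is_silent = st$is_silent,
      is_planted_deg = .data$gene_id %in% planted$gene_id
    )
  left_join(
    truth,
    planted %>% rename(planted_treatment = "treatment"),
    by = "gene_id"
  )
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the same file dialects the readers consume — gene map TSV,
#' expression TSV, sample-metadata TSV, PAR gene list — plus the truth table
#' and the generator configuration as YAML.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- generate_annotation(config)
  expr <- generate_expression(ann, config)
  samples <- generate_design(config)
  truth <- truth_table(config)
  paths <- c(
    gene_map = file.path(dir, "gene_map.tsv"),
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    par_list = file.path(dir, "par_genes.txt"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_gene_map(ann, paths[["gene_map"]])
  write_expression_matrix(expr, paths[["expression"]])
  readr::write_tsv(samples, paths[["samples"]], progress = FALSE)
  writeLines(
    c("# pseudoautosomal genes", ann$gene_id[ann$is_par]),
    paths[["par_list"]]
  )
  readr::write_tsv(truth, paths[["truth"]], progress = FALSE)
  cfg <- unclass(config)
  cfg$design <- as.data.frame(cfg$design)
  cfg$planted_degs <- as.data.frame(cfg$planted_degs)
  cfg$genes_per_chromosome <- as.list(cfg$genes_per_chromosome)
  yaml::write_yaml(cfg, paths[["config"]])
  invisible(paths)
}
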