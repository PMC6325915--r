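#' Bootstrap differential-expression configuration
#'
#' @param n_replicates Number of bootstrap replicates, default 200.
#' @param fc_threshold_log2 Absolute log2 fold-change cut-off for calling a
#'   gene differentially expressed, default 1 (i.e. 2-fold).
#' @param alpha Significance level on the empirical p-value, default 0.05.
#' @param seed Integer seed; required by [bootstrap_de()].
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replicates = 200, fc_threshold_log2 = 1,
                             alpha = 0.05, seed = NULL) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(
    list(
      n_replicates = as.integer(n_replicates),
      fc_threshold_log2 = fc_threshold_log2,
      alpha = alpha,
      seed = seed
    ),
    class = "bootstrap_config"
  )
}

#' Bootstrap differential expression between two groups
#'
#' Calls differential expression from gene-level TPM by resampling samples
#' with replacement, stratified by group.  In every replicate the sample
#' columns of each group are resampled (the resampling unit is the sample,
#' since the input is gene-level TPM, not reads), group means are recomputed,
#' and the bootstrap fold change `FC_b = mean_alt_b / mean_ref_b` is recorded
#' (conventions: 0/0 gives 1, x/0 gives +Inf, 0/x gives 0).  The two-sided
#' empirical p-value is `2 * min(P(FC_b >= 1), P(FC_b <= 1))`, clipped to
#' `[1/n_replicates, 1]` so finite resampling never reports exactly zero.
#' The reported effect size is the log2 ratio of the *observed* group means,
#' with `+Inf`/`-Inf` when one group's mean is exactly zero; a gene is
#' flagged significant when `|log2_fc| > fc_threshold_log2` and
#' `p_value <= alpha`.  No distributional assumptions are made and no
#' multiple-testing correction is applied by default; set `adjust = "BH"` for
#' Benjamini-Hochberg-adjusted significance calls.
#'
#' Identical seed, configuration and input reproduce bit-identical results.
#' Resampling indices are drawn per group in a fixed (alphabetical) group
#' order, so swapping which level is called reference only flips the sign of
#' `log2_fc` and leaves p-values unchanged.
#'
#' @param expr Expression tibble (`gene_id` plus sample columns, TPM).
#' @param samples Sample-metadata tibble with `sample_id` and the grouping
#'   column.
#' @param group_col Metadata column defining the groups, default
#'   `"treatment"`.
#' @param reference,alternative Group levels to compare; fold changes are
#'   alternative over reference.
#' @param config A [bootstrap_config()].
#' @param adjust `"none"` (default) or `"BH"`; with `"BH"` the significance
#'   flag uses Benjamini-Hochberg adjusted p-values (the raw `p_value`
#'   column is kept and an `p_adjusted` column added).
#' @return An object of class `bootstrap_de`: use [tidy()] for the per-gene
#'   table (`gene_id`, `mean_ref_tpm`, `mean_alt_tpm`, `log2_fc`, `p_value`,
#'   `significant`), [glance()] for a one-row summary, [autoplot()] for a
#'   volcano plot.
#' @export
bootstrap_de <- function(expr, samples, group_col = "treatment",
                         reference, alternative,
                         config = bootstrap_config(),
                         adjust = c("none", "BH")) {
  adjust <- arg_match(adjust)
  if (is.null(config$seed)) {
    abort("A seed is required in `config` for reproducible resampling.")
  }
  if (!group_col %in% names(samples)) {
    abort(paste0("Grouping column ", group_col, " not found in sample metadata."))
  }
  m <- expr_to_matrix(expr)
  grp <- setNames(samples[[group_col]], samples$sample_id)[colnames(m)]
  cols_by_level <- lapply(
    setNames(nm = sort(c(reference, alternative))),
    function(lv) which(!is.na(grp) & grp == lv)
  )
  for (lv in c(reference, alternative)) {
    if (length(cols_by_level[[lv]]) == 0) {
      abort(paste0("Group ", lv, " has no samples in the expression matrix."))
    }
  }
  ref_m <- m[, cols_by_level[[reference]], drop = FALSE]
  alt_m <- m[, cols_by_level[[alternative]], drop = FALSE]

  mean_ref <- unname(rowMeans(ref_m))
  mean_alt <- unname(rowMeans(alt_m))
  log2_fc <- ifelse(
    mean_ref == 0 & mean_alt == 0, 0,
    ifelse(mean_ref == 0, Inf,
      ifelse(mean_alt == 0, -Inf, log2(mean_alt / mean_ref))
    )
  )

  B <- config$n_replicates
  n_ge <- numeric(nrow(m))
  n_le <- numeric(nrow(m))
  withr::with_seed(config$seed, {
    for (b in seq_len(B)) {
      # one index draw per group level, in fixed level order, so the draws do
      # not depend on which level plays "reference"
      idx <- lapply(cols_by_level, function(cols) {
        sample.int(length(cols), replace = TRUE)
      })
      mr <- rowMeans(ref_m[, idx[[reference]], drop = FALSE])
      ma <- rowMeans(alt_m[, idx[[alternative]], drop = FALSE])
      fc <- ifelse(mr == 0 & ma == 0, 1, ma / mr) # ma/0 -> Inf, 0/mr -> 0
      n_ge <- n_ge + (fc >= 1)
      n_le <- n_le + (fc <= 1)
    }
  })
  p <- unname(pmin(pmax(2 * pmin(n_ge, n_le) / B, 1 / B), 1))

  res <- tibble(
    gene_id = rownames(m),
    mean_ref_tpm = mean_ref,
    mean_alt_tpm = mean_alt,
    log2_fc = log2_fc,
    p_value = p
  )
  if (adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    p_for_call <- res$p_adjusted
  } else {
    p_for_call <- res$p_value
  }
  res$significant <- abs(res$log2_fc) > config$fc_threshold_log2 &
    p_for_call <= config$alpha

  structure(
    list(
      results = res,
      reference = reference,
      alternative = alternative,
      group_col = group_col,
      config = config,
      adjust = adjust
    ),
    class = "bootstrap_de"
  )
}

#' @export
print.bootstrap_de <- function(x, ...) {
  cat(
    "Bootstrap differential expression: ", x$alternative, " vs ", x$reference,
    " (", x$config$n_replicates, " replicates)\n",
    sum(x$results$significant), " of ", nrow(x$results),
    " genes significant at |log2FC| > ", x$config$fc_threshold_log2,
    ", p <= ", x$config$alpha, "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a bootstrap DE result
#'
#' @param x A `bootstrap_de` object.
#' @param ... Unused.
#' @return The per-gene result tibble with `comparison` prepended.
#' @export
tidy.bootstrap_de <- function(x, ...) {
  mutate(x$results,
    comparison = paste(x$reference, "vs", x$alternative),
    .before = 1
  )
}

#' One-row summary of a bootstrap DE result
#'
#' @inheritParams tidy.bootstrap_de
#' @return A one-row tibble: comparison, gene counts, settings, seed.
#' @export
glance.bootstrap_de <- function(x, ...) {
  tibble(
    reference = x$reference,
    alternative = x$alternative,
    n_genes = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_replicates = x$config$n_replicates,
    fc_threshold_log2 = x$config$fc_threshold_log2,
    alpha = x$config$alpha,
    seed = x$config$seed
  )
}

#' Volcano plot of a bootstrap DE result
#'
#' Infinite log2 fold changes (one group mean exactly zero) are drawn at the
#' edge of the finite range with a distinct shape.
#'
#' @param object A `bootstrap_de` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_de <- function(object, ...) {
  d <- object$results
  finite_max <- max(abs(d$log2_fc[is.finite(d$log2_fc)]), 1)
  d$plotted_fc <- pmin(pmax(d$log2_fc, -1.1 * finite_max), 1.1 * finite_max)
  d$infinite <- !is.finite(d$log2_fc)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$plotted_fc, y = -log10(.data$p_value),
    colour = .data$significant, shape = .data$infinite
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(
      x = "log2 fold change (alt / ref)", y = "-log10 bootstrap p",
      title = paste(object$alternative, "vs", object$reference),
      shape = "infinite FC"
    )
}

#' Restrict differential-expression calls to X-linked genes
#'
#' @param degs A `bootstrap_de` object or a tibble with a `gene_id` column.
#' @param annotation Annotation tibble covering the DE gene identifiers.
#' @return Same type as `degs`, subset to genes on the X chromosome, input
#'   order preserved.
#' @export
filter_x_linked <- function(degs, annotation) {
  annotation <- check_annotation(annotation)
  x_ids <- annotation$gene_id[annotation$chromosome == "X"]
  if (inherits(degs, "bootstrap_de")) {
    degs$results <- filter(degs$results, .data$gene_id %in% x_ids)
    return(degs)
  }
  filter(degs, .data$gene_id %in% x_ids)
}

#' Write a differential-expression table
#'
#' TSV with one row per gene: comparison, group means in TPM, log2 fold
#' change (literal `inf`/`-inf` for one-sided zero means), p-value and
#' significance flag.
#'
#' @param degs A `bootstrap_de` object or tidy DEG tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(degs, path) {
  tab <- if (inherits(degs, "bootstrap_de")) tidy(degs) else degs
  tab$log2_fc <- ifelse(
    is.finite(tab$log2_fc), format_num(tab$log2_fc),
    ifelse(tab$log2_fc > 0, "inf", "-inf")
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

format_num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
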