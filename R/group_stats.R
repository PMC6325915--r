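#' Count expressed X-linked genes per sample
#'
#' Number of X-linked genes at or above the expression threshold (inclusive,
#' default TPM >= 1) in each sample.
#'
#' @inheritParams compute_rxe
#' @param threshold Expression cut-off in TPM, default 1.
#' @return A tibble with columns `sample_id`, `n_expressed_x`.
#' @seealso [anova_expressed_counts()] for the treatment comparison;
#'   [summarize_expressed_counts()] for mean +/- SD per tissue x treatment.
#' @export
count_expressed_x_genes <- function(expr, annotation, threshold = 1) {
  annotation <- check_annotation(annotation)
  m <- expr_to_matrix(expr)
  x_ids <- annotation$gene_id[annotation$chromosome == "X"]
  if (length(x_ids) == 0) {
    abort("Annotation contains no X-linked genes.")
  }
  on_x <- rownames(m) %in% x_ids
  tibble(
    sample_id = colnames(m),
    n_expressed_x = as.integer(colSums(m[on_x, , drop = FALSE] >= threshold))
  )
}

#' Mean and SD of expressed X-linked gene counts per tissue and treatment
#'
#' @param counts_tbl Result of [count_expressed_x_genes()].
#' @param samples Sample-metadata tibble.
#' @return A tibble with `tissue`, `treatment`, `n_samples`, `mean_count`,
#'   `sd_count`.
#' @export
summarize_expressed_counts <- function(counts_tbl, samples) {
  inner_join(counts_tbl, samples, by = "sample_id") %>%
    group_by(.data$tissue, .data$treatment) %>%
    summarise(
      n_samples = n(),
      mean_count = mean(.data$n_expressed_x),
      sd_count = sd(.data$n_expressed_x),
      .groups = "drop"
    )
}

#' Compare RXE between sexes (two-sample t-test)
#'
#' Two-sided two-sample t-test of per-sample RXE between female and male
#' samples.  Defaults to the classic pooled-variance Student form; Welch's
#' unequal-variance form is available.  By default the test is run within
#' each tissue (comparing sexes in the same somatic tissue); set
#' `by = NULL` to pool all samples.
#'
#' @param rxe_tbl Result of [compute_rxe()].
#' @param samples Sample-metadata tibble with `sex` labels.
#' @param by Optional metadata column to stratify by (default `"tissue"`;
#'   `NULL` pools everything).
#' @param var_equal Use the pooled-variance Student form (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return A tibble with one row per stratum: group sizes, t statistic,
#'   p-value.
#' @export
compare_rxe_by_sex <- function(rxe_tbl, samples, by = "tissue",
                               var_equal = TRUE) {
  d <- inner_join(rxe_tbl, samples, by = "sample_id") %>%
    filter(.data$sex %in% c("female", "male"))
  strata <- split_strata(d, by)
  bind_rows(purrr::map(strata, function(s) {
    f <- s$rxe[s$sex == "female"]
    m <- s$rxe[s$sex == "male"]
    if (length(f) < 2 || length(m) < 2) {
      abort("The t-test needs at least 2 samples per sex in every stratum.")
    }
    ht <- t.test(f, m, var.equal = var_equal)
    tibble(
      test = "t_test",
      stratum = s$.stratum[1],
      n_female = length(f),
      n_male = length(m),
      statistic = unname(ht$statistic),
      p_value = ht$p.value
    )
  }))
}

#' Compare RXE between diet groups (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of per-sample RXE between
#' a reference diet and an alternative diet.  The exact null distribution is
#' enumerated when both groups have at most 8 untied values; otherwise the
#' normal approximation with continuity and tie correction is used.  Fully
#' tied data yield p = 1 by convention.
#'
#' @param rxe_tbl Result of [compute_rxe()].
#' @param samples Sample-metadata tibble with `treatment` labels.
#' @param reference,alternative Treatment levels to compare.
#' @param by Optional metadata column to stratify by (default `NULL`,
#'   pooled).
#' @return A tibble with one row per stratum: group sizes, W statistic,
#'   p-value.
#' @export
compare_rxe_by_diet <- function(rxe_tbl, samples, reference = "Con",
                                alternative = "Over", by = NULL) {
  d <- inner_join(rxe_tbl, samples, by = "sample_id") %>%
    filter(.data$treatment %in% c(reference, alternative))
  strata <- split_strata(d, by)
  bind_rows(purrr::map(strata, function(s) {
    x <- s$rxe[s$treatment == reference]
    y <- s$rxe[s$treatment == alternative]
    if (length(x) == 0 || length(y) == 0) {
      abort("Both treatment groups must be nonempty.")
    }
    wt <- rank_sum_test(x, y)
    tibble(
      test = "wilcoxon_rank_sum",
      stratum = s$.stratum[1],
      n_reference = length(x),
      n_alternative = length(y),
      statistic = wt$statistic,
      p_value = wt$p_value
    )
  }))
}

# Wilcoxon rank-sum with the conventions documented in
# compare_rxe_by_diet(); shared with the pipeline report.
rank_sum_test <- function(x, y) {
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  }
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = min(p, 1))
}

#' One-way ANOVA on expressed X-linked gene counts
#'
#' Tests whether the number of expressed X-linked genes differs across
#' treatment groups, within each tissue (matching the per-tissue design of
#' the comparison).  Uses `stats::aov`.  Degenerate inputs are resolved by
#' convention: if the between-group sum of squares is zero the test reports
#' F = 0, p = 1; if only the within-group sum of squares is zero, F = Inf,
#' p = 0.
#'
#' @param counts_tbl Result of [count_expressed_x_genes()].
#' @param samples Sample-metadata tibble with `treatment` labels.
#' @param by Metadata column to stratify by, default `"tissue"` (`NULL`
#'   pools).
#' @return A tibble with one row per stratum: group count, F statistic,
#'   degrees of freedom, p-value.
#' @export
anova_expressed_counts <- function(counts_tbl, samples, by = "tissue") {
  d <- inner_join(counts_tbl, samples, by = "sample_id")
  strata <- split_strata(d, by)
  bind_rows(purrr::map(strata, function(s) {
    sizes <- table(s$treatment)
    if (length(sizes) < 2 || any(sizes < 2)) {
      abort("One-way ANOVA needs >= 2 groups with >= 2 values each.")
    }
    s$treatment <- factor(s$treatment)
    # degenerate (zero-variance) strata are resolved by convention below, so
    # aov's perfect-fit warning is redundant here
    at <- suppressWarnings(stats::anova(aov(n_expressed_x ~ treatment, data = s)))
    ss_b <- at$`Sum Sq`[1]
    ss_w <- at$`Sum Sq`[2]
    df_b <- at$Df[1]
    df_w <- at$Df[2]
    if (ss_b <= .Machine$double.eps * max(1, ss_w)) {
      f_stat <- 0
      p <- 1
    } else if (ss_w == 0) {
      f_stat <- Inf
      p <- 0
    } else {
      f_stat <- at$`F value`[1]
      p <- at$`Pr(>F)`[1]
    }
    tibble(
      test = "one_way_anova",
      stratum = s$.stratum[1],
      n_groups = length(sizes),
      df_between = df_b,
      df_within = df_w,
      statistic = f_stat,
      p_value = p
    )
  }))
}

# Split a joined table into strata by a metadata column; a NULL column means
# a single pooled stratum.
split_strata <- function(d, by) {
  if (is.null(by)) {
    d$.stratum <- "all"
  } else {
    if (!by %in% names(d)) {
      abort(paste0("Stratification column ", by, " not found."))
    }
    d$.stratum <- as.character(d[[by]])
  }
  split(d, d$.stratum)
}
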