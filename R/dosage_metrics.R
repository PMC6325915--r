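#' Select a gene subgroup for chromosome-relative expression
#'
#' The four subgroups used when estimating X upregulation:
#' \describe{
#'   \item{ALL}{every annotated gene present in the matrix, including low-
#'     and non-expressed genes;}
#'   \item{EXPRESSED}{genes with TPM >= `expressed_threshold` (inclusive) in
#'     the queried sample;}
#'   \item{XCI_SUBJECT}{EXPRESSED minus pseudoautosomal (PAR) genes, i.e. the
#'     genes actually subject to X inactivation;}
#'   \item{DOSAGE_SENSITIVE}{genes at or above the threshold in *every*
#'     sample of the matrix — the ubiquitously expressed, largely
#'     housekeeping set.}
#' }
#' EXPRESSED and XCI_SUBJECT membership is evaluated per sample;
#' DOSAGE_SENSITIVE is a property of the whole matrix.
#'
#' @param expr Expression tibble (`gene_id` plus sample columns, TPM).
#' @param annotation Annotation tibble.
#' @param subgroup One of `"ALL"`, `"EXPRESSED"`, `"XCI_SUBJECT"`,
#'   `"DOSAGE_SENSITIVE"`.
#' @param sample_id Sample column to evaluate per-sample subgroups in.
#' @param expressed_threshold Expression cut-off in TPM, default 1.
#' @return Character vector of gene identifiers.
#' @export
select_subgroup <- function(expr, annotation, subgroup = SUBGROUP_NAMES,
                            sample_id, expressed_threshold = 1) {
  subgroup <- arg_match(subgroup)
  annotation <- check_annotation(annotation)
  m <- expr_to_matrix(expr)
  keep <- subgroup_membership(m, annotation, subgroup, sample_id,
                              expressed_threshold)
  ids <- rownames(m)[keep[, sample_id]]
  if (length(ids) == 0) {
    abort(paste0("Subgroup ", subgroup, " is empty for sample ", sample_id, "."))
  }
  ids
}

# Membership matrix (genes x samples) for a subgroup; genes absent from the
# annotation are dropped from consideration.
subgroup_membership <- function(m, annotation, subgroup, sample_id = NULL,
                                expressed_threshold = 1) {
  if (expressed_threshold <= 0) {
    abort("`expressed_threshold` must be positive.")
  }
  annotated <- rownames(m) %in% annotation$gene_id
  keep <- switch(subgroup,
    ALL = matrix(TRUE, nrow(m), ncol(m)),
    EXPRESSED = m >= expressed_threshold,
    XCI_SUBJECT = {
      par_ids <- annotation$gene_id[annotation$is_par]
      (m >= expressed_threshold) & !(rownames(m) %in% par_ids)
    },
    DOSAGE_SENSITIVE = {
      ds <- rowSums(m >= expressed_threshold) == ncol(m)
      matrix(ds, nrow(m), ncol(m))
    }
  )
  keep <- keep & annotated
  dimnames(keep) <- dimnames(m)
  keep
}

#' Relative X expression (RXE)
#'
#' For every sample, the log2 ratio of the mean TPM over X-linked genes to
#' the mean TPM over autosomal genes in the chosen subgroup:
#' `RXE = log2(x) - log2(a)` with `x` the X gene-set mean and `a` the
#' autosomal gene-set mean.  An RXE of 0 means X and autosomal output are
#' balanced (complete upregulation of the single active X); -1 means the X
#' transcribes at half the autosomal level (no upregulation); values in
#' between indicate partial compensation.  Y-linked and mitochondrial genes,
#' if annotated, belong to neither side.
#'
#' The default follows the log-of-means form of the X:A ratio; `method =
#' "mean_of_log"` instead averages `log2(TPM)` over genes with positive TPM,
#' for sensitivity analyses against the geometric-mean variant used in parts
#' of the dosage-compensation literature.
#'
#' @inheritParams select_subgroup
#' @param subgroup One or more subgroup names; one result row per sample and
#'   subgroup.
#' @param method `"log_of_mean"` (default) or `"mean_of_log"`.
#' @return A tibble with columns `sample_id`, `subgroup`, `n_x_genes`,
#'   `n_autosomal_genes`, `x_mean_tpm`, `autosomal_mean_tpm`, `rxe`,
#'   `compensation`.
#' @seealso [classify_compensation()], [compute_rge()]
#' @export
compute_rxe <- function(expr, annotation, subgroup = "ALL",
                        expressed_threshold = 1,
                        method = c("log_of_mean", "mean_of_log")) {
  method <- arg_match(method)
  subgroup <- match.arg(subgroup, SUBGROUP_NAMES, several.ok = TRUE)
  annotation <- check_annotation(annotation, require_x = TRUE)
  m <- expr_to_matrix(expr)
  chrom <- annotation$chromosome[match(rownames(m), annotation$gene_id)]
  on_x <- !is.na(chrom) & chrom == "X"
  on_a <- !is.na(chrom) & is_autosome(chrom)

  res <- purrr::map(subgroup, function(sg) {
    keep <- subgroup_membership(m, annotation, sg,
                                expressed_threshold = expressed_threshold)
    x_stats <- set_mean(m, keep & on_x, method)
    a_stats <- set_mean(m, keep & on_a, method)
    for (j in seq_len(ncol(m))) {
      sid <- colnames(m)[j]
      if (x_stats$n[j] == 0 || !is.finite(x_stats$mean[j]) || x_stats$mean[j] <= 0) {
        abort(paste0(
          "X-linked gene-set mean undefined or zero for sample ", sid,
          " in subgroup ", sg, "."
        ))
      }
      if (a_stats$n[j] == 0 || !is.finite(a_stats$mean[j]) || a_stats$mean[j] <= 0) {
        abort(paste0(
          "Autosomal gene-set mean undefined or zero for sample ", sid,
          " in subgroup ", sg, "."
        ))
      }
    }
    rxe <- log2(x_stats$mean) - log2(a_stats$mean)
    tibble(
      sample_id = colnames(m),
      subgroup = sg,
      n_x_genes = as.integer(x_stats$n),
      n_autosomal_genes = as.integer(a_stats$n),
      x_mean_tpm = x_stats$mean,
      autosomal_mean_tpm = a_stats$mean,
      rxe = rxe,
      compensation = classify_compensation(rxe)
    )
  })
  bind_rows(res)
}

# Per-sample mean TPM over a masked gene set.  For mean_of_log the "mean" is
# the geometric mean (2^mean(log2 tpm)) over strictly positive entries.
set_mean <- function(m, mask, method) {
  n <- colSums(mask)
  if (method == "log_of_mean") {
    mean <- ifelse(n > 0, colSums(m * mask) / n, NA_real_)
  } else {
    pos <- mask & m > 0
    npos <- colSums(pos)
    lg <- suppressWarnings(log2(m))
    lg[!pos] <- 0
    mean <- ifelse(npos > 0, 2^(colSums(lg) / npos), NA_real_)
  }
  list(mean = unname(mean), n = unname(n))
}

#' Relative expression of each autosome pair (RGE)
#'
#' For every autosome `i`, the log2 ratio of the mean TPM of its genes to the
#' mean TPM of genes on all other autosomes:
#' `RGE_i = log2(a_i) - log2(a_{n-i})`.  The X chromosome is excluded from
#' both sides.  RGE values define the normal band of chromosome-level
#' expression against which RXE is judged, and flag unusually quiet or active
#' autosomes.  Autosomes whose subgroup gene set is empty in a sample are
#' omitted with a warning.
#'
#' @inheritParams compute_rxe
#' @param subgroup A single subgroup name.
#' @return A tibble with columns `sample_id`, `subgroup`, `chromosome`,
#'   `n_genes`, `rge`.
#' @export
compute_rge <- function(expr, annotation, subgroup = "ALL",
                        expressed_threshold = 1) {
  subgroup <- arg_match(subgroup, SUBGROUP_NAMES)
  annotation <- check_annotation(annotation)
  m <- expr_to_matrix(expr)
  chrom <- annotation$chromosome[match(rownames(m), annotation$gene_id)]
  keep <- subgroup_membership(m, annotation, subgroup,
                              expressed_threshold = expressed_threshold)
  autosomes <- unique(chrom[!is.na(chrom) & is_autosome(chrom)])
  if (length(autosomes) < 2) {
    abort("RGE needs at least two autosomes in the annotation.")
  }
  autosomes <- autosomes[order(suppressWarnings(as.numeric(autosomes)), autosomes)]
  on_a <- !is.na(chrom) & is_autosome(chrom)
  a_mask <- keep & on_a
  tot_sum <- unname(colSums(m * a_mask))
  tot_n <- unname(colSums(a_mask))

  res <- purrr::map(autosomes, function(ch) {
    mask_i <- a_mask & !is.na(chrom) & chrom == ch
    n_i <- unname(colSums(mask_i))
    sum_i <- unname(colSums(m * mask_i))
    empty <- n_i == 0 | (tot_n - n_i) == 0
    if (any(empty)) {
      warn(paste0(
        "Chromosome ", ch, " omitted for sample(s) ",
        paste(colnames(m)[empty], collapse = ", "),
        ": empty subgroup gene set."
      ))
    }
    mean_i <- sum_i / n_i
    mean_rest <- (tot_sum - sum_i) / (tot_n - n_i)
    tibble(
      sample_id = colnames(m),
      subgroup = subgroup,
      chromosome = ch,
      n_genes = as.integer(n_i),
      rge = log2(mean_i) - log2(mean_rest)
    )[!empty, ]
  })
  bind_rows(res)
}

#' Classify dosage-compensation status from RXE
#'
#' `complete` for RXE >= 0 (full upregulation of the single active X),
#' `partial` for -1 < RXE < 0, `none` for RXE <= -1 (X transcribing at or
#' below half the autosomal level).  Exactly one label applies to every
#' finite RXE.
#'
#' @param rxe Numeric vector of RXE values (log2 units).
#' @return Character vector of labels in `{"complete", "partial", "none"}`.
#' @export
classify_compensation <- function(rxe) {
  if (any(!is.finite(rxe))) {
    abort("RXE must be finite to classify compensation status.")
  }
  case_when(
    rxe >= 0 ~ "complete",
    rxe > -1 ~ "partial",
    TRUE ~ "none"
  )
}

#' Tukey boxplot summary of labelled values
#'
#' Hinges are the 25th and 75th percentiles (linear interpolation between
#' order statistics, `stats::quantile(type = 7)`); whiskers extend to the
#' most extreme data value within 1.5 x IQR of the hinges; values beyond the
#' whiskers are returned individually with their labels — the construction
#' used to display chromosome-level RGE with deviant autosomes called out.
#'
#' @param data A data frame of values to summarise.
#' @param value Column holding the numeric values (tidy-eval).
#' @param label Optional column holding labels for outlier reporting; row
#'   numbers are used when absent.
#' @return A one-row tibble: `n`, `lower_hinge`, `upper_hinge`, `iqr`,
#'   `lower_whisker`, `upper_whisker`, and an `outliers` list-column holding
#'   a tibble of `(label, value)` pairs.
#' @examples
#' summarize_group(tibble::tibble(v = 1:9), v)
#' @export
summarize_group <- function(data, value, label = NULL) {
  vals <- dplyr::pull(data, {{ value }})
  lab_quo <- enquo(label)
  labs <- if (quo_is_null(lab_quo)) {
    as.character(seq_along(vals))
  } else {
    as.character(dplyr::pull(data, !!lab_quo))
  }
  if (length(vals) < 2) {
    abort("A boxplot summary needs at least 2 values.")
  }
  hinges <- unname(quantile(vals, c(0.25, 0.75), type = 7))
  iqr <- hinges[2] - hinges[1]
  in_fence <- vals >= hinges[1] - 1.5 * iqr & vals <= hinges[2] + 1.5 * iqr
  lower_whisker <- min(vals[in_fence])
  upper_whisker <- max(vals[in_fence])
  out <- !in_fence
  tibble(
    n = length(vals),
    lower_hinge = hinges[1],
    upper_hinge = hinges[2],
    iqr = iqr,
    lower_whisker = lower_whisker,
    upper_whisker = upper_whisker,
    outliers = list(tibble(label = labs[out], value = vals[out]))
  )
}

#' Group means of per-sample RXE
#'
#' Arithmetic mean of per-sample RXE within each tissue (or treatment, or any
#' other metadata grouping) — the red-dot summaries overlaid on
#' chromosome-level boxplots.  Samples are computed individually first and
#' averaged second.
#'
#' @param rxe_tbl Result of [compute_rxe()].
#' @param samples Sample-metadata tibble with a `sample_id` column.
#' @param group Metadata column to group by (string), default `"tissue"`.
#' @return A tibble with the group column, `n_samples` and `mean_rxe`, one
#'   row per group and subgroup.
#' @export
tissue_mean_rxe <- function(rxe_tbl, samples, group = "tissue") {
  if (!group %in% names(samples)) {
    abort(paste0("Grouping column ", group, " not found in sample metadata."))
  }
  joined <- inner_join(rxe_tbl, samples, by = "sample_id")
  dropped <- anti_join(rxe_tbl, samples, by = "sample_id")
  if (nrow(dropped) > 0) {
    warn(paste0(
      "Sample(s) without metadata omitted from group means: ",
      paste(unique(dropped$sample_id), collapse = ", "), "."
    ))
  }
  joined %>%
    group_by(across(all_of(c(group, "subgroup")))) %>%
    summarise(n_samples = n(), mean_rxe = mean(.data$rxe), .groups = "drop")
}

#' Correlation between chromosome activity and expressed-gene count
#'
#' Pearson correlation, across autosomes, between mean RGE (chromosome-level
#' expression activity) and the number of expressed genes on the chromosome.
#' A strong negative correlation indicates that gene-poor chromosomes carry
#' proportionally more highly expressed genes.
#'
#' @param rge_tbl Tibble with columns `chromosome` and `rge` (per-sample
#'   values are averaged per chromosome first) or `mean_rge`.
#' @param counts_tbl Tibble with columns `chromosome` and `n_expressed`.
#' @return The Pearson correlation coefficient (length-1 numeric).
#' @export
activity_gene_count_correlation <- function(rge_tbl, counts_tbl) {
  if (!all(c("chromosome") %in% names(rge_tbl)) ||
      !all(c("chromosome", "n_expressed") %in% names(counts_tbl))) {
    abort("Need `chromosome` + rge columns and `chromosome` + `n_expressed` columns.")
  }
  if (!"mean_rge" %in% names(rge_tbl)) {
    rge_tbl <- rge_tbl %>%
      group_by(.data$chromosome) %>%
      summarise(mean_rge = mean(.data$rge), .groups = "drop")
  }
  joined <- inner_join(rge_tbl, counts_tbl, by = "chromosome")
  if (nrow(joined) < 3) {
    abort("Correlation needs at least 3 chromosomes present in both tables.")
  }
  if (sd(joined$mean_rge) == 0 || sd(joined$n_expressed) == 0) {
    abort("Correlation undefined: zero variance in RGE or gene counts.")
  }
  cor(joined$mean_rge, joined$n_expressed, method = "pearson")
}
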