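#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-separated expression table whose first column is `gene_id` and
#' whose remaining columns are one sample each (values in TPM).  When
#' `meta_path` is given the sample columns are validated against the metadata
#' table: every sample column must have a metadata row.  Negative or
#' non-numeric cells are rejected with their coordinates.
#'
#' @param path Path to the expression TSV.
#' @param meta_path Optional path to a sample-metadata TSV (see
#'   [read_sample_metadata()]).
#' @return A tibble: `gene_id` plus one numeric column per sample.
#' @export
read_expression_matrix <- function(path, meta_path = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Expression file not found: ", path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  if (!"gene_id" %in% names(tab)) {
    abort(paste0("Expression matrix ", path, " must have a gene_id first column."))
  }
  sample_ids <- setdiff(names(tab), "gene_id")
  if (length(sample_ids) == 0) {
    abort(paste0("Expression matrix ", path, " has no sample columns."))
  }
  for (s in sample_ids) {
    num <- suppressWarnings(as.numeric(tab[[s]]))
    bad <- which(is.na(num) & !is.na(tab[[s]]) | is.na(tab[[s]]))
    if (length(bad) > 0) {
      abort(paste0(
        "Non-numeric expression value at gene ", tab$gene_id[bad[1]],
        ", sample ", s, "."
      ))
    }
    neg <- which(num < 0)
    if (length(neg) > 0) {
      abort(paste0(
        "Negative expression value (", num[neg[1]], ") at gene ",
        tab$gene_id[neg[1]], ", sample ", s, "."
      ))
    }
    tab[[s]] <- num
  }
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup) > 0) {
    abort(paste0(
      "Duplicate gene_id in expression matrix: ",
      paste(unique(dup), collapse = ", "), "."
    ))
  }
  if (!is.null(meta_path)) {
    samples <- read_sample_metadata(meta_path)
    orphan <- setdiff(sample_ids, samples$sample_id)
    if (length(orphan) > 0) {
      abort(paste0(
        "Sample(s) in expression matrix missing from metadata: ",
        paste(orphan, collapse = ", "), "."
      ))
    }
  }
  as_tibble(tab)
}

#' Read per-sample metadata
#'
#' Reads a TSV keyed by `sample_id` with the design columns used downstream:
#' `tissue`, `sex` (female/male/unknown), `treatment` and `dataset`.
#' Missing design columns are filled with `"unknown"` so partially annotated
#' studies still load.
#'
#' @param path Path to the metadata TSV.
#' @return A tibble with columns `sample_id`, `tissue`, `sex`, `treatment`,
#'   `dataset`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Sample metadata file not found: ", path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (!"sample_id" %in% names(tab)) {
    abort(paste0("Sample metadata ", path, " must have a sample_id column."))
  }
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup) > 0) {
    abort(paste0(
      "Duplicate sample_id in metadata: ",
      paste(unique(dup), collapse = ", "), "."
    ))
  }
  for (col in c("tissue", "sex", "treatment", "dataset")) {
    if (!col %in% names(tab)) tab[[col]] <- "unknown"
  }
  bad_sex <- !tab$sex %in% c("female", "male", "unknown")
  if (any(bad_sex)) {
    abort(paste0(
      "sex must be one of female/male/unknown; offending sample(s): ",
      paste(tab$sample_id[bad_sex], collapse = ", "), "."
    ))
  }
  select(as_tibble(tab), all_of(c("sample_id", "tissue", "sex", "treatment", "dataset")))
}

#' Write an expression matrix TSV
#'
#' @param expr Expression tibble (`gene_id` plus sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

# Internal: expression tibble -> numeric matrix with gene_id rownames.
expr_to_matrix <- function(expr) {
  if (!is.data.frame(expr) || !"gene_id" %in% names(expr)) {
    abort("`expr` must be a data frame with a gene_id column.")
  }
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
  if (!is.numeric(m)) abort("Expression values must be numeric.")
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("Expression values must be finite and nonnegative.")
  }
  rownames(m) <- expr$gene_id
  m
}

#' Compute TPM from raw counts
#'
#' Transcripts per kilobase million: each gene's count is first divided by its
#' length in kilobases (reads per kilobase), then each sample's rates are
#' scaled to sum to one million.  Length normalization before depth
#' normalization makes the resulting columns comparable across samples with
#' different transcriptome compositions, which is why TPM is preferred over
#' RPKM/FPKM for cross-sample ratios.
#'
#' @param counts Tibble of nonnegative counts, `gene_id` plus one column per
#'   sample.
#' @param annotation Annotation tibble supplying `length_bp` for every
#'   counted gene.
#' @return A tibble of the same shape with TPM values; every sample column
#'   sums to 1e6 (within 1e-6 relative tolerance).
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10, 10))
#' ann <- tibble::tibble(
#'   gene_id = c("g1", "g2"), chromosome = c("1", "2"),
#'   length_bp = c(1000L, 2000L), is_par = FALSE
#' )
#' compute_tpm(counts, ann)
#' @export
compute_tpm <- function(counts, annotation) {
  annotation <- check_annotation(annotation)
  m <- expr_to_matrix(counts)
  missing_len <- setdiff(rownames(m), annotation$gene_id)
  if (length(missing_len) > 0) {
    abort(paste0(
      "Gene(s) in counts without a length in the annotation: ",
      paste(head(missing_len, 5), collapse = ", "), "."
    ))
  }
  len_kb <- annotation$length_bp[match(rownames(m), annotation$gene_id)] / 1000
  rates <- m / len_kb
  totals <- colSums(rates)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0) {
    abort(paste0(
      "TPM undefined for all-zero sample(s): ",
      paste(zero, collapse = ", "), "."
    ))
  }
  tpm <- sweep(rates, 2, totals, "/") * 1e6
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(tpm))
}
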