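#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix (case-insensitive) and upper-cases the sex
#' chromosome and mitochondrial labels, so Ensembl-style (`"1"`, `"X"`) and
#' UCSC-style (`"chr1"`, `"chrx"`) inputs map onto one naming scheme.  The
#' operation is idempotent.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_chromosomes(c("chr1", "chrX", "x", "26", "chrMT"))
#' @export
normalize_chromosomes <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  ifelse(toupper(x) %in% c("X", "Y", "MT", "M"),
    sub("^M$", "MT", toupper(x)),
    x
  )
}

# Shared validation for annotation tibbles (gene_id, chromosome, length_bp,
# is_par).  All readers and the synthetic generator funnel through this.
check_annotation <- function(annotation, require_x = FALSE) {
  if (!is.data.frame(annotation)) {
    abort("`annotation` must be a data frame.")
  }
  needed <- c("gene_id", "chromosome", "length_bp")
  missing_cols <- setdiff(needed, names(annotation))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Annotation is missing column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  if (!"is_par" %in% names(annotation)) {
    annotation$is_par <- FALSE
  }
  annotation <- as_tibble(annotation)
  if (any(is.na(annotation$gene_id) | annotation$gene_id == "")) {
    abort("Annotation gene_id values must be nonempty.")
  }
  dup <- annotation$gene_id[duplicated(annotation$gene_id)]
  if (length(dup) > 0) {
    abort(paste0(
      "Duplicate gene_id in annotation: ",
      paste(unique(dup), collapse = ", "), "."
    ))
  }
  if (any(is.na(annotation$length_bp)) || any(annotation$length_bp < 1)) {
    abort("Annotation length_bp values must be >= 1.")
  }
  annotation$length_bp <- as.integer(round(annotation$length_bp))
  annotation$chromosome <- normalize_chromosomes(annotation$chromosome)
  annotation$is_par <- as.logical(annotation$is_par)
  bad_par <- annotation$is_par & annotation$chromosome != "X"
  if (any(bad_par)) {
    abort(paste0(
      "is_par = TRUE is only valid for X-linked genes; offending gene(s): ",
      paste(annotation$gene_id[bad_par], collapse = ", "), "."
    ))
  }
  if (require_x) {
    chroms <- unique(annotation$chromosome)
    if (!"X" %in% chroms || !any(!chroms %in% NON_AUTOSOMES)) {
      abort("Annotation must contain at least one X-linked and one autosomal gene.")
    }
  }
  annotation
}

# Autosomes are everything that is not X, Y or mitochondrial.
is_autosome <- function(chromosome) !(chromosome %in% NON_AUTOSOMES)

#' Read a gene map (gene to chromosome, length and PAR flag)
#'
#' Reads the gene annotation that defines the X/autosome partition used by
#' every downstream statistic.  Two formats are supported: a tab-separated
#' table with columns `gene_id`, `chromosome`, `length_bp` and optionally
#' `is_par` (0/1), or an Ensembl-dialect GTF from which `gene`-type features
#' are taken (gene length is `end - start + 1` on the 1-based inclusive
#' coordinates unless the record carries an explicit `length` attribute).
#'
#' Chromosome labels are normalized with [normalize_chromosomes()]; duplicate
#' gene identifiers are rejected.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by file extension), `"tsv"`, or `"gtf"`.
#' @return A tibble with columns `gene_id`, `chromosome`, `length_bp`,
#'   `is_par`.
#' @seealso [read_par_list()] to flag pseudoautosomal genes afterwards.
#' @export
read_gene_map <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- arg_match(format)
  if (!file.exists(path)) {
    abort(paste0("Gene map file not found: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  if (format == "gtf") {
    return(read_gene_map_gtf(path))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                         progress = FALSE, show_col_types = FALSE)
  needed <- c("gene_id", "chromosome", "length_bp")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Gene map ", path, " is missing column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  tab$gene_id <- as.character(tab$gene_id)
  if (!"is_par" %in% names(tab)) tab$is_par <- FALSE
  tab$is_par <- as.logical(as.integer(tab$is_par))
  check_annotation(tab[, c("gene_id", "chromosome", "length_bp", "is_par")])
}

read_gene_map_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading GTF requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0) {
    abort(paste0("No gene-type features found in GTF: ", path))
  }
  meta <- as.data.frame(gr)
  if (!"gene_id" %in% names(meta)) {
    abort(paste0("GTF gene features lack a gene_id attribute: ", path))
  }
  len <- if ("length" %in% names(meta)) {
    suppressWarnings(as.integer(meta$length))
  } else {
    rep(NA_integer_, nrow(meta))
  }
  len <- ifelse(is.na(len), meta$end - meta$start + 1L, len)
  check_annotation(tibble(
    gene_id = as.character(meta$gene_id),
    chromosome = as.character(meta$seqnames),
    length_bp = len,
    is_par = FALSE
  ))
}

#' Write a gene map TSV
#'
#' Inverse of [read_gene_map()] on the TSV dialect (columns `gene_id`,
#' `chromosome`, `length_bp`, `is_par` as 0/1); reading the written file back
#' reproduces the records.
#'
#' @param annotation Annotation tibble (see [read_gene_map()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(annotation, path) {
  annotation <- check_annotation(annotation)
  out <- mutate(annotation, is_par = as.integer(.data$is_par))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Flag pseudoautosomal (PAR) genes from a gene list
#'
#' Reads a plain-text list of gene identifiers (one per line, `#` comments
#' allowed) and sets `is_par = TRUE` for those genes in the annotation.  PAR
#' genes sit in the region shared by X and Y, escape X inactivation, and are
#' removed from the "genes subject to XCI" subgroup.  Listed genes absent
#' from the annotation produce a warning (annotations routinely lag the PAR
#' catalogue); a listed gene present but not X-linked is an error.
#'
#' @param annotation Annotation tibble (see [read_gene_map()]).
#' @param path Path to the PAR gene list.
#' @return The annotation with `is_par` updated.
#' @export
read_par_list <- function(annotation, path) {
  annotation <- check_annotation(annotation)
  if (!file.exists(path)) {
    abort(paste0("PAR list file not found: ", path))
  }
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(sub("#.*$", "", ids))
  ids <- unique(ids[ids != ""])
  absent <- setdiff(ids, annotation$gene_id)
  if (length(absent) > 0) {
    warn(paste0(
      length(absent), " PAR gene(s) not present in the annotation: ",
      paste(absent, collapse = ", "), "."
    ))
  }
  hit <- annotation$gene_id %in% ids
  off_x <- hit & annotation$chromosome != "X"
  if (any(off_x)) {
    abort(paste0(
      "PAR gene(s) not located on the X chromosome: ",
      paste(annotation$gene_id[off_x], collapse = ", "), "."
    ))
  }
  mutate(annotation, is_par = .data$is_par | hit)
}
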