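# In-code fixtures shared across the suite.

# Small annotation: n_per autosomal genes on each of `autosomes`, n_x X-linked
# genes of which the first n_par are PAR.
tiny_annotation <- function(autosomes = c("1", "2"), n_per = 3, n_x = 2,
                            n_par = 0, length_bp = 1000L) {
  a <- tibble::tibble(
    gene_id = paste0("a", seq_len(n_per * length(autosomes))),
    chromosome = rep(autosomes, each = n_per),
    length_bp = length_bp,
    is_par = FALSE
  )
  x <- tibble::tibble(
    gene_id = paste0("x", seq_len(n_x)),
    chromosome = "X",
    length_bp = length_bp,
    is_par = seq_len(n_x) <= n_par
  )
  dplyr::bind_rows(a, x)
}

# Expression tibble from a named list of per-sample value vectors aligned to
# annotation gene order.
make_expr <- function(annotation, ...) {
  cols <- list(...)
  tibble::as_tibble(c(list(gene_id = annotation$gene_id), cols))
}

# Expression where every gene of chromosome X has TPM x_tpm and every
# autosomal gene a_tpm, single sample s1.
flat_expr <- function(annotation, x_tpm, a_tpm) {
  v <- ifelse(annotation$chromosome == "X", x_tpm, a_tpm)
  make_expr(annotation, s1 = v)
}

# Write a tiny gene-map TSV; returns the path.
write_tmp_gene_map <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "gene_map.tsv")
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

# A down-scaled synthetic config for fast simulation-based tests.
small_synth_config <- function(..., seed = 1) {
  synthetic_config(
    genes_per_chromosome = c("1" = 400, "2" = 350, "3" = 300, X = 150),
    n_par = 5,
    design = tibble::tibble(
      tissue = "brain",
      treatment = c("Con", "Con", "Over", "Over", "Res", "Res"),
      sex = rep(c("female", "male"), 3),
      n_samples = c(4L, 3L, 2L, 2L, 2L, 2L)
    ),
    planted_degs = tibble::tibble(
      gene_id = NA_character_,
      treatment = rep(c("Over", "Res"), 3),
      log2_effect = c(3.2, -3.5, 3.8, -4.1, 4.4, -4.7)
    ),
    seed = seed,
    ...
  )
}

# Per-sample RXE table + metadata fixture keyed by one grouping column.
rxe_with_meta <- function(values_by_group, meta_col, tissue = "brain") {
  ids <- paste0("s", seq_len(sum(lengths(values_by_group))))
  samples <- tibble::tibble(
    sample_id = ids,
    tissue = tissue,
    sex = "unknown", treatment = "unknown", dataset = "d"
  )
  samples[[meta_col]] <- rep(names(values_by_group), lengths(values_by_group))
  rxe_tbl <- tibble::tibble(
    sample_id = ids, subgroup = "EXPRESSED",
    rxe = unlist(values_by_group, use.names = FALSE)
  )
  list(rxe = rxe_tbl, samples = samples)
}
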