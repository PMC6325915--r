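test_that("default generated annotation matches the sheep-like gene universe", {
  cfg <- synthetic_config(seed = 4)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 20519)
  expect_equal(sum(ann$chromosome == "X"), 1228)
  expect_equal(sum(ann$is_par), 20)
  expect_equal(length(unique(ann$chromosome)), 27)
  expect_true(all(ann$length_bp >= 1))
})

test_that("generator is deterministic under a fixed seed and sensitive to it", {
  cfg <- small_synth_config(seed = 7)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  e1 <- generate_expression(a1, cfg)
  e2 <- generate_expression(a2, cfg)
  expect_identical(e1, e2)
  expect_identical(truth_table(cfg), truth_table(cfg))

  cfg2 <- small_synth_config(seed = 8)
  expect_false(identical(generate_annotation(cfg2), a1))
})

test_that("custom chromosome layouts produce the requested record counts", {
  cfg <- synthetic_config(
    genes_per_chromosome = c("1" = 10, "2" = 10, X = 5),
    n_par = 0, seed = 3
  )
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 25)
  expect_equal(sum(ann$chromosome == "X"), 5)
})

test_that("noise-free generation hits the analytic RXE exactly", {
  # u = 1, single active X at the autosomal per-copy rate -> RXE = -1
  base <- list(
    genes_per_chromosome = c("1" = 60, "2" = 60, X = 40),
    n_par = 0, baseline_log2_sd = 0, sample_noise_log2_sd = 0,
    silent_fraction = 0, planted_degs = tibble::tibble(
      gene_id = character(), treatment = character(), log2_effect = numeric()
    ),
    design = tibble::tibble(tissue = "brain", treatment = "Con",
                            sex = "female", n_samples = 3L),
    seed = 11
  )
  cfg1 <- do.call(synthetic_config, c(base, upregulation_factor_u = 1))
  ann1 <- generate_annotation(cfg1)
  rxe1 <- compute_rxe(generate_expression(ann1, cfg1), ann1)
  expect_equal(rxe1$rxe, rep(-1, 3))
  expect_equal(rxe1$compensation, rep("none", 3))

  # u = 2, doubled transcription from the single active X -> RXE = 0
  cfg2 <- do.call(synthetic_config, c(base, upregulation_factor_u = 2))
  ann2 <- generate_annotation(cfg2)
  rxe2 <- compute_rxe(generate_expression(ann2, cfg2), ann2)
  expect_equal(rxe2$rxe, rep(0, 3))
  expect_equal(rxe2$compensation, rep("complete", 3))
})

test_that("estimated RXE recovers log2(u) - 1 on average (parameter recovery)", {
  truth_rxe <- log2(1.8) - 1
  vals <- sapply(1:25, function(s) {
    cfg <- synthetic_config(
      genes_per_chromosome = c("1" = 700, "2" = 700, "3" = 600, X = 200),
      n_par = 0, upregulation_factor_u = 1.8, silent_fraction = 0,
      sample_noise_log2_sd = 0.25,
      planted_degs = tibble::tibble(gene_id = character(),
                                    treatment = character(),
                                    log2_effect = numeric()),
      design = tibble::tibble(tissue = "brain", treatment = "Con",
                              sex = "female", n_samples = 8L),
      seed = 1000 + s
    )
    ann <- generate_annotation(cfg)
    mean(compute_rxe(generate_expression(ann, cfg), ann)$rxe)
  })
  expect_lt(abs(mean(vals) - truth_rxe), 0.05)
})

test_that("truth table is consistent bookkeeping for planted effects and silencing", {
  cfg <- small_synth_config(seed = 6)
  truth <- truth_table(cfg)
  ann <- generate_annotation(cfg)
  expect_equal(truth$gene_id, ann$gene_id)
  expect_equal(sum(truth$is_planted_deg), 6)
  planted <- truth[truth$is_planted_deg, ]
  expect_true(all(planted$chromosome == "X"))
  expect_true(all(!planted$is_par))
  expect_true(all(!planted$is_silent))
  expect_setequal(planted$planted_treatment, c("Over", "Res"))
  expect_equal(sort(planted$log2_effect),
               sort(cfg$planted_degs$log2_effect))
  expect_equal(sum(truth$is_silent), round(0.3 * nrow(truth)))

  no_silent <- truth_table(small_synth_config(silent_fraction = 0, seed = 6))
  expect_equal(sum(no_silent$is_silent), 0)

  explicit <- small_synth_config(seed = 6)
  explicit$planted_degs <- tibble::tibble(
    gene_id = ann$gene_id[ann$chromosome == "X"][1],
    treatment = "Over", log2_effect = 3.0
  )
  t2 <- truth_table(explicit)
  expect_equal(t2$log2_effect[t2$is_planted_deg], 3.0)
})

test_that("PAR genes carry two copies, so their removal raises measured RXE", {
  cfg <- synthetic_config(
    genes_per_chromosome = c("1" = 500, "2" = 500, X = 150),
    n_par = 30, upregulation_factor_u = 1.2, silent_fraction = 0,
    sample_noise_log2_sd = 0,
    planted_degs = tibble::tibble(gene_id = character(),
                                  treatment = character(),
                                  log2_effect = numeric()),
    design = tibble::tibble(tissue = "brain", treatment = "Con",
                            sex = "female", n_samples = 2L),
    seed = 14
  )
  ann <- generate_annotation(cfg)
  expr <- generate_expression(ann, cfg)
  truth <- truth_table(cfg)
  expect_equal(unique(truth$copies[truth$is_par]), 2)
  expect_equal(unique(truth$copies[truth$chromosome == "X" & !truth$is_par]), 1.2)
  # with u < 2, PAR genes (2 copies) outexpress XCI-subject genes on average
  with_par <- compute_rxe(expr, ann, "EXPRESSED")
  without <- compute_rxe(expr, ann, "XCI_SUBJECT")
  expect_true(all(without$rxe < with_par$rxe))
})

test_that("TPM renormalization preserves RXE (ratio invariance)", {
  cfg <- small_synth_config(seed = 9)
  ann <- generate_annotation(cfg)
  expr <- generate_expression(ann, cfg)
  m <- as.matrix(expr[, -1])
  # columns are already TPM; arbitrary per-sample rescaling then
  # renormalization must not move RXE
  rescaled <- sweep(m, 2, seq_len(ncol(m)) * 0.37, "*")
  renorm <- sweep(rescaled, 2, colSums(rescaled), "/") * 1e6
  expr2 <- dplyr::bind_cols(tibble::tibble(gene_id = expr$gene_id),
                            tibble::as_tibble(renorm))
  expect_equal(compute_rxe(expr2, ann)$rxe, compute_rxe(expr, ann)$rxe,
               tolerance = 1e-12)
  expect_equal(colSums(as.matrix(expr[, -1])), colSums(renorm),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("planted differential effects are recovered by the bootstrap test", {
  cfg <- small_synth_config(seed = 15)
  ann <- generate_annotation(cfg)
  expr <- generate_expression(ann, cfg)
  samples <- generate_design(cfg)
  truth <- truth_table(cfg)
  planted_over <- truth$gene_id[truth$is_planted_deg &
                                  truth$planted_treatment == "Over"]
  de <- bootstrap_de(expr, samples, reference = "Con", alternative = "Over",
                     config = bootstrap_config(seed = 16))
  called <- de$results$gene_id[de$results$significant]
  expect_true(all(planted_over %in% called))
})

test_that("a written synthetic dataset round-trips through the readers", {
  cfg <- small_synth_config(seed = 10)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(cfg, dir)
  expect_true(all(file.exists(paths)))
  ann <- read_gene_map(paths[["gene_map"]])
  expect_equal(ann, generate_annotation(cfg))
  expr <- read_expression_matrix(paths[["expression"]], paths[["samples"]])
  direct <- generate_expression(ann, cfg)
  expect_equal(expr$gene_id, direct$gene_id)
  expect_equal(as.matrix(expr[, -1]), as.matrix(direct[, -1]),
               tolerance = 1e-12)
  samples <- read_sample_metadata(paths[["samples"]])
  expect_equal(samples, generate_design(cfg))
  # PAR list re-flags the same genes
  ann_noflag <- dplyr::mutate(ann, is_par = FALSE)
  reflagged <- read_par_list(ann_noflag, paths[["par_list"]])
  expect_equal(reflagged$is_par, ann$is_par)
})
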