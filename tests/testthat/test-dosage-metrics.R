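test_that("subgroup selection applies inclusive thresholds, PAR removal and universality", {
  ann <- tiny_annotation(autosomes = "1", n_per = 2, n_x = 2, n_par = 1)
  # x1 is PAR; columns: s1 queries per-sample membership, s2 breaks
  # universality for a1
  expr <- make_expr(ann,
    s1 = c(1.0, 0.99, 50, 2),
    s2 = c(0.5, 3, 7, 2)
  )
  expect_setequal(
    select_subgroup(expr, ann, "ALL", "s1"),
    c("a1", "a2", "x1", "x2")
  )
  # TPM exactly 1 is expressed; 0.99 is not
  expect_setequal(select_subgroup(expr, ann, "EXPRESSED", "s1"),
                  c("a1", "x1", "x2"))
  # PAR gene x1 excluded despite TPM 50
  expect_setequal(select_subgroup(expr, ann, "XCI_SUBJECT", "s1"),
                  c("a1", "x2"))
  # a1 expressed in s1 only -> not dosage sensitive
  expect_setequal(select_subgroup(expr, ann, "DOSAGE_SENSITIVE", "s1"),
                  c("x1", "x2"))
  expect_error(
    select_subgroup(make_expr(ann, s1 = c(0, 0, 0, 0)), ann, "EXPRESSED", "s1"),
    "empty"
  )
})

test_that("RXE matches the log2 ratio of gene-set means", {
  ann <- tiny_annotation(autosomes = c("1", "2"), n_per = 5, n_x = 4)
  expect_equal(compute_rxe(flat_expr(ann, 100, 100), ann)$rxe, 0)
  expect_equal(compute_rxe(flat_expr(ann, 50, 100), ann)$rxe, -1)
  r <- compute_rxe(flat_expr(ann, 60, 100), ann)
  expect_equal(r$rxe, log2(0.6))
  expect_equal(r$n_x_genes, 4L)
  expect_equal(r$n_autosomal_genes, 10L)
  expect_error(compute_rxe(flat_expr(ann, 0, 100), ann), "X-linked.*s1")
  expect_error(compute_rxe(flat_expr(ann, 10, 0), ann), "Autosomal.*s1")
})

test_that("RXE is invariant under uniform rescaling of a sample (property)", {
  withr::local_seed(11)
  ann <- tiny_annotation(autosomes = c("1", "2", "3"), n_per = 8, n_x = 6)
  for (rep in 1:10) {
    v <- rlnorm(nrow(ann), 2, 1)
    scale <- runif(1, 0.01, 50)
    r1 <- compute_rxe(make_expr(ann, s1 = v), ann)$rxe
    r2 <- compute_rxe(make_expr(ann, s1 = v * scale), ann)$rxe
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("removing PAR genes changes RXE only through the X-side mean", {
  ann <- tiny_annotation(autosomes = "1", n_per = 6, n_x = 6, n_par = 2)
  withr::local_seed(3)
  expr <- make_expr(ann, s1 = rlnorm(nrow(ann), 3, 0.5) + 1)
  with_par <- compute_rxe(expr, ann, "EXPRESSED")
  no_par <- compute_rxe(expr, ann, "XCI_SUBJECT")
  expect_equal(with_par$autosomal_mean_tpm, no_par$autosomal_mean_tpm)
  expect_equal(no_par$n_x_genes, with_par$n_x_genes - 2L)
  expect_equal(
    no_par$rxe - with_par$rxe,
    log2(no_par$x_mean_tpm) - log2(with_par$x_mean_tpm)
  )
})

test_that("RGE matches a brute-force two-set mean computation", {
  ann <- tiny_annotation(autosomes = c("1", "2", "3", "4"), n_per = 6, n_x = 3)
  withr::local_seed(5)
  expr <- make_expr(ann, s1 = rlnorm(nrow(ann), 2, 1),
                    s2 = rlnorm(nrow(ann), 2, 1))
  rge <- compute_rge(expr, ann, "ALL")
  for (s in c("s1", "s2")) {
    v <- expr[[s]]
    for (ch in c("1", "2", "3", "4")) {
      on_i <- ann$chromosome == ch
      on_rest <- !(ann$chromosome %in% c(ch, "X"))
      expected <- log2(mean(v[on_i])) - log2(mean(v[on_rest]))
      got <- rge$rge[rge$sample_id == s & rge$chromosome == ch]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
  # the X chromosome appears on neither side
  expect_false("X" %in% rge$chromosome)
})

test_that("RGE symmetry and two-chromosome cases", {
  ann <- tiny_annotation(autosomes = c("1", "2", "3"), n_per = 4, n_x = 2)
  rge <- compute_rge(flat_expr(ann, 7, 100), ann)
  expect_equal(rge$rge, rep(0, 3))

  ann5 <- tiny_annotation(autosomes = c("1", "5"), n_per = 4, n_x = 2)
  v <- ifelse(ann5$chromosome == "5", 200,
              ifelse(ann5$chromosome == "1", 100, 1))
  rge5 <- compute_rge(make_expr(ann5, s1 = v), ann5)
  expect_equal(rge5$rge[rge5$chromosome == "5"], 1)
  expect_equal(rge5$rge[rge5$chromosome == "1"], -1)
})

test_that("compensation classification partitions the RXE line", {
  expect_equal(classify_compensation(0.16), "complete")
  expect_equal(classify_compensation(-0.12), "partial")
  expect_equal(classify_compensation(-1), "none")
  expect_equal(classify_compensation(0), "complete")
  # every finite value receives exactly one label
  grid <- c(seq(-3, 2, by = 0.01), -1, 0, -1 + 1e-12, -1e-12)
  labels <- classify_compensation(grid)
  expect_true(all(labels %in% c("complete", "partial", "none")))
  expect_equal(labels[grid >= 0], rep("complete", sum(grid >= 0)))
  expect_equal(labels[grid <= -1], rep("none", sum(grid <= -1)))
  expect_error(classify_compensation(c(0, Inf)), "finite")
})

test_that("boxplot summaries use linear-interpolation hinges and 1.5 IQR whiskers", {
  s <- summarize_group(tibble::tibble(v = 1:9), v)
  expect_equal(s$lower_hinge, 3)
  expect_equal(s$upper_hinge, 7)
  expect_equal(s$iqr, 4)
  expect_equal(nrow(s$outliers[[1]]), 0)
  expect_equal(s$lower_whisker, 1)
  expect_equal(s$upper_whisker, 9)

  d <- tibble::tibble(v = c(0, 0, 0, 0, 10), chr = as.character(1:5))
  s2 <- summarize_group(d, v, chr)
  expect_equal(s2$iqr, 0)
  expect_equal(s2$upper_whisker, 0)
  expect_equal(s2$outliers[[1]]$label, "5")
  expect_equal(s2$outliers[[1]]$value, 10)

  s3 <- summarize_group(tibble::tibble(v = rep(4, 6)), v)
  expect_equal(s3$lower_hinge, s3$upper_hinge)
  expect_equal(nrow(s3$outliers[[1]]), 0)

  expect_error(summarize_group(tibble::tibble(v = 1), v), "at least 2")
})

test_that("group mean RXE is a per-group arithmetic mean, order-invariant", {
  rxe_tbl <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"), subgroup = "ALL",
    rxe = c(-0.2, 0.0, 0.4)
  )
  samples <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    tissue = c("brain", "brain", "kidney")
  )
  m <- tissue_mean_rxe(rxe_tbl, samples)
  expect_equal(m$mean_rxe[m$tissue == "brain"], -0.1)
  expect_equal(m$mean_rxe[m$tissue == "kidney"], 0.4)
  shuffled <- tissue_mean_rxe(rxe_tbl[c(3, 1, 2), ], samples)
  expect_equal(dplyr::arrange(m, tissue), dplyr::arrange(shuffled, tissue))
})

test_that("activity/gene-count correlation matches the covariance formula", {
  rge_tbl <- tibble::tibble(chromosome = c("1", "2", "3"),
                            rge = c(0.3, 0.0, -0.3))
  counts <- tibble::tibble(chromosome = c("1", "2", "3"),
                           n_expressed = c(100L, 200L, 300L))
  expect_equal(activity_gene_count_correlation(rge_tbl, counts), -1)

  affine <- tibble::tibble(chromosome = c("1", "2", "3"),
                           rge = 0.01 * c(100, 200, 300) + 2)
  expect_equal(activity_gene_count_correlation(affine, counts), 1)

  withr::local_seed(13)
  r <- tibble::tibble(chromosome = as.character(1:8), rge = rnorm(8))
  k <- tibble::tibble(chromosome = as.character(1:8),
                      n_expressed = rpois(8, 100))
  # textbook formula oracle
  x <- r$rge; y <- k$n_expressed
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(activity_gene_count_correlation(r, k), oracle,
               tolerance = 1e-12)

  flat <- tibble::tibble(chromosome = as.character(1:3), rge = rep(1, 3))
  expect_error(activity_gene_count_correlation(flat, counts), "variance")
})

test_that("mean-of-log RXE variant uses the geometric mean of positive TPM", {
  ann <- tiny_annotation(autosomes = "1", n_per = 3, n_x = 2)
  expr <- make_expr(ann, s1 = c(4, 16, 64, 8, 32))
  r <- compute_rxe(expr, ann, method = "mean_of_log")
  expect_equal(r$rxe, mean(log2(c(8, 32))) - mean(log2(c(4, 16, 64))))
})
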