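mk_pm <- function(values, widths = NULL, kind = "count", lib = NULL) {
  n <- nrow(values)
  if (is.null(widths)) widths <- rep(1000, n)
  peaks <- genomic_intervals(rep("chr1", n),
                             seq(0, by = 5000, length.out = n),
                             seq(0, by = 5000, length.out = n) + widths,
                             name = paste0("p", seq_len(n)))
  peak_matrix(peaks, values, kind, library_sizes = lib)
}

test_that("rpkm applies the reads-per-kb-per-million formula", {
  pm <- mk_pm(matrix(c(10, 0), 2, 1), widths = c(1000, 800),
              lib = 1e6)
  r <- rpkm(pm)
  expect_equal(r$values[1, 1], 10)
  expect_equal(r$values[2, 1], 0)
  # doubling the library halves RPKM
  r2 <- rpkm(pm, library_sizes = 2e6)
  expect_equal(r2$values, r$values / 2)
  expect_error(rpkm(mk_pm(matrix(1), widths = 0), ), "0 <= start")
})

test_that("the presence and CV filters keep exactly the stated rows", {
  v <- rbind(c(6, 6, 1, 1),    # passes presence (two stages > 5), CV high
             c(8, 8, 8, 8),    # constant: CV 0 -> removed
             c(4, 4, 4, 9),    # only one stage > 5 -> removed
             c(30, 10, 20, 25))
  pm <- mk_pm(v, kind = "RPKM")
  f <- filter_peaks(pm)
  expect_equal(f$kept, c(TRUE, FALSE, FALSE, TRUE))
  # presence-only filter keeps the constant row
  expect_equal(filter_peaks(pm, variability = FALSE)$kept,
               c(TRUE, TRUE, FALSE, TRUE))
  # CV boundary: a row exactly at the cutoff is kept (>= rule)
  row_b <- c(9, 9, 10, 12)
  pmb <- mk_pm(rbind(row_b), kind = "RPKM")
  cv <- sqrt(mean((row_b - mean(row_b))^2)) / mean(row_b)
  expect_true(filter_peaks(pmb, min_cv = cv)$kept)
  expect_false(filter_peaks(pmb, min_cv = cv + 1e-12)$kept)
})

test_that("quantile normalization equalizes column distributions", {
  # columns (1, 10) and (2, 20): mean-of-sorted is (1.5, 15) in each
  pm <- mk_pm(matrix(c(1, 10, 2, 20), 2), kind = "RPKM")
  qn <- quantile_normalize(pm)
  expect_equal(unname(qn$values), matrix(c(1.5, 15, 1.5, 15), 2))
  # identical columns are a fixed point
  pm2 <- mk_pm(matrix(c(3, 1, 7, 3, 1, 7), 3), kind = "RPKM")
  expect_equal(quantile_normalize(pm2)$values, pm2$values)
  # idempotence and identical sorted columns
  set.seed(5)
  pm3 <- mk_pm(matrix(rexp(40), 10), kind = "RPKM")
  q1 <- quantile_normalize(pm3)
  q2 <- quantile_normalize(q1)
  expect_equal(q1$values, q2$values, tolerance = 1e-9)
  sorted <- apply(q1$values, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(q1$provenance, c("RPKM", "quantile_normalize"))
})

test_that("row z-scoring uses the population sd", {
  pm <- mk_pm(rbind(c(1, 2, 3), c(10, 20, 60)), kind = "RPKM")
  z <- zscore_rows(pm)
  expect_equal(z$values[1, ], c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  expect_equal(unname(rowMeans(z$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(z$values^2))), c(1, 1),
               tolerance = 1e-12)
  # affine invariance
  pm_aff <- mk_pm(rbind(c(1, 2, 3) * 7 + 3), kind = "RPKM")
  expect_equal(unname(zscore_rows(pm_aff)$values[1, ]),
               unname(z$values[1, ]))
  expect_error(zscore_rows(mk_pm(rbind(c(2, 2, 2)), kind = "RPKM")),
               "zero-variance")
})

test_that("the preparation chain runs presence, double qnorm, CV, zscore", {
  set.seed(9)
  v <- matrix(rexp(200, 1 / 10), 50)
  pm <- mk_pm(v, kind = "RPKM")
  prep <- prepare_peak_matrix(pm)
  expect_equal(prep$value_kind, "zscore")
  expect_equal(prep$provenance,
               c("RPKM", "filter(presence=TRUE,variability=FALSE)",
                 "quantile_normalize",
                 "filter(presence=FALSE,variability=TRUE)",
                 "quantile_normalize", "zscore"))
  expect_true(all(abs(rowMeans(prep$values)) < 1e-9))
  single <- prepare_peak_matrix(pm, single_qnorm = TRUE)
  expect_equal(sum(single$provenance == "quantile_normalize"), 1)
})

test_that("fuzzy c-means degenerates, descends, and recovers plantings", {
  set.seed(7)
  x <- matrix(rnorm(60), 20, 3)
  f1 <- fuzzy_cmeans(x, c = 1, m = 1.25, seed = 1, n_restarts = 1)
  expect_true(all(f1$membership == 1))
  expect_equal(unname(f1$centroids[1, ]), unname(colMeans(x)),
               tolerance = 1e-6)

  # objective non-increasing
  planted <- rep(1:2, each = 30)
  centers <- rbind(c(2, 2, -2, -2), c(-2, -2, 2, 2))
  y <- centers[planted, ] + matrix(rnorm(240, sd = 0.3), 60)
  f2 <- fuzzy_cmeans(y, c = 2, m = 1.25, seed = 4)
  expect_true(all(diff(f2$objective_trace) <= 1e-9))
  expect_true(all(abs(rowSums(f2$membership) - 1) < 1e-9))
  expect_true(all(f2$membership >= 0 & f2$membership <= 1))
  expect_equal(adjusted_rand(f2$hard_assignment, planted), 1)

  # determinism under a fixed seed
  f3 <- fuzzy_cmeans(y, c = 2, m = 1.25, seed = 4)
  expect_identical(f2$membership, f3$membership)
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(15)
  planted <- rep(1:3, each = 25)
  centers <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  x <- centers[planted, ] + matrix(rnorm(225, sd = 0.4), 75)
  ours <- fuzzy_cmeans(x, c = 3, m = 1.25, seed = 2)
  ref <- e1071::cmeans(x, centers = 3, m = 1.25)
  expect_equal(adjusted_rand(ours$hard_assignment, ref$cluster), 1)
  # matched centroids agree
  map <- apply(ours$centroids, 1, function(cc)
    which.min(colSums((t(ref$centers) - cc)^2)))
  expect_equal(unname(ours$centroids),
               unname(ref$centers[map, , drop = FALSE]), tolerance = 0.05)
})

test_that("category assignment follows the consecutive-pair argmax", {
  mk <- function(cen) structure(list(centroids = cen, c = nrow(cen)),
                                class = "fuzzy_clustering")
  stages <- c("hPSC", "VME", "EPC", "HPC")
  cen <- rbind(c(1.2, 0.8, -0.9, -1.1),
               c(-1, 0.9, 1.0, -0.9),
               c(-1.1, -0.9, 0.8, 1.2))
  expect_equal(assign_categories(mk(cen), stages), c("I", "II", "III"))
  # tie resolves to the earlier category
  expect_equal(assign_categories(mk(rbind(c(1, 1, 1, 1))), stages), "I")
  expect_error(assign_categories(mk(cen), c("a", "b", "c")), "4-stage")
})

test_that("nearest-gene expression averages log2 counts per cluster", {
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    tss = c(100, 400), strand = "+",
                    stringsAsFactors = FALSE)
  peaks <- genomic_intervals("chr1", c(100, 120), c(200, 180),
                             name = c("p1", "p2"))
  expect_equal(nearest_gene(peaks, ann), c("gA", "gA"))
  # midpoint 150, equidistant TSSs 100 and 200 -> smaller coordinate
  ann2 <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                     tss = c(100, 200), strand = "+",
                     stringsAsFactors = FALSE)
  expect_equal(nearest_gene(peaks[1, ], ann2), "gA")

  expr <- matrix(c(3, 7), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  clust <- structure(list(membership = matrix(1, 2, 1), c = 1,
                          hard_assignment = c(1, 1)),
                     class = "fuzzy_clustering")
  peaks2 <- genomic_intervals("chr1", c(50, 380), c(150, 420),
                              name = c("p1", "p2"))
  m <- nearest_gene_expression(peaks2, ann, expr, clust)
  expect_equal(m[1, 1], (log2(4) + log2(8)) / 2)  # = 2.5
})
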