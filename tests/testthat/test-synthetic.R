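test_that("the generator is a pure function of config and seed", {
  s1 <- simulate_all(tiny_config(seed = 5))
  s2 <- simulate_all(tiny_config(seed = 5))
  expect_identical(s1$genome$sequences, s2$genome$sequences)
  expect_identical(s1$genome$annotation, s2$genome$annotation)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$atac$counts, s2$atac$counts)
  expect_identical(s1$ko, s2$ko)
  expect_identical(s1$chip_tracks$hPSC$H3K4me3$bins,
                   s2$chip_tracks$hPSC$H3K4me3$bins)

  s3 <- simulate_all(tiny_config(seed = 6))
  expect_false(identical(s1$genome$sequences, s3$genome$sequences))
})

test_that("infeasible genome geometry errors", {
  expect_error(simulate_genome(synthetic_config(n_genes = 1000,
                                                n_chroms = 1,
                                                chrom_length = 5e6,
                                                n_intergenic_peaks = 10)),
               "infeasible")
  # too many peaks per gene slot
  expect_error(simulate_genome(synthetic_config(n_genes = 10,
                                                n_intergenic_peaks = 500)),
               "infeasible")
})

test_that("background base composition is near uniform", {
  cfg <- synthetic_config(seed = 2, n_genes = 40, n_intergenic_peaks = 40,
                          n_chroms = 1)  # 1 Mb chromosome
  g <- simulate_genome(cfg)
  n <- nchar(g$sequences$chr1)
  expect_gte(n, 1e6)
  comp <- table(strsplit(g$sequences$chr1, "")[[1]]) / n
  expect_true(all(abs(comp - 0.25) < 0.01))
})

test_that("promoter windows never overlap by construction", {
  g <- simulate_genome(tiny_config())
  for (chrom in unique(g$annotation$chrom)) {
    tss <- sort(g$annotation$tss[g$annotation$chrom == chrom])
    if (length(tss) > 1) expect_true(all(diff(tss) >= 5000))
  }
})

test_that("chip tracks emit Poisson counts at planted promoter states", {
  cfg <- tiny_config(seed = 9)
  g <- simulate_genome(cfg)
  chip <- simulate_chip_tracks(g, cfg)
  states <- g$truth$genes$states

  # a bivalent promoter is high in BOTH marks at the same bins
  biv <- g$annotation[states[g$annotation$gene_id, "hPSC"] == "bivalent", ][1, ]
  bins <- (biv$tss - 2500) %/% 200 + seq_len(25)
  k4 <- chip$hPSC$H3K4me3$bins[[biv$chrom]][bins]
  k27 <- chip$hPSC$H3K27me3$bins[[biv$chrom]][bins]
  expect_gt(mean(k4), cfg$lambda_hi / 2)
  expect_gt(mean(k27), cfg$lambda_hi / 2)

  # empirical mean of marked bins is lambda_hi within 3 standard errors
  marked <- unlist(lapply(seq_len(nrow(g$annotation)), function(i) {
    a <- g$annotation[i, ]
    if (!states[a$gene_id, "hPSC"] %in% c("H3K4me3_only", "bivalent"))
      return(NULL)
    chip$hPSC$H3K4me3$bins[[a$chrom]][(a$tss - 2500) %/% 200 + seq_len(25)]
  }))
  se <- sqrt(cfg$lambda_hi / length(marked))
  expect_lt(abs(mean(marked) - cfg$lambda_hi), 3 * se)
})

test_that("lambda_lo = 0 silences all non-promoter bins", {
  cfg <- tiny_config(seed = 3, lambda_lo = 0, lambda_hi = 10)
  g <- simulate_genome(cfg)
  chip <- simulate_chip_tracks(g, cfg)
  v <- chip$hPSC$H3K4me3$bins$chr1
  prom_bins <- unlist(lapply(which(g$annotation$chrom == "chr1"),
                             function(i)
    (g$annotation$tss[i] - 2500) %/% 200 + seq_len(25)))
  expect_true(all(v[-prom_bins] == 0))
})

test_that("atac peaks follow archetypes and carry planted motifs", {
  cfg <- tiny_config(seed = 13)
  g <- simulate_genome(cfg)
  atac <- simulate_atac(g, cfg)
  peaks <- atac$peaks

  # a peak open only late is absent from the first-stage BED
  late <- peaks[peaks$archetype == 6, ]
  expect_false(any(late$peak_id %in% atac$stage_beds$hPSC$name))
  expect_true(all(late$peak_id %in% atac$stage_beds$HPC$name))

  # every planted motif occurs verbatim at its recorded offset
  consensus <- vapply(cfg$motif_counts, function(m)
    paste(c("A", "C", "G", "T")[apply(m, 2, which.max)], collapse = ""), "")
  planted <- peaks[!is.na(peaks$motif_tf), ]
  for (i in seq_len(nrow(planted))) {
    expected <- consensus[[planted$motif_tf[i]]]
    if (planted$motif_strand[i] == "-")
      expected <- reverse_complement(expected)
    found <- substr(atac$peak_fasta[[planted$peak_id[i]]],
                    planted$motif_offset[i] + 1,
                    planted$motif_offset[i] + nchar(expected))
    expect_identical(found, expected)
  }
})

test_that("motif planting rate is recovered within binomial error", {
  cfg <- synthetic_config(seed = 21, n_genes = 300,
                          n_intergenic_peaks = 3000, with_cuts = FALSE)
  g <- simulate_genome(cfg)
  atac <- simulate_atac(g, cfg)
  p2 <- atac$peaks[atac$peaks$category == "II", ]
  rate <- mean(!is.na(p2$motif_tf))
  se <- sqrt(cfg$motif_planting_rate * (1 - cfg$motif_planting_rate) /
               nrow(p2))
  expect_lt(abs(rate - cfg$motif_planting_rate), 3 * se)
})

test_that("expression is negative binomial with state-dependent means", {
  cfg <- tiny_config(seed = 17)
  g <- simulate_genome(cfg)
  expr <- simulate_expression(g, cfg)
  expect_identical(expr, simulate_expression(g, cfg))
  states <- g$truth$genes$states

  on <- expr[, "hPSC"][states[rownames(expr), "hPSC"] == "H3K4me3_only"]
  off <- expr[, "hPSC"][states[rownames(expr), "hPSC"] == "bivalent"]
  expect_gt(mean(on), mean(off))

  # Poisson limit: dispersion -> Inf gives variance ~ mean
  cfg2 <- synthetic_config(seed = 17, n_genes = 600,
                           n_intergenic_peaks = 600,
                           nb_dispersion = Inf, with_sequence = FALSE,
                           with_cuts = FALSE)
  g2 <- simulate_genome(cfg2)
  e2 <- simulate_expression(g2, cfg2)
  unmarked <- e2[, 1][g2$truth$genes$states[rownames(e2), 1] == "unmarked"]
  mu <- cfg2$nb_mean_by_state["unmarked"]
  # variance of Poisson sample ~ mu; allow 4 sd of the variance estimator
  expect_lt(abs(var(unmarked) - mu), 4 * mu * sqrt(2 / length(unmarked)) + 1)
})

test_that("ko planting is exact, disjoint, and inert at fold 1", {
  cfg <- tiny_config(seed = 23)
  g <- simulate_genome(cfg)
  ko <- simulate_ko(g, cfg)
  n <- nrow(g$truth$peaks)
  expect_equal(sum(ko$labels == "dependent"),
               round(cfg$ko_dependent_fraction * n))
  expect_equal(sum(ko$labels == "independent"),
               round(cfg$ko_independent_fraction * n))
  expect_equal(length(ko$labels), n)

  cfg1 <- tiny_config(seed = 23, ko_fold = 1)
  ko1 <- simulate_ko(g, cfg1)
  expect_true(all(ko1$labels == "unchanged"))

  expect_error(tiny_config(ko_dependent_fraction = 0.8,
                           ko_independent_fraction = 0.3),
               "sum to more than 1")
})
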