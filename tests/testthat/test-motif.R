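test_that("PWM construction applies pseudocounts and log2 odds", {
  counts <- cbind(c(8, 0, 0, 0), c(2, 2, 2, 2))
  p <- pwm_from_counts(counts, tf_name = "toy")
  expect_equal(unname(p$matrix["A", 1]), 9 / 12)
  expect_equal(unname(p$log_odds["A", 1]), log2(3))
  # uniform column has zero log-odds everywhere
  expect_equal(unname(p$log_odds[, 2]), rep(0, 4))
  expect_equal(unname(colSums(p$matrix)), c(1, 1), tolerance = 1e-9)
})

test_that("JASPAR-style matrices roundtrip through the reader", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 GATA2",
               "A [ 1 9 0 ]",
               "C [ 2 0 0 ]",
               "G [ 3 1 0 ]",
               "T [ 4 0 10 ]",
               ">MA0002.1 RUNX1",
               "0 5 5",
               "0 0 0",
               "10 5 0",
               "0 0 5"), f)
  pwms <- read_jaspar(f)
  expect_named(pwms, c("GATA2", "RUNX1"))
  expect_equal(pwms$GATA2$width, 3)
  expect_equal(unname(pwms$GATA2$matrix["T", 1]), 5 / 14)
  expect_equal(unname(pwms$RUNX1$matrix["G", 1]), 11 / 14)
})

test_that("PWM scanning matches a brute-force window oracle", {
  set.seed(27)
  counts <- cbind(c(9, 1, 0, 0), c(0, 0, 10, 0), c(0, 8, 1, 1),
                  c(10, 0, 0, 0))
  pwm <- pwm_from_counts(counts, tf_name = "toy")
  bg <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  bg[11:14] <- c("A", "G", "C", "A")  # embed the consensus
  seqs <- c(s1 = paste(bg, collapse = ""))
  hits <- scan_pwm(seqs, pwm, threshold_fraction = 0.5)

  # oracle: score every window on both strands directly
  brute <- list()
  lo <- pwm$log_odds
  max_score <- sum(apply(lo, 2, max))
  sc_one <- function(s) sum(vapply(seq_len(nchar(s)), function(j)
    lo[substr(s, j, j), j], numeric(1)))
  for (o in 0:(30 - 4)) {
    win <- substr(seqs[[1]], o + 1, o + 4)
    if (sc_one(win) >= 0.5 * max_score)
      brute[[length(brute) + 1]] <- c(o, "+", sc_one(win))
    rc <- reverse_complement(win)
    if (sc_one(rc) >= 0.5 * max_score)
      brute[[length(brute) + 1]] <- c(o, "-", sc_one(rc))
  }
  brute <- do.call(rbind, brute)
  expect_gte(nrow(brute), 1)
  expect_equal(nrow(hits), nrow(brute))
  ord_h <- order(hits$offset, hits$strand)
  ord_b <- order(as.integer(brute[, 1]), brute[, 2])
  expect_equal(hits$offset[ord_h], as.integer(brute[ord_b, 1]))
  expect_equal(hits$strand[ord_h], brute[ord_b, 2])
  expect_equal(hits$score[ord_h], as.numeric(brute[ord_b, 3]),
               tolerance = 1e-12)
})

test_that("scanning is symmetric under reverse complement", {
  pwm <- pwm_from_counts(cbind(c(9, 0, 0, 0), c(0, 9, 0, 0),
                               c(0, 0, 9, 0)), tf_name = "acg")
  seqs <- c(p1 = "TTACGTT")  # ACG at offset 2 on +
  fwd <- scan_pwm(seqs, pwm)
  expect_true(any(fwd$offset == 2 & fwd$strand == "+"))
  top <- fwd[which.max(fwd$score), ]
  expect_equal(top$score, sum(apply(pwm$log_odds, 2, max)))

  rc <- setNames(reverse_complement(seqs), names(seqs))
  rev <- scan_pwm(rc, pwm)
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(sort(rev$score), sort(fwd$score))
  # offsets mirror: L - offset - width
  expect_setequal(rev$offset, nchar(seqs) - fwd$offset - pwm$width)
  flip <- c("+" = "-", "-" = "+")
  expect_setequal(paste(rev$strand), paste(flip[fwd$strand]))

  # N scores as background and short sequences are skipped with warning
  expect_silent(scan_pwm(c(x = "ANNNACG"), pwm))
  expect_warning(scan_pwm(c(x = "AC"), pwm), "shorter than motif")
})

test_that("motif enrichment reproduces the hypergeometric tail", {
  # fg 10/100 vs bg 5/900
  occ <- list(TF1 = data.frame(
    peak_id = c(paste0("f", 1:10), paste0("b", 1:5)),
    offset = 0L, strand = "+", score = 1))
  fg <- paste0("f", 1:100)
  bg <- paste0("b", 1:900)
  e <- motif_enrichment(occ, fg, bg)
  expect_equal(e$p_value, hyper_tail_p(10, 90, 5, 895), tolerance = 1e-12)
  expect_equal(e$fg_proportion, 0.10)
  expect_equal(e$bg_proportion, 5 / 900)

  # equal proportions: odds ratio 1, p >= 0.5
  occ2 <- list(TF1 = data.frame(
    peak_id = c(paste0("f", 1:10), paste0("b", 1:90)),
    offset = 0L, strand = "+", score = 1))
  e2 <- motif_enrichment(occ2, fg, bg)
  expect_equal(e2$odds_ratio, 1)
  expect_gte(e2$p_value, 0.5)

  expect_error(motif_enrichment(occ, character(0), bg), "empty foreground")
  expect_error(motif_enrichment(occ, fg, c(fg[1], bg)), "overlap")

  # BH adjustment across the TFs of one call
  occ3 <- c(occ, list(TF2 = data.frame(peak_id = "b1", offset = 0L,
                                       strand = "+", score = 1)))
  e3 <- motif_enrichment(occ3, fg, bg)
  expect_equal(e3$q_value,
               p.adjust(e3$p_value, "BH"))
})

test_that("candidate regulators are enriched factors that activated", {
  enr <- list(
    II = data.frame(tf_name = c("RUNX1", "GATA2", "SOX17"),
                    q_value = c(0.001, 0.01, 0.2)),
    III = data.frame(tf_name = c("JUNB", "GATA2"),
                     q_value = c(0.002, 0.001)))
  out <- candidate_regulators(enr, c("JUNB", "GATA2", "MYB"))
  expect_equal(out$tf_name, c("GATA2", "JUNB"))
  expect_equal(out$best_q, c(0.001, 0.002))
  # empty enrichment
  expect_equal(nrow(candidate_regulators(list(), c("JUNB"))), 0)
  # category filter excludes factors enriched elsewhere only
  enr$I <- data.frame(tf_name = "MYB", q_value = 1e-6)
  expect_false("MYB" %in% candidate_regulators(enr, c("MYB"))$tf_name)
})

test_that("footprint profiles extract, orient, and summarize windows", {
  v <- rep(2, 1000)
  track <- signal_track(list(chr1 = v), 1)
  sites <- data.frame(chrom = "chr1", start = c(300, 500), end = c(308, 508),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  fp <- footprint_profile(track, sites, radius = 100)
  expect_equal(length(fp$profile), 208)
  expect_true(all(fp$profile == 2))
  expect_equal(footprint_depth(fp), 0)

  # single occurrence: the profile is its window verbatim
  v2 <- seq_len(1000)
  tr2 <- signal_track(list(chr1 = v2), 1)
  fp1 <- footprint_profile(tr2, sites[1, ], radius = 10)
  expect_equal(fp1$profile, v2[(300 - 10 + 1):(308 + 10)])
  # minus-strand window is the reverse of the plus-strand extraction
  sites_m <- sites[1, ]; sites_m$strand <- "-"
  fpm <- footprint_profile(tr2, sites_m, radius = 10)
  expect_equal(fpm$profile, rev(fp1$profile))

  # core at half the flank level gives depth 0.5
  prof <- c(rep(4, 100), rep(2, 8), rep(4, 100))
  fph <- structure(list(profile = prof, radius = 100, width = 8,
                        n_sites = 1), class = "footprint_profile")
  expect_equal(footprint_depth(fph), 0.5)

  # out-of-bounds sites are skipped and counted
  sites_oob <- rbind(sites, data.frame(chrom = "chr1", start = 5,
                                       end = 13, strand = "+"))
  fpo <- footprint_profile(track, sites_oob, radius = 100)
  expect_equal(fpo$n_skipped, 1L)
  expect_equal(fpo$n_sites, 2L)
})

test_that("occurrences lift from peak to genome coordinates", {
  peaks <- genomic_intervals("chr2", c(1000, 3000), c(1400, 3400),
                             name = c("p1", "p2"))
  occ <- data.frame(peak_id = c("p2", "p1"), offset = c(50L, 10L),
                    strand = c("-", "+"), score = 1)
  g <- occurrences_to_genome(occ, peaks, width = 8)
  expect_equal(g$start, c(3050, 1010))
  expect_equal(g$end, c(3058, 1018))
  expect_equal(g$chrom, c("chr2", "chr2"))
  expect_error(occurrences_to_genome(
    data.frame(peak_id = "zz", offset = 0L, strand = "+"), peaks, 8),
    "not found")
})
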