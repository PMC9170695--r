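test_that("Poisson binarization thresholds at the upper-tail probability", {
  # mean exactly 1: one 7, one 6, 87 ones, 11 zeros over 100 bins
  v <- c(7, 6, rep(1, 87), rep(0, 11))
  tr <- signal_track(list(chr1 = v), 200)
  b <- binarize_poisson(list(H3K4me3 = tr), alpha = 1e-4)
  expect_equal(unname(b$lambda), 1)
  # P(X >= 7 | 1) ~ 8.3e-5 < 1e-4 <= P(X >= 6 | 1) ~ 5.9e-4
  expect_equal(unname(b$threshold), 7)
  expect_equal(b$bins$chr1[1:2, 1], c(1L, 0L))
  expect_true(all(b$bins$chr1[-1, 1] == 0L))

  zero <- signal_track(list(chr1 = rep(0, 50)), 200)
  bz <- binarize_poisson(list(H3K4me3 = zero))
  expect_true(all(bz$bins$chr1 == 0L))
})

test_that("binarization threshold tracks a rescaled background", {
  set.seed(4)
  v <- rpois(5000, 2)
  v[1:10] <- 30
  tr1 <- list(m = signal_track(list(c1 = v), 200))
  tr2 <- list(m = signal_track(list(c1 = 2 * v), 200))
  b1 <- binarize_poisson(tr1)
  b2 <- binarize_poisson(tr2)
  expect_equal(unname(b2$lambda), 2 * unname(b1$lambda))
  # recompute both thresholds with a direct tail-sum oracle
  for (b in list(b1, b2)) {
    lam <- unname(b$lambda); thr <- unname(b$threshold)
    tail_p <- function(c) sum(dpois(c:(c + 200), lam))
    expect_lt(tail_p(thr), 1e-4)
    expect_gte(tail_p(thr - 1), 1e-4)
  }
  expect_equal(b1$bins$c1[1:10, 1], rep(1L, 10))
  expect_equal(b2$bins$c1[1:10, 1], rep(1L, 10))
})

test_that("EM log-likelihood is monotone and K=1 matches the closed form", {
  set.seed(8)
  obs <- cbind(rbinom(400, 1, 0.3), rbinom(400, 1, 0.3))
  colnames(obs) <- c("H3K4me3", "H3K27me3")
  b <- binarized_track(list(chr1 = obs))

  m1 <- fit_hmm(b, K = 1, seed = 1, n_restarts = 1)
  expect_true(all(diff(m1$loglik_trace) > -1e-8))
  phat <- colMeans(obs)
  expect_equal(unname(m1$E[1, ]), unname(phat), tolerance = 1e-6)
  ll <- sum(obs %*% log(phat) + (1 - obs) %*% log(1 - phat))
  expect_equal(m1$loglik, ll, tolerance = 1e-6)

  m4 <- fit_hmm(b, K = 4, seed = 1, n_restarts = 2, max_iter = 50)
  expect_true(all(diff(m4$loglik_trace) > -1e-8))
  expect_true(all(abs(rowSums(m4$A) - 1) < 1e-9))
  expect_equal(sum(m4$pi), 1, tolerance = 1e-9)
})

test_that("fit_hmm rejects non-binary input", {
  bad <- structure(list(bins = list(c1 = matrix(c(0, 2, 1, 0), 2)),
                        marks = c("a", "b"), bin_size = 200),
                   class = "binarized_track")
  expect_error(fit_hmm(bad), "non-binary")
  expect_error(binarized_track(list(c1 = matrix(c(0, 2, 1, 0), 2)),
                               marks = c("a", "b")), "non-binary")
})

test_that("a planted sticky 2-state chain is recovered almost exactly", {
  set.seed(31)
  K <- 2; Tlen <- 4000
  A <- matrix(c(0.98, 0.02, 0.02, 0.98), 2, byrow = TRUE)
  E <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  states <- integer(Tlen); states[1] <- 1
  for (t in 2:Tlen) states[t] <- sample(1:2, 1, prob = A[states[t - 1], ])
  obs <- cbind(rbinom(Tlen, 1, E[states, 1]), rbinom(Tlen, 1, E[states, 2]))
  colnames(obs) <- c("H3K4me3", "H3K27me3")
  b <- binarized_track(list(c1 = obs))
  m <- fit_hmm(b, K = 2, seed = 2, n_restarts = 3)
  dec <- decode_states(m, b)$c1
  acc <- max(mean(dec == states), mean(dec == 3 - states))
  expect_gte(acc, 0.99)
})

test_that("Viterbi equals exhaustive enumeration on short sequences", {
  set.seed(12)
  for (rep in 1:25) {
    K <- 2
    pi <- as.vector(gtools_rdirichlet(K))
    A <- t(replicate(K, gtools_rdirichlet(K)))
    E <- matrix(runif(K * 2, 0.05, 0.95), K)
    L <- sample(2:6, 1)
    obs <- matrix(rbinom(L * 2, 1, 0.5), L)
    colnames(obs) <- c("H3K4me3", "H3K27me3")
    model <- structure(list(K = K, marks = colnames(obs), pi = pi, A = A,
                            E = E), class = "chromhmm_model")
    b <- binarized_track(list(c1 = obs))
    path <- decode_states(model, b)$c1

    # independent oracle: brute-force symbol probabilities and all paths
    B <- t(apply(E, 1, function(p) {
      s <- expand.grid(m1 = 0:1, m2 = 0:1)
      p[1]^s$m1 * (1 - p[1])^(1 - s$m1) * p[2]^s$m2 * (1 - p[2])^(1 - s$m2)
    }))
    sym <- obs[, 1] + 2 * obs[, 2] + 1
    paths <- all_paths(K, L)
    probs <- apply(paths, 1, path_prob_oracle, sym = sym, pi = pi,
                   A = A, B = B)
    expect_equal(unname(path), unname(paths[which.max(probs), ]))
  }
})

test_that("forward-backward posteriors normalize and dominate sampling", {
  set.seed(19)
  obs <- cbind(rbinom(200, 1, 0.4), rbinom(200, 1, 0.2))
  colnames(obs) <- c("H3K4me3", "H3K27me3")
  b <- binarized_track(list(c1 = obs))
  m <- fit_hmm(b, K = 2, seed = 3, n_restarts = 2, max_iter = 40)
  post <- state_posteriors(m, b)$c1
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))

  vit <- decode_states(m, b)$c1
  lp_vit <- path_logprob(m, obs, vit)
  for (i in 1:100) {
    rnd <- sample(1:2, nrow(obs), replace = TRUE)
    expect_gte(lp_vit, path_logprob(m, obs, rnd))
  }

  m1 <- fit_hmm(b, K = 1, seed = 1, n_restarts = 1)
  expect_true(all(decode_states(m1, b)$c1 == 1L))
})

test_that("state labeling follows the two-mark emission rule", {
  mk <- function(E) structure(list(K = nrow(E),
                                   marks = c("H3K4me3", "H3K27me3"),
                                   E = E), class = "chromhmm_model")
  E <- rbind(c(0.9, 0.85), c(0.9, 0.05), c(0.1, 0.8), c(0.1, 0.2))
  expect_equal(label_states(mk(E)),
               c("bivalent", "H3K4me3_only", "H3K27me3_only", "unmarked"))
  expect_warning(label_states(mk(rbind(c(0.9, 0.9), c(0.95, 0.85)))),
                 "share a label")
})

test_that("segmentation merges constant runs into disjoint intervals", {
  states <- list(c1 = c(1L, 1L, 2L, 2L, 1L), c2 = c(2L, 2L, 2L, 1L, 1L))
  seg <- chromatin_segmentation(states,
                                c("H3K4me3_only", "unmarked"), 200)
  k4 <- seg$segments$H3K4me3_only
  expect_equal(k4$start, c(0, 800, 600))
  expect_equal(k4$end, c(400, 1000, 1000))
  expect_equal(k4$chrom, c("c1", "c1", "c2"))
  labs <- segmentation_labels(seg)
  expect_equal(labs$c1[3], "unmarked")
})
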