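#' Multivariate Bernoulli hidden Markov model for chromatin states
#'
#' Fits a K-state HMM with independent Bernoulli emissions per mark to a
#' binarized track by Baum-Welch EM, restarted from random emission
#' initializations; the restart with the highest log-likelihood is kept.
#' Chromosomes are treated as independent chains sharing one parameter set.
#' Forward-backward uses per-position scaling, so arbitrarily long
#' chromosomes do not underflow.
#'
#' @param binarized a `binarized_track` from [binarize_poisson()] (entries
#'   must be exactly 0/1).
#' @param K number of hidden states (default 4).
#' @param seed integer seed; the fit is deterministic given it.
#' @param n_restarts restarts refined to convergence (default 5). Each
#'   restart is chosen from a pool of `8 * n_restarts` random starts by a
#'   short burn-in (20 EM iterations), which reliably identifies the
#'   high-likelihood basin before spending full iterations on it.
#' @param tol EM stops when the log-likelihood improves by less than `tol`
#'   (default `1e-4`).
#' @param max_iter maximum EM iterations per refined restart (default
#'   200).
#' @return A `chromhmm_model`: list with `K`, `marks`, `pi` (initial
#'   distribution), `A` (K x K transition matrix), `E` (K x marks Bernoulli
#'   emission probabilities), `loglik`, `loglik_trace` of the winning
#'   restart, and `n_iter`.
#' @export
fit_hmm <- function(binarized, K = 4, seed = 1, n_restarts = 5,
                    tol = 1e-4, max_iter = 200) {
  obs <- check_binary_obs(binarized)
  M <- length(binarized$marks)
  sym <- lapply(obs, obs_to_symbols)   # per chrom, 0-based symbol codes
  symbits <- symbol_bits(M)            # 2^M x M
  if (nrow(unique(do.call(rbind, obs))) < K)
    warning("fewer than K distinct observation rows; states may collapse")

  set.seed(as.integer(seed))
  # burn in a pool of random starts, then refine only the most promising:
  # with few marks the EM surface has wide merged-state basins, and a
  # short burn-in separates them from the full-rank optimum cheaply
  burned <- lapply(seq_len(8L * n_restarts), function(r) {
    E0 <- matrix(runif(K * M, 0.2, 0.8), K, M)
    A0 <- matrix(runif(K * K, 0.5, 1.5), K, K) + diag(K) * K
    A0 <- A0 / rowSums(A0)
    baum_welch(sym, symbits, rep(1 / K, K), A0, E0, -Inf, 20L)
  })
  ranked <- order(vapply(burned, `[[`, numeric(1), "loglik"),
                  decreasing = TRUE)
  best <- NULL
  for (r in ranked[seq_len(n_restarts)]) {
    b <- burned[[r]]
    fit <- baum_welch(sym, symbits, b$pi, b$A, b$E, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(K = K, marks = binarized$marks, pi = best$pi, A = best$A,
                 E = best$E, loglik = best$loglik,
                 loglik_trace = best$trace, n_iter = length(best$trace)),
            class = "chromhmm_model")
}

check_binary_obs <- function(binarized) {
  stopifnot(inherits(binarized, "binarized_track"))
  obs <- binarized$bins
  for (m in obs) if (!all(m %in% c(0L, 1L))) stop("non-binary input")
  obs
}

obs_to_symbols <- function(m) {
  as.integer(m %*% 2^(seq_len(ncol(m)) - 1))
}

symbol_bits <- function(M) {
  s <- 0:(2^M - 1)
  vapply(seq_len(M), function(j) (s %/% 2^(j - 1)) %% 2, numeric(2^M))
}

baum_welch <- function(sym, symbits, pi, A, E, tol, max_iter) {
  K <- length(pi)
  trace <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    B <- bernoulli_symbol_probs(E, symbits)
    loglik <- 0
    pi_acc <- numeric(K)
    A_acc <- matrix(0, K, K)
    on_acc <- matrix(0, K, ncol(E))   # expected mark-on counts per state
    g_acc <- numeric(K)               # expected occupancy per state
    for (ch in sym) {
      fb <- hmm_forward_backward(ch, pi, A, B)
      loglik <- loglik + fb$loglik
      pi_acc <- pi_acc + fb$gamma[1, ]
      A_acc <- A_acc + fb$xi
      # per-symbol posterior mass, then project onto marks
      gsum <- rowsum(fb$gamma, ch)                  # symbols x K
      symrows <- as.numeric(rownames(gsum)) + 1
      on_acc <- on_acc + t(gsum) %*% symbits[symrows, , drop = FALSE]
      g_acc <- g_acc + colSums(fb$gamma)
    }
    trace <- c(trace, loglik)
    pi <- pi_acc / sum(pi_acc)
    A <- (A_acc + 1e-12) / rowSums(A_acc + 1e-12)  # guard empty states
    E <- on_acc / pmax(g_acc, 1e-12)
    stopifnot(abs(sum(pi) - 1) < 1e-9, all(abs(rowSums(A) - 1) < 1e-9))
    if (loglik - prev < tol && iter > 1) break
    prev <- loglik
  }
  list(pi = pi, A = A, E = E, loglik = trace[length(trace)], trace = trace)
}

# K x 2^M matrix of P(symbol | state) under independent Bernoulli marks
bernoulli_symbol_probs <- function(E, symbits) {
  K <- nrow(E)
  S <- nrow(symbits)
  B <- matrix(1, K, S)
  for (j in seq_len(ncol(E))) {
    p <- pmin(pmax(E[, j], 1e-8), 1 - 1e-8)
    bit <- symbits[, j]
    B <- B * (outer(p, bit) + outer(1 - p, 1 - bit))
  }
  B
}

#' Viterbi decoding of a binarized track
#'
#' @param model a `chromhmm_model`.
#' @param binarized a `binarized_track` over the same marks.
#' @return Named list, chromosome -> integer vector of 1-based state indices
#'   along the bins (the maximum-probability path).
#' @export
decode_states <- function(model, binarized) {
  stopifnot(identical(model$marks, binarized$marks))
  obs <- check_binary_obs(binarized)
  symbits <- symbol_bits(length(model$marks))
  logB <- log(bernoulli_symbol_probs(model$E, symbits))
  logA <- log(pmax(model$A, 1e-300))
  logpi <- log(pmax(model$pi, 1e-300))
  lapply(obs, function(m) {
    v <- hmm_viterbi(obs_to_symbols(m), logpi, logA, logB)
    v$path + 1L
  })
}

#' Posterior state probabilities of a binarized track
#'
#' Forward-backward posteriors per bin; rows sum to 1.
#'
#' @inheritParams decode_states
#' @return Named list, chromosome -> bins x K posterior matrix.
#' @export
state_posteriors <- function(model, binarized) {
  stopifnot(identical(model$marks, binarized$marks))
  obs <- check_binary_obs(binarized)
  symbits <- symbol_bits(length(model$marks))
  B <- bernoulli_symbol_probs(model$E, symbits)
  lapply(obs, function(m) {
    hmm_forward_backward(obs_to_symbols(m), model$pi, model$A, B)$gamma
  })
}

#' Log-probability of a fixed state path
#'
#' Joint log-probability of a given state path and the observations; used to
#' check that the Viterbi path dominates alternatives.
#'
#' @param model a `chromhmm_model`.
#' @param obs bins x marks binary matrix (one chromosome).
#' @param path integer vector of 1-based states, same length as `nrow(obs)`.
#' @return Log joint probability.
#' @export
path_logprob <- function(model, obs, path) {
  symbits <- symbol_bits(length(model$marks))
  logB <- log(bernoulli_symbol_probs(model$E, symbits))
  sym <- obs_to_symbols(obs) + 1L
  lp <- log(model$pi[path[1]]) + logB[path[1], sym[1]]
  for (t in seq_along(path)[-1]) {
    lp <- lp + log(model$A[path[t - 1], path[t]]) + logB[path[t], sym[t]]
  }
  lp
}

#' Semantic labels for fitted chromatin states
#'
#' With marks exactly H3K4me3 and H3K27me3, each state's marks are called
#' "on" when the fitted emission probability reaches `threshold`; both on is
#' bivalent, only H3K4me3 is H3K4me3_only, only H3K27me3 is H3K27me3_only,
#' neither is unmarked. If two states map to the same label a warning is
#' recorded and the labels are kept.
#'
#' @param model a `chromhmm_model` over marks H3K4me3 and H3K27me3.
#' @param threshold emission probability calling a mark on (default 0.5).
#' @return Character vector of length K with the state labels.
#' @export
label_states <- function(model, threshold = 0.5) {
  stopifnot(setequal(model$marks, c("H3K4me3", "H3K27me3")))
  k4 <- model$E[, match("H3K4me3", model$marks)] >= threshold
  k27 <- model$E[, match("H3K27me3", model$marks)] >= threshold
  labels <- ifelse(k4 & k27, "bivalent",
                   ifelse(k4, "H3K4me3_only",
                          ifelse(k27, "H3K27me3_only", "unmarked")))
  if (anyDuplicated(labels))
    warning("multiple states share a label: ",
            paste(labels[duplicated(labels)], collapse = ", "))
  labels
}

#' Assemble a chromatin segmentation
#'
#' @param states decoded states, chromosome -> 1-based state index per bin.
#' @param state_labels labels per state from [label_states()].
#' @param bin_size bin width in bp.
#' @return A `chromatin_segmentation`: the inputs plus `segments`, a
#'   label -> sorted disjoint interval data frame of merged constant runs.
#' @export
chromatin_segmentation <- function(states, state_labels, bin_size) {
  labels <- sort(unique(state_labels))
  segments <- lapply(setNames(labels, labels), function(lab) {
    pieces <- lapply(names(states), function(chrom) {
      r <- rle(state_labels[states[[chrom]]])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      sel <- r$values == lab
      if (!any(sel)) return(NULL)
      genomic_intervals(chrom, starts[sel] * bin_size, ends[sel] * bin_size)
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (!length(pieces)) return(genomic_intervals(character(), 0, 1)[0, ])
    do.call(rbind, pieces)
  })
  structure(list(states = states, state_labels = state_labels,
                 bin_size = bin_size, segments = segments),
            class = "chromatin_segmentation")
}

#' Per-bin labels of a segmentation
#'
#' @param segmentation a `chromatin_segmentation`.
#' @return Named list, chromosome -> character vector of labels per bin.
#' @export
segmentation_labels <- function(segmentation) {
  lapply(segmentation$states, function(s) segmentation$state_labels[s])
}
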