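#' Construct a binarized track directly
#'
#' Mainly useful for fitting an HMM to externally binarized data.
#'
#' @param bins named list, chromosome -> bins x marks 0/1 integer matrix.
#' @param marks mark names (defaults to the first matrix's column names).
#' @param bin_size bin width in bp.
#' @return A `binarized_track`.
#' @export
binarized_track <- function(bins, marks = colnames(bins[[1]]),
                            bin_size = 200) {
  stopifnot(is.list(bins), length(bins) >= 1, !is.null(marks))
  for (m in bins) {
    if (!all(m %in% c(0L, 1L))) stop("non-binary input")
    if (ncol(m) != length(marks)) stop("mark count mismatch")
  }
  structure(list(bins = lapply(bins, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "integer"; colnames(m) <- marks; m
  }), marks = marks, bin_size = bin_size), class = "binarized_track")
}

#' Poisson-background binarization of binned mark signal
#'
#' Per mark, the background rate lambda is the genome-wide mean bin count; a
#' bin is called present (1) iff its upper-tail Poisson probability
#' `P(X >= count | lambda)` falls below `alpha`. An all-zero track binarizes
#' to all zeros.
#'
#' @param tracks named list of [signal_track()]s, one per mark (values are
#'   nonnegative counts per bin).
#' @param alpha upper-tail probability threshold (default `1e-4`).
#' @return A `binarized_track`: list with `bins` (chromosome -> integer
#'   matrix, bins x marks, entries 0/1), `marks`, `bin_size` and the per-mark
#'   `lambda` and integer `threshold` used (smallest count called present).
#' @export
binarize_poisson <- function(tracks, alpha = 1e-4) {
  stopifnot(is.list(tracks), length(tracks) >= 1, !is.null(names(tracks)))
  marks <- names(tracks)
  bin_size <- tracks[[1]]$bin_size
  chroms <- names(tracks[[1]]$bins)
  for (tr in tracks) {
    stopifnot(identical(names(tr$bins), chroms), tr$bin_size == bin_size)
    if (any(unlist(tr$bins) < 0)) stop("negative counts in track")
  }
  lambda <- vapply(tracks, function(tr) mean(unlist(tr$bins)), numeric(1))
  thr <- vapply(lambda, poisson_upper_threshold, numeric(1), alpha = alpha)
  bins <- lapply(chroms, function(chrom) {
    m <- vapply(seq_along(marks), function(j) {
      as.integer(tracks[[j]]$bins[[chrom]] >= thr[j])
    }, integer(length(tracks[[1]]$bins[[chrom]])))
    m <- matrix(m, ncol = length(marks))
    colnames(m) <- marks
    m
  })
  names(bins) <- chroms
  structure(list(bins = bins, marks = marks, bin_size = bin_size,
                 lambda = lambda, threshold = thr),
            class = "binarized_track")
}

# smallest integer c with P(X >= c | lambda) < alpha; Inf for lambda = 0
# handled as threshold 1 (any nonzero count is above an all-zero background,
# but an all-zero track then stays all-zero).
poisson_upper_threshold <- function(lambda, alpha) {
  if (lambda == 0) return(1)
  ct <- stats::qpois(1 - alpha, lambda)  # lower bound for the search
  while (ppois(ct - 1, lambda, lower.tail = FALSE) >= alpha) ct <- ct + 1
  while (ct > 0 && ppois(ct - 2, lambda, lower.tail = FALSE) < alpha)
    ct <- ct - 1
  ct
}
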