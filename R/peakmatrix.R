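#' Peak-by-stage matrices
#'
#' A `peak_matrix` couples a consensus peak set with a peaks x stages value
#' matrix and records what the values are (`count`, `RPKM`,
#' `quantile_normalized`, `zscore`) plus an append-only provenance of the
#' transforms applied.
#'
#' @param peaks interval data frame of consensus peaks.
#' @param values peaks x stages numeric matrix.
#' @param value_kind one of count, RPKM, quantile_normalized, zscore.
#' @param library_sizes per-stage total read counts (optional).
#' @param provenance character vector of transforms applied so far.
#' @return A `peak_matrix` object.
#' @export
peak_matrix <- function(peaks, values, value_kind = "count",
                        library_sizes = NULL, provenance = value_kind) {
  stopifnot(nrow(peaks) == nrow(values))
  value_kind <- match.arg(value_kind,
                          c("count", "RPKM", "quantile_normalized", "zscore"))
  if (value_kind %in% c("count", "RPKM") && any(values < 0))
    stop("counts/RPKM must be nonnegative")
  structure(list(peaks = peaks, values = values, value_kind = value_kind,
                 library_sizes = library_sizes, provenance = provenance),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat("peak_matrix: ", nrow(x$values), " peaks x ", ncol(x$values),
      " stages [", x$value_kind, "]\n  provenance: ",
      paste(x$provenance, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Count track signal in peaks
#'
#' Sums each stage's signal track over every consensus peak, yielding the
#' raw count matrix.
#'
#' @param peaks consensus peak interval data frame.
#' @param tracks_by_stage list: stage -> [signal_track()].
#' @return A `peak_matrix` of kind `count` with library sizes set to each
#'   track's genome-wide total.
#' @export
count_peak_matrix <- function(peaks, tracks_by_stage) {
  values <- vapply(tracks_by_stage, function(tr) {
    vapply(seq_len(nrow(peaks)), function(i)
      window_signal_sum(tr, peaks$chrom[i], peaks$start[i], peaks$end[i]),
      numeric(1))
  }, numeric(nrow(peaks)))
  values <- matrix(values, nrow = nrow(peaks),
                   dimnames = list(NULL, names(tracks_by_stage)))
  lib <- vapply(tracks_by_stage, function(tr) sum(unlist(tr$bins)),
                numeric(1))
  peak_matrix(peaks, values, "count", library_sizes = lib)
}

#' RPKM-normalize a count matrix
#'
#' `RPKM = count / (library_size / 1e6) / (length / 1e3)`.
#'
#' @param pm a `peak_matrix` of kind `count`.
#' @param library_sizes per-stage totals; defaults to those stored in `pm`.
#' @return A `peak_matrix` of kind `RPKM`.
#' @export
rpkm <- function(pm, library_sizes = pm$library_sizes) {
  stopifnot(pm$value_kind == "count", !is.null(library_sizes),
            all(library_sizes > 0))
  len <- pm$peaks$end - pm$peaks$start
  if (any(len <= 0)) stop("zero-length peak")
  values <- sweep(pm$values / (len / 1e3), 2, library_sizes / 1e6, "/")
  peak_matrix(pm$peaks, values, "RPKM", library_sizes,
              c(pm$provenance, "RPKM"))
}

#' Filter peaks by presence and temporal variability
#'
#' Keeps rows with RPKM strictly above `min_rpkm` in at least `min_stages`
#' stages and a coefficient of variation (population sd / mean) of at least
#' `min_cv` across stages; static peaks (CV below the cutoff, including
#' constant rows) and all-zero rows are removed.
#'
#' @param pm a `peak_matrix` (kind RPKM for the presence filter to be
#'   meaningful).
#' @param min_rpkm presence threshold, strict (default 5).
#' @param min_stages number of stages that must exceed it (default 2).
#' @param min_cv minimum CV, kept when `CV >= min_cv` (default 0.10).
#' @param presence,variability toggle the two filters independently.
#' @return List with `matrix` (filtered `peak_matrix`) and `kept` (logical
#'   index into the input rows).
#' @export
filter_peaks <- function(pm, min_rpkm = 5, min_stages = 2, min_cv = 0.10,
                         presence = TRUE, variability = TRUE) {
  v <- pm$values
  keep <- rep(TRUE, nrow(v))
  if (presence)
    keep <- keep & rowSums(v > min_rpkm) >= min_stages
  if (variability) {
    mu <- rowMeans(v)
    cv <- ifelse(mu > 0, pop_sd_rows(v) / mu, 0)
    keep <- keep & mu > 0 & cv >= min_cv
  }
  out <- peak_matrix(pm$peaks[keep, , drop = FALSE],
                     v[keep, , drop = FALSE], pm$value_kind,
                     pm$library_sizes,
                     c(pm$provenance,
                       sprintf("filter(presence=%s,variability=%s)",
                               presence, variability)))
  list(matrix = out, kept = keep)
}

pop_sd_rows <- function(v) {
  mu <- rowMeans(v)
  sqrt(rowMeans((v - mu)^2))
}

#' Quantile-normalize a peak matrix across stages
#'
#' Each column's sorted values are replaced by the across-column mean of
#' sorted values (ties receive the mean of their target quantiles), making
#' every column's distribution identical while preserving within-column
#' rank order. Delegates to `limma::normalizeQuantiles`.
#'
#' @param pm a `peak_matrix`.
#' @return A `peak_matrix` of kind `quantile_normalized`.
#' @export
quantile_normalize <- function(pm) {
  values <- limma::normalizeQuantiles(pm$values, ties = TRUE)
  dimnames(values) <- dimnames(pm$values)
  peak_matrix(pm$peaks, values, "quantile_normalized", pm$library_sizes,
              c(pm$provenance, "quantile_normalize"))
}

#' Z-score each peak's temporal profile
#'
#' Per-row `(x - mean) / sd` with the population sd (divide by n). Rows with
#' zero sd are an error; the CV filter is expected to have removed them.
#'
#' @param pm a `peak_matrix`.
#' @return A `peak_matrix` of kind `zscore`; rows have mean 0 and
#'   population sd 1.
#' @export
zscore_rows <- function(pm) {
  mu <- rowMeans(pm$values)
  s <- pop_sd_rows(pm$values)
  if (any(s == 0)) stop("zero-variance row; apply the CV filter first")
  values <- (pm$values - mu) / s
  peak_matrix(pm$peaks, values, "zscore", pm$library_sizes,
              c(pm$provenance, "zscore"))
}

#' Full peak-matrix preparation chain
#'
#' The exact transform order used ahead of temporal clustering: RPKM
#' presence filter, quantile normalization, CV filter, a second quantile
#' normalization, z-scoring. `single_qnorm = TRUE` drops the first
#' normalization for the simpler single-pass variant.
#'
#' @param pm a `peak_matrix` of kind `RPKM`.
#' @param min_rpkm,min_stages,min_cv filter parameters (see
#'   [filter_peaks()]).
#' @param single_qnorm apply quantile normalization only once, after the CV
#'   filter (default `FALSE`).
#' @return A z-scored `peak_matrix` restricted to the kept peaks.
#' @export
prepare_peak_matrix <- function(pm, min_rpkm = 5, min_stages = 2,
                                min_cv = 0.10, single_qnorm = FALSE) {
  stopifnot(pm$value_kind == "RPKM")
  step <- filter_peaks(pm, min_rpkm, min_stages, variability = FALSE)$matrix
  if (!single_qnorm) step <- quantile_normalize(step)
  step <- filter_peaks(step, min_cv = min_cv, presence = FALSE)$matrix
  step <- quantile_normalize(step)
  zscore_rows(step)
}
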