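#' Aggregate ATAC footprint profile around motif occurrences
#'
#' For each genome-mapped motif occurrence the window
#' `[site_start - radius, site_end + radius)` of the base-resolution
#' cut-count track is extracted (reversed for minus-strand sites, so
#' position runs 5'->3' along the motif) and the profile is the
#' position-wise mean over sites. Sites whose window leaves the chromosome
#' are skipped and counted.
#'
#' @param cut_track a [signal_track()] with `bin_size = 1` (per-bp cut
#'   counts).
#' @param sites data frame of genome-coordinate occurrences: `chrom`,
#'   `start`, `end` (0-based half-open motif span), `strand`.
#' @param radius flank in bp on each side of the motif (default 100).
#' @return A `footprint_profile`: list with `profile` (length
#'   `2 * radius + motif width`), `n_sites`, `n_skipped`, `radius`,
#'   `width`.
#' @export
footprint_profile <- function(cut_track, sites, radius = 100) {
  stopifnot(cut_track$bin_size == 1, radius > 0, nrow(sites) >= 1)
  width <- unique(sites$end - sites$start)
  if (length(width) != 1) stop("sites must share one motif width")
  len <- 2 * radius + width
  acc <- numeric(len)
  n <- 0L; skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    v <- cut_track$bins[[sites$chrom[i]]]
    if (is.null(v)) stop("unknown chromosome: ", sites$chrom[i])
    lo <- sites$start[i] - radius
    hi <- sites$end[i] + radius
    if (lo < 0 || hi > length(v)) { skipped <- skipped + 1L; next }
    win <- v[(lo + 1):hi]
    if (identical(sites$strand[i], "-")) win <- rev(win)
    acc <- acc + win
    n <- n + 1L
  }
  if (n == 0L) stop("no usable sites within chromosome bounds")
  structure(list(profile = acc / n, n_sites = n, n_skipped = skipped,
                 radius = radius, width = width),
            class = "footprint_profile")
}

#' Footprint depth of an aggregate profile
#'
#' `depth = 1 - mean(core) / mean(flank)`, where the core is the motif span
#' and the flank is the outermost `radius / 2` positions on each side. A
#' flat profile has depth 0; a core at half the flank signal has depth 0.5;
#' a zero flank mean gives NA.
#'
#' @param fp a `footprint_profile`.
#' @return Scalar depth in `(-Inf, 1]`, or NA.
#' @export
footprint_depth <- function(fp) {
  stopifnot(inherits(fp, "footprint_profile"))
  half <- max(1L, floor(fp$radius / 2))
  n <- length(fp$profile)
  flank <- c(fp$profile[seq_len(half)],
             fp$profile[(n - half + 1):n])
  core <- fp$profile[(fp$radius + 1):(fp$radius + fp$width)]
  if (mean(flank) == 0) return(NA_real_)
  1 - mean(core) / mean(flank)
}

#' Lift peak-relative motif occurrences to genome coordinates
#'
#' @param occurrences occurrence data frame from [scan_pwm()] whose
#'   `peak_id`s index rows of `peaks` (by `name`).
#' @param peaks interval data frame with `name` column matching the
#'   occurrence `peak_id`s.
#' @param width motif width in bp.
#' @return Data frame `chrom`, `start`, `end`, `strand` in genome
#'   coordinates.
#' @export
occurrences_to_genome <- function(occurrences, peaks, width) {
  idx <- match(occurrences$peak_id, peaks$name)
  if (anyNA(idx)) stop("occurrence peak_id not found among peaks")
  start <- peaks$start[idx] + occurrences$offset
  data.frame(chrom = peaks$chrom[idx], start = start, end = start + width,
             strand = occurrences$strand, stringsAsFactors = FALSE)
}
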