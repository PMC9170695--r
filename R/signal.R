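#' Binned signal tracks
#'
#' A `signal_track` stores one nonnegative value per fixed-width genomic bin:
#' a list with `bins` (named list, chromosome -> numeric vector of length
#' `ceiling(chrom_length / bin_size)`) and `bin_size` in bp. Histone-mark and
#' accessibility coverage are carried in this form; ATAC cut-site tracks use
#' `bin_size = 1`.
#'
#' @param bins named list of per-chromosome numeric vectors.
#' @param bin_size bin width in bp.
#' @return A `signal_track` object.
#' @export
signal_track <- function(bins, bin_size) {
  stopifnot(is.list(bins), length(names(bins)) == length(bins),
            bin_size >= 1)
  for (v in bins) {
    if (any(v < 0)) stop("signal track values must be nonnegative")
  }
  structure(list(bins = bins, bin_size = bin_size), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track: ", length(x$bins), " chromosome(s), bin size ",
      x$bin_size, " bp\n", sep = "")
  invisible(x)
}

#' Bin a bedGraph into fixed-width bins
#'
#' Each bin receives the sum over bedGraph records of value x overlapping
#' bases, so total mass is conserved: the sum over all bins equals the sum
#' over records of value x record length. Bins with no record are 0.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param bin_size bin width in bp (200 for chromatin-state binning).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return A [signal_track()].
#' @export
bin_bedgraph <- function(path, bin_size, chrom_sizes) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  bins <- lapply(chrom_sizes, function(len) numeric(ceiling(len / bin_size)))
  if (any(keep)) {
    df <- read.delim(text = lines[keep], header = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("bedGraph needs 4 columns")
    names(df)[1:4] <- c("chrom", "start", "end", "value")
    bins <- bin_records(df, bin_size, chrom_sizes, bins)
  }
  signal_track(bins, bin_size)
}

# distribute records (0-based half-open, per-base value) into bin sums
bin_records <- function(df, bin_size, chrom_sizes, bins) {
  if (!all(df$chrom %in% names(chrom_sizes)))
    stop("bedGraph record on unknown chromosome")
  if (any(df$end > chrom_sizes[df$chrom]))
    stop("bedGraph record beyond chromosome end")
  if (any(df$start < 0 | df$start >= df$end))
    stop("invalid bedGraph interval")
  first_bin <- df$start %/% bin_size
  last_bin <- (df$end - 1) %/% bin_size
  within <- first_bin == last_bin
  for (chrom in unique(df$chrom)) {
    sel <- df$chrom == chrom
    # records fully inside one bin: one increment each
    w <- sel & within
    if (any(w)) {
      add <- rowsum(df$value[w] * (df$end[w] - df$start[w]), first_bin[w])
      idx <- as.numeric(rownames(add)) + 1
      bins[[chrom]][idx] <- bins[[chrom]][idx] + add[, 1]
    }
    # spanning records: split at bin boundaries
    s <- which(sel & !within)
    for (i in s) {
      b <- first_bin[i]:last_bin[i]
      lo <- pmax(df$start[i], b * bin_size)
      hi <- pmin(df$end[i], (b + 1) * bin_size)
      bins[[chrom]][b + 1L] <- bins[[chrom]][b + 1L] + df$value[i] * (hi - lo)
    }
  }
  bins
}

#' Write a signal track as bedGraph
#'
#' One record per nonzero bin, value = bin sum / bin width (per-base rate),
#' so that [bin_bedgraph()] recovers the original bin sums.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$bins)) {
    v <- track$bins[[chrom]]
    nz <- which(v != 0)
    if (!length(nz)) next
    start <- (nz - 1L) * track$bin_size
    writeLines(paste(chrom, format_coord(start),
                     format_coord(start + track$bin_size),
                     format(v[nz] / track$bin_size, scientific = FALSE,
                            trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Total signal within a window
#'
#' Sums the per-base signal of a track over `[start, end)`, counting partial
#' bin overlaps proportionally (bin values are sums, assumed uniform within
#' the bin).
#'
#' @param track a [signal_track()].
#' @param chrom,start,end window coordinates (0-based half-open).
#' @return Summed signal (numeric scalar).
#' @export
window_signal_sum <- function(track, chrom, start, end) {
  v <- track$bins[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  bs <- track$bin_size
  b0 <- start %/% bs
  b1 <- (end - 1) %/% bs
  b1 <- min(b1, length(v) - 1L)
  if (b0 > b1) return(0)
  b <- b0:b1
  lo <- pmax(start, b * bs)
  hi <- pmin(end, (b + 1) * bs)
  sum(v[b + 1L] * (hi - lo) / bs)
}

#' Per-gene promoter signal sums
#'
#' @param track a [signal_track()].
#' @param annotation gene annotation data frame (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param flank promoter half-width in bp (default 2500).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return Named numeric vector of summed signal per gene.
#' @export
promoter_signal_sums <- function(track, annotation, flank = 2500,
                                 chrom_sizes) {
  vapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    w <- promoter_window(g, flank, chrom_sizes)
    window_signal_sum(track, w$chrom, w$start, w$end)
  }, numeric(1)) |> setNames(annotation$gene_id)
}
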