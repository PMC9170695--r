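#' Genomic interval data frames
#'
#' Intervals are plain data frames in the BED convention: 0-based, half-open
#' `[start, end)`. `genomic_intervals()` builds and validates one; most other
#' functions in the package accept and return this shape.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param name optional feature names (BED column 4).
#' @param score optional numeric scores (BED column 5).
#' @param strand strand characters, each one of `"+"`, `"-"`, `"."`.
#' @return A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = 0,
                              strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$chrom == "" | is.na(df$chrom)))
    stop("interval with empty chromosome name")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at row ", bad[1])
  if ("strand" %in% names(df) &&
      !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Read a BED file
#'
#' Reads BED3-BED6; columns beyond the sixth are ignored, `track` and
#' `browser` lines are skipped. Coordinates are kept 0-based half-open as in
#' the file.
#'
#' @param path path to a BED file.
#' @return An interval data frame (see [genomic_intervals()]), rows in file
#'   order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", idx[which(nf < 3)[1]], ": fewer than 3 columns")
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", idx[bad[1]], ": malformed coordinate")
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("line ", idx[bad[1]], ": invalid interval (start >= end)")
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[is.na(score)] <- 0
  strand <- get(6, ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  genomic_intervals(get(1, ""), start, end,
                    name = get(4, "."), score = score, strand = strand)
}

#' Write intervals as BED
#'
#' Writes the first six BED columns; `write_bed(read_bed(f))` reproduces the
#' coordinate columns byte-identically.
#'
#' @param intervals an interval data frame.
#' @param path output path.
#' @param columns number of BED columns to write (3-6).
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, columns = 6) {
  validate_intervals(intervals)
  stopifnot(columns >= 3, columns <= 6)
  df <- intervals
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "."
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(columns)]
  out <- df[, cols, drop = FALSE]
  out$start <- format_coord(out$start)
  out$end <- format_coord(out$end)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a two-column chromosome sizes table
#'
#' @param path TSV with columns (chromosome name, length in bp), no header.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom.sizes needs two columns")
  sizes <- as.numeric(df[[2]])
  if (any(is.na(sizes) | sizes <= 0)) stop("invalid chromosome length")
  setNames(sizes, as.character(df[[1]]))
}

#' Overlap length of two intervals
#'
#' Overlap in bp between `a` and `b`; zero when they are on different
#' chromosomes or merely abut (half-open convention).
#'
#' @param a,b single-row interval data frames (or lists with `chrom`,
#'   `start`, `end`).
#' @return Overlap length in bp.
#' @export
overlap_length <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0)
  max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]))
}

#' Promoter window around a TSS
#'
#' The window `[tss - flank, tss + flank)` clamped to the chromosome;
#' symmetric regardless of strand.
#'
#' @param gene one annotation record: a list/row with `gene_id`, `chrom`,
#'   `tss` (0-based), `strand`.
#' @param flank flank size in bp (default 2500, i.e. a +/- 2.5 kb promoter).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return A one-row interval data frame.
#' @export
promoter_window <- function(gene, flank = 2500, chrom_sizes) {
  stopifnot(flank > 0)
  chrom <- as.character(gene$chrom[1])
  if (!chrom %in% names(chrom_sizes))
    stop("unknown chromosome: ", chrom)
  tss <- as.numeric(gene$tss[1])
  start <- max(0, tss - flank)
  end <- min(chrom_sizes[[chrom]], tss + flank)
  genomic_intervals(chrom, start, end,
                    name = as.character(gene$gene_id[1]),
                    strand = as.character(gene$strand[1]))
}

#' Merge intervals within a gap
#'
#' Overlapping intervals and intervals separated by at most `gap` bp are
#' merged transitively into single intervals, per chromosome.
#'
#' @param intervals interval data frame.
#' @param gap maximum separation in bp to merge across (default 100).
#' @return Sorted, merged interval data frame; merged output intervals are
#'   pairwise separated by more than `gap`.
#' @export
merge_within <- function(intervals, gap = 100) {
  validate_intervals(intervals)
  if (!nrow(intervals)) return(intervals)
  ord <- order(intervals$chrom, intervals$start, intervals$end)
  df <- intervals[ord, , drop = FALSE]
  new_chrom <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)])
  out_chrom <- character(0); out_start <- numeric(0); out_end <- numeric(0)
  cur_chrom <- ""; cur_start <- 0; cur_end <- -Inf
  for (i in seq_len(nrow(df))) {
    if (new_chrom[i] || df$start[i] > cur_end + gap) {
      if (!new_chrom[i] || i > 1) {
        out_chrom <- c(out_chrom, cur_chrom)
        out_start <- c(out_start, cur_start)
        out_end <- c(out_end, cur_end)
      }
      cur_chrom <- df$chrom[i]; cur_start <- df$start[i]; cur_end <- df$end[i]
    } else {
      cur_end <- max(cur_end, df$end[i])
    }
  }
  out_chrom <- c(out_chrom, cur_chrom)
  out_start <- c(out_start, cur_start)
  out_end <- c(out_end, cur_end)
  genomic_intervals(out_chrom, out_start, out_end)
}

#' Consensus union of per-stage peak sets
#'
#' Pools the peak lists of all stages and merges peaks closer than `gap` bp,
#' yielding one consensus set covering every input peak.
#'
#' @param peak_lists list of interval data frames, one per stage.
#' @param gap merge distance in bp (default 100).
#' @return Merged consensus interval data frame.
#' @export
consensus_union <- function(peak_lists, gap = 100) {
  stopifnot(length(peak_lists) >= 1)
  pooled <- do.call(rbind, lapply(peak_lists, function(p)
    p[, c("chrom", "start", "end"), drop = FALSE]))
  pooled$name <- "."; pooled$score <- 0; pooled$strand <- "."
  merge_within(pooled, gap = gap)
}

# total bp overlap of one window with each row of a sorted interval set
interval_overlap_total <- function(window, intervals) {
  if (!nrow(intervals)) return(0)
  same <- intervals$chrom == window$chrom[1]
  if (!any(same)) return(0)
  iv <- intervals[same, , drop = FALSE]
  sum(pmax(0, pmin(iv$end, window$end[1]) - pmax(iv$start, window$start[1])))
}
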