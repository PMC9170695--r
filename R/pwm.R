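DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix from a count matrix
#'
#' Column probabilities are `(count + pseudocount) / (column total + 4 *
#' pseudocount)`; log-odds are `log2(probability / background)`.
#'
#' @param counts 4 x width nonnegative count matrix, rows A, C, G, T.
#' @param tf_name factor name attached to the PWM.
#' @param pseudocount added per cell (default 1).
#' @param background per-base background frequencies (default uniform).
#' @return A `pwm`: list with `tf_name`, `matrix` (probabilities),
#'   `background`, `log_odds`, `width`.
#' @export
pwm_from_counts <- function(counts, tf_name = "TF", pseudocount = 1,
                            background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1, all(counts >= 0),
            all(colSums(counts) > 0), abs(sum(background) - 1) < 1e-6)
  rownames(counts) <- DNA_BASES
  prob <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount,
                "/")
  log_odds <- log2(prob / background)
  structure(list(tf_name = tf_name, matrix = prob, background = background,
                 log_odds = log_odds, width = ncol(prob)),
            class = "pwm")
}

#' Read JASPAR-style position count matrices
#'
#' Accepts the common JASPAR text layout: a `>identifier name` header line
#' followed by four rows (A, C, G, T) of counts, optionally wrapped in
#' `A [ ... ]` bracket syntax.
#'
#' @param path PFM text file; may hold several matrices.
#' @param pseudocount,background passed to [pwm_from_counts()].
#' @return Named list of `pwm` objects (named by TF name).
#' @export
read_jaspar <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no '>' header found in ", path)
  out <- list()
  bounds <- c(headers, length(lines) + 1)
  for (i in seq_along(headers)) {
    block <- lines[(bounds[i] + 1):(bounds[i + 1] - 1)]
    if (length(block) != 4)
      stop("expected 4 count rows after header ", lines[headers[i]])
    rows <- lapply(block, function(l) {
      l <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("ragged count rows after header ", lines[headers[i]])
    counts <- do.call(rbind, rows)
    hdr <- sub("^>\\s*", "", lines[headers[i]])
    parts <- strsplit(hdr, "[ \t]+")[[1]]
    name <- parts[length(parts)]
    out[[name]] <- pwm_from_counts(counts, tf_name = name,
                                   pseudocount = pseudocount,
                                   background = background)
  }
  out
}

#' Reverse complement of a DNA string
#'
#' @param seq character vector of sequences (ACGTN).
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# per-position log-odds lookup over a coded sequence; N (code NA) adds 0
score_windows <- function(codes, lo) {
  w <- ncol(lo)
  n_win <- length(codes) - w + 1
  if (n_win < 1) return(numeric(0))
  sc <- numeric(n_win)
  for (j in seq_len(w)) {
    contrib <- lo[codes[j:(j + n_win - 1)], j]
    contrib[is.na(contrib)] <- 0
    sc <- sc + contrib
  }
  sc
}

#' Scan sequences with a PWM
#'
#' Scores every window on both strands; a window is reported when its
#' log-odds score reaches `threshold_fraction` of the maximum achievable
#' score. Minus-strand windows are scored on the reverse complement and
#' reported at the forward coordinate of the window start. `N` bases
#' contribute 0 (background) to the score. Sequences shorter than the motif
#' are skipped with a warning.
#'
#' @param sequences named character vector of uppercase ACGTN sequences
#'   (names become `peak_id`s).
#' @param pwm a `pwm` object.
#' @param threshold_fraction fraction of the maximum achievable score
#'   (default 0.8).
#' @return Data frame of motif occurrences: `peak_id`, `offset` (0-based
#'   window start), `strand`, `score`.
#' @export
scan_pwm <- function(sequences, pwm, threshold_fraction = 0.8) {
  stopifnot(inherits(pwm, "pwm"), threshold_fraction > 0,
            threshold_fraction <= 1)
  lo <- pwm$log_odds
  w <- pwm$width
  max_score <- sum(apply(lo, 2, max))
  threshold <- threshold_fraction * max_score
  # minus strand = forward scan with the reverse-complemented matrix
  lo_rc <- lo[4:1, w:1, drop = FALSE]
  rownames(lo_rc) <- DNA_BASES
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  res <- list()
  for (id in names(sequences)) {
    s <- sequences[[id]]
    if (nchar(s) < w) {
      warning("sequence ", id, " shorter than motif; skipped")
      next
    }
    codes <- match(strsplit(s, "")[[1]], DNA_BASES)
    fwd <- score_windows(codes, lo)
    rev <- score_windows(codes, lo_rc)
    hit_f <- which(fwd >= threshold)
    hit_r <- which(rev >= threshold)
    if (length(hit_f))
      res[[length(res) + 1]] <- data.frame(
        peak_id = id, offset = hit_f - 1L, strand = "+",
        score = fwd[hit_f], stringsAsFactors = FALSE)
    if (length(hit_r))
      res[[length(res) + 1]] <- data.frame(
        peak_id = id, offset = hit_r - 1L, strand = "-",
        score = rev[hit_r], stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(peak_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
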