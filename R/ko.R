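#' Classify open regions by knockout fold change
#'
#' Per peak the stabilized fold change
#' `r = (wt + pseudocount) / (ko + pseudocount)` is computed; a peak is
#' `dependent` (on the deleted factor) when `r >= fold`, `independent`
#' (gained in the knockout) when `1 / r >= fold`, and `unchanged`
#' otherwise. The label partition is exhaustive and exclusive.
#'
#' @param wt,ko equal-length nonnegative per-peak accessibility values
#'   (counts or RPKM) for wildtype and knockout.
#' @param fold fold-change threshold, > 1 (default 2, the two-fold rule).
#' @param pseudocount added to both values for stability on low counts
#'   (default 0.5).
#' @return A `ko_classification`: list with `labels` (per peak),
#'   `fold_change` (r), `counts`, `fractions`, `fold`, `pseudocount`.
#' @export
classify_ko_peaks <- function(wt, ko, fold = 2, pseudocount = 0.5) {
  stopifnot(length(wt) == length(ko), fold > 1, length(wt) > 0)
  if (any(wt < 0) || any(ko < 0)) stop("negative accessibility values")
  r <- (wt + pseudocount) / (ko + pseudocount)
  labels <- ifelse(r >= fold, "dependent",
                   ifelse(1 / r >= fold, "independent", "unchanged"))
  lv <- c("dependent", "independent", "unchanged")
  counts <- vapply(lv, function(l) sum(labels == l), numeric(1))
  structure(list(labels = labels, fold_change = r, counts = counts,
                 fractions = counts / length(labels), fold = fold,
                 pseudocount = pseudocount),
            class = "ko_classification")
}

#' Fractions and printed percentages of a KO classification
#'
#' Percentages are `100 * count / total`, rounded half-up to one decimal
#' (so 20705/60761 prints as 34.1%); the exact ratios are reported
#' alongside.
#'
#' @param counts either a `ko_classification` or a named numeric vector of
#'   per-label counts.
#' @param total total number of peaks; defaults to `sum(counts)`.
#' @return Data frame `label`, `count`, `total`, `fraction`, `percent`
#'   (numeric, one decimal), `percent_string` (e.g. "34.1%").
#' @export
fraction_summary <- function(counts, total = NULL) {
  if (inherits(counts, "ko_classification")) counts <- counts$counts
  if (is.null(total)) total <- sum(counts)
  stopifnot(total > 0)
  pct <- round_half_up(100 * counts / total, 1)
  data.frame(label = names(counts), count = as.numeric(counts),
             total = total, fraction = as.numeric(counts) / total,
             percent = pct,
             percent_string = sprintf("%.1f%%", pct),
             stringsAsFactors = FALSE, row.names = NULL)
}

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Motif enrichment in dependent versus independent open regions
#'
#' Delegates to [motif_enrichment()] with the dependent peaks as
#' foreground and the independent peaks as background.
#'
#' @param classification a `ko_classification`.
#' @param peak_ids peak identifiers aligned with the classification labels.
#' @param occurrences named list, TF -> occurrence data frame (see
#'   [motif_enrichment()]).
#' @return Enrichment data frame (see [motif_enrichment()]).
#' @export
dependent_vs_independent_enrichment <- function(classification, peak_ids,
                                                occurrences) {
  stopifnot(length(peak_ids) == length(classification$labels))
  fg <- peak_ids[classification$labels == "dependent"]
  bg <- peak_ids[classification$labels == "independent"]
  if (!length(fg) || !length(bg))
    stop("both dependent and independent classes must be non-empty")
  motif_enrichment(occurrences, fg, bg)
}
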