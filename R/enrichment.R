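#' Motif enrichment in a peak set by Fisher's exact test
#'
#' Peaks are counted binarily (has at least one occurrence of the motif or
#' not) in the foreground and background sets; the one-sided Fisher exact
#' test asks whether the foreground proportion exceeds the background
#' proportion. q-values are Benjamini-Hochberg adjusted across the TFs
#' tested within one call.
#'
#' @param occurrences named list, TF name -> occurrence data frame from
#'   [scan_pwm()] (or one data frame with a `tf_name` column).
#' @param foreground,background disjoint character vectors of peak ids.
#' @return Data frame per TF: `tf_name`, `fg_hits`, `fg_total`,
#'   `fg_proportion`, `bg_hits`, `bg_total`, `bg_proportion`, `odds_ratio`
#'   (sample odds ratio), `p_value`, `q_value`.
#' @export
motif_enrichment <- function(occurrences, foreground, background) {
  if (!length(foreground)) stop("empty foreground peak set")
  if (length(intersect(foreground, background)))
    stop("foreground and background overlap")
  if (is.data.frame(occurrences))
    occurrences <- split(occurrences, occurrences$tf_name)
  rows <- lapply(names(occurrences), function(tf) {
    with_hit <- unique(occurrences[[tf]]$peak_id)
    a <- sum(foreground %in% with_hit)   # fg with motif
    b <- length(foreground) - a
    c_ <- sum(background %in% with_hit)  # bg with motif
    d <- length(background) - c_
    tab <- matrix(c(a, b, c_, d), 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    or <- (a * d) / (b * c_)
    data.frame(tf_name = tf, fg_hits = a, fg_total = length(foreground),
               fg_proportion = a / length(foreground), bg_hits = c_,
               bg_total = length(background),
               bg_proportion = if (length(background)) c_ / length(background)
                               else NA_real_,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$tf_name), , drop = FALSE]
}

#' Candidate regulators: enriched factors that are activated bivalent genes
#'
#' Intersects the factors whose motifs are enriched in the chosen peak
#' categories (typically II and III, the mid- and late-accessible regions)
#' with the set of activated bivalent genes, yielding an ordered candidate
#' regulator list (best q first, ties alphabetically).
#'
#' @param enrichment_by_category named list, category -> enrichment data
#'   frame from [motif_enrichment()].
#' @param activated_genes character vector of activated bivalent gene
#'   symbols (uppercase, shared namespace with TF names).
#' @param categories categories whose enriched TFs are pooled (default
#'   `c("II", "III")`).
#' @param alpha q-value cutoff for calling a motif enriched (default 0.05).
#' @return Data frame `tf_name`, `best_q`, sorted by `best_q` then name.
#' @export
candidate_regulators <- function(enrichment_by_category, activated_genes,
                                 categories = c("II", "III"),
                                 alpha = 0.05) {
  pool <- list()
  for (cat in intersect(categories, names(enrichment_by_category))) {
    e <- enrichment_by_category[[cat]]
    e <- e[e$q_value <= alpha, , drop = FALSE]
    pool[[cat]] <- e[, c("tf_name", "q_value")]
  }
  if (!length(pool))
    return(data.frame(tf_name = character(), best_q = numeric(),
                      stringsAsFactors = FALSE))
  pooled <- do.call(rbind, pool)
  best <- tapply(pooled$q_value, pooled$tf_name, min)
  hits <- intersect(names(best), activated_genes)
  out <- data.frame(tf_name = hits, best_q = as.numeric(best[hits]),
                    stringsAsFactors = FALSE)
  out[order(out$best_q, out$tf_name), , drop = FALSE]
}
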