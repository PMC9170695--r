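#' Fuzzy c-means clustering of temporal profiles
#'
#' Standard fuzzy c-means with alternating membership/centroid updates:
#' memberships are proportional to `d^(-2/(m-1))`, centroids are
#' `membership^m`-weighted means. The objective `sum(u^m d^2)` is
#' non-increasing across iterations; the best of `n_restarts` random
#' initializations (by final objective) is returned, deterministically for
#' a given seed.
#'
#' @param x rows-to-cluster numeric matrix (peaks x stages; typically
#'   z-scored).
#' @param c number of clusters (default 6).
#' @param m fuzzifier, > 1 (default 1.25; suits standardized profiles,
#'   where m = 2 over-fuzzifies).
#' @param seed integer seed.
#' @param tol convergence tolerance on the objective (default 1e-6).
#' @param max_iter maximum iterations (default 500).
#' @param n_restarts random restarts (default 10).
#' @return A `fuzzy_clustering`: `membership` (rows sum to 1), `centroids`
#'   (c x stages), `m`, `c`, `objective`, `objective_trace`,
#'   `hard_assignment` (argmax membership, ties to the lowest cluster
#'   index).
#' @export
fuzzy_cmeans <- function(x, c = 6, m = 1.25, seed = 1, tol = 1e-6,
                         max_iter = 500, n_restarts = 10) {
  stopifnot(is.matrix(x), nrow(x) >= c, m > 1, c >= 1)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- fcm_once(x, c, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(c(best, list(m = m, c = c,
                         hard_assignment = max.col(best$membership,
                                                   ties.method = "first"))),
            class = "fuzzy_clustering")
}

fcm_once <- function(x, c, m, tol, max_iter) {
  n <- nrow(x)
  centroids <- x[sample.int(n, c), , drop = FALSE]
  trace <- numeric(0)
  prev <- Inf
  u <- NULL
  for (iter in seq_len(max_iter)) {
    # re-seed centroids that collapsed onto each other
    if (c > 1) {
      dup <- duplicated(round(centroids, 12))
      if (any(dup)) {
        warning("re-seeding ", sum(dup), " collapsed centroid(s)")
        centroids[dup, ] <- x[sample.int(n, sum(dup)), , drop = FALSE]
      }
    }
    d2 <- sq_dist(x, centroids)
    u <- fcm_memberships(d2, m)
    obj <- sum(u^m * d2)
    trace <- c(trace, obj)
    if (abs(prev - obj) < tol) break
    prev <- obj
    um <- u^m
    centroids <- (t(um) %*% x) / colSums(um)
  }
  list(membership = u, centroids = centroids,
       objective = trace[length(trace)], objective_trace = trace)
}

sq_dist <- function(x, centroids) {
  n <- nrow(x); c <- nrow(centroids)
  d2 <- matrix(0, n, c)
  for (k in seq_len(c)) {
    d2[, k] <- rowSums(sweep(x, 2, centroids[k, ])^2)
  }
  d2
}

fcm_memberships <- function(d2, m) {
  expo <- 1 / (m - 1)
  w <- (1 / pmax(d2, 1e-300))^expo
  zero <- d2 < 1e-300
  u <- w / rowSums(w)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- zero[hit, , drop = FALSE] /
      rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Assign temporal clusters to stage categories
#'
#' For a 4-stage series, each cluster centroid is summarized by its mean
#' over the three consecutive stage pairs (stages 1+2, 2+3, 3+4); the
#' argmax pair assigns category I, II or III respectively (ties to the
#' earlier category). Category I peaks are most accessible early, category
#' III late.
#'
#' @param clustering a `fuzzy_clustering`.
#' @param stages stage labels; must have exactly 4 (categories are defined
#'   for the 4-stage design).
#' @return Character vector, cluster index -> "I", "II" or "III".
#' @export
assign_categories <- function(clustering, stages) {
  if (length(stages) != 4)
    stop("categories are defined only for a 4-stage series")
  cen <- clustering$centroids
  pair_means <- cbind((cen[, 1] + cen[, 2]) / 2,
                      (cen[, 2] + cen[, 3]) / 2,
                      (cen[, 3] + cen[, 4]) / 2)
  c("I", "II", "III")[apply(pair_means, 1, which.max)]
}

#' Nearest gene for each peak
#'
#' The gene whose TSS is closest to the peak midpoint on the same
#' chromosome; equidistant TSSs resolve to the smaller coordinate.
#'
#' @param peaks interval data frame.
#' @param annotation gene annotation data frame.
#' @return Character vector of gene ids, one per peak.
#' @export
nearest_gene <- function(peaks, annotation) {
  out <- character(nrow(peaks))
  mid <- (peaks$start + peaks$end) %/% 2
  for (chrom in unique(peaks$chrom)) {
    genes <- annotation[annotation$chrom == chrom, ]
    if (!nrow(genes)) stop("no genes on chromosome ", chrom)
    ord <- order(genes$tss)
    tss <- genes$tss[ord]
    ids <- genes$gene_id[ord]
    sel <- which(peaks$chrom == chrom)
    pos <- findInterval(mid[sel], tss)
    lo <- pmax(pos, 1)
    hi <- pmin(pos + 1, length(tss))
    d_lo <- abs(mid[sel] - tss[lo])
    d_hi <- abs(mid[sel] - tss[hi])
    # strict < keeps the smaller TSS on ties
    out[sel] <- ifelse(d_lo <= d_hi, ids[lo], ids[hi])
  }
  out
}

#' Mean nearest-gene expression per cluster and stage
#'
#' Each peak is attached to its nearest gene; per hard-assigned cluster and
#' stage the mean of log2(count + 1) over the cluster's peaks is reported.
#'
#' @param peaks interval data frame (rows match `clustering` membership
#'   rows).
#' @param annotation gene annotation data frame.
#' @param expression gene x stage count matrix (rownames = gene ids).
#' @param clustering a `fuzzy_clustering` over the same peaks.
#' @return Clusters x stages matrix of mean log2(count + 1); empty clusters
#'   give NA rows.
#' @export
nearest_gene_expression <- function(peaks, annotation, expression,
                                    clustering) {
  stopifnot(nrow(peaks) == nrow(clustering$membership))
  genes <- nearest_gene(peaks, annotation)
  stopifnot(all(genes %in% rownames(expression)))
  loge <- log2(expression[genes, , drop = FALSE] + 1)
  k <- clustering$c
  out <- matrix(NA_real_, k, ncol(expression),
                dimnames = list(paste0("cluster", seq_len(k)),
                                colnames(expression)))
  for (cl in seq_len(k)) {
    sel <- clustering$hard_assignment == cl
    if (any(sel)) out[cl, ] <- colMeans(loge[sel, , drop = FALSE])
  }
  out
}
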