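# shared fixtures: built once per test run, in code

# tiny config exercising every component quickly
tiny_config <- function(seed = 11, ...) {
  synthetic_config(seed = seed, n_genes = 40, n_intergenic_peaks = 120, ...)
}

# adjusted Rand index (independent of any clustering package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# hypergeometric upper-tail oracle for a 2x2 table: P(X >= a) where X is
# the count in cell (1,1) with margins fixed
hyper_tail_p <- function(a, b, c_, d) {
  m <- a + b      # foreground total
  n <- c_ + d     # background total
  k <- a + c_     # total with the property
  xs <- max(0, k - n):min(k, m)
  sum(stats::dhyper(xs[xs >= a], m, n, k))
}

# joint probability of a state path under an HMM, by direct product
# (enumeration oracle, independent of the package's recursions)
path_prob_oracle <- function(path, sym, pi, A, B) {
  p <- pi[path[1]] * B[path[1], sym[1]]
  for (t in seq_along(path)[-1])
    p <- p * A[path[t - 1], path[t]] * B[path[t], sym[t]]
  p
}

# uniform Dirichlet draw (probability vector)
gtools_rdirichlet <- function(k) {
  x <- rgamma(k, 1)
  x / sum(x)
}

# all state paths of length L over K states
all_paths <- function(K, L) {
  as.matrix(expand.grid(rep(list(seq_len(K)), L)))
}

# bedGraph written from a record data frame
write_bedgraph_records <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# segmentation built from explicit per-bin labels
segmentation_from_labels <- function(labels_by_chrom, bin_size) {
  labs <- sort(unique(unlist(labels_by_chrom)))
  states <- lapply(labels_by_chrom, function(v) match(v, labs))
  chromatin_segmentation(states, labs, bin_size)
}
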