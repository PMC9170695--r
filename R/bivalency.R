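#' Call per-gene promoter chromatin states
#'
#' A gene is bivalent when its promoter window (TSS +/- `flank`) overlaps
#' bivalent segments by strictly more than `min_bivalent_overlap` bp in
#' total (aggregated across segments, so bin-edge fragmentation of a domain
#' does not break the call). Otherwise the non-bivalent label with the
#' largest promoter overlap wins, ties broken by the priority
#' H3K4me3_only > H3K27me3_only > unmarked.
#'
#' @param segmentation a `chromatin_segmentation`.
#' @param annotation gene annotation data frame (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param stage stage label recorded in the output (default `NA`).
#' @param flank promoter half-width in bp (default 2500).
#' @param min_bivalent_overlap bp of bivalent overlap that must be exceeded
#'   (default 200).
#' @return Data frame with `gene_id`, `stage`, `state`, `bivalent_overlap`.
#' @export
call_promoter_state <- function(segmentation, annotation, chrom_sizes,
                                stage = NA_character_, flank = 2500,
                                min_bivalent_overlap = 200) {
  labels_by_chrom <- segmentation_labels(segmentation)
  missing_chrom <- setdiff(unique(annotation$chrom), names(labels_by_chrom))
  if (length(missing_chrom)) {
    genes <- annotation$gene_id[annotation$chrom %in% missing_chrom]
    stop("genes on chromosomes absent from segmentation: ",
         paste(utils::head(genes, 5), collapse = ", "))
  }
  bs <- segmentation$bin_size
  non_biv <- c("H3K4me3_only", "H3K27me3_only", "unmarked")
  out_state <- character(nrow(annotation))
  out_biv <- numeric(nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    w <- promoter_window(g, flank, chrom_sizes)
    labs <- labels_by_chrom[[g$chrom]]
    b0 <- w$start %/% bs
    b1 <- min((w$end - 1) %/% bs, length(labs) - 1)
    b <- b0:b1
    ov <- pmin(w$end, (b + 1) * bs) - pmax(w$start, b * bs)
    by_label <- tapply(ov, labs[b + 1], sum)
    biv <- if ("bivalent" %in% names(by_label)) by_label[["bivalent"]] else 0
    out_biv[i] <- biv
    if (biv > min_bivalent_overlap) {
      out_state[i] <- "bivalent"
    } else {
      cand <- setNames(rep(0, 3), non_biv)
      present <- intersect(names(by_label), non_biv)
      cand[present] <- by_label[present]
      # which.max respects the priority order of `non_biv` on ties
      out_state[i] <- non_biv[which.max(cand)]
    }
  }
  data.frame(gene_id = annotation$gene_id, stage = stage, state = out_state,
             bivalent_overlap = out_biv, stringsAsFactors = FALSE)
}

#' Classify the fate of bivalent promoters between two stages
#'
#' For every gene bivalent at the earlier stage, the later-stage state
#' determines the transition mode: still bivalent -> `stable_bivalent`;
#' H3K4me3_only -> `activated` (the domain resolved by losing H3K27me3);
#' H3K27me3_only -> `repressed`; unmarked -> `resolved_unmarked`.
#'
#' @param calls_a,calls_b promoter state calls (from
#'   [call_promoter_state()]) for the earlier and later stage; must cover
#'   the same genes.
#' @return List with `records` (data frame `gene_id`, `stage_pair`, `mode`)
#'   and `summary` (list with `stage_pair`, `n_bivalent_start`, per-mode
#'   `counts` and `ratios`; ratios sum to 1 when any gene was bivalent, and
#'   are reported as 0 with `degenerate = TRUE` otherwise).
#' @export
classify_bivalent_transitions <- function(calls_a, calls_b) {
  if (!setequal(calls_a$gene_id, calls_b$gene_id))
    stop("stage call sets cover different genes")
  modes <- c(stable_bivalent = "bivalent", activated = "H3K4me3_only",
             repressed = "H3K27me3_only", resolved_unmarked = "unmarked")
  b <- calls_b$state[match(calls_a$gene_id, calls_b$gene_id)]
  sel <- calls_a$state == "bivalent"
  stage_pair <- paste0(calls_a$stage[1], "->", calls_b$stage[1])
  mode <- names(modes)[match(b[sel], modes)]
  records <- data.frame(gene_id = calls_a$gene_id[sel],
                        stage_pair = rep_len(stage_pair, sum(sel)),
                        mode = mode, stringsAsFactors = FALSE)
  counts <- vapply(names(modes), function(m) sum(mode == m), numeric(1))
  n0 <- sum(sel)
  summary <- list(stage_pair = stage_pair, n_bivalent_start = n0,
                  counts = counts,
                  ratios = if (n0 > 0) counts / n0 else counts * 0,
                  degenerate = n0 == 0)
  list(records = records, summary = summary)
}

#' Activated bivalent genes per successive stage pair
#'
#' Genes whose bivalent promoter resolves to H3K4me3-only between each pair
#' of successive stages. Sets for different pairs may share members (a gene
#' can regain bivalency and resolve again).
#'
#' @param calls_by_stage list of promoter state call data frames, in stage
#'   order (length >= 2).
#' @return Named list, `"A->B"` -> character vector of gene ids.
#' @export
activated_gene_sets <- function(calls_by_stage) {
  stopifnot(length(calls_by_stage) >= 2)
  out <- list()
  for (i in seq_len(length(calls_by_stage) - 1)) {
    tr <- classify_bivalent_transitions(calls_by_stage[[i]],
                                        calls_by_stage[[i + 1]])
    out[[tr$summary$stage_pair]] <-
      tr$records$gene_id[tr$records$mode == "activated"]
  }
  out
}

#' Promoter-level correlation of expression and chromatin assays
#'
#' Per stage, builds per-gene feature vectors log2(expression + 1) and
#' log2(promoter-window summed signal + 1) for each assay track, and returns
#' the matrix of pairwise Pearson correlations. Zero-variance features give
#' missing (NA) correlations rather than an error.
#'
#' @param expression gene x stage numeric matrix (rownames = gene ids).
#' @param tracks_by_stage list: stage -> named list of [signal_track()]s
#'   (e.g. H3K4me3, H3K27me3, ATAC).
#' @param annotation gene annotation data frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param flank promoter half-width in bp (default 2500).
#' @return Named list, stage -> symmetric Pearson correlation matrix over
#'   (expression, assays).
#' @export
promoter_signal_correlation <- function(expression, tracks_by_stage,
                                        annotation, chrom_sizes,
                                        flank = 2500) {
  stopifnot(all(annotation$gene_id %in% rownames(expression)))
  lapply(setNames(names(tracks_by_stage), names(tracks_by_stage)),
         function(stage) {
    feats <- list(expression =
                    log2(expression[annotation$gene_id, stage] + 1))
    for (assay in names(tracks_by_stage[[stage]])) {
      s <- promoter_signal_sums(tracks_by_stage[[stage]][[assay]],
                                annotation, flank, chrom_sizes)
      feats[[assay]] <- log2(s + 1)
    }
    m <- do.call(cbind, feats)
    suppressWarnings(cor(m, method = "pearson"))
  })
}
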