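#' Default archetype profiles for temporal accessibility
#'
#' Six stage-profiles in `[0, 1]` over a 4-stage series, two per category:
#' category I peaks are open early (stages 1-2), category II in the middle
#' (stages 2-3), category III late (stages 3-4).
#'
#' @return 6 x 4 numeric matrix with an `categories` attribute.
#' @export
default_archetypes <- function() {
  # every stage column carries the same multiset of levels
  # {1, 0.7, 0.3, 0.1, 0, 0}, so cross-stage quantile normalization is
  # close to the identity and cannot crush any archetype's shape
  p <- rbind(
    c(1.00, 0.70, 0.10, 0.00),  # I: broad early, closes on differentiation
    c(0.70, 0.10, 0.00, 0.00),  # I: pluripotency-restricted
    c(0.30, 1.00, 0.70, 0.30),  # II: broad transient mid-course
    c(0.00, 0.30, 1.00, 0.10),  # II: sharp mid-course spike
    c(0.00, 0.00, 0.30, 0.70),  # III: opens late, moderate early rise
    c(0.10, 0.00, 0.00, 1.00)   # III: endpoint-restricted
  )
  attr(p, "categories") <- c("I", "I", "II", "II", "III", "III")
  p
}

#' Built-in position count matrices for the planted factors
#'
#' Strong-consensus 8-bp count matrices for the five factors the simulator
#' plants: POU5F1 (octamer, category I), GATA2 and SOX17 (category II),
#' RUNX1 and JUNB (category III). Counts are 18 on the consensus base, so
#' with the default pseudocount essentially only exact consensus matches
#' pass an 0.8-of-maximum scanning threshold.
#'
#' @return Named list of 4 x 8 count matrices (rows A, C, G, T).
#' @export
default_motif_counts <- function() {
  consensus <- c(POU5F1 = "ATGCAAAT", GATA2 = "AGATAAGA",
                 SOX17 = "AACAATGG", RUNX1 = "TGTGGTTT", JUNB = "TGACTCAT")
  lapply(consensus, function(s) {
    bases <- strsplit(s, "")[[1]]
    m <- matrix(0, 4, length(bases), dimnames = list(DNA_BASES, NULL))
    m[cbind(match(bases, DNA_BASES), seq_along(bases))] <- 18
    m
  })
}

#' Synthetic-dataset configuration
#'
#' Bundles every parameter of the generator with defaults chosen to mimic
#' a 4-stage differentiation time course: planted promoter chromatin
#' states with a 20% activated bivalent-resolution rate at the first
#' transition, six accessibility archetypes in three categories,
#' category-specific motif planting, state-coupled negative-binomial
#' expression, footprint-shaped cut-site dips (factor 0.5 over the motif
#' core), and a WT/KO pair with planted dependent/independent fractions.
#'
#' @param seed root seed; submodule streams are derived by fixed offsets.
#' @param n_chroms,n_genes,n_intergenic_peaks genome geometry.
#' @param chrom_length bp per chromosome; `NULL` sizes it to fit the
#'   geometry.
#' @param bin_size signal bin width in bp (default 200).
#' @param stages ordered stage labels.
#' @param flank promoter half-width in bp.
#' @param state_proportions initial (first-stage) promoter state mix.
#' @param mode_proportions bivalent transition-mode mix per stage pair
#'   (must sum to 1); default activated 0.20, stable 0.70, repressed 0.05,
#'   resolved-unmarked 0.05.
#' @param lambda_lo,lambda_hi Poisson bin rates for unmarked vs marked
#'   regions (default 2 / 20, a 10x contrast).
#' @param archetype_profiles 6 x 4 profile matrix with a `categories`
#'   attribute (see [default_archetypes()]).
#' @param motif_assignments named character vector, TF -> category.
#' @param motif_counts named list of count matrices for those TFs.
#' @param motif_planting_rate probability a peak of the assigned category
#'   carries a planted motif instance (default 0.4).
#' @param candidate_tfs TFs forced to be activated bivalent genes (the
#'   planted candidate-regulator truth).
#' @param noncandidate_tfs TFs forced not activated (enrichment decoys).
#' @param nb_mean_by_state expression means per promoter state
#'   (H3K4me3-only highest).
#' @param nb_dispersion negative-binomial size parameter; `Inf` gives the
#'   Poisson limit.
#' @param peak_width,atac_base,atac_scale,atac_presence_min intergenic peak
#'   geometry and expected ATAC coverage model (peak present in a stage's
#'   BED iff expected coverage exceeds `atac_presence_min`).
#' @param cut_base,cut_rate per-bp cut-count rates outside/inside open
#'   peaks.
#' @param footprint_dip multiplicative dip of the cut rate over the motif
#'   core (default 0.5).
#' @param ko_dependent_fraction,ko_independent_fraction,ko_fold,ko_wt_mean
#'   knockout contrast: fractions of peaks attenuated / gained by
#'   `ko_fold`, and the mean WT per-peak count.
#' @param with_sequence,with_cuts generate genome sequence / bp-resolution
#'   cut tracks (disable to simulate large gene sets cheaply).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1,
    n_chroms = 2,
    n_genes = 150,
    n_intergenic_peaks = 450,
    chrom_length = NULL,
    bin_size = 200,
    stages = c("hPSC", "VME", "EPC", "HPC"),
    flank = 2500,
    state_proportions = c(bivalent = 0.40, H3K4me3_only = 0.25,
                          H3K27me3_only = 0.15, unmarked = 0.20),
    mode_proportions = c(activated = 0.20, stable_bivalent = 0.70,
                         repressed = 0.05, resolved_unmarked = 0.05),
    lambda_lo = 2,
    lambda_hi = 20,
    archetype_profiles = default_archetypes(),
    motif_assignments = c(POU5F1 = "I", GATA2 = "II", SOX17 = "II",
                          RUNX1 = "III", JUNB = "III"),
    motif_counts = default_motif_counts(),
    motif_planting_rate = 0.4,
    candidate_tfs = c("GATA2", "RUNX1", "JUNB"),
    noncandidate_tfs = c("POU5F1", "SOX17"),
    nb_mean_by_state = c(H3K4me3_only = 120, bivalent = 12,
                         H3K27me3_only = 6, unmarked = 10),
    nb_dispersion = 5,
    peak_width = 400,
    atac_base = 3,
    atac_scale = 200,
    atac_presence_min = 60,
    cut_base = 0.2,
    cut_rate = 10,
    footprint_dip = 0.5,
    ko_dependent_fraction = 0.341,
    ko_independent_fraction = 0.133,
    ko_fold = 4,
    ko_wt_mean = 50,
    with_sequence = TRUE,
    with_cuts = TRUE) {
  stopifnot(abs(sum(mode_proportions) - 1) < 1e-9,
            abs(sum(state_proportions) - 1) < 1e-9,
            lambda_hi > lambda_lo, lambda_lo >= 0,
            ko_dependent_fraction >= 0, ko_dependent_fraction <= 1,
            length(stages) >= 2, !anyDuplicated(stages))
  if (ko_dependent_fraction + ko_independent_fraction > 1)
    stop("KO fractions sum to more than 1")
  cfg <- as.list(environment())
  # each gene gets one slot: the 2*flank promoter window followed by a
  # 20 kb intergenic stretch that hosts up to 11 peak slots; keeping
  # promoters a small fraction of the genome keeps the genome-wide mean
  # (the binarization background) close to lambda_lo, as in real data
  cfg$gene_slot <- 2 * flank + 20000
  cfg$peak_slot <- 1500
  class(cfg) <- "synthetic_config"
  cfg
}

slot_geometry <- function(config) {
  genes_per <- ceiling(config$n_genes / config$n_chroms)
  peaks_per_slot <- ceiling(config$n_intergenic_peaks / config$n_genes)
  max_slots <- (config$gene_slot - 2 * config$flank - 3000) %/%
    config$peak_slot
  if (peaks_per_slot > max_slots)
    stop("genome geometry infeasible: ", peaks_per_slot,
         " peaks per gene slot exceed the ", max_slots, " available")
  required <- genes_per * config$gene_slot + 2 * config$bin_size
  len <- config$chrom_length
  if (is.null(len)) len <- required
  if (required > len)
    stop("genome geometry infeasible: need ", required,
         " bp per chromosome, have ", len)
  list(genes_per = genes_per, peaks_per_slot = peaks_per_slot,
       chrom_length = len)
}

#' Simulate the genome skeleton: sequence, annotation, truth tables
#'
#' Lays out non-overlapping promoter slots (so promoter-state truth is
#' unambiguous) and intergenic peak slots on `n_chroms` chromosomes, draws
#' an i.i.d. uniform background sequence, assigns every gene a first-stage
#' promoter state and, for bivalent promoters, a transition mode per stage
#' pair; a handful of genes are renamed to the planted TF symbols with
#' forced fates (candidate TFs: bivalent then activated; decoys: never
#' activated). Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return List: `sequences` (named character, or NULL when
#'   `with_sequence = FALSE`), `chrom_sizes`, `annotation`, `truth`
#'   (list with `genes` state/mode tables and a `peaks` skeleton).
#' @export
simulate_genome <- function(config) {
  geo <- slot_geometry(config)
  set.seed(as.integer(config$seed) + 1L)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(geo$chrom_length, config$n_chroms), chroms)

  # genes fill slots chromosome by chromosome; peaks fill the intergenic
  # stretch of the slots round-robin so every peak has a well-defined
  # nearest gene
  gene_chrom_i <- pmin((seq_len(config$n_genes) - 1) %/% geo$genes_per + 1,
                       config$n_chroms)
  slot_in_chrom <- (seq_len(config$n_genes) - 1) %% geo$genes_per
  slot_start <- slot_in_chrom * config$gene_slot
  annotation <- data.frame(
    gene_id = sprintf("GENE%05d", seq_len(config$n_genes)),
    chrom = chroms[gene_chrom_i],
    tss = slot_start + config$flank,
    strand = rep_len(c("+", "-"), config$n_genes),
    stringsAsFactors = FALSE)

  host <- (seq_len(config$n_intergenic_peaks) - 1) %% config$n_genes + 1
  rank <- (seq_len(config$n_intergenic_peaks) - 1) %/% config$n_genes
  start <- slot_start[host] + 2 * config$flank + 1500 +
    rank * config$peak_slot
  peak_tab <- data.frame(
    peak_id = sprintf("PEAK%05d", seq_len(config$n_intergenic_peaks)),
    chrom = chroms[gene_chrom_i[host]],
    start = start, end = start + config$peak_width,
    stringsAsFactors = FALSE)
  peak_tab <- peak_tab[order(peak_tab$chrom, peak_tab$start), ]
  rownames(peak_tab) <- NULL

  # rename planted TF genes; spread them over the first slots
  tfs <- c(config$candidate_tfs, config$noncandidate_tfs)
  if (nrow(annotation) < length(tfs))
    stop("need at least ", length(tfs), " genes for the planted TFs")
  annotation$gene_id[seq_along(tfs)] <- tfs
  annotation <- annotation[, c("gene_id", "chrom", "tss", "strand")]

  truth <- list(
    genes = plant_gene_states(annotation, config),
    peaks = peak_tab
  )
  sequences <- NULL
  if (config$with_sequence) {
    sequences <- setNames(lapply(chrom_sizes, function(len) {
      paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    }), chroms)
  }
  list(sequences = sequences, chrom_sizes = chrom_sizes,
       annotation = annotation, truth = truth)
}

# first-stage states + per-pair transition modes; forced fates for TFs
plant_gene_states <- function(annotation, config) {
  n <- nrow(annotation)
  stages <- config$stages
  n_pairs <- length(stages) - 1
  mode_next_state <- c(activated = "H3K4me3_only",
                       stable_bivalent = "bivalent",
                       repressed = "H3K27me3_only",
                       resolved_unmarked = "unmarked")
  states <- matrix(NA_character_, n, length(stages),
                   dimnames = list(annotation$gene_id, stages))
  modes <- matrix(NA_character_, n, n_pairs,
                  dimnames = list(annotation$gene_id,
                                  paste0(stages[-length(stages)], "->",
                                         stages[-1])))
  states[, 1] <- sample(names(config$state_proportions), n, replace = TRUE,
                        prob = config$state_proportions)
  states[config$candidate_tfs, 1] <- "bivalent"
  states[config$noncandidate_tfs, 1] <- "bivalent"
  for (p in seq_len(n_pairs)) {
    cur <- states[, p]
    nxt <- cur  # non-bivalent promoters keep their state
    biv <- which(cur == "bivalent")
    if (length(biv)) {
      # exact-count planting: each mode gets round(proportion * n) genes
      # (largest remainder), randomly permuted, so the planted ratios are
      # recoverable from the truth tables exactly
      m <- sample(rep(names(config$mode_proportions),
                      exact_counts(length(biv), config$mode_proportions)))
      names(m) <- annotation$gene_id[biv]
      forced <- c(setNames(rep("activated", length(config$candidate_tfs)),
                           config$candidate_tfs),
                  setNames(rep("stable_bivalent",
                               length(config$noncandidate_tfs)),
                           config$noncandidate_tfs))
      if (p > 1) forced <- forced[names(forced) %in%
                                    config$noncandidate_tfs]
      m <- force_modes(m, forced[names(forced) %in% names(m)])
      modes[biv, p] <- m
      nxt[biv] <- mode_next_state[m]
    }
    states[, p + 1] <- nxt
  }
  list(states = states, modes = modes)
}

# integer split of n by proportions, largest remainder
exact_counts <- function(n, prob) {
  raw <- n * prob / sum(prob)
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base
}

# pin named genes to required modes by swapping labels with unconstrained
# genes, leaving the overall mode counts untouched
force_modes <- function(m, forced) {
  for (g in names(forced)) {
    want <- forced[[g]]
    if (m[[g]] == want) next
    pool <- setdiff(names(m)[m == want], names(forced))
    if (!length(pool)) { m[[g]] <- want; next }  # degenerate tiny inputs
    m[[pool[1]]] <- m[[g]]
    m[[g]] <- want
  }
  m
}

#' Simulate per-stage histone-mark and promoter-accessibility tracks
#'
#' Bin counts are Poisson: rate `lambda_hi` over the promoter window for
#' each mark the gene's planted state carries at that stage (bivalent
#' promoters emit both marks), `lambda_lo` elsewhere. An ATAC promoter
#' track is emitted alongside, open (`lambda_hi`) at H3K4me3-only
#' promoters, partially open (0.6 x) at bivalent ones.
#'
#' @param genome output of [simulate_genome()].
#' @param config the [synthetic_config()].
#' @return Named list, stage -> list of [signal_track()]s (`H3K4me3`,
#'   `H3K27me3`, `ATAC`).
#' @export
simulate_chip_tracks <- function(genome, config) {
  set.seed(as.integer(config$seed) + 2L)
  bs <- config$bin_size
  ann <- genome$annotation
  states <- genome$truth$genes$states
  n_bins <- ceiling(genome$chrom_sizes / bs)
  out <- list()
  for (stage in config$stages) {
    st <- states[ann$gene_id, stage]
    rates <- list(
      H3K4me3 = ifelse(st %in% c("H3K4me3_only", "bivalent"),
                       config$lambda_hi, config$lambda_lo),
      H3K27me3 = ifelse(st %in% c("H3K27me3_only", "bivalent"),
                        config$lambda_hi, config$lambda_lo),
      ATAC = ifelse(st == "H3K4me3_only", config$lambda_hi,
                    ifelse(st == "bivalent", 0.6 * config$lambda_hi,
                           config$lambda_lo))
    )
    tracks <- lapply(rates, function(r) {
      bins <- lapply(seq_along(n_bins), function(ci) {
        chrom <- names(n_bins)[ci]
        rate <- rep(config$lambda_lo, n_bins[ci])
        sel <- which(ann$chrom == chrom)
        for (i in sel) {
          b0 <- max(0, ann$tss[i] - config$flank) %/% bs
          b1 <- min((ann$tss[i] + config$flank - 1) %/% bs, n_bins[ci] - 1)
          rate[(b0 + 1):(b1 + 1)] <- r[i]
        }
        rpois(n_bins[ci], rate)
      })
      names(bins) <- names(n_bins)
      signal_track(bins, bs)
    })
    out[[stage]] <- tracks
  }
  out
}

#' Simulate the gene-by-stage expression count matrix
#'
#' Counts are negative binomial with a state-dependent mean (H3K4me3-only
#' promoters highest) and common dispersion; `nb_dispersion = Inf` gives
#' the Poisson limit. Deterministic given the config seed.
#'
#' @param genome output of [simulate_genome()].
#' @param config the [synthetic_config()].
#' @return Gene x stage integer matrix (rownames = gene ids).
#' @export
simulate_expression <- function(genome, config) {
  set.seed(as.integer(config$seed) + 4L)
  states <- genome$truth$genes$states
  mu <- matrix(config$nb_mean_by_state[states], nrow(states),
               dimnames = dimnames(states))
  counts <- if (is.infinite(config$nb_dispersion)) {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), mu = mu, size = config$nb_dispersion)
  }
  matrix(counts, nrow(states), dimnames = dimnames(states))
}

#' Simulate the WT/KO accessibility contrast
#'
#' A planted fraction of peaks has knockout expected counts attenuated by
#' `ko_fold` (dependent), a disjoint fraction gains `ko_fold`-fold
#' (independent), the rest are unchanged; `ko_fold = 1` labels everything
#' unchanged. Observed counts are Poisson around per-peak WT means.
#'
#' @param genome output of [simulate_genome()].
#' @param config the [synthetic_config()].
#' @return List: `wt`, `ko` (per-peak counts), `labels` (planted truth),
#'   `peak_id`.
#' @export
simulate_ko <- function(genome, config) {
  set.seed(as.integer(config$seed) + 5L)
  n <- nrow(genome$truth$peaks)
  n_dep <- round(config$ko_dependent_fraction * n)
  n_ind <- round(config$ko_independent_fraction * n)
  if (n_dep + n_ind > n) stop("KO fractions sum to more than 1")
  labels <- rep("unchanged", n)
  pick <- sample.int(n, n_dep + n_ind)
  labels[pick[seq_len(n_dep)]] <- "dependent"
  if (n_ind > 0) labels[pick[n_dep + seq_len(n_ind)]] <- "independent"
  if (config$ko_fold == 1) labels[] <- "unchanged"
  wt_mu <- config$ko_wt_mean * runif(n, 0.6, 1.4)
  ko_mu <- wt_mu
  ko_mu[labels == "dependent"] <- wt_mu[labels == "dependent"] / config$ko_fold
  ko_mu[labels == "independent"] <- wt_mu[labels == "independent"] *
    config$ko_fold
  list(wt = rpois(n, wt_mu), ko = rpois(n, ko_mu), labels = labels,
       peak_id = genome$truth$peaks$peak_id)
}
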