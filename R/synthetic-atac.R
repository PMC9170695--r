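motif_consensus <- function(counts) {
  paste(DNA_BASES[apply(counts, 2, which.max)], collapse = "")
}

#' Simulate ATAC peaks, sequences, motif planting and cut-site tracks
#'
#' Every intergenic peak is assigned one of the six temporal archetypes
#' (near-equal counts, shuffled); its per-stage expected coverage follows
#' the archetype profile, and it appears in a stage's peak BED iff that
#' expected coverage exceeds `atac_presence_min`. Peaks of a motif's
#' assigned category carry a planted consensus instance with probability
#' `motif_planting_rate` (uniform choice among the category's factors,
#' random offset away from the edges, random strand), written into the
#' genome sequence so peak FASTA and genome coordinates agree. Cut-count
#' tracks at bp resolution have rate `cut_base + cut_rate * profile` over
#' each peak, multiplied by `footprint_dip` over the motif core at stages
#' where the profile is high (>= 0.5) — the planted footprint.
#'
#' @param genome output of [simulate_genome()] (with sequences when motif
#'   planting or peak FASTA is wanted).
#' @param config the [synthetic_config()].
#' @return List: `peaks` (truth-annotated peak table with archetype,
#'   category and motif placement columns), `counts` (peaks x stages),
#'   `stage_beds` (stage -> interval data frame of present peaks),
#'   `sequences` (genome sequences with motifs inserted, or NULL),
#'   `peak_fasta` (named peak sequences, or NULL), `cut_tracks`
#'   (stage -> bp-resolution [signal_track()], or NULL), `library_sizes`.
#' @export
simulate_atac <- function(genome, config) {
  set.seed(as.integer(config$seed) + 3L)
  peaks <- genome$truth$peaks
  n <- nrow(peaks)
  profiles <- config$archetype_profiles
  cats <- attr(profiles, "categories")
  peaks$archetype <- sample(rep_len(seq_len(nrow(profiles)), n))
  peaks$category <- cats[peaks$archetype]
  # per-peak overall strength (log-normal), as real peaks vary in
  # amplitude; row z-scoring cancels it, but it keeps the per-stage count
  # distributions continuous
  peaks$strength <- exp(rnorm(n, 0, 0.25))

  expected <- config$atac_base +
    config$atac_scale * peaks$strength *
      profiles[peaks$archetype, , drop = FALSE]
  colnames(expected) <- config$stages
  counts <- matrix(rpois(length(expected), expected), n,
                   dimnames = list(peaks$peak_id, config$stages))

  # motif planting
  peaks$motif_tf <- NA_character_
  peaks$motif_offset <- NA_integer_
  peaks$motif_strand <- NA_character_
  widths <- vapply(config$motif_counts, ncol, numeric(1))
  if (any(widths > config$peak_width))
    stop("motif longer than peak width")
  for (i in seq_len(n)) {
    tfs <- names(config$motif_assignments)[
      config$motif_assignments == peaks$category[i]]
    if (!length(tfs) || runif(1) >= config$motif_planting_rate) next
    tf <- if (length(tfs) == 1) tfs else sample(tfs, 1)
    w <- widths[[tf]]
    lo <- min(100, config$peak_width - w)
    hi <- max(lo, config$peak_width - w - 100)
    peaks$motif_tf[i] <- tf
    peaks$motif_offset[i] <- if (hi > lo) sample(lo:hi, 1) else lo
    peaks$motif_strand[i] <- sample(c("+", "-"), 1)
  }

  sequences <- genome$sequences
  peak_fasta <- NULL
  if (!is.null(sequences)) {
    consensus <- vapply(config$motif_counts, motif_consensus, "")
    planted <- which(!is.na(peaks$motif_tf))
    for (i in planted) {
      s <- consensus[[peaks$motif_tf[i]]]
      if (peaks$motif_strand[i] == "-") s <- reverse_complement(s)
      at <- peaks$start[i] + peaks$motif_offset[i]
      substr(sequences[[peaks$chrom[i]]], at + 1, at + nchar(s)) <- s
    }
    peak_fasta <- setNames(vapply(seq_len(n), function(i) {
      substr(sequences[[peaks$chrom[i]]], peaks$start[i] + 1, peaks$end[i])
    }, ""), peaks$peak_id)
  }

  stage_beds <- lapply(setNames(config$stages, config$stages),
                       function(stage) {
    sel <- expected[, stage] > config$atac_presence_min
    genomic_intervals(peaks$chrom[sel], peaks$start[sel], peaks$end[sel],
                      name = peaks$peak_id[sel])
  })

  cut_tracks <- NULL
  if (config$with_cuts) {
    cut_tracks <- lapply(setNames(config$stages, config$stages),
                         function(stage) {
      bins <- lapply(genome$chrom_sizes, function(len) {
        rep(config$cut_base, len)
      })
      prof <- profiles[peaks$archetype, match(stage, config$stages)]
      for (i in seq_len(n)) {
        idx <- (peaks$start[i] + 1):peaks$end[i]
        bins[[peaks$chrom[i]]][idx] <- config$cut_base +
          config$cut_rate * prof[i]
        if (!is.na(peaks$motif_tf[i]) && prof[i] >= 0.5) {
          w <- widths[[peaks$motif_tf[i]]]
          at <- peaks$start[i] + peaks$motif_offset[i]
          core <- (at + 1):(at + w)
          bins[[peaks$chrom[i]]][core] <-
            bins[[peaks$chrom[i]]][core] * config$footprint_dip
        }
      }
      signal_track(lapply(bins, function(r) rpois(length(r), r)), 1)
    })
  }

  genome$truth$peaks <- peaks
  list(peaks = peaks, counts = counts, stage_beds = stage_beds,
       sequences = sequences, peak_fasta = peak_fasta,
       cut_tracks = cut_tracks,
       library_sizes = colSums(counts))
}

#' Run the full synthetic generator
#'
#' Chains genome, ChIP tracks, ATAC, expression and KO simulation under
#' one root seed (submodule streams use fixed offsets, so the pieces can
#' also be regenerated independently). The result is a pure function of
#' the config: identical configs give identical output.
#'
#' @param config a [synthetic_config()].
#' @return List with `config`, `genome`, `chip_tracks`, `atac`,
#'   `expression`, `ko`, and `truth` (gene and peak truth tables, with the
#'   ATAC/KO plantings filled in).
#' @export
simulate_all <- function(config = synthetic_config()) {
  genome <- simulate_genome(config)
  chip <- simulate_chip_tracks(genome, config)
  atac <- simulate_atac(genome, config)
  expr <- simulate_expression(genome, config)
  ko <- simulate_ko(genome, config)
  truth <- genome$truth
  truth$peaks <- atac$peaks
  truth$peaks$ko_label <- ko$labels
  list(config = config, genome = genome, chip_tracks = chip, atac = atac,
       expression = expr, ko = ko, truth = truth)
}
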