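#' Pipeline run configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or `input_dir` (a
#' directory holding a dataset in the layout of
#' [write_synthetic_dataset()]) must be given; every module parameter has
#' the documented default.
#'
#' @param synthetic a [synthetic_config()], or NULL.
#' @param input_dir dataset directory, or NULL.
#' @param stages stage labels (required for `input_dir` mode; taken from
#'   the synthetic config otherwise).
#' @param seed seed for the HMM and clustering fits.
#' @param ... module parameter overrides (see [validate_config()]).
#' @return An unvalidated `run_config` list.
#' @export
run_config <- function(synthetic = NULL, input_dir = NULL, stages = NULL,
                       seed = 1, ...) {
  structure(c(list(synthetic = synthetic, input_dir = input_dir,
                   stages = stages, seed = seed), list(...)),
            class = "run_config")
}

#' Validate and normalize a run configuration
#'
#' Fills defaults, resolves paths and rejects contradictory settings
#' (both or neither input mode; category assignment on a non-4-stage
#' series).
#'
#' @param config a [run_config()].
#' @return The normalized config with all defaults present.
#' @export
validate_config <- function(config) {
  defaults <- list(
    bin_size = 200, states = 4, alpha = 1e-4, hmm_restarts = 5,
    refit_per_stage = FALSE, flank = 2500, min_bivalent_overlap = 200,
    gap = 100, min_rpkm = 5, min_stages = 2, min_cv = 0.10,
    single_qnorm = FALSE, clusters = 6, fuzzifier = 1.25,
    assign_categories = TRUE, threshold_fraction = 0.8,
    enrich_alpha = 0.05, candidate_categories = c("II", "III"),
    footprint_radius = 100, ko_fold_threshold = 2, ko_pseudocount = 0.5
  )
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  has_syn <- !is.null(config$synthetic)
  has_dir <- !is.null(config$input_dir)
  if (has_syn == has_dir)
    stop("exactly one of 'synthetic' and 'input_dir' must be set")
  if (has_dir) {
    if (is.null(config$stages))
      stop("'stages' is required with input_dir")
    need <- c("chrom.sizes", "annotation.tsv", "expression.tsv",
              "atac_counts.tsv", "ko_counts.tsv",
              sprintf("%s_H3K4me3.bedGraph", config$stages),
              sprintf("%s_peaks.bed", config$stages))
    missing <- need[!file.exists(file.path(config$input_dir, need))]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  } else {
    config$stages <- config$synthetic$stages
    config$bin_size <- config$synthetic$bin_size
    config$flank <- config$synthetic$flank
  }
  if (config$assign_categories && length(config$stages) != 4)
    stop("category assignment requires a 4-stage series; got ",
         length(config$stages), " stages (disable assign_categories ",
         "for other designs)")
  config
}

#' Load a dataset directory into the pipeline's in-memory shape
#'
#' Reads the standard-format files written by
#' [write_synthetic_dataset()]: chrom sizes, annotation, per-stage mark
#' bedGraphs, per-stage peak BEDs, peak/genome FASTA, expression and KO
#' count TSVs. No truth tables are assumed.
#'
#' @param dir dataset directory.
#' @param stages ordered stage labels.
#' @param bin_size signal bin width in bp (default 200).
#' @return List shaped like the output of [simulate_all()] minus `truth`.
#' @export
load_dataset <- function(dir, stages, bin_size = 200) {
  p <- function(...) file.path(dir, ...)
  chrom_sizes <- read_chrom_sizes(p("chrom.sizes"))
  annotation <- read_annotation(p("annotation.tsv"))
  chip <- lapply(setNames(stages, stages), function(stage) {
    marks <- c("H3K4me3", "H3K27me3", "ATAC")
    files <- p(sprintf("%s_%s.bedGraph", stage, marks))
    present <- file.exists(files)
    setNames(lapply(files[present], bin_bedgraph, bin_size = bin_size,
                    chrom_sizes = chrom_sizes), marks[present])
  })
  beds <- lapply(setNames(stages, stages), function(stage)
    read_bed(p(sprintf("%s_peaks.bed", stage))))
  counts <- read_expression(p("atac_counts.tsv"))
  ko <- read.delim(p("ko_counts.tsv"), stringsAsFactors = FALSE)
  genome_fa <- if (file.exists(p("genome.fa"))) read_fasta(p("genome.fa"))
  list(genome = list(sequences = genome_fa, chrom_sizes = chrom_sizes,
                     annotation = annotation),
       chip_tracks = chip,
       atac = list(stage_beds = beds, counts = counts,
                   sequences = genome_fa,
                   library_sizes = colSums(counts), cut_tracks = NULL),
       expression = read_expression(p("expression.tsv")),
       ko = list(wt = ko$wt, ko = ko$ko, peak_id = ko$peak_id),
       truth = NULL)
}

#' Run the full integrative pipeline
#'
#' Orchestrates chromatin-state segmentation, bivalent-promoter transition
#' analysis, temporal accessibility clustering with category assignment,
#' per-category motif enrichment, candidate-regulator intersection,
#' footprint profiling (when cut tracks are available) and WT/KO open-
#' region classification, in dependency order, and aggregates per-module
#' summaries into one report. Re-running with an identical config yields
#' an identical report.
#'
#' @param config a [run_config()]; validated internally.
#' @param outdir optional directory: intermediates (segment BEDs, call and
#'   membership TSVs, report JSON) are written there in plain formats.
#' @param motif_pwms named list of `pwm` objects to scan; defaults to the
#'   built-in planted set.
#' @return A `run_report` list; see the elements it carries.
#' @export
run_all <- function(config, outdir = NULL, motif_pwms = NULL) {
  if (inherits(config, "synthetic_config"))
    config <- run_config(synthetic = config, seed = config$seed)
  config <- validate_config(config)
  stages <- config$stages
  warnings <- character(0)
  note <- function(w) warnings <<- c(warnings, w)

  data <- if (!is.null(config$synthetic)) simulate_all(config$synthetic)
          else load_dataset(config$input_dir, stages, config$bin_size)
  chrom_sizes <- data$genome$chrom_sizes
  annotation <- data$genome$annotation

  # --- chromatin states ------------------------------------------------
  marks <- c("H3K4me3", "H3K27me3")
  binarized <- lapply(stages, function(stage)
    binarize_poisson(data$chip_tracks[[stage]][marks], config$alpha))
  names(binarized) <- stages
  model <- withCallingHandlers(
    fit_hmm(binarized[[1]], K = config$states, seed = config$seed,
            n_restarts = config$hmm_restarts),
    warning = function(w) { note(conditionMessage(w))
                            invokeRestart("muffleWarning") })
  model_labels <- withCallingHandlers(
    label_states(model),
    warning = function(w) { note(conditionMessage(w))
                            invokeRestart("muffleWarning") })
  segmentations <- lapply(setNames(stages, stages), function(stage) {
    m <- model; labels <- model_labels
    if (config$refit_per_stage && stage != stages[1]) {
      m <- fit_hmm(binarized[[stage]], K = config$states,
                   seed = config$seed, n_restarts = config$hmm_restarts)
      labels <- withCallingHandlers(
        label_states(m),
        warning = function(w) { note(conditionMessage(w))
                                invokeRestart("muffleWarning") })
    }
    chromatin_segmentation(decode_states(m, binarized[[stage]]), labels,
                           config$bin_size)
  })

  # --- bivalency -------------------------------------------------------
  calls <- lapply(setNames(stages, stages), function(stage)
    call_promoter_state(segmentations[[stage]], annotation, chrom_sizes,
                        stage = stage, flank = config$flank,
                        min_bivalent_overlap = config$min_bivalent_overlap))
  transitions <- lapply(seq_len(length(stages) - 1), function(i)
    classify_bivalent_transitions(calls[[i]], calls[[i + 1]]))
  names(transitions) <- vapply(transitions,
                               function(t) t$summary$stage_pair, "")
  activated <- activated_gene_sets(calls)

  # --- temporal accessibility clustering -------------------------------
  consensus <- consensus_union(data$atac$stage_beds, gap = config$gap)
  consensus$name <- paste0("consensus_", seq_len(nrow(consensus)))
  counts_m <- match_counts_to_consensus(data$atac, consensus)
  pm <- peak_matrix(consensus, counts_m, "count",
                    library_sizes = data$atac$library_sizes)
  prepared <- prepare_peak_matrix(rpkm(pm), config$min_rpkm,
                                  config$min_stages, config$min_cv,
                                  config$single_qnorm)
  clustering <- withCallingHandlers(
    fuzzy_cmeans(prepared$values, c = config$clusters,
                 m = config$fuzzifier, seed = config$seed),
    warning = function(w) { note(conditionMessage(w))
                            invokeRestart("muffleWarning") })
  categories <- if (config$assign_categories)
    assign_categories(clustering, stages) else NULL
  cluster_expr <- nearest_gene_expression(prepared$peaks, annotation,
                                          data$expression, clustering)

  # --- motifs, enrichment, candidates ----------------------------------
  if (is.null(motif_pwms)) {
    cm <- if (!is.null(config$synthetic)) config$synthetic$motif_counts
          else default_motif_counts()
    motif_pwms <- lapply(names(cm), function(tf)
      pwm_from_counts(cm[[tf]], tf_name = tf))
    names(motif_pwms) <- names(cm)
  }
  enrichment <- NULL; candidates <- NULL; occurrences <- NULL
  if (!is.null(data$atac$sequences) && !is.null(categories)) {
    seqs <- extract_sequences(data$atac$sequences, prepared$peaks)
    occurrences <- lapply(motif_pwms, function(p)
      scan_pwm(seqs, p, config$threshold_fraction))
    peak_cat <- categories[clustering$hard_assignment]
    enrichment <- lapply(setNames(c("I", "II", "III"), c("I", "II", "III")),
                         function(cat) {
      fg <- prepared$peaks$name[peak_cat == cat]
      if (!length(fg)) return(NULL)
      motif_enrichment(occurrences, fg,
                       setdiff(prepared$peaks$name, fg))
    })
    enrichment <- enrichment[!vapply(enrichment, is.null, logical(1))]
    candidates <- candidate_regulators(enrichment,
                                       unique(unlist(activated)),
                                       config$candidate_categories,
                                       config$enrich_alpha)
  }

  # --- footprints ------------------------------------------------------
  footprints <- NULL
  if (!is.null(data$atac$cut_tracks) && !is.null(occurrences)) {
    footprints <- lapply(names(occurrences), function(tf) {
      occ <- occurrences[[tf]]
      if (!nrow(occ)) return(NULL)
      sites <- occurrences_to_genome(occ, prepared$peaks,
                                     motif_pwms[[tf]]$width)
      depths <- vapply(stages, function(stage) {
        fp <- footprint_profile(data$atac$cut_tracks[[stage]], sites,
                                config$footprint_radius)
        footprint_depth(fp)
      }, numeric(1))
      list(tf_name = tf, n_sites = nrow(sites), depth_by_stage = depths)
    })
    names(footprints) <- names(occurrences)
    footprints <- footprints[!vapply(footprints, is.null, logical(1))]
  }

  # --- knockout contrast -----------------------------------------------
  ko_class <- classify_ko_peaks(data$ko$wt, data$ko$ko,
                                fold = config$ko_fold_threshold,
                                pseudocount = config$ko_pseudocount)
  ko_summary <- fraction_summary(ko_class)

  report <- structure(list(
    config = config, stages = stages,
    hmm = list(loglik = model$loglik, E = model$E, A = model$A,
               labels = model_labels),
    transitions = lapply(transitions, `[[`, "summary"),
    activated_genes = activated,
    clustering = list(sizes = tabulate(clustering$hard_assignment,
                                       clustering$c),
                      centroids = clustering$centroids,
                      categories = categories),
    cluster_expression = cluster_expr,
    enrichment = enrichment,
    candidates = candidates,
    footprints = footprints,
    ko = ko_summary,
    warnings = warnings,
    truth = data$truth
  ), class = "run_report")

  if (!is.null(outdir)) write_report(report, segmentations, calls,
                                     clustering, prepared, outdir)
  report
}

match_counts_to_consensus <- function(atac, consensus) {
  # generator peak ids: reuse their counts when consensus peaks coincide;
  # otherwise re-derive by midpoint containment
  counts <- atac$counts
  src <- if (!is.null(atac$peaks)) atac$peaks else NULL
  if (is.null(src)) {
    ids <- rownames(counts)
    stopifnot(!is.null(ids))
    # file mode: counts rows are the consensus of that dataset already
    if (nrow(counts) == nrow(consensus)) return(unname_rows(counts))
    stop("cannot align count matrix to consensus peaks")
  }
  mid <- (consensus$start + consensus$end) %/% 2
  idx <- integer(nrow(consensus))
  for (i in seq_len(nrow(consensus))) {
    j <- which(src$chrom == consensus$chrom[i] &
                 src$start < consensus$end[i] & src$end > consensus$start[i])
    if (!length(j))
      stop("consensus peak without source counts at row ", i)
    idx[i] <- j[1]
  }
  unname_rows(counts[idx, , drop = FALSE])
}

unname_rows <- function(m) { rownames(m) <- NULL; m }

extract_sequences <- function(sequences, peaks) {
  setNames(vapply(seq_len(nrow(peaks)), function(i)
    substr(sequences[[peaks$chrom[i]]], peaks$start[i] + 1, peaks$end[i]),
    ""), peaks$name)
}

write_report <- function(report, segmentations, calls, clustering,
                         prepared, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  for (stage in names(segmentations)) {
    seg <- segmentations[[stage]]
    segs <- do.call(rbind, lapply(names(seg$segments), function(lab) {
      s <- seg$segments[[lab]]
      if (nrow(s)) s$name <- lab
      s
    }))
    write_bed(segs[order(segs$chrom, segs$start), ],
              p(sprintf("%s_segments.bed", stage)), columns = 4)
    write.table(calls[[stage]], p(sprintf("%s_promoter_calls.tsv", stage)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_bed(prepared$peaks, p("consensus_filtered.bed"), columns = 4)
  mem <- clustering$membership
  rownames(mem) <- prepared$peaks$name
  write_matrix_tsv(mem, p("membership.tsv"), "peak_id")
  json <- report[setdiff(names(report), c("config", "truth"))]
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(outdir)
}
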