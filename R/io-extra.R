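#' Write sequences as FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (uppercased).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA header in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "[ \t]"), `[`, "", 1)
  bounds <- c(hdr, length(lines) + 1)
  seqs <- vapply(seq_along(hdr), function(i) {
    toupper(paste(lines[(bounds[i] + 1):(bounds[i + 1] - 1)], collapse = ""))
  }, "")
  setNames(seqs, ids)
}

#' Read a gene annotation TSV
#'
#' Expects a header row with columns `gene_id`, `chrom`, `tss` (0-based),
#' `strand`.
#'
#' @param path TSV file.
#' @return Annotation data frame.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  if (any(df$tss < 0)) stop("negative TSS")
  df[, need]
}

#' Read a gene-by-stage expression count TSV
#'
#' First column = gene id, remaining columns = stages (header row).
#'
#' @param path TSV file.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to disk in standard formats
#'
#' Emits genome FASTA, chrom.sizes TSV, annotation TSV, per-stage per-mark
#' bedGraphs, per-stage peak BEDs, peak FASTA, expression TSV, WT/KO count
#' TSV and a JSON truth file into `outdir`.
#'
#' @param sim output of [simulate_all()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  if (!is.null(sim$atac$sequences))
    write_fasta(sim$atac$sequences, p("genome.fa"))
  write.table(data.frame(names(sim$genome$chrom_sizes),
                         sim$genome$chrom_sizes),
              p("chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$genome$annotation, p("annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (stage in names(sim$chip_tracks)) {
    for (mark in names(sim$chip_tracks[[stage]])) {
      write_bedgraph(sim$chip_tracks[[stage]][[mark]],
                     p(sprintf("%s_%s.bedGraph", stage, mark)))
    }
    write_bed(sim$atac$stage_beds[[stage]],
              p(sprintf("%s_peaks.bed", stage)), columns = 4)
  }
  if (!is.null(sim$atac$peak_fasta))
    write_fasta(sim$atac$peak_fasta, p("peaks.fa"))
  write_matrix_tsv(sim$expression, p("expression.tsv"), "gene_id")
  write_matrix_tsv(sim$atac$counts, p("atac_counts.tsv"), "peak_id")
  write.table(data.frame(peak_id = sim$ko$peak_id, wt = sim$ko$wt,
                         ko = sim$ko$ko),
              p("ko_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(
    gene_states = as.data.frame(sim$truth$genes$states),
    gene_modes = as.data.frame(sim$truth$genes$modes),
    peaks = sim$truth$peaks
  )
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       na = "null", auto_unbox = FALSE)
  invisible(outdir)
}
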