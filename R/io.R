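# Readers and writers for the plain-text formats the pipeline consumes
# and emits: FASTA (via Biostrings), marker and SNP tables as TSV, BED /
# BedGraph tracks (0-based half-open), and truth-set sidecars (BED + YAML).

#' Write sequences as 60-column-wrapped FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of upper-case sequences.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bulk allele-count SNP table
#'
#' Expected header: CHROM, POS, plus ref/alt depth columns for each bulk
#' (`bulk1_ref`, `bulk1_alt`, `bulk2_ref`, `bulk2_alt`; the AD-style
#' aliases AD_bulk1_ref etc. are also accepted).
#'
#' @param path TSV path.
#' @return data.frame with columns chrom, pos, bulk1_ref, bulk1_alt,
#'   bulk2_ref, bulk2_alt.
#' @export
readSnpTable <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  names(df) <- sub("^AD_", "", names(df))
  names(df) <- tolower(names(df))
  need <- c("chrom", "pos", "bulk1_ref", "bulk1_alt", "bulk2_ref", "bulk2_alt")
  if (!all(need %in% names(df)))
    stop("SNP table must provide columns: ", paste(need, collapse = ", "))
  df[, need]
}

#' Read an F2 marker table with a genotype matrix
#'
#' Expected columns: marker, chrom, pos_bp, optionally cM (or cM_true),
#' followed by one column per individual holding AA/AB/BB or empty/NA.
#'
#' @param path TSV path.
#' @return list with `markers` (data.frame) and `geno` (character matrix).
#' @export
readMarkerTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", "", "-"))
  meta <- intersect(c("marker", "chrom", "pos_bp", "cM", "cM_true"),
                    names(df))
  genoCols <- setdiff(names(df), meta)
  geno <- as.matrix(df[, genoCols, drop = FALSE])
  rownames(geno) <- df$marker
  bad <- !(geno %in% c("AA", "AB", "BB") | is.na(geno))
  if (any(bad)) stop("genotype entries must be AA/AB/BB or missing")
  list(markers = df[, meta, drop = FALSE], geno = geno)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param chrom,start,end interval columns, or a `GRanges` passed as
#'   `chrom` (converted from 1-based closed).
#' @param name optional name column.
#' @param path output path.
#' @export
writeBed <- function(chrom, start = NULL, end = NULL, name = NULL, path) {
  if (is(chrom, "GRanges")) {
    gr <- chrom
    chrom <- as.character(GenomicRanges::seqnames(gr))
    start <- GenomicRanges::start(gr) - 1L
    end <- GenomicRanges::end(gr)
  }
  df <- data.frame(chrom = chrom, start = format(start, scientific = FALSE),
                   end = format(end, scientific = FALSE))
  if (!is.null(name)) df$name <- name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a binned track as BedGraph (0-based half-open)
#'
#' @param track data.frame with columns `chrom`, `bin_start`, `bin_width`
#'   and a value column (e.g. from [uniqueKmerTrack()]).
#' @param path output path.
#' @param valueCol name of the value column (default "count").
#' @export
writeBedGraph <- function(track, path, valueCol = "count") {
  df <- data.frame(track$chrom,
                   format(track$bin_start, scientific = FALSE),
                   format(track$bin_start + track$bin_width,
                          scientific = FALSE),
                   track[[valueCol]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Serialize a simulator truth set (BED + YAML sidecar)
#'
#' Tabular truth components (planted ROH, crossover density, panel block
#' provenance) are written as BED/TSV; scalar parameters go into a YAML
#' sidecar `truth.yaml`.
#'
#' @param truth the `truth` element returned by a simulator.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeTruthSet <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  scalars <- truth$config
  if (!is.null(truth$roh) && nrow(truth$roh)) {
    p <- file.path(dir, "roh.bed")
    writeBed(truth$roh$chrom, truth$roh$start, truth$roh$end, path = p)
    paths <- c(paths, p)
  }
  if (!is.null(truth$density)) {
    p <- file.path(dir, "crossover_density.tsv")
    writeTsv(truth$density, p)
    paths <- c(paths, p)
  }
  if (!is.null(truth$blocks)) {
    p <- file.path(dir, "blocks.tsv")
    writeTsv(truth$blocks, p)
    paths <- c(paths, p)
  }
  if (!is.null(truth$causal_pos)) scalars$causal_pos <- truth$causal_pos
  p <- file.path(dir, "truth.yaml")
  yaml::write_yaml(scalars, p)
  paths <- c(paths, p)
  invisible(paths)
}
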