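#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data.frame
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Write a read set to FASTQ
#'
#' Quality strings are taken from the set when present, otherwise a constant
#' high quality ("I") is written.
#'
#' @param rs A [read_set()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  r <- rs$reads
  qual <- if ("quality" %in% names(r)) r$quality else
    vapply(nchar(r$sequence), function(n) strrep("I", n), character(1))
  lines <- character(4L * nrow(r))
  if (nrow(r) > 0) {
    idx <- seq_len(nrow(r))
    lines[4 * idx - 3] <- paste0("@", r$read_id)
    lines[4 * idx - 2] <- r$sequence
    lines[4 * idx - 1] <- "+"
    lines[4 * idx] <- qual
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path.
#' @param sample_id,assay Metadata attached to the set.
#' @return A [read_set()].
#' @export
read_fastq <- function(path, sample_id = basename(path), assay = "RPF") {
  sr <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  reads <- data.frame(read_id = names(sr), sequence = as.character(sr),
                      stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  read_set(sample_id, assay, reads)
}

#' Write a gene-by-sample count matrix as TSV
#'
#' First column `gene`, then one column per sample id.
#'
#' @param counts Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a gene-by-sample count matrix from TSV
#' @param path Input path (as written by [write_count_matrix()]).
#' @return Numeric matrix.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write a coverage profile as bedGraph
#'
#' Positions are relative to the CDS start of the transcript (0-based
#' half-open intervals); adjacent equal values are merged into one record.
#'
#' @param profile Numeric vector of per-position footprint 5'-end counts.
#' @param transcript_id Transcript the profile belongs to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, transcript_id, path) {
  L <- length(profile)
  if (L == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  runs <- rle(profile)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  keep <- runs$values != 0
  lines <- sprintf("%s\t%d\t%d\t%g", transcript_id,
                   starts[keep], ends[keep], runs$values[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Export a compatibility map as SAM
#'
#' Writes one alignment record per (read, transcript) pair: the first
#' compatibility of a read as a primary record, the rest as secondary
#' (flag 256). MAPQ is written as 255 (unavailable), matching the exact
#' matcher which has no mapping-quality model.
#'
#' @param compat Compatibility data.frame (`read_id`, `transcript_id`,
#'   `offset`) as returned by [assign_reads()].
#' @param reads A [read_set()] supplying the sequences.
#' @param annotation Annotation data.frame (for the header).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(compat, reads, annotation, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", annotation$transcript_id,
                   nchar(annotation$sequence)))
  seq_of <- stats::setNames(reads$reads$sequence, reads$reads$read_id)
  if (nrow(compat) > 0) {
    ord <- order(compat$read_id)
    compat <- compat[ord, , drop = FALSE]
    primary <- !duplicated(compat$read_id)
    flag <- ifelse(primary, 0L, 256L)
    sq <- unname(seq_of[compat$read_id])
    recs <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                    compat$read_id, flag, compat$transcript_id,
                    compat$offset + 1L, nchar(sq), sq)
  } else recs <- character(0)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
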