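# Hand-built miniature annotation: three coding transcripts plus one tRNA
# and one rRNA contaminant. Sequences are drawn once under a fixed seed;
# at these lengths 26+ nt cross-matches between records cannot occur by
# accident.
.tiny_seqs <- local({
  set.seed(20240301)
  vapply(c(120, 120, 150, 72, 200), function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
})
tiny_annotation <- function() {
  data.frame(
    gene_id = c("mt-Nd1", "mt-Nd2", "NuOx1", "mt-Trna01", "mt-Rnr1"),
    transcript_id = c("mt-Nd1", "mt-Nd2", "NuOx1", "mt-Trna01", "mt-Rnr1"),
    sequence = .tiny_seqs,
    cds_start = c(10L, 10L, 15L, 0L, 0L),
    cds_end = c(100L, 100L, 135L, 0L, 0L),
    genome_of_origin = c("mitochondrial", "mitochondrial", "nuclear",
                         "mitochondrial", "mitochondrial"),
    gene_class = c("mt-OXPHOS", "mt-OXPHOS", "nu-OXPHOS",
                   "contaminant-tRNA", "contaminant-rRNA"),
    stringsAsFactors = FALSE
  )
}

make_read_set <- function(seqs, sample_id = "s1", assay = "RPF") {
  read_set(sample_id, assay,
           data.frame(read_id = sprintf("r%03d", seq_along(seqs)),
                      sequence = seqs, stringsAsFactors = FALSE))
}

random_read <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent brute-force oracle for the trimming rules, one read at a time:
# leftmost full adapter occurrence, else longest suffix-prefix overlap, then
# end trimming and the length filter
oracle_trim <- function(seq, adapter, end_trim, min_length) {
  n <- nchar(seq)
  cut <- NA
  if (n >= nchar(adapter)) {
    for (p in 0:(n - nchar(adapter))) {
      if (substr(seq, p + 1, p + nchar(adapter)) == adapter) {
        cut <- p
        break
      }
    }
  }
  if (is.na(cut)) {
    for (l in seq(min(nchar(adapter) - 1, n), 1)) {
      if (substr(seq, n - l + 1, n) == substr(adapter, 1, l)) {
        cut <- n - l
        break
      }
    }
  }
  kept <- if (is.na(cut)) seq else substr(seq, 1, cut)
  m <- nchar(kept)
  final <- if (m - 2 * end_trim >= 1)
    substr(kept, end_trim + 1, m - end_trim) else ""
  list(sequence = final, retained = nchar(final) >= min_length)
}
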