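#' Default mitochondrial protein-coding gene names
#'
#' The 13 protein-coding genes of the mammalian mitochondrial genome
#' (complex I NADH dehydrogenase subunits, cytochrome b, cytochrome c
#' oxidase subunits, and ATP synthase subunits), mouse-style symbols.
#'
#' @return Character vector of length 13.
#' @export
mito_gene_names <- function() {
  c("mt-Nd1", "mt-Nd2", "mt-Nd3", "mt-Nd4", "mt-Nd4l", "mt-Nd5", "mt-Nd6",
    "mt-Cytb", "mt-Co1", "mt-Co2", "mt-Co3", "mt-Atp6", "mt-Atp8")
}

# Symbol pools for the nuclear-encoded classes; names beyond the pool are
# generated systematically.
.nuclear_oxphos_pool <- c(
  "Ndufv1", "Ndufa2", "Ndufa6", "Ndufb10", "Sdha", "Sdhb", "Cyc1",
  "Uqcrb", "Uqcrc1", "Cox5a", "Cox7a2l", "Cox7c", "Atp5o", "Ndufa10"
)

.mito_assoc_pool <- c(
  "Mrpl12", "Ptcd3", "Cavin1", "Bsg", "Prxl2a", "Plpp3", "Pck2",
  "Nfs1", "Scp2", "Comt", "Tmlhe", "Mgst3", "Ece1", "Timm23", "Tomm5",
  "Mrps22"
)

.class_names <- function(pool, prefix, n) {
  if (n <= length(pool)) return(pool[seq_len(n)])
  c(pool, sprintf("%s%03d", prefix, seq_len(n - length(pool))))
}

#' Generator configuration for the synthetic annotation and experiment
#'
#' Gene counts per class, transcript length ranges (nt), and the UTR margin
#' flanking each CDS. Defaults reflect the mammalian mitochondrial genome
#' (13 protein-coding genes, 2 rRNAs, 22 tRNAs) plus a modest nuclear
#' complement.
#'
#' @param n_mito Number of mitochondrially encoded protein-coding genes.
#'   Default 13; larger values append systematically named extra genes.
#' @param n_nuclear_oxphos Number of nuclear-encoded OXPHOS genes.
#' @param n_mito_assoc Number of nuclear-encoded mitochondria-associated
#'   (non-OXPHOS) genes.
#' @param n_other Number of unrelated nuclear genes.
#' @param n_rrna,n_trna Number of contaminant rRNA / tRNA records.
#' @param mito_len,nuclear_len,rrna_len,trna_len Integer length-2 vectors,
#'   inclusive transcript length ranges in nt.
#' @param utr_margin UTR width (nt) added on each side of a CDS.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mito = 13L, n_nuclear_oxphos = 10L,
                       n_mito_assoc = 8L, n_other = 20L,
                       n_rrna = 2L, n_trna = 22L,
                       mito_len = c(300L, 1800L),
                       nuclear_len = c(500L, 3000L),
                       rrna_len = c(900L, 1600L),
                       trna_len = c(60L, 90L),
                       utr_margin = 30L) {
  cfg <- list(
    n_mito = as.integer(n_mito), n_nuclear_oxphos = as.integer(n_nuclear_oxphos),
    n_mito_assoc = as.integer(n_mito_assoc), n_other = as.integer(n_other),
    n_rrna = as.integer(n_rrna), n_trna = as.integer(n_trna),
    mito_len = as.integer(mito_len), nuclear_len = as.integer(nuclear_len),
    rrna_len = as.integer(rrna_len), trna_len = as.integer(trna_len),
    utr_margin = as.integer(utr_margin)
  )
  for (nm in c("mito_len", "nuclear_len", "rrna_len", "trna_len")) {
    rng <- cfg[[nm]]
    if (length(rng) != 2L || rng[1] > rng[2])
      stop("invalid length range for '", nm, "': min > max", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic transcript annotation
#'
#' Generates random transcript sequences for the mitochondrially encoded
#' protein-coding genes (default symbols `mt-Nd1` ... `mt-Atp8`), a
#' configurable nuclear complement (OXPHOS, mitochondria-associated, other)
#' and a contaminant pool of rRNA and tRNA records. Protein-coding records
#' carry a CDS interval (0-based, half-open, on transcript coordinates)
#' flanked by `utr_margin` nt of UTR; contaminant records have no CDS
#' (`cds_start == cds_end == 0` by convention, full record used for
#' matching).
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed; the annotation is deterministic given the seed.
#' @return A data.frame with columns `gene_id`, `transcript_id`, `sequence`,
#'   `cds_start`, `cds_end`, `genome_of_origin`
#'   (`"mitochondrial"`/`"nuclear"`), and `gene_class` (one of `mt-OXPHOS`,
#'   `nu-OXPHOS`, `mito-associated`, `other`, `contaminant-rRNA`,
#'   `contaminant-tRNA`).
#' @export
build_default_annotation <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))

  mk_coding <- function(names, len_range, origin, class, margin) {
    n <- length(names)
    if (n == 0L) return(NULL)
    total <- if (len_range[1] == len_range[2]) rep(len_range[1], n) else
      sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    # CDS occupies the transcript minus the UTR margins, trimmed to a
    # multiple of 3 (at least one codon)
    cds_len <- pmax(3L, ((total - 2L * margin) %/% 3L) * 3L)
    margin_eff <- pmin(margin, (total - cds_len) %/% 2L)
    data.frame(
      gene_id = names,
      transcript_id = names,
      sequence = vapply(total, .random_seq, character(1)),
      cds_start = as.integer(margin_eff),
      cds_end = as.integer(margin_eff + cds_len),
      genome_of_origin = origin,
      gene_class = class,
      stringsAsFactors = FALSE
    )
  }
  mk_contaminant <- function(names, len_range, class) {
    n <- length(names)
    if (n == 0L) return(NULL)
    total <- if (len_range[1] == len_range[2]) rep(len_range[1], n) else
      sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    data.frame(
      gene_id = names, transcript_id = names,
      sequence = vapply(total, .random_seq, character(1)),
      cds_start = 0L, cds_end = 0L,
      genome_of_origin = "mitochondrial",
      gene_class = class,
      stringsAsFactors = FALSE
    )
  }

  mito_names <- .class_names(mito_gene_names(), "mt-Gene", config$n_mito)
  ann <- rbind(
    mk_coding(mito_names, config$mito_len, "mitochondrial", "mt-OXPHOS",
              config$utr_margin),
    mk_coding(.class_names(.nuclear_oxphos_pool, "NuOx", config$n_nuclear_oxphos),
              config$nuclear_len, "nuclear", "nu-OXPHOS", config$utr_margin),
    mk_coding(.class_names(.mito_assoc_pool, "MitoAssoc", config$n_mito_assoc),
              config$nuclear_len, "nuclear", "mito-associated", config$utr_margin),
    mk_coding(if (config$n_other > 0) sprintf("Gene%04d", seq_len(config$n_other)) else character(0),
              config$nuclear_len, "nuclear", "other", config$utr_margin),
    mk_contaminant(if (config$n_rrna > 0) sprintf("mt-Rnr%d", seq_len(config$n_rrna)) else character(0),
                   config$rrna_len, "contaminant-rRNA"),
    mk_contaminant(if (config$n_trna > 0) sprintf("mt-Trna%02d", seq_len(config$n_trna)) else character(0),
                   config$trna_len, "contaminant-tRNA")
  )
  rownames(ann) <- NULL
  validate_annotation(ann)
  ann
}

#' Validate an annotation table
#'
#' Checks the structural invariants: unique gene ids, sequences over
#' \{A,C,G,T\}, and CDS intervals within transcript bounds for coding
#' records.
#'
#' @param annotation Annotation data.frame as from
#'   [build_default_annotation()].
#' @return The annotation, invisibly; errors on violation.
#' @export
validate_annotation <- function(annotation) {
  req <- c("gene_id", "transcript_id", "sequence", "cds_start", "cds_end",
           "genome_of_origin", "gene_class")
  if (!all(req %in% names(annotation)))
    stop("annotation missing columns: ",
         paste(setdiff(req, names(annotation)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(annotation$gene_id))
    stop("duplicated gene_id in annotation", call. = FALSE)
  if (any(stringi::stri_detect_regex(annotation$sequence, "[^ACGT]")))
    stop("annotation sequences must be over {A,C,G,T}", call. = FALSE)
  coding <- !is_contaminant_class(annotation$gene_class)
  len <- nchar(annotation$sequence)
  bad <- coding & !(annotation$cds_start >= 0 &
                    annotation$cds_start < annotation$cds_end &
                    annotation$cds_end <= len)
  if (any(bad))
    stop("CDS interval out of bounds for: ",
         paste(annotation$gene_id[bad], collapse = ", "), call. = FALSE)
  invisible(annotation)
}

is_contaminant_class <- function(gene_class) {
  gene_class %in% c("contaminant-rRNA", "contaminant-tRNA")
}

#' Subset an annotation to coding (non-contaminant) records
#' @param annotation Annotation data.frame.
#' @return The coding rows.
#' @export
coding_annotation <- function(annotation) {
  annotation[!is_contaminant_class(annotation$gene_class), , drop = FALSE]
}

#' Subset an annotation to contaminant records
#' @param annotation Annotation data.frame.
#' @return The contaminant (rRNA/tRNA) rows.
#' @export
contaminant_annotation <- function(annotation) {
  annotation[is_contaminant_class(annotation$gene_class), , drop = FALSE]
}

#' Write annotation sequences to FASTA
#'
#' @param annotation Annotation data.frame (any subset).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_annotation_fasta <- function(annotation, path) {
  seqs <- Biostrings::DNAStringSet(annotation$sequence)
  names(seqs) <- annotation$transcript_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read transcript sequences from FASTA into an annotation skeleton
#'
#' @param fasta_path FASTA of transcript sequences.
#' @param cds_bed_path Optional BED of CDS intervals on transcript
#'   coordinates (0-based half-open; `name` column carries the gene id).
#' @return Annotation data.frame; records absent from the BED are marked as
#'   contaminants of class `contaminant-rRNA` unless `cds_bed_path` is NULL.
#' @export
read_annotation <- function(fasta_path, cds_bed_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- data.frame(
    gene_id = names(seqs), transcript_id = names(seqs),
    sequence = as.character(seqs),
    cds_start = 0L, cds_end = nchar(as.character(seqs)),
    genome_of_origin = ifelse(startsWith(names(seqs), "mt-"),
                              "mitochondrial", "nuclear"),
    gene_class = "other", stringsAsFactors = FALSE
  )
  rownames(ann) <- NULL
  if (!is.null(cds_bed_path)) {
    bed <- rtracklayer::import(cds_bed_path, format = "BED")
    idx <- match(as.character(GenomicRanges::seqnames(bed)), ann$transcript_id)
    if (anyNA(idx))
      stop("CDS BED references transcripts absent from the FASTA", call. = FALSE)
    ann$cds_start[idx] <- GenomicRanges::start(bed) - 1L
    ann$cds_end[idx] <- GenomicRanges::end(bed)
    ann$gene_id[idx] <- bed$name
    missing <- setdiff(seq_len(nrow(ann)), idx)
    ann$gene_class[missing] <- "contaminant-rRNA"
    ann$cds_start[missing] <- 0L
    ann$cds_end[missing] <- 0L
  }
  validate_annotation(ann)
  ann
}

#' Write CDS intervals to BED (transcript coordinates)
#'
#' Coding records only; intervals are 0-based half-open in the file, as BED
#' requires. The `name` field carries the gene id, the score the CDS length.
#'
#' @param annotation Annotation data.frame.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_cds_bed <- function(annotation, path) {
  cod <- coding_annotation(annotation)
  gr <- GenomicRanges::GRanges(
    seqnames = cod$transcript_id,
    ranges = IRanges::IRanges(start = cod$cds_start + 1L, end = cod$cds_end),
    strand = "+",
    name = cod$gene_id,
    score = cod$cds_end - cod$cds_start
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
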