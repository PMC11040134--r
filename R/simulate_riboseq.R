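#' Paired Ribo-seq / RNA-seq sample design
#'
#' One RPF (ribosome-protected fragment) and one mRNA library per
#' (genotype, replicate); three genotypes by default, matching a
#' control / heterozygous / homozygous knock-in comparison.
#'
#' @param genotypes Character vector of genotype labels; the first is the
#'   control used by the many-to-one comparisons.
#' @param replicates Replicates per genotype (>= 2 required for statistics).
#' @return data.frame with columns `sample_id`, `genotype`, `replicate`,
#'   `assay` (`"RPF"` or `"mRNA"`).
#' @export
riboseq_design <- function(genotypes = c("control", "het", "homo"),
                           replicates = 3L) {
  g <- rep(genotypes, each = replicates)
  r <- rep(seq_len(replicates), times = length(genotypes))
  base <- data.frame(genotype = g, replicate = r, stringsAsFactors = FALSE)
  des <- rbind(transform(base, assay = "RPF"), transform(base, assay = "mRNA"))
  des$sample_id <- sprintf("%s_%d_%s", des$genotype, des$replicate, des$assay)
  rownames(des) <- NULL
  des[, c("sample_id", "genotype", "replicate", "assay")]
}

.check_design <- function(design) {
  stopifnot(all(c("sample_id", "genotype", "replicate", "assay") %in% names(design)))
  key <- paste(design$genotype, design$replicate, design$assay)
  if (anyDuplicated(key))
    stop("duplicate (genotype, replicate, assay) in design", call. = FALSE)
  rpf <- design[design$assay == "RPF", ]
  mrna <- design[design$assay == "mRNA", ]
  unpaired <- !paste(rpf$genotype, rpf$replicate) %in% paste(mrna$genotype, mrna$replicate)
  if (any(unpaired))
    stop("RPF samples without an mRNA partner: ",
         paste(rpf$sample_id[unpaired], collapse = ", "), call. = FALSE)
  invisible(design)
}

#' Ground-truth effect table for the Ribo-seq generator
#'
#' One row per coding gene with the planted mRNA-abundance fold changes,
#' occupancy (RPF/mRNA) fold changes for each mutant genotype relative to
#' control, the positional skew of footprint starts in [-1, 1] (positive =
#' 3'-shifted), and an optional per-gene dropout flag that zeroes the gene's
#' reads in a random replicate (emulating genes whose footprints are not
#' discernible in every replicate).
#'
#' @param annotation Annotation data.frame; contaminants are ignored.
#' @param occ_fc_het,occ_fc_homo Named numeric vectors of occupancy fold
#'   changes (> 0), or a single value recycled; genes not named keep 1.
#' @param mrna_fc_het,mrna_fc_homo Same, for mRNA abundance.
#' @param skew Named numeric in [-1, 1]; genes not named keep 0.
#' @param dropout Character vector of gene ids subject to replicate dropout.
#' @return data.frame keyed by `gene_id`.
#' @export
truth_table <- function(annotation, occ_fc_het = NULL, occ_fc_homo = NULL,
                        mrna_fc_het = NULL, mrna_fc_homo = NULL,
                        skew = NULL, dropout = character(0)) {
  cod <- coding_annotation(annotation)
  tt <- data.frame(gene_id = cod$gene_id,
                   occ_fc_het = 1, occ_fc_homo = 1,
                   mrna_fc_het = 1, mrna_fc_homo = 1,
                   skew = 0, dropout = cod$gene_id %in% dropout,
                   stringsAsFactors = FALSE)
  fill <- function(col, val) {
    if (is.null(val)) return(col)
    if (is.null(names(val))) return(rep(val, length.out = length(col)))
    idx <- match(names(val), tt$gene_id)
    if (anyNA(idx))
      stop("truth names not in annotation: ",
           paste(names(val)[is.na(idx)], collapse = ", "), call. = FALSE)
    col[idx] <- val
    col
  }
  tt$occ_fc_het <- fill(tt$occ_fc_het, occ_fc_het)
  tt$occ_fc_homo <- fill(tt$occ_fc_homo, occ_fc_homo)
  tt$mrna_fc_het <- fill(tt$mrna_fc_het, mrna_fc_het)
  tt$mrna_fc_homo <- fill(tt$mrna_fc_homo, mrna_fc_homo)
  tt$skew <- fill(tt$skew, skew)
  if (any(tt$occ_fc_het <= 0 | tt$occ_fc_homo <= 0 |
          tt$mrna_fc_het <= 0 | tt$mrna_fc_homo <= 0))
    stop("fold changes must be > 0", call. = FALSE)
  if (any(abs(tt$skew) > 1))
    stop("skew must lie in [-1, 1]", call. = FALSE)
  tt
}

.truth_fc <- function(truth, genotype, what = c("occ", "mrna")) {
  what <- match.arg(what)
  switch(genotype,
         control = rep(1, nrow(truth)),
         het = truth[[paste0(what, "_fc_het")]],
         homo = truth[[paste0(what, "_fc_homo")]],
         rep(1, nrow(truth)))
}

#' Simulate per-gene RPF and mRNA counts (negative binomial)
#'
#' The count layer of the Ribo-seq generator: per-gene baseline abundances
#' are drawn once (log-normal), the mRNA mean of gene g in genotype y is
#' `depth_share * base_g * mrna_fc(g, y)` and the RPF mean is the mRNA mean
#' times `occ_fc(g, y)`, so the planted occupancy fold change is exactly the
#' ratio of expected RPF/mRNA ratios. Counts are negative binomial with a
#' common dispersion; `reads_per_sample` is the expected on-target yield of
#' a control library (effect genotypes may yield slightly more or fewer
#' footprints, as planted effects change the amount of ribosome-protected
#' material, not the per-gene proportions).
#'
#' @param annotation Annotation data.frame.
#' @param design Sample design from [riboseq_design()].
#' @param truth Truth table from [truth_table()].
#' @param reads_per_sample Expected on-target reads per control library.
#' @param dispersion Negative-binomial dispersion (1/size); 0 gives Poisson.
#'   Default 0.01, reflecting isogenic cell-line replicates.
#' @param seed Integer seed.
#' @return list with `rpf` and `mrna` gene-by-sample count matrices, the
#'   per-gene baseline proportions (`base`), `truth`, and `design`.
#' @export
simulate_riboseq_counts <- function(annotation, design = riboseq_design(),
                                    truth = truth_table(annotation),
                                    reads_per_sample = 50000,
                                    dispersion = 0.01, seed = 1L) {
  .check_design(design)
  set.seed(as.integer(seed))
  cod <- coding_annotation(annotation)
  stopifnot(identical(cod$gene_id, truth$gene_id))
  n_genes <- nrow(cod)
  base <- exp(stats::rnorm(n_genes, 0, 1))
  base <- base / sum(base)

  draw <- function(mu) {
    if (dispersion <= 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  mk <- function(assay) {
    sub <- design[design$assay == assay, , drop = FALSE]
    m <- matrix(0, n_genes, nrow(sub),
                dimnames = list(cod$gene_id, sub$sample_id))
    for (j in seq_len(nrow(sub))) {
      fc_m <- .truth_fc(truth, sub$genotype[j], "mrna")
      mu <- reads_per_sample * base * fc_m
      if (assay == "RPF") mu <- mu * .truth_fc(truth, sub$genotype[j], "occ")
      cnt <- draw(mu)
      # per-gene dropout: the gene yields no reads in replicate 1, emulating
      # transcripts whose footprints are not discernible in every replicate
      if (any(truth$dropout) && sub$replicate[j] == 1L)
        cnt[truth$dropout] <- 0L
      m[, j] <- cnt
    }
    m
  }
  list(rpf = mk("RPF"), mrna = mk("mRNA"), base = base,
       truth = truth, design = design)
}

#' A set of reads from one sequencing library
#'
#' @param sample_id Sample identifier.
#' @param assay `"RPF"` or `"mRNA"`.
#' @param reads data.frame with `read_id`, `sequence` (and optionally
#'   `quality`).
#' @return Object of class `read_set`.
#' @export
read_set <- function(sample_id, assay, reads) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (anyDuplicated(reads$read_id))
    stop("read_ids must be unique within a read set", call. = FALSE)
  if (nrow(reads) > 0 && any(!nzchar(reads$sequence)))
    stop("read sequences must be non-empty", call. = FALSE)
  structure(list(sample_id = sample_id, assay = assay, reads = reads),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s (%s): %d reads\n",
              x$sample_id, x$assay, nrow(x$reads)))
  invisible(x)
}

# Sample footprint start positions on [0, n_pos) under a linear tilt:
# weight(i) proportional to 1 + skew * (2 i / (n_pos - 1) - 1), clamped >= 0.
.tilted_positions <- function(n, n_pos, skew) {
  if (n_pos == 1L) return(rep(0L, n))
  w <- 1 + skew * (2 * (seq_len(n_pos) - 1) / (n_pos - 1) - 1)
  w <- pmax(w, 0)
  sample.int(n_pos, n, replace = TRUE, prob = w) - 1L
}

.mutate_reads <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n <- nchar(seqs)
  hits <- stats::rbinom(length(seqs), n, rate)
  idx <- which(hits > 0)
  for (i in idx) {
    pos <- sample.int(n[i], hits[i])
    s <- strsplit(seqs[i], "")[[1]]
    s[pos] <- sample(c("A", "C", "G", "T"), hits[i], replace = TRUE)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a paired Ribo-seq / RNA-seq read-level experiment
#'
#' Renders the count layer of [simulate_riboseq_counts()] into reads.
#' Footprint inserts are 26-32 nt (uniform), start positions within the CDS
#' follow the per-gene linear positional tilt (`skew` > 0 concentrates
#' footprints toward the 3' end of the CDS); mRNA reads are drawn uniformly
#' along the whole transcript. A stated fraction of each library is drawn
#' from the contaminant (rRNA/tRNA) records. Reads are rendered with the
#' library chemistry the trimming stage expects: 4 random nt on each side of
#' the insert followed by the full 3' adapter.
#'
#' @param annotation Annotation data.frame (coding + contaminant records).
#' @param design Sample design ([riboseq_design()]).
#' @param truth Truth table ([truth_table()]).
#' @param reads_per_sample Expected on-target reads per control library.
#' @param dispersion NB dispersion of the count layer.
#' @param contaminant_fraction Fraction of each library drawn from the
#'   contaminant pool (default 0.1).
#' @param subst_rate Per-base uniform substitution error rate (default 0).
#' @param adapter 3' adapter sequence appended to every read.
#' @param mrna_read_length Read length used for the mRNA libraries.
#' @param seed Integer seed; outputs are byte-identical given the seed.
#' @param outdir Optional directory; when given, FASTQ files, the sample
#'   sheet, and the truth tables are written there.
#' @return list with `read_sets` (list of [read_set()]), `read_truth`
#'   (per-read origin bookkeeping), `counts` (the count layer), `design`,
#'   `truth`, and (if written) `files`.
#' @export
simulate_riboseq_experiment <- function(annotation, design = riboseq_design(),
                                        truth = truth_table(annotation),
                                        reads_per_sample = 20000,
                                        dispersion = 0.01,
                                        contaminant_fraction = 0.1,
                                        subst_rate = 0,
                                        adapter = default_adapter(),
                                        mrna_read_length = 50L,
                                        seed = 1L, outdir = NULL) {
  stopifnot(contaminant_fraction >= 0, contaminant_fraction < 1)
  counts <- simulate_riboseq_counts(annotation, design, truth,
                                    reads_per_sample, dispersion, seed)
  # continue the RNG stream from the count layer
  cod <- coding_annotation(annotation)
  contam <- contaminant_annotation(annotation)
  if (contaminant_fraction > 0 && nrow(contam) == 0L)
    stop("contaminant_fraction > 0 but annotation has no contaminant records",
         call. = FALSE)
  cds_len <- cod$cds_end - cod$cds_start
  bases <- c("A", "C", "G", "T")

  render_sample <- function(sample_id, assay, gene_counts) {
    n_contam <- if (contaminant_fraction > 0)
      stats::rpois(1, sum(gene_counts) * contaminant_fraction /
                     (1 - contaminant_fraction)) else 0L
    origin_idx <- c(rep(seq_len(nrow(cod)), gene_counts),
                    if (n_contam > 0)
                      -sample.int(nrow(contam), n_contam, replace = TRUE))
    n <- length(origin_idx)
    if (n == 0L) {
      return(list(rs = read_set(sample_id, assay,
                                data.frame(read_id = character(0),
                                           sequence = character(0))),
                  tr = NULL))
    }
    ins_len <- if (assay == "RPF") sample(26:32, n, replace = TRUE)
               else rep(as.integer(mrna_read_length), n)
    src_seq <- character(n)
    start <- integer(n)
    is_gene <- origin_idx > 0
    # gene reads: per gene, tilted starts within the CDS (RPF) or uniform
    # along the transcript (mRNA)
    for (g in unique(origin_idx[is_gene])) {
      sel <- which(origin_idx == g)
      L <- nchar(cod$sequence[g])
      if (assay == "RPF") {
        lo <- cod$cds_start[g]
        n_pos <- pmax(1L, cds_len[g] - ins_len[sel] + 1L)
        # draw against the widest window, then clamp per read
        npmax <- max(n_pos)
        pos <- .tilted_positions(length(sel), npmax, truth$skew[g])
        pos <- pmin(pos, n_pos - 1L)
        start[sel] <- lo + pos
      } else {
        ins_len[sel] <- pmin(ins_len[sel], L)
        start[sel] <- vapply(L - ins_len[sel] + 1L,
                             function(k) sample.int(k, 1L) - 1L, integer(1))
      }
      src_seq[sel] <- cod$sequence[g]
    }
    if (any(!is_gene)) {
      sel <- which(!is_gene)
      ci <- -origin_idx[sel]
      L <- nchar(contam$sequence)[ci]
      ins_len[sel] <- pmin(ins_len[sel], L)
      start[sel] <- vapply(L - ins_len[sel] + 1L,
                           function(k) sample.int(k, 1L) - 1L, integer(1))
      src_seq[sel] <- contam$sequence[ci]
    }
    insert <- substring(src_seq, start + 1L, start + ins_len)
    insert <- .mutate_reads(insert, subst_rate)
    rnd4 <- function(n) {
      m <- matrix(sample(bases, 4L * n, replace = TRUE), nrow = n)
      paste0(m[, 1], m[, 2], m[, 3], m[, 4])
    }
    seqs <- paste0(rnd4(n), insert, rnd4(n), adapter)
    ids <- sprintf("%s_r%06d", sample_id, seq_len(n))
    rs <- read_set(sample_id, assay,
                   data.frame(read_id = ids, sequence = seqs,
                              stringsAsFactors = FALSE))
    tr <- data.frame(
      read_id = ids, sample_id = sample_id, assay = assay,
      origin = ifelse(is_gene, cod$transcript_id[pmax(origin_idx, 1L)],
                      contam$transcript_id[pmax(-origin_idx, 1L)]),
      origin_class = ifelse(is_gene, "gene", "contaminant"),
      insert_start = start, insert_length = ins_len,
      stringsAsFactors = FALSE
    )
    list(rs = rs, tr = tr)
  }

  read_sets <- list()
  read_truth <- list()
  for (j in seq_len(nrow(design))) {
    sid <- design$sample_id[j]
    assay <- design$assay[j]
    cnts <- if (assay == "RPF") counts$rpf[, sid] else counts$mrna[, sid]
    out <- render_sample(sid, assay, cnts)
    read_sets[[sid]] <- out$rs
    read_truth[[sid]] <- out$tr
  }
  read_truth <- do.call(rbind, read_truth)
  rownames(read_truth) <- NULL

  res <- list(read_sets = read_sets, read_truth = read_truth,
              counts = counts, design = design, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      annotation = file.path(outdir, "annotation.fasta"),
      cds = file.path(outdir, "cds.bed"),
      contaminants = file.path(outdir, "contaminants.fasta"),
      samples = file.path(outdir, "samples.tsv"),
      truth_genes = file.path(outdir, "truth_genes.tsv"),
      truth_reads = file.path(outdir, "truth_reads.tsv")
    )
    write_annotation_fasta(coding_annotation(annotation), files["annotation"])
    write_cds_bed(annotation, files["cds"])
    if (nrow(contam) > 0)
      write_annotation_fasta(contam, files["contaminants"])
    write_tsv(design, files["samples"])
    write_tsv(truth, files["truth_genes"])
    write_tsv(read_truth, files["truth_reads"])
    fq_dir <- file.path(outdir, "fastq")
    dir.create(fq_dir, showWarnings = FALSE)
    for (rs in read_sets) {
      f <- file.path(fq_dir, paste0(rs$sample_id, ".fastq"))
      write_fastq(rs, f)
      files[paste0("fastq_", rs$sample_id)] <- f
    }
    res$files <- files
  }
  res
}

#' Default 3' adapter sequence
#'
#' The small-RNA 3' adapter trimmed from footprint libraries.
#' @return Character scalar.
#' @export
default_adapter <- function() "TGGAATTCTCGGGTGCCAAGG"
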