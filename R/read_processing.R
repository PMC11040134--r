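#' Trim the 3' adapter and fixed end bases from a read set
#'
#' The adapter is located by the leftmost full occurrence of the adapter
#' sequence within the read; failing that, by the longest suffix of the read
#' that equals a prefix of the adapter (ties resolved longest-first, then
#' leftmost — the suffix-prefix overlap of a given length is unique). The
#' read is cut at the located adapter start, `end_trim` bases are then
#' removed from each end (the randomized bases of small-RNA library
#' chemistry), and reads shorter than `min_length` are discarded.
#'
#' @param rs A [read_set()].
#' @param adapter 3' adapter sequence (ACGT only).
#' @param end_trim Bases removed from each end after adapter removal
#'   (default 4).
#' @param min_length Minimum retained read length (default 23).
#' @param max_mismatch Mismatches tolerated in the adapter match (default 0,
#'   exact).
#' @return list with `reads` (trimmed [read_set()]) and `log` (per-read
#'   disposition: `retained` or `adapter_too_short`, with trimmed length and
#'   whether an adapter match was found).
#' @export
trim_reads <- function(rs, adapter = default_adapter(), end_trim = 4L,
                       min_length = 23L, max_mismatch = 0L) {
  stopifnot(end_trim >= 0, min_length >= 1)
  if (stringi::stri_detect_regex(adapter, "[^ACGT]"))
    stop("adapter must be over {A,C,G,T}", call. = FALSE)
  seqs <- rs$reads$sequence
  n <- nchar(seqs)
  cut_at <- rep(NA_integer_, length(seqs))  # 0-based adapter start

  if (max_mismatch == 0L) {
    loc <- stringi::stri_locate_first_fixed(seqs, adapter)[, 1]
    cut_at <- loc - 1L
    # partial suffix-prefix overlap, longest first
    la <- nchar(adapter)
    todo <- is.na(cut_at)
    for (l in seq(min(la - 1L, max(n, 1L)), 1L)) {
      if (!any(todo)) break
      idx <- which(todo & n >= l)
      if (!length(idx)) next
      hit <- substring(seqs[idx], n[idx] - l + 1L, n[idx]) ==
        substr(adapter, 1L, l)
      cut_at[idx[hit]] <- n[idx[hit]] - l
      todo[idx[hit]] <- FALSE
    }
  } else {
    # tolerant scan: leftmost position where the (possibly truncated)
    # adapter aligns with at most max_mismatch mismatches
    la <- nchar(adapter)
    for (i in seq_along(seqs)) {
      best <- NA_integer_
      for (p in 0:(n[i] - 1L)) {
        l <- min(la, n[i] - p)
        if (l < 1L) break
        mm <- sum(strsplit(substr(seqs[i], p + 1L, p + l), "")[[1]] !=
                    strsplit(substr(adapter, 1L, l), "")[[1]])
        if (mm <= max_mismatch) { best <- p; break }
      }
      cut_at[i] <- best
    }
  }

  kept_len <- ifelse(is.na(cut_at), n, cut_at)
  trimmed <- substr(seqs, 1L, kept_len)
  final <- substr(trimmed, end_trim + 1L, kept_len - end_trim)
  final_len <- pmax(kept_len - 2L * end_trim, 0L)
  ok <- final_len >= min_length
  log <- data.frame(
    read_id = rs$reads$read_id,
    disposition = ifelse(ok, "retained", "adapter_too_short"),
    adapter_found = !is.na(cut_at),
    trimmed_length = final_len,
    stringsAsFactors = FALSE
  )
  out <- data.frame(read_id = rs$reads$read_id[ok], sequence = final[ok],
                    stringsAsFactors = FALSE)
  list(reads = read_set(rs$sample_id, rs$assay, out), log = log)
}

#' Remove reads matching abundant contaminant sequences
#'
#' A read is removed iff it occurs as an exact substring of a contaminant
#' record on either strand (mismatch tolerance configurable). Matching uses
#' a preprocessed dictionary per read width against the contaminant pool and
#' its reverse complement. An empty contaminant set is the identity.
#'
#' @param rs A [read_set()].
#' @param contaminants Annotation data.frame rows for the contaminant pool
#'   (rRNA/tRNA records); may be empty.
#' @param max_mismatch Mismatches tolerated (default 0, exact substring).
#' @return list with `reads` (kept [read_set()]), `removed_count`, and
#'   `log` (per-read disposition `kept` / `contaminant`).
#' @export
filter_contaminants <- function(rs, contaminants, max_mismatch = 0L) {
  seqs <- rs$reads$sequence
  hit <- rep(FALSE, length(seqs))
  if (nrow(contaminants) > 0 && length(seqs) > 0) {
    subj <- Biostrings::DNAStringSet(contaminants$sequence)
    subj <- c(subj, Biostrings::reverseComplement(subj))
    if (max_mismatch == 0L) {
      # both strands concatenated with a separator absent from any read, so
      # no pattern can match across a boundary
      big <- paste(as.character(subj), collapse = "\r")
      hit <- stringi::stri_detect_fixed(big, seqs)
    } else {
      widths <- nchar(seqs)
      for (w in unique(widths)) {
        idx <- which(widths == w)
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
        cnt <- Biostrings::vcountPDict(pd, subj,
                                       max.mismatch = as.integer(max_mismatch))
        hit[idx] <- rowSums(cnt) > 0
      }
    }
  }
  log <- data.frame(read_id = rs$reads$read_id,
                    disposition = ifelse(hit, "contaminant", "kept"),
                    stringsAsFactors = FALSE)
  kept <- rs$reads[!hit, , drop = FALSE]
  rownames(kept) <- NULL
  list(reads = read_set(rs$sample_id, rs$assay, kept),
       removed_count = sum(hit), log = log)
}

#' Size-select footprint reads
#'
#' Retains reads with length in `[min_len, max_len]` inclusive, emulating
#' gel excision between the 26 and 32 nt markers. Applied to RPF sets only;
#' mRNA sets pass through unchanged.
#'
#' @param rs A [read_set()].
#' @param min_len,max_len Inclusive length window (defaults 26, 32).
#' @return list with `reads` and `log` (`retained` / `size_rejected`).
#' @export
size_select <- function(rs, min_len = 26L, max_len = 32L) {
  stopifnot(min_len <= max_len)
  if (rs$assay != "RPF") {
    log <- data.frame(read_id = rs$reads$read_id, disposition = "retained",
                      stringsAsFactors = FALSE)
    return(list(reads = rs, log = log))
  }
  n <- nchar(rs$reads$sequence)
  ok <- n >= min_len & n <= max_len
  log <- data.frame(read_id = rs$reads$read_id,
                    disposition = ifelse(ok, "retained", "size_rejected"),
                    stringsAsFactors = FALSE)
  kept <- rs$reads[ok, , drop = FALSE]
  rownames(kept) <- NULL
  list(reads = read_set(rs$sample_id, rs$assay, kept), log = log)
}

#' Build a k-mer index over an annotation
#'
#' Index of every k-mer position in every transcript sequence, used to seed
#' the exact-substring matcher.
#'
#' @param annotation Annotation data.frame (usually the coding records).
#' @param k K-mer size (default 12).
#' @return A `data.table` keyed by `kmer` with columns `transcript_id`,
#'   `pos` (0-based).
#' @export
build_kmer_index <- function(annotation, k = 12L) {
  parts <- lapply(seq_len(nrow(annotation)), function(i) {
    s <- annotation$sequence[i]
    L <- nchar(s)
    if (L < k) return(NULL)
    data.table::data.table(
      kmer = substring(s, 1:(L - k + 1L), k:L),
      transcript_id = annotation$transcript_id[i],
      pos = 0:(L - k)
    )
  })
  idx <- data.table::rbindlist(parts)
  data.table::setkey(idx, kmer)
  idx
}

#' Assign reads to compatible transcripts
#'
#' Each read is mapped to every transcript that contains it as an exact
#' substring (sense strand). Candidate positions are seeded from the read's
#' first k-mer via the index, then verified over the full read, so the
#' result equals a brute-force substring scan.
#'
#' @param rs A [read_set()] (trimmed/filtered).
#' @param annotation Annotation data.frame of target transcripts.
#' @param k K-mer size (default 12); must not exceed the shortest read.
#' @param index Optional prebuilt [build_kmer_index()] for `annotation`/`k`.
#' @return list with `compat` (data.frame `read_id`, `transcript_id`,
#'   `offset` 0-based) and `log` (per-read `assigned` / `unmapped`).
#' @export
assign_reads <- function(rs, annotation, k = 12L, index = NULL) {
  seqs <- rs$reads$sequence
  ids <- rs$reads$read_id
  if (length(seqs) > 0 && k > min(nchar(seqs)))
    stop("k-mer size k = ", k, " exceeds the shortest read", call. = FALSE)
  if (is.null(index)) index <- build_kmer_index(annotation, k)
  empty <- data.frame(read_id = character(0), transcript_id = character(0),
                      offset = integer(0), stringsAsFactors = FALSE)
  if (length(seqs) == 0L) {
    return(list(compat = empty,
                log = data.frame(read_id = character(0),
                                 disposition = character(0))))
  }
  q <- data.table::data.table(read_id = ids, sequence = seqs,
                              len = nchar(seqs), kmer = substr(seqs, 1L, k))
  cand <- index[q, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand) > 0) {
    tseq <- stats::setNames(annotation$sequence, annotation$transcript_id)
    full <- substring(tseq[cand$transcript_id], cand$pos + 1L,
                      cand$pos + cand$len)
    cand <- cand[full == cand$sequence]
  }
  compat <- if (nrow(cand) > 0) {
    data.frame(read_id = cand$read_id, transcript_id = cand$transcript_id,
               offset = cand$pos, stringsAsFactors = FALSE)
  } else empty
  mapped <- ids %in% compat$read_id
  log <- data.frame(read_id = ids,
                    disposition = ifelse(mapped, "assigned", "unmapped"),
                    stringsAsFactors = FALSE)
  list(compat = compat, log = log)
}

#' Resolve multi-mapping reads by expectation-maximization
#'
#' Standard multinomial abundance model: transcript proportions start
#' uniform; each read's weight over its compatible transcripts is
#' proportional to the current proportions (E step); proportions are then
#' the normalized expected counts (M step). Reads are collapsed into
#' equivalence classes by compatibility set, so the cost is per class, not
#' per read. Iteration stops when the largest proportion change is below
#' `tol` (default 1e-8) or after `max_iter` iterations.
#'
#' @param compat Compatibility data.frame from [assign_reads()].
#' @param tol Convergence tolerance on the abundance vector.
#' @param max_iter Iteration cap (default 1000).
#' @return list with `weights` (`read_id`, `transcript_id`, `offset` if
#'   present, `weight`; weights of a read sum to 1), `abundance`
#'   (proportions), `expected_counts` per transcript, `n_iter`, and
#'   `loglik` (trace; non-decreasing).
#' @export
em_resolve_multimappers <- function(compat, tol = 1e-8, max_iter = 1000L) {
  if (nrow(compat) == 0L)
    stop("no mapped reads: compatibility map is empty", call. = FALSE)
  dt <- data.table::as.data.table(compat)
  if ("offset" %in% names(dt)) data.table::setorder(dt, read_id,
                                                    transcript_id, offset)
  else data.table::setorder(dt, read_id, transcript_id)
  # a read matching one transcript at several positions is still one
  # (read, transcript) compatibility; keep the leftmost position
  dt <- unique(dt, by = c("read_id", "transcript_id"))
  cls_of_read <- dt[, .(class = paste(transcript_id, collapse = "\r")),
                    by = read_id]
  classes <- cls_of_read[, .(n_reads = .N), by = class]
  tids <- sort(unique(dt$transcript_id))
  # class membership matrix rows: class, cols via list of transcript indices
  memb <- strsplit(classes$class, "\r", fixed = TRUE)
  memb_idx <- lapply(memb, match, tids)
  n_cls <- nrow(classes)
  cls_rep <- rep(seq_len(n_cls), lengths(memb_idx))
  t_rep <- unlist(memb_idx)
  n_reads_total <- sum(classes$n_reads)

  theta <- rep(1 / length(tids), length(tids))
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    th <- theta[t_rep]
    denom <- rowsum(th, cls_rep)[, 1]
    loglik <- c(loglik, sum(classes$n_reads * log(denom)))
    w <- th / denom[cls_rep]                    # E step
    exp_cnt <- rowsum(w * classes$n_reads[cls_rep], t_rep)[, 1]
    new_theta <- exp_cnt / n_reads_total        # M step
    delta <- max(abs(new_theta - theta))
    theta <- new_theta
    if (delta < tol) break
  }
  names(theta) <- tids
  # final per-pair weights back on reads
  th <- theta[t_rep]
  denom <- rowsum(th, cls_rep)[, 1]
  w_cls <- th / denom[cls_rep]
  cls_key <- data.table::data.table(class = classes$class[cls_rep],
                                    transcript_id = tids[t_rep],
                                    weight = w_cls)
  dt2 <- dt[cls_of_read, on = "read_id"]
  dt2 <- cls_key[dt2, on = c("class", "transcript_id")]
  weights <- as.data.frame(dt2[, c("read_id", "transcript_id",
                                   if ("offset" %in% names(dt2)) "offset",
                                   "weight"), with = FALSE])
  expected_counts <- theta * n_reads_total
  list(weights = weights, abundance = theta,
       expected_counts = expected_counts, n_iter = it, loglik = loglik)
}

#' Aggregate weights into gene counts and coverage profiles
#'
#' Gene counts sum the fractional weights of all reads assigned to the
#' gene's transcripts. Coverage profiles record footprint 5'-end weight at
#' each CDS position (reads whose 5' end falls outside the CDS contribute
#' to the count but not to the profile).
#'
#' @param weights Weight data.frame from [em_resolve_multimappers()]
#'   (must include `offset`).
#' @param annotation Annotation data.frame.
#' @return list with `gene_counts` (named numeric over all coding genes) and
#'   `profiles` (named list of per-CDS-position numeric vectors).
#' @export
count_and_profile <- function(weights, annotation) {
  cod <- coding_annotation(annotation)
  gene_of <- stats::setNames(cod$gene_id, cod$transcript_id)
  gene_counts <- stats::setNames(numeric(nrow(cod)), cod$gene_id)
  if (nrow(weights) > 0) {
    g <- gene_of[weights$transcript_id]
    if (anyNA(g))
      stop("weights reference transcripts absent from the annotation",
           call. = FALSE)
    agg <- rowsum(weights$weight, g)
    gene_counts[rownames(agg)] <- agg[, 1]
  }
  profiles <- list()
  for (i in seq_len(nrow(cod))) {
    L <- cod$cds_end[i] - cod$cds_start[i]
    prof <- numeric(L)
    sel <- weights$transcript_id == cod$transcript_id[i]
    if (any(sel)) {
      pos <- weights$offset[sel] - cod$cds_start[i]
      inside <- pos >= 0 & pos < L
      if (any(inside)) {
        agg <- rowsum(weights$weight[sel][inside], pos[inside])
        prof[as.integer(rownames(agg)) + 1L] <- agg[, 1]
      }
    }
    profiles[[cod$transcript_id[i]]] <- prof
  }
  list(gene_counts = gene_counts, profiles = profiles)
}

#' Ingest alignments from SAM/BAM into a compatibility map
#'
#' Records with mapping quality below `mapq_min` (default 5) are dropped
#' (MAPQ 255, "unavailable", is kept); unmapped records are dropped with a
#' warning if nothing maps. Primary, secondary and supplementary records
#' sharing a read id form that read's compatibility set.
#'
#' @param path SAM or BAM file aligned against transcript references.
#' @param annotation Annotation data.frame; reference names must be a subset
#'   of its transcript ids.
#' @param mapq_min Minimum mapping quality retained (default 5).
#' @return Compatibility data.frame (`read_id`, `transcript_id`, `offset`).
#' @export
ingest_alignments <- function(path, annotation, mapq_min = 5L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "mapq"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(rec$flag, 4L)
  keep <- mapped & (is.na(rec$mapq) | rec$mapq == 255L | rec$mapq >= mapq_min)
  if (!any(keep)) {
    warning("no usable alignment records in ", path, call. = FALSE)
    return(data.frame(read_id = character(0), transcript_id = character(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  }
  tid <- as.character(rec$rname[keep])
  unknown <- setdiff(unique(tid), annotation$transcript_id)
  if (length(unknown))
    stop("alignment references absent from annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- data.frame(read_id = rec$qname[keep], transcript_id = tid,
                    offset = rec$pos[keep] - 1L, stringsAsFactors = FALSE)
  unique(out)
}

#' Process one library from raw reads to gene counts
#'
#' Runs trimming, contaminant filtering, size selection (RPF only),
#' assignment, EM resolution, and aggregation, keeping a per-read
#' disposition log in which every input read lands in exactly one category:
#' `adapter_too_short`, `contaminant`, `size_rejected`, `unmapped`, or
#' `assigned`.
#'
#' @param rs A raw [read_set()].
#' @param annotation Annotation data.frame (coding + contaminants).
#' @param adapter,end_trim,min_length Trimming parameters ([trim_reads()]).
#' @param size_min,size_max Footprint window ([size_select()]).
#' @param k K-mer size for the matcher.
#' @param index Optional prebuilt k-mer index over the coding records.
#' @return list with `gene_counts`, `profiles`, `weights`, `log`
#'   (read_id, disposition), and `library_size` (reads surviving all
#'   filters, i.e. assigned + unmapped).
#' @export
process_sample <- function(rs, annotation, adapter = default_adapter(),
                           end_trim = 4L, min_length = 23L,
                           size_min = 26L, size_max = 32L, k = 12L,
                           index = NULL) {
  tr <- trim_reads(rs, adapter, end_trim, min_length)
  fl <- filter_contaminants(tr$reads, contaminant_annotation(annotation))
  sz <- size_select(fl$reads, size_min, size_max)
  cod <- coding_annotation(annotation)
  as_ <- assign_reads(sz$reads, cod, k = k, index = index)
  disposition <- stats::setNames(tr$log$disposition, tr$log$read_id)
  disposition[fl$log$read_id[fl$log$disposition == "contaminant"]] <- "contaminant"
  disposition[sz$log$read_id[sz$log$disposition == "size_rejected"]] <- "size_rejected"
  disposition[as_$log$read_id] <- as_$log$disposition
  log <- data.frame(read_id = names(disposition),
                    disposition = unname(disposition),
                    stringsAsFactors = FALSE)
  if (nrow(as_$compat) > 0) {
    em <- em_resolve_multimappers(as_$compat)
    cp <- count_and_profile(em$weights, annotation)
    weights <- em$weights
  } else {
    cp <- count_and_profile(
      data.frame(read_id = character(0), transcript_id = character(0),
                 offset = integer(0), weight = numeric(0)), annotation)
    weights <- NULL
  }
  list(gene_counts = cp$gene_counts, profiles = cp$profiles,
       weights = weights, log = log,
       library_size = nrow(sz$reads$reads))
}

#' Process a full experiment into RPF and mRNA count matrices
#'
#' @param read_sets Named list of raw [read_set()]s (names = sample ids).
#' @param annotation Annotation data.frame.
#' @param design Sample design data.frame.
#' @param ... Passed to [process_sample()].
#' @return list with `rpf` / `mrna` gene-by-sample matrices (attribute
#'   `library_size`), `profiles` (per sample), and `logs` (per sample).
#' @export
process_experiment <- function(read_sets, annotation, design, ...) {
  .check_design(design)
  extra <- setdiff(names(read_sets), design$sample_id)
  if (length(extra))
    stop("read sets not in design: ", paste(extra, collapse = ", "),
         call. = FALSE)
  cod <- coding_annotation(annotation)
  dots <- list(...)
  k <- if (!is.null(dots$k)) dots$k else 12L
  index <- build_kmer_index(cod, k)
  res <- lapply(read_sets, process_sample, annotation = annotation,
                index = index, ...)
  mk <- function(assay) {
    sub <- design[design$assay == assay & design$sample_id %in% names(res), ]
    m <- sapply(sub$sample_id, function(s) res[[s]]$gene_counts)
    m <- matrix(m, nrow = nrow(cod),
                dimnames = list(cod$gene_id, sub$sample_id))
    attr(m, "library_size") <-
      stats::setNames(vapply(sub$sample_id,
                             function(s) res[[s]]$library_size, numeric(1)),
                      sub$sample_id)
    m
  }
  list(rpf = mk("RPF"), mrna = mk("mRNA"),
       profiles = lapply(res, `[[`, "profiles"),
       logs = lapply(res, `[[`, "log"))
}
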