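adapter <- default_adapter()

test_that("adapter trimming follows the stated arithmetic", {
  ins <- strrep("ACGT", 10)            # 40 nt insert
  ins31 <- substr(ins, 1, 31)
  rs <- make_read_set(c(paste0(ins31, adapter),   # full adapter
                        random_read(25)))         # no adapter, too short
  out <- trim_reads(rs, adapter, end_trim = 4L, min_length = 23L)
  # insert 31 nt minus 4 from each end = 23, retained
  expect_equal(nchar(out$reads$reads$sequence[1]), 31 - 2 * 4)
  expect_equal(out$log$disposition[1], "retained")
  # 25 nt - 8 = 17 < 23 regardless of adapter outcome
  expect_equal(out$log$disposition[2], "adapter_too_short")
  expect_equal(nrow(out$reads$reads), 1)
})

test_that("partial 3' adapters are located by longest suffix-prefix overlap", {
  ins <- strrep("TTGACCAGTA", 4)       # 40 nt
  partial <- substr(adapter, 1, 8)
  rs <- make_read_set(paste0(ins, partial))
  out <- trim_reads(rs, adapter)
  expect_equal(out$reads$reads$sequence, substr(ins, 5, 36))
  expect_true(out$log$adapter_found)
})

test_that("trimming equals the brute-force per-read oracle on 100 reads", {
  set.seed(71)
  seqs <- vapply(1:100, function(i) {
    ins <- random_read(sample(15:45, 1))
    tail <- switch(sample(3, 1),
                   adapter,                              # full
                   substr(adapter, 1, sample(1:20, 1)),  # partial
                   "")                                   # none
    paste0(ins, tail)
  }, character(1))
  rs <- make_read_set(seqs)
  out <- trim_reads(rs, adapter, end_trim = 4L, min_length = 23L)
  orc <- lapply(seqs, oracle_trim, adapter = adapter, end_trim = 4L,
                min_length = 23L)
  keep <- vapply(orc, `[[`, logical(1), "retained")
  expect_equal(out$log$disposition == "retained", keep)
  expect_equal(out$reads$reads$sequence,
               vapply(orc[keep], `[[`, character(1), "sequence"))
})

test_that("non-ACGT adapter is an input error", {
  expect_error(trim_reads(make_read_set("ACGT"), adapter = "ACGTN"),
               "A,C,G,T")
})

test_that("contaminant filtering removes exact matches on either strand", {
  ann <- tiny_annotation()
  contam <- contaminant_annotation(ann)
  trna <- contam$sequence[contam$gene_class == "contaminant-tRNA"]
  hit_fwd <- substr(trna, 3, 32)
  hit_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(trna, 5, 34))))
  miss <- substr(coding_annotation(ann)$sequence[1], 11, 40)
  rs <- make_read_set(c(hit_fwd, hit_rev, miss))
  out <- filter_contaminants(rs, contam)
  expect_equal(out$removed_count, 2)
  expect_equal(out$reads$reads$sequence, miss)
  # empty contaminant set is the identity
  id <- filter_contaminants(rs, contam[0, ])
  expect_equal(id$removed_count, 0)
  expect_identical(id$reads$reads, rs$reads)
})

test_that("planted contaminant reads are removed exactly, by truth file", {
  ann <- build_default_annotation(seed = 4)
  sim <- simulate_riboseq_experiment(
    ann, riboseq_design(replicates = 2L), truth_table(ann),
    reads_per_sample = 2000, contaminant_fraction = 0.1, seed = 13)
  rs <- sim$read_sets[[1]]
  tr <- trim_reads(rs)
  out <- filter_contaminants(tr$reads, contaminant_annotation(ann))
  truth <- sim$read_truth[sim$read_truth$sample_id == rs$sample_id, ]
  planted <- truth$read_id[truth$origin_class == "contaminant"]
  removed <- out$log$read_id[out$log$disposition == "contaminant"]
  # every planted contaminant read must be caught; a handful of gene reads
  # may coincide with a contaminant subsequence by chance
  expect_true(all(planted %in% removed))
  expect_lte(length(setdiff(removed, planted)), 2)
})

test_that("size selection is inclusive at both boundaries, RPF only", {
  seqs <- vapply(c(25, 26, 32, 33), random_read, character(1))
  out <- size_select(make_read_set(seqs))
  expect_equal(nchar(out$reads$reads$sequence), c(26, 32))
  mrna <- size_select(make_read_set(seqs, assay = "mRNA"))
  expect_equal(nrow(mrna$reads$reads), 4)
  # uniform lengths 20..40: exactly the lengths in [26, 32] survive
  set.seed(5)
  lens <- sample(20:40, 200, replace = TRUE)
  all_rs <- make_read_set(vapply(lens, random_read, character(1)))
  kept <- size_select(all_rs)
  expect_equal(nrow(kept$reads$reads), sum(lens >= 26 & lens <= 32))
})

test_that("read assignment equals a brute-force substring scan", {
  ann <- build_default_annotation(
    sim_config(n_nuclear_oxphos = 3L, n_mito_assoc = 0L, n_other = 3L),
    seed = 9)
  cod <- coding_annotation(ann)
  set.seed(17)
  # reads drawn from transcripts plus pure-random decoys
  picks <- sample(nrow(cod), 80, replace = TRUE)
  seqs <- vapply(picks, function(i) {
    L <- nchar(cod$sequence[i]); w <- sample(26:32, 1)
    s <- sample(L - w + 1, 1)
    substr(cod$sequence[i], s, s + w - 1)
  }, character(1))
  seqs <- c(seqs, vapply(rep(28, 20), random_read, character(1)))
  rs <- make_read_set(seqs)
  out <- assign_reads(rs, cod, k = 12L)
  # quadratic oracle
  for (j in seq_along(seqs)) {
    hits <- which(stringi::stri_detect_fixed(cod$sequence, seqs[j]))
    got <- out$compat[out$compat$read_id == rs$reads$read_id[j], ]
    expect_setequal(got$transcript_id, cod$transcript_id[hits])
    if (nrow(got) > 0) {
      off <- stringi::stri_locate_first_fixed(
        cod$sequence[match(got$transcript_id, cod$transcript_id)],
        seqs[j])[, 1] - 1L
      expect_equal(got$offset[order(got$transcript_id)],
                   unname(off[order(got$transcript_id)]))
    }
  }
  expect_equal(sum(out$log$disposition == "unmapped"), 20)
})

test_that("k larger than the shortest read is a configuration error", {
  rs <- make_read_set(c(random_read(30), random_read(10)))
  expect_error(assign_reads(rs, coding_annotation(tiny_annotation()), k = 12L),
               "exceeds the shortest read")
})

test_that("EM resolves the worked multimapper fixed points", {
  # two reads unique to A, one shared A/B: shared weight on A converges to 1
  compat <- data.frame(
    read_id = c("r1", "r2", "r3", "r3"),
    transcript_id = c("A", "A", "A", "B"),
    offset = 0L, stringsAsFactors = FALSE)
  em <- em_resolve_multimappers(compat)
  w3 <- em$weights[em$weights$read_id == "r3", ]
  expect_lt(abs(w3$weight[w3$transcript_id == "A"] - 1), 1e-6)
  # symmetric case: shared read splits 0.5/0.5
  sym <- data.frame(
    read_id = c("a", "b", "s", "s"),
    transcript_id = c("A", "B", "A", "B"),
    offset = 0L, stringsAsFactors = FALSE)
  em2 <- em_resolve_multimappers(sym)
  ws <- em2$weights[em2$weights$read_id == "s", ]
  expect_equal(ws$weight, c(0.5, 0.5), tolerance = 1e-9)
  # unique read keeps weight 1
  expect_equal(em2$weights$weight[em2$weights$read_id == "a"], 1)
})

test_that("EM log-likelihood is non-decreasing and weights sum to 1", {
  set.seed(23)
  tx <- LETTERS[1:5]
  compat <- do.call(rbind, lapply(1:60, function(i) {
    k <- sample(1:3, 1)
    data.frame(read_id = sprintf("r%02d", i),
               transcript_id = sample(tx, k), offset = 0L)
  }))
  em <- em_resolve_multimappers(compat)
  expect_true(all(diff(em$loglik) > -1e-9))
  per_read <- tapply(em$weights$weight, em$weights$read_id, sum)
  expect_true(all(abs(per_read - 1) < 1e-9))
  expect_equal(sum(em$expected_counts), 60, tolerance = 1e-6)
})

test_that("counting conserves assigned reads and recovers planted counts", {
  ann <- tiny_annotation()
  cod <- coding_annotation(ann)
  # 7 unique reads on mt-Nd1, 3 on NuOx1
  seqs <- c(vapply(10 + (1:7), function(s)
    substr(cod$sequence[1], s, s + 27), character(1)),
    vapply(20 + (1:3), function(s)
      substr(cod$sequence[3], s, s + 27), character(1)))
  rs <- make_read_set(seqs)
  as_ <- assign_reads(rs, cod, k = 12L)
  em <- em_resolve_multimappers(as_$compat)
  cp <- count_and_profile(em$weights, ann)
  # repeat-built sequences make reads multi-map within a transcript is not
  # possible across transcripts here; totals must be conserved regardless
  expect_equal(sum(cp$gene_counts), 10, tolerance = 1e-6)
  expect_equal(unname(cp$gene_counts["mt-Nd1"]), 7, tolerance = 1e-6)
  expect_equal(unname(cp$gene_counts["NuOx1"]), 3, tolerance = 1e-6)
  expect_equal(sum(cp$profiles[["mt-Nd1"]]), 7, tolerance = 1e-6)
  expect_equal(length(cp$profiles[["mt-Nd1"]]),
               cod$cds_end[1] - cod$cds_start[1])
})

test_that("zero-noise pipeline recovers planted per-gene counts exactly", {
  ann <- build_default_annotation(
    sim_config(n_nuclear_oxphos = 2L, n_mito_assoc = 0L, n_other = 2L),
    seed = 14)
  des <- riboseq_design(replicates = 2L)
  sim <- simulate_riboseq_experiment(ann, des, truth_table(ann),
                                     reads_per_sample = 1500,
                                     contaminant_fraction = 0, seed = 15)
  proc <- process_experiment(sim$read_sets, ann, des)
  truth <- sim$read_truth
  for (s in colnames(proc$rpf)) {
    tr <- truth[truth$sample_id == s, ]
    planted <- table(factor(tr$origin, levels = rownames(proc$rpf)))
    expect_equal(unname(proc$rpf[, s]), as.numeric(planted),
                 tolerance = 1e-6)
  }
})

test_that("every read lands in exactly one disposition category", {
  ann <- build_default_annotation(seed = 4)
  des <- riboseq_design(replicates = 2L)
  sim <- simulate_riboseq_experiment(ann, des, truth_table(ann),
                                     reads_per_sample = 1500,
                                     contaminant_fraction = 0.1, seed = 16)
  proc <- process_experiment(sim$read_sets, ann, des)
  for (s in names(proc$logs)) {
    lg <- proc$logs[[s]]
    input_ids <- sim$read_sets[[s]]$reads$read_id
    expect_setequal(lg$read_id, input_ids)
    expect_equal(nrow(lg), length(input_ids))
    expect_true(all(lg$disposition %in%
      c("adapter_too_short", "contaminant", "size_rejected",
        "unmapped", "assigned")))
    expect_equal(sum(lg$disposition == "assigned") +
                   sum(lg$disposition == "unmapped"),
                 attr(if (grepl("RPF", s)) proc$rpf else proc$mrna,
                      "library_size")[s][[1]])
  }
})

test_that("SAM export / ingest round-trips the compatibility map", {
  ann <- tiny_annotation()
  cod <- coding_annotation(ann)
  seqs <- vapply(10 + (1:10), function(s)
    substr(cod$sequence[1 + (s %% 3)], s, s + 27), character(1))
  rs <- make_read_set(seqs)
  as_ <- assign_reads(rs, cod, k = 12L)
  d <- withr::local_tempdir()
  sam <- file.path(d, "aln.sam")
  write_alignments_sam(as_$compat, rs, cod, sam)
  back <- ingest_alignments(sam, cod, mapq_min = 5L)
  key <- function(x) x[order(x$read_id, x$transcript_id, x$offset), ]
  expect_equal(key(back), key(as_$compat), ignore_attr = TRUE)
})

test_that("MAPQ filtering drops below-threshold records at the boundary", {
  ann <- tiny_annotation()
  d <- withr::local_tempdir()
  sam <- file.path(d, "m.sam")
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", ann$transcript_id, nchar(ann$sequence)),
    sprintf("r1\t0\tmt-Nd1\t11\t4\t28M\t*\t0\t0\t%s\t*",
            substr(ann$sequence[1], 11, 38)),
    sprintf("r2\t0\tmt-Nd1\t11\t5\t28M\t*\t0\t0\t%s\t*",
            substr(ann$sequence[1], 11, 38))), sam)
  out <- ingest_alignments(sam, ann, mapq_min = 5L)
  expect_equal(out$read_id, "r2")
  expect_equal(out$offset, 10L)
  # unknown reference is a mismatch error
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrX\tLN:100",
               "r\t0\tchrX\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*"),
             file.path(d, "bad.sam"))
  expect_error(ingest_alignments(file.path(d, "bad.sam"), ann),
               "absent from annotation")
  # only unmapped records: empty map with a warning
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", ann$transcript_id[1],
                       nchar(ann$sequence[1])),
               "r\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*"),
             file.path(d, "unmapped.sam"))
  expect_warning(res <- ingest_alignments(file.path(d, "unmapped.sam"), ann),
                 "no usable")
  expect_equal(nrow(res), 0)
})
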