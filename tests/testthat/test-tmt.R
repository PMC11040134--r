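pep_table <- function(mat, proteins = NULL) {
  n <- nrow(mat)
  if (is.null(proteins)) proteins <- sprintf("P%02d", seq_len(n))
  data.frame(peptide_id = sprintf("pep%02d", seq_len(n)),
             protein_id = proteins, mat, check.names = FALSE,
             stringsAsFactors = FALSE)
}

test_that("identity impurity matrix leaves intensities unchanged", {
  M <- diag(3); dimnames(M) <- list(c("c1", "c2", "c3"), c("c1", "c2", "c3"))
  x <- matrix(c(100, 50, 25, 10, NA, 5), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("c1", "c2", "c3")))
  tab <- pep_table(x)
  out <- correct_isotope_impurities(tab, M)
  expect_equal(out, tab)
})

test_that("2-channel 10% crosstalk is inverted exactly", {
  M <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE,
              dimnames = list(c("c1", "c2"), c("c1", "c2")))
  # true (100, 0) observed as (0.9*100, 0.1*100)
  tab <- pep_table(matrix(c(90, 10), 1, 2,
                          dimnames = list(NULL, c("c1", "c2"))))
  out <- correct_isotope_impurities(tab, M)
  expect_equal(unlist(out[1, c("c1", "c2")]), c(c1 = 100, c2 = 0),
               tolerance = 1e-10)
})

test_that("forward mixing then correction round-trips within 1e-8", {
  set.seed(12)
  M <- default_impurity_matrix(sprintf("c%02d", 1:16))
  true <- matrix(rlnorm(10 * 16, 10, 1), 10, 16,
                 dimnames = list(NULL, sprintf("c%02d", 1:16)))
  obs <- true %*% M
  out <- correct_isotope_impurities(pep_table(obs), M)
  expect_equal(as.matrix(out[, colnames(true)]), true, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("all-missing rows and singular matrices degrade gracefully", {
  M <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
              dimnames = list(c("c1", "c2"), c("c1", "c2")))
  tab <- pep_table(matrix(c(NA, NA), 1, 2,
                          dimnames = list(NULL, c("c1", "c2"))))
  expect_warning(out <- correct_isotope_impurities(tab, M), "singular")
  expect_equal(out, tab)
  M2 <- diag(2); dimnames(M2) <- dimnames(M)
  out2 <- correct_isotope_impurities(tab, M2)
  expect_true(all(is.na(out2[, c("c1", "c2")])))
})

test_that("median sweep equalizes channel medians; doubling shifts by -1", {
  set.seed(3)
  v <- 2^rnorm(50, 15, 1)
  x <- cbind(c1 = v, c2 = 2 * v)   # channel 2 globally doubled
  out <- normalize_channels(pep_table(x))
  # after the sweep the doubled channel coincides with the original, i.e.
  # its log2 values were shifted down by exactly 1
  expect_equal(out$c2, out$c1, tolerance = 1e-12)
  expect_equal((log2(x[, "c2"]) - out$c2) - (log2(x[, "c1"]) - out$c1),
               rep(1, 50), tolerance = 1e-12, ignore_attr = TRUE)
  meds <- apply(as.matrix(out[, c("c1", "c2")]), 2, median)
  expect_lt(max(meds) - min(meds), 1e-9)
})

test_that("log-uniform loading imbalance is removed to 1e-9", {
  set.seed(8)
  ch <- paste0("c", 1:6)
  x <- matrix(2^rnorm(300 * 6, 18, 1.5), 300, 6, dimnames = list(NULL, ch))
  fac <- 2^runif(6, -1, 1)
  out <- normalize_channels(pep_table(sweep(x, 2, fac, "*")))
  m <- as.matrix(out[, ch])
  meds <- apply(m, 2, median, na.rm = TRUE)
  expect_lt(max(meds) - min(meds), 1e-9)
})

test_that("rollup is the group mean, ignoring missing values", {
  tab <- data.frame(peptide_id = c("p1", "p2", "p3"),
                    protein_id = c("A", "A", "B"),
                    c1 = c(4, 6, 1), c2 = c(2, NA, 3),
                    stringsAsFactors = FALSE)
  m <- rollup_proteins(tab)
  expect_equal(m["A", "c1"], 5)
  expect_equal(m["A", "c2"], 2)   # missing ignored
  expect_equal(m["B", "c1"], 1)
  expect_equal(unname(attr(m, "n_peptides")["A"]), 2L)
  # random table vs brute-force oracle
  set.seed(9)
  big <- data.frame(peptide_id = sprintf("p%03d", 1:120),
                    protein_id = sample(LETTERS[1:10], 120, replace = TRUE),
                    matrix(rnorm(120 * 5), 120, 5,
                           dimnames = list(NULL, paste0("ch", 1:5))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  got <- rollup_proteins(big)
  for (p in rownames(got)) {
    sub <- as.matrix(big[big$protein_id == p, paste0("ch", 1:5)])
    expect_equal(got[p, ], colMeans(sub), tolerance = 1e-12)
  }
})

test_that("shared peptides are dropped or assigned first per config", {
  tab <- data.frame(peptide_id = c("p1", "p1", "p2"),
                    protein_id = c("A", "B", "A"),
                    c1 = c(1, 1, 5), stringsAsFactors = FALSE)
  dropped <- rollup_proteins(tab)
  expect_equal(rownames(dropped), "A")
  expect_equal(dropped["A", "c1"], 5)
  first <- rollup_proteins(tab, shared_peptides = "assign_first")
  expect_equal(first["A", "c1"], 3)
})

test_that("BH step-up matches the hand-worked example and brute force", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # brute-force step-up oracle on random vectors
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    out <- numeric(m)
    out[o] <- pmin(q, 1)
    out
  }
  set.seed(10)
  for (i in 1:25) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, method = "BH"), bh_oracle(p),
                 tolerance = 1e-12)
  }
})

test_that("protein statistics implement the gated cascade", {
  des <- tmt_plex_design()
  prots <- sprintf("P%02d", 1:40)
  tmt <- simulate_tmt_experiment(
    prots, truth = tmt_truth_table(prots, shift_homo = c(P01 = -1)),
    sigma = 0.1, loading_sd = 0, dropout_rate = 0, seed = 19)
  pm <- rollup_proteins(normalize_channels(tmt$peptides, des), des)
  st <- protein_statistics(pm, des)
  expect_equal(st$protein_id, rownames(pm))
  hit <- st[st$protein_id == "P01", ]
  expect_true(hit$passes_homo)
  expect_lt(abs(hit$log2fc_homo + 1), 0.15)
  expect_true(all(st$bh_q >= st$anova_p - 1e-12, na.rm = TRUE))
  # flat protein: near-null ANOVA, not passing
  expect_false(any(st$passes_het[st$protein_id != "P01"] &
                     st$passes_homo[st$protein_id != "P01"]))
  # fold change definition
  expect_equal(st$log2fc_homo, st$mean_homo - st$mean_control)
})

test_that("planted homo shift passes the gate with accurate fold change", {
  # sigma 0.1, 5 replicates: the gate must fire nearly always and the
  # estimated shift stay within +/-0.15 of -1
  prots <- sprintf("P%02d", 1:30)
  hits <- 0; fcs <- numeric(0)
  for (s in 1:20) {
    tmt <- simulate_tmt_experiment(
      prots, truth = tmt_truth_table(prots, shift_homo = c(P01 = -1)),
      sigma = 0.1, dropout_rate = 0, seed = 100 + s)
    pm <- rollup_proteins(normalize_channels(tmt$peptides, tmt$design),
                          tmt$design)
    st <- protein_statistics(pm, tmt$design)
    row <- st[st$protein_id == "P01", ]
    hits <- hits + row$passes_homo
    fcs <- c(fcs, row$log2fc_homo)
  }
  expect_gte(hits / 20, 0.95)
  expect_gte(mean(abs(fcs + 1) <= 0.15), 0.95)
})

test_that("missing values in one protein do not perturb another", {
  des <- tmt_plex_design()
  tmt <- simulate_tmt_experiment(c("A", "B"), sigma = 0.1,
                                 dropout_rate = 0, seed = 23)
  # few peptides: the low-count channel warning is expected here
  pm1 <- rollup_proteins(suppressWarnings(normalize_channels(tmt$peptides, des)),
                         des)
  pep2 <- tmt$peptides
  bidx <- which(pep2$protein_id == "B")[1]
  pep2[bidx, des$channel[1]] <- NA
  pm2 <- rollup_proteins(suppressWarnings(normalize_channels(pep2, des)), des)
  s1 <- protein_statistics(pm1, des)
  s2 <- protein_statistics(pm2, des)
  a1 <- s1[s1$protein_id == "A", c("anova_p", "ttest_p_het", "ttest_p_homo")]
  a2 <- s2[s2$protein_id == "A", c("anova_p", "ttest_p_het", "ttest_p_homo")]
  # identical up to the (tiny) change in the normalization medians
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("mitochondrial flagging is case-insensitive and idempotent", {
  rec <- data.frame(protein_id = c("Mrpl12", "Gapdh", "MT-ND1"),
                    stringsAsFactors = FALSE)
  out <- annotate_mito(rec, c("MRPL12", "mt-Nd1"))
  expect_equal(out$mito_flag, c(TRUE, FALSE, TRUE))
  dup <- annotate_mito(rec, c("MRPL12", "MRPL12", "mt-Nd1"))
  expect_equal(dup$mito_flag, out$mito_flag)
  expect_warning(none <- annotate_mito(rec, character(0)), "empty")
  expect_false(any(none$mito_flag))
})

test_that("dot-plot table has one row per protein and comparison", {
  rec <- data.frame(protein_id = c("A", "B"),
                    log2fc_het = c(0.5, -1), log2fc_homo = c(0, 2),
                    ttest_p_het = c(0.01, 1), ttest_p_homo = c(0, 0.5),
                    stringsAsFactors = FALSE)
  dot <- dotplot_table(rec, cap = 16)
  expect_equal(nrow(dot), 4)
  expect_equal(dot$neg_log10_p[dot$protein_id == "A" &
                                 dot$comparison == "het_vs_control"], 2)
  expect_equal(dot$neg_log10_p[dot$protein_id == "B" &
                                 dot$comparison == "het_vs_control"], 0)
  # p = 0 is capped
  expect_equal(dot$neg_log10_p[dot$protein_id == "A" &
                                 dot$comparison == "homo_vs_control"], 16)
})
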