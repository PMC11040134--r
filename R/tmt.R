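.channel_cols <- function(peptides, impurity = NULL, design = NULL) {
  meta <- c("peptide_id", "protein_id")
  ch <- setdiff(names(peptides), meta)
  if (!is.null(impurity)) ch <- intersect(ch, rownames(impurity))
  if (!is.null(design)) ch <- intersect(ch, design$channel)
  ch
}

#' Correct TMT reporter intensities for channel isotope impurities
#'
#' The label of channel i reports fraction `M[i, j]` of its signal in
#' channel j, so observed intensities are `obs = true %*% M` per peptide.
#' The correction solves the linear system for the true intensities, with
#' negative solutions clamped to zero. Missing values are treated as zero
#' during the solve and restored to missing afterwards; rows that are
#' entirely missing pass through unchanged. A singular impurity matrix
#' leaves the table unchanged with a warning.
#'
#' @param peptides Peptide table (`peptide_id`, `protein_id`, one intensity
#'   column per channel).
#' @param impurity Square impurity matrix with channel dimnames; rows must
#'   sum to at most 1 (plus rounding).
#' @return The corrected peptide table.
#' @export
correct_isotope_impurities <- function(peptides, impurity) {
  stopifnot(nrow(impurity) == ncol(impurity))
  if (any(rowSums(impurity) > 1 + 1e-6))
    stop("impurity matrix rows must sum to <= 1", call. = FALSE)
  ch <- .channel_cols(peptides, impurity = impurity)
  if (!setequal(ch, rownames(impurity)))
    stop("peptide table channels do not match the impurity matrix",
         call. = FALSE)
  M <- impurity[ch, ch]
  obs <- as.matrix(peptides[, ch, drop = FALSE])
  miss <- is.na(obs)
  inv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(inv)) {
    warning("impurity matrix is singular; raw intensities passed through",
            call. = FALSE)
    return(peptides)
  }
  x <- obs
  x[miss] <- 0
  true <- x %*% inv
  true[true < 0] <- 0
  true[miss] <- NA_real_
  peptides[, ch] <- true
  peptides
}

#' Normalize TMT channels by median sweep (log2 scale)
#'
#' Intensities are log2-transformed (zeros treated as missing); each
#' occupied channel's peptide-level median is subtracted and the grand
#' median (over all occupied channels) added back, so afterwards every
#' occupied channel has the same peptide-level median. This is the
#' fixed-effects median solution of the ANOVA-style normalization model for
#' channel loading. A channel with fewer than 10 non-missing values is left
#' at the grand-median shift only (warning).
#'
#' @param peptides Peptide table on the intensity scale.
#' @param design Optional plex design; unused channels are excluded from the
#'   grand median and left unshifted.
#' @return Peptide table on the log2 scale, channel medians equalized.
#' @export
normalize_channels <- function(peptides, design = NULL) {
  ch <- .channel_cols(peptides, design = design)
  occupied <- if (!is.null(design)) {
    intersect(ch, design$channel[design$genotype != "unused"])
  } else ch
  x <- as.matrix(peptides[, ch, drop = FALSE])
  x[x <= 0] <- NA_real_
  x <- log2(x)
  med <- apply(x[, occupied, drop = FALSE], 2, stats::median, na.rm = TRUE)
  grand <- stats::median(x[, occupied], na.rm = TRUE)
  nval <- colSums(!is.na(x[, occupied, drop = FALSE]))
  low <- nval < 10
  if (any(low))
    warning("channels with < 10 non-missing values left at grand median: ",
            paste(occupied[low], collapse = ", "), call. = FALSE)
  shift <- ifelse(low, 0, med - grand)
  x[, occupied] <- sweep(x[, occupied, drop = FALSE], 2, shift, "-")
  peptides[, ch] <- x
  peptides
}

#' Roll peptides up to proteins (mean of log2 values)
#'
#' The protein value in a channel is the mean of its peptides' normalized
#' log2 values, ignoring missing values. Peptides mapped to more than one
#' protein are dropped by default (`shared_peptides = "drop"`) or assigned
#' to their first protein (`"assign_first"`). Every protein with at least
#' one peptide is retained.
#'
#' @param peptides Normalized peptide table (log2 scale).
#' @param design Optional design restricting the channel columns.
#' @param shared_peptides `"drop"` or `"assign_first"`.
#' @return Protein-by-channel numeric matrix; attribute `n_peptides` gives
#'   the peptide count per protein.
#' @export
rollup_proteins <- function(peptides, design = NULL,
                            shared_peptides = c("drop", "assign_first")) {
  shared_peptides <- match.arg(shared_peptides)
  ch <- .channel_cols(peptides, design = design)
  np <- tapply(peptides$protein_id, peptides$peptide_id,
               function(p) length(unique(p)))
  shared <- names(np)[np > 1]
  if (length(shared)) {
    if (shared_peptides == "drop") {
      peptides <- peptides[!peptides$peptide_id %in% shared, , drop = FALSE]
    } else {
      keep1 <- !duplicated(peptides$peptide_id)
      peptides <- peptides[keep1 | !peptides$peptide_id %in% shared, ,
                           drop = FALSE]
    }
  }
  x <- as.matrix(peptides[, ch, drop = FALSE])
  prot <- factor(peptides$protein_id, levels = unique(peptides$protein_id))
  sums <- rowsum(ifelse(is.na(x), 0, x), prot)
  ns <- rowsum((!is.na(x)) * 1, prot)
  m <- sums / ns
  m[ns == 0] <- NA_real_
  attr(m, "n_peptides") <- stats::setNames(as.integer(table(prot)[rownames(m)]),
                                           rownames(m))
  m
}

# row-wise group summaries with missing values
.group_summaries <- function(x, groups, levels) {
  lapply(levels, function(g) {
    xi <- x[, groups == g, drop = FALSE]
    n <- rowSums(!is.na(xi))
    s <- rowSums(xi, na.rm = TRUE)
    m <- ifelse(n > 0, s / n, NA_real_)
    ss <- rowSums(xi^2, na.rm = TRUE)
    v <- ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_)
    v <- pmax(v, 0)  # guard rounding
    list(n = n, mean = m, var = v)
  })
}

.welch_t <- function(g1, g2) {
  se2 <- g1$var / g1$n + g2$var / g2$n
  t <- (g1$mean - g2$mean) / sqrt(se2)
  df <- se2^2 / ((g1$var / g1$n)^2 / (g1$n - 1) +
                 (g2$var / g2$n)^2 / (g2$n - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, p = p)
}

.pooled_t <- function(g1, g2) {
  df <- g1$n + g2$n - 2
  sp2 <- ((g1$n - 1) * g1$var + (g2$n - 1) * g2$var) / df
  t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, p = p)
}

#' Per-protein statistics: ANOVA + BH gate, then pairwise t tests
#'
#' One-way ANOVA across the genotypes per protein, Benjamini-Hochberg
#' correction over all testable proteins, and pairwise two-sample t tests
#' (Welch by default) of each mutant genotype against control. A protein
#' "passes" a comparison (for the downstream dichotomy) when its BH q-value
#' is below `fdr_alpha` and the comparison's t-test p is below `t_alpha` —
#' the gated cascade. Fold changes are reported for all proteins as
#' `mean(log2 mutant) - mean(log2 control)`.
#'
#' @param protmat Protein-by-channel log2 matrix from [rollup_proteins()].
#' @param design Plex design; unused channels are excluded.
#' @param fdr_alpha BH FDR level for the ANOVA gate (default 0.05).
#' @param t_alpha Pairwise t-test level (default 0.05).
#' @param var_equal Use pooled-variance t tests instead of Welch.
#' @param control Control genotype label.
#' @return data.frame with one row per protein: `n_peptides`, per-genotype
#'   means and ns, `log2fc_het` / `log2fc_homo`, `anova_p`, `bh_q`,
#'   `ttest_p_het` / `ttest_p_homo`, `passes_het` / `passes_homo`, `status`.
#' @export
protein_statistics <- function(protmat, design = tmt_plex_design(),
                               fdr_alpha = 0.05, t_alpha = 0.05,
                               var_equal = FALSE, control = "control") {
  used <- design[design$genotype != "unused", ]
  miss_ch <- setdiff(used$channel, colnames(protmat))
  if (length(miss_ch))
    stop("design channels missing from the protein matrix: ",
         paste(miss_ch, collapse = ", "), call. = FALSE)
  x <- protmat[, used$channel, drop = FALSE]
  groups <- used$genotype
  glev <- c(control, setdiff(unique(groups), control))
  gs <- .group_summaries(x, groups, glev)
  names(gs) <- glev
  treat <- glev[-1]

  nmat <- sapply(gs, `[[`, "n")
  nmat <- matrix(nmat, nrow = nrow(x), dimnames = list(NULL, glev))
  testable <- rowSums(nmat >= 2) == length(glev)

  # one-way ANOVA with per-protein missingness
  Ntot <- rowSums(nmat)
  grand <- rowSums(sapply(glev, function(g) gs[[g]]$n * gs[[g]]$mean)) / Ntot
  ssb <- rowSums(sapply(glev, function(g)
    gs[[g]]$n * (gs[[g]]$mean - grand)^2))
  ssw <- rowSums(sapply(glev, function(g)
    ifelse(gs[[g]]$n > 1, (gs[[g]]$n - 1) * gs[[g]]$var, 0)))
  df1 <- length(glev) - 1
  df2 <- Ntot - length(glev)
  fstat <- (ssb / df1) / (ssw / df2)
  anova_p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  degen <- testable & ssw == 0
  anova_p[!testable | degen] <- NA_real_

  bh_q <- rep(NA_real_, nrow(x))
  ok <- !is.na(anova_p)
  bh_q[ok] <- stats::p.adjust(anova_p[ok], method = "BH")

  tt <- lapply(treat, function(g) {
    f <- if (var_equal) .pooled_t else .welch_t
    out <- f(gs[[g]], gs[[control]])
    out$p[nmat[, g] < 2 | nmat[, control] < 2] <- NA_real_
    out
  })
  names(tt) <- treat

  np <- attr(protmat, "n_peptides")
  res <- data.frame(protein_id = rownames(protmat),
                    n_peptides = if (is.null(np)) NA_integer_ else
                      unname(np[rownames(protmat)]),
                    stringsAsFactors = FALSE)
  for (g in glev) {
    res[[paste0("mean_", g)]] <- gs[[g]]$mean
    res[[paste0("n_", g)]] <- nmat[, g]
  }
  for (g in treat)
    res[[paste0("log2fc_", g)]] <- gs[[g]]$mean - gs[[control]]$mean
  res$anova_p <- anova_p
  res$bh_q <- bh_q
  for (g in treat) {
    res[[paste0("ttest_p_", g)]] <- tt[[g]]$p
    res[[paste0("passes_", g)]] <-
      !is.na(bh_q) & bh_q < fdr_alpha &
      !is.na(tt[[g]]$p) & tt[[g]]$p < t_alpha
  }
  res$status <- ifelse(!testable, "untested",
                       ifelse(degen, "degenerate", "tested"))
  rownames(res) <- NULL
  res
}

#' Flag mitochondrial proteins against a curated gene list
#'
#' Case-insensitive symbol match against a supplied mitochondrial inventory
#' (MitoCarta-style list); duplicates in the list are ignored.
#'
#' @param records Protein statistics data.frame (`protein_id` column).
#' @param mito_genes Character vector of mitochondrial gene symbols.
#' @return `records` with an added logical `mito_flag` column.
#' @export
annotate_mito <- function(records, mito_genes) {
  if (length(mito_genes) == 0) {
    warning("empty mitochondrial gene list: all proteins flagged FALSE",
            call. = FALSE)
    records$mito_flag <- FALSE
    return(records)
  }
  records$mito_flag <- tolower(records$protein_id) %in%
    unique(tolower(mito_genes))
  records
}

#' Plot-ready dot-plot table of fold changes and p-values
#'
#' One row per (protein, comparison) with the comparison's log2 fold change
#' and -log10 t-test p-value (capped for p = 0).
#'
#' @param records Protein statistics data.frame.
#' @param cap Maximum -log10 p reported (default 16).
#' @return data.frame `protein_id`, `comparison`, `log2fc`, `neg_log10_p`.
#' @export
dotplot_table <- function(records, cap = 16) {
  treat <- sub("^ttest_p_", "", grep("^ttest_p_", names(records),
                                     value = TRUE))
  rows <- lapply(treat, function(g) {
    p <- records[[paste0("ttest_p_", g)]]
    data.frame(protein_id = records$protein_id,
               comparison = paste0(g, "_vs_control"),
               log2fc = records[[paste0("log2fc_", g)]],
               neg_log10_p = pmin(-log10(p), cap),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify protein-abundance changes per comparison
#'
#' `up`/`down` iff the protein passes the gated cascade (BH q below the FDR
#' level and comparison t-test p below its level) with the matching fold
#' change sign; `unchanged` otherwise; untestable proteins propagate
#' `untested`.
#'
#' @param records Protein statistics data.frame.
#' @return `records` with added `verdict_<genotype>` columns.
#' @export
classify_protein_change <- function(records) {
  treat <- sub("^passes_", "", grep("^passes_", names(records), value = TRUE))
  for (g in treat) {
    pass <- records[[paste0("passes_", g)]]
    fc <- records[[paste0("log2fc_", g)]]
    v <- ifelse(records$status != "tested", "untested",
                ifelse(pass, ifelse(fc > 0, "up", "down"), "unchanged"))
    records[[paste0("verdict_", g)]] <- v
  }
  records
}
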