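# run expr under a fixed RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-gene, per-replicate ribosome occupancy (RPF/mRNA)
#'
#' Occupancy of gene g in replicate r is the ratio of its RPF count to its
#' mRNA count. In `raw` mode the ratio uses the counts as given; in `cpm`
#' mode both counts are first scaled to counts-per-million of their library
#' (library sizes from the matrix attribute `library_size`, falling back to
#' column sums). A zero mRNA count makes the occupancy undefined (NA), never
#' infinite; RPF 0 over mRNA > 0 is a valid 0.
#'
#' @param rpf,mrna Gene-by-sample count matrices with a shared gene order.
#' @param design Sample design pairing RPF and mRNA libraries by
#'   (genotype, replicate).
#' @param mode `"raw"` (default) or `"cpm"`.
#' @return Gene-by-pair matrix of occupancies with columns named
#'   `<genotype>_<replicate>`; attribute `genotype` gives each column's
#'   genotype.
#' @export
compute_occupancy <- function(rpf, mrna, design, mode = c("raw", "cpm")) {
  mode <- match.arg(mode)
  if (!identical(rownames(rpf), rownames(mrna)))
    stop("RPF and mRNA matrices must share gene order", call. = FALSE)
  .check_design(design)
  rd <- design[design$assay == "RPF", ]
  md <- design[design$assay == "mRNA", ]
  pair <- paste(rd$genotype, rd$replicate, sep = "_")
  mpair <- paste(md$genotype, md$replicate, sep = "_")
  mi <- match(pair, mpair)
  if (anyNA(mi)) stop("unpaired RPF replicate", call. = FALSE)
  if (!all(rd$sample_id %in% colnames(rpf)) ||
      !all(md$sample_id %in% colnames(mrna)))
    stop("design samples missing from count matrices", call. = FALSE)
  r <- rpf[, rd$sample_id, drop = FALSE]
  m <- mrna[, md$sample_id[mi], drop = FALSE]
  if (mode == "cpm") {
    ls_r <- attr(rpf, "library_size")
    ls_m <- attr(mrna, "library_size")
    if (is.null(ls_r)) ls_r <- colSums(rpf)
    if (is.null(ls_m)) ls_m <- colSums(mrna)
    r <- sweep(r, 2, ls_r[rd$sample_id] / 1e6, "/")
    m <- sweep(m, 2, ls_m[md$sample_id[mi]] / 1e6, "/")
  }
  occ <- r / m
  occ[m == 0] <- NA_real_
  colnames(occ) <- pair
  attr(occ, "genotype") <- stats::setNames(rd$genotype, pair)
  occ
}

#' Dunnett many-to-one adjusted p-values
#'
#' Two-sided adjusted p-values for comparing each treatment group with a
#' shared control, from the equicorrelated multivariate-t distribution of
#' the contrast statistics (correlation
#' `rho_jl = sqrt(n_j n_l / ((n_j + n0)(n_l + n0)))`). `method = "mc"` is a
#' Monte-Carlo evaluation of the same distribution (default 1e6 draws).
#'
#' @param tstats Numeric vector of contrast t statistics (one per treatment
#'   group vs control).
#' @param n Group sizes, control first, in the order of `tstats`.
#' @param df Error degrees of freedom.
#' @param method `"mvt"` (numerical integration) or `"mc"`.
#' @param mc_draws Draws for the Monte-Carlo method.
#' @param seed RNG seed used internally (both methods draw random numbers);
#'   the caller's RNG stream is left untouched.
#' @return Numeric vector of adjusted p-values, `>=` the unadjusted
#'   two-sided p of each contrast.
#' @export
dunnett_p_adjust <- function(tstats, n, df, method = c("mvt", "mc"),
                             mc_draws = 1e6, seed = 1L) {
  method <- match.arg(method)
  k <- length(tstats)
  stopifnot(length(n) == k + 1L)
  n0 <- n[1]
  ni <- n[-1]
  lam <- sqrt(ni / (ni + n0))
  R <- outer(lam, lam)
  diag(R) <- 1
  .with_seed(seed, {
    if (method == "mvt") {
      vapply(abs(tstats), function(tt) {
        if (!is.finite(tt)) return(NA_real_)
        p <- 1 - mvtnorm::pmvt(lower = rep(-tt, k), upper = rep(tt, k),
                               df = df, corr = R, type = "shifted",
                               algorithm = mvtnorm::GenzBretz(abseps = 1e-6))
        min(max(p, 0), 1)
      }, numeric(1))
    } else {
      z <- mvtnorm::rmvnorm(mc_draws, sigma = R)
      s <- sqrt(stats::rchisq(mc_draws, df) / df)
      maxt <- apply(abs(z / s), 1, max)
      vapply(abs(tstats), function(tt) {
        if (!is.finite(tt)) return(NA_real_)
        mean(maxt >= tt)
      }, numeric(1))
    }
  })
}

#' Genotype statistics on a per-gene occupancy table
#'
#' One-way ANOVA across genotypes followed by Dunnett many-to-one
#' comparisons of each mutant genotype against the control. Genes with any
#' undefined replicate, or fewer than two defined replicates in any
#' genotype, are reported as `untested` rather than imputed; genes with zero
#' within-group variance everywhere are flagged `degenerate` and their
#' p-values left undefined. With exactly two genotypes the procedure falls
#' back to a pooled-variance Student's t test.
#'
#' @param occ Occupancy matrix from [compute_occupancy()] (columns carry a
#'   `genotype` attribute), or any gene-by-sample matrix plus `genotypes`.
#' @param genotypes Genotype of each column (defaults to the attribute).
#' @param control Control genotype label (default `"control"`).
#' @param method,mc_draws,seed Passed to [dunnett_p_adjust()].
#' @return data.frame with one row per gene: group means and defined-n,
#'   `anova_p`, per-comparison `t_<g>`, `dunnett_p_<g>`, `direction_<g>`
#'   (`up`/`down`/`unchanged` by sign of the mean difference), and `status`
#'   (`tested` / `untested` / `degenerate`).
#' @export
occupancy_stats <- function(occ, genotypes = NULL, control = "control",
                            method = c("mvt", "mc"), mc_draws = 1e6,
                            seed = 1L) {
  method <- match.arg(method)
  if (is.null(genotypes)) genotypes <- attr(occ, "genotype")
  if (is.null(genotypes))
    stop("column genotypes must be supplied", call. = FALSE)
  genotypes <- unname(genotypes)
  stopifnot(length(genotypes) == ncol(occ))
  if (!control %in% genotypes)
    stop("control genotype '", control, "' absent", call. = FALSE)
  glev <- c(control, setdiff(unique(genotypes), control))
  kgrp <- length(glev)
  treat <- glev[-1]

  gidx <- lapply(glev, function(g) which(genotypes == g))
  def <- !is.na(occ)
  n_def <- sapply(gidx, function(ii) rowSums(def[, ii, drop = FALSE]))
  n_def <- matrix(n_def, nrow = nrow(occ), dimnames = list(NULL, glev))
  complete <- rowSums(!def) == 0
  enough <- apply(n_def >= 2, 1, all)
  testable <- complete & enough

  means <- sapply(gidx, function(ii) rowMeans(occ[, ii, drop = FALSE]))
  means <- matrix(means, nrow = nrow(occ), dimnames = list(NULL, glev))
  ssw <- sapply(seq_along(gidx), function(j) {
    ii <- gidx[[j]]
    rowSums((occ[, ii, drop = FALSE] - means[, j])^2)
  })
  ssw <- rowSums(matrix(ssw, nrow = nrow(occ)))
  ng <- lengths(gidx)
  N <- sum(ng)
  grand <- as.vector(occ %*% rep(1 / N, ncol(occ)))
  ssb <- as.vector((means - grand)^2 %*% ng)
  df1 <- kgrp - 1L
  df2 <- N - kgrp
  msw <- ssw / df2
  fstat <- (ssb / df1) / msw
  anova_p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)

  res <- data.frame(gene_id = rownames(occ), stringsAsFactors = FALSE)
  for (g in glev) {
    res[[paste0("mean_", g)]] <- means[, g]
    res[[paste0("n_", g)]] <- n_def[, g]
  }
  res$anova_p <- NA_real_
  status <- ifelse(testable, "tested", "untested")
  degen <- testable & msw == 0
  status[degen] <- "degenerate"
  ok <- testable & !degen
  res$anova_p[ok] <- anova_p[ok]

  if (kgrp == 2L) {
    # two-group fallback: pooled-variance Student's t
    tstat <- (means[, 2] - means[, 1]) /
      sqrt(msw * (1 / ng[2] + 1 / ng[1]))
    pt2 <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
    res[[paste0("t_", treat)]] <- ifelse(ok, tstat, NA_real_)
    res[[paste0("dunnett_p_", treat)]] <- ifelse(ok, pt2, NA_real_)
    res$anova_p[ok] <- pt2[ok]
    res[[paste0("direction_", treat)]] <-
      ifelse(means[, 2] > means[, 1], "up", "down")
  } else {
    tmat <- sapply(treat, function(g) {
      (means[, g] - means[, control]) /
        sqrt(msw * (1 / ng[match(g, glev)] + 1 / ng[1]))
    })
    tmat <- matrix(tmat, nrow = nrow(occ), dimnames = list(NULL, treat))
    pmat <- matrix(NA_real_, nrow(occ), length(treat),
                   dimnames = list(NULL, treat))
    for (i in which(ok)) {
      pmat[i, ] <- dunnett_p_adjust(tmat[i, ], ng, df2, method = method,
                                    mc_draws = mc_draws, seed = seed)
    }
    for (g in treat) {
      res[[paste0("t_", g)]] <- ifelse(ok, tmat[, g], NA_real_)
      res[[paste0("dunnett_p_", g)]] <- pmat[, g]
      res[[paste0("direction_", g)]] <-
        ifelse(means[, g] > means[, control], "up", "down")
    }
  }
  res$status <- status
  res
}

#' Coverage polarity (5'/3' skew) score
#'
#' The coverage-weighted mean of a linear position map over the CDS:
#' position i (0-based, length L) maps to `w_i = 2 i / (L - 1) - 1`, so a
#' profile concentrated at the 5' end scores -1, uniform coverage scores
#' ~0, and all mass at the 3' end scores +1.
#'
#' @param profile Numeric vector of per-CDS-position footprint 5'-end
#'   counts.
#' @return list with `polarity` (NA when the profile is empty or all-zero)
#'   and `total` (summed footprints).
#' @export
polarity_score <- function(profile) {
  L <- length(profile)
  total <- sum(profile)
  if (L == 0 || total == 0)
    return(list(polarity = NA_real_, total = total))
  w <- if (L == 1L) 0 else 2 * (seq_len(L) - 1) / (L - 1) - 1
  list(polarity = sum(profile * w) / total, total = total)
}

#' Polarity scores for all (transcript, sample) profiles
#'
#' @param profiles Nested list `profiles[[sample_id]][[transcript_id]]` as
#'   produced by [process_experiment()].
#' @return data.frame `transcript_id`, `sample_id`, `polarity`, `total`.
#' @export
polarity_table <- function(profiles) {
  rows <- list()
  for (s in names(profiles)) {
    for (tx in names(profiles[[s]])) {
      sc <- polarity_score(profiles[[s]][[tx]])
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx, sample_id = s,
        polarity = sc$polarity, total = sc$total, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(0), sample_id = character(0),
                      polarity = numeric(0), total = numeric(0))
  rownames(out) <- NULL
  out
}

#' Classify occupancy changes per comparison
#'
#' `up`/`down` iff the Dunnett-adjusted p is below `alpha` and the mean
#' difference has the matching sign; `unchanged` otherwise; genes not tested
#' (missing replicates or degenerate variance) propagate `untested`.
#'
#' @param stats Result of [occupancy_stats()].
#' @param alpha Significance level (default 0.05).
#' @return `stats` with an added `verdict_<genotype>` column per comparison.
#' @export
classify_occupancy_change <- function(stats, alpha = 0.05) {
  treat <- sub("^dunnett_p_", "", grep("^dunnett_p_", names(stats),
                                       value = TRUE))
  for (g in treat) {
    p <- stats[[paste0("dunnett_p_", g)]]
    dir <- stats[[paste0("direction_", g)]]
    v <- ifelse(stats$status != "tested" | is.na(p), "untested",
                ifelse(p < alpha, dir, "unchanged"))
    stats[[paste0("verdict_", g)]] <- v
  }
  stats
}
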