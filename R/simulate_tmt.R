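#' Default 16-plex TMT design
#'
#' The channel layout of a 16-plex experiment with five replicates per
#' genotype and one unused channel: homozygous and heterozygous replicates
#' alternate over the first ten channels, channel TMT131C is left unused,
#' and the five control replicates occupy the last five channels.
#'
#' @return data.frame with `channel`, `genotype`
#'   (`control`/`het`/`homo`/`unused`), `replicate` (NA for the unused
#'   channel).
#' @export
tmt_plex_design <- function() {
  channels <- c("TMT126", "TMT127N", "TMT127C", "TMT128N", "TMT128C",
                "TMT129N", "TMT129C", "TMT130N", "TMT130C", "TMT131N",
                "TMT131C", "TMT132N", "TMT132C", "TMT133N", "TMT133C",
                "TMT134N")
  genotype <- c(rep(c("homo", "het"), 5), "unused", rep("control", 5))
  replicate <- c(rep(1:5, each = 2), NA, 1:5)
  data.frame(channel = channels, genotype = genotype, replicate = replicate,
             stringsAsFactors = FALSE)
}

#' Default TMT channel isotope-impurity matrix
#'
#' Row i gives the observed channel composition of label i: a fraction
#' `spill_prev` reports one channel earlier and `spill_next` one channel
#' later, the rest in the nominal channel. Rows sum to at most 1.
#'
#' @param channels Channel labels (default, the 16-plex layout).
#' @param spill_prev,spill_next Spill fractions to the neighboring channels.
#' @return Square numeric matrix with channel dimnames.
#' @export
default_impurity_matrix <- function(channels = tmt_plex_design()$channel,
                                    spill_prev = 0.01, spill_next = 0.02) {
  n <- length(channels)
  M <- diag(1 - spill_prev - spill_next, n)
  for (i in seq_len(n)) {
    if (i > 1) M[i, i - 1] <- spill_prev else M[i, i] <- M[i, i] + spill_prev
    if (i < n) M[i, i + 1] <- spill_next else M[i, i] <- M[i, i] + spill_next
  }
  dimnames(M) <- list(channels, channels)
  M
}

#' Ground-truth log2 abundance shifts for the TMT generator
#'
#' @param protein_ids Character vector of protein identifiers.
#' @param shift_het,shift_homo Named numeric log2 shifts (vs control);
#'   proteins not named keep 0.
#' @return data.frame keyed by `protein_id`.
#' @export
tmt_truth_table <- function(protein_ids, shift_het = NULL, shift_homo = NULL) {
  tt <- data.frame(protein_id = protein_ids, shift_het = 0, shift_homo = 0,
                   stringsAsFactors = FALSE)
  fill <- function(col, val) {
    if (is.null(val)) return(col)
    idx <- match(names(val), tt$protein_id)
    if (anyNA(idx)) stop("unknown protein in truth shifts", call. = FALSE)
    col[idx] <- val
    col
  }
  tt$shift_het <- fill(tt$shift_het, shift_het)
  tt$shift_homo <- fill(tt$shift_homo, shift_homo)
  tt
}

#' Simulate a peptide-level TMT reporter-intensity table
#'
#' Each protein gets one or more peptides; a peptide's log2 reporter
#' intensity in a channel is the protein baseline, plus a peptide ionization
#' offset, plus the planted genotype shift, plus a per-channel loading
#' factor, plus Gaussian noise. Intensities are reported on the raw scale.
#' Peptide detection is abundance-dependent: low-intensity peptides are more
#' likely to be missing, emulating the bias of data-dependent acquisition
#' toward abundant proteins. When an impurity matrix is given, observed
#' channel intensities are the forward mixture of the true ones, so the
#' correction stage is exercised.
#'
#' @param protein_ids Character vector of proteins to simulate.
#' @param design Plex design ([tmt_plex_design()]); must not assign more
#'   samples than channels.
#' @param truth Truth table ([tmt_truth_table()]).
#' @param peptides_per_protein Mean peptide count (Poisson, floored at 1).
#' @param sigma Channel-level log2 noise SD (default 0.1).
#' @param loading_sd SD of per-channel log2 loading factors (default 0.1);
#'   exercised by the normalization stage.
#' @param dropout_rate Overall missingness target at the baseline abundance
#'   midpoint (default 0.05); dropout probability decreases with abundance.
#' @param impurity Optional impurity matrix applied as forward mixing.
#' @param seed Integer seed.
#' @return list with `peptides` (data.frame `peptide_id`, `protein_id`, one
#'   intensity column per channel, NA = missing), `design`, `truth`,
#'   `impurity`.
#' @export
simulate_tmt_experiment <- function(protein_ids,
                                    design = tmt_plex_design(),
                                    truth = tmt_truth_table(protein_ids),
                                    peptides_per_protein = 3,
                                    sigma = 0.1, loading_sd = 0.1,
                                    dropout_rate = 0.05,
                                    impurity = NULL, seed = 1L) {
  stopifnot(identical(sort(truth$protein_id), sort(protein_ids)))
  if (anyDuplicated(design$channel))
    stop("duplicate channel labels in design", call. = FALSE)
  n_samples <- sum(design$genotype != "unused")
  if (n_samples > nrow(design))
    stop("more samples than channels in the plex design", call. = FALSE)
  set.seed(as.integer(seed))
  truth <- truth[match(protein_ids, truth$protein_id), ]

  n_pep <- pmax(1L, stats::rpois(length(protein_ids), peptides_per_protein))
  pid <- rep(protein_ids, n_pep)
  pep_id <- sprintf("%s_pep%02d", pid, unlist(lapply(n_pep, seq_len)))
  base_prot <- stats::setNames(stats::rnorm(length(protein_ids), 20, 2),
                               protein_ids)
  pep_off <- stats::rnorm(length(pid), 0, 1)
  loading <- stats::rnorm(nrow(design), 0, loading_sd)

  shift_of <- function(genotype) {
    switch(genotype,
           het = truth$shift_het[match(pid, truth$protein_id)],
           homo = truth$shift_homo[match(pid, truth$protein_id)],
           rep(0, length(pid)))
  }
  log2_mat <- matrix(NA_real_, length(pid), nrow(design),
                     dimnames = list(pep_id, design$channel))
  for (j in seq_len(nrow(design))) {
    mu <- base_prot[pid] + pep_off + shift_of(design$genotype[j]) + loading[j]
    log2_mat[, j] <- mu + stats::rnorm(length(pid), 0, sigma)
  }
  inten <- 2^log2_mat
  if (!is.null(impurity)) {
    stopifnot(identical(colnames(impurity), design$channel))
    inten <- inten %*% impurity   # observed_j = sum_i true_i * M[i, j]
  }
  # abundance-dependent dropout on the peptide's baseline log2 intensity
  if (dropout_rate > 0) {
    ab <- base_prot[pid] + pep_off
    p_drop <- dropout_rate * stats::plogis(-(ab - stats::median(ab)) / 2) /
      stats::plogis(0)
    drop <- matrix(stats::runif(length(inten)) <
                     rep(p_drop, times = ncol(inten)), nrow = nrow(inten))
    inten[drop] <- NA_real_
  }
  # unused channel carries no sample: reported as missing
  inten[, design$genotype == "unused"] <- NA_real_
  peptides <- data.frame(peptide_id = pep_id, protein_id = pid,
                         inten, check.names = FALSE,
                         stringsAsFactors = FALSE)
  rownames(peptides) <- NULL
  list(peptides = peptides, design = design, truth = truth,
       impurity = impurity)
}
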