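---
title: "Methods: occupancy statistics, TMT cascade, and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy statistics, TMT cascade, and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboprot)
```

# The model

`riboprot` contrasts two per-gene readouts across three genotypes
(control, heterozygous, homozygous mutant):

1. **ribosome occupancy** — the per-replicate ratio of ribosome-protected
   fragment (RPF) counts to mRNA counts, a proxy for how densely a
   transcript is loaded with ribosomes relative to its abundance; and
2. **protein abundance** — log2 reporter intensities from a 16-plex TMT
   experiment with five replicates per genotype.

A gene whose occupancy rises while its protein output does not is the
signature of unproductive or stalled translation; a gene whose protein
moves while occupancy is flat points at regulation downstream of
translation initiation (turnover, import, assembly). The dichotomy
classifier makes that contrast explicit per gene and comparison.

## Occupancy statistics

Occupancy is computed per replicate pair as `RPF(g, r) / mRNA(g, r)`.
Design choices worth stating:

* **Raw counts by default.** The headline readout uses raw counts, which
  makes per-replicate occupancies library-size confounded in principle; a
  `cpm` mode divides both counts by their library size first. Both are
  exposed because the raw ratio is the field's customary display and the
  confound cancels in genotype contrasts when depths are comparable.
* **Zero mRNA means undefined, not infinite.** `RPF > 0, mRNA = 0` is
  flagged; `RPF = 0, mRNA > 0` is a valid occupancy of 0.
* **Genes with any undefined replicate are excluded from testing**
  (`status = "untested"`), not imputed — mirroring how transcripts without
  discernible reads in every replicate are treated in practice. The
  generator exposes a per-gene dropout option to exercise exactly this
  path, rather than guessing which real-data mechanism produces it.
* **Per-replicate ratios, then group means.** Occupancy could also be
  defined as the ratio of replicate-mean abundances; outputs report the
  per-genotype means of per-replicate ratios, which keeps a per-replicate
  dispersion estimate available for testing. The count matrices are
  retained so either summary can be recomputed.

Genotype effects use one-way ANOVA followed by Dunnett many-to-one
comparisons of each mutant genotype against control. The adjusted p-value
for contrast *j* is

> P( max_k |T_k| ≥ |t_j| )

under the equicorrelated multivariate-t distribution of the contrast
statistics (correlation `sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`,
error degrees of freedom from the pooled within-group variance). The
default evaluator is numerical integration (`mvtnorm::pmvt`, absolute
tolerance 1e-6); `method = "mc"` draws ≥ 1e6 samples of the maximum
statistic from the same distribution — both run under an internally fixed
RNG state so results are reproducible and the caller's stream is
untouched. With two genotypes the procedure degrades to a pooled-variance
Student's t test. Genes with zero within-group variance everywhere are
flagged `degenerate` and reported untestable rather than given p = 0.

**Calibration.** The Dunnett implementation is exact under normality
(a 25,000-gene normal-data null simulation in the test suite realizes the
nominal family-wise level within Monte-Carlo noise). On simulated
count-ratio data with n = 3/group the realized family-wise error runs
slightly *conservative* (the null-simulation quantity the acceptance
script recomputes), because ratios of counts are heavier-tailed than
normal at this group size; there is no anti-conservative inflation.

## Polarity (5'/3' skew)

The polarity of a coverage profile over a CDS of length *L* is the
coverage-weighted mean of the linear position map `w_i = 2i/(L−1) − 1`
(0-based *i*): −1 when all footprint 5' ends sit at the 5' edge, 0 for
uniform coverage, +1 at the 3' edge. It is the simplest signed score whose
sign matches the direction of visible density shifts along a transcript;
it is reported per (transcript, sample) together with the footprint total,
and undefined on empty profiles. Coverage positions are footprint 5' ends
— no A/P-site offsetting is applied, since no offsetting rule is part of
the processing contract.

## Read processing

* **Adapter trimming.** The 3' adapter is located by the leftmost full
  occurrence inside the read; failing that, by the longest read-suffix /
  adapter-prefix overlap (exact by default; a mismatch-tolerant scan is
  available). Ties resolve longest-first, then leftmost. After cutting,
  4 nt are removed from each end — the randomized bases of the small-RNA
  library chemistry the generator renders — and reads shorter than 23 nt
  are discarded. Defaults: `end_trim = 4`, `min_length = 23`.
* **Contaminant filter.** A read is removed iff it is an exact substring
  of an rRNA/tRNA record on either strand. The exact path concatenates the
  pool (both strands) with a separator character that cannot occur in a
  read, so no match can span a boundary; the mismatch-tolerant path uses a
  per-width pattern dictionary.
* **Size selection** retains 26–32 nt inclusive, RPF libraries only.
* **Matching.** Transcripts are indexed by k-mers (k = 12 default); a
  read's first k-mer seeds candidate positions which are verified over the
  full read, so the result equals a brute-force substring scan (the test
  suite asserts this equivalence). Matching is sense-strand, as footprint
  libraries are directional.
* **EM resolution.** Multi-mapping reads are resolved under the standard
  multinomial abundance model with uniform initialization, iterated to
  `max |Δθ| < 1e-8` or 1000 iterations; reads are collapsed into
  equivalence classes by compatibility set first. A read matching one
  transcript at several positions counts once, at the leftmost position.
  The data log-likelihood is non-decreasing across iterations (asserted in
  tests); per-read weights sum to 1 and totals are conserved.
* **SAM/BAM ingestion** (`mapq_min = 5`, MAPQ 255 = "unavailable" kept)
  replaces the internal matcher for externally aligned data; the internal
  matcher can export SAM for round-tripping.

The internal matcher + EM stand in for a full aligner/quantifier: the
synthetic reads are error-free by default, so exact substring matching is
the appropriate model; SAM ingestion is the path for real reads.

## TMT cascade

* **Impurity correction.** Channel labels leak known fractions of signal
  into neighboring channels; with mixing matrix `M` (rows = observed
  composition of each label), observed row-vectors are `true %*% M`, and
  the correction solves the system per peptide, clamping negative
  solutions to zero. Missing values are treated as zero during the solve
  and restored afterwards — neighbors of a missing channel absorb a small
  bias rather than the whole row failing; a singular matrix passes raw
  values through with a warning.
* **Normalization** is a median sweep on log2: subtract each occupied
  channel's peptide-level median, add back the grand median — the
  fixed-effects median solution of the ANOVA-style loading model (full
  mixed-model normalization is out of scope; the sweep equalizes channel
  medians exactly, which the tests assert to 1e-9). Channels with < 10
  non-missing values are left unshifted with a warning.
* **Rollup** is the mean of peptide log2 values per protein and channel,
  ignoring missing values; shared peptides are dropped by default
  (`assign_first` optional) since external grouping decisions are not
  reproducible here. Proteins with ≥ 1 peptide are retained.
* **Statistics: the gated cascade.** One-way ANOVA per protein, BH
  correction across all testable proteins, and pairwise t tests (Welch by
  default — the variance assumption is deliberately weak; a pooled mode
  exists) of each mutant vs control. A protein *passes* a comparison only
  if `bh_q < 0.05` **and** the comparison's t-test `p < 0.05`; log2 fold
  changes (`mean(log2 mutant) − mean(log2 control)`) are reported for all
  proteins regardless. Peptide/protein identification probabilities are
  upstream of this module's input table and are not recomputed.

## Dichotomy classification

Verdicts are significance-based, not equivalence-tested: `unchanged`
means "failed the gate at α", which mirrors how such calls are made from
figure-legend significance levels; an optional fold-change band can
tighten it. Het and homo comparisons are kept separate throughout — no
pooling — because allele-dose-specific effects are part of the signal of
interest. The category function is total over the 4 × 5 verdict grid
(property-tested): the two headline categories are flagged, concordant
and remaining discordant combinations are labelled combinatorially, and
`untested`/`not-detected` propagate. `not_detected` is reserved for genes
absent from the proteomics table entirely (never identified), as opposed
to identified-but-untestable (`untested`).

# The synthetic generator

The generator defines the study conditions the tests run under.

* **Annotation**: 13 mitochondrially encoded protein-coding genes (the
  standard mouse-style symbols `mt-Nd1` … `mt-Atp8`), a configurable
  nuclear complement (OXPHOS, mitochondria-associated, other), 2 rRNA and
  22 tRNA contaminant records. Transcripts are random ACGT sequences; CDSs
  are codon-multiple intervals inside a configurable UTR margin (30 nt
  default). No introns, no splicing.
* **Counts**: negative binomial per gene and sample. The mRNA mean is
  `depth × base_g × mrna_fc(g, genotype)`; the RPF mean multiplies in
  `occ_fc(g, genotype)`, so the planted occupancy fold change is exactly
  the ratio of expected RPF/mRNA ratios. `reads_per_sample` is the
  expected on-target yield of a *control* library; planted effects change
  total ribosome-protected material rather than being renormalized away
  (renormalizing would silently shrink every planted fold change).
  Dispersion defaults to 0.01 — knock-in cell-line replicates share a
  genetic background and culture regime, so within-group variance is low;
  it is configurable for noisier designs. Baseline abundances are
  log-normal(0, 1).
* **Reads**: footprint inserts are uniform on 26–32 nt with start
  positions inside the CDS drawn from a linear tilt,
  `weight(i) ∝ 1 + skew·(2i/(n−1) − 1)` clamped at 0, so `skew > 0`
  concentrates footprints 3'-ward; mRNA reads are 50 nt, uniform along the
  transcript. A stated fraction of each library (default 0.1) comes from
  the contaminant pool. Reads are rendered as
  `4 random nt + insert + 4 random nt + 3' adapter` so the trimming stage
  is genuinely exercised, and every read's origin is recorded in a truth
  table for exact bookkeeping. Sequencing error is uniform substitution
  only (default 0); no indels, no chimeras, no quality model.
* **TMT**: one or more peptides per protein (Poisson, floored at 1);
  log2 intensity = protein baseline (N(20, 2)) + peptide ionization offset
  (N(0, 1)) + planted genotype shift + channel loading (N(0, 0.1)) +
  noise (N(0, 0.1) default). Dropout probability decreases with peptide
  abundance (logistic, 5% overall default), emulating data-dependent
  acquisition's bias toward abundant proteins. The default 16-plex layout
  interleaves homo/het replicates over the first ten channels, leaves one
  channel unused, and puts the five controls last. Forward impurity mixing
  is applied when a matrix is supplied, so the correction stage has real
  work to do. Not modeled: co-isolation interference, batch effects across
  plexes, peptide-specific missingness mechanisms beyond abundance.

What passing tests on this generator do **not** show: robustness to
alignment ambiguity from sequence homology (random transcripts share no
paralogy), to GC or position-dependent coverage bias, to real missingness
structure in MS data, or to misannotation. They do show that every stage's
contract — trimming arithmetic, filter bookkeeping, EM fixed points,
test calibration, gate logic, category assignment — holds exactly under
known ground truth.

# Problem sizes and runtime choices

The shipped test suite and acceptance script run the statistical checks at
50 simulations each: occupancy recovery on 20 planted genes at 50,000
reads/sample, null error control on 500-gene Ribo-seq and 2,000-protein
TMT experiments (count-level simulation, which is exact for these
quantities since the statistics consume counts), and dichotomy recovery
on 12 planted genes. Read-level rendering — trimming through EM — is
exercised by dedicated oracle tests and by a full `run_all` smoke run at
a few thousand reads per library; these sizes are a deliberate trade
between statistical resolution and a test suite that stays pleasant to
run.

# Known limitations

* The exact matcher requires error-free (or near-exact) reads; real data
  should come in through SAM/BAM ingestion after external alignment.
* Occupancy tests on raw ratios at n = 3 are slightly conservative (see
  Calibration above); log-scale testing showed no better calibration at
  this group size.
* The impurity solve treats missing channels as zero signal, biasing
  neighbors of missing values by up to the spill fraction.
* `unchanged` is a failed significance gate, not demonstrated
  equivalence; with few replicates it includes underpowered genes.
* Dunnett correlations assume the balanced form with a shared control;
  unbalanced designs use the same formula with per-group n (exact for the
  common-control structure), but unequal variances are not modeled.
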