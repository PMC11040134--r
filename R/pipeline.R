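#' Default pipeline configuration
#'
#' Nested list of every stage parameter, with defaults equal to the
#' pipeline's processing constants: 4-nt end trimming, 23-nt minimum read
#' length, 26-32 nt footprint window, MAPQ cutoff 5, occupancy alpha 0.05,
#' proteomics FDR and t-test levels 0.05. The simulation block sizes the
#' default smoke-scale run.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    annotation = list(
      n_mito = 13L, n_nuclear_oxphos = 10L, n_mito_assoc = 8L,
      n_other = 20L, n_rrna = 2L, n_trna = 22L, utr_margin = 30L
    ),
    simulate = list(
      replicates = 3L, reads_per_sample = 20000L, dispersion = 0.01,
      contaminant_fraction = 0.1, subst_rate = 0,
      occ_fc_het = 3, occ_fc_homo = 1.5, n_planted = 8L
    ),
    trimming = list(adapter = default_adapter(), end_trim = 4L,
                    min_length = 23L),
    size_select = list(min = 26L, max = 32L),
    mapping = list(k = 12L, mapq_min = 5L),
    occupancy = list(mode = "raw", alpha = 0.05),
    proteomics = list(fdr_alpha = 0.05, t_alpha = 0.05, var_equal = FALSE,
                      shared_peptides = "drop", sigma = 0.1,
                      peptides_per_protein = 3, dropout_rate = 0.05,
                      shift_het = 0, shift_homo = -1)
  )
}

#' Resolve a configuration against the defaults
#'
#' Overrides are merged into [default_config()]; unknown keys at any level
#' are rejected.
#'
#' @param overrides Nested list of overrides (possibly empty), or a path to
#'   a YAML file of them.
#' @return The resolved configuration.
#' @export
resolve_config <- function(overrides = list()) {
  if (is.character(overrides))
    overrides <- yaml::read_yaml(overrides)
  merge_into <- function(base, over, path = "") {
    unknown <- setdiff(names(over), names(base))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste0(path, unknown, collapse = ", "), call. = FALSE)
    for (nm in names(over)) {
      if (is.list(base[[nm]])) {
        if (!is.list(over[[nm]]))
          stop("configuration key '", path, nm, "' must be a section",
               call. = FALSE)
        base[[nm]] <- merge_into(base[[nm]], over[[nm]],
                                 paste0(path, nm, "."))
      } else base[[nm]] <- over[[nm]]
    }
    base
  }
  merge_into(default_config(), overrides)
}

#' Run the full pipeline: simulate, process, test, integrate
#'
#' Executes, in order: synthetic annotation and read simulation, read
#' processing to count matrices and coverage profiles, occupancy statistics
#' and polarity scores, TMT simulation and protein statistics, and the
#' dichotomy integration. All artifacts are written under `outdir` together
#' with the resolved configuration and a manifest of content hashes;
#' rerunning with the same configuration and seed reproduces identical
#' hashes.
#'
#' @param config Overrides merged into [default_config()] (list or YAML
#'   path).
#' @param outdir Output directory (created).
#' @param seed Optional seed overriding the configured one.
#' @return list with `manifest` (file, md5), `paths`, and the in-memory
#'   stage results (`annotation`, `counts`, `occupancy`, `proteins`,
#'   `dichotomy`, `report`).
#' @export
run_all <- function(config = list(), outdir, seed = NULL) {
  cfg <- resolve_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ## simulate
  ac <- cfg$annotation
  full_ann <- stage("simulate", build_default_annotation(
    sim_config(n_mito = ac$n_mito, n_nuclear_oxphos = ac$n_nuclear_oxphos,
               n_mito_assoc = ac$n_mito_assoc, n_other = ac$n_other,
               n_rrna = ac$n_rrna, n_trna = ac$n_trna,
               utr_margin = ac$utr_margin),
    seed = cfg$seed))
  sim <- stage("simulate", {
    sc <- cfg$simulate
    mito <- coding_annotation(full_ann)
    planted <- mito$gene_id[mito$gene_class == "mt-OXPHOS"]
    planted <- planted[seq_len(min(sc$n_planted, length(planted)))]
    tt <- truth_table(
      full_ann,
      occ_fc_het = stats::setNames(rep(sc$occ_fc_het, length(planted)), planted),
      occ_fc_homo = stats::setNames(rep(sc$occ_fc_homo, length(planted)), planted))
    simulate_riboseq_experiment(
      full_ann, riboseq_design(replicates = sc$replicates), tt,
      reads_per_sample = sc$reads_per_sample, dispersion = sc$dispersion,
      contaminant_fraction = sc$contaminant_fraction,
      subst_rate = sc$subst_rate, adapter = cfg$trimming$adapter,
      seed = cfg$seed, outdir = outdir)
  })

  ## process reads
  proc <- stage("process-reads", {
    process_experiment(sim$read_sets, full_ann, sim$design,
                       adapter = cfg$trimming$adapter,
                       end_trim = cfg$trimming$end_trim,
                       min_length = cfg$trimming$min_length,
                       size_min = cfg$size_select$min,
                       size_max = cfg$size_select$max,
                       k = cfg$mapping$k)
  })
  write_count_matrix(proc$rpf, file.path(outdir, "counts_rpf.tsv"))
  write_count_matrix(proc$mrna, file.path(outdir, "counts_mrna.tsv"))
  logs <- do.call(rbind, lapply(names(proc$logs), function(s)
    cbind(sample_id = s, proc$logs[[s]])))
  write_tsv(logs, file.path(outdir, "disposition_log.tsv"))

  ## occupancy
  occr <- stage("occupancy", {
    occ <- compute_occupancy(proc$rpf, proc$mrna, sim$design,
                             mode = cfg$occupancy$mode)
    st <- occupancy_stats(occ, seed = cfg$seed)
    st <- classify_occupancy_change(st, alpha = cfg$occupancy$alpha)
    pol <- polarity_table(proc$profiles)
    list(occ = occ, stats = st, polarity = pol)
  })
  occ_df <- data.frame(gene_id = rownames(occr$occ), occr$occ,
                       check.names = FALSE)
  write_tsv(occ_df, file.path(outdir, "occupancy.tsv"))
  write_tsv(occr$stats, file.path(outdir, "occupancy_stats.tsv"))
  write_tsv(occr$polarity, file.path(outdir, "polarity.tsv"))

  ## proteomics
  protr <- stage("proteomics", {
    pc <- cfg$proteomics
    cod <- coding_annotation(full_ann)
    prot_ids <- cod$gene_id
    planted <- cod$gene_id[cod$gene_class == "mt-OXPHOS"]
    planted <- planted[seq_len(min(cfg$simulate$n_planted, length(planted)))]
    ptt <- tmt_truth_table(
      prot_ids,
      shift_het = stats::setNames(rep(pc$shift_het, length(planted)), planted),
      shift_homo = stats::setNames(rep(pc$shift_homo, length(planted)), planted))
    imp <- default_impurity_matrix()
    tmt <- simulate_tmt_experiment(
      prot_ids, truth = ptt, peptides_per_protein = pc$peptides_per_protein,
      sigma = pc$sigma, dropout_rate = pc$dropout_rate, impurity = imp,
      seed = cfg$seed + 1L)
    pep <- correct_isotope_impurities(tmt$peptides, imp)
    pep <- normalize_channels(pep, tmt$design)
    pm <- rollup_proteins(pep, tmt$design,
                          shared_peptides = pc$shared_peptides)
    st <- protein_statistics(pm, tmt$design, fdr_alpha = pc$fdr_alpha,
                             t_alpha = pc$t_alpha,
                             var_equal = pc$var_equal)
    mito_list <- cod$gene_id[cod$gene_class %in%
                               c("mt-OXPHOS", "nu-OXPHOS", "mito-associated")]
    st <- annotate_mito(st, mito_list)
    st <- classify_protein_change(st)
    list(tmt = tmt, stats = st, dot = dotplot_table(st))
  })
  write_tsv(protr$tmt$peptides, file.path(outdir, "peptides.tsv"))
  write_tsv(protr$tmt$design, file.path(outdir, "plex_design.tsv"))
  write_tsv(protr$stats, file.path(outdir, "protein_stats.tsv"))
  write_tsv(protr$dot, file.path(outdir, "dotplot.tsv"))

  ## integrate
  intr <- stage("integrate", {
    joined <- join_omics(occr$stats, protr$stats, full_ann)
    dich <- classify_dichotomy(joined)
    rep_ <- stratify_report(dich)
    list(dichotomy = dich, report = rep_)
  })
  write_tsv(intr$dichotomy, file.path(outdir, "dichotomy.tsv"))
  write_tsv(intr$report$counts, file.path(outdir, "stratified_summary.tsv"))
  writeLines(intr$report$text, file.path(outdir, "stratified_summary.txt"))

  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))

  list(manifest = manifest, outdir = outdir, config = cfg,
       annotation = full_ann, counts = proc, occupancy = occr,
       proteins = protr, dichotomy = intr$dichotomy, report = intr$report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline input files
#'
#' Well-formedness checks for the standard inputs: FASTA/FASTQ structure,
#' CDS-within-transcript bounds, paired RPF/mRNA design completeness, and
#' plex-design channel counts. Each violation is reported with the file, a
#' line (where meaningful) and a rule id.
#'
#' @param paths Named list; any of `annotation` (FASTA), `cds` (BED),
#'   `fastq` (vector), `samples` (TSV design), `plex` (TSV plex design).
#' @param max_channels Plex size against which the design is checked
#'   (default 16).
#' @return data.frame `file`, `line`, `rule`, `message`; zero rows when
#'   everything is well-formed.
#' @export
validate_formats <- function(paths, max_channels = 16L) {
  viol <- list()
  add <- function(file, line, rule, message)
    viol[[length(viol) + 1L]] <<- data.frame(
      file = file, line = line, rule = rule, message = message,
      stringsAsFactors = FALSE)

  seqs <- NULL
  if (!is.null(paths$annotation)) {
    seqs <- tryCatch(Biostrings::readDNAStringSet(paths$annotation),
                     error = function(e) {
                       add(paths$annotation, NA, "fasta-parse",
                           conditionMessage(e)); NULL })
    if (!is.null(seqs) && anyDuplicated(names(seqs)))
      add(paths$annotation, NA, "fasta-dup-id", "duplicate sequence ids")
  }
  if (!is.null(paths$cds)) {
    bed <- tryCatch(utils::read.table(paths$cds, sep = "\t",
                                      stringsAsFactors = FALSE),
                    error = function(e) {
                      add(paths$cds, NA, "bed-parse", conditionMessage(e))
                      NULL })
    if (!is.null(bed)) {
      for (i in seq_len(nrow(bed))) {
        if (bed[i, 3] <= bed[i, 2])
          add(paths$cds, i, "bed-interval", "end <= start")
        if (!is.null(seqs)) {
          w <- match(bed[i, 1], names(seqs))
          if (is.na(w))
            add(paths$cds, i, "bed-unknown-seq",
                paste("unknown transcript", bed[i, 1]))
          else if (bed[i, 3] > Biostrings::width(seqs)[w])
            add(paths$cds, i, "bed-bounds",
                paste("interval exceeds transcript length on", bed[i, 1]))
        }
      }
    }
  }
  for (fq in paths$fastq %||% character(0)) {
    n <- length(readLines(fq))
    if (n %% 4 != 0)
      add(fq, n, "fastq-records", "line count not a multiple of 4")
  }
  if (!is.null(paths$samples)) {
    des <- read_tsv(paths$samples)
    err <- tryCatch({ .check_design(des); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) add(paths$samples, NA, "design-pairing", err)
  }
  if (!is.null(paths$plex)) {
    plex <- read_tsv(paths$plex)
    if (nrow(plex) > max_channels)
      add(paths$plex, NA, "plex-size",
          sprintf("%d channels against a %d-plex", nrow(plex), max_channels))
    if (anyDuplicated(plex$channel))
      add(paths$plex, NA, "plex-dup-channel", "duplicate channel labels")
  }
  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(file = character(0), line = numeric(0),
               rule = character(0), message = character(0))
  rownames(out) <- NULL
  out
}
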