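#' Join occupancy and protein statistics per gene and comparison
#'
#' Full outer join on gene symbol (after optional id mapping from transcript
#' symbols to protein symbols), reshaped to one row per (gene, comparison).
#' Genes absent from the occupancy table carry an `untested` occupancy
#' verdict; genes absent from the proteomics table carry a `not_detected`
#' protein verdict (the proteomics run did not identify them at all, as
#' opposed to identified-but-untestable).
#'
#' @param occ_stats Occupancy statistics with verdict columns
#'   ([classify_occupancy_change()]).
#' @param prot_stats Protein statistics with verdict columns
#'   ([classify_protein_change()]).
#' @param annotation Annotation supplying `genome_of_origin` / `gene_class`.
#' @param id_map Optional data.frame (`gene_id`, `protein_id`) translating
#'   transcript symbols to protein symbols; identity by default.
#' @return data.frame with one row per (gene, comparison): verdicts, fold
#'   changes and p-values from both sides; attribute `join_cardinality`
#'   records the sizes of both inputs and the join.
#' @export
join_omics <- function(occ_stats, prot_stats, annotation = NULL,
                       id_map = NULL) {
  treat_o <- sub("^verdict_", "", grep("^verdict_", names(occ_stats),
                                       value = TRUE))
  treat_p <- sub("^verdict_", "", grep("^verdict_", names(prot_stats),
                                       value = TRUE))
  treat <- union(treat_o, treat_p)
  if (length(treat) == 0)
    stop("no verdict columns; classify both inputs first", call. = FALSE)

  pid <- occ_stats$gene_id
  if (!is.null(id_map)) {
    idx <- match(occ_stats$gene_id, id_map$gene_id)
    pid <- ifelse(is.na(idx), occ_stats$gene_id, id_map$protein_id[idx])
  }
  if (anyDuplicated(pid))
    stop("ambiguous gene symbols after mapping: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(prot_stats$protein_id))
    stop("ambiguous protein symbols: ",
         paste(unique(prot_stats$protein_id[duplicated(prot_stats$protein_id)]),
               collapse = ", "), call. = FALSE)
  occ_stats$.join_id <- pid
  genes <- union(pid, prot_stats$protein_id)

  oi <- match(genes, occ_stats$.join_id)
  pix <- match(genes, prot_stats$protein_id)
  rows <- list()
  for (g in treat) {
    occ_v <- ifelse(is.na(oi), "untested",
                    occ_stats[[paste0("verdict_", g)]][oi])
    occ_v[is.na(occ_v)] <- "untested"
    prot_v <- ifelse(is.na(pix), "not_detected",
                     prot_stats[[paste0("verdict_", g)]][pix])
    prot_v[is.na(prot_v)] <- "not_detected"
    df <- data.frame(
      gene_id = genes,
      comparison = paste0(g, "_vs_control"),
      occupancy_verdict = occ_v,
      protein_verdict = prot_v,
      dunnett_p = if (paste0("dunnett_p_", g) %in% names(occ_stats))
        occ_stats[[paste0("dunnett_p_", g)]][oi] else NA_real_,
      protein_log2fc = if (paste0("log2fc_", g) %in% names(prot_stats))
        prot_stats[[paste0("log2fc_", g)]][pix] else NA_real_,
      ttest_p = if (paste0("ttest_p_", g) %in% names(prot_stats))
        prot_stats[[paste0("ttest_p_", g)]][pix] else NA_real_,
      stringsAsFactors = FALSE
    )
    rows[[g]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(annotation)) {
    ai <- match(out$gene_id, annotation$gene_id)
    out$genome_of_origin <- annotation$genome_of_origin[ai]
    out$gene_class <- annotation$gene_class[ai]
  }
  attr(out, "join_cardinality") <- c(
    occupancy = nrow(occ_stats), proteins = nrow(prot_stats),
    joined_genes = length(genes))
  out
}

#' Map a (occupancy verdict, protein verdict) pair to a dichotomy category
#'
#' The two headline categories: `category-1` — occupancy up while the
#' protein is down or unchanged (ribosomes accumulate without a matching
#' protein gain, the stalled-translation signature); `category-2` —
#' occupancy unchanged while the protein moves (protein-level regulation
#' without a translation-occupancy change). All other verdict combinations
#' are labelled combinatorially; unevaluable pairs propagate `untested` /
#' `not-detected`.
#'
#' @param occupancy_verdict One of `up`, `unchanged`, `down`, `untested`.
#' @param protein_verdict One of `up`, `unchanged`, `down`, `untested`,
#'   `not_detected`.
#' @return Character category label (vectorized).
#' @export
dichotomy_category <- function(occupancy_verdict, protein_verdict) {
  stopifnot(length(occupancy_verdict) == length(protein_verdict))
  ok_o <- occupancy_verdict %in% c("up", "unchanged", "down", "untested")
  ok_p <- protein_verdict %in% c("up", "unchanged", "down", "untested",
                                 "not_detected")
  if (!all(ok_o) || !all(ok_p))
    stop("unknown verdict value", call. = FALSE)
  out <- character(length(occupancy_verdict))
  for (i in seq_along(out)) {
    o <- occupancy_verdict[i]
    p <- protein_verdict[i]
    out[i] <-
      if (o == "untested") "untested"
      else if (p == "untested") "untested"
      else if (p == "not_detected") "not-detected"
      else if (o == "up" && p %in% c("down", "unchanged")) "category-1"
      else if (o == "unchanged" && p %in% c("down", "up")) "category-2"
      else if (o == "up" && p == "up") "concordant-up"
      else if (o == "down" && p == "down") "concordant-down"
      else if (o == "down" && p == "unchanged") "occupancy-down-only"
      else if (o == "down" && p == "up") "discordant-down-up"
      else "concordant-unchanged"   # unchanged / unchanged
  }
  out
}

#' Assign dichotomy categories to a joined table
#'
#' @param joined Output of [join_omics()].
#' @return `joined` with an added `category` column.
#' @export
classify_dichotomy <- function(joined) {
  joined$category <- dichotomy_category(joined$occupancy_verdict,
                                        joined$protein_verdict)
  joined
}

#' Stratified summary of dichotomy records
#'
#' Counts of occupancy verdicts and dichotomy categories per gene-class
#' stratum (mt-OXPHOS, nu-OXPHOS, mito-associated, other) and comparison.
#'
#' @param records Classified dichotomy table ([classify_dichotomy()]).
#' @param annotation Annotation (used when `records` lacks `gene_class`).
#' @return list with `counts` (long data.frame `comparison`, `gene_class`,
#'   `category`, `n`) and `text` (human-readable lines).
#' @export
stratify_report <- function(records, annotation = NULL) {
  if (!"gene_class" %in% names(records)) {
    if (is.null(annotation))
      stop("records lack gene_class; supply an annotation", call. = FALSE)
    records$gene_class <-
      annotation$gene_class[match(records$gene_id, annotation$gene_id)]
  }
  records$gene_class[is.na(records$gene_class)] <- "other"
  tab <- as.data.frame(table(comparison = records$comparison,
                             gene_class = records$gene_class,
                             category = records$category),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "n"
  tab <- tab[tab$n > 0, , drop = FALSE]
  tab <- tab[order(tab$comparison, tab$gene_class, -tab$n), , drop = FALSE]
  rownames(tab) <- NULL
  lines <- character(0)
  for (cmp in unique(tab$comparison)) {
    lines <- c(lines, sprintf("== %s ==", cmp))
    sub <- tab[tab$comparison == cmp, ]
    for (gc in unique(sub$gene_class)) {
      s2 <- sub[sub$gene_class == gc, ]
      lines <- c(lines, sprintf("  %s: %s", gc,
                                paste(sprintf("%s=%d", s2$category, s2$n),
                                      collapse = ", ")))
    }
  }
  list(counts = tab, text = lines)
}
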