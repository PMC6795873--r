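#' Configuration for the lncRNA candidate cascade
#'
#' @param min_identity protein hits above this percent identity can remove
#'   a transcript (default 30, strict `>`).
#' @param max_evalue e-value cutoff for a removing hit (default 1e-2; a hit
#'   removes when `evalue <= max_evalue`, or `evalue > max_evalue` under
#'   `literal_evalue`, see [drop_protein_similar()]).
#' @param max_gene_distance antisense-proximity distance in bp (default
#'   5000, inclusive).
#' @param min_length minimum summed exon length in bp (default 200;
#'   shorter transcripts are removed, strict `<`).
#' @return list of class `"lncrna_config"`.
#' @export
lncrna_config <- function(min_identity = 30, max_evalue = 1e-2,
                          max_gene_distance = 5000L, min_length = 200L) {
  stopifnot(min_identity > 0, max_evalue > 0, max_gene_distance > 0,
            min_length > 0)
  structure(list(min_identity = min_identity, max_evalue = max_evalue,
                 max_gene_distance = as.integer(max_gene_distance),
                 min_length = as.integer(min_length)),
            class = "lncrna_config")
}

#' @keywords internal
filter_report <- function(step, tx, removed_ids) {
  list(step = step, n_in = nrow(tx$transcripts),
       n_removed = length(removed_ids),
       n_out = nrow(tx$transcripts) - length(removed_ids),
       removed = removed_ids)
}

#' @keywords internal
apply_removal <- function(tx, removed_ids, step) {
  rep <- filter_report(step, tx, removed_ids)
  keep <- setdiff(tx$transcripts$transcript_id, removed_ids)
  list(tx = tx_subset(tx, keep), report = rep)
}

#' Remove transcripts overlapping coding genes on the same strand
#'
#' A transcript is removed iff any of its exons overlaps (>= 1 bp) the body
#' of a coding gene on the same strand. Antisense overlaps are retained.
#'
#' @param tx a `"transcript_set"`.
#' @param genes gene table; only rows with `biotype == "coding"` are used.
#' @return list with `tx` (survivors) and `report`.
#' @export
drop_coding_overlap <- function(tx, genes) {
  coding <- genes[genes$biotype == "coding", , drop = FALSE]
  removed <- character()
  if (nrow(coding) && nrow(tx$exons)) {
    for (st in c("+", "-")) {
      e <- tx$exons[tx$exons$strand == st, , drop = FALSE]
      g <- coding[coding$strand == st, , drop = FALSE]
      if (!nrow(e) || !nrow(g)) next
      ov <- interval_overlaps(e, g)
      removed <- c(removed, unique(e$transcript_id[ov$query]))
    }
  }
  apply_removal(tx, unique(removed), "coding_overlap")
}

#' Remove transcripts with significant protein similarity
#'
#' A transcript is removed iff any hit has
#' `percent_identity > min_identity` and (by default)
#' `evalue <= max_evalue`. With `literal_evalue = TRUE` the e-value
#' inequality is inverted (`evalue > max_evalue`), reproducing a
#' weak-significance reading of the cutoff. Hits referencing transcripts
#' outside the set are ignored; invalid hit records (identity outside
#' [0, 100], e-value <= 0) are an error.
#'
#' @param tx a `"transcript_set"`.
#' @param hits protein hits table (see [read_protein_hits()]).
#' @param cfg a [lncrna_config()].
#' @param literal_evalue invert the e-value inequality (default FALSE).
#' @return list with `tx` and `report`.
#' @export
drop_protein_similar <- function(tx, hits, cfg = lncrna_config(),
                                 literal_evalue = FALSE) {
  removed <- character()
  if (!is.null(hits) && nrow(hits)) {
    validate_protein_hits(hits)
    eval_ok <- if (literal_evalue) hits$evalue > cfg$max_evalue
               else hits$evalue <= cfg$max_evalue
    bad <- hits$percent_identity > cfg$min_identity & eval_ok
    removed <- intersect(unique(hits$transcript_id[bad]),
                         tx$transcripts$transcript_id)
  }
  apply_removal(tx, removed, "protein_similarity")
}

#' Remove unspliced (single-exon) transcripts
#' @param tx a `"transcript_set"`.
#' @return list with `tx` and `report`.
#' @export
drop_unspliced <- function(tx) {
  removed <- tx$transcripts$transcript_id[tx$transcripts$n_exons == 1L]
  apply_removal(tx, removed, "unspliced")
}

#' Keep transcripts antisense to a nearby coding gene
#'
#' A transcript is retained iff its nearest coding gene (gene-body
#' distance, ties broken by distance then lexicographic gene id) lies
#' within `max_gene_distance` (inclusive) AND is on the opposite strand.
#' Note the rule consults only the single nearest gene, even if a farther
#' gene within range is antisense.
#'
#' @param tx a `"transcript_set"`.
#' @param genes gene table.
#' @param cfg a [lncrna_config()].
#' @return list with `tx` and `report`.
#' @export
keep_antisense_proximal <- function(tx, genes, cfg = lncrna_config()) {
  coding <- genes[genes$biotype == "coding", , drop = FALSE]
  t <- tx$transcripts
  if (!nrow(coding)) {
    warning("no coding genes; antisense-proximity removes every transcript")
    return(apply_removal(tx, t$transcript_id, "antisense_proximal"))
  }
  ng <- nearest_gene(t, coding)
  gstrand <- coding$strand[match(ng$gene_id, coding$gene_id)]
  keep <- !is.na(ng$gene_id) & ng$distance <= cfg$max_gene_distance &
    gstrand != t$strand
  apply_removal(tx, t$transcript_id[!keep], "antisense_proximal")
}

#' Remove short transcripts
#'
#' Removes transcripts whose summed exon length is strictly below
#' `min_length` (a 199 bp transcript is removed, a 200 bp one retained).
#'
#' @param tx a `"transcript_set"`.
#' @param cfg a [lncrna_config()].
#' @return list with `tx` and `report`.
#' @export
drop_short <- function(tx, cfg = lncrna_config()) {
  removed <- tx$transcripts$transcript_id[
    tx$transcripts$length < cfg$min_length]
  apply_removal(tx, removed, "length")
}

#' Run the five-rule lncRNA candidate cascade
#'
#' Applies, in order: same-strand coding overlap removal, protein
#' similarity removal, unspliced removal, antisense-proximity retention,
#' and the minimum-length filter. Each step's survivors feed the next; the
#' per-step audit chain reconciles exactly (`n_in - n_removed = n_out`).
#'
#' @inheritParams drop_protein_similar
#' @param genes gene table (coding genes drive rules 1 and 4).
#' @return object of class `"lncrna_cascade"`: `lncrnas` (surviving
#'   `"transcript_set"`), `reports` (data.frame, one row per step),
#'   `removed` (named list of removed ids per step).
#' @export
run_cascade <- function(tx, genes, hits = NULL, cfg = lncrna_config(),
                        literal_evalue = FALSE) {
  steps <- list(
    function(t) drop_coding_overlap(t, genes),
    function(t) drop_protein_similar(t, hits, cfg, literal_evalue),
    function(t) drop_unspliced(t),
    function(t) keep_antisense_proximal(t, genes, cfg),
    function(t) drop_short(t, cfg))
  reports <- list()
  removed <- list()
  cur <- tx
  for (f in steps) {
    res <- f(cur)
    cur <- res$tx
    reports[[res$report$step]] <- res$report
    removed[[res$report$step]] <- res$report$removed
  }
  rep_df <- do.call(rbind, lapply(reports, function(r)
    data.frame(step = r$step, n_in = r$n_in, n_removed = r$n_removed,
               n_out = r$n_out, stringsAsFactors = FALSE)))
  rownames(rep_df) <- NULL
  structure(list(lncrnas = cur, reports = rep_df, removed = removed),
            class = "lncrna_cascade")
}

#' @export
print.lncrna_cascade <- function(x, ...) {
  cat("lncRNA filter cascade:\n")
  print.data.frame(x$reports, row.names = FALSE)
  cat("final candidates:", nrow(x$lncrnas$transcripts), "\n")
  invisible(x)
}

#' Fraction of lncRNAs overlapping accessible (ATAC-positive) regions
#'
#' Strand-blind: a transcript counts when any exon overlaps (>= 1 bp) any
#' peak. An empty transcript set yields `NaN` with a warning.
#'
#' @param tx a `"transcript_set"` (e.g. `run_cascade(...)$lncrnas`).
#' @param peaks interval table of accessible regions.
#' @return fraction in [0, 1] (or NaN).
#' @export
atac_overlap_fraction <- function(tx, peaks) {
  n <- nrow(tx$transcripts)
  if (n == 0L) {
    warning("empty transcript set; overlap fraction undefined")
    return(NaN)
  }
  if (nrow(peaks) == 0L) return(0)
  ov <- interval_overlaps(tx$exons, peaks)
  length(unique(tx$exons$transcript_id[ov$query])) / n
}
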