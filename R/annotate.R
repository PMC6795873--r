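#' Configuration for peak classification and filtering
#'
#' @param promoter_flank promoter window size upstream of the TSS in bp
#'   (default 2000).
#' @param proximity_max retain intergenic/intronic peaks strictly closer
#'   than this to an enriched gene, in bp (default 50000).
#' @param min_gene_length genes with a shorter body span are dropped before
#'   classification, in bp (default 1500).
#' @param enrichment_padj,enrichment_lfc a gene is "enriched" when
#'   `padj < enrichment_padj` and `log2fc > enrichment_lfc` (defaults 0.05
#'   and 0).
#' @return list of class `"annotation_config"`.
#' @export
annotation_config <- function(promoter_flank = 2000L, proximity_max = 50000L,
                              min_gene_length = 1500L,
                              enrichment_padj = 0.05, enrichment_lfc = 0) {
  stopifnot(promoter_flank > 0, proximity_max > 0, min_gene_length > 0,
            enrichment_padj > 0)
  structure(list(promoter_flank = as.integer(promoter_flank),
                 proximity_max = as.integer(proximity_max),
                 min_gene_length = as.integer(min_gene_length),
                 enrichment_padj = enrichment_padj,
                 enrichment_lfc = enrichment_lfc),
            class = "annotation_config")
}

#' Merge per-stage peak sets into a consensus peakset
#'
#' Concatenates the stage peak lists and merges overlapping/abutting
#' intervals ([merge_intervals()]). Each consensus peak records which
#' stages contributed at least one (overlapping or abutting) input peak.
#'
#' @param stage_peaks named list of interval tables, one per stage.
#' @return interval table with consensus peak names (`cons_1`, ...) and a
#'   `stages` column (comma-separated contributing stage labels).
#' @export
build_consensus <- function(stage_peaks) {
  if (!length(stage_peaks)) stop("at least one stage peak set is required")
  if (is.null(names(stage_peaks)))
    names(stage_peaks) <- sprintf("stage%d", seq_along(stage_peaks))
  all_pk <- do.call(rbind, lapply(stage_peaks, function(p)
    p[, c("seqid", "start", "end")]))
  cons <- merge_intervals(gintervals(all_pk$seqid, all_pk$start, all_pk$end))
  cons$name <- sprintf("cons_%d", seq_len(nrow(cons)))
  prov <- matrix(FALSE, nrow(cons), length(stage_peaks),
                 dimnames = list(NULL, names(stage_peaks)))
  for (st in names(stage_peaks)) {
    ov <- interval_overlaps(cons, stage_peaks[[st]], maxgap = 0L)
    prov[unique(ov$query), st] <- TRUE
  }
  cons$stages <- apply(prov, 1L, function(r)
    paste(colnames(prov)[r], collapse = ","))
  cons
}

#' Strand-aware promoter windows for gene models
#'
#' For a `+` strand gene the window is `[TSS - flank, TSS)`; for a `-`
#' strand gene `(TSS, TSS + flank]` (half-open genomic coordinates:
#' `[tss + 1, tss + 1 + flank)`). The TSS base itself is excluded. Windows
#' are clipped at position 0.
#'
#' @param genes gene table.
#' @param flank window size in bp.
#' @return interval table with a `gene_id` column.
#' @export
promoter_windows <- function(genes, flank = 2000L) {
  if (nrow(genes) == 0L)
    return(cbind(gintervals(character(), integer(), integer()),
                 gene_id = character()))
  start <- ifelse(genes$strand == "-", genes$tss + 1L,
                  pmax(genes$tss - flank, 0L))
  end <- ifelse(genes$strand == "-", genes$tss + 1L + flank, genes$tss)
  keep <- start < end
  w <- gintervals(genes$seqid[keep], start[keep], end[keep],
                  strand = genes$strand[keep])
  w$gene_id <- genes$gene_id[keep]
  w
}

#' Classify consensus peaks into promoter/exonic/intronic/intergenic
#'
#' Categories are assigned with priority promoter > exonic > intronic >
#' intergenic: a peak overlapping any strand-aware promoter window is a
#' promoter peak regardless of other overlaps; otherwise exon overlap wins
#' over gene-body (intron) overlap; peaks touching nothing are intergenic.
#' Genes (and their transcripts) with body span below
#' `cfg$min_gene_length` are removed before classification. The nearest
#' gene (gene-body distance, deterministic tie-break) is reported per peak.
#'
#' @param peaks consensus peak table.
#' @param transcripts a `"transcript_set"` of the de novo models (may be
#'   NULL: no exon/intron evidence).
#' @param genes gene table matching the transcript models.
#' @param cfg an [annotation_config()].
#' @return the peak table with `category`, `nearest_gene`,
#'   `nearest_distance`, `signed_distance` columns.
#' @export
classify_peaks <- function(peaks, transcripts, genes,
                           cfg = annotation_config()) {
  n <- nrow(peaks)
  if (nrow(genes)) {
    keep <- (genes$end - genes$start) >= cfg$min_gene_length
    genes <- genes[keep, , drop = FALSE]
  }
  if (!is.null(transcripts))
    transcripts <- tx_subset(
      transcripts,
      transcripts$transcripts$transcript_id[
        is.na(transcripts$transcripts$gene_id) |
          transcripts$transcripts$gene_id %in% genes$gene_id])
  category <- rep("intergenic", n)
  if (nrow(genes)) {
    pw <- promoter_windows(genes, cfg$promoter_flank)
    in_prom <- unique(interval_overlaps(peaks, pw)$query)
    in_exon <- integer()
    if (!is.null(transcripts) && nrow(transcripts$exons))
      in_exon <- unique(interval_overlaps(peaks, transcripts$exons)$query)
    in_body <- unique(interval_overlaps(
      peaks, genes[, c("seqid", "start", "end")])$query)
    category[in_body] <- "intronic"
    category[in_exon] <- "exonic"
    category[in_prom] <- "promoter"
    # peaks overlapping a body but no exon of an exon-bearing gene are
    # intronic; when no transcript models exist, body overlap counts as
    # intronic as well (no exon evidence).
  }
  ng <- nearest_gene(peaks, genes)
  peaks$category <- category
  peaks$nearest_gene <- ng$gene_id
  peaks$nearest_distance <- ng$distance
  peaks$signed_distance <- ng$signed_distance
  peaks
}

#' Move intergenic peaks overlapping curated promoters to the promoter set
#'
#' Peaks classified intergenic against the de novo models but overlapping a
#' promoter window of the curated (e.g. germline-genome) annotation are
#' relabelled `promoter`. Coordinates never change; the outputs partition
#' the input.
#'
#' @param annotated classified peak table (from [classify_peaks()]).
#' @param curated_genes curated gene table.
#' @param cfg an [annotation_config()].
#' @return the input table with updated `category` and a logical
#'   `reassigned` column.
#' @export
reassign_intergenic_promoters <- function(annotated, curated_genes,
                                          cfg = annotation_config()) {
  annotated$reassigned <- FALSE
  ig <- which(annotated$category == "intergenic")
  if (!length(ig) || is.null(curated_genes) || nrow(curated_genes) == 0L)
    return(annotated)
  pw <- promoter_windows(curated_genes, cfg$promoter_flank)
  hit <- unique(interval_overlaps(annotated[ig, , drop = FALSE], pw)$query)
  annotated$category[ig[hit]] <- "promoter"
  annotated$reassigned[ig[hit]] <- TRUE
  annotated
}

#' Filter peaks by proximity to stage-enriched genes
#'
#' Retains a peak iff its gene-body distance to the closest enriched gene
#' is strictly below `cfg$proximity_max` (so a peak at exactly the
#' threshold is removed). Enriched genes are those with
#' `padj < enrichment_padj` and `log2fc > enrichment_lfc`. Intended for the
#' intergenic and intronic sets.
#'
#' @param peaks peak table.
#' @param genes gene table (coordinates for the DE gene ids).
#' @param de differential-expression table (see [read_de_table()]).
#' @param cfg an [annotation_config()].
#' @return the retained subset, with `enriched_distance` column.
#' @export
proximity_filter <- function(peaks, genes, de, cfg = annotation_config()) {
  enriched <- de$gene_id[!is.na(de$padj) & de$padj < cfg$enrichment_padj &
                           de$log2fc > cfg$enrichment_lfc]
  eg <- genes[genes$gene_id %in% enriched, , drop = FALSE]
  if (nrow(eg) == 0L) {
    warning("no enriched genes; proximity filter removes every peak")
    out <- peaks[integer(), , drop = FALSE]
    out$enriched_distance <- numeric()
    return(out)
  }
  ng <- nearest_gene(peaks, eg)
  keep <- ng$distance < cfg$proximity_max
  out <- peaks[keep, , drop = FALSE]
  out$enriched_distance <- ng$distance[keep]
  out
}

#' Full peak annotation pipeline
#'
#' Consensus building, classification against the de novo models, curated
#' promoter reassignment, and the enriched-gene proximity filter applied to
#' the intergenic and intronic sets.
#'
#' @inheritParams build_consensus
#' @inheritParams classify_peaks
#' @param curated_genes curated annotation for promoter reassignment
#'   (NULL to skip).
#' @param de DE table for the proximity filter (NULL to skip).
#' @param cfg an [annotation_config()].
#' @return list with `consensus` (classified, post-reassignment) and
#'   `filtered` (named list of per-category peak tables after the proximity
#'   filter on intergenic/intronic).
#' @export
annotate_pipeline <- function(stage_peaks, transcripts, genes,
                              curated_genes = NULL, de = NULL,
                              cfg = annotation_config()) {
  cons <- build_consensus(stage_peaks)
  cons <- classify_peaks(cons, transcripts, genes, cfg)
  cons <- reassign_intergenic_promoters(cons, curated_genes, cfg)
  sets <- split(cons, cons$category)
  for (cat in intersect(c("intergenic", "intronic"), names(sets))) {
    if (!is.null(de))
      sets[[cat]] <- proximity_filter(sets[[cat]], genes, de, cfg)
  }
  list(consensus = cons, filtered = sets)
}
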