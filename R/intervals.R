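#' Construct a table of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based start,
#' exclusive end (half-open), so `end - start` is the length in base pairs.
#' GFF3/GTF input is converted to this convention at the boundary by
#' [read_gff3_genes()] and [read_gtf_transcripts()].
#'
#' @param seqid character, sequence (chromosome/contig) names.
#' @param start integer, 0-based inclusive start positions.
#' @param end integer, exclusive end positions; must satisfy `start < end`.
#' @param name optional interval labels.
#' @param score optional numeric scores (default 0).
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @return A `data.frame` with columns `seqid`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @examples
#' gintervals("chr1", c(100, 400), c(250, 500), name = c("pk1", "pk2"))
#' @export
gintervals <- function(seqid, start, end, name = NA_character_, score = 0,
                       strand = ".") {
  n <- length(start)
  df <- data.frame(
    seqid = rep_len(as.character(seqid), n),
    start = as.integer(start),
    end = as.integer(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' @keywords internal
validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("seqid", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval start/end must not be NA")
  if (any(df$start < 0L))
    stop("interval start must be >= 0")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("invalid interval(s) with start >= end at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Gap distance between genomic intervals
#'
#' Distance is 0 when intervals overlap or abut (half-open coordinates:
#' `(100,200)` and `(200,300)` abut); otherwise the size of the gap between
#' the nearest ends. Strand is ignored. Intervals on different sequences are
#' at distance `Inf` (a sentinel, never an error). Vectorised elementwise
#' with the usual recycling.
#'
#' @param a,b interval tables as built by [gintervals()] (single rows or
#'   equal-length/recyclable tables).
#' @return Numeric vector of distances in base pairs (`Inf` across seqids).
#' @examples
#' a <- gintervals("chr1", 100, 200)
#' interval_distance(a, gintervals("chr1", 260, 300))  # 60
#' interval_distance(a, gintervals("chr1", 200, 300))  # 0 (abutting)
#' @export
interval_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  d <- pmax(pmax(a$start[ia], b$start[ib]) - pmin(a$end[ia], b$end[ib]), 0)
  d <- as.numeric(d)
  d[a$seqid[ia] != b$seqid[ib]] <- Inf
  d
}

#' Merge overlapping or abutting intervals into a strand-blind union
#'
#' Mirrors `bedtools merge` defaults: any two intervals that overlap or
#' abut (gap 0) end up in one output interval; strand is ignored. Output is
#' sorted by `seqid`, then `start`. The merge is idempotent and invariant
#' under input permutation.
#'
#' @param x an interval table; may be empty.
#' @return A sorted interval table (`name` = NA, `score` = 0, `strand` = ".").
#' @examples
#' merge_intervals(gintervals("chr1", c(100, 150, 400), c(200, 250, 500)))
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L)
    return(gintervals(character(), integer(), integer()))
  out <- lapply(split(x, x$seqid), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(seqid = d$seqid[1L],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  gintervals(out$seqid, out$start, out$end)
}

#' Overlap hits between two interval tables
#'
#' @param query,subject interval tables.
#' @param maxgap largest gap still counted as a hit; `0` treats abutting
#'   intervals as hits, the default `-1` requires >= 1 bp overlap.
#' @return data.frame with columns `query`, `subject` (row indices).
#' @keywords internal
interval_overlaps <- function(query, subject, maxgap = -1L) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(), subject = integer()))
  res <- vector("list", 0L)
  for (sq in intersect(unique(query$seqid), unique(subject$seqid))) {
    qi <- which(query$seqid == sq)
    si <- which(subject$seqid == sq)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(query$start[qi] + 1L, query$end[qi]),
      IRanges::IRanges(subject$start[si] + 1L, subject$end[si]),
      maxgap = maxgap)
    res[[sq]] <- data.frame(query = qi[S4Vectors::queryHits(hits)],
                            subject = si[S4Vectors::subjectHits(hits)])
  }
  if (!length(res)) return(data.frame(query = integer(), subject = integer()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$query, out$subject), , drop = FALSE]
}

#' Nearest gene for each interval
#'
#' Distance is gene-body [interval_distance()] (overlap => 0); ties are
#' broken by smaller distance, then lexicographic `gene_id`, so results are
#' deterministic.
#'
#' @param x an interval table.
#' @param genes a gene table as from [read_gff3_genes()].
#' @return data.frame with `gene_id`, `distance` (Inf and NA gene when no
#'   gene shares the sequence) and `signed_distance` (negative when the
#'   interval lies left of the gene on the genomic axis).
#' @export
nearest_gene <- function(x, genes) {
  n <- nrow(x)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(Inf, n),
                    signed_distance = rep(NA_real_, n))
  if (n == 0L || nrow(genes) == 0L) return(out)
  g_ord <- order(genes$gene_id)
  for (i in seq_len(n)) {
    gi <- g_ord[genes$seqid[g_ord] == x$seqid[i]]
    if (!length(gi)) next
    d <- pmax(pmax(genes$start[gi], x$start[i]) -
                pmin(genes$end[gi], x$end[i]), 0)
    j <- gi[which.min(d)]  # first hit in gene_id order breaks ties
    out$gene_id[i] <- genes$gene_id[j]
    out$distance[i] <- min(d)
    sgn <- if (x$end[i] <= genes$start[j]) -1 else 1
    out$signed_distance[i] <- sgn * min(d)
  }
  out
}
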