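#' Read a BED file of intervals
#'
#' Handles BED3 through BED6. `track`/`browser`/`#` header lines are skipped
#' silently. A missing score column becomes 0 and a missing strand column
#' becomes ".". Malformed lines raise an error naming the offending line
#' number. Coordinates are passed through unchanged (BED is already 0-based
#' half-open).
#'
#' @param path path to a BED file.
#' @return An interval table (see [gintervals()]) carrying the original
#'   column count in attribute `"bedcols"` so [write_bed()] can round-trip.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- gintervals(character(), integer(), integer())
    attr(out, "bedcols") <- 3L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line (fewer than 3 fields) at line ",
         lineno[which(nf < 3L)[1L]])
  ncol <- min(nf, 6L)
  get <- function(k) vapply(fields, function(f)
    if (length(f) >= k) f[[k]] else NA_character_, character(1))
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED coordinates at line ", lineno[bad[1L]])
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop("invalid BED interval (start >= end or negative) at line ",
         lineno[bad[1L]])
  name <- if (ncol >= 4L) get(4L) else NA_character_
  score <- if (ncol >= 5L) suppressWarnings(as.numeric(get(5L))) else 0
  score[is.na(score)] <- 0
  strand <- if (ncol >= 6L) get(6L) else "."
  strand[!strand %in% c("+", "-", ".")] <- "."
  out <- gintervals(get(1L), start, end, name = name, score = score,
                    strand = strand)
  attr(out, "bedcols") <- as.integer(min(max(nf), 6L))
  out
}

#' Write intervals as BED
#'
#' Writes as many columns as `ncols` (default: the `"bedcols"` attribute
#' set by [read_bed()], else 6), so a read/write round trip reproduces
#' well-formed input.
#'
#' @param x an interval table.
#' @param path output path.
#' @param ncols number of BED columns to emit (3--6).
#' @export
write_bed <- function(x, path, ncols = NULL) {
  if (is.null(ncols)) ncols <- attr(x, "bedcols")
  if (is.null(ncols)) ncols <- 6L
  ncols <- max(3L, min(6L, as.integer(ncols)))
  cols <- list(x$seqid, format(x$start, trim = TRUE, scientific = FALSE),
               format(x$end, trim = TRUE, scientific = FALSE))
  if (ncols >= 4L) cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (ncols >= 5L) cols <- c(cols, list(format(x$score, trim = TRUE,
                                               scientific = FALSE)))
  if (ncols >= 6L) cols <- c(cols, list(x$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path path to a bedGraph file (`seqid start end value`, 0-based
#'   half-open). `track`/`#` headers are skipped.
#' @return data.frame with columns `seqid`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), value = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("malformed bedGraph line at line ",
         lineno[which(lengths(fields) < 4L)[1L]])
  df <- data.frame(
    seqid = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    value = as.numeric(vapply(fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (any(is.na(df$start) | is.na(df$end) | is.na(df$value)))
    stop("malformed bedGraph values in ", path)
  df
}

#' Build a queryable per-stage signal track
#'
#' Converts one bedGraph table per stage into run-length encoded per-base
#' coverage, supporting window queries and fast binned sums (used by
#' [build_profiles()]). Intervals within one stage track must not overlap.
#'
#' @param ... named bedGraph tables (one per stage), or a single named list.
#' @return An object of class `"signal_track"`.
#' @export
signal_track <- function(...) {
  tracks <- list(...)
  if (length(tracks) == 1L && is.list(tracks[[1L]]) &&
      !is.data.frame(tracks[[1L]]))
    tracks <- tracks[[1L]]
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("signal_track() needs one *named* bedGraph table per stage")
  rles <- lapply(tracks, function(bg) {
    out <- list()
    for (sq in unique(bg$seqid)) {
      d <- bg[bg$seqid == sq, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (any(d$start[-1L] < d$end[-nrow(d)]))
        stop("overlapping bedGraph intervals on ", sq)
      # interleave zero-gap runs with value runs
      gaps <- c(d$start, 0L) - c(0L, d$end)
      vals <- as.vector(rbind(0, d$value))
      lens <- as.vector(rbind(gaps[seq_len(nrow(d))], d$end - d$start))
      keep <- lens > 0L
      out[[sq]] <- S4Vectors::Rle(vals[keep], lens[keep])
    }
    out
  })
  structure(list(stages = rles), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$stages), "stage(s):",
      paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}

#' Query total signal over a window
#'
#' Returns the sum of per-base coverage over `[start, end)` (0-based
#' half-open); regions outside any track interval (or off the end of the
#' recorded sequence) contribute 0. Unknown stage labels are an error.
#'
#' @param track a [signal_track()].
#' @param stage stage label.
#' @param seqid sequence name.
#' @param start,end window, 0-based half-open.
#' @return numeric scalar.
#' @export
signal_query <- function(track, stage, seqid, start, end) {
  if (!stage %in% names(track$stages))
    stop("unknown stage label: ", stage)
  rle <- track$stages[[stage]][[seqid]]
  if (is.null(rle)) return(0)
  len <- length(rle)
  s <- max(start + 1L, 1L)
  e <- min(end, len)
  if (s > e) return(0)
  sum(S4Vectors::window(rle, s, e))
}

#' Read a peaks-by-stages counts table
#'
#' @param path TSV with a `peak` id column followed by one column per stage.
#' @return numeric matrix, rows named by peak, columns by stage.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Look up counts for a peak and stage
#' @param counts matrix from [read_counts()].
#' @param peak peak name.
#' @param stage stage label.
#' @export
counts_lookup <- function(counts, peak, stage) {
  if (!stage %in% colnames(counts)) stop("unknown stage label: ", stage)
  if (!peak %in% rownames(counts)) stop("unknown peak: ", peak)
  counts[peak, stage]
}

#' Read gene models from GFF3
#'
#' Imports via rtracklayer and converts 1-based inclusive coordinates to the
#' package's 0-based half-open convention (`start' = start - 1`, `end' =
#' end`). The TSS is strand-dependent: `start` for `+`, `end - 1` for `-`.
#'
#' @param path GFF3 file; features of type `gene` are used.
#' @param default_biotype biotype assumed when no `gene_biotype`/`biotype`
#'   attribute is present.
#' @return data.frame with `gene_id`, `seqid`, `start`, `end`, `strand`,
#'   `tss`, `biotype`.
#' @export
read_gff3_genes <- function(path, default_biotype = "coding") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  gid <- if ("gene_id" %in% names(mc)) mc$gene_id else mc$ID
  bt <- if ("gene_biotype" %in% names(mc)) mc$gene_biotype
        else if ("biotype" %in% names(mc)) mc$biotype
        else rep(default_biotype, length(gr))
  bt[is.na(bt)] <- default_biotype
  g <- data.frame(
    gene_id = as.character(gid),
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = as.character(bt),
    stringsAsFactors = FALSE)
  if (any(g$start >= g$end))
    stop("invalid gene interval after coordinate conversion in ", path)
  g$tss <- ifelse(g$strand == "-", g$end - 1L, g$start)
  g[, c("gene_id", "seqid", "start", "end", "strand", "tss", "biotype")]
}

#' Read transcript models from GTF
#'
#' Groups `exon` features by `transcript_id`; exons are sorted by start and
#' coordinates converted to 0-based half-open.
#'
#' @param path GTF file.
#' @return A list of class `"transcript_set"` with elements `transcripts`
#'   (one row per transcript: id, gene, seqid, strand, span, exon count,
#'   summed exon length) and `exons` (one row per exon).
#' @export
read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ex <- data.frame(
    transcript_id = as.character(gr$transcript_id),
    gene_id = if (!is.null(gr$gene_id)) as.character(gr$gene_id)
              else NA_character_,
    seqid = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  transcript_set(ex)
}

#' Build a transcript set from an exon table
#'
#' @param exons data.frame with `transcript_id`, optional `gene_id`,
#'   `seqid`, `strand`, `start`, `end` (0-based half-open).
#' @return A `"transcript_set"` (see [read_gtf_transcripts()]).
#' @export
transcript_set <- function(exons) {
  validate_intervals(exons)
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (!"gene_id" %in% names(exons)) exons$gene_id <- NA_character_
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  tx <- do.call(rbind, lapply(sp, function(idx) {
    e <- exons[idx, , drop = FALSE]
    if (length(unique(e$seqid)) != 1L || length(unique(e$strand)) != 1L)
      stop("transcript ", e$transcript_id[1L],
           " has exons on multiple seqids/strands")
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("transcript ", e$transcript_id[1L], " has overlapping exons")
    data.frame(transcript_id = e$transcript_id[1L],
               gene_id = e$gene_id[1L], seqid = e$seqid[1L],
               strand = e$strand[1L], start = min(e$start),
               end = max(e$end), n_exons = nrow(e),
               length = sum(e$end - e$start), stringsAsFactors = FALSE)
  }))
  rownames(tx) <- NULL
  structure(list(transcripts = tx, exons = exons), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcript(s),",
      nrow(x$exons), "exon(s)\n")
  invisible(x)
}

#' Subset a transcript set by transcript id
#' @param x a `"transcript_set"`.
#' @param ids transcript ids to keep.
#' @export
tx_subset <- function(x, ids) {
  structure(list(
    transcripts = x$transcripts[x$transcripts$transcript_id %in% ids, ,
                                drop = FALSE],
    exons = x$exons[x$exons$transcript_id %in% ids, , drop = FALSE]),
    class = "transcript_set")
}

#' Write gene models as GFF3
#' @param genes gene table (see [read_gff3_genes()]).
#' @param path output path.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tcrestreg\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_biotype=%s",
                     genes$seqid, genes$start + 1L, genes$end, genes$strand,
                     genes$gene_id, genes$biotype))
  writeLines(lines, path)
  invisible(path)
}

#' Write a transcript set as GTF
#' @param tx a `"transcript_set"`.
#' @param path output path.
#' @export
write_gtf_transcripts <- function(tx, path) {
  e <- tx$exons
  gid <- ifelse(is.na(e$gene_id), e$transcript_id, e$gene_id)
  lines <- sprintf(
    '%s\tcrestreg\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    e$seqid, e$start + 1L, e$end, e$strand, gid, e$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression gene table
#'
#' @param path TSV with columns `gene_id`, `log2fc`, `padj`, `base_mean`.
#' @return data.frame with those columns.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj", "base_mean")
  if (!all(need %in% names(df)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE))
    stop("padj must lie in [0, 1]")
  df[, need]
}

#' Read protein similarity hits (BLAST outfmt 6 dialect)
#'
#' Column order: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Only the query id, percent identity and
#' e-value are retained.
#'
#' @param path tabular hits file (no header).
#' @return data.frame with `transcript_id`, `percent_identity`, `evalue`.
#' @export
read_protein_hits <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 outfmt-6 columns in ", path)
  out <- data.frame(transcript_id = as.character(df[[1L]]),
                    percent_identity = as.numeric(df[[3L]]),
                    evalue = as.numeric(df[[11L]]),
                    stringsAsFactors = FALSE)
  validate_protein_hits(out)
  out
}

#' @keywords internal
validate_protein_hits <- function(hits) {
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(is.na(hits$percent_identity)) ||
      any(hits$percent_identity < 0 | hits$percent_identity > 100))
    stop("percent_identity must lie in [0, 100]")
  if (any(is.na(hits$evalue)) || any(hits$evalue <= 0))
    stop("e-values must be > 0")
  invisible(hits)
}
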