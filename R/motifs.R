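BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix (PWM)
#'
#' Probabilities are stored as a positions x 4 matrix (columns A, C, G, T).
#' Count matrices are converted to probabilities by row (position) sums.
#' Scoring uses natural-log odds against a background composition with a
#' pseudocount proportional to the background (see [logodds_matrix()]).
#'
#' @param probs positions x 4 numeric matrix of base probabilities or
#'   counts (rows = motif positions).
#' @param label motif label.
#' @param background length-4 background base probabilities (must sum to 1,
#'   all > 0); default uniform.
#' @param pseudo pseudocount weight (> 0); default `1e-3`.
#' @return An object of class `"pwm"`.
#' @export
pwm <- function(probs, label = "motif", background = rep(0.25, 4),
                pseudo = 1e-3) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  if (any(probs < 0)) stop("PWM entries must be non-negative")
  rs <- rowSums(probs)
  if (any(rs <= 0)) stop("PWM has an all-zero position")
  probs <- probs / rs
  colnames(probs) <- BASES
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 probabilities summing to 1")
  if (any(background <= 0)) stop("background probabilities must be > 0")
  if (pseudo <= 0) stop("pseudo must be > 0")
  structure(list(label = label, probs = probs,
                 background = stats::setNames(as.numeric(background), BASES),
                 pseudo = pseudo),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm '", x$label, "': ", nrow(x$probs), " positions, consensus ",
      pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param x a `"pwm"`.
#' @export
pwm_consensus <- function(x) {
  paste(BASES[max.col(x$probs, ties.method = "first")], collapse = "")
}

#' Natural-log odds score matrix of a PWM
#'
#' Entry for position i, base b is
#' `ln((p[i,b] + pseudo * bg[b]) / (bg[b] * (1 + pseudo)))`, so a uniform
#' PWM over a uniform background scores 0 everywhere and larger pseudocounts
#' shrink scores toward 0.
#'
#' @param x a `"pwm"`.
#' @return positions x 4 numeric matrix.
#' @export
logodds_matrix <- function(x) {
  stopifnot(inherits(x, "pwm"))
  bg <- matrix(x$background, nrow = nrow(x$probs), ncol = 4L, byrow = TRUE)
  lo <- log((x$probs + x$pseudo * bg) / (bg * (1 + x$pseudo)))
  colnames(lo) <- BASES
  lo
}

#' Maximum attainable scan score of a PWM
#' @param x a `"pwm"`.
#' @export
pwm_max_score <- function(x) sum(apply(logodds_matrix(x), 1L, max))

#' Reverse complement of a PWM
#' @param x a `"pwm"`.
#' @export
pwm_revcomp <- function(x) {
  p <- x$probs[rev(seq_len(nrow(x$probs))), rev(seq_len(4L)), drop = FALSE]
  colnames(p) <- BASES
  pwm(p, label = x$label, background = as.numeric(x$background),
      pseudo = x$pseudo)
}

#' @keywords internal
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], BASES)
}

#' Scan a sequence with a PWM on both strands
#'
#' Reports every offset (0-based, on the forward sequence) where the summed
#' log-odds score reaches the threshold; overlapping hits are all reported.
#' Windows containing `N` (or any non-ACGT letter) never score. A
#' reverse-strand hit at offset `i` means the reverse complement of the
#' motif matches the forward sequence starting at `i`.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param x a `"pwm"`.
#' @param min_score threshold; with `score_type = "fraction"` (default) it
#'   is the fraction of the maximum attainable score, with `"absolute"` a
#'   raw log-odds score.
#' @param score_type `"fraction"` or `"absolute"`.
#' @return data.frame with `offset`, `strand`, `score` (empty when the
#'   sequence is shorter than the motif).
#' @export
scan_pwm <- function(seq, x, min_score = 0.8,
                     score_type = c("fraction", "absolute")) {
  score_type <- match.arg(score_type)
  stopifnot(inherits(x, "pwm"))
  thr <- if (score_type == "fraction") min_score * pwm_max_score(x)
         else min_score
  code <- encode_dna(seq)
  L <- nrow(x$probs)
  n <- length(code) - L + 1L
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric())
  if (n < 1L) return(empty)
  score_strand <- function(lo) {
    idx <- outer(seq_len(n) - 1L, seq_len(L), `+`)  # n x L positions
    b <- matrix(code[idx], nrow = n)
    sc <- matrix(lo[cbind(rep(seq_len(L), each = n), as.vector(b))],
                 nrow = n)
    rowSums(sc)  # NA wherever an N fell in the window
  }
  lo <- logodds_matrix(x)
  lo_rc <- lo[rev(seq_len(L)), rev(seq_len(4L)), drop = FALSE]
  res <- list()
  for (st in c("+", "-")) {
    sc <- score_strand(if (st == "+") lo else lo_rc)
    hit <- which(!is.na(sc) & sc >= thr)
    res[[st]] <- data.frame(offset = hit - 1L,
                            strand = rep(st, length(hit)),
                            score = sc[hit])
  }
  out <- rbind(res[["+"]], res[["-"]])
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Read motifs in JASPAR PFM format
#'
#' Accepts the JASPAR text dialect (`>ID NAME` header, then four rows
#' `A [ 1 2 3 ]` ... in A/C/G/T order) and a plain 4-row whitespace table
#' per motif.
#'
#' @param path PFM file, possibly with several motifs.
#' @inheritParams pwm
#' @return list of `"pwm"` objects, named by label.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudo = 1e-3) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) heads <- 1L  # headerless single motif
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    block <- lines[heads[i]:(bounds[i + 1L] - 1L)]
    lab <- if (grepl("^>", block[1L])) {
      parts <- strsplit(sub("^>\\s*", "", block[1L]), "\\s+")[[1L]]
      parts[length(parts)]
    } else sprintf("motif%d", i)
    rows <- grep("^>", block, invert = TRUE, value = TRUE)
    if (length(rows) < 4L) stop("motif block with fewer than 4 rows in ", path)
    vals <- lapply(rows[1:4], function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("[][]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    })
    if (length(unique(lengths(vals))) != 1L)
      stop("ragged motif rows in ", path)
    mat <- do.call(rbind, vals)  # 4 x L, rows A/C/G/T
    out[[lab]] <- pwm(t(mat), label = lab, background = background,
                      pseudo = pseudo)
  }
  out
}

#' Write motifs in JASPAR PFM format
#' @param pwms list of `"pwm"` objects.
#' @param path output path.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    counts <- round(t(p$probs) * 100)
    c(paste0(">", p$label, " ", p$label),
      sprintf("%s [ %s ]", BASES, apply(counts, 1L, paste, collapse = " ")))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Binary motif presence matrix over peak-centre windows
#'
#' For each peak, the sequence around the peak centre (floor midpoint) is
#' scanned with every PWM; cell (region, motif) is 1 iff at least one hit's
#' start offset lies within `centre - window .. centre + window`
#' (inclusive) in genomic coordinates. Windows extending past a sequence
#' end are clipped.
#'
#' @param peaks interval table with unique `name`s.
#' @param genome a named [Biostrings::DNAStringSet] (names = seqids) or a
#'   FASTA path.
#' @param pwms list of `"pwm"` objects.
#' @param window half-width of the scan window in bp (default 250).
#' @inheritParams scan_pwm
#' @return binary integer matrix, rows = peak names, columns = motif labels.
#' @export
presence_matrix <- function(peaks, genome, pwms, window = 250,
                            min_score = 0.8,
                            score_type = c("fraction", "absolute")) {
  score_type <- match.arg(score_type)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  names(genome) <- sub("\\s.*$", "", names(genome))
  labels <- vapply(pwms, function(p) p$label, character(1))
  maxL <- max(vapply(pwms, function(p) nrow(p$probs), integer(1)))
  ids <- if (all(!is.na(peaks$name)) && !anyDuplicated(peaks$name))
    peaks$name else sprintf("region_%d", seq_len(nrow(peaks)))
  m <- matrix(0L, nrow = nrow(peaks), ncol = length(pwms),
              dimnames = list(ids, labels))
  for (i in seq_len(nrow(peaks))) {
    sq <- peaks$seqid[i]
    if (!sq %in% names(genome)) stop("sequence not in genome: ", sq)
    slen <- Biostrings::width(genome[sq])
    centre <- (peaks$start[i] + peaks$end[i]) %/% 2L
    lo0 <- max(0L, centre - window)
    hi0 <- min(slen, centre + window + maxL)  # room for a hit starting late
    if (hi0 <= lo0) next
    subseq <- as.character(Biostrings::subseq(genome[[sq]], lo0 + 1L, hi0))
    for (j in seq_along(pwms)) {
      hits <- scan_pwm(subseq, pwms[[j]], min_score = min_score,
                       score_type = score_type)
      if (!nrow(hits)) next
      gstart <- lo0 + hits$offset
      if (any(gstart >= centre - window & gstart <= centre + window))
        m[i, j] <- 1L
    }
  }
  m
}

#' Sample control regions from the non-coding, non-peak genome
#'
#' Draws fixed-width regions uniformly over the given sequence lengths,
#' rejecting any draw that overlaps a gene body or a peak. Deterministic
#' under a fixed seed.
#'
#' @param n number of regions.
#' @param width region width in bp.
#' @param chrom_sizes named integer vector of sequence lengths.
#' @param genes gene table to avoid (may be empty).
#' @param peaks peak table to avoid (may be empty).
#' @param seed RNG seed.
#' @param max_tries attempts per region before giving up.
#' @return interval table of `n` control regions.
#' @export
sample_control_regions <- function(n, width, chrom_sizes, genes = NULL,
                                   peaks = NULL, seed = 1L,
                                   max_tries = 1000L) {
  set.seed(seed)
  avoid <- rbind(
    if (!is.null(genes) && nrow(genes))
      genes[, c("seqid", "start", "end")] else NULL,
    if (!is.null(peaks) && nrow(peaks))
      peaks[, c("seqid", "start", "end")] else NULL)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      sq <- sample(names(chrom_sizes), 1L,
                   prob = as.numeric(chrom_sizes) / sum(chrom_sizes))
      s <- sample.int(chrom_sizes[[sq]] - width, 1L) - 1L
      cand <- data.frame(seqid = sq, start = s, end = s + width)
      ok <- is.null(avoid) ||
        nrow(interval_overlaps(cand, avoid)) == 0L
      if (ok) break
      if (try == max_tries) stop("could not place control region ", i)
    }
    out[[i]] <- cand
  }
  out <- do.call(rbind, out)
  gintervals(out$seqid, out$start, out$end,
             name = sprintf("ctrl_%d", seq_len(n)))
}
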