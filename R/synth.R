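#' Default synthetic motif set
#'
#' Eighteen position frequency matrices built from fixed 8-mer consensus
#' sequences (main base probability 0.85), labelled after transcription
#' factor families typical of neural-crest regulatory studies. The set is
#' deterministic: consensus 8-mers are drawn under a fixed internal seed,
#' rejecting duplicates and reverse-complement duplicates so every motif is
#' distinguishable at scan thresholds near the maximum score.
#'
#' @param n number of motifs (default 18).
#' @param p_main probability of the consensus base at each position.
#' @return named list of `"pwm"` objects.
#' @export
default_motifs <- function(n = 18L, p_main = 0.85) {
  labels <- c("Sox10", "Smad2", "Tfap2a", "Pit1", "Bcl6", "Pbx3", "FoxD3",
              "Ets1", "Tead1", "Grhl2", "Pax3", "Msx2", "Zic1", "Snai2",
              "Twist1", "Rest", "Ctcf", "Hoxa2")
  if (n > length(labels))
    labels <- c(labels, sprintf("TF%02d", seq_len(n - length(labels))))
  labels <- labels[seq_len(n)]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(20391L)
  revcomp_chr <- function(s) chartr("ACGT", "TGCA",
                                    paste(rev(strsplit(s, "")[[1L]]),
                                          collapse = ""))
  seen <- character()
  cons <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- paste(sample(BASES, 8L, replace = TRUE), collapse = "")
      if (!s %in% seen && !revcomp_chr(s) %in% seen) break
    }
    seen <- c(seen, s)
    cons[i] <- s
  }
  out <- lapply(seq_len(n), function(i) {
    idx <- match(strsplit(cons[i], "")[[1L]], BASES)
    probs <- matrix((1 - p_main) / 3, nrow = 8L, ncol = 4L)
    probs[cbind(seq_len(8L), idx)] <- p_main
    pwm(probs, label = labels[i])
  })
  names(out) <- labels
  out
}

#' Configuration for the synthetic-data generator
#'
#' The defaults define the study conditions emulated throughout the test
#' suite: a 4 x 2 Mb genome, three developmental stages (T20, T21, T23), a
#' planted dynamically opening ("EMT") peak cluster with late/early fold
#' 2.5 under lognormal multiplicative noise (sigma 0.25), a motif pair
#' co-planted at a higher joint rate in the target cluster than in the
#' control cluster, and a transcript set of true antisense lncRNAs plus
#' decoys that each violate exactly one cascade rule.
#'
#' @param seed master RNG seed; every generator derives its stream from it.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes number of coding genes (non-overlapping per strand; a
#'   subset of minus-strand genes is placed antisense-overlapping a
#'   plus-strand gene).
#' @param frac_enriched fraction of genes flagged enriched at the middle
#'   stage in the DE table (padj below 0.05, log2fc > 1).
#' @param n_peaks_per_category named counts for `promoter`, `intronic`,
#'   `intergenic` peaks.
#' @param stages ordered stage labels (first = early, last = late).
#' @param n_clusters planted profile-shape clusters per run.
#' @param emt_cluster id of the planted EMT cluster (0 = none).
#' @param emt_fold expected late/early signal ratio for the EMT cluster
#'   (> 1 for a detectable planting; 1 = null).
#' @param noise `"lognormal"` (multiplicative, `sigma`) or `"nbinom"`
#'   (counts, `nb_dispersion`).
#' @param sigma lognormal noise sd on the log scale (default 0.25).
#' @param nb_dispersion negative-binomial dispersion (default 0.3).
#' @param motif_set named list of `"pwm"`s (default [default_motifs()]).
#' @param coocc_pair labels of the co-planted motif pair (default: first
#'   two motifs).
#' @param coocc_target_cluster,coocc_control_cluster cluster ids whose
#'   peaks receive target / control joint-planting rates.
#' @param p_joint_target,p_joint_control joint planting probabilities.
#' @param p_single marginal singleton planting probability per motif.
#' @param n_true_lncrnas,n_decoys_per_rule transcript planting counts.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, n_chromosomes = 4L, chrom_length = 2e6,
                         n_genes = 120L, frac_enriched = 0.4,
                         n_peaks_per_category = c(promoter = 40L,
                                                  intronic = 40L,
                                                  intergenic = 40L),
                         stages = c("T20", "T21", "T23"),
                         n_clusters = 3L, emt_cluster = 1L, emt_fold = 2.5,
                         noise = c("lognormal", "nbinom"), sigma = 0.25,
                         nb_dispersion = 0.3, motif_set = default_motifs(),
                         coocc_pair = NULL, coocc_target_cluster = 1L,
                         coocc_control_cluster = 2L, p_joint_target = 0.4,
                         p_joint_control = 0.05, p_single = 0.15,
                         n_true_lncrnas = 5L, n_decoys_per_rule = 2L) {
  noise <- match.arg(noise)
  if (is.null(coocc_pair)) coocc_pair <- names(motif_set)[1:2]
  stopifnot(n_chromosomes >= 1L, chrom_length > 1e4, length(stages) >= 2L,
            n_clusters >= 1L, emt_fold > 0,
            p_joint_target >= 0, p_joint_target <= 1,
            p_joint_control >= 0, p_joint_control <= 1,
            p_single >= 0, p_single <= 1,
            all(coocc_pair %in% names(motif_set)))
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 frac_enriched = frac_enriched,
                 n_peaks_per_category = n_peaks_per_category,
                 stages = stages, n_clusters = as.integer(n_clusters),
                 emt_cluster = as.integer(emt_cluster),
                 emt_fold = emt_fold, noise = noise, sigma = sigma,
                 nb_dispersion = nb_dispersion, motif_set = motif_set,
                 coocc_pair = coocc_pair,
                 coocc_target_cluster = as.integer(coocc_target_cluster),
                 coocc_control_cluster = as.integer(coocc_control_cluster),
                 p_joint_target = p_joint_target,
                 p_joint_control = p_joint_control, p_single = p_single,
                 n_true_lncrnas = as.integer(n_true_lncrnas),
                 n_decoys_per_rule = as.integer(n_decoys_per_rule)),
            class = "synth_config")
}

#' @keywords internal
chrom_names <- function(cfg) sprintf("chr%d", seq_len(cfg$n_chromosomes))

#' Generate a synthetic gene annotation and DE table
#'
#' Genes are packed sequentially per chromosome with random lengths
#' (2--8 kb) and gaps (3--20 kb); every sixth minus-strand gene is
#' relocated to overlap the preceding plus-strand gene, providing
#' antisense gene pairs. Each gene carries one transcript with 2--3 exons.
#' Exactly `round(frac_enriched * n_genes)` genes are flagged enriched at
#' the middle stage (padj drawn below 0.05, log2fc > 1); the remainder are
#' null. Deterministic under `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list of class `"synth_annotation"`: `genes`, `transcripts`
#'   (a `"transcript_set"`), `de`.
#' @export
generate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- chrom_names(cfg)
  if (cfg$n_genes == 0L) {
    genes <- data.frame(gene_id = character(), seqid = character(),
                        start = integer(), end = integer(),
                        strand = character(), tss = integer(),
                        biotype = character(), stringsAsFactors = FALSE)
    de <- data.frame(gene_id = character(), log2fc = numeric(),
                     padj = numeric(), base_mean = numeric())
    return(structure(list(genes = genes,
                          transcripts = transcript_set(
                            data.frame(transcript_id = character(),
                                       gene_id = character(),
                                       seqid = character(),
                                       strand = character(),
                                       start = integer(), end = integer())),
                          de = de), class = "synth_annotation"))
  }
  per_chrom <- table(factor(rep_len(chroms, cfg$n_genes), levels = chroms))
  rows <- list()
  gi <- 0L
  for (ch in chroms) {
    cursor <- 10000L
    prev_plus <- NULL
    for (i in seq_len(per_chrom[[ch]])) {
      gi <- gi + 1L
      len <- as.integer(round(stats::runif(1L, 2000, 8000)))
      strand <- sample(c("+", "-"), 1L, prob = c(0.6, 0.4))
      # every sixth slot hosts an antisense gene overlapping the previous
      # plus-strand gene, guaranteeing antisense gene pairs
      relocate <- i %% 6L == 0L && !is.null(prev_plus)
      if (relocate) strand <- "-"
      if (relocate) {
        plen <- prev_plus$end - prev_plus$start
        len <- min(len, plen)
        start <- prev_plus$start + plen %/% 3L
      } else {
        start <- cursor
        cursor <- cursor + len +
          as.integer(round(stats::runif(1L, 3000, 20000)))
        if (cursor > cfg$chrom_length - 10000L)
          stop("infeasible gene packing: too many genes for chrom_length")
      }
      g <- data.frame(gene_id = sprintf("gene%04d", gi), seqid = ch,
                      start = start, end = start + len, strand = strand,
                      biotype = "coding", stringsAsFactors = FALSE)
      if (strand == "+" && !relocate) prev_plus <- g
      rows[[gi]] <- g
    }
  }
  genes <- do.call(rbind, rows)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  genes <- genes[, c("gene_id", "seqid", "start", "end", "strand", "tss",
                     "biotype")]
  # one transcript per gene, 2-3 exons spanning the gene body
  ex <- list()
  for (i in seq_len(nrow(genes))) {
    len <- genes$end[i] - genes$start[i]
    n_ex <- if (len < 3000L) 2L else sample(2:3, 1L)
    elen <- as.integer(round(stats::runif(n_ex, 200, 400)))
    ilen <- (len - sum(elen)) %/% (n_ex - 1L)
    starts <- genes$start[i] +
      cumsum(c(0L, utils::head(elen, -1L) + ilen))
    starts[n_ex] <- genes$end[i] - elen[n_ex]  # last exon ends the gene
    ex[[i]] <- data.frame(
      transcript_id = paste0(genes$gene_id[i], ".t1"),
      gene_id = genes$gene_id[i], seqid = genes$seqid[i],
      strand = genes$strand[i], start = as.integer(starts),
      end = as.integer(starts + elen), stringsAsFactors = FALSE)
  }
  transcripts <- transcript_set(do.call(rbind, ex))
  n_enr <- round(cfg$frac_enriched * nrow(genes))
  enr <- sample(genes$gene_id, n_enr)
  is_enr <- genes$gene_id %in% enr
  de <- data.frame(
    gene_id = genes$gene_id,
    log2fc = ifelse(is_enr, stats::runif(nrow(genes), 1, 4),
                    stats::rnorm(nrow(genes), 0, 0.5)),
    padj = ifelse(is_enr, 10^stats::runif(nrow(genes), -8, -2.5),
                  stats::runif(nrow(genes), 0.1, 1)),
    base_mean = stats::rlnorm(nrow(genes), log(100), 1),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, transcripts = transcripts, de = de),
            class = "synth_annotation")
}

#' @export
print.synth_annotation <- function(x, ...) {
  cat("synth_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts$transcripts), "transcripts,",
      sum(x$de$padj < 0.05 & x$de$log2fc > 0), "enriched in DE table\n")
  invisible(x)
}

#' @keywords internal
cluster_template <- function(cluster, nbins) {
  # deterministic multi-bump shape per cluster id; bump positions differ
  # between clusters so shapes stay separable under per-peak depth noise
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(7000L + as.integer(cluster))
  k <- sample(2:3, 1L)
  mu <- sort(stats::runif(k, 0.15, 0.85)) * nbins
  w <- stats::runif(k, 0.02, 0.08) * nbins
  h <- stats::runif(k, 25, 80)
  b <- seq_len(nbins)
  bumps <- vapply(seq_len(k), function(j)
    h[j] * exp(-(b - mu[j])^2 / (2 * w[j]^2)), numeric(nbins))
  2 + rowSums(bumps)
}

#' Generate synthetic peaks with planted categories, clusters and signal
#'
#' Peaks are placed to realise the configured category quotas (promoter
#' peaks inside the 2 kb strand-aware upstream window of a gene TSS,
#' intronic peaks inside introns clear of exons and promoter windows,
#' intergenic peaks clear of genes and promoter windows), with centres at
#' least `2 * flank + 100` bp apart so profile windows never overlap.
#' Each peak is assigned a planted cluster; cluster `cfg$emt_cluster` has
#' expected late-stage signal `emt_fold` times its early-stage signal.
#' Per-bin signal is a cluster template times stage multiplier under the
#' configured noise model.
#'
#' @param cfg a [synth_config()].
#' @param ann a `"synth_annotation"`.
#' @param flank,bin profile geometry (defaults match
#'   [clustering_config()]).
#' @return list of class `"synth_peaks"`: `peaks` (interval table with
#'   `category` and `cluster` truth columns), `profiles` (peaks x bins x
#'   stages array, the planted signal), `counts` (peaks x stages totals),
#'   `truth` (data.frame of planted labels).
#' @export
generate_peaks_and_signal <- function(cfg, ann, flank = 1500L, bin = 15L) {
  set.seed(cfg$seed + 1L)
  genes <- ann$genes
  quotas <- cfg$n_peaks_per_category
  nbins <- 2L * flank %/% bin
  min_sep <- 2L * flank + 100L
  placed <- data.frame(seqid = character(), centre = integer())
  sep_ok <- function(sq, centre) {
    prev <- placed$centre[placed$seqid == sq]
    !length(prev) || min(abs(prev - centre)) >= min_sep
  }
  pw <- promoter_windows(genes, 2000L)
  out <- list()
  pid <- 0L
  add_peak <- function(sq, s, e, category) {
    pid <<- pid + 1L
    placed[nrow(placed) + 1L, ] <<- list(sq, (s + e) %/% 2L)
    out[[pid]] <<- data.frame(seqid = sq, start = s, end = e,
                              name = sprintf("peak_%04d", pid),
                              category = category, stringsAsFactors = FALSE)
  }
  # promoter peaks: anchored in the upstream window of distinct genes
  if (!is.na(quotas["promoter"]) && quotas[["promoter"]] > 0L) {
    if (nrow(genes) == 0L) stop("promoter quota needs genes")
    cand_genes <- sample(genes$gene_id)
    n_done <- 0L
    for (gid in cand_genes) {
      if (n_done == quotas[["promoter"]]) break
      g <- genes[genes$gene_id == gid, ]
      for (try in 1:20) {
        u <- round(stats::runif(1L, 300, 1700))
        w <- round(stats::runif(1L, 200, 400))
        centre <- if (g$strand == "-") g$tss + u else g$tss - u
        s <- as.integer(centre - w %/% 2L); e <- as.integer(s + w)
        if (s < flank + 10L || e > cfg$chrom_length - flank - 10L) next
        if (!sep_ok(g$seqid, (s + e) %/% 2L)) next
        add_peak(g$seqid, s, e, "promoter")
        n_done <- n_done + 1L
        break
      }
    }
    if (n_done < quotas[["promoter"]])
      stop("promoter peak quota unsatisfiable with this annotation")
  }
  # intronic peaks: inside an intron, clear of exons and promoter windows
  if (!is.na(quotas["intronic"]) && quotas[["intronic"]] > 0L) {
    exons <- ann$transcripts$exons
    used <- vapply(out, function(d) d$category[1L] == "promoter",
                   logical(1))
    anchor_used <- character()
    cand_genes <- sample(genes$gene_id)
    n_done <- 0L
    for (gid in cand_genes) {
      if (n_done == quotas[["intronic"]]) break
      e <- exons[exons$gene_id == gid, , drop = FALSE]
      if (nrow(e) < 2L) next
      g <- genes[genes$gene_id == gid, ]
      introns <- data.frame(start = e$end[-nrow(e)], end = e$start[-1L])
      introns <- introns[introns$end - introns$start >= 700L, ,
                         drop = FALSE]
      if (!nrow(introns)) next
      ok <- FALSE
      for (try in 1:20) {
        it <- introns[sample.int(nrow(introns), 1L), ]
        w <- round(stats::runif(1L, 200, 400))
        lo <- it$start + 50L
        hi <- it$end - 50L - w
        if (hi <= lo) next
        s <- as.integer(round(stats::runif(1L, lo, hi)))
        e2 <- as.integer(s + w)
        cand <- gintervals(g$seqid, s, e2)
        if (!sep_ok(g$seqid, (s + e2) %/% 2L)) next
        if (nrow(interval_overlaps(cand, exons))) next
        if (nrow(pw) && nrow(interval_overlaps(cand, pw))) next
        add_peak(g$seqid, s, e2, "intronic")
        n_done <- n_done + 1L
        ok <- TRUE
        break
      }
    }
    if (n_done < quotas[["intronic"]])
      stop("intronic peak quota unsatisfiable with this annotation")
  }
  # intergenic peaks: clear of gene bodies and promoter windows
  if (!is.na(quotas["intergenic"]) && quotas[["intergenic"]] > 0L) {
    n_done <- 0L
    tries <- 0L
    max_tries <- 400L * quotas[["intergenic"]]
    while (n_done < quotas[["intergenic"]]) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("intergenic peak quota unsatisfiable")
      sq <- sample(chrom_names(cfg), 1L)
      w <- round(stats::runif(1L, 200, 400))
      s <- as.integer(round(stats::runif(1L, flank + 10L,
                                         cfg$chrom_length - flank - 10L - w)))
      e <- as.integer(s + w)
      cand <- gintervals(sq, s, e)
      if (!sep_ok(sq, (s + e) %/% 2L)) next
      if (nrow(genes) &&
          nrow(interval_overlaps(cand, genes, maxgap = 500L))) next
      if (nrow(pw) && nrow(interval_overlaps(cand, pw, maxgap = 100L)))
        next
      add_peak(sq, s, e, "intergenic")
      n_done <- n_done + 1L
    }
  }
  peaks <- do.call(rbind, out)
  peaks <- gintervals(peaks$seqid, peaks$start, peaks$end,
                      name = peaks$name)
  peaks$category <- unlist(lapply(out, `[[`, "category"))
  # planted cluster labels, balanced within each category
  peaks$cluster <- NA_integer_
  for (cat in unique(peaks$category)) {
    idx <- which(peaks$category == cat)
    peaks$cluster[idx] <- sample(rep_len(seq_len(cfg$n_clusters),
                                         length(idx)))
  }
  # planted signal: template(cluster) x stage multiplier x noise
  stages <- cfg$stages
  mult <- matrix(1, nrow = cfg$n_clusters, ncol = length(stages))
  if (cfg$emt_cluster >= 1L && cfg$emt_cluster <= cfg$n_clusters)
    mult[cfg$emt_cluster, -1L] <- cfg$emt_fold
  arr <- array(0, dim = c(nrow(peaks), nbins, length(stages)),
               dimnames = list(peaks$name, NULL, stages))
  amp <- exp(stats::rnorm(nrow(peaks), 0, cfg$sigma))  # per-peak depth
  templates <- lapply(seq_len(cfg$n_clusters), cluster_template,
                      nbins = nbins)
  for (p in seq_len(nrow(peaks))) {
    tpl <- templates[[peaks$cluster[p]]] * amp[p]
    for (s in seq_along(stages)) {
      mu <- tpl * mult[peaks$cluster[p], s]
      arr[p, , s] <- if (cfg$noise == "lognormal")
        mu * exp(stats::rnorm(nbins, 0, cfg$sigma))
      else stats::rnbinom(nbins, mu = mu, size = 1 / cfg$nb_dispersion)
    }
  }
  counts <- apply(arr, c(1L, 3L), sum)
  truth <- data.frame(name = peaks$name, category = peaks$category,
                      cluster = peaks$cluster,
                      emt = peaks$cluster == cfg$emt_cluster &
                        cfg$emt_fold > 1,
                      stringsAsFactors = FALSE)
  structure(list(peaks = peaks, profiles = arr, counts = counts,
                 truth = truth, flank = flank, bin = bin),
            class = "synth_peaks")
}

#' @export
print.synth_peaks <- function(x, ...) {
  cat("synth_peaks:", nrow(x$peaks), "peaks;",
      paste(names(table(x$peaks$category)),
            table(x$peaks$category), collapse = ", "),
      "\n")
  invisible(x)
}

#' Render planted profiles as per-stage bedGraph tables
#'
#' Emits one interval per profile bin with a per-base rate so that
#' integrating the track over a bin returns the planted bin value exactly.
#' Windows never overlap by construction (peak centres are separated by
#' more than the window width).
#'
#' @param sp a `"synth_peaks"`.
#' @return named list of bedGraph data.frames, one per stage.
#' @export
render_bedgraph <- function(sp) {
  stages <- dimnames(sp$profiles)[[3L]]
  nbins <- dim(sp$profiles)[2L]
  centre <- (sp$peaks$start + sp$peaks$end) %/% 2L
  win_start <- centre - sp$flank
  out <- list()
  for (s in stages) {
    starts <- rep(win_start, each = nbins) +
      sp$bin * rep(seq_len(nbins) - 1L, nrow(sp$peaks))
    df <- data.frame(
      seqid = rep(sp$peaks$seqid, each = nbins),
      start = starts, end = starts + sp$bin,
      value = as.vector(t(sp$profiles[, , s])) / sp$bin,
      stringsAsFactors = FALSE)
    df <- df[df$value > 0, , drop = FALSE]
    df <- df[order(df$seqid, df$start), , drop = FALSE]
    rownames(df) <- NULL
    out[[s]] <- df
  }
  out
}

#' Per-stage peak calls derived from the planted consensus peaks
#'
#' Each planted peak appears in each stage with probability `keep_prob`
#' (always in at least one stage), with endpoints jittered by up to
#' `jitter` bp, emulating independent per-stage peak calling ahead of
#' consensus merging.
#'
#' @param sp a `"synth_peaks"`.
#' @param cfg a [synth_config()].
#' @param keep_prob per-stage retention probability.
#' @param jitter maximum endpoint jitter in bp.
#' @return named list of interval tables, one per stage.
#' @export
generate_stage_beds <- function(sp, cfg, keep_prob = 0.9, jitter = 30L) {
  set.seed(cfg$seed + 4L)
  stages <- cfg$stages
  n <- nrow(sp$peaks)
  keep <- matrix(stats::runif(n * length(stages)) < keep_prob, nrow = n)
  none <- which(rowSums(keep) == 0L)
  keep[cbind(none, sample.int(length(stages), length(none),
                              replace = TRUE))] <- TRUE
  out <- list()
  for (si in seq_along(stages)) {
    idx <- which(keep[, si])
    j1 <- sample(-jitter:jitter, length(idx), replace = TRUE)
    j2 <- sample(-jitter:jitter, length(idx), replace = TRUE)
    out[[stages[si]]] <- gintervals(
      sp$peaks$seqid[idx],
      pmax(sp$peaks$start[idx] + j1, 0L),
      sp$peaks$end[idx] + j2,
      name = sp$peaks$name[idx])
  }
  out
}

#' Generate genome sequence with planted motif (co-)occurrences
#'
#' Background sequence is i.i.d. uniform over A/C/G/T. For peaks in the
#' target cluster the configured motif pair is co-planted (both consensus
#' sequences inserted at non-overlapping offsets within +/- 250 bp of the
#' peak centre, each on a random strand) with probability
#' `p_joint_target`; in the control cluster with `p_joint_control`.
#' Independently, every motif is singleton-planted with probability
#' `p_single` per peak. Every insertion is recorded in the placement
#' table.
#'
#' @param cfg a [synth_config()].
#' @param peaks peak table with `name` and `cluster` columns (e.g.
#'   `synth_peaks$peaks`).
#' @param window planting half-window around the peak centre (default 250).
#' @return list of class `"synth_sequences"`: `genome` (a
#'   [Biostrings::DNAStringSet]), `placements` (data.frame: peak, motif,
#'   start (0-based genomic), strand, joint flag).
#' @export
generate_sequences_with_motifs <- function(cfg, peaks, window = 250L) {
  set.seed(cfg$seed + 2L)
  maxL <- max(vapply(cfg$motif_set, function(p) nrow(p$probs), integer(1)))
  if (2L * window < 2L * maxL)
    stop("motif longer than the planting window")
  chroms <- chrom_names(cfg)
  seqs <- lapply(chroms, function(ch)
    sample(BASES, cfg$chrom_length, replace = TRUE))
  names(seqs) <- chroms
  placements <- list()
  revcomp_chr <- function(s) chartr("ACGT", "TGCA",
                                    paste(rev(strsplit(s, "")[[1L]]),
                                          collapse = ""))
  plant <- function(sq, pos0, motif, strand) {
    cons <- pwm_consensus(cfg$motif_set[[motif]])
    if (strand == "-") cons <- revcomp_chr(cons)
    L <- nchar(cons)
    seqs[[sq]][(pos0 + 1L):(pos0 + L)] <<- strsplit(cons, "")[[1L]]
  }
  for (i in seq_len(nrow(peaks))) {
    sq <- peaks$seqid[i]
    centre <- (peaks$start[i] + peaks$end[i]) %/% 2L
    lo <- max(0L, centre - window)
    hi <- min(cfg$chrom_length - maxL, centre + window - maxL)
    if (hi <= lo) next
    used <- integer()
    draw_offset <- function(L) {
      for (try in 1:50) {
        o <- as.integer(round(stats::runif(1L, lo, hi)))
        if (!length(used) || min(abs(used - o)) >= maxL) return(o)
      }
      NA_integer_
    }
    insertions <- list()
    cl <- peaks$cluster[i]
    p_joint <- if (!is.na(cl) && cl == cfg$coocc_target_cluster)
      cfg$p_joint_target
    else if (!is.na(cl) && cl == cfg$coocc_control_cluster)
      cfg$p_joint_control
    else 0
    if (stats::runif(1L) < p_joint) {
      for (mo in cfg$coocc_pair)
        insertions[[length(insertions) + 1L]] <-
          list(motif = mo, joint = TRUE)
    }
    for (mo in names(cfg$motif_set)) {
      if (stats::runif(1L) < cfg$p_single)
        insertions[[length(insertions) + 1L]] <-
          list(motif = mo, joint = FALSE)
    }
    for (ins in insertions) {
      L <- nrow(cfg$motif_set[[ins$motif]]$probs)
      o <- draw_offset(L)
      if (is.na(o)) next
      used <- c(used, o)
      st <- sample(c("+", "-"), 1L)
      plant(sq, o, ins$motif, st)
      placements[[length(placements) + 1L]] <- data.frame(
        peak = peaks$name[i], motif = ins$motif, start = o, strand = st,
        joint = ins$joint, stringsAsFactors = FALSE)
    }
  }
  genome <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- chroms
  placements <- if (length(placements)) do.call(rbind, placements)
    else data.frame(peak = character(), motif = character(),
                    start = integer(), strand = character(),
                    joint = logical())
  structure(list(genome = genome, placements = placements),
            class = "synth_sequences")
}

#' @export
print.synth_sequences <- function(x, ...) {
  cat("synth_sequences:", length(x$genome), "sequence(s),",
      nrow(x$placements), "planted motif instance(s)\n")
  invisible(x)
}

#' Simulate binary motif presence matrices for a planted pair
#'
#' Direct presence-level counterpart of the sequence planting model, for
#' large calibration and power studies: every motif is present
#' independently with probability `p_single`; additionally a joint event
#' with probability `p_joint_target` (target rows) or `p_joint_control`
#' (control rows) switches both motifs of `coocc_pair` on.
#'
#' When the two joint rates differ, the singleton rate of the pair motifs
#' in the lower-joint group is raised so that each pair motif's *marginal*
#' occurrence rate is equal in both groups (clamped to \[0, 1\]). The
#' planted signal is then purely the excess joint occurrence, so pairs
#' sharing just one planted motif stay null -- the property the power and
#' specificity analyses rely on.
#'
#' @param cfg a [synth_config()].
#' @param n_target,n_control region counts.
#' @return list with binary matrices `target`, `control` and the planted
#'   `pair` labels.
#' @export
generate_presence <- function(cfg, n_target = 500L, n_control = 500L) {
  set.seed(cfg$seed + 5L)
  labels <- names(cfg$motif_set)
  # marginal rate of a pair motif under joint rate pj and singleton rate ps
  marginal <- function(pj, ps) pj + (1 - pj) * ps
  # singleton rate needed to reach marginal m under joint rate pj
  needed <- function(m, pj) if (pj >= 1) 0 else
    min(1, max(0, (m - pj) / (1 - pj)))
  m_top <- marginal(max(cfg$p_joint_target, cfg$p_joint_control),
                    cfg$p_single)
  ps_pair_t <- needed(m_top, cfg$p_joint_target)
  ps_pair_c <- needed(m_top, cfg$p_joint_control)
  sim <- function(n, p_joint, ps_pair) {
    ps <- rep(cfg$p_single, length(labels))
    ps[match(cfg$coocc_pair, labels)] <- ps_pair
    m <- matrix(as.integer(stats::runif(n * length(labels)) <
                             rep(ps, each = n)),
                nrow = n, dimnames = list(NULL, labels))
    joint <- stats::runif(n) < p_joint
    m[joint, cfg$coocc_pair] <- 1L
    m
  }
  list(target = sim(n_target, cfg$p_joint_target, ps_pair_t),
       control = sim(n_control, cfg$p_joint_control, ps_pair_c),
       pair = cfg$coocc_pair)
}

#' Generate transcripts with planted true lncRNAs and per-rule decoys
#'
#' Emits `n_true_lncrnas` transcripts satisfying every cascade rule
#' (spliced, >= 200 bp, no same-strand coding overlap, no qualifying
#' protein hit, antisense to the nearest coding gene within 5 kb) and
#' `n_decoys_per_rule` transcripts per rule violating exactly that rule:
#' `coding_overlap` decoys overlap a coding gene on their own strand while
#' their nearest gene (tie at distance 0, broken by gene id) is antisense;
#' `protein_similarity` decoys receive a strong protein hit;
#' `unspliced` decoys are single-exon; `antisense_proximal` decoys are
#' either too far from any gene or sense to their nearest gene; `length`
#' decoys are spliced but 180 bp. A protein hit below the identity cutoff
#' is attached to one true lncRNA as a negative control.
#'
#' @param cfg a [synth_config()].
#' @param ann a `"synth_annotation"`.
#' @return list of class `"synth_transcripts"`: `transcripts` (a
#'   `"transcript_set"`), `hits`, `truth` (transcript_id, class,
#'   violated_rule).
#' @export
generate_transcripts_for_lncrna <- function(cfg, ann) {
  set.seed(cfg$seed + 3L)
  genes <- ann$genes
  if (!nrow(genes) && (cfg$n_true_lncrnas > 0L ||
                       cfg$n_decoys_per_rule > 0L))
    stop("lncRNA planting needs coding genes")
  flip <- function(s) ifelse(s == "+", "-", "+")
  # upstream clearance (genomic-left of gene start) per gene
  clearance <- function(g, c) {
    win <- gintervals(g$seqid, max(0L, g$start - c), g$start)
    others <- genes[genes$gene_id != g$gene_id, , drop = FALSE]
    g$start >= c + 400L &&
      nrow(interval_overlaps(win, others, maxgap = 0L)) == 0L
  }
  qualified <- function(c) {
    ok <- vapply(seq_len(nrow(genes)), function(i)
      clearance(genes[i, ], c), logical(1))
    genes$gene_id[ok]
  }
  pool_small <- sample(qualified(4500L))
  pool_big <- sample(qualified(13000L))
  exons <- list()
  truth <- list()
  hits <- list()
  tid <- 0L
  take_anchor <- function(big = FALSE) {
    pool <- if (big) intersect(pool_big, pool_small) else pool_small
    if (!length(pool)) stop("not enough isolated genes for lncRNA planting")
    gid <- pool[1L]
    pool_small <<- setdiff(pool_small, gid)
    pool_big <<- setdiff(pool_big, gid)
    genes[genes$gene_id == gid, ]
  }
  emit <- function(prefix, class, rule, exdf) {
    tid <<- tid + 1L
    id <- sprintf("%s%03d", prefix, tid)
    exdf$transcript_id <- id
    exons[[tid]] <<- exdf
    truth[[tid]] <<- data.frame(transcript_id = id, class = class,
                                violated_rule = rule,
                                stringsAsFactors = FALSE)
    id
  }
  std_exons <- function(g, strand, dist, elens, gap = 50L) {
    # exons end `dist` bp genomic-left of the gene start
    tot <- sum(elens) + gap * (length(elens) - 1L)
    e_end <- g$start - dist
    starts <- e_end - tot + cumsum(c(0L, utils::head(elens, -1L) + gap))
    data.frame(transcript_id = NA_character_, gene_id = NA_character_,
               seqid = g$seqid, strand = strand,
               start = as.integer(starts),
               end = as.integer(starts + elens),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_true_lncrnas)) {
    g <- take_anchor()
    id <- emit("lnc", "true_lncrna", NA_character_,
               std_exons(g, flip(g$strand), 1000L, c(150L, 150L)))
    if (i == 1L)  # weak hit: identity below the cutoff, must not remove
      hits[[length(hits) + 1L]] <- data.frame(
        transcript_id = id, percent_identity = 20, evalue = 1e-30)
  }
  for (i in seq_len(cfg$n_decoys_per_rule)) {
    # rule 1: same-strand coding overlap (nearest gene still antisense)
    pair <- find_antisense_pair(genes, used = unlist(
      lapply(truth, function(t) t$transcript_id)))
    y <- pair$y; x <- pair$x  # id(y) < id(x), opposite strands
    ov_lo <- max(x$start, y$start); ov_hi <- min(x$end, y$end)
    mid <- (ov_lo + ov_hi) %/% 2L + (i - 1L) * 40L  # offset repeat decoys
    e1 <- data.frame(transcript_id = NA_character_,
                     gene_id = NA_character_, seqid = x$seqid,
                     strand = x$strand,
                     start = as.integer(c(mid - 175L, mid + 25L)),
                     end = as.integer(c(mid - 25L, mid + 175L)),
                     stringsAsFactors = FALSE)
    emit("dec_overlap", "decoy", "coding_overlap", e1)
    # rule 2: strong protein hit
    g <- take_anchor()
    id <- emit("dec_protein", "decoy", "protein_similarity",
               std_exons(g, flip(g$strand), 1000L, c(150L, 150L)))
    hits[[length(hits) + 1L]] <- data.frame(
      transcript_id = id, percent_identity = 85, evalue = 1e-40)
    # rule 3: unspliced
    g <- take_anchor()
    emit("dec_unspliced", "decoy", "unspliced",
         std_exons(g, flip(g$strand), 1000L, 300L))
    # rule 4: far from any gene (odd i) or sense to the nearest (even i)
    if (i %% 2L == 1L) {
      g <- take_anchor(big = TRUE)
      emit("dec_antisense", "decoy", "antisense_proximal",
           std_exons(g, flip(g$strand), 7000L, c(150L, 150L)))
    } else {
      g <- take_anchor()
      emit("dec_antisense", "decoy", "antisense_proximal",
           std_exons(g, g$strand, 1000L, c(150L, 150L)))
    }
    # rule 5: short (180 bp spliced)
    g <- take_anchor()
    emit("dec_short", "decoy", "length",
         std_exons(g, flip(g$strand), 1000L, c(90L, 90L)))
  }
  exdf <- if (length(exons)) do.call(rbind, exons)
    else data.frame(transcript_id = character(), gene_id = character(),
                    seqid = character(), strand = character(),
                    start = integer(), end = integer())
  hitdf <- if (length(hits)) do.call(rbind, hits)
    else data.frame(transcript_id = character(),
                    percent_identity = numeric(), evalue = numeric())
  truthdf <- if (length(truth)) do.call(rbind, truth)
    else data.frame(transcript_id = character(), class = character(),
                    violated_rule = character())
  structure(list(transcripts = transcript_set(exdf), hits = hitdf,
                 truth = truthdf),
            class = "synth_transcripts")
}

#' @keywords internal
find_antisense_pair <- function(genes, used = character()) {
  # overlapping opposite-strand gene pair with >= 500 bp shared body;
  # returned so that y (the lexicographically smaller id) is the
  # tie-break winner at distance 0
  for (i in seq_len(nrow(genes))) {
    gi <- genes[i, ]
    cand <- genes[genes$seqid == gi$seqid & genes$strand != gi$strand &
                    genes$start < gi$end - 500L &
                    genes$end > gi$start + 500L, , drop = FALSE]
    if (!nrow(cand)) next
    gj <- cand[1L, ]
    ids <- c(gi$gene_id, gj$gene_id)
    y <- if (gi$gene_id < gj$gene_id) gi else gj
    x <- if (gi$gene_id < gj$gene_id) gj else gi
    # no third gene may tie at distance 0 with a smaller id than y:
    ov_lo <- max(x$start, y$start); ov_hi <- min(x$end, y$end)
    win <- gintervals(x$seqid, ov_lo, ov_hi)
    touching <- interval_overlaps(win, genes, maxgap = 0L)$subject
    if (any(genes$gene_id[touching] < y$gene_id)) next
    return(list(x = x, y = y))
  }
  stop("no antisense-overlapping gene pair available")
}

#' @export
print.synth_transcripts <- function(x, ...) {
  cat("synth_transcripts:", sum(x$truth$class == "true_lncrna"), "true,",
      sum(x$truth$class == "decoy"), "decoy transcript(s)\n")
  invisible(x)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator under `cfg` and writes the full file set:
#' annotation (GFF3 + GTF), DE table, per-stage peak BEDs, per-category
#' truth, counts table, per-stage bedGraph tracks, genome FASTA, motif
#' PFMs, placement table, lncRNA transcripts (GTF), protein hits and truth
#' tables, plus a YAML echo of the scalar configuration. Identical
#' configurations (including the seed) produce byte-identical files.
#'
#' @param cfg a [synth_config()].
#' @param outdir output directory (created if needed).
#' @param sequences also generate the genome FASTA with planted motifs
#'   (slowest step; default TRUE).
#' @return invisibly, a named list of written file paths.
#' @export
generate_dataset <- function(cfg, outdir, sequences = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  files <- list()
  ann <- generate_annotation(cfg)
  write_gff3_genes(ann$genes, files$genes <- pth("genes.gff3"))
  write_gtf_transcripts(ann$transcripts,
                        files$gene_models <- pth("gene_models.gtf"))
  utils::write.table(ann$de, files$de <- pth("de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp <- generate_peaks_and_signal(cfg, ann)
  pk <- sp$peaks
  write_bed(pk, files$peaks <- pth("peaks_consensus.bed"))
  utils::write.table(sp$truth, files$peak_truth <- pth("peak_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cts <- data.frame(peak = rownames(sp$counts), sp$counts,
                    check.names = FALSE)
  utils::write.table(cts, files$counts <- pth("counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage_beds <- generate_stage_beds(sp, cfg)
  for (st in names(stage_beds))
    write_bed(stage_beds[[st]],
              files[[paste0("peaks_", st)]] <- pth(paste0(st, ".bed")))
  bgs <- render_bedgraph(sp)
  for (st in names(bgs)) {
    f <- files[[paste0("signal_", st)]] <- pth(paste0(st, ".bedgraph"))
    writeLines(sprintf("%s\t%d\t%d\t%s", bgs[[st]]$seqid, bgs[[st]]$start,
                       bgs[[st]]$end,
                       format(bgs[[st]]$value, trim = TRUE,
                              scientific = FALSE, digits = 10)), f)
  }
  if (sequences) {
    sm <- generate_sequences_with_motifs(cfg, pk)
    Biostrings::writeXStringSet(sm$genome,
                                files$genome <- pth("genome.fa"))
    utils::write.table(sm$placements,
                       files$placements <- pth("motif_placements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_jaspar(cfg$motif_set, files$motifs <- pth("motifs.pfm"))
  tx <- generate_transcripts_for_lncrna(cfg, ann)
  write_gtf_transcripts(tx$transcripts,
                        files$transcripts <- pth("transcripts.gtf"))
  h <- tx$hits
  writeLines(sprintf("%s\tsprot\t%g\t100\t0\t0\t1\t100\t1\t100\t%g\t200",
                     h$transcript_id, h$percent_identity, h$evalue),
             files$hits <- pth("hits.tsv"))
  utils::write.table(tx$truth, files$tx_truth <- pth("transcript_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  scalars <- cfg[!vapply(cfg, is.list, logical(1))]
  scalars$motif_labels <- names(cfg$motif_set)
  yaml::write_yaml(scalars, files$config <- pth("config.yaml"))
  invisible(files)
}
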