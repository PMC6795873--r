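# Shared fixtures and independent oracles used across test files.

# a compact synthetic-data configuration used where full scale is not needed
small_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chromosomes = 2L, chrom_length = 5e5,
               n_genes = 20L,
               n_peaks_per_category = c(promoter = 6L, intronic = 6L,
                                        intergenic = 8L))
  args <- utils::modifyList(args, list(...))
  do.call(synth_config, args)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# sweep-line interval-union oracle (independent of IRanges)
sweep_merge <- function(df) {
  out <- list()
  for (sq in sort(unique(df$seqid))) {
    d <- df[df$seqid == sq, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cur_s <- d$start[1L]; cur_e <- d$end[1L]
    for (i in seq_len(nrow(d))[-1L]) {
      if (d$start[i] <= cur_e) {        # overlap or abut
        cur_e <- max(cur_e, d$end[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(seqid = sq, start = cur_s,
                                              end = cur_e)
        cur_s <- d$start[i]; cur_e <- d$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(seqid = sq, start = cur_s,
                                          end = cur_e)
  }
  do.call(rbind, out)
}

# naive per-position PWM rescoring oracle, both strands
naive_scan <- function(seq, p, min_score = 0.8,
                       score_type = "fraction") {
  lo <- logodds_matrix(p)
  L <- nrow(lo)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  thr <- if (score_type == "fraction")
    min_score * sum(apply(lo, 1L, max)) else min_score
  n <- length(chars) - L + 1L
  hits <- list()
  if (n >= 1L) for (i in seq_len(n)) {
    win <- chars[i:(i + L - 1L)]
    if (all(win %in% names(comp))) {
      sc <- sum(lo[cbind(seq_len(L), match(win, names(comp)))])
      if (sc >= thr)
        hits[[length(hits) + 1L]] <- data.frame(offset = i - 1L,
                                                strand = "+", score = sc)
      scr <- sum(lo[cbind(seq_len(L),
                          match(comp[rev(win)], names(comp)))])
      if (scr >= thr)
        hits[[length(hits) + 1L]] <- data.frame(offset = i - 1L,
                                                strand = "-", score = scr)
    }
  }
  if (!length(hits))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# direct sum((O-E)^2/E) chi-squared oracle with a normal-tail p-value,
# vectorised; algebraically independent of the cross-product form
chisq_oracle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  deg <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  e11 <- r1 * c1 / n; e12 <- r1 * c2 / n
  e21 <- r2 * c1 / n; e22 <- r2 * c2 / n
  chi2 <- ifelse(deg, 0,
                 (a - e11)^2 / e11 + (b - e12)^2 / e12 +
                   (c - e21)^2 / e21 + (d - e22)^2 / e22)
  p <- ifelse(deg, 1, 2 * stats::pnorm(sqrt(chi2), lower.tail = FALSE))
  list(chi2 = chi2, p = p)
}

# fabricate a clusters object from planted labels (to exercise the offset
# detector in isolation from k-means)
clusters_from_truth <- function(labels, names, k = max(labels)) {
  structure(list(assignments = stats::setNames(as.integer(labels), names),
                 k = as.integer(k)),
            class = "profile_clusters")
}

random_pwm <- function(len, label = "rand") {
  m <- matrix(stats::rgamma(len * 4L, shape = 1), nrow = len)
  pwm(m / rowSums(m), label = label)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
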