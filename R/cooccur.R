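#' Chi-squared test for a 2x2 contingency table
#'
#' Computes the 1-df Pearson chi-squared statistic via the cross-product
#' form `N (ad - bc)^2 / (r1 r2 c1 c2)` (optionally Yates-corrected) and
#' the upper-tail p-value. A table with any zero margin carries no
#' information and returns `chi2 = 0`, `p = 1`. Vectorised over cells.
#'
#' @param a,b,c,d cell counts: rows are the two groups, columns the
#'   with/without condition, i.e. the table is `rbind(c(a, b), c(c, d))`.
#' @param yates apply Yates' continuity correction (default FALSE).
#' @return list with numeric vectors `chi2` and `p`.
#' @export
chisq_2x2 <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  den <- r1 * r2 * c1 * c2
  num <- abs(a * d - b * c)
  if (yates) num <- pmax(num - n / 2, 0)
  chi2 <- ifelse(den > 0, n * num^2 / den, 0)
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  p[den == 0] <- 1
  list(chi2 = chi2, p = p)
}

#' Pairwise motif co-occurrence testing against a control cluster
#'
#' For every unordered motif pair, counts the regions where both motifs are
#' present in the target cluster and in the control cluster, forms the 2x2
#' table (target with-both / target rest; control with-both / control rest)
#' and tests it with the 1-df chi-squared statistic (no Yates correction by
#' default). The p-value is the upper tail of chi-squared(1); direction is
#' read off the sign of observed minus expected in the target-with-both
#' cell. A pair is retained when `p < alpha / m` (strict) AND the pair is
#' enriched in the target. `m` counts pairs actually tested: pairs among
#' motifs present in at least one region overall. When any expected cell
#' falls below `min_expected`, the two-sided Fisher exact p-value is used
#' instead and the row is flagged.
#'
#' @param target,control binary presence matrices (regions x motifs) with
#'   identical motif columns, as from [presence_matrix()].
#' @param alpha family-wise error level (default 0.05).
#' @param yates Yates correction for the chi-squared statistic.
#' @param min_expected expected-cell threshold below which the Fisher exact
#'   fallback is used (default 1).
#' @return data.frame of class `"cooccurrence"`: one row per tested pair
#'   with counts, `chi2`, `p`, `odds_ratio`, `direction`, `fallback`,
#'   `retained`; attributes `m`, `alpha`, `threshold`.
#' @export
cooccurrence_scan <- function(target, control, alpha = 0.05, yates = FALSE,
                              min_expected = 1) {
  if (!identical(colnames(target), colnames(control)))
    stop("target and control must have identical motif columns")
  if (ncol(target) < 2L) stop("need at least 2 motifs")
  if (!all(target %in% c(0L, 1L)) || !all(control %in% c(0L, 1L)))
    stop("presence matrices must be strictly binary")
  present <- (colSums(target) + colSums(control)) > 0
  labels <- colnames(target)[present]
  if (length(labels) < 2L)
    stop("fewer than 2 motifs present in any region")
  n_t <- nrow(target); n_c <- nrow(control)
  joint_t <- crossprod(target[, present, drop = FALSE])
  joint_c <- crossprod(control[, present, drop = FALSE])
  pr <- utils::combn(length(labels), 2L)
  m <- ncol(pr)
  a <- joint_t[cbind(pr[1L, ], pr[2L, ])]
  c_ <- joint_c[cbind(pr[1L, ], pr[2L, ])]
  b <- n_t - a
  d <- n_c - c_
  cs <- chisq_2x2(a, b, c_, d, yates = yates)
  n <- a + b + c_ + d
  e_a <- (a + b) * (a + c_) / n
  direction <- ifelse(a > e_a, "enriched",
                      ifelse(a < e_a, "depleted", "none"))
  # Fisher exact fallback for sparse tables
  emin <- pmin((a + b) * (a + c_), (a + b) * (b + d),
               (c_ + d) * (a + c_), (c_ + d) * (b + d)) / n
  fallback <- emin < min_expected
  p <- cs$p
  for (i in which(fallback)) {
    p[i] <- stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]),
                                      nrow = 2L, byrow = TRUE))$p.value
  }
  or <- ifelse(b * c_ > 0 & a * d > 0, (a * d) / (b * c_),
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)))
  threshold <- alpha / m
  out <- data.frame(
    motif_a = labels[pr[1L, ]], motif_b = labels[pr[2L, ]],
    target_both = as.integer(a), target_rest = as.integer(b),
    control_both = as.integer(c_), control_rest = as.integer(d),
    chi2 = cs$chi2, p = p, odds_ratio = or, direction = direction,
    fallback = fallback,
    retained = p < threshold & direction == "enriched",
    stringsAsFactors = FALSE)
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- threshold
  class(out) <- c("cooccurrence", "data.frame")
  out
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat("Pairwise motif co-occurrence:", nrow(x), "pairs tested (m =",
      attr(x, "m"), "), Bonferroni threshold",
      format(attr(x, "threshold"), digits = 4), "\n")
  kept <- x[x$retained, , drop = FALSE]
  cat(nrow(kept), "pair(s) retained\n")
  if (nrow(kept)) print.data.frame(utils::head(
    kept[order(kept$p), c("motif_a", "motif_b", "target_both",
                          "control_both", "chi2", "p")], 10L),
    row.names = FALSE)
  invisible(x)
}

#' Bonferroni retention of co-occurrence results
#'
#' Retains enriched pairs with `p < alpha / m` (strict), where `m` is the
#' number of result rows. Monotone in `alpha`.
#'
#' @param results a `"cooccurrence"` table (or any data.frame with `p` and
#'   `direction`).
#' @param alpha family-wise error level.
#' @return list with `retained` (subset of rows), `threshold` and `m`.
#' @export
bonferroni_retain <- function(results, alpha = 0.05) {
  m <- nrow(results)
  if (m == 0L) stop("no results to correct")
  threshold <- alpha / m
  keep <- results$p < threshold & results$direction == "enriched"
  list(retained = results[keep, , drop = FALSE], threshold = threshold,
       m = m)
}

#' Per-motif enrichment of a target set against a control set
#'
#' Fold change of presence rates and one-sided hypergeometric p-value of
#' drawing at least the observed number of motif-positive regions in the
#' target, treating target + control as the pooled population.
#' Benjamini-Hochberg q-values across motifs.
#'
#' @param target,control binary presence matrices with identical columns.
#' @return data.frame with `motif`, `k_target`, `k_control`, `fold`
#'   (0.5-count continuity correction applied to the control rate when its
#'   count is 0), `p`, `q`.
#' @export
motif_enrichment <- function(target, control) {
  if (!identical(colnames(target), colnames(control)))
    stop("target and control must have identical motif columns")
  n_t <- nrow(target); n_c <- nrow(control)
  if (n_t == 0L || n_c == 0L) stop("empty region set")
  k_t <- colSums(target); k_c <- colSums(control)
  rate_c <- ifelse(k_c > 0, k_c / n_c, 0.5 / n_c)
  fold <- (k_t / n_t) / rate_c
  p <- stats::phyper(k_t - 1, m = k_t + k_c, n = n_t + n_c - (k_t + k_c),
                     k = n_t, lower.tail = FALSE)
  data.frame(motif = colnames(target), k_target = as.integer(k_t),
             k_control = as.integer(k_c), fold = fold, p = p,
             q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}
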