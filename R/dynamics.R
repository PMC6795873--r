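#' Configuration for profile building, clustering and EMT detection
#'
#' Defaults mirror a SeqMINER-style setup: 1500 bp either side of the peak
#' centre in 15 bp bins (200 bins per stage), linear (library-size)
#' normalisation, early stage T20 against late stage T23.
#'
#' @param flank bp profiled on each side of the peak centre (default 1500).
#' @param bin bin width in bp (default 15); `flank` must be divisible by
#'   `bin`.
#' @param seed RNG seed for k-means restarts.
#' @param n_init number of k-means restarts (best inertia kept).
#' @param normalisation `"linear"` (divide each stage by its total profiled
#'   signal) or `"none"`.
#' @param early_stage,late_stage stage labels compared by the offset test.
#' @param offset_alpha family-wise level for the EMT flag (default 0.05).
#' @param min_fold minimum mean late/early fold for the EMT flag
#'   (default 1.5).
#' @param pseudocount added to stage totals before log-ratios (default 1).
#' @return list of class `"clustering_config"`.
#' @export
clustering_config <- function(flank = 1500L, bin = 15L, seed = 1L,
                              n_init = 10L,
                              normalisation = c("linear", "none"),
                              early_stage = "T20", late_stage = "T23",
                              offset_alpha = 0.05, min_fold = 1.5,
                              pseudocount = 1) {
  normalisation <- match.arg(normalisation)
  if (flank %% bin != 0L)
    stop("flank must be divisible by bin")
  structure(list(flank = as.integer(flank), bin = as.integer(bin),
                 seed = as.integer(seed), n_init = as.integer(n_init),
                 normalisation = normalisation, early_stage = early_stage,
                 late_stage = late_stage, offset_alpha = offset_alpha,
                 min_fold = min_fold, pseudocount = pseudocount),
            class = "clustering_config")
}

#' Build binned per-stage signal profiles around peak centres
#'
#' For each peak the centre is `floor((start + end) / 2)`; bin `b` covers
#' `[centre - flank + b*bin, centre - flank + (b+1)*bin)` and its value is
#' the summed signal over the bin. Windows running past a sequence end are
#' zero-padded and the peak is flagged (attribute `"edge_flagged"`). With
#' `normalisation = "linear"` each stage's values are divided by that
#' stage's total signal over all profiled bins.
#'
#' @param peaks interval table with unique peak names.
#' @param signal a [signal_track()].
#' @param cfg a [clustering_config()].
#' @param normalise override `cfg$normalisation`.
#' @return 3-d array `peaks x bins x stages` with dimnames.
#' @export
build_profiles <- function(peaks, signal, cfg = clustering_config(),
                           normalise = cfg$normalisation) {
  nbins <- 2L * cfg$flank %/% cfg$bin
  stages <- names(signal$stages)
  ids <- if (all(!is.na(peaks$name)) && !anyDuplicated(peaks$name))
    peaks$name else sprintf("peak_%d", seq_len(nrow(peaks)))
  arr <- array(0, dim = c(nrow(peaks), nbins, length(stages)),
               dimnames = list(ids, NULL, stages))
  centre <- (peaks$start + peaks$end) %/% 2L
  win_start <- centre - cfg$flank  # 0-based start of bin 0
  edge <- rep(FALSE, nrow(peaks))
  for (st in stages) {
    for (sq in unique(peaks$seqid)) {
      rle <- signal$stages[[st]][[sq]]
      pk <- which(peaks$seqid == sq)
      if (is.null(rle)) next
      len <- length(rle)
      # all bin intervals for these peaks, 1-based closed for Views
      s1 <- rep(win_start[pk], each = nbins) +
        cfg$bin * rep(seq_len(nbins) - 1L, length(pk)) + 1L
      e1 <- s1 + cfg$bin - 1L
      bad <- win_start[pk] < 0L | win_start[pk] + 2L * cfg$flank > len
      edge[pk[bad]] <- TRUE
      cs <- pmax(s1, 1L); ce <- pmin(e1, len)
      ok <- cs <= ce
      vals <- numeric(length(s1))
      if (any(ok)) {
        v <- IRanges::Views(rle, start = cs[ok], end = ce[ok])
        vals[ok] <- IRanges::viewSums(v)
      }
      arr[pk, , st] <- matrix(vals, ncol = nbins, byrow = TRUE)
    }
  }
  if (normalise == "linear") {
    for (st in stages) {
      tot <- sum(arr[, , st])
      if (tot > 0) arr[, , st] <- arr[, , st] / tot
    }
  }
  attr(arr, "edge_flagged") <- ids[edge]
  attr(arr, "bin") <- cfg$bin
  attr(arr, "flank") <- cfg$flank
  arr
}

#' @keywords internal
flatten_profiles <- function(mat) {
  stages <- dimnames(mat)[[3L]]
  do.call(cbind, lapply(stages, function(s) mat[, , s, drop = TRUE]))
}

#' k-means clustering of concatenated per-stage profiles
#'
#' Profiles are concatenated across stages (peaks x bins*stages), clustered
#' with Euclidean k-means using `cfg$n_init` random restarts (best inertia
#' kept), deterministic under `cfg$seed`. Clusters are relabelled 1..k in
#' descending order of total mean signal.
#'
#' @param mat profile array from [build_profiles()].
#' @param k number of clusters (1 <= k <= number of peaks).
#' @param cfg a [clustering_config()].
#' @return object of class `"profile_clusters"`: `assignments` (named
#'   integer), `centroids`, `sizes`, `mean_profiles` (k x bins x stages),
#'   `inertia`, `k`, `stages`.
#' @export
cluster_profiles <- function(mat, k, cfg = clustering_config()) {
  n <- dim(mat)[1L]
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of peaks")
  flat <- flatten_profiles(mat)
  set.seed(cfg$seed)
  km <- if (k == 1L) {
    list(cluster = rep(1L, n), centers = matrix(colMeans(flat), 1L),
         tot.withinss = sum(sweep(flat, 2L, colMeans(flat))^2))
  } else {
    stats::kmeans(flat, centers = k, nstart = cfg$n_init, iter.max = 100L)
  }
  ord <- order(rowMeans(km$centers), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  assignments <- stats::setNames(relabel[km$cluster], dimnames(mat)[[1L]])
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  stages <- dimnames(mat)[[3L]]
  nbins <- dim(mat)[2L]
  mean_profiles <- array(0, dim = c(k, nbins, length(stages)),
                         dimnames = list(seq_len(k), NULL, stages))
  for (cl in seq_len(k)) {
    members <- which(assignments == cl)
    for (s in stages)
      mean_profiles[cl, , s] <-
        colMeans(mat[members, , s, drop = FALSE])
  }
  structure(list(assignments = assignments, centroids = centroids,
                 sizes = as.integer(table(factor(assignments,
                                                 levels = seq_len(k)))),
                 mean_profiles = mean_profiles,
                 inertia = km$tot.withinss, k = k, stages = stages),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat("profile_clusters: k =", x$k, "over", length(x$assignments),
      "peaks; sizes:", paste(x$sizes, collapse = ", "),
      "\ninertia:", format(x$inertia, digits = 6), "\n")
  invisible(x)
}

#' Mean coverage curve of a cluster at one stage
#'
#' @param result a `"profile_clusters"`.
#' @param mat the profile array the clustering was run on.
#' @param cluster cluster id (1..k).
#' @param stage stage label.
#' @return numeric vector over bins (arithmetic mean across member peaks).
#' @export
mean_coverage <- function(result, mat, cluster, stage) {
  members <- which(result$assignments == cluster)
  if (!length(members)) stop("cluster ", cluster, " is empty")
  if (!stage %in% dimnames(mat)[[3L]]) stop("unknown stage: ", stage)
  colMeans(matrix(mat[members, , stage], nrow = length(members)))
}

#' Early-versus-late offset test for dynamically opening (EMT) clusters
#'
#' Per cluster, each member peak contributes its total profiled signal at
#' the early and late stages. Reported per cluster: the Pearson correlation
#' between early and late totals across members, the mean paired
#' `log2((late + c) / (early + c))` with pseudocount `c`, and a two-sided
#' one-sample Wilcoxon signed-rank test of the log-ratios against 0,
#' Bonferroni-corrected across clusters. A cluster is flagged EMT iff the
#' corrected p-value is below `cfg$offset_alpha` AND the mean fold
#' (`2^mean-log2-ratio`) is at least `cfg$min_fold`. Clusters with fewer
#' than 5 members report statistics but are never flagged (with a warning).
#' Run this on *unnormalised* profiles (raw binned counts).
#'
#' @param result a `"profile_clusters"`.
#' @param mat unnormalised profile array.
#' @param cfg a [clustering_config()].
#' @return data.frame of class `"emt_test"`: one row per cluster with `n`,
#'   `pearson_r`, `mean_log2_ratio`, `fold`, `p`, `p_bonferroni`,
#'   `emt_flag`.
#' @export
emt_offset_test <- function(result, mat, cfg = clustering_config()) {
  stages <- dimnames(mat)[[3L]]
  if (!all(c(cfg$early_stage, cfg$late_stage) %in% stages))
    stop("early/late stage not present in the profile array")
  s_e_all <- rowSums(mat[, , cfg$early_stage, drop = TRUE])
  s_l_all <- rowSums(mat[, , cfg$late_stage, drop = TRUE])
  k <- result$k
  rows <- lapply(seq_len(k), function(cl) {
    members <- which(result$assignments == cl)
    s_e <- s_e_all[members]; s_l <- s_l_all[members]
    lr <- log2((s_l + cfg$pseudocount) / (s_e + cfg$pseudocount))
    r <- if (length(members) > 2L && stats::sd(s_e) > 0 &&
             stats::sd(s_l) > 0) stats::cor(s_e, s_l) else NA_real_
    p <- if (all(lr == 0) || length(lr) < 2L) 1
         else suppressWarnings(stats::wilcox.test(lr, mu = 0)$p.value)
    data.frame(cluster = cl, n = length(members), pearson_r = r,
               mean_log2_ratio = mean(lr), fold = 2^mean(lr), p = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * k)
  out$emt_flag <- out$p_bonferroni < cfg$offset_alpha &
    out$fold >= cfg$min_fold & out$n >= 5L
  small <- out$n < 5L
  if (any(small))
    warning("cluster(s) ", paste(out$cluster[small], collapse = ", "),
            " have < 5 members; EMT flag forced FALSE")
  class(out) <- c("emt_test", "data.frame")
  out
}

#' @export
print.emt_test <- function(x, ...) {
  cat("Early-vs-late offset test (", sum(x$emt_flag), " EMT cluster(s) of ",
      nrow(x), ")\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}
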