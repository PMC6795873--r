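test_that("profile geometry: 200 bins at defaults, bin value = width x depth", {
  cfg <- clustering_config()
  # uniform coverage of 1 per base over the whole window
  bg <- data.frame(seqid = "chr1", start = 0L, end = 20000L, value = 1)
  sig <- signal_track(T20 = bg, T23 = bg)
  pk <- gintervals("chr1", 9000, 9400, name = "pk")
  prof <- build_profiles(pk, sig, cfg, normalise = "none")
  expect_equal(dim(prof), c(1, 200, 2))
  expect_true(all(prof == 15))
  # zero signal everywhere
  z <- build_profiles(pk, signal_track(T20 = bg[0, ]), cfg,
                      normalise = "none")
  expect_true(all(z == 0))
  expect_error(clustering_config(flank = 1000, bin = 13), "divisible")
})

test_that("profiles are translation-equivariant and conserve windowed totals", {
  set.seed(2)
  cfg <- clustering_config(flank = 300L, bin = 15L)
  iv <- data.frame(seqid = "chr1",
                   start = seq(1000L, 3000L, by = 100L))
  iv$end <- iv$start + 100L
  iv$value <- round(runif(nrow(iv), 0, 10), 2)
  delta <- 1234L
  shifted <- transform(iv, start = start + delta, end = end + delta)
  pk <- gintervals("chr1", 1800, 1900, name = "pk")
  pk2 <- gintervals("chr1", 1800 + delta, 1900 + delta, name = "pk")
  p1 <- build_profiles(pk, signal_track(T20 = iv), cfg,
                       normalise = "none")
  p2 <- build_profiles(pk2, signal_track(T20 = shifted), cfg,
                       normalise = "none")
  expect_equal(p1, p2)
  # conservation: bin sums equal the windowed signal total
  centre <- (1800 + 1900) %/% 2
  tot <- signal_query(signal_track(T20 = iv), "T20", "chr1",
                      centre - 300, centre + 300)
  expect_equal(sum(p1), tot)
})

test_that("edge windows are zero-padded and flagged", {
  cfg <- clustering_config(flank = 300L, bin = 15L)
  bg <- data.frame(seqid = "chr1", start = 0L, end = 1000L, value = 1)
  pk <- gintervals("chr1", c(100, 600), c(140, 640),
                   name = c("edge", "ok"))
  prof <- build_profiles(pk, signal_track(T20 = bg), cfg,
                         normalise = "none")
  expect_equal(attr(prof, "edge_flagged"), "edge")
  # bins before position 0 contribute nothing
  expect_true(all(prof["edge", 1:12, "T20"] == 0))
  expect_true(all(prof["ok", , "T20"] == 15))
})

test_that("linear normalisation divides each stage by its profiled total", {
  cfg <- clustering_config(flank = 300L, bin = 15L)
  bg1 <- data.frame(seqid = "chr1", start = 0L, end = 5000L, value = 2)
  bg2 <- data.frame(seqid = "chr1", start = 0L, end = 5000L, value = 8)
  pk <- gintervals("chr1", 2000, 2100, name = "pk")
  raw <- build_profiles(pk, signal_track(A = bg1, B = bg2), cfg,
                        normalise = "none")
  nrm <- build_profiles(pk, signal_track(A = bg1, B = bg2), cfg,
                        normalise = "linear")
  expect_equal(nrm[, , "A"], raw[, , "A"] / sum(raw[, , "A"]))
  expect_equal(nrm[, , "B"], raw[, , "B"] / sum(raw[, , "B"]))
  expect_equal(nrm[, , "A"], nrm[, , "B"])  # scale differences removed
})

test_that("k-means clustering is deterministic and recovers planted shapes", {
  cfg <- small_cfg(seed = 23, n_peaks_per_category = c(intergenic = 60L),
                   n_clusters = 2L)
  sp <- generate_peaks_and_signal(cfg, generate_annotation(cfg))
  cc <- clustering_config(seed = 4)
  cl1 <- cluster_profiles(sp$profiles, 2, cc)
  cl2 <- cluster_profiles(sp$profiles, 2, cc)
  expect_identical(cl1$assignments, cl2$assignments)
  expect_gte(ari(cl1$assignments, sp$peaks$cluster), 0.8)
  # k = 1: centroid is the column-mean profile
  k1 <- cluster_profiles(sp$profiles, 1, cc)
  expect_equal(as.numeric(k1$centroids),
               colMeans(crestreg:::flatten_profiles(sp$profiles)))
  expect_error(cluster_profiles(sp$profiles, 1000, cc), "exceeds")
  # relabelling: cluster 1 has the highest total mean signal
  expect_true(which.max(rowMeans(cl1$centroids)) == 1)
})

test_that("mean_coverage averages member profiles elementwise", {
  mat <- array(0, dim = c(2, 4, 1), dimnames = list(c("a", "b"), NULL,
                                                    "T20"))
  mat["a", , "T20"] <- c(1, 2, 3, 4)
  mat["b", , "T20"] <- c(3, 2, 1, 0)
  res <- clusters_from_truth(c(1, 1), c("a", "b"), k = 1)
  expect_equal(mean_coverage(res, mat, 1, "T20"), c(2, 2, 2, 2))
  res2 <- clusters_from_truth(c(1, 2), c("a", "b"), k = 2)
  expect_equal(mean_coverage(res2, mat, 2, "T20"), c(3, 2, 1, 0))
  expect_error(mean_coverage(res2, mat, 3, "T20"), "empty")
})

test_that("offset test: identical stages give r = 1, log-ratio 0, no flag", {
  mat <- array(5, dim = c(10, 6, 2),
               dimnames = list(letters[1:10], NULL, c("T20", "T23")))
  mat[, 1, ] <- seq_len(10)  # spread so the correlation is defined
  res <- clusters_from_truth(rep(1, 10), letters[1:10], k = 1)
  cc <- clustering_config()
  emt <- emt_offset_test(res, mat, cc)
  expect_equal(emt$pearson_r, 1)
  expect_equal(emt$mean_log2_ratio, 0)
  expect_false(emt$emt_flag)
})

test_that("offset test flags a doubled late stage but not tiny clusters", {
  set.seed(9)
  n <- 60
  mat <- array(0, dim = c(n, 4, 2),
               dimnames = list(sprintf("p%02d", 1:n), NULL,
                               c("T20", "T23")))
  base <- rlnorm(n, log(50), 0.2)
  mat[, , "T20"] <- base
  mat[, , "T23"] <- base * 2 * exp(rnorm(n, 0, 0.05))
  res <- clusters_from_truth(rep(1, n), dimnames(mat)[[1]], k = 1)
  emt <- emt_offset_test(res, mat, clustering_config())
  expect_true(emt$emt_flag)
  expect_lt(abs(emt$mean_log2_ratio - 1), 0.15)
  # < 5 members: statistics reported, flag forced FALSE with a warning
  small <- mat[1:4, , , drop = FALSE]
  res4 <- clusters_from_truth(rep(1, 4), dimnames(small)[[1]], k = 1)
  expect_warning(e4 <- emt_offset_test(res4, small, clustering_config()),
                 "< 5 members")
  expect_false(e4$emt_flag)
  expect_true(is.finite(e4$p))
})
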