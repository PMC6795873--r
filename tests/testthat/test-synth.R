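test_that("annotation generation hits exact enrichment counts and is seeded", {
  cfg <- small_cfg(seed = 3, n_genes = 50L, frac_enriched = 0.4)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 50)
  enriched <- ann$de$padj < 0.05 & ann$de$log2fc > 1
  expect_equal(sum(enriched), 20)
  # genes non-overlapping per strand
  for (st in c("+", "-")) {
    g <- ann$genes[ann$genes$strand == st, ]
    g <- g[order(g$seqid, g$start), ]
    same <- g$seqid[-1] == g$seqid[-nrow(g)]
    expect_true(all(g$start[-1][same] >= g$end[-nrow(g)][same]))
  }
  # determinism
  ann2 <- generate_annotation(small_cfg(seed = 3, n_genes = 50L,
                                        frac_enriched = 0.4))
  expect_identical(ann, ann2)
  # empty and infeasible configurations
  empty <- generate_annotation(small_cfg(n_genes = 0L))
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$de), 0)
  expect_error(generate_annotation(synth_config(n_chromosomes = 1,
                                                chrom_length = 1e5,
                                                n_genes = 50)),
               "infeasible")
})

test_that("planted peaks realise category quotas recoverable by classification", {
  cfg <- small_cfg(seed = 5)
  ann <- generate_annotation(cfg)
  sp <- generate_peaks_and_signal(cfg, ann)
  expect_equal(unname(table(sp$peaks$category)[c("promoter", "intronic",
                                                 "intergenic")]),
               c(6L, 6L, 8L), ignore_attr = TRUE)
  cl <- classify_peaks(sp$peaks[, 1:6], ann$transcripts, ann$genes)
  expect_equal(cl$category, sp$peaks$category)
  # ground truth is complete and unique
  expect_setequal(sp$truth$name, sp$peaks$name)
  expect_equal(anyDuplicated(sp$truth$name), 0)
})

test_that("planted EMT fold is realised in the signal within 10%", {
  cfg <- small_cfg(seed = 8, n_peaks_per_category = c(intergenic = 60L),
                   n_clusters = 2L, emt_cluster = 1L, emt_fold = 2.5)
  ann <- generate_annotation(cfg)
  sp <- generate_peaks_and_signal(cfg, ann)
  emt <- sp$peaks$cluster == 1
  ratio <- sp$counts[emt, "T23"] / sp$counts[emt, "T20"]
  expect_lt(abs(mean(ratio) - 2.5) / 2.5, 0.10)
  # null planting: fold 1 leaves stages exchangeable
  cfg0 <- small_cfg(seed = 8, n_peaks_per_category = c(intergenic = 60L),
                    n_clusters = 2L, emt_fold = 1)
  sp0 <- generate_peaks_and_signal(cfg0, generate_annotation(cfg0))
  r0 <- sp0$counts[, "T23"] / sp0$counts[, "T20"]
  expect_lt(abs(mean(r0) - 1), 0.1)
  expect_false(any(sp0$truth$emt))
})

test_that("negative-binomial noise produces integer counts at the right mean", {
  cfg <- small_cfg(seed = 13, n_peaks_per_category = c(intergenic = 40L),
                   n_clusters = 1L, emt_cluster = 0L, noise = "nbinom")
  sp <- generate_peaks_and_signal(cfg, generate_annotation(cfg))
  expect_true(all(sp$profiles == floor(sp$profiles)))
  tpl_total <- sum(crestreg:::cluster_template(1L, dim(sp$profiles)[2]))
  expect_lt(abs(mean(sp$counts) / tpl_total - 1), 0.15)
})

test_that("sequence planting respects the window and placement table", {
  cfg <- small_cfg(seed = 2, n_peaks_per_category = c(intergenic = 20L),
                   n_clusters = 2L, p_joint_target = 1, p_joint_control = 0,
                   motif_set = default_motifs(4))
  ann <- generate_annotation(cfg)
  sp <- generate_peaks_and_signal(cfg, ann)
  sm <- generate_sequences_with_motifs(cfg, sp$peaks)
  pl <- sm$placements
  centre <- (sp$peaks$start + sp$peaks$end) %/% 2
  names(centre) <- sp$peaks$name
  expect_true(all(abs(pl$start - centre[pl$peak]) <= 250))
  # every target-cluster peak has the joint pair planted
  tgt <- sp$peaks$name[sp$peaks$cluster == cfg$coocc_target_cluster]
  joint <- pl[pl$joint, ]
  expect_setequal(unique(joint$peak), tgt)
  # no joint planting in the control cluster
  ctl <- sp$peaks$name[sp$peaks$cluster == cfg$coocc_control_cluster]
  expect_equal(length(intersect(joint$peak, ctl)), 0)
  expect_error(
    generate_sequences_with_motifs(cfg, sp$peaks, window = 3),
    "longer than")
})

test_that("presence-level simulator reflects the planted joint rates", {
  cfg <- synth_config(seed = 17, p_joint_target = 0.4,
                      p_joint_control = 0.05, p_single = 0.15)
  pm <- generate_presence(cfg, n_target = 2000, n_control = 2000)
  pair <- pm$pair
  both_t <- mean(pm$target[, pair[1]] & pm$target[, pair[2]])
  both_c <- mean(pm$control[, pair[1]] & pm$control[, pair[2]])
  # target joint rate ~ p_joint + (1 - p_joint) * p_single^2
  expect_lt(abs(both_t - (0.4 + 0.6 * 0.15^2)), 0.05)
  # control singles are raised to match marginals; its joint rate is
  # p_jc + (1 - p_jc) * ps_c^2 with ps_c = (m - p_jc) / (1 - p_jc)
  ps_c <- ((0.4 + 0.6 * 0.15) - 0.05) / 0.95
  expect_lt(abs(both_c - (0.05 + 0.95 * ps_c^2)), 0.05)
  # pair-motif marginal rates are equal across groups by construction
  expect_lt(abs(mean(pm$target[, pair[1]]) -
                  mean(pm$control[, pair[1]])), 0.05)
  # non-pair motifs are independent Bernoulli(p_single)
  expect_lt(abs(mean(pm$target[, 3]) - 0.15), 0.03)
})

test_that("a full dataset is byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 99, n_genes = 24L,
                   n_peaks_per_category = c(promoter = 4L, intronic = 4L,
                                            intergenic = 6L),
                   chrom_length = 5e5, motif_set = default_motifs(4))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- generate_dataset(cfg, d1)
  f2 <- generate_dataset(cfg, d2)
  expect_setequal(names(f1), names(f2))
  for (nm in names(f1)) {
    expect_identical(unname(tools::md5sum(f1[[nm]])),
                     unname(tools::md5sum(f2[[nm]])), label = nm)
  }
})
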