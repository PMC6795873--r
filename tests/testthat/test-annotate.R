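mk_genes <- function(...) {
  g <- data.frame(..., stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "-", g$end - 1L, g$start)
  g$biotype <- "coding"
  g
}

test_that("consensus merging records per-stage provenance", {
  stages <- list(T20 = gintervals("chr1", 100, 200, name = "a"),
                 T23 = gintervals("chr1", 150, 250, name = "b"))
  cons <- build_consensus(stages)
  expect_equal(nrow(cons), 1)
  expect_equal(c(cons$start, cons$end), c(100, 250))
  expect_equal(cons$stages, "T20,T23")
  # single stage: consensus is that stage merged
  one <- build_consensus(list(T20 = gintervals("chr1", c(10, 15, 400),
                                               c(20, 30, 500))))
  expect_equal(one$start, c(10, 400))
  expect_equal(one$stages, c("T20", "T20"))
  # disjoint stage-unique peaks keep singleton provenance
  tri <- build_consensus(list(T20 = gintervals("chr1", 0, 10),
                              T21 = gintervals("chr1", 100, 110),
                              T23 = gintervals("chr2", 0, 10)))
  expect_equal(sort(tri$stages), c("T20", "T21", "T23"))
  expect_error(build_consensus(list()), "at least one")
})

test_that("promoter windows are strand-aware, half-open, TSS-exclusive", {
  gp <- mk_genes(gene_id = "g+", seqid = "chr1", start = 5000L,
                 end = 9000L, strand = "+")
  gm <- mk_genes(gene_id = "g-", seqid = "chr1", start = 20000L,
                 end = 24000L, strand = "-")
  wp <- promoter_windows(gp, 2000L)
  expect_equal(c(wp$start, wp$end), c(3000, 5000))   # [TSS-2000, TSS)
  wm <- promoter_windows(gm, 2000L)
  expect_equal(c(wm$start, wm$end), c(24000, 26000)) # (TSS, TSS+2000]
  # near-origin clipping
  w0 <- promoter_windows(mk_genes(gene_id = "g0", seqid = "chr1",
                                  start = 500L, end = 3000L,
                                  strand = "+"), 2000L)
  expect_equal(w0$start, 0)
})

test_that("classification follows the promoter > exonic > intronic priority", {
  genes <- mk_genes(gene_id = c("gA", "gB"), seqid = "chr1",
                    start = c(10000L, 23000L), end = c(20000L, 30000L),
                    strand = c("+", "+"))
  exons <- data.frame(
    transcript_id = c("tA", "tA", "tB"), gene_id = c("gA", "gA", "gB"),
    seqid = "chr1", strand = "+",
    start = c(10000L, 19000L, 23000L), end = c(11000L, 20000L, 30000L))
  tx <- transcript_set(exons)
  cfg <- annotation_config()
  pk <- gintervals("chr1",
                   c(8100, 12000, 10500, 40000, 21500),
                   c(8300, 12400, 10800, 40200, 21700),
                   name = c("prom", "intron", "exon", "inter", "both"))
  # "both": inside gA's intron region? no - it is in gB's promoter window
  # [21000,23000) and outside gA body: promoter wins anyway.
  got <- classify_peaks(pk, tx, genes, cfg)
  expect_equal(got$category,
               c("promoter", "intronic", "exonic", "intergenic",
                 "promoter"))
  # a peak inside gA's intron AND gB's promoter window is promoter
  pk2 <- gintervals("chr1", 22000, 22200, name = "ovl")
  genes2 <- mk_genes(gene_id = c("gA", "gB"), seqid = "chr1",
                     start = c(10000L, 24000L), end = c(23000L, 30000L),
                     strand = c("+", "+"))
  exons2 <- data.frame(
    transcript_id = c("tA", "tA"), gene_id = "gA", seqid = "chr1",
    strand = "+", start = c(10000L, 22500L), end = c(11000L, 23000L))
  got2 <- classify_peaks(pk2, transcript_set(exons2), genes2, cfg)
  expect_equal(got2$category, "promoter")
  # empty annotation: everything intergenic, no nearest gene
  none <- classify_peaks(pk, NULL, genes[0, ], cfg)
  expect_true(all(none$category == "intergenic"))
  expect_true(all(is.na(none$nearest_gene)))
})

test_that("the promoter flank boundary is exactly 2000 bp, exclusive of the TSS", {
  g <- mk_genes(gene_id = "g", seqid = "chr1", start = 10000L,
                end = 15000L, strand = "+")
  cfg <- annotation_config()
  # window is [8000, 10000): abutting on either side is not promoter
  cls <- function(s, e) classify_peaks(gintervals("chr1", s, e), NULL, g,
                                       cfg)$category
  expect_equal(cls(7800, 8000), "intergenic")  # abuts window start
  expect_equal(cls(7999, 8001), "promoter")    # 1 bp overlap at the edge
  expect_equal(cls(9999, 10000), "promoter")   # last window base
  expect_equal(cls(10000, 10050), "intronic")  # TSS base itself: gene body
})

test_that("short genes are dropped before classification", {
  g <- mk_genes(gene_id = "tiny", seqid = "chr1", start = 10000L,
                end = 11000L, strand = "+")  # span 1000 < 1500
  got <- classify_peaks(gintervals("chr1", 10100, 10300), NULL, g,
                        annotation_config())
  expect_equal(got$category, "intergenic")
  expect_true(is.na(got$nearest_gene))
})

test_that("curated-promoter reassignment relabels without moving peaks", {
  curated <- mk_genes(gene_id = "cur", seqid = "chr1", start = 50000L,
                      end = 60000L, strand = "+")
  pk <- gintervals("chr1", c(48500, 55000, 70000), c(48700, 55200, 70200),
                   name = c("in_window", "in_body", "far"))
  ann <- classify_peaks(pk, NULL, curated[0, ], annotation_config())
  expect_true(all(ann$category == "intergenic"))
  re <- reassign_intergenic_promoters(ann, curated)
  expect_equal(re$category, c("promoter", "intergenic", "intergenic"))
  expect_equal(re$reassigned, c(TRUE, FALSE, FALSE))
  expect_equal(re[, c("start", "end")], ann[, c("start", "end")])
  expect_equal(nrow(re), nrow(ann))
  # no curated genes: nothing moves
  re0 <- reassign_intergenic_promoters(ann, curated[0, ])
  expect_equal(re0$category, ann$category)
})

test_that("proximity filter uses a strict 50 kb cutoff on enriched genes", {
  genes <- mk_genes(gene_id = c("enr", "null"), seqid = "chr1",
                    start = c(100000L, 500000L),
                    end = c(110000L, 510000L), strand = c("+", "+"))
  de <- data.frame(gene_id = c("enr", "null"), log2fc = c(2, 3),
                   padj = c(1e-4, 0.9), base_mean = c(100, 100))
  cfg <- annotation_config()
  pk <- gintervals("chr1",
                   c(159999L, 160000L, 105000L, 490000L),
                   c(170000L, 170001L, 105100L, 495000L),
                   name = c("at49999", "at50000", "inside", "near_null"))
  kept <- proximity_filter(pk, genes, de, cfg)
  expect_setequal(kept$name, c("at49999", "inside"))
  expect_equal(kept$enriched_distance[kept$name == "at49999"], 49999)
  expect_equal(kept$enriched_distance[kept$name == "inside"], 0)
  # larger threshold keeps a superset
  cfg2 <- annotation_config(proximity_max = 60000)
  expect_true(all(kept$name %in% proximity_filter(pk, genes, de,
                                                  cfg2)$name))
  # no enriched genes: empty with a warning
  de0 <- de; de0$padj <- 1
  expect_warning(out <- proximity_filter(pk, genes, de0, cfg),
                 "no enriched")
  expect_equal(nrow(out), 0)
})

test_that("classification partitions the synthetic consensus exactly", {
  cfg <- small_cfg(seed = 31)
  ann <- generate_annotation(cfg)
  sp <- generate_peaks_and_signal(cfg, ann)
  beds <- generate_stage_beds(sp, cfg)
  res <- annotate_pipeline(beds, ann$transcripts, ann$genes,
                           curated_genes = NULL, de = ann$de)
  cons <- res$consensus
  cats <- table(factor(cons$category,
                       levels = c("promoter", "exonic", "intronic",
                                  "intergenic")))
  expect_equal(sum(cats), nrow(cons))
  expect_equal(anyDuplicated(cons$name), 0)
})
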