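mk_tx <- function(id, strand, starts, ends, seqid = "chr1") {
  data.frame(transcript_id = id, gene_id = NA_character_, seqid = seqid,
             strand = strand, start = as.integer(starts),
             end = as.integer(ends), stringsAsFactors = FALSE)
}
mk_gene <- function(id, start, end, strand, seqid = "chr1",
                    biotype = "coding") {
  data.frame(gene_id = id, seqid = seqid, start = as.integer(start),
             end = as.integer(end), strand = strand,
             tss = if (strand == "-") as.integer(end) - 1L
                   else as.integer(start),
             biotype = biotype, stringsAsFactors = FALSE)
}

test_that("coding-overlap rule is strand-aware down to 1 bp", {
  genes <- mk_gene("g1", 1000, 2000, "+")
  tx <- transcript_set(rbind(
    mk_tx("inside_same", "+", c(1200, 1600), c(1400, 1800)),
    mk_tx("inside_anti", "-", c(1200, 1600), c(1400, 1800)),
    mk_tx("one_bp", "+", c(500, 1999), c(700, 2200)),
    mk_tx("clear", "+", c(3000, 3400), c(3200, 3600))))
  res <- drop_coding_overlap(tx, genes)
  expect_setequal(res$report$removed, c("inside_same", "one_bp"))
  expect_setequal(res$tx$transcripts$transcript_id,
                  c("inside_anti", "clear"))
  expect_equal(res$report$n_in - res$report$n_removed, res$report$n_out)
})

test_that("protein-similarity rule applies the identity and e-value cutoffs", {
  tx <- transcript_set(rbind(mk_tx("t1", "+", 100, 400),
                             mk_tx("t2", "+", 1000, 1300),
                             mk_tx("t3", "+", 2000, 2300)))
  hits <- data.frame(
    transcript_id = c("t1", "t2", "ghost"),
    percent_identity = c(35, 25, 99),
    evalue = c(1e-5, 1e-20, 1e-50))
  res <- drop_protein_similar(tx, hits)
  expect_equal(res$report$removed, "t1")       # 35% > 30 and significant
  expect_true("t2" %in% res$tx$transcripts$transcript_id)  # 25% <= 30
  # literal reading of the printed inequality: removes only weak hits
  lit_hits <- data.frame(transcript_id = c("t1", "t2"),
                         percent_identity = c(35, 35),
                         evalue = c(1e-5, 0.5))
  res_lit <- drop_protein_similar(tx, lit_hits, literal_evalue = TRUE)
  expect_equal(res_lit$report$removed, "t2")
  # no hits: everything survives
  expect_equal(drop_protein_similar(tx, NULL)$report$n_removed, 0)
  bad <- data.frame(transcript_id = "t1", percent_identity = -1,
                    evalue = 1)
  expect_error(drop_protein_similar(tx, bad), "identity")
})

test_that("splice and length rules use exon count and summed exon length", {
  tx <- transcript_set(rbind(
    mk_tx("mono", "+", 100, 400),
    mk_tx("spliced", "+", c(1000, 1500), c(1100, 1600)),
    mk_tx("len199", "+", c(3000, 3200), c(3099, 3300)),
    mk_tx("len200", "+", c(5000, 5200), c(5100, 5300))))
  expect_equal(drop_unspliced(tx)$report$removed, "mono")
  lens <- tx$transcripts$length[match(c("len199", "len200"),
                                      tx$transcripts$transcript_id)]
  expect_equal(lens, c(199, 200))
  short <- drop_short(tx)
  expect_true("len199" %in% short$report$removed)   # strict <
  expect_false("len200" %in% short$report$removed)
  expect_equal(drop_short(tx_subset(tx, character()))$report$n_out, 0)
})

test_that("antisense-proximity consults only the nearest coding gene", {
  genes <- mk_gene("g1", 10000, 15000, "+")
  tx <- transcript_set(rbind(
    mk_tx("anti_3kb", "-", c(6500, 6800), c(6700, 7000)),   # 3 kb away
    mk_tx("anti_6kb", "-", c(3500, 3800), c(3700, 4000)),   # 6 kb away
    mk_tx("sense_1kb", "+", c(8700, 8900), c(8800, 9000)))) # same strand
  res <- keep_antisense_proximal(tx, genes)
  expect_equal(res$tx$transcripts$transcript_id, "anti_3kb")
  expect_setequal(res$report$removed, c("anti_6kb", "sense_1kb"))
  # exactly 5 kb is retained (inclusive)
  at5k <- transcript_set(mk_tx("at5k", "-", c(4600, 4800), c(4700, 5000)))
  expect_equal(keep_antisense_proximal(at5k, genes)$report$n_removed, 0)
  # no coding genes: empty survivors with a warning
  expect_warning(res0 <- keep_antisense_proximal(tx, genes[0, ]),
                 "no coding genes")
  expect_equal(nrow(res0$tx$transcripts), 0)
})

test_that("the cascade recovers planted truth with a reconciling audit", {
  cfg <- small_cfg(seed = 41)
  ann <- generate_annotation(cfg)
  stx <- generate_transcripts_for_lncrna(cfg, ann)
  res <- run_cascade(stx$transcripts, ann$genes, stx$hits)
  truth <- stx$truth
  expect_setequal(res$lncrnas$transcripts$transcript_id,
                  truth$transcript_id[truth$class == "true_lncrna"])
  # each decoy is removed exactly at its planted step, never earlier
  for (step in res$reports$step) {
    planted <- truth$transcript_id[!is.na(truth$violated_rule) &
                                     truth$violated_rule == step]
    expect_setequal(res$removed[[step]], planted)
  }
  # chained audit reconciles end-to-end
  expect_equal(res$reports$n_in - res$reports$n_removed,
               res$reports$n_out)
  expect_equal(res$reports$n_in[-1], res$reports$n_out[-5])
  expect_equal(res$reports$n_in[1], nrow(stx$transcripts$transcripts))
  # idempotence: re-running on the survivors removes nothing
  again <- run_cascade(res$lncrnas, ann$genes, stx$hits)
  expect_equal(sum(again$reports$n_removed), 0)
  expect_setequal(again$lncrnas$transcripts$transcript_id,
                  res$lncrnas$transcripts$transcript_id)
})

test_that("the final set is invariant to filter order on the fixture", {
  cfg <- small_cfg(seed = 43)
  ann <- generate_annotation(cfg)
  stx <- generate_transcripts_for_lncrna(cfg, ann)
  lcfg <- lncrna_config()
  perm <- list(
    function(t) drop_short(t, lcfg),
    function(t) keep_antisense_proximal(t, ann$genes, lcfg),
    function(t) drop_unspliced(t),
    function(t) drop_protein_similar(t, stx$hits, lcfg),
    function(t) drop_coding_overlap(t, ann$genes))
  cur <- stx$transcripts
  for (f in perm) cur <- suppressWarnings(f(cur))$tx
  ref <- run_cascade(stx$transcripts, ann$genes, stx$hits, lcfg)
  expect_setequal(cur$transcripts$transcript_id,
                  ref$lncrnas$transcripts$transcript_id)
})

test_that("ATAC overlap fraction counts exonic overlap, strand-blind", {
  tx <- transcript_set(do.call(rbind, lapply(1:10, function(i)
    mk_tx(sprintf("t%02d", i), "-", i * 10000, i * 10000 + 500))))
  peaks <- gintervals("chr1", (1:7) * 10000 + 100, (1:7) * 10000 + 200)
  expect_equal(atac_overlap_fraction(tx, peaks), 0.7)
  expect_equal(atac_overlap_fraction(tx, peaks[0, ]), 0)
  expect_equal(atac_overlap_fraction(
    tx, gintervals("chr1", 0, 2e6)), 1)
  empty <- tx_subset(tx, character())
  expect_warning(f <- atac_overlap_fraction(empty, peaks), "undefined")
  expect_true(is.nan(f))
})
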