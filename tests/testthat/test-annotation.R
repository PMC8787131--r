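feat <- function(id, chrom, start, end, strand, biotype = "protein_coding",
                 symbol = id) {
  data.frame(feature_id = id, gene_symbol = symbol, chrom = chrom,
             start = start, end = end, strand = strand, biotype = biotype,
             stringsAsFactors = FALSE)
}

test_that("positional classes follow overlap strand and promoter geometry", {
  coding <- rbind(feat("g1", "chr1", 11000, 15000, "+"),
                  feat("g2", "chr2", 11000, 15000, "-"),
                  feat("g3", "chr3", 50000, 60000, "+"),
                  feat("g4", "chr4", 20000, 30000, "+"))
  lnc <- rbind(
    feat("sense", "chr1", 10000, 12000, "+", "lncRNA"),
    feat("anti", "chr2", 10000, 12000, "+", "lncRNA"),
    feat("far", "chr3", 560000, 561000, "+", "lncRNA"),
    # head-to-head: gene g4 on + has 5' at 20000; lncRNA on - ends at 19500
    feat("bidir", "chr4", 18000, 19500, "-", "lncRNA"))
  cls <- classify_lncrna(lnc, coding)
  got <- setNames(cls$positional_class, cls$lncrna_id)
  expect_equal(got[["sense"]], "sense_overlap")
  expect_equal(got[["anti"]], "antisense_overlap")
  expect_equal(got[["far"]], "intergenic")
  expect_equal(got[["bidir"]], "bidirectional")
})

test_that("sense overlap outranks antisense; head-to-head beyond 1 kb is intergenic", {
  coding <- rbind(feat("gp", "chr1", 10000, 20000, "+"),
                  feat("gm", "chr1", 12000, 22000, "-"),
                  feat("g4", "chr4", 20000, 30000, "+"))
  lnc <- rbind(feat("both", "chr1", 15000, 16000, "+", "lncRNA"),
               feat("toofar", "chr4", 17000, 18900, "-", "lncRNA"))
  cls <- classify_lncrna(lnc, coding)
  expect_equal(cls$positional_class[cls$lncrna_id == "both"], "sense_overlap")
  expect_equal(cls$positional_class[cls$lncrna_id == "toofar"], "intergenic")
})

test_that("lncRNAs on chromosomes unseen in the coding annotation fall back to intergenic", {
  coding <- feat("g1", "chr1", 1000, 2000, "+")
  lnc <- feat("lone", "chrUn", 1000, 2000, "+", "lncRNA")
  expect_warning(cls <- classify_lncrna(lnc, coding), "chrUn")
  expect_equal(cls$positional_class, "intergenic")
})

test_that("classification is a partition on generated annotations", {
  sim <- generate_bundle(simulation_config(n_mrna = 80, n_lncrna = 40,
                                           n_mirna = 5, seed = 5))
  ann <- sim$bundle$annotation
  cls <- classify_lncrna(ann[ann$biotype == "lncRNA", ],
                         ann[ann$biotype == "protein_coding", ])
  expect_equal(nrow(cls), 40)
  expect_false(any(duplicated(cls$lncrna_id)))
  expect_true(all(cls$positional_class %in%
                    c("intergenic", "antisense_overlap", "sense_overlap",
                      "bidirectional")))
  # planted classes are recovered exactly
  truth <- sim$truth$planted_lncrna_classes
  expect_equal(cls$positional_class[match(truth$lncrna_id, cls$lncrna_id)],
               truth$positional_class)
})

test_that("the cis window is edge-to-edge, boundary inclusive at 300 kb", {
  linc <- feat("L", "chr1", 1000000, 1001000, "+", "lncRNA")
  gene_at_gap <- function(gap) feat("G", "chr1", 1001000 + gap, 1010000 + gap, "+")
  expect_equal(nrow(cis_targets(linc, gene_at_gap(299000))), 1)
  expect_equal(cis_targets(linc, gene_at_gap(299000))$gap, 299000)
  expect_equal(nrow(cis_targets(linc, gene_at_gap(300000))), 1)
  expect_equal(nrow(cis_targets(linc, gene_at_gap(300001))), 0)
  # overlap counts as gap 0
  expect_equal(cis_targets(linc, feat("G", "chr1", 1000500, 1002000, "-"))$gap, 0)
  expect_error(cis_targets(linc, gene_at_gap(1000), window = 0), "window")
})

test_that("cis pairing is symmetric under reflecting gene placement", {
  linc <- feat("L", "chr1", 1000000, 1001000, "+", "lncRNA")
  down <- feat("G", "chr1", 1250000, 1260000, "+")
  up <- feat("G", "chr1", 741000, 751000, "+")  # same 249 kb gap upstream
  expect_equal(cis_targets(linc, down)$gap, 249000)
  expect_equal(cis_targets(linc, up)$gap, 249000)
})

test_that("target intersections deduplicate by accession and are idempotent", {
  pairs <- data.frame(
    mirna_id = c("m1", "m2", "m1", "m1"),
    target_id = c("t1", "t1", "t2", "t2"),
    target_symbol = c("A", "A", "B", "B"),
    target_class = "mRNA", source = "db", stringsAsFactors = FALSE)
  degs <- data.frame(feature_id = c("t1", "t9"), rna_class = "mRNA",
                     fc_ratio = 2, fc_abs = 2, regulation = "up",
                     p_value = 0.01, fdr = 0.01, significant = TRUE,
                     rescued = FALSE, stringsAsFactors = FALSE)
  got <- intersect_mrna_targets(pairs, degs)
  expect_equal(nrow(got), 2)  # (m1,t1) and (m2,t1); duplicates collapsed
  expect_equal(attr(got, "n_distinct_targets"), 1)
  again <- intersect_mrna_targets(got, degs)
  expect_equal(as.data.frame(again), as.data.frame(got))
  # empty target table allowed
  empty <- intersect_mrna_targets(pairs[0, ], degs)
  expect_equal(nrow(empty), 0)
})

test_that("cis-differential pairs require both ends differential and respect the window", {
  sim <- generate_bundle(simulation_config(n_mrna = 150, n_lncrna = 60,
                                           n_mirna = 10, frac_de = 0.2,
                                           effect_fold = 4, noise_cv = 0.02,
                                           frac_absent = 0, seed = 8))
  ann <- sim$bundle$annotation
  truth <- sim$truth
  linc <- ann[ann$feature_id %in% truth$planted_lncrna_classes$lncrna_id[
    truth$planted_lncrna_classes$positional_class == "intergenic"], ]
  cis <- cis_targets(linc, ann[ann$biotype == "protein_coding", ])
  de_l <- run_de(sim$bundle$panels$lncRNA)
  de_m <- run_de(sim$bundle$panels$mRNA)
  got <- cis_differential_pairs(cis, de_l, de_m)
  want <- truth$planted_cis_pairs
  expect_setequal(paste(got$lncrna_id, got$gene_id),
                  paste(want$lncrna_id, want$gene_id))
  # no differential features -> empty
  none <- de_l; none$significant <- FALSE; none$rescued <- FALSE
  expect_equal(nrow(cis_differential_pairs(cis, none, de_m)), 0)
})
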