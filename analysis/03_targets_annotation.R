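#!/usr/bin/env Rscript
# Stage 3: positional lncRNA classification, 300-kb cis targets, and
# intersection of differential features with the miRNA target maps.

suppressMessages(library(cernaflow))

ann <- read_annotation_bed("results/bundle/annotation.bed")
de_m <- utils::read.delim("results/de_mRNA.tsv")
de_l <- utils::read.delim("results/de_lncRNA.tsv")

lnc <- ann[ann$biotype == "lncRNA", ]
coding <- ann[ann$biotype == "protein_coding", ]
cls <- classify_lncrna(lnc, coding)
utils::write.table(cls, "results/lncrna_classes.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
frac <- round(100 * table(cls$positional_class) / nrow(cls))
cat(sprintf("lncRNA classes: %s\n",
            paste(sprintf("%s %d%%", names(frac), frac), collapse = ", ")))

linc <- lnc[lnc$feature_id %in%
              cls$lncrna_id[cls$positional_class == "intergenic"], ]
cis <- cis_targets(linc, coding)
cis_de <- cis_differential_pairs(cis, de_l, de_m)
utils::write.table(cis_de, "results/cis_differential_pairs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("cis pairs within 300 kb: %d; with both ends differential: %d\n",
            nrow(cis), nrow(cis_de)))

tg_m <- read_target_table("results/bundle/targets_mrna.tsv")
tg_l <- read_target_table("results/bundle/targets_lncrna.tsv")
im <- intersect_mrna_targets(tg_m, de_m)
il <- intersect_lncrna_targets(tg_l, de_l)
utils::write.table(im, "results/intersected_mrna_targets.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(il, "results/intersected_lncrna_targets.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("target intersection: %d distinct differential mRNA targets, %d distinct differential lncRNA targets\n",
            attr(im, "n_distinct_targets"), attr(il, "n_distinct_targets")))
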