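#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study bundle.
#
# Emulates the study design downstream stages expect: two groups of three
# pooled hippocampus samples profiled on mRNA, lncRNA and miRNA panels, with
# planted differential effects, sponge-coupled ceRNA triads, a genome
# annotation realizing all four positional lncRNA classes, miRNA target maps,
# a scored gene-gene interaction table and a functional term annotation.

suppressMessages(library(cernaflow))

cfg <- simulation_config(seed = 20260921)
sim <- generate_bundle(cfg)
dir.create("results", showWarnings = FALSE)
write_bundle(sim, "results/bundle")

truth <- sim$truth
cat("Synthetic bundle written to results/bundle\n")
cat(sprintf("  features: %d mRNA, %d lncRNA, %d miRNA; %d samples per group\n",
            cfg$n_mrna, cfg$n_lncrna, cfg$n_mirna, cfg$n_per_group))
cat(sprintf("  planted differential features: %s\n",
            paste(sprintf("%s=%d", names(table(truth$de_features$rna_class)),
                          table(truth$de_features$rna_class)), collapse = ", ")))
cat(sprintf("  planted ceRNA triads: %d (%d sponge-coupled)\n",
            nrow(truth$planted_triads), sum(truth$planted_triads$coupled)))
cat(sprintf("  planted cis lincRNA-gene pairs within 300 kb: %d\n",
            nrow(truth$planted_cis_pairs)))
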