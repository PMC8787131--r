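#!/usr/bin/env Rscript
# Stage 4: tripartite network assembly, dense modules, hubs, ceRNA triads and
# term enrichment on the synthetic bundle, with planted-truth scoring.

suppressMessages(library(cernaflow))

de <- do.call(rbind, lapply(c("mRNA", "lncRNA", "miRNA"), function(cls)
  utils::read.delim(sprintf("results/de_%s.tsv", cls))))
tg_m <- read_target_table("results/bundle/targets_mrna.tsv")
tg_l <- read_target_table("results/bundle/targets_lncrna.tsv")
interactions <- read_interaction_table("results/bundle/interactions.tsv")
truth <- jsonlite::read_json("results/bundle/ground_truth.json",
                             simplifyVector = TRUE)

net <- build_network(tg_m, tg_l, de, gene_edges = interactions)
write_network_sif(net, "results/network.sif", "results/network_nodes.tsv")
cat(sprintf("network: %d nodes, %d edges (differential features only, interaction score > 0.4)\n",
            igraph::vcount(net), igraph::ecount(net)))

hubs <- hub_by_degree(net)
utils::write.table(hubs, "results/hubs.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("hub node(s): %s (degree %d)\n",
            paste(hubs$node[hubs$is_hub], collapse = ", "), hubs$degree[1]))

modules <- mine_dense_modules(net)
cat(sprintf("dense modules: %d", length(modules)))
if (length(modules) > 0) {
  cat(sprintf("; top module: %d nodes, density %.2f",
              modules[[1]]$size, modules[[1]]$density))
}
cat("\n")

triads <- extract_cerna_triads(net)
utils::write.table(triads, "results/cerna_triads.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
planted <- truth$planted_triads[truth$planted_triads$coupled, , drop = FALSE]
key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)
cat(sprintf("ceRNA triads: %d extracted; %d/%d planted sponge-coupled triads recovered\n",
            nrow(triads), sum(key(planted) %in% key(triads)), nrow(planted)))

terms <- read_gmt("results/bundle/terms.gmt")
ann <- read_annotation_bed("results/bundle/annotation.bed")
query <- unique(triads$mrna_symbol)
universe <- unique(ann$gene_symbol[ann$biotype == "protein_coding"])
if (length(query) > 0) {
  enr <- enrich(query, terms, universe)
  utils::write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf("enrichment over %d terms: best term %s (p = %.3g, FDR = %.3g)\n",
              nrow(enr), enr$term_id[1], enr$p_value[1], enr$fdr[1]))
}
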