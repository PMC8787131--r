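#' Pipeline configuration
#'
#' Bundles every knob of an end-to-end run. Two modes: \code{"synthetic"}
#' (inputs generated by [generate_bundle()]) and \code{"fixtures"} (the
#' packaged printed interaction tables drive the network stages directly).
#'
#' @param mode \code{"synthetic"} or \code{"fixtures"}.
#' @param out_dir Output directory for tables and the JSON run report.
#' @param sim A [simulation_config()] (synthetic mode).
#' @param thresholds A [de_thresholds()].
#' @param cis_window Cis-regulation window in bp (default 300000).
#' @param score_cutoff Gene-interaction confidence cutoff (default 0.4).
#' @param mcode List of [mine_dense_modules()] parameters.
#' @param gene_set Optional character vector of gene symbols restricting the
#'   ceRNA triads (functional sub-network selection), or a file path readable
#'   by [read_gene_set()].
#' @param table1_path,table2_path Fixture table paths (fixture mode); default
#'   to the packaged tables.
#' @param seed Integer seed for the run (synthetic mode reseeds the
#'   simulation config with it).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(mode = c("synthetic", "fixtures"),
                            out_dir = tempfile("cernaflow_run_"),
                            sim = simulation_config(),
                            thresholds = de_thresholds(),
                            cis_window = 300000, score_cutoff = 0.4,
                            mcode = list(), gene_set = NULL,
                            table1_path = NULL, table2_path = NULL,
                            seed = 1) {
  mode <- match.arg(mode)
  if (cis_window <= 0) stop_config("cis_window", "must be positive")
  structure(list(mode = mode, out_dir = out_dir, sim = sim,
                 thresholds = thresholds, cis_window = cis_window,
                 score_cutoff = score_cutoff, mcode = mcode,
                 gene_set = gene_set, table1_path = table1_path,
                 table2_path = table2_path, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirroring [pipeline_config()] arguments; nested \code{sim},
#' \code{thresholds} and \code{mcode} blocks map onto the respective
#' constructors.
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("sim", "thresholds"))]
  if (!is.null(y$sim)) args$sim <- do.call(simulation_config, y$sim)
  if (!is.null(y$thresholds)) {
    args$thresholds <- do.call(de_thresholds, y$thresholds)
  }
  do.call(pipeline_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input generation or fixture loading, differential
#' expression per panel, lncRNA positional classification and cis targeting,
#' target-table intersection, tripartite network assembly, dense-module and
#' hub analysis, ceRNA triad extraction with optional functional restriction,
#' and term enrichment. All tables are written under \code{config$out_dir}
#' together with \code{report.json} holding every headline count. On any
#' stage failure the partial outputs written by this run are removed.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (a named list of counts and paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }
  on_fail_cleanup <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch(
    run_pipeline_impl(config, note),
    error = on_fail_cleanup)
}

run_pipeline_impl <- function(config, note) {
  report <- list(mode = config$mode, seed = config$seed,
                 parameters = list(
                   min_abs_fc = config$thresholds$min_abs_fc,
                   max_fdr = config$thresholds$max_fdr,
                   cis_window = config$cis_window,
                   score_cutoff = config$score_cutoff))
  out <- config$out_dir
  gene_set <- config$gene_set
  if (is.character(gene_set) && length(gene_set) == 1L &&
      file.exists(gene_set)) {
    gene_set <- read_gene_set(gene_set)
  }

  if (config$mode == "fixtures") {
    fixtures <- run_stage("fixtures", {
      args <- list()
      if (!is.null(config$table1_path)) args$table1_path <- config$table1_path
      if (!is.null(config$table2_path)) args$table2_path <- config$table2_path
      suppressMessages(do.call(read_fixture_tables, args))
    })
    inputs <- run_stage("fixtures", fixtures_to_network_inputs(fixtures))
    de_records <- inputs$de_records
    mirna_mrna <- inputs$mirna_mrna
    mirna_lncrna <- inputs$mirna_lncrna
    interactions <- NULL
    inter_m <- intersect_mrna_targets(mirna_mrna, de_records)
    inter_l <- intersect_lncrna_targets(mirna_lncrna, de_records)
  } else {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    sim <- run_stage("simulate", generate_bundle(sim_cfg))
    run_stage("simulate", write_bundle(sim, note(file.path(out, "bundle"))))
    de <- run_stage("differential_expression", lapply(
      sim$bundle$panels, run_de, thresholds = config$thresholds))
    for (cls in names(de)) {
      write_tsv(de[[cls]], note(file.path(out, sprintf("de_%s.tsv", cls))))
    }
    de_records <- do.call(rbind, de)
    report$n_deg <- sum(de$mRNA$significant | de$mRNA$rescued)
    report$n_deg_up <- sum((de$mRNA$significant | de$mRNA$rescued) &
                             de$mRNA$regulation == "up")
    report$n_deg_down <- report$n_deg - report$n_deg_up
    report$n_del <- sum(de$lncRNA$significant | de$lncRNA$rescued)
    report$n_del_up <- sum((de$lncRNA$significant | de$lncRNA$rescued) &
                             de$lncRNA$regulation == "up")
    report$n_del_down <- report$n_del - report$n_del_up
    report$n_dem <- sum(de$miRNA$significant | de$miRNA$rescued)

    ann <- sim$bundle$annotation
    lnc <- ann[ann$biotype == "lncRNA", ]
    coding <- ann[ann$biotype == "protein_coding", ]
    cls_tab <- run_stage("annotation", classify_lncrna(lnc, coding))
    write_tsv(cls_tab, note(file.path(out, "lncrna_classes.tsv")))
    report$lncrna_class_fractions <- as.list(
      table(cls_tab$positional_class) / nrow(cls_tab))
    linc <- lnc[lnc$feature_id %in%
                  cls_tab$lncrna_id[cls_tab$positional_class == "intergenic"], ]
    cis <- run_stage("annotation",
                     cis_targets(linc, coding, config$cis_window))
    cis_de <- cis_differential_pairs(cis, de$lncRNA, de$mRNA)
    write_tsv(cis_de, note(file.path(out, "cis_differential_pairs.tsv")))
    report$n_cis_pairs <- nrow(cis)
    report$n_cis_differential_pairs <- nrow(cis_de)

    mirna_mrna <- sim$bundle$targets_mrna
    mirna_lncrna <- sim$bundle$targets_lncrna
    interactions <- sim$bundle$interactions
    inter_m <- run_stage("intersect",
                         intersect_mrna_targets(mirna_mrna, de$mRNA))
    inter_l <- run_stage("intersect",
                         intersect_lncrna_targets(mirna_lncrna, de$lncRNA))
  }

  report$intersected_mRNAs <- attr(inter_m, "n_distinct_targets")
  report$intersected_lncRNAs <- attr(inter_l, "n_distinct_targets")
  write_tsv(inter_m, note(file.path(out, "intersected_mrna_targets.tsv")))
  write_tsv(inter_l, note(file.path(out, "intersected_lncrna_targets.tsv")))

  net <- run_stage("network", suppressMessages(
    build_network(mirna_mrna, mirna_lncrna, de_records,
                  gene_edges = interactions,
                  score_cutoff = config$score_cutoff)))
  write_network_sif(net, note(file.path(out, "network.sif")),
                    note(file.path(out, "network_nodes.tsv")))
  report$network_nodes <- igraph::vcount(net)
  report$network_edges <- igraph::ecount(net)

  if (igraph::vcount(net) > 0L) {
    hubs <- run_stage("network", hub_by_degree(net))
    write_tsv(hubs, note(file.path(out, "hubs.tsv")))
    report$hub_nodes <- hubs$node[hubs$is_hub]
    report$hub_degree <- max(hubs$degree)
    modules <- run_stage("network", do.call(
      mine_dense_modules, c(list(net), config$mcode)))
    report$n_dense_modules <- length(modules)
    triads <- run_stage("cerna", extract_cerna_triads(net))
  } else {
    report$hub_nodes <- character(0)
    report$hub_degree <- 0L
    report$n_dense_modules <- 0L
    triads <- extract_cerna_triads(net)
  }
  write_tsv(triads, note(file.path(out, "cerna_triads.tsv")))
  report$n_cerna_triads <- nrow(triads)
  if (!is.null(gene_set)) {
    restricted <- run_stage("cerna", restrict_by_function(triads, gene_set))
    write_tsv(restricted, note(file.path(out, "cerna_triads_restricted.tsv")))
    report$n_cerna_triads_restricted <- nrow(restricted)
  }

  if (config$mode == "synthetic") {
    query <- unique(inter_m$target_symbol)
    universe <- unique(sim$bundle$annotation$gene_symbol[
      sim$bundle$annotation$biotype == "protein_coding"])
    if (length(query) > 0L) {
      enr <- run_stage("enrichment",
                       enrich(query, sim$bundle$terms, universe))
      write_tsv(enr, note(file.path(out, "enrichment.tsv")))
      report$n_enriched_terms_fdr05 <- sum(enr$fdr < 0.05)
    }
  }

  report_path <- note(file.path(out, "report.json"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
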