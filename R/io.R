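# Readers and writers for the pipeline's delimited formats. All tables are
# tab-delimited UTF-8 with a header row.

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# parse a numeric column, reporting the first offending row
parse_numeric_column <- function(x, column, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L) {
    stop(sprintf("%s: malformed numeric value '%s' in column '%s' at row %d",
                 what, x[bad[1]], column, bad[1]), call. = FALSE)
  }
  out
}

#' Write an intensity panel to a directory
#'
#' Writes \code{foreground.tsv}, \code{background.tsv}, \code{flags.tsv}
#' (feature_id column plus one column per sample) and \code{design.tsv}
#' (sample, group).
#'
#' @param panel An [intensity_panel()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_intensity_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_df <- function(m) data.frame(feature_id = rownames(m), m,
                                   check.names = FALSE,
                                   stringsAsFactors = FALSE)
  write_tsv(mat_df(panel$foreground), file.path(dir, "foreground.tsv"))
  write_tsv(mat_df(panel$background), file.path(dir, "background.tsv"))
  write_tsv(mat_df(panel$flags), file.path(dir, "flags.tsv"))
  write_tsv(data.frame(sample = names(panel$design),
                       group = unname(panel$design)),
            file.path(dir, "design.tsv"))
  invisible(dir)
}

#' Read an intensity panel from a directory
#'
#' @param dir Directory written by [write_intensity_panel()].
#' @param rna_class RNA class of the panel.
#' @return An [intensity_panel()].
#' @export
read_intensity_panel <- function(dir, rna_class) {
  read_mat <- function(name, numeric = TRUE) {
    df <- read_tsv_checked(file.path(dir, name), "intensity panel")
    ids <- df$feature_id
    m <- as.matrix(df[, -1, drop = FALSE])
    if (numeric) storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
  design_df <- read_tsv_checked(file.path(dir, "design.tsv"), "design")
  intensity_panel(read_mat("foreground.tsv"), read_mat("background.tsv"),
                  read_mat("flags.tsv", numeric = FALSE),
                  stats::setNames(design_df$group, design_df$sample),
                  rna_class)
}

#' Write a genomic annotation as a BED-like file plus symbol map
#'
#' The BED-like dialect has six columns (chrom, start, end, feature_id,
#' biotype, strand; 0-based half-open, no header); gene symbols go to a
#' two-column sidecar \code{<path>.symbols.tsv}.
#'
#' @param features Genomic feature table (see [genomic_features()]).
#' @param path Output BED path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_bed <- function(features, path) {
  features <- genomic_features(features)
  utils::write.table(
    features[, c("chrom", "start", "end", "feature_id", "biotype", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(features[, c("feature_id", "gene_symbol")],
            paste0(path, ".symbols.tsv"))
  invisible(path)
}

#' Read a BED-like annotation plus symbol map
#'
#' @param path BED path written by [write_annotation_bed()].
#' @return Genomic feature table.
#' @export
read_annotation_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "feature_id", "biotype", "strand"))
  sym <- read_tsv_checked(paste0(path, ".symbols.tsv"), "symbol map")
  df <- merge(bed, sym, by = "feature_id", sort = FALSE)
  genomic_features(df[, c("feature_id", "gene_symbol", "chrom", "start",
                          "end", "strand", "biotype")])
}

#' Read a miRNA target table
#'
#' @param path Tab-delimited file with columns mirna_id, target_id,
#'   target_symbol, target_class, source.
#' @return Validated target table (see [target_pairs()]).
#' @export
read_target_table <- function(path) {
  target_pairs(read_tsv_checked(path, "target table"))
}

#' Read a gene-gene interaction table
#'
#' @param path Tab-delimited file with columns node_a, node_b, score.
#' @return data.frame with scores parsed and validated to [0, 1].
#' @export
read_interaction_table <- function(path) {
  df <- read_tsv_checked(path, "interaction table")
  assert_columns(df, c("node_a", "node_b", "score"), "interaction table")
  df$score <- parse_numeric_column(as.character(df$score), "score",
                                   "interaction table")
  if (any(df$score < 0 | df$score > 1)) {
    stop("interaction scores must lie in [0, 1]", call. = FALSE)
  }
  df
}

#' Read a GMT-style term annotation
#'
#' Each line: term_id, term_name (optionally \code{name|category}), then
#' member gene symbols, tab-separated.
#'
#' @param path GMT file path.
#' @return Term annotation table (see [term_annotation()]).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop(sprintf("GMT line has fewer than 3 fields: '%s'",
                   substr(line, 1, 40)), call. = FALSE)
    }
    desc <- strsplit(parts[2], "|", fixed = TRUE)[[1]]
    data.frame(term_id = parts[1], term_name = desc[1],
               category = if (length(desc) > 1) desc[2] else "custom",
               gene = parts[-(1:2)], stringsAsFactors = FALSE)
  })
  term_annotation(do.call(rbind, rows))
}

#' Write a term annotation as GMT
#'
#' @param terms Term annotation table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(terms, path) {
  terms <- term_annotation(terms)
  lines <- vapply(split(terms, terms$term_id), function(t) {
    paste(c(t$term_id[1], paste(t$term_name[1], t$category[1], sep = "|"),
            t$gene), collapse = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a one-symbol-per-line gene set
#'
#' @param path File with one gene symbol per line.
#' @return Character vector.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Export a network as a SIF-style edge list plus node attributes
#'
#' @param network Graph from [build_network()].
#' @param sif_path Output path for the (node_a, edge_type, node_b) table.
#' @param nodes_path Output path for the node-attribute table.
#' @return \code{sif_path}, invisibly.
#' @export
write_network_sif <- function(network, sif_path, nodes_path) {
  e <- igraph::as_data_frame(network, what = "edges")
  utils::write.table(data.frame(node_a = e$from, edge_type = e$type,
                                node_b = e$to),
                     sif_path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  v <- igraph::as_data_frame(network, what = "vertices")
  write_tsv(v, nodes_path)
  invisible(sif_path)
}

#' Write a full synthetic bundle to disk
#'
#' Writes the three intensity panels, annotation, target tables, interaction
#' table, term annotation (GMT) and the ground truth as JSON, in the formats
#' the pipeline reads back.
#'
#' @param sim List with \code{bundle} and \code{truth} from
#'   [generate_bundle()].
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- sim$bundle
  for (cls in names(b$panels)) {
    write_intensity_panel(b$panels[[cls]], file.path(dir, paste0("panel_", cls)))
  }
  write_annotation_bed(b$annotation, file.path(dir, "annotation.bed"))
  write_tsv(b$targets_mrna, file.path(dir, "targets_mrna.tsv"))
  write_tsv(b$targets_lncrna, file.path(dir, "targets_lncrna.tsv"))
  write_tsv(b$interactions, file.path(dir, "interactions.tsv"))
  write_gmt(b$terms, file.path(dir, "terms.gmt"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read packaged or external miRNA-target fixture tables
#'
#' Parses the two printed interaction tables shipped with the package (or
#' compatible files): miRNA rows paired with their differentially expressed
#' mRNA targets (table 1) and lncRNA targets (table 2). Numeric fields are
#' validated with row-level error reporting.
#'
#' @param table1_path,table2_path Paths; default to the packaged fixtures.
#' @return A \code{fixture_tables} list with elements \code{table1} and
#'   \code{table2}.
#' @export
read_fixture_tables <- function(
    table1_path = system.file("extdata", "table1_mirna_mrna.tsv",
                              package = "cernaflow"),
    table2_path = system.file("extdata", "table2_mirna_lncrna.tsv",
                              package = "cernaflow")) {
  parse_one <- function(path, what) {
    df <- read_tsv_checked(path, what)
    assert_columns(df, c("mirna_id", "mirna_name", "mirna_fc", "mirna_fdr",
                         "mirna_regulation", "mirna_raw_p_lt_0.05",
                         "target_seqname", "target_symbol", "target_fc_abs",
                         "target_fdr", "target_regulation"), what)
    for (col in c("mirna_fc", "mirna_fdr", "target_fc_abs", "target_fdr")) {
      df[[col]] <- parse_numeric_column(as.character(df[[col]]), col, what)
    }
    for (col in c("mirna_regulation", "target_regulation")) {
      bad <- which(!df[[col]] %in% c("Up", "Down"))
      if (length(bad) > 0L) {
        stop(sprintf("%s: regulation must be 'Up' or 'Down' at row %d",
                     what, bad[1]), call. = FALSE)
      }
    }
    if (any(df$target_fc_abs < 1)) {
      stop(sprintf("%s: absolute fold change must be >= 1", what),
           call. = FALSE)
    }
    if (any(df$target_fdr <= 0 | df$target_fdr >= 1)) {
      stop(sprintf("%s: FDR must lie in (0, 1)", what), call. = FALSE)
    }
    df$mirna_raw_p_lt_0.05 <- as.logical(df$`mirna_raw_p_lt_0.05`)
    df
  }
  t1 <- parse_one(table1_path, "miRNA-mRNA fixture")
  t2 <- parse_one(table2_path, "miRNA-lncRNA fixture")
  message(sprintf("fixture tables: %d miRNA-mRNA rows, %d miRNA-lncRNA rows",
                  nrow(t1), nrow(t2)))
  structure(list(table1 = t1, table2 = t2), class = "fixture_tables")
}

#' Convert fixture tables into network inputs
#'
#' Each fixture row becomes one target pair; miRNAs and targets become
#' differential records with directions taken from the printed Regulation
#' columns (duplicates collapsed by accession). miRNAs whose FDR misses the
#' 0.05 cutoff but whose raw p-value is flagged below 0.05 are marked
#' \code{rescued}; everything else is \code{significant}. Conflicting
#' directions for one accession raise a consistency error.
#'
#' @param fixtures A \code{fixture_tables} object from
#'   [read_fixture_tables()].
#' @return List with \code{de_records} (combined differential records),
#'   \code{mirna_mrna} and \code{mirna_lncrna} target tables.
#' @export
fixtures_to_network_inputs <- function(fixtures) {
  stopifnot(inherits(fixtures, "fixture_tables"))
  both <- rbind(
    cbind(fixtures$table1, target_class = "mRNA", stringsAsFactors = FALSE),
    cbind(fixtures$table2, target_class = "lncRNA", stringsAsFactors = FALSE))

  rec <- function(id, class, fc_ratio, fc_abs, p_known_small, fdr) {
    data.frame(feature_id = id, rna_class = class, fc_ratio = fc_ratio,
               fc_abs = fc_abs,
               regulation = ifelse(fc_ratio > 1, "up", "down"),
               p_value = NA_real_, fdr = fdr,
               significant = fdr < 0.05,
               rescued = fdr >= 0.05 & p_known_small,
               stringsAsFactors = FALSE)
  }
  check_consistent <- function(df, id_col, dir_col, what) {
    tab <- unique(df[, c(id_col, dir_col)])
    dup <- tab[[id_col]][duplicated(tab[[id_col]])]
    if (length(dup) > 0L) {
      stop(sprintf("conflicting %s directions for accession %s", what,
                   dup[1]), call. = FALSE)
    }
  }
  check_consistent(both, "mirna_name", "mirna_regulation", "miRNA")
  check_consistent(both, "target_seqname", "target_regulation", "target")

  mi <- both[!duplicated(both$mirna_name), ]
  de_mirna <- rec(mi$mirna_name, "miRNA", mi$mirna_fc,
                  pmax(mi$mirna_fc, 1 / mi$mirna_fc),
                  mi$`mirna_raw_p_lt_0.05`, mi$mirna_fdr)
  tg <- both[!duplicated(both$target_seqname), ]
  fc_dirled <- ifelse(tg$target_regulation == "Up", tg$target_fc_abs,
                      1 / tg$target_fc_abs)
  de_target <- rec(tg$target_seqname, ifelse(tg$target_class == "mRNA",
                                             "mRNA", "lncRNA"),
                   fc_dirled, tg$target_fc_abs, FALSE, tg$target_fdr)
  pairs <- function(df, class) {
    out <- unique(data.frame(
      mirna_id = df$mirna_name, target_id = df$target_seqname,
      target_symbol = df$target_symbol, target_class = class,
      source = "fixture", stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
  }
  list(de_records = rbind(de_mirna, de_target),
       mirna_mrna = pairs(fixtures$table1, "mRNA"),
       mirna_lncrna = pairs(fixtures$table2, "lncRNA"))
}
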