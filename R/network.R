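#' Assemble the tripartite lncRNA-miRNA-mRNA regulatory network
#'
#' Nodes are differential features; edges are miRNA->mRNA and miRNA->lncRNA
#' target relations plus gene-gene interaction edges passing the confidence
#' cutoff (strictly greater than \code{score_cutoff}). Gene-gene edges are
#' given at the gene-symbol level and are expanded onto all mRNA transcript
#' nodes carrying those symbols. Edges touching a non-differential feature are
#' dropped (count reported via a message). The graph is simple: duplicate
#' target rows collapse to one edge.
#'
#' @param mirna_mrna,mirna_lncrna Target tables (see [target_pairs()]).
#' @param de_records Combined differential records across RNA classes
#'   (rows for miRNAs, mRNAs and lncRNAs).
#' @param gene_edges Optional data.frame with \code{node_a}, \code{node_b}
#'   (gene symbols) and \code{score} in [0, 1].
#' @param score_cutoff Interaction-confidence cutoff (default 0.4, strict).
#' @return An undirected \pkg{igraph} graph with vertex attributes
#'   \code{rna_class}, \code{symbol}, \code{direction} and edge attribute
#'   \code{type} in \code{mirna_mrna}, \code{mirna_lncrna}, \code{mrna_mrna}.
#' @export
build_network <- function(mirna_mrna, mirna_lncrna, de_records,
                          gene_edges = NULL, score_cutoff = 0.4) {
  de <- de_records[de_records$significant | de_records$rescued, , drop = FALSE]
  de_ids <- de$feature_id
  dir_of <- stats::setNames(de$regulation, de$feature_id)
  class_of <- stats::setNames(de$rna_class, de$feature_id)

  edge_rows <- function(pairs, type, class) {
    pairs <- target_pairs(pairs)
    pairs <- pairs[pairs$target_class == class, , drop = FALSE]
    ok <- pairs$mirna_id %in% de_ids & pairs$target_id %in% de_ids
    list(kept = data.frame(from = pairs$mirna_id[ok], to = pairs$target_id[ok],
                           type = rep(type, sum(ok)),
                           symbol = pairs$target_symbol[ok],
                           stringsAsFactors = FALSE),
         dropped = sum(!ok))
  }
  em <- edge_rows(mirna_mrna, "mirna_mrna", "mRNA")
  el <- edge_rows(mirna_lncrna, "mirna_lncrna", "lncRNA")
  symbol_of <- stats::setNames(c(em$kept$symbol, el$kept$symbol),
                               c(em$kept$to, el$kept$to))
  dropped <- em$dropped + el$dropped

  gg <- data.frame(from = character(0), to = character(0), type = character(0),
                   stringsAsFactors = FALSE)
  if (!is.null(gene_edges) && nrow(gene_edges) > 0L) {
    assert_columns(gene_edges, c("node_a", "node_b", "score"),
                   "gene interaction table")
    if (any(gene_edges$score < 0 | gene_edges$score > 1)) {
      stop("interaction scores must lie in [0, 1]", call. = FALSE)
    }
    ge <- gene_edges[gene_edges$score > score_cutoff, , drop = FALSE]
    # map symbols onto differential mRNA transcript nodes
    mrna_ids <- de$feature_id[de$rna_class == "mRNA"]
    sym_map <- split(intersect(mrna_ids, names(symbol_of)),
                     symbol_of[intersect(mrna_ids, names(symbol_of))])
    # fall back to symbols recorded on the de records themselves
    if (length(sym_map) == 0L && "gene_symbol" %in% names(de)) {
      sym_map <- split(mrna_ids, de$gene_symbol[de$rna_class == "mRNA"])
    }
    for (k in seq_len(nrow(ge))) {
      a <- sym_map[[ge$node_a[k]]]
      b <- sym_map[[ge$node_b[k]]]
      if (is.null(a) || is.null(b)) { dropped <- dropped + 1L; next }
      grid <- expand.grid(from = a, to = b, stringsAsFactors = FALSE)
      grid <- grid[grid$from != grid$to, , drop = FALSE]
      if (nrow(grid) > 0L) {
        gg <- rbind(gg, data.frame(grid, type = "mrna_mrna",
                                   stringsAsFactors = FALSE))
      }
    }
  }
  if (dropped > 0L) {
    message(sprintf("build_network: dropped %d edge(s) referencing non-differential nodes",
                    dropped))
  }

  edges <- rbind(em$kept[, c("from", "to", "type")],
                 el$kept[, c("from", "to", "type")], gg)
  nodes <- unique(c(edges$from, edges$to))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes,
                          rna_class = unname(class_of[nodes]),
                          symbol = unname(ifelse(nodes %in% names(symbol_of),
                                                 symbol_of[nodes], nodes)),
                          direction = unname(dir_of[nodes]),
                          stringsAsFactors = FALSE))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(type = "first"))
}

#' Rank network nodes by degree and flag hubs
#'
#' Nodes are ranked by decreasing degree with ties broken lexicographically;
#' every node attaining the maximum degree is flagged a hub.
#'
#' @param network An \pkg{igraph} graph.
#' @return data.frame with \code{node}, \code{degree}, \code{is_hub}, ordered
#'   by rank.
#' @export
hub_by_degree <- function(network) {
  if (igraph::vcount(network) == 0L) {
    stop("cannot rank hubs in an empty network", call. = FALSE)
  }
  deg <- igraph::degree(network)
  ord <- order(-deg, names(deg))
  out <- data.frame(node = names(deg)[ord], degree = unname(deg[ord]),
                    stringsAsFactors = FALSE)
  out$is_hub <- out$degree == max(out$degree)
  rownames(out) <- NULL
  out
}

# MCODE vertex weighting: weight(v) = kmax * density of the kmax-core of the
# closed neighborhood of v; vertices below the degree cutoff score 0.
mcode_vertex_weights <- function(g, degree_cutoff = 2) {
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  for (v in igraph::V(g)$name) {
    if (deg[v] < degree_cutoff) next
    nb <- igraph::induced_subgraph(
      g, c(v, igraph::neighbors(g, v)$name))
    core <- igraph::coreness(nb)
    kmax <- max(core)
    sub <- igraph::induced_subgraph(nb, names(core)[core == kmax])
    dens <- igraph::edge_density(sub)
    if (is.nan(dens) || is.na(dens)) dens <- 0
    w[v] <- kmax * dens
  }
  w
}

#' Mine dense modules (MCODE-style)
#'
#' Greedy dense-subgraph mining on the undirected projection of the network:
#' (1) every vertex is weighted by the product of its neighborhood's highest
#' k-core number and that core's edge density (vertices below
#' \code{degree_cutoff} score 0); (2) complexes grow outward from the
#' highest-weight unassigned seed, including neighbors whose weight is at
#' least \code{(1 - node_score_cutoff)} times the seed weight; (3) complexes
#' lacking a \code{k_core}-core are discarded and, with \code{haircut},
#' tree-like fringes are trimmed to the 2-core. Modules are ranked by
#' density x size.
#'
#' @param network An \pkg{igraph} graph (treated as undirected and simple).
#' @param degree_cutoff Minimum vertex degree to receive a weight (default 2).
#' @param node_score_cutoff Fractional weight tolerance for inclusion relative
#'   to the seed (default 0.2).
#' @param k_core Minimum core a module must contain (default 2).
#' @param haircut Trim singly-connected fringe vertices (default TRUE).
#' @return List of modules, each a list with \code{members}, \code{density},
#'   \code{size}, \code{score}, \code{rank}; empty list for graphs with fewer
#'   than 3 vertices.
#' @export
mine_dense_modules <- function(network, degree_cutoff = 2,
                               node_score_cutoff = 0.2, k_core = 2,
                               haircut = TRUE) {
  g <- igraph::as_undirected(igraph::simplify(network), mode = "collapse")
  if (igraph::vcount(g) < 3L) return(list())
  w <- mcode_vertex_weights(g, degree_cutoff)
  assigned <- character(0)
  modules <- list()
  repeat {
    cand <- setdiff(names(w)[w > 0], assigned)
    if (length(cand) == 0L) break
    seed <- cand[order(-w[cand], cand)][1]
    thr <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    frontier <- seed
    while (length(frontier) > 0L) {
      nb <- unique(unlist(lapply(frontier, function(v)
        igraph::neighbors(g, v)$name)))
      nb <- setdiff(nb, c(members, assigned))
      nb <- nb[w[nb] >= thr]
      members <- c(members, nb)
      frontier <- nb
    }
    assigned <- c(assigned, members)
    sub <- igraph::induced_subgraph(g, members)
    core <- igraph::coreness(sub)
    if (max(core) < k_core) next
    if (haircut) {
      keep <- names(core)[core >= 2]
      if (length(keep) < 2L) next
      sub <- igraph::induced_subgraph(sub, keep)
      members <- keep
    }
    dens <- igraph::edge_density(sub)
    modules[[length(modules) + 1L]] <- list(
      members = sort(members), density = dens,
      size = length(members), score = dens * length(members))
  }
  if (length(modules) == 0L) return(modules)
  ord <- order(-vapply(modules, `[[`, numeric(1), "score"))
  modules <- modules[ord]
  for (i in seq_along(modules)) modules[[i]]$rank <- i
  modules
}

#' Extract sponge-consistent ceRNA triads
#'
#' For every miRNA node, emits one (lncRNA, miRNA, mRNA) triad per pair of a
#' lncRNA target and an mRNA target whose differential directions are both
#' opposite to the miRNA's (the sponge rule: a miRNA negatively regulates its
#' targets, so a ceRNA triad requires anti-correlated directions). Output is
#' ordered lexicographically by (miRNA, lncRNA, mRNA).
#'
#' @param network Graph built by [build_network()] (node \code{direction}
#'   attributes required).
#' @return data.frame with \code{lncrna_id}, \code{mirna_id}, \code{mrna_id},
#'   \code{mrna_symbol} and the three direction columns.
#' @export
extract_cerna_triads <- function(network) {
  empty <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), mrna_symbol = character(0),
                      mirna_direction = character(0),
                      lncrna_direction = character(0),
                      mrna_direction = character(0), stringsAsFactors = FALSE)
  if (igraph::vcount(network) == 0L) return(empty)
  v <- igraph::as_data_frame(network, what = "vertices")
  e <- igraph::as_data_frame(network, what = "edges")
  dir_of <- stats::setNames(v$direction, v$name)
  sym_of <- stats::setNames(v$symbol, v$name)
  out <- list()
  for (m in v$name[v$rna_class == "miRNA"]) {
    inc <- e[e$from == m | e$to == m, , drop = FALSE]
    other <- ifelse(inc$from == m, inc$to, inc$from)
    gs <- other[inc$type == "mirna_mrna"]
    ls <- other[inc$type == "mirna_lncrna"]
    gs <- gs[!is.na(dir_of[gs]) & dir_of[gs] != dir_of[m]]
    ls <- ls[!is.na(dir_of[ls]) & dir_of[ls] != dir_of[m]]
    if (length(gs) == 0L || length(ls) == 0L) next
    grid <- expand.grid(lncrna_id = ls, mrna_id = gs,
                        stringsAsFactors = FALSE)
    out[[m]] <- data.frame(
      lncrna_id = grid$lncrna_id, mirna_id = m, mrna_id = grid$mrna_id,
      mrna_symbol = unname(sym_of[grid$mrna_id]),
      mirna_direction = unname(dir_of[m]),
      lncrna_direction = unname(dir_of[grid$lncrna_id]),
      mrna_direction = unname(dir_of[grid$mrna_id]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$mirna_id, res$lncrna_id, res$mrna_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Restrict ceRNA triads to a functional gene set
#'
#' Keeps triads whose mRNA gene symbol belongs to \code{term_genes}; lncRNAs
#' and miRNAs persist only through their remaining triads. An empty gene set
#' yields an empty result.
#'
#' @param triads Output of [extract_cerna_triads()].
#' @param term_genes Character vector of gene symbols.
#' @return Filtered triad data.frame.
#' @export
restrict_by_function <- function(triads, term_genes) {
  out <- triads[triads$mrna_symbol %in% term_genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}
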