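# Shared builders and independent oracles used across the suite.

# minimal panel from a matrix of net (foreground - background) values
make_panel <- function(net, rna_class = "mRNA", bg_value = 30,
                       flags = NULL,
                       groups = rep(c("depression", "healthy"),
                                    length.out = ncol(net))) {
  if (is.null(rownames(net))) rownames(net) <- sprintf("f%02d", seq_len(nrow(net)))
  if (is.null(colnames(net))) colnames(net) <- sprintf("s%02d", seq_len(ncol(net)))
  bg <- matrix(bg_value, nrow(net), ncol(net), dimnames = dimnames(net))
  if (is.null(flags)) {
    flags <- matrix("P", nrow(net), ncol(net), dimnames = dimnames(net))
  }
  intensity_panel(bg + net, bg, flags, stats::setNames(groups, colnames(net)),
                  rna_class)
}

# brute-force step-up BH evaluated directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(sorted[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# textbook Welch t p-value (Satterthwaite df), independent of stats::t.test
welch_oracle <- function(x, y) {
  sx <- stats::var(x) / length(x)
  sy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# exhaustive triad enumeration over all vertex triples of a network
triads_oracle <- function(network) {
  v <- igraph::as_data_frame(network, what = "vertices")
  e <- igraph::as_data_frame(network, what = "edges")
  ekey <- c(paste(e$from, e$to, e$type), paste(e$to, e$from, e$type))
  has_edge <- function(a, b, type) paste(a, b, type) %in% ekey
  out <- expand.grid(lncrna_id = v$name[v$rna_class == "lncRNA"],
                     mirna_id = v$name[v$rna_class == "miRNA"],
                     mrna_id = v$name[v$rna_class == "mRNA"],
                     stringsAsFactors = FALSE)
  dir_of <- stats::setNames(v$direction, v$name)
  keep <- vapply(seq_len(nrow(out)), function(i) {
    l <- out$lncrna_id[i]; m <- out$mirna_id[i]; g <- out$mrna_id[i]
    has_edge(m, g, "mirna_mrna") && has_edge(m, l, "mirna_lncrna") &&
      dir_of[m] != dir_of[g] && dir_of[m] != dir_of[l]
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$mirna_id, out$lncrna_id, out$mrna_id), , drop = FALSE]
  data.frame(lncrna_id = out$lncrna_id, mirna_id = out$mirna_id,
             mrna_id = out$mrna_id, stringsAsFactors = FALSE)
}

# random tripartite network with directions, for oracle comparisons
random_tripartite <- function(n_mirna, n_mrna, n_lncrna, p_edge = 0.3) {
  mir <- sprintf("mir%02d", seq_len(n_mirna))
  mrna <- sprintf("g%03d", seq_len(n_mrna))
  lnc <- sprintf("l%03d", seq_len(n_lncrna))
  nodes <- c(mir, mrna, lnc)
  v <- data.frame(
    name = nodes,
    rna_class = rep(c("miRNA", "mRNA", "lncRNA"),
                    c(n_mirna, n_mrna, n_lncrna)),
    symbol = nodes,
    direction = sample(c("up", "down"), length(nodes), replace = TRUE),
    stringsAsFactors = FALSE)
  eg <- rbind(
    expand.grid(from = mir, to = mrna, stringsAsFactors = FALSE),
    expand.grid(from = mir, to = lnc, stringsAsFactors = FALSE))
  eg <- eg[stats::runif(nrow(eg)) < p_edge, , drop = FALSE]
  eg$type <- ifelse(eg$to %in% mrna, "mirna_mrna", "mirna_lncrna")
  igraph::graph_from_data_frame(eg, directed = FALSE, vertices = v)
}

# exact hypergeometric upper tail by direct pmf summation
hyper_oracle <- function(overlap, term_size, universe_size, query_size) {
  xs <- overlap:min(term_size, query_size)
  sum(stats::dhyper(xs, term_size, universe_size - term_size, query_size))
}

triad_key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)

default_gene_set <- c("Adcy1", "Nr4a2", "Six4", "Stx16", "Ube3a")
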