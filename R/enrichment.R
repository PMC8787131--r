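#' Validate a term annotation table
#'
#' @param df data.frame with columns \code{term_id}, \code{term_name},
#'   \code{category} (one of biological_process, cellular_component,
#'   molecular_function, pathway, custom) and \code{gene} (one row per term
#'   member gene symbol).
#' @return The validated data.frame.
#' @export
term_annotation <- function(df) {
  assert_columns(df, c("term_id", "term_name", "category", "gene"),
                 "term annotation")
  ok <- c("biological_process", "cellular_component", "molecular_function",
          "pathway", "custom")
  if (!all(df$category %in% ok)) {
    stop(sprintf("category must be one of: %s", paste(ok, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("term annotation has no members", call. = FALSE)
  df
}

#' Hypergeometric term over-representation
#'
#' For each term, the p-value is the upper-tail hypergeometric probability of
#' drawing at least the observed overlap when sampling \code{|query|} genes
#' without replacement from the universe. Term memberships are intersected
#' with the universe first; p-values are BH-adjusted across terms and results
#' are sorted by p.
#'
#' @param query Character vector of gene symbols (must lie in the universe).
#' @param annotation Term annotation table (see [term_annotation()]).
#' @param universe Character vector of background gene symbols.
#' @return data.frame with \code{term_id}, \code{term_name}, \code{category},
#'   \code{overlap}, \code{term_size}, \code{query_size}, \code{universe_size},
#'   \code{p_value}, \code{fdr}.
#' @export
enrich <- function(query, annotation, universe) {
  annotation <- term_annotation(annotation)
  query <- unique(query)
  universe <- unique(universe)
  if (length(query) == 0L || length(universe) == 0L) {
    stop("query and universe must be nonempty", call. = FALSE)
  }
  if (!all(query %in% universe)) {
    stop("query genes must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  k <- length(query)
  terms <- split(annotation$gene, annotation$term_id)
  meta <- annotation[!duplicated(annotation$term_id),
                     c("term_id", "term_name", "category")]
  rows <- lapply(meta$term_id, function(tid) {
    members <- intersect(unique(terms[[tid]]), universe)
    K <- length(members)
    x <- length(intersect(members, query))
    p <- if (K == 0L) 1 else
      stats::phyper(x - 1, K, N - K, k, lower.tail = FALSE)
    data.frame(term_id = tid, overlap = x, term_size = K, query_size = k,
               universe_size = N, p_value = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- merge(meta, out, by = "term_id", sort = FALSE)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
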