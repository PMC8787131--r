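#' Validate a genomic feature table
#'
#' Features are stranded intervals in 0-based half-open coordinates with a
#' biotype. Used both for protein-coding genes and for non-coding features.
#'
#' @param df data.frame with columns \code{feature_id}, \code{gene_symbol},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{biotype}.
#' @return The validated data.frame (invisibly identical content).
#' @export
genomic_features <- function(df) {
  assert_columns(df, c("feature_id", "gene_symbol", "chrom", "start", "end",
                       "strand", "biotype"), "genomic feature table")
  if (any(df$start >= df$end)) {
    stop("genomic features require start < end (0-based half-open)",
         call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (!all(df$biotype %in% c("protein_coding", "lncRNA", "miRNA"))) {
    stop("biotype must be protein_coding, lncRNA or miRNA", call. = FALSE)
  }
  df
}

# 0-based half-open feature table -> GRanges (1-based closed internally).
# seqlevels can be supplied so two annotations share a common genome space.
features_to_granges <- function(df, seqlevels = unique(df$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand,
    feature_id = df$feature_id
  )
}

#' Positional classification of lncRNAs against protein-coding genes
#'
#' Each lncRNA receives exactly one class by precedence:
#' \describe{
#'   \item{sense_overlap}{interval overlaps a coding gene on the same strand}
#'   \item{antisense_overlap}{overlaps coding genes on the opposite strand only}
#'   \item{bidirectional}{no overlap, but a coding gene's 5' start lies
#'     head-to-head (divergent, opposite strand) within
#'     \code{bidirectional_window} bp of the lncRNA's 5' start}
#'   \item{intergenic}{none of the above}
#' }
#' lncRNAs on chromosomes absent from the coding annotation are classified
#' intergenic with a warning.
#'
#' @param lncrnas,coding Genomic feature tables (see [genomic_features()]).
#' @param bidirectional_window Head-to-head promoter distance in bp (default
#'   1000, the conventional bidirectional-promoter window).
#' @return data.frame with \code{lncrna_id} and \code{positional_class}.
#' @export
classify_lncrna <- function(lncrnas, coding, bidirectional_window = 1000) {
  lncrnas <- genomic_features(lncrnas)
  coding <- genomic_features(coding)
  unknown <- setdiff(unique(lncrnas$chrom), unique(coding$chrom))
  if (length(unknown) > 0L) {
    warning(sprintf("chromosome(s) %s absent from coding annotation; lncRNAs there treated as intergenic",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  chroms <- union(unique(lncrnas$chrom), unique(coding$chrom))
  gl <- features_to_granges(lncrnas, chroms)
  gc <- features_to_granges(coding, chroms)
  hits <- GenomicRanges::findOverlaps(gl, gc, ignore.strand = TRUE)
  same <- as.character(GenomicRanges::strand(gl))[S4Vectors::queryHits(hits)] ==
    as.character(GenomicRanges::strand(gc))[S4Vectors::subjectHits(hits)]
  sense_idx <- unique(S4Vectors::queryHits(hits)[same])
  anti_idx <- setdiff(unique(S4Vectors::queryHits(hits)[!same]), sense_idx)
  overlapped <- union(sense_idx, anti_idx)

  # bidirectional: divergent 5' starts within the window, opposite strands,
  # no overlap with any coding gene
  tss_l <- ifelse(lncrnas$strand == "+", lncrnas$start, lncrnas$end)
  tss_g <- ifelse(coding$strand == "+", coding$start, coding$end)
  bidir <- vapply(seq_len(nrow(lncrnas)), function(i) {
    if (i %in% overlapped) return(FALSE)
    j <- which(coding$chrom == lncrnas$chrom[i] &
                 coding$strand != lncrnas$strand[i])
    if (length(j) == 0L) return(FALSE)
    d <- abs(tss_g[j] - tss_l[i])
    # head-to-head: the partner's TSS lies on the lncRNA's upstream side
    upstream_ok <- if (lncrnas$strand[i] == "+") tss_g[j] <= tss_l[i]
                   else tss_g[j] >= tss_l[i]
    any(d <= bidirectional_window & upstream_ok)
  }, logical(1))

  cls <- rep("intergenic", nrow(lncrnas))
  cls[bidir] <- "bidirectional"
  cls[anti_idx] <- "antisense_overlap"
  cls[sense_idx] <- "sense_overlap"
  data.frame(lncrna_id = lncrnas$feature_id, positional_class = cls,
             stringsAsFactors = FALSE)
}

#' Cis targets of intergenic lncRNAs within a genomic window
#'
#' Emits a (lincRNA, gene) pair whenever the minimum gap between the two loci
#' is at most \code{window} bp; overlapping loci count as gap 0. The rule is
#' symmetric in upstream/downstream placement and strand-agnostic.
#'
#' @param lincrnas Genomic feature table of intergenic lncRNAs.
#' @param coding Genomic feature table of protein-coding genes.
#' @param window Window size in bp (default 300000).
#' @return data.frame with \code{lncrna_id}, \code{gene_id},
#'   \code{gene_symbol}, \code{gap}.
#' @export
cis_targets <- function(lincrnas, coding, window = 300000) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  lincrnas <- genomic_features(lincrnas)
  coding <- genomic_features(coding)
  chroms <- union(unique(lincrnas$chrom), unique(coding$chrom))
  gl <- features_to_granges(lincrnas, chroms)
  gc <- features_to_granges(coding, chroms)
  hits <- GenomicRanges::findOverlaps(gl, gc, maxgap = window,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gap <- GenomicRanges::distance(gl[qi], gc[si], ignore.strand = TRUE)
  keep <- !is.na(gap) & gap <= window
  out <- data.frame(
    lncrna_id = lincrnas$feature_id[qi[keep]],
    gene_id = coding$feature_id[si[keep]],
    gene_symbol = coding$gene_symbol[si[keep]],
    gap = as.integer(gap[keep]),
    stringsAsFactors = FALSE
  )
  out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
}

#' Validate a miRNA target table
#'
#' @param df data.frame with columns \code{mirna_id}, \code{target_id},
#'   \code{target_symbol}, \code{target_class} (\code{"mRNA"} or
#'   \code{"lncRNA"}), \code{source}.
#' @return The validated data.frame.
#' @export
target_pairs <- function(df) {
  assert_columns(df, c("mirna_id", "target_id", "target_symbol",
                       "target_class", "source"), "target table")
  if (!all(df$target_class %in% c("mRNA", "lncRNA"))) {
    stop("target_class must be 'mRNA' or 'lncRNA'", call. = FALSE)
  }
  df
}

# shared intersection core: restrict target pairs to differential targets,
# identity at the transcript-accession level
intersect_targets <- function(pairs, records, target_class) {
  pairs <- target_pairs(pairs)
  pairs <- pairs[pairs$target_class == target_class, , drop = FALSE]
  de_ids <- differential_ids(records)
  kept <- pairs[pairs$target_id %in% de_ids, , drop = FALSE]
  kept <- unique(kept)
  kept <- kept[order(kept$mirna_id, kept$target_id), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "n_distinct_targets") <- length(unique(kept$target_id))
  kept
}

#' Intersect predicted miRNA target mRNAs with differential mRNAs
#'
#' Keeps target pairs whose target transcript accession is a differentially
#' expressed mRNA. The distinct-target count is attached as attribute
#' \code{n_distinct_targets}.
#'
#' @param pairs Target table (see [target_pairs()]).
#' @param degs Differential records for the mRNA panel.
#' @return Filtered, deduplicated target table.
#' @export
intersect_mrna_targets <- function(pairs, degs) {
  intersect_targets(pairs, degs, "mRNA")
}

#' Intersect predicted miRNA target lncRNAs with differential lncRNAs
#'
#' @param pairs Target table (see [target_pairs()]).
#' @param dels Differential records for the lncRNA panel.
#' @return Filtered, deduplicated target table with attribute
#'   \code{n_distinct_targets}.
#' @export
intersect_lncrna_targets <- function(pairs, dels) {
  intersect_targets(pairs, dels, "lncRNA")
}

#' Cis pairs where both sides are differentially expressed
#'
#' @param cis_pairs Output of [cis_targets()].
#' @param dels,degs Differential records for lncRNAs and mRNAs.
#' @return Subset of \code{cis_pairs} with differential lincRNA and gene.
#' @export
cis_differential_pairs <- function(cis_pairs, dels, degs) {
  keep <- cis_pairs$lncrna_id %in% differential_ids(dels) &
    cis_pairs$gene_id %in% differential_ids(degs)
  out <- cis_pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
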