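#' Construct an intensity panel
#'
#' Container for one RNA class worth of raw microarray measurements: per
#' feature-by-sample foreground and background fluorescence, detection flags,
#' and a two-group design. Rows are features, columns are samples.
#'
#' @param foreground,background Nonnegative numeric matrices with identical
#'   dimnames (features x samples), arbitrary fluorescence units.
#' @param flags Character matrix of the same shape with per-cell detection
#'   calls: \code{"P"} (Present), \code{"M"} (Marginal) or \code{"A"} (Absent).
#' @param design Named character vector mapping every sample id to its group;
#'   exactly two distinct groups are required.
#' @param rna_class One of \code{"mRNA"}, \code{"lncRNA"}, \code{"miRNA"}.
#' @return An object of class \code{intensity_panel}.
#' @export
intensity_panel <- function(foreground, background, flags, design,
                            rna_class = c("mRNA", "lncRNA", "miRNA")) {
  rna_class <- match.arg(rna_class)
  if (!is.matrix(foreground) || !is.matrix(background) || !is.matrix(flags)) {
    stop("foreground, background and flags must be matrices", call. = FALSE)
  }
  if (!identical(dim(foreground), dim(background)) ||
      !identical(dim(foreground), dim(flags))) {
    stop("foreground, background and flags must have identical dimensions",
         call. = FALSE)
  }
  if (is.null(rownames(foreground)) || is.null(colnames(foreground))) {
    stop("foreground must carry feature rownames and sample colnames",
         call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(flags)), c("P", "M", "A"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown detection flag symbol(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  samples <- colnames(foreground)
  if (!all(samples %in% names(design))) {
    stop("every sample must be assigned to a group in `design`", call. = FALSE)
  }
  design <- design[samples]
  if (length(unique(design)) != 2L) {
    stop("design must contain exactly two groups", call. = FALSE)
  }
  structure(
    list(rna_class = rna_class, foreground = foreground,
         background = background, flags = flags, design = design),
    class = "intensity_panel"
  )
}

#' @export
print.intensity_panel <- function(x, ...) {
  cat(sprintf("<intensity_panel> %s: %d features x %d samples (%s)\n",
              x$rna_class, nrow(x$foreground), ncol(x$foreground),
              paste(sprintf("%s=%d", names(table(x$design)), table(x$design)),
                    collapse = ", ")))
  invisible(x)
}

#' Differential-expression thresholds
#'
#' @param min_abs_fc Minimum absolute fold change (linear scale), default 1.5.
#' @param max_fdr Benjamini-Hochberg FDR cutoff, default 0.05 (strict
#'   \code{fdr < max_fdr}).
#' @param min_flagged_samples Minimum number of samples with Present or
#'   Marginal flags for a feature to enter the analysis (default 3 of 6).
#' @param min_intensity Minimum mean raw foreground intensity (miRNA panels
#'   only), boundary inclusive; default 30.
#' @param rescue_raw_p Optional raw p-value cutoff: features passing the fold
#'   change threshold but failing \code{max_fdr} are retained (marked
#'   \code{rescued}) when their unadjusted p is below this value. Disabled
#'   (\code{NULL}) by default.
#' @return A \code{de_thresholds} list.
#' @export
de_thresholds <- function(min_abs_fc = 1.5, max_fdr = 0.05,
                          min_flagged_samples = 3L, min_intensity = 30,
                          rescue_raw_p = NULL) {
  if (min_abs_fc < 1) stop_config("min_abs_fc", "must be >= 1")
  if (max_fdr <= 0) stop_config("max_fdr", "must be positive")
  if (min_flagged_samples < 0) stop_config("min_flagged_samples", "must be >= 0")
  if (min_intensity < 0) stop_config("min_intensity", "must be >= 0")
  if (!is.null(rescue_raw_p) && (rescue_raw_p <= 0 || rescue_raw_p > 1)) {
    stop_config("rescue_raw_p", "must lie in (0, 1]")
  }
  structure(list(min_abs_fc = min_abs_fc, max_fdr = max_fdr,
                 min_flagged_samples = as.integer(min_flagged_samples),
                 min_intensity = min_intensity, rescue_raw_p = rescue_raw_p),
            class = "de_thresholds")
}

#' Collapse replicated features by averaging
#'
#' Replicate probes sharing one feature id are mean-collapsed (foreground and
#' background averaged per sample); the collapsed flag is the most confident
#' call among replicates (Present > Marginal > Absent).
#'
#' @param panel An \code{intensity_panel}.
#' @return An \code{intensity_panel} with unique feature ids.
#' @export
collapse_replicates <- function(panel) {
  ids <- rownames(panel$foreground)
  if (!anyDuplicated(ids)) return(panel)
  groups <- split(seq_along(ids), factor(ids, levels = unique(ids)))
  agg <- function(m, fun) {
    out <- t(vapply(groups, function(idx) fun(m[idx, , drop = FALSE]),
                    numeric(ncol(m))))
    colnames(out) <- colnames(m)
    out
  }
  fg <- agg(panel$foreground, colMeans)
  bg <- agg(panel$background, colMeans)
  best_flag <- function(m) {
    apply(m, 2, function(col) {
      if ("P" %in% col) "P" else if ("M" %in% col) "M" else "A"
    })
  }
  fl <- t(vapply(groups, function(idx)
    best_flag(panel$flags[idx, , drop = FALSE]), character(ncol(fg))))
  dimnames(fl) <- dimnames(fg)
  intensity_panel(fg, bg, fl, panel$design, panel$rna_class)
}

#' Detection-flag filter
#'
#' Retains features for which at least \code{min_flagged_samples} samples carry
#' a Present or Marginal detection flag.
#'
#' @param panel An \code{intensity_panel}.
#' @param thresholds A \code{de_thresholds} object.
#' @return Character vector of retained feature ids.
#' @export
filter_by_flags <- function(panel, thresholds = de_thresholds()) {
  detected <- rowSums(panel$flags == "P" | panel$flags == "M")
  rownames(panel$flags)[detected >= thresholds$min_flagged_samples]
}

#' Mean-intensity filter for miRNA panels
#'
#' Retains miRNAs whose mean raw foreground intensity across all samples is at
#' least \code{min_intensity} (boundary inclusive).
#'
#' @inheritParams filter_by_flags
#' @return Character vector of retained feature ids.
#' @export
filter_by_intensity <- function(panel, thresholds = de_thresholds()) {
  if (panel$rna_class != "miRNA") {
    stop("the intensity filter applies to miRNA panels only", call. = FALSE)
  }
  means <- rowMeans(panel$foreground)
  rownames(panel$foreground)[means >= thresholds$min_intensity]
}

#' Background-subtracted median normalization
#'
#' Computes \code{(foreground - background) / median_s} per cell, where
#' \code{median_s} is the per-sample median of \code{foreground - background}
#' over the features being normalized. By this construction every sample's
#' median normalized value is 1.
#'
#' @param panel An \code{intensity_panel}.
#' @param features Optional character vector restricting normalization to a
#'   subset of features (e.g. the flag-filtered set); defaults to all.
#' @return Numeric matrix of normalized intensities (may contain zeros or
#'   negatives where background exceeded foreground; downstream log transforms
#'   floor these).
#' @export
normalize_panel <- function(panel, features = NULL) {
  fg <- panel$foreground
  bg <- panel$background
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(fg))
    if (length(missing) > 0L) {
      stop(sprintf("unknown feature id(s): %s",
                   paste(utils::head(missing, 3), collapse = ", ")),
           call. = FALSE)
    }
    fg <- fg[features, , drop = FALSE]
    bg <- bg[features, , drop = FALSE]
  }
  net <- fg - bg
  med <- apply(net, 2, stats::median)
  bad <- med <= 0
  if (any(bad)) {
    stop(sprintf("normalization error: nonpositive median net intensity in sample(s) %s",
                 paste(colnames(net)[bad], collapse = ", ")), call. = FALSE)
  }
  sweep(net, 2, med, "/")
}

# Two-sample t-test p-value with degenerate-case conventions:
# both groups constant -> p = 1 when means agree, 0 otherwise.
two_sample_p <- function(x, y, var_equal) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Per-feature fold change and t-test p-value
#'
#' Fold change is the ratio of group means on the linear normalized scale
#' (numerator group over denominator group); the p-value comes from a
#' two-sample t statistic on log2-transformed normalized values. The default
#' is the pooled (equal-variance) t — with three arrays per group the Welch
#' degrees-of-freedom penalty costs substantial power and the equal-variance
#' assumption is standard for identically processed arrays; set
#' \code{var_equal = FALSE} for the Welch (unequal-variance) form.
#' Nonpositive normalized values are floored at \code{floor} before either
#' computation.
#'
#' @param normalized Numeric matrix of normalized intensities.
#' @param design Named character vector mapping samples to two groups.
#' @param numerator,denominator Group labels defining the fold-change
#'   orientation (default depression/healthy).
#' @param floor Positive floor applied before log2 (default 1e-6).
#' @param var_equal Pool the group variances (default TRUE); FALSE gives the
#'   Welch test.
#' @param detected Optional logical matrix (same shape as \code{normalized}):
#'   cells flagged Absent are below the detection limit, and including their
#'   floored values would corrupt the variance estimate, so they receive zero
#'   weight — the spot-quality-weight convention for flagged array features.
#'   A feature with fewer than two detected cells in either group gets
#'   \code{p = 1} and a fold change over all cells.
#' @return data.frame with columns \code{feature_id}, \code{fc_ratio},
#'   \code{p_value}.
#' @export
test_differential <- function(normalized, design,
                              numerator = "depression",
                              denominator = "healthy",
                              floor = 1e-6, var_equal = TRUE,
                              detected = NULL) {
  design <- design[colnames(normalized)]
  groups <- unique(design)
  if (!all(c(numerator, denominator) %in% groups)) {
    stop(sprintf("design lacks group '%s' or '%s'", numerator, denominator),
         call. = FALSE)
  }
  idx_n <- which(design == numerator)
  idx_d <- which(design == denominator)
  if (length(idx_n) < 2L || length(idx_d) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  x <- pmax(normalized, floor)
  lg <- log2(x)
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(x), ncol(x))
  } else if (!identical(dim(detected), dim(normalized))) {
    stop("`detected` must match the dimensions of `normalized`", call. = FALSE)
  }
  res <- vapply(seq_len(nrow(lg)), function(i) {
    dn <- idx_n[detected[i, idx_n]]
    dd <- idx_d[detected[i, idx_d]]
    if (length(dn) < 2L || length(dd) < 2L) {
      return(c(mean(x[i, idx_n]) / mean(x[i, idx_d]), 1))
    }
    c(mean(x[i, dn]) / mean(x[i, dd]),
      two_sample_p(lg[i, dn], lg[i, dd], var_equal))
  }, numeric(2))
  data.frame(feature_id = rownames(normalized), fc_ratio = res[1, ],
             p_value = res[2, ], stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false discovery rate control: with p-values sorted ascending,
#' \code{q_(i) = min over j >= i of p_(j) * m / j}, capped at 1 and returned in
#' the original input order (ties stable).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Numeric vector of BH-adjusted p-values (FDR), same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Significance calls from fold change and FDR
#'
#' A feature is significant when \code{fc_abs >= min_abs_fc} and
#' \code{fdr < max_fdr}. When \code{rescue_raw_p} is set, features meeting the
#' fold-change threshold with \code{fdr >= max_fdr} but raw
#' \code{p < rescue_raw_p} are retained with \code{rescued = TRUE}.
#'
#' @param records data.frame with \code{feature_id}, \code{fc_ratio},
#'   \code{p_value} (as from [test_differential()]).
#' @param thresholds A \code{de_thresholds} object.
#' @param rna_class RNA class label stamped onto the records.
#' @return data.frame of differential records: \code{feature_id},
#'   \code{rna_class}, \code{fc_ratio}, \code{fc_abs}, \code{regulation},
#'   \code{p_value}, \code{fdr}, \code{significant}, \code{rescued}.
#' @export
call_differential <- function(records, thresholds = de_thresholds(),
                              rna_class = "mRNA") {
  assert_columns(records, c("feature_id", "fc_ratio", "p_value"),
                 "differential records")
  fdr <- bh_adjust(records$p_value)
  fc_abs <- pmax(records$fc_ratio, 1 / records$fc_ratio)
  regulation <- ifelse(records$fc_ratio > 1, "up", "down")
  significant <- fc_abs >= thresholds$min_abs_fc & fdr < thresholds$max_fdr
  rescued <- rep(FALSE, nrow(records))
  if (!is.null(thresholds$rescue_raw_p)) {
    rescued <- fc_abs >= thresholds$min_abs_fc & fdr >= thresholds$max_fdr &
      records$p_value < thresholds$rescue_raw_p
  }
  data.frame(feature_id = records$feature_id, rna_class = rna_class,
             fc_ratio = records$fc_ratio, fc_abs = fc_abs,
             regulation = regulation, p_value = records$p_value, fdr = fdr,
             significant = significant, rescued = rescued,
             stringsAsFactors = FALSE)
}

#' Full differential-expression pass over one panel
#'
#' Chains replicate collapsing, the detection-flag filter, the miRNA
#' mean-intensity filter, background-subtracted median normalization, the
#' per-feature Welch test, BH adjustment and threshold calls.
#'
#' @param panel An \code{intensity_panel}.
#' @param thresholds A \code{de_thresholds} object.
#' @inheritParams test_differential
#' @return data.frame of differential records for the retained features (see
#'   [call_differential()]).
#' @export
run_de <- function(panel, thresholds = de_thresholds(),
                   numerator = "depression", denominator = "healthy",
                   var_equal = TRUE) {
  panel <- collapse_replicates(panel)
  keep <- filter_by_flags(panel, thresholds)
  if (panel$rna_class == "miRNA") {
    keep <- intersect(keep, filter_by_intensity(panel, thresholds))
  }
  if (length(keep) == 0L) {
    return(call_differential(
      data.frame(feature_id = character(0), fc_ratio = numeric(0),
                 p_value = numeric(0)), thresholds, panel$rna_class))
  }
  norm <- normalize_panel(panel, keep)
  rec <- test_differential(norm, panel$design, numerator, denominator,
                           var_equal = var_equal,
                           detected = panel$flags[keep, , drop = FALSE] != "A")
  call_differential(rec, thresholds, panel$rna_class)
}

#' Ids of differential features (significant or rescued)
#'
#' @param records Differential-record data.frame.
#' @return Character vector of feature ids.
#' @export
differential_ids <- function(records) {
  records$feature_id[records$significant | records$rescued]
}
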