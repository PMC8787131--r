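test_that("normalization divides background-subtracted signal by the sample median", {
  # one sample with net values 100/50/20: median 50, so 100 -> 2.0
  net <- cbind(s1 = c(100, 50, 20), s2 = c(60, 40, 10),
               s3 = c(80, 50, 30), s4 = c(90, 45, 25))
  rownames(net) <- c("a", "b", "c")
  panel <- make_panel(net)
  norm <- normalize_panel(panel)
  expect_equal(norm["a", "s1"], 2.0)
  # foreground == background gives 0 before flooring
  net0 <- net; net0["c", "s1"] <- 0
  expect_equal(normalize_panel(make_panel(net0))["c", "s1"], 0)
  # per-sample median of normalized values is 1 by construction
  expect_equal(unname(apply(norm, 2, median)), rep(1, 4))
})

test_that("normalization fails loudly on a nonpositive sample median", {
  net <- cbind(s1 = c(-5, -2, -1), s2 = c(10, 20, 30))
  panel <- make_panel(net)
  expect_error(normalize_panel(panel), "s1")
})

test_that("flag filter keeps features detected in enough samples", {
  flags <- rbind(f1 = c("P", "P", "M", "A", "A", "A"),
                 f2 = c("P", "M", "A", "A", "A", "A"),
                 f3 = c("A", "A", "A", "A", "A", "A"),
                 f4 = c("P", "P", "P", "P", "P", "P"))
  net <- matrix(100, 4, 6, dimnames = list(rownames(flags), NULL))
  panel <- make_panel(net, flags = `dimnames<-`(flags, dimnames(net)))
  kept <- filter_by_flags(panel, de_thresholds(min_flagged_samples = 3))
  expect_setequal(kept, c("f1", "f4"))
})

test_that("unknown flag symbols are rejected at construction", {
  net <- matrix(100, 2, 4)
  expect_error(make_panel(net, flags = matrix("X", 2, 4)), "flag")
})

test_that("miRNA mean-intensity filter is boundary inclusive and class guarded", {
  fg <- rbind(hi = rep(30, 6), lo = rep(29.9, 6), zero = rep(0, 6))
  colnames(fg) <- sprintf("s%d", 1:6)
  bg <- matrix(0, 3, 6, dimnames = dimnames(fg))
  flags <- matrix("P", 3, 6, dimnames = dimnames(fg))
  design <- setNames(rep(c("depression", "healthy"), each = 3), colnames(fg))
  panel <- intensity_panel(fg, bg, flags, design, "miRNA")
  expect_identical(filter_by_intensity(panel), "hi")
  mpanel <- intensity_panel(fg, bg, flags, design, "mRNA")
  expect_error(filter_by_intensity(mpanel), "miRNA")
})

test_that("fold change and p-value behave at the null and under label swap", {
  set.seed(42)
  norm <- matrix(rlnorm(5 * 6), 5, 6,
                 dimnames = list(sprintf("f%d", 1:5), sprintf("s%d", 1:6)))
  norm[1, ] <- 2  # identical values in both groups
  design <- setNames(rep(c("depression", "healthy"), each = 3), colnames(norm))
  res <- test_differential(norm, design)
  expect_equal(res$fc_ratio[1], 1)
  expect_equal(res$p_value[1], 1)
  swapped <- setNames(ifelse(design == "depression", "healthy", "depression"),
                      names(design))
  res2 <- test_differential(norm, swapped)
  expect_equal(res2$fc_ratio, 1 / res$fc_ratio)
  expect_equal(res2$p_value, res$p_value)
})

test_that("Welch p-values match the textbook formula", {
  cases <- list(
    list(x = c(1.1, 2.3, 1.9), y = c(3.4, 4.1, 3.8)),
    list(x = c(0.2, 0.25, 0.31), y = c(0.2, 0.4, 0.9)),
    list(x = rnorm(3, 0, 1), y = rnorm(3, 2, 0.2)))
  for (cs in cases) {
    norm <- 2 ^ rbind(f1 = c(cs$x, cs$y))
    colnames(norm) <- sprintf("s%d", 1:6)
    design <- setNames(rep(c("depression", "healthy"), each = 3),
                       colnames(norm))
    got <- test_differential(norm, design, var_equal = FALSE)$p_value
    expect_equal(got, welch_oracle(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("Absent cells are excluded from the test via detection weights", {
  # one wild value in a flagged-Absent cell must not affect p
  x <- c(5, 5.1, 4.9); y <- c(8, 8.2, 7.9)
  norm <- 2 ^ rbind(f1 = c(x, y), f2 = c(x, y))
  colnames(norm) <- sprintf("s%d", 1:6)
  norm["f2", 1] <- 1e-6
  det <- matrix(TRUE, 2, 6); det[2, 1] <- FALSE
  design <- setNames(rep(c("depression", "healthy"), each = 3),
                     colnames(norm))
  res <- test_differential(norm, design, detected = det)
  expect_lt(res$p_value[2], 0.01)
  # fewer than two detected cells in a group -> p = 1 by convention
  det2 <- det; det2[2, 2] <- FALSE
  expect_equal(test_differential(norm, design, detected = det2)$p_value[2], 1)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(11)
  for (i in 1:25) {
    p <- round(runif(sample(1:12, 1)), 3)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH is monotone in sorted order and permutation invariant", {
  set.seed(12)
  for (i in 1:10) {
    p <- runif(30)
    q <- bh_adjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    perm <- sample(30)
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("significance calls honor fold-change, FDR and raw-p rescue rules", {
  rec <- data.frame(feature_id = "a", fc_ratio = 1.6, p_value = 0.03)
  expect_true(call_differential(rec)$significant)
  rec2 <- data.frame(feature_id = "a", fc_ratio = 1.49, p_value = 0.001)
  expect_false(call_differential(rec2)$significant)
  # fc passes, fdr misses 0.05, raw p below 0.05 -> rescued when enabled
  rec3 <- data.frame(feature_id = c("m", "x", "y"),
                     fc_ratio = c(0.4718, 1.0, 1.0),
                     p_value = c(0.02, 0.9, 0.95))
  plain <- call_differential(rec3)
  expect_false(plain$significant[1])
  expect_false(plain$rescued[1])
  resc <- call_differential(rec3, de_thresholds(rescue_raw_p = 0.05))
  expect_gte(resc$fdr[1], 0.05)
  expect_true(resc$rescued[1])
  expect_false(resc$significant[1])
  expect_equal(resc$regulation[1], "down")
})

test_that("absolute fold change is reciprocal-symmetric and direction flips on swap", {
  set.seed(3)
  ratios <- rlnorm(50)
  fc_abs <- pmax(ratios, 1 / ratios)
  expect_equal(fc_abs, pmax(1 / ratios, ratios))
  rec <- data.frame(feature_id = sprintf("f%d", 1:50), fc_ratio = ratios,
                    p_value = runif(50))
  a <- call_differential(rec)
  rec$fc_ratio <- 1 / rec$fc_ratio
  b <- call_differential(rec)
  flip <- ratios != 1
  expect_true(all(a$regulation[flip] != b$regulation[flip]))
  expect_equal(a$fc_abs, b$fc_abs)
})

test_that("replicated probe ids are mean-collapsed before filtering", {
  net <- rbind(a = rep(100, 4), a = rep(200, 4), b = rep(50, 4))
  panel <- make_panel(net)
  collapsed <- collapse_replicates(panel)
  expect_equal(nrow(collapsed$foreground), 2)
  expect_equal(unname(collapsed$foreground["a", 1]),
               mean(panel$foreground[c(1, 2), 1]))
})

test_that("a null panel yields essentially no significant calls", {
  hits <- vapply(1:5, function(s) {
    sim <- generate_bundle(simulation_config(n_mrna = 2000, n_lncrna = 20,
                                             n_mirna = 10, frac_de = 0,
                                             seed = 100 + s))
    sum(run_de(sim$bundle$panels$mRNA)$significant)
  }, numeric(1))
  expect_lte(mean(hits), 1)
})
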