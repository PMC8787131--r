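#' Simulation configuration
#'
#' Defines one synthetic study: a two-group (depression-microbiota vs
#' healthy-microbiota recipients) microarray experiment over mRNA, lncRNA and
#' miRNA panels, with planted differential effects, a genome annotation that
#' realizes every positional lncRNA class, miRNA target maps, planted
#' sponge-consistent ceRNA triads, a gene-gene interaction table and a term
#' annotation.
#'
#' @param n_mrna,n_lncrna,n_mirna Feature counts per RNA class.
#' @param n_per_group Samples per group (default 3, one array per pooled
#'   sample).
#' @param frac_de Fraction of features per class carrying a planted
#'   differential effect; the planted count is \code{round(frac_de * n)}.
#' @param effect_fold Planted linear fold change (> 1), applied to the
#'   depression group (up features multiplied, down features divided).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   noise on the true signal.
#' @param baseline_log2_mean,baseline_log2_sd Location/scale of per-feature
#'   baseline intensity on the log2 scale.
#' @param frac_absent Per-cell probability of an Absent detection flag (the
#'   cell's signal is then drawn from the background-only distribution).
#' @param targets_per_mirna Mean out-degree of the random miRNA->mRNA target
#'   map (the miRNA->lncRNA map uses half this mean).
#' @param frac_coupled_triads Fraction of planted triads wired with
#'   sponge-consistent directions (partners forced opposite to the miRNA).
#' @param interaction_density Edge probability for the gene-gene score table.
#' @param n_cis_pairs Number of planted lincRNA-gene pairs placed within the
#'   300-kb cis window (default 4).
#' @param class_mix Named proportions for the positional lncRNA classes
#'   (default 50\% intergenic, 26\% antisense overlap, 12\% sense overlap,
#'   12\% bidirectional).
#' @param seed Integer seed; all randomness flows from one generator stream.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(n_mrna = 2000, n_lncrna = 600, n_mirna = 120,
                              n_per_group = 3, frac_de = 0.05,
                              effect_fold = 2.5, noise_cv = 0.1,
                              baseline_log2_mean = 10, baseline_log2_sd = 1.5,
                              frac_absent = 0.02, targets_per_mirna = 20,
                              frac_coupled_triads = 1,
                              interaction_density = 0.002, n_cis_pairs = 4,
                              class_mix = c(intergenic = 0.50,
                                            antisense_overlap = 0.26,
                                            sense_overlap = 0.12,
                                            bidirectional = 0.12),
                              seed = 1) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              n_per_group = as.integer(n_per_group), frac_de = frac_de,
              effect_fold = effect_fold, noise_cv = noise_cv,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd, frac_absent = frac_absent,
              targets_per_mirna = targets_per_mirna,
              frac_coupled_triads = frac_coupled_triads,
              interaction_density = interaction_density,
              n_cis_pairs = as.integer(n_cis_pairs), class_mix = class_mix,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  for (f in c("n_mrna", "n_lncrna", "n_mirna")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop_config(f, "must be >= 1")
  }
  if (cfg$n_per_group < 2L) stop_config("n_per_group", "must be >= 2")
  for (f in c("frac_de", "frac_absent", "frac_coupled_triads",
              "interaction_density")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop_config(f, "must lie in [0, 1]")
    }
  }
  if (cfg$effect_fold <= 1) stop_config("effect_fold", "must be > 1")
  if (cfg$noise_cv < 0) stop_config("noise_cv", "must be >= 0")
  if (cfg$baseline_log2_sd < 0) stop_config("baseline_log2_sd", "must be >= 0")
  if (cfg$targets_per_mirna < 0) stop_config("targets_per_mirna", "must be >= 0")
  if (cfg$n_cis_pairs < 0) stop_config("n_cis_pairs", "must be >= 0")
  cm <- cfg$class_mix
  need <- c("intergenic", "antisense_overlap", "sense_overlap", "bidirectional")
  if (!all(need %in% names(cm)) || any(cm < 0) ||
      abs(sum(cm) - 1) > 1e-8) {
    stop_config("class_mix", "must name all four positional classes and sum to 1")
  }
  n_hosts <- sum(round_counts(cfg$n_lncrna, cm)[c("antisense_overlap",
                                                  "sense_overlap",
                                                  "bidirectional")])
  if (min(cfg$n_cis_pairs, cfg$n_mrna) + n_hosts > cfg$n_mrna) {
    stop_config("n_mrna", "too small to host the requested lncRNA classes and cis pairs")
  }
  invisible(cfg)
}

# apportion n into named integer counts by largest remainder
round_counts <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

# one RNA-class intensity panel from planted direction exponents
simulate_panel <- function(ids, exponents, cfg, rna_class) {
  n <- length(ids)
  k <- cfg$n_per_group
  samples <- c(sprintf("dep_%d", seq_len(k)), sprintf("hea_%d", seq_len(k)))
  design <- stats::setNames(rep(c("depression", "healthy"), each = k), samples)
  ns <- 2 * k
  mu <- 2 ^ stats::rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  sigma <- sqrt(log(1 + cfg$noise_cv^2))
  noise <- matrix(exp(stats::rnorm(n * ns, 0, sigma) - sigma^2 / 2), n, ns)
  e <- exponents[ids]
  e[is.na(e)] <- 0
  fold <- matrix(1, n, ns)
  fold[, seq_len(k)] <- cfg$effect_fold ^ e
  signal <- mu * fold * noise
  bg <- matrix(stats::runif(n * ns, 10, 30), n, ns)
  absent <- matrix(stats::runif(n * ns) < cfg$frac_absent, n, ns)
  fg <- bg + signal
  fg[absent] <- bg[absent] + stats::runif(sum(absent), 0, 3)
  flags <- matrix("P", n, ns)
  marginal <- matrix(stats::runif(n * ns) < 0.05, n, ns) & !absent
  flags[marginal] <- "M"
  flags[absent] <- "A"
  dimnames(fg) <- dimnames(bg) <- dimnames(flags) <- list(ids, samples)
  intensity_panel(fg, bg, flags, design, rna_class)
}

# genome layout: one 3-Mb slot per locus, cycling over 19 autosomes; overlap
# classes are realized against dedicated host genes, planted cis lincRNAs sit
# 50-250 kb from their partner gene, all other loci are > 300 kb apart
simulate_annotation <- function(cfg) {
  counts <- round_counts(cfg$n_lncrna, cfg$class_mix)
  n_cis <- min(cfg$n_cis_pairs, counts[["intergenic"]], cfg$n_mrna)
  n_slots <- cfg$n_mrna + (counts[["intergenic"]] - n_cis) + cfg$n_mirna
  slot_chrom <- sprintf("chr%d", (seq_len(n_slots) - 1L) %% 19L + 1L)
  slot_base <- (seq_len(n_slots) - 1L) %/% 19L * 3000000L

  gene_len <- sample(5000:50000, cfg$n_mrna, replace = TRUE)
  gene_strand <- sample(c("+", "-"), cfg$n_mrna, replace = TRUE)
  genes <- data.frame(
    feature_id = sprintf("NM_%06d", seq_len(cfg$n_mrna)),
    gene_symbol = sprintf("Gene%04d", seq_len(cfg$n_mrna)),
    chrom = slot_chrom[seq_len(cfg$n_mrna)],
    start = slot_base[seq_len(cfg$n_mrna)] + 1200000L,
    end = slot_base[seq_len(cfg$n_mrna)] + 1200000L + gene_len,
    strand = gene_strand, biotype = "protein_coding",
    stringsAsFactors = FALSE)

  lnc_ids <- sprintf("LNC_%05d", seq_len(cfg$n_lncrna))
  lnc_sym <- sprintf("Lnc%04d", seq_len(cfg$n_lncrna))
  classes <- rep(names(counts), counts)
  lnc <- data.frame(feature_id = lnc_ids, gene_symbol = lnc_sym,
                    chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    biotype = "lncRNA", stringsAsFactors = FALSE)
  cis_pairs <- data.frame(lncrna_id = character(0), gene_id = character(0),
                          stringsAsFactors = FALSE)
  i_int <- which(classes == "intergenic")
  free_slot <- cfg$n_mrna  # next unused slot index
  host <- n_cis            # next unused host gene index
  for (i in seq_len(cfg$n_lncrna)) {
    len <- sample(500:5000, 1)
    cls <- classes[i]
    if (cls == "intergenic" && match(i, i_int) <= n_cis) {
      g <- match(i, i_int)  # partner gene index
      gap <- sample(50000:250000, 1)
      lnc$chrom[i] <- genes$chrom[g]
      lnc$start[i] <- genes$end[g] + gap
      lnc$end[i] <- lnc$start[i] + len
      lnc$strand[i] <- sample(c("+", "-"), 1)
      cis_pairs <- rbind(cis_pairs, data.frame(
        lncrna_id = lnc_ids[i], gene_id = genes$feature_id[g],
        stringsAsFactors = FALSE))
    } else if (cls == "intergenic") {
      free_slot <- free_slot + 1L
      lnc$chrom[i] <- slot_chrom[free_slot]
      lnc$start[i] <- slot_base[free_slot] + 1500000L
      lnc$end[i] <- lnc$start[i] + len
      lnc$strand[i] <- sample(c("+", "-"), 1)
    } else {
      host <- host + 1L
      g <- host
      if (cls == "sense_overlap" || cls == "antisense_overlap") {
        lnc$chrom[i] <- genes$chrom[g]
        lnc$start[i] <- genes$start[g] + 500L
        lnc$end[i] <- min(lnc$start[i] + len, genes$end[g] - 100L)
        if (lnc$end[i] <= lnc$start[i]) lnc$end[i] <- lnc$start[i] + 200L
        lnc$strand[i] <- if (cls == "sense_overlap") genes$strand[g] else
          setdiff(c("+", "-"), genes$strand[g])
      } else {  # bidirectional: divergent promoters within 1 kb, no overlap
        gap <- sample(100:900, 1)
        lnc$chrom[i] <- genes$chrom[g]
        if (genes$strand[g] == "+") {
          lnc$strand[i] <- "-"
          lnc$end[i] <- genes$start[g] - gap
          lnc$start[i] <- lnc$end[i] - len
        } else {
          lnc$strand[i] <- "+"
          lnc$start[i] <- genes$end[g] + gap
          lnc$end[i] <- lnc$start[i] + len
        }
      }
    }
  }

  mir_slots <- free_slot + seq_len(cfg$n_mirna)
  mirs <- data.frame(
    feature_id = sprintf("mmu-sim-miR-%03d", seq_len(cfg$n_mirna)),
    gene_symbol = sprintf("mmu-sim-miR-%03d", seq_len(cfg$n_mirna)),
    chrom = slot_chrom[mir_slots], start = slot_base[mir_slots] + 1400000L,
    end = slot_base[mir_slots] + 1400090L, strand = "+", biotype = "miRNA",
    stringsAsFactors = FALSE)

  list(annotation = rbind(genes, lnc, mirs),
       classes = data.frame(lncrna_id = lnc_ids, positional_class = classes,
                            stringsAsFactors = FALSE),
       cis_pairs = cis_pairs)
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Produces everything the pipeline consumes: three intensity panels
#' (foreground, background, detection flags; two groups of
#' \code{n_per_group} samples), a genomic annotation realizing every
#' positional lncRNA class plus \code{n_cis_pairs} lincRNA-gene pairs inside
#' the 300-kb cis window, miRNA->mRNA and miRNA->lncRNA target tables, a
#' gene-gene interaction table with scores in [0, 1], and a term annotation.
#' Differential effects are planted in \code{round(frac_de * n)} features per
#' class; one ceRNA triad is planted per differential miRNA (capped by the
#' differential mRNA/lncRNA pools, partners distinct across triads), and
#' \code{frac_coupled_triads} of them are wired sponge-consistently via
#' [plant_sponge_signal()]. Deterministic given \code{config$seed}.
#'
#' @param config A [simulation_config()].
#' @return List with elements \code{bundle} (panels, annotation, targets,
#'   interactions, terms) and \code{truth} (de_features, planted_triads,
#'   planted_lncrna_classes, planted_cis_pairs).
#' @export
generate_bundle <- function(config = simulation_config()) {
  validate_simulation_config(config)
  with_local_seed(config$seed, {
    layout <- simulate_annotation(config)
    ann <- layout$annotation
    mrna_ids <- ann$feature_id[ann$biotype == "protein_coding"]
    lnc_ids <- ann$feature_id[ann$biotype == "lncRNA"]
    mir_ids <- ann$feature_id[ann$biotype == "miRNA"]

    # planted differential sets: cis-pair members enter first so the planted
    # cis pairs are recoverable as differential-differential pairs
    pick_de <- function(ids, n_de, forced = character(0)) {
      forced <- utils::head(intersect(forced, ids), n_de)
      extra <- sample(setdiff(ids, forced), max(0L, n_de - length(forced)))
      sort(c(forced, extra))
    }
    n_de <- vapply(c(mRNA = config$n_mrna, lncRNA = config$n_lncrna,
                     miRNA = config$n_mirna),
                   function(n) as.integer(round(config$frac_de * n)),
                   integer(1))
    de_m <- pick_de(mrna_ids, n_de[["mRNA"]], layout$cis_pairs$gene_id)
    de_l <- pick_de(lnc_ids, n_de[["lncRNA"]], layout$cis_pairs$lncrna_id)
    de_r <- pick_de(mir_ids, n_de[["miRNA"]])
    de_features <- data.frame(
      feature_id = c(de_m, de_l, de_r),
      rna_class = rep(c("mRNA", "lncRNA", "miRNA"),
                      c(length(de_m), length(de_l), length(de_r))),
      direction = sample(c("up", "down"),
                         length(de_m) + length(de_l) + length(de_r),
                         replace = TRUE),
      stringsAsFactors = FALSE)

    # random target maps
    sym_of <- stats::setNames(ann$gene_symbol, ann$feature_id)
    random_targets <- function(pool, mean_deg, class) {
      rows <- lapply(mir_ids, function(m) {
        d <- min(stats::rpois(1, mean_deg), length(pool))
        if (d == 0L) return(NULL)
        t <- sample(pool, d)
        data.frame(mirna_id = m, target_id = t,
                   target_symbol = unname(sym_of[t]), target_class = class,
                   source = "sim", stringsAsFactors = FALSE)
      })
      do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    }
    tg_m <- random_targets(mrna_ids, config$targets_per_mirna, "mRNA")
    tg_l <- random_targets(lnc_ids, config$targets_per_mirna / 2, "lncRNA")

    # planted triads: one per differential miRNA, distinct partners
    n_triads <- min(length(de_r), length(de_m), length(de_l))
    triads <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                         mrna_id = character(0), coupled = logical(0),
                         stringsAsFactors = FALSE)
    if (n_triads > 0L) {
      tm <- sample(de_r, n_triads)
      tg <- sample(de_m, n_triads)
      tl <- sample(de_l, n_triads)
      coupled <- rep(FALSE, n_triads)
      n_coup <- round(config$frac_coupled_triads * n_triads)
      if (n_coup > 0L) coupled[sample(n_triads, n_coup)] <- TRUE
      triads <- data.frame(lncrna_id = tl, mirna_id = tm, mrna_id = tg,
                           coupled = coupled, stringsAsFactors = FALSE)
      tg_m <- unique(rbind(tg_m, data.frame(
        mirna_id = tm, target_id = tg, target_symbol = unname(sym_of[tg]),
        target_class = "mRNA", source = "planted", stringsAsFactors = FALSE)))
      tg_l <- unique(rbind(tg_l, data.frame(
        mirna_id = tm, target_id = tl, target_symbol = unname(sym_of[tl]),
        target_class = "lncRNA", source = "planted",
        stringsAsFactors = FALSE)))
      tg_m <- tg_m[!duplicated(tg_m[c("mirna_id", "target_id")]), ]
      tg_l <- tg_l[!duplicated(tg_l[c("mirna_id", "target_id")]), ]
    }

    # gene-gene interaction table
    gene_syms <- unname(sym_of[mrna_ids])
    npairs <- choose(length(gene_syms), 2)
    n_edges <- stats::rbinom(1, npairs, config$interaction_density)
    interactions <- data.frame(node_a = character(0), node_b = character(0),
                               score = numeric(0), stringsAsFactors = FALSE)
    if (n_edges > 0L) {
      a <- sample(gene_syms, 3 * n_edges, replace = TRUE)
      b <- sample(gene_syms, 3 * n_edges, replace = TRUE)
      keep <- a != b
      key <- ifelse(a < b, paste(a, b), paste(b, a))
      keep <- keep & !duplicated(key)
      idx <- utils::head(which(keep), n_edges)
      interactions <- data.frame(node_a = pmin(a[idx], b[idx]),
                                 node_b = pmax(a[idx], b[idx]),
                                 score = stats::runif(length(idx)),
                                 stringsAsFactors = FALSE)
    }

    # functional term annotation over gene symbols
    n_terms <- 25L
    cats <- rep(c("biological_process", "cellular_component",
                  "molecular_function", "pathway", "custom"), length.out = n_terms)
    terms <- do.call(rbind, lapply(seq_len(n_terms), function(t) {
      size <- sample(10:60, 1)
      data.frame(term_id = sprintf("TERM%04d", t),
                 term_name = sprintf("synthetic term %d", t),
                 category = cats[t],
                 gene = sample(gene_syms, min(size, length(gene_syms))),
                 stringsAsFactors = FALSE)
    }))

    exponents <- stats::setNames(ifelse(de_features$direction == "up", 1, -1),
                                 de_features$feature_id)
    panels <- list(
      mRNA = simulate_panel(mrna_ids, exponents, config, "mRNA"),
      lncRNA = simulate_panel(lnc_ids, exponents, config, "lncRNA"),
      miRNA = simulate_panel(mir_ids, exponents, config, "miRNA"))

    bundle <- list(panels = panels, annotation = ann, targets_mrna = tg_m,
                   targets_lncrna = tg_l, interactions = interactions,
                   terms = terms)
    truth <- list(de_features = de_features, planted_triads = triads,
                  planted_lncrna_classes = layout$classes,
                  planted_cis_pairs = layout$cis_pairs)
    planted <- plant_sponge_signal(bundle, truth, config)
    list(bundle = planted$bundle, truth = planted$truth)
  })
}

#' Wire planted triads with sponge-consistent directions
#'
#' For every planted triad flagged \code{coupled}, forces the mRNA and lncRNA
#' partners' planted directions opposite to the miRNA's by rescaling their
#' depression-group signal (foreground minus background) by the appropriate
#' power of \code{effect_fold}; detection flags are untouched and Absent cells
#' keep their background-only signal. Ground-truth directions are updated to
#' match. Deterministic (no randomness).
#'
#' @param bundle,truth As produced by the generator core.
#' @param config The [simulation_config()] used to build the bundle.
#' @return List with the adjusted \code{bundle} and updated \code{truth}.
#' @export
plant_sponge_signal <- function(bundle, truth, config) {
  triads <- truth$planted_triads
  if (nrow(triads) == 0L) return(list(bundle = bundle, truth = truth))
  exp_of <- stats::setNames(
    ifelse(truth$de_features$direction == "up", 1, -1),
    truth$de_features$feature_id)
  dep_cols <- function(panel) which(panel$design == "depression")

  shift_feature <- function(panel, id, cur, want) {
    if (cur == want) return(panel)
    cols <- dep_cols(panel)
    fg <- panel$foreground[id, cols]
    bg <- panel$background[id, cols]
    not_absent <- panel$flags[id, cols] != "A"
    factor <- config$effect_fold ^ (want - cur)
    fg[not_absent] <- bg[not_absent] + (fg[not_absent] - bg[not_absent]) * factor
    panel$foreground[id, cols] <- fg
    panel
  }

  for (r in seq_len(nrow(triads))) {
    if (!triads$coupled[r]) next
    m <- triads$mirna_id[r]; g <- triads$mrna_id[r]; l <- triads$lncrna_id[r]
    if (!m %in% rownames(bundle$panels$miRNA$foreground) ||
        !g %in% rownames(bundle$panels$mRNA$foreground) ||
        !l %in% rownames(bundle$panels$lncRNA$foreground)) {
      stop(sprintf("triad (%s, %s, %s) references a feature absent from the bundle",
                   l, m, g), call. = FALSE)
    }
    if (is.na(exp_of[m])) {
      stop(sprintf("triad miRNA %s carries no planted direction", m),
           call. = FALSE)
    }
    want <- -exp_of[m]
    for (partner in list(list(id = g, class = "mRNA"),
                         list(id = l, class = "lncRNA"))) {
      cur <- exp_of[partner$id]
      if (is.na(cur)) cur <- 0
      bundle$panels[[partner$class]] <- shift_feature(
        bundle$panels[[partner$class]], partner$id, cur, want)
      exp_of[partner$id] <- want
    }
  }
  dirs <- ifelse(exp_of[truth$de_features$feature_id] > 0, "up", "down")
  truth$de_features$direction <- unname(dirs)
  list(bundle = bundle, truth = truth)
}
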