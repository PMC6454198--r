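#' Configuration of the synthetic-data generator
#'
#' Bundles every knob of the simulator into one validated list. The
#' defaults emulate a 3-group, 3-replicate RNA-seq study with a handful of
#' planted lncRNA-mRNA regulatory pairs (co-expressed and genomically
#' adjacent), near decoys (adjacent but with orthogonal expression
#' patterns), far decoys (beyond the co-localization window) and a body of
#' background coding genes, a fraction of which is differentially
#' expressed.
#'
#' Each artifact type (annotation, counts, reads) draws from its own RNG
#' stream derived from the master `seed`, so e.g. adding read fixtures
#' never perturbs the count matrices.
#'
#' @param seed Master seed (integer).
#' @param n_chrom Number of synthetic chromosomes.
#' @param n_coding_genes Number of coding genes (distributed over
#'   chromosomes).
#' @param planted Either an integer number of planted pairs (layout drawn
#'   by the generator) or a tibble with columns `distance_bp`, `location`
#'   (`upstream`/`downstream`/`overlapping`) and `target_r`. A planted
#'   distance of 0 must carry location `overlapping` and vice versa.
#' @param n_decoy_near Number of lncRNAs placed within `window` of a coding
#'   gene but with an expression pattern orthogonal to it.
#' @param n_decoy_far Number of lncRNAs placed farther than `window` from
#'   every coding gene.
#' @param n_annotated_lnc How many far-decoy loci are mirrored in the
#'   reference annotation as annotated lncRNAs.
#' @param window Co-localization window the layout respects (bp).
#' @param groups Group labels.
#' @param n_replicates Replicates per group.
#' @param target_r Default target Pearson correlation (log scale) of
#'   planted pairs.
#' @param planted_log2_offsets Per-group log2 fold-change pattern shared by
#'   both members of a planted pair.
#' @param planted_mu,planted_dispersion NB mean and dispersion of planted
#'   features.
#' @param mu_mrna_meanlog,mu_lnc_meanlog,mu_sdlog Lognormal baseline-mean
#'   parameters for background mRNAs and lncRNAs.
#' @param dispersion NB dispersion of background features
#'   (`variance = mu + dispersion * mu^2`).
#' @param de_frac Fraction of background mRNAs given a differential
#'   pattern.
#' @param de_log2fc_range Magnitude range of background log2 fold changes.
#' @param depth_variation Half-width of the uniform per-sample depth
#'   multiplier around 1 (0 disables depth variation).
#' @param cascade_failures When `TRUE`, five extra candidate transcripts
#'   are planted that fail (or survive) the filtration cascade in known
#'   ways, recorded in the truth ledger.
#' @param read_fixture Named list for the FASTQ generator: `n_adapter`,
#'   `n_poly_n`, `n_low_quality`, `n_clean`, `read_length`, `adapter`.
#' @return A `lnc_sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chrom = 2L,
                              n_coding_genes = 60L,
                              planted = 5L,
                              n_decoy_near = 8L,
                              n_decoy_far = 7L,
                              n_annotated_lnc = 3L,
                              window = 1e5,
                              groups = c("g1", "g2", "g3"),
                              n_replicates = 3L,
                              target_r = 0.99,
                              planted_log2_offsets = c(0, 3, 1.5),
                              planted_mu = 600,
                              planted_dispersion = 0.003,
                              mu_mrna_meanlog = log(300),
                              mu_lnc_meanlog = log(60),
                              mu_sdlog = 0.8,
                              dispersion = 0.1,
                              de_frac = 0.15,
                              de_log2fc_range = c(1.8, 2.8),
                              depth_variation = 0.1,
                              cascade_failures = FALSE,
                              read_fixture = list(n_adapter = 10L,
                                                  n_poly_n = 5L,
                                                  n_low_quality = 5L,
                                                  n_clean = 80L,
                                                  read_length = 100L,
                                                  adapter = "AGATCGGAAGAGC")) {
  if (!is.numeric(seed) || length(seed) != 1) abort("seed must be a single integer")
  if (n_chrom < 1 || n_coding_genes < 1) abort("need >= 1 chromosome and gene")
  if (length(groups) < 1 || n_replicates < 1) abort("invalid design")
  if (length(planted_log2_offsets) != length(groups)) {
    abort("planted_log2_offsets must have one entry per group")
  }
  if (is.numeric(planted) && length(planted) == 1) {
    n_planted <- as.integer(planted)
    planted <- NULL
  } else {
    planted <- as_tibble(planted)
    if (!all(c("distance_bp", "location", "target_r") %in% names(planted))) {
      abort("planted needs columns distance_bp, location, target_r")
    }
    if (any(planted$distance_bp < 0) || any(abs(planted$target_r) > 1)) {
      abort("planted distances must be >= 0 and |target_r| <= 1")
    }
    if (any((planted$distance_bp == 0) != (planted$location == "overlapping"))) {
      abort("planted distance 0 <=> location 'overlapping'")
    }
    n_planted <- nrow(planted)
  }
  nf <- c("n_decoy_near", "n_decoy_far", "n_annotated_lnc")
  for (v in nf) if (get(v) < 0) abort(paste0(v, " must be >= 0"))
  if (n_annotated_lnc > n_decoy_far) {
    abort("n_annotated_lnc cannot exceed n_decoy_far")
  }
  rf <- read_fixture
  for (v in c("n_adapter", "n_poly_n", "n_low_quality", "n_clean")) {
    if (is.null(rf[[v]]) || rf[[v]] < 0) abort(paste0("read_fixture$", v, " must be >= 0"))
  }
  if (dispersion < 0 || planted_dispersion < 0) abort("dispersions must be >= 0")
  if (planted_mu <= 0) abort("planted_mu must be > 0")
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    n_coding_genes = as.integer(n_coding_genes),
    planted = planted, n_planted = n_planted,
    n_decoy_near = as.integer(n_decoy_near),
    n_decoy_far = as.integer(n_decoy_far),
    n_annotated_lnc = as.integer(n_annotated_lnc),
    window = window, groups = groups, n_replicates = as.integer(n_replicates),
    target_r = target_r, planted_log2_offsets = planted_log2_offsets,
    planted_mu = planted_mu, planted_dispersion = planted_dispersion,
    mu_mrna_meanlog = mu_mrna_meanlog, mu_lnc_meanlog = mu_lnc_meanlog,
    mu_sdlog = mu_sdlog, dispersion = dispersion, de_frac = de_frac,
    de_log2fc_range = de_log2fc_range, depth_variation = depth_variation,
    cascade_failures = isTRUE(cascade_failures), read_fixture = rf
  )
  class(cfg) <- "lnc_sim_config"
  cfg
}

sub_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 7 + offset) %% (.Machine$integer.max - 1))
}

# build exon rows for one transcript laid left-to-right from `start`
build_exons <- function(start, widths, introns, chrom, strand, tx, gene, biotype) {
  starts <- start + cumsum(c(0, head(widths, -1) + introns))
  tibble(chrom = chrom, start = starts, end = starts + widths,
         strand = strand, transcript_id = tx, gene_id = gene, biotype = biotype)
}

#' Generate a synthetic genome annotation with planted geometry
#'
#' Lays out coding genes along synthetic chromosomes with intergenic gaps
#' wide enough that the only (lncRNA, mRNA gene) pairs within the
#' co-localization window are the planted pairs and near decoys; planted
#' distances and locations are realised exactly (recomputing
#' [genomic_gap()] and the location rule on the emitted annotation returns
#' the planted values). lncRNA transcripts are built shorter and with
#' fewer exons than mRNAs; all get at least 2 exons and length > 200
#' unless deliberate cascade failures are requested.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `reference` (coding genes, plus any annotated
#'   lncRNAs), `candidates` (candidate lncRNA transcripts), `annotation`
#'   (both combined) and `truth` (the ledger: `$pairs`, `$lnc`,
#'   `$cascade`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "lnc_sim_config"))
  set.seed(sub_seed(cfg, 11L))
  n_genes <- cfg$n_coding_genes
  chroms <- paste0("chr", rep(seq_len(cfg$n_chrom), length.out = n_genes))
  chroms <- sort(chroms)

  gene_rows <- list()
  cursor <- setNames(rep(150000, cfg$n_chrom), paste0("chr", seq_len(cfg$n_chrom)))
  meta <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    ch <- chroms[[i]]
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(3:8, 1)
    widths <- round(runif(n_ex, 120, 400))
    introns <- round(runif(n_ex - 1, 500, 3000))
    gid <- sprintf("GENE_%04d", i)
    tid <- sprintf("MRNA_%04d", i)
    ex <- build_exons(cursor[[ch]], widths, introns, ch, strand, tid, gid, "coding")
    gene_rows[[length(gene_rows) + 1]] <- ex
    span <- c(min(ex$start), max(ex$end))
    meta[[i]] <- tibble(gene_id = gid, transcript_id = tid, chrom = ch,
                        strand = strand, start = span[[1]], end = span[[2]],
                        n_exons = n_ex)
    cursor[[ch]] <- span[[2]] + round(runif(1, 240000, 320000))
  }
  genes <- bind_rows(meta)

  planted <- cfg$planted
  if (is.null(planted)) {
    n <- cfg$n_planted
    loc <- if (n > 0) sample(c("upstream", "downstream"), n, replace = TRUE) else character(0)
    planted <- tibble(
      distance_bp = if (n > 0) round(runif(n, 200, 0.9 * cfg$window)) else integer(0),
      location = loc,
      target_r = rep(cfg$target_r, n)
    )
  }
  n_near <- cfg$n_decoy_near
  n_far <- cfg$n_decoy_far
  n_lnc <- nrow(planted) + n_near + n_far
  if (nrow(planted) + n_near > n_genes) {
    abort("unsatisfiable layout: more partnered lncRNAs than coding genes")
  }
  partner_idx <- sample.int(n_genes, nrow(planted) + n_near)

  # second isoforms only for unpartnered genes: partner expression profiles
  # must stay single-transcript so gene-level summaries are not blurred
  iso_pool <- setdiff(seq_len(n_genes), partner_idx)
  iso_pool <- iso_pool[genes$n_exons[iso_pool] >= 4]
  iso_pool <- iso_pool[runif(length(iso_pool)) < 0.2]
  for (i in iso_pool) {
    ex <- gene_rows[[i]]
    keep <- sort(sample(seq_len(nrow(ex)), nrow(ex) - 1))
    ex2 <- ex[keep, ]
    ex2$transcript_id <- paste0(ex2$transcript_id, "b")
    gene_rows[[length(gene_rows) + 1]] <- ex2
  }

  lnc_rows <- list()
  lnc_meta <- list()
  place_lnc <- function(idx, gene, distance, location, kind) {
    id <- sprintf("LNC_%04d", idx)
    n_ex <- sample(2:4, 1)
    widths <- round(runif(n_ex, 100, 500))
    introns <- if (n_ex > 1) round(runif(n_ex - 1, 200, 1500)) else integer(0)
    span_len <- sum(widths) + sum(introns)
    if (location == "overlapping") {
      # antisense transcript overlapping the gene's first exon
      gstrand <- if (gene$strand == "+") "-" else "+"
      start <- gene$start + 10
      ex <- build_exons(start, widths, introns, gene$chrom, gstrand, id,
                        paste0(id, "_G"), "unknown")
    } else {
      left <- (location == "upstream") == (gene$strand == "+")
      start <- if (left) gene$start - distance - span_len else gene$end + distance
      if (start < 0) abort("unsatisfiable layout: planted distance exceeds chromosome margin")
      ex <- build_exons(start, widths, introns, gene$chrom, sample(c("+", "-"), 1),
                        id, paste0(id, "_G"), "unknown")
    }
    lnc_rows[[length(lnc_rows) + 1]] <<- ex
    lnc_meta[[length(lnc_meta) + 1]] <<- tibble(
      lnc_id = id, kind = kind,
      partner_gene = if (is.na(distance)) NA_character_ else gene$gene_id,
      distance_bp = distance, location = location
    )
  }

  k <- 0L
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      k <- k + 1L
      place_lnc(k, genes[partner_idx[[i]], ], planted$distance_bp[[i]],
                planted$location[[i]], "planted")
    }
  }
  if (n_near > 0) {
    for (i in seq_len(n_near)) {
      k <- k + 1L
      place_lnc(k, genes[partner_idx[[nrow(planted) + i]], ],
                round(runif(1, 500, 0.9 * cfg$window)),
                sample(c("upstream", "downstream"), 1), "decoy_near")
    }
  }
  if (n_far > 0) {
    far_genes <- sample.int(n_genes, n_far, replace = n_far > n_genes)
    for (i in seq_len(n_far)) {
      k <- k + 1L
      g <- genes[far_genes[[i]], ]
      id <- sprintf("LNC_%04d", k)
      n_ex <- sample(2:4, 1)
      widths <- round(runif(n_ex, 100, 500))
      introns <- round(runif(n_ex - 1, 200, 1500))
      start <- g$end + round(110000 + runif(1, 0, 10000))
      ex <- build_exons(start, widths, introns, g$chrom, sample(c("+", "-"), 1),
                        id, paste0(id, "_G"), "unknown")
      lnc_rows[[length(lnc_rows) + 1]] <- ex
      lnc_meta[[length(lnc_meta) + 1]] <- tibble(
        lnc_id = id, kind = "decoy_far", partner_gene = NA_character_,
        distance_bp = NA_integer_, location = NA_character_
      )
    }
  }

  empty_lnc <- tibble(lnc_id = character(), kind = character(),
                      partner_gene = character(), distance_bp = integer(),
                      location = character())
  candidates <- bind_rows(c(list(empty_lnc[, 0]), lnc_rows))
  if (nrow(candidates) == 0) {
    candidates <- as_annotation(tibble(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), transcript_id = character(),
      gene_id = character(), biotype = character()
    ))
  }
  lnc_truth <- bind_rows(c(list(empty_lnc), lnc_meta))

  # mirror some far decoys in the reference as annotated lncRNAs
  reference <- bind_rows(gene_rows)
  if (cfg$n_annotated_lnc > 0) {
    far_ids <- lnc_truth$lnc_id[lnc_truth$kind == "decoy_far"]
    ann_ids <- head(far_ids, cfg$n_annotated_lnc)
    mirrored <- candidates[candidates$transcript_id %in% ann_ids, ]
    mirrored$transcript_id <- sub("^LNC_", "ANN_", mirrored$transcript_id)
    mirrored$gene_id <- sub("^LNC_", "ANN_", mirrored$gene_id)
    mirrored$biotype <- "annotated_lncRNA"
    reference <- bind_rows(reference, mirrored)
    lnc_truth$annotated <- lnc_truth$lnc_id %in% ann_ids
  } else {
    lnc_truth$annotated <- FALSE
  }

  cascade <- tibble(transcript_id = character(), expected_outcome = character(),
                    expected_first_failing_step = character())
  if (cfg$cascade_failures) {
    g <- genes[n_genes, ]
    far_start <- function() g$end + round(120000 + runif(1, 0, 5000))
    add <- function(ex, outcome, step) {
      candidates <<- bind_rows(candidates, ex)
      cascade <<- bind_rows(cascade, tibble(
        transcript_id = ex$transcript_id[[1]], expected_outcome = outcome,
        expected_first_failing_step = step
      ))
    }
    add(build_exons(far_start(), 600, integer(0), g$chrom, "+",
                    "FAIL_EXON", "FAIL_EXON_G", "unknown"),
        "rejected", "exon_count")
    add(build_exons(far_start(), c(80, 80), 300, g$chrom, "+",
                    "FAIL_LEN", "FAIL_LEN_G", "unknown"),
        "rejected", "length")
    gex <- reference[reference$gene_id == g$gene_id, ][1, ]
    add(tibble(chrom = gex$chrom,
               start = c(gex$start, gex$end + 500),
               end = c(gex$end, gex$end + 800),
               strand = gex$strand, transcript_id = "FAIL_OVERLAP",
               gene_id = "FAIL_OVERLAP_G", biotype = "unknown"),
        "rejected", "coding_exon_overlap")
    add(build_exons(far_start(), c(300, 300), 400, g$chrom, "-",
                    "FAIL_EXPR", "FAIL_EXPR_G", "unknown"),
        "rejected", "expression")
    add(build_exons(far_start(), c(400, 400), 500, g$chrom, "+",
                    "TUCP_CAND", "TUCP_CAND_G", "unknown"),
        "TUCP", NA_character_)
  }

  truth <- list(pairs = filter(lnc_truth, .data$kind == "planted") |>
                  left_join(planted |>
                              mutate(.row = dplyr::row_number()) |>
                              select(".row", "target_r") |>
                              mutate(lnc_id = sprintf("LNC_%04d", .data$.row)) |>
                              select("lnc_id", "target_r"),
                            by = "lnc_id"),
                lnc = lnc_truth,
                cascade = cascade,
                genes = genes)
  list(reference = as_annotation(reference),
       candidates = as_annotation(candidates),
       annotation = as_annotation(bind_rows(reference, candidates)),
       truth = truth)
}

# variance of the per-sample log fold-change pattern over the design
pattern_logvar <- function(log2_offsets, groups, n_rep) {
  v <- rep(log(2) * log2_offsets, each = n_rep)
  mean((v - mean(v))^2)
}

# shared-factor variance needed to reach |target_r| given common variance
# cg and member noise variances v1, v2 (solved numerically; 0 when the
# fold-change pattern alone already reaches the target)
solve_factor_variance <- function(target_r, cg, v1, v2) {
  target <- abs(target_r)
  r_of <- function(s2) (cg + s2) / sqrt((cg + s2 + v1) * (cg + s2 + v2))
  if (r_of(0) >= target) return(0)
  if (r_of(1000) < target) return(1000)
  uniroot(function(s2) r_of(s2) - target, c(0, 1000))$root
}

#' Generate NB count matrices with planted structure
#'
#' Counts are drawn per feature and sample from a negative binomial with
#' `variance = mu + phi * mu^2`. Differential features carry per-group
#' mean multipliers `2^offset`; both members of a planted pair share the
#' same offset pattern (mirrored for a negative target correlation) plus a
#' shared per-sample lognormal factor whose variance is solved numerically
#' so the expected log-scale Pearson correlation reaches the target
#' (NB noise alone caps the achievable correlation). Near decoys get
#' orthogonal patterns: the lncRNA and its neighbouring mRNA are both
#' differential, but never co-expressed.
#'
#' @param cfg A [simulation_config()].
#' @param sim Output of [simulate_annotation()] for the same config.
#' @return A list with `counts` (tibble, one row per transcript), `design`
#'   (a [study_design()]) and `truth` (the ledger extended with
#'   `$features`, per-feature per-group means and dispersions, and `$de`,
#'   the planted per-comparison fold changes).
#' @export
simulate_counts <- function(cfg, sim) {
  stopifnot(inherits(cfg, "lnc_sim_config"))
  set.seed(sub_seed(cfg, 127L))
  groups <- cfg$groups
  n_rep <- cfg$n_replicates
  samples <- paste0(rep(groups, each = n_rep), "_r", rep(seq_len(n_rep), length(groups)))
  design <- study_design(samples, rep(groups, each = n_rep))

  tx <- transcript_table(sim$annotation)
  truth <- sim$truth
  lnc_truth <- truth$lnc
  genes <- truth$genes

  ng <- length(groups)
  feats <- tx |>
    mutate(type = dplyr::case_when(
      .data$biotype == "coding" ~ "mRNA",
      .data$biotype == "annotated_lncRNA" ~ "annotated_lncRNA",
      TRUE ~ "lncRNA"
    ))
  # reference-mirrored annotated lncRNAs are not separate expressed units
  feats <- filter(feats, !grepl("^ANN_", .data$transcript_id))
  n_feat <- nrow(feats)

  mu_base <- ifelse(
    feats$type == "mRNA",
    exp(rnorm(n_feat, cfg$mu_mrna_meanlog, cfg$mu_sdlog)),
    exp(rnorm(n_feat, cfg$mu_lnc_meanlog, cfg$mu_sdlog))
  )
  mu_base <- pmax(mu_base, 5)
  phi <- rep(cfg$dispersion, n_feat)
  offsets <- matrix(0, n_feat, ng, dimnames = list(feats$transcript_id, groups))

  rand_pattern <- function() {
    x <- runif(1, cfg$de_log2fc_range[[1]], cfg$de_log2fc_range[[2]]) *
      sample(c(-1, 1), 1)
    shape <- sample(1:3, 1)
    if (ng < 3) return(c(0, rep(x, ng - 1)))
    out <- rep(0, ng)
    if (shape == 1) out[2] <- x
    if (shape == 2) out[3] <- x
    if (shape == 3) { out[2] <- x; out[3] <- x / 2 }
    out
  }

  planted_ids <- lnc_truth$lnc_id[lnc_truth$kind == "planted"]
  near_ids <- lnc_truth$lnc_id[lnc_truth$kind == "decoy_near"]
  partner_of <- setNames(lnc_truth$partner_gene, lnc_truth$lnc_id)
  gene_tx <- setNames(genes$transcript_id, genes$gene_id)

  # planted pairs: shared pattern, boosted mean, tight dispersion
  pair_sigma2 <- setNames(rep(0, length(planted_ids)), planted_ids)
  for (id in planted_ids) {
    tr <- truth$pairs$target_r[truth$pairs$lnc_id == id][[1]]
    sgn <- if (tr < 0) -1 else 1
    p_lnc <- match(id, feats$transcript_id)
    p_mrna <- match(gene_tx[[partner_of[[id]]]], feats$transcript_id)
    offsets[p_mrna, ] <- cfg$planted_log2_offsets
    offsets[p_lnc, ] <- sgn * cfg$planted_log2_offsets
    mu_base[c(p_lnc, p_mrna)] <- cfg$planted_mu
    phi[c(p_lnc, p_mrna)] <- cfg$planted_dispersion
    cg <- pattern_logvar(cfg$planted_log2_offsets, groups, n_rep)
    v <- 1 / cfg$planted_mu + cfg$planted_dispersion
    pair_sigma2[[id]] <- solve_factor_variance(tr, cg, v, v)
  }

  # near decoys: lncRNA and neighbour mRNA differential but orthogonal
  for (i in seq_along(near_ids)) {
    id <- near_ids[[i]]
    p_lnc <- match(id, feats$transcript_id)
    p_mrna <- match(gene_tx[[partner_of[[id]]]], feats$transcript_id)
    x <- runif(1, cfg$de_log2fc_range[[1]], cfg$de_log2fc_range[[2]])
    y <- runif(1, cfg$de_log2fc_range[[1]], cfg$de_log2fc_range[[2]])
    if (ng >= 3) {
      # exactly orthogonal group patterns: "up in the middle group only"
      # vs a monotonic gradient; differential in every comparison yet with
      # zero group-level correlation, so proximity alone never yields a
      # co-expression edge
      offsets[p_mrna, 2] <- x
      sgn <- sample(c(-1, 1), 1)
      offsets[p_lnc, 1] <- sgn * y / 2
      offsets[p_lnc, 3] <- -sgn * y / 2
    } else {
      offsets[p_mrna, ng] <- x
      offsets[p_lnc, ng] <- -y
    }
    mu_base[c(p_lnc, p_mrna)] <- pmax(mu_base[c(p_lnc, p_mrna)], 100)
  }

  # background differential mRNAs
  partnered_tx <- gene_tx[stats::na.omit(unname(partner_of))]
  bg <- which(feats$type == "mRNA" & !feats$transcript_id %in% partnered_tx &
                !grepl("b$", feats$transcript_id))
  n_de_bg <- round(cfg$de_frac * length(bg))
  if (n_de_bg > 0) {
    for (j in sample(bg, n_de_bg)) offsets[j, ] <- rand_pattern()
  }

  # deliberate expression failure
  if (nrow(truth$cascade) > 0) {
    fe <- match("FAIL_EXPR", feats$transcript_id)
    if (!is.na(fe)) mu_base[[fe]] <- 0
  }

  # isoforms of a multi-transcript gene share the gene's pattern
  iso <- grepl("b$", feats$transcript_id)
  if (any(iso)) {
    main <- sub("b$", "", feats$transcript_id[iso])
    offsets[iso, ] <- offsets[match(main, feats$transcript_id), , drop = FALSE]
  }

  depth <- if (cfg$depth_variation > 0) {
    runif(length(samples), 1 - cfg$depth_variation, 1 + cfg$depth_variation)
  } else rep(1, length(samples))

  group_of <- rep(seq_along(groups), each = n_rep)
  mu_mat <- mu_base * 2^offsets[, group_of, drop = FALSE]
  colnames(mu_mat) <- samples

  # shared per-sample lognormal factor for planted pairs
  for (id in planted_ids) {
    s2 <- pair_sigma2[[id]]
    if (s2 <= 0) next
    tr <- truth$pairs$target_r[truth$pairs$lnc_id == id][[1]]
    sgn <- if (tr < 0) -1 else 1
    u <- rnorm(length(samples), 0, sqrt(s2))
    p_lnc <- match(id, feats$transcript_id)
    p_mrna <- match(gene_tx[[partner_of[[id]]]], feats$transcript_id)
    mu_mat[p_mrna, ] <- mu_mat[p_mrna, ] * exp(u - s2 / 2)
    mu_mat[p_lnc, ] <- mu_mat[p_lnc, ] * exp(sgn * u - s2 / 2)
  }

  mu_mat <- sweep(mu_mat, 2, depth, "*")
  counts <- matrix(0L, n_feat, length(samples),
                   dimnames = list(feats$transcript_id, samples))
  for (j in seq_along(samples)) {
    mu_j <- mu_mat[, j]
    pois <- phi <= 1e-12 & mu_j > 0
    nb <- phi > 1e-12 & mu_j > 0
    if (any(pois)) counts[pois, j] <- stats::rpois(sum(pois), mu_j[pois])
    if (any(nb)) {
      counts[nb, j] <- rnbinom(sum(nb), mu = mu_j[nb], size = 1 / phi[nb])
    }
  }

  feature_truth <- bind_cols(
    tibble(feature_id = feats$transcript_id, type = feats$type,
           gene_id = feats$gene_id, mu_base = mu_base, dispersion = phi),
    as_tibble(setNames(as.data.frame(mu_base * 2^offsets),
                       paste0("mu_", groups)))
  )
  ordered_pairs <- expand.grid(b = groups, a = groups,
                               stringsAsFactors = FALSE)
  ordered_pairs <- ordered_pairs[ordered_pairs$b != ordered_pairs$a, ]
  de_truth <- bind_rows(c(
    list(tibble(feature_id = character(), comparison = character(),
                log2fc_true = numeric())),
    lapply(seq_len(nrow(ordered_pairs)), function(i) {
      b <- ordered_pairs$b[[i]]; a <- ordered_pairs$a[[i]]
      tibble(feature_id = feats$transcript_id,
             comparison = paste(b, "vs", a),
             log2fc_true = offsets[, match(b, groups)] - offsets[, match(a, groups)])
    })))

  truth$features <- feature_truth
  truth$de <- filter(de_truth, .data$log2fc_true != 0)
  truth$pairs$sigma2 <- unname(pair_sigma2[truth$pairs$lnc_id])

  list(counts = matrix_to_tibble(counts), design = design, truth = truth)
}

#' Generate a FASTQ fixture with known contamination
#'
#' Emits exactly the configured numbers of adapter-bearing, poly-N,
#' low-quality and clean reads (Phred+33), tagged by category in the read
#' ids so QC results can be checked against the ledger. Clean reads are
#' adapter-free, N-free and high-quality by construction; contaminated
#' reads fail exactly their own rule.
#'
#' @param cfg A [simulation_config()] (the `read_fixture` entry is used).
#' @param path Optional path; when given the reads are also written as
#'   FASTQ.
#' @return A tibble of reads (`id`, `seq`, `qual`).
#' @export
simulate_reads <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "lnc_sim_config"))
  set.seed(sub_seed(cfg, 911L))
  rf <- cfg$read_fixture
  len <- rf$read_length
  adapter <- rf$adapter

  rand_seq <- function(n) {
    vapply(seq_len(n), function(i) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
        if (!grepl(adapter, s, fixed = TRUE)) return(s)
      }
    }, character(1))
  }
  qual_str <- function(n, lo, hi) {
    vapply(seq_len(n), function(i) {
      intToUtf8(33L + sample(lo:hi, len, replace = TRUE))
    }, character(1))
  }
  insert_adapter <- function(s) {
    pos <- sample.int(len - nchar(adapter) + 1, 1)
    paste0(substr(s, 1, pos - 1), adapter,
           substr(s, pos + nchar(adapter), len))
  }
  add_n <- function(s, frac) {
    k <- ceiling(frac * len)
    pos <- sample.int(len, k)
    v <- strsplit(s, "")[[1]]
    v[pos] <- "N"
    paste(v, collapse = "")
  }

  blocks <- list()
  if (rf$n_adapter > 0) {
    blocks$adapter <- tibble(
      id = sprintf("adapter_%04d", seq_len(rf$n_adapter)),
      seq = vapply(rand_seq(rf$n_adapter), insert_adapter, character(1),
                   USE.NAMES = FALSE),
      qual = qual_str(rf$n_adapter, 30, 40)
    )
  }
  if (rf$n_poly_n > 0) {
    blocks$poly_n <- tibble(
      id = sprintf("polyn_%04d", seq_len(rf$n_poly_n)),
      seq = vapply(rand_seq(rf$n_poly_n), add_n, character(1), frac = 0.2,
                   USE.NAMES = FALSE),
      qual = qual_str(rf$n_poly_n, 30, 40)
    )
  }
  if (rf$n_low_quality > 0) {
    n_low <- ceiling(0.6 * len)
    blocks$low_quality <- tibble(
      id = sprintf("lowqual_%04d", seq_len(rf$n_low_quality)),
      seq = rand_seq(rf$n_low_quality),
      qual = vapply(seq_len(rf$n_low_quality), function(i) {
        q <- c(sample(0:4, n_low, replace = TRUE),
               sample(30:40, len - n_low, replace = TRUE))
        intToUtf8(33L + sample(q))
      }, character(1))
    )
  }
  if (rf$n_clean > 0) {
    blocks$clean <- tibble(
      id = sprintf("clean_%04d", seq_len(rf$n_clean)),
      seq = rand_seq(rf$n_clean),
      qual = qual_str(rf$n_clean, 30, 40)
    )
  }
  reads <- if (length(blocks) > 0) bind_rows(blocks) else
    tibble(id = character(), seq = character(), qual = character())
  if (!is.null(path)) write_fastq(reads, path)
  reads
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_annotation()] and [simulate_counts()] and assembles the
#' inputs the analysis pipeline consumes: reference and candidate
#' annotations, transcript-level counts, the study design, coding-potential
#' calls for the candidates (all non-coding except any planted TUCP), and
#' the truth ledger.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `reference`, `candidates`, `annotation`, `counts`,
#'   `design`, `coding_calls`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  sim <- simulate_annotation(cfg)
  cc <- simulate_counts(cfg, sim)
  cand_ids <- unique(sim$candidates$transcript_id)
  coding_calls <- tibble(
    transcript_id = cand_ids,
    orf = cand_ids %in% sim$truth$cascade$transcript_id[
      sim$truth$cascade$expected_outcome == "TUCP"]
  )
  list(reference = sim$reference, candidates = sim$candidates,
       annotation = sim$annotation, counts = cc$counts, design = cc$design,
       coding_calls = coding_calls, truth = cc$truth)
}
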