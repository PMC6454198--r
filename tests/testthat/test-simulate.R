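test_that("the generator is reproducible by seed and sensitive to it", {
  cfg <- simulation_config(seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(simulation_config(seed = 5))
  expect_identical(a$counts, b$counts)
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
  expect_identical(simulate_reads(cfg), simulate_reads(cfg))
  c_ <- simulate_dataset(simulation_config(seed = 6))
  expect_false(identical(a$counts, c_$counts))
})

test_that("planted genomic geometry is realised exactly across layouts", {
  set.seed(99)
  for (i in 1:20) {
    planted <- tibble::tibble(
      distance_bp = sample(c(0L, sample(100:90000, 3)), 4),
      location = NA,
      target_r = 0.99
    )
    planted$location <- ifelse(
      planted$distance_bp == 0, "overlapping",
      sample(c("upstream", "downstream"), 4, replace = TRUE))
    cfg <- simulation_config(seed = 1000 + i, planted = planted,
                             n_decoy_near = 2, n_decoy_far = 2,
                             n_annotated_lnc = 0, n_coding_genes = 30)
    sim <- simulate_annotation(cfg)
    edges <- colocalization_edges(sim$annotation, sim$truth$pairs$lnc_id,
                                  unique(sim$truth$pairs$partner_gene),
                                  window = 2e5)
    got <- dplyr::inner_join(
      sim$truth$pairs, edges,
      by = c(lnc_id = "lnc_id", partner_gene = "mrna_id"))
    expect_equal(nrow(got), nrow(sim$truth$pairs))
    expect_equal(got$distance_bp.y, as.integer(got$distance_bp.x))
    expect_equal(got$location.y, got$location.x)
  }
})

test_that("a planted distance of zero is overlapping, and inconsistency errors", {
  expect_error(
    simulation_config(planted = tibble::tibble(
      distance_bp = 0, location = "downstream", target_r = 0.9)),
    "overlapping")
})

test_that("NB counts match configured moments in the near-Poisson limit", {
  cfg <- simulation_config(
    seed = 8, n_coding_genes = 5, planted = 0, n_decoy_near = 0,
    n_decoy_far = 0, n_annotated_lnc = 0, groups = "g1", n_replicates = 200,
    planted_log2_offsets = 0, mu_mrna_meanlog = log(1000), mu_sdlog = 0,
    dispersion = 0, de_frac = 0, depth_variation = 0)
  cc <- simulate_counts(cfg, simulate_annotation(cfg))
  m <- as.matrix(cc$counts[, -1])
  expect_true(all(abs(rowMeans(m) / 1000 - 1) < 0.05))
})

test_that("empirical NB variance tracks mu + phi * mu^2", {
  cfg <- simulation_config(
    seed = 9, n_coding_genes = 8, planted = 0, n_decoy_near = 0,
    n_decoy_far = 0, n_annotated_lnc = 0, groups = "g1", n_replicates = 400,
    planted_log2_offsets = 0, mu_mrna_meanlog = log(500), mu_sdlog = 0,
    dispersion = 0.1, de_frac = 0, depth_variation = 0)
  cc <- simulate_counts(cfg, simulate_annotation(cfg))
  m <- as.matrix(cc$counts[, -1])
  expected <- 500 + 0.1 * 500^2
  ratio <- apply(m, 1, var) / expected
  expect_true(all(ratio > 0.6 & ratio < 1.6))
})

test_that("a null configuration plants no group differences", {
  cfg <- simulation_config(seed = 10, n_coding_genes = 10, planted = 0,
                           n_decoy_near = 0, n_decoy_far = 2,
                           n_annotated_lnc = 0, de_frac = 0)
  cc <- simulate_counts(cfg, simulate_annotation(cfg))
  mu_cols <- paste0("mu_", cfg$groups)
  mus <- cc$truth$features[, mu_cols]
  expect_true(all(mus[[1]] == mus[[2]] & mus[[2]] == mus[[3]]))
  expect_equal(nrow(cc$truth$de), 0)
})

test_that("planted correlation is realised on the log-expression scale", {
  hits <- 0
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(seed = 2000 + s, n_coding_genes = 12,
                             planted = 1, n_decoy_near = 0, n_decoy_far = 2,
                             n_annotated_lnc = 0)
    sim <- simulate_annotation(cfg)
    cc <- simulate_counts(cfg, sim)
    tx <- transcript_table(sim$annotation)
    fpkm <- compute_fpkm(cc$counts,
                         setNames(tx$length, tx$transcript_id))
    m <- log2(as.matrix(fpkm[, -1]) + 1)
    rownames(m) <- fpkm$feature_id
    pair <- cc$truth$pairs
    gene_tx <- cc$truth$genes$transcript_id[
      cc$truth$genes$gene_id == pair$partner_gene]
    r <- cor(m[pair$lnc_id, ], m[gene_tx, ])
    if (r >= 0.9) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("read fixtures carry exactly the configured contamination", {
  cfg <- simulation_config(seed = 4)
  reads <- simulate_reads(cfg)
  expect_equal(nrow(reads), 100)
  expect_equal(sum(grepl("^adapter", reads$id)), 10)
  expect_equal(sum(grepl("^polyn", reads$id)), 5)
  expect_equal(sum(grepl("^lowqual", reads$id)), 5)
  expect_equal(sum(grepl("^clean", reads$id)), 80)

  # an all-clean configuration and the empty configuration
  clean_cfg <- simulation_config(seed = 4, read_fixture = list(
    n_adapter = 0L, n_poly_n = 0L, n_low_quality = 0L, n_clean = 100L,
    read_length = 80L, adapter = "AGATCGGAAGAGC"))
  clean <- simulate_reads(clean_cfg)
  res <- filter_reads(clean)
  expect_equal(nrow(res$clean), 100)

  empty_cfg <- simulation_config(seed = 4, read_fixture = list(
    n_adapter = 0L, n_poly_n = 0L, n_low_quality = 0L, n_clean = 0L,
    read_length = 80L, adapter = "AGATCGGAAGAGC"))
  f <- withr::local_tempfile(fileext = ".fastq")
  empty <- simulate_reads(empty_cfg, f)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(read_fastq(f)), 0)
})

test_that("the FASTQ writer round-trips generated reads", {
  reads <- simulate_reads(simulation_config(seed = 12))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(as.data.frame(back), as.data.frame(reads))
})
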