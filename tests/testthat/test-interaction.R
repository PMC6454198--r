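test_that("pearson_test matches the covariance formula and t model", {
  x <- 1:9
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_test(x, 2 * x + 1)$p, .Machine$double.xmin)

  set.seed(12)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    pt_res <- pearson_test(a, b)
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pt_res$r, r_oracle, tolerance = 1e-12)
    t_oracle <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
    expect_equal(pt_res$p, 2 * pt(-abs(t_oracle), n - 2), tolerance = 1e-12)
  }

  expect_error(pearson_test(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_test(1:2, 1:2), "n >= 3")
})

test_that("the p-value decreases strictly in |r| at fixed n", {
  rs <- seq(0.1, 0.99, by = 0.01)
  ps <- vapply(rs, function(r) {
    lncpair:::pearson_p(r, 9)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("co-expression edges honour their thresholds", {
  set.seed(13)
  m <- matrix(rnorm(9 * 8), 8)
  m[2, ] <- m[1, ] + rnorm(9, sd = 0.01)  # one strongly correlated pair
  expr <- dplyr::bind_cols(
    tibble::tibble(feature_id = c(paste0("l", 1:4), paste0("g", 1:4))),
    tibble::as_tibble(matrix(m, 8, dimnames = list(NULL, paste0("s", 1:9)))))
  lnc <- paste0("l", 1:4); mrna <- paste0("g", 1:4)

  all_edges <- coexpression_edges(expr, lnc, mrna, min_abs_r = 0, max_p = 1)
  expect_equal(nrow(all_edges), 16)

  none <- coexpression_edges(expr, lnc, mrna, min_abs_r = 1.01, max_p = 1)
  expect_equal(nrow(none), 0)

  # the planted pair survives default thresholds (l2 tracks l1's profile,
  # which is feature g-side here); rebuild with the pair split across sides
  expr2 <- expr
  expr2[5, -1] <- expr[1, -1] + rnorm(9, sd = 0.01)
  strong <- coexpression_edges(expr2, "l1", "g1", 0.95, 1e-4)
  expect_equal(nrow(strong), 1)
  expect_gt(abs(strong$r), 0.99)

  expect_error(coexpression_edges(expr, c(lnc, "missing"), mrna),
               "missing from expr")

  # edges computed from the same data with tighter thresholds are a subset
  loose <- coexpression_edges(expr2, lnc, mrna, 0.3, 0.9)
  tight <- coexpression_edges(expr2, lnc, mrna, 0.6, 0.5)
  expect_true(all(paste(tight$lnc_id, tight$mrna_id) %in%
                    paste(loose$lnc_id, loose$mrna_id)))
})

test_that("co-expression p-values are uniform under independence", {
  set.seed(14)
  n_rep <- 3000
  ps <- vapply(seq_len(n_rep), function(i) {
    pearson_test(rnorm(9), rnorm(9))$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("co-localization distance and orientation follow the mRNA's strand", {
  ann <- as_annotation(dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = c(10000, 11500), end = c(10800, 12000),
                   strand = "+", transcript_id = "m1", gene_id = "geneA",
                   biotype = "coding"),
    tibble::tibble(chrom = "chr1", start = c(12200, 12700), end = c(12500, 12900),
                   strand = "+", transcript_id = "lnc1", gene_id = "lnc1g",
                   biotype = "unknown")
  ))
  e <- colocalization_edges(ann, "lnc1", "geneA", window = 1e5)
  expect_equal(e$distance_bp, 200L)
  expect_equal(e$location, "downstream")

  ann_minus <- ann
  ann_minus$strand[ann_minus$gene_id == "geneA"] <- "-"
  e2 <- colocalization_edges(ann_minus, "lnc1", "geneA", window = 1e5)
  expect_equal(e2$distance_bp, 200L)
  expect_equal(e2$location, "upstream")

  # overlap means distance zero and location 'overlapping'
  ann_ov <- ann
  ann_ov$start[ann_ov$transcript_id == "lnc1"] <- c(10500, 11000)
  ann_ov$end[ann_ov$transcript_id == "lnc1"] <- c(10900, 11200)
  e3 <- colocalization_edges(ann_ov, "lnc1", "geneA", window = 1e5)
  expect_equal(e3$distance_bp, 0L)
  expect_equal(e3$location, "overlapping")

  # beyond the window: no edge
  expect_equal(nrow(colocalization_edges(ann, "lnc1", "geneA", window = 100)), 0)
  expect_error(colocalization_edges(ann, "nope", "geneA"), "missing")
})

test_that("edges are monotone in the window on random layouts", {
  for (s in c(31, 32, 33)) {
    sim <- simulate_annotation(simulation_config(seed = s))
    lnc <- sim$truth$lnc$lnc_id
    genes <- gene_table(sim$reference)$gene_id
    small <- colocalization_edges(sim$annotation, lnc, genes, window = 5e4)
    big <- colocalization_edges(sim$annotation, lnc, genes, window = 1e5)
    expect_true(all(paste(small$lnc_id, small$mrna_id) %in%
                      paste(big$lnc_id, big$mrna_id)))
  }
})

test_that("interaction overlap is the pairwise intersection of edge lists", {
  coexp <- tibble::tibble(lnc_id = c("l1", "l2"), mrna_id = c("m1", "m2"),
                          r = c(0.99, -0.97), p = c(1e-6, 1e-5))
  coloc <- tibble::tibble(lnc_id = c("l1", "l3"), mrna_id = c("m1", "m3"),
                          distance_bp = c(100L, 5L),
                          location = c("upstream", "downstream"))
  both <- overlap_interactions(coexp, coloc)
  expect_equal(nrow(both), 1)
  expect_equal(both$lnc_id, "l1")
  expect_lte(nrow(both), min(nrow(coexp), nrow(coloc)))

  disjoint <- overlap_interactions(coexp[2, ], coloc[2, ])
  expect_equal(nrow(disjoint), 0)

  same <- overlap_interactions(coexp, dplyr::mutate(
    coexp[, 1:2], distance_bp = 1L, location = "upstream"))
  expect_equal(nrow(same), nrow(coexp))
})

test_that("cross-comparison intersection keeps only ubiquitous pairs", {
  a <- tibble::tibble(lnc_id = c("l1", "l2", "l3"),
                      mrna_id = c("m1", "m2", "m3"))
  b <- tibble::tibble(lnc_id = c("l1", "l3"), mrna_id = c("m1", "m3"))
  c_ <- tibble::tibble(lnc_id = "l1", mrna_id = "m1")
  shared <- intersect_across_comparisons(list(A = a, B = b, C = c_))
  expect_equal(nrow(shared), 1)
  expect_equal(shared$lnc_id, "l1")
  expect_equal(shared$comparisons, "A;B;C")
  # result is a subset of every per-comparison list
  for (d in list(a, b, c_)) {
    expect_true(all(paste(shared$lnc_id, shared$mrna_id) %in%
                      paste(d$lnc_id, d$mrna_id)))
  }

  expect_equal(nrow(intersect_across_comparisons(list(A = a))), nrow(a))
  expect_equal(nrow(intersect_across_comparisons(list(A = a, B = a[0, ]))), 0)
})

test_that("venn region counts equal brute-force membership enumeration", {
  same <- list(A = letters[1:5], B = letters[1:5], C = letters[1:5])
  v <- venn_counts(same)
  expect_equal(v$count[v$region == "A&B&C"], 5)
  expect_equal(sum(v$count), 5)

  disjoint <- list(A = letters[1:3], B = letters[4:6], C = letters[7:9])
  v2 <- venn_counts(disjoint)
  expect_equal(v2$count[v2$region == "A&B&C"], 0)

  set.seed(15)
  for (i in 1:10) {
    sets <- list(A = sample(letters, 8), B = sample(letters, 12),
                 C = sample(letters, 5))
    v3 <- venn_counts(sets)
    universe <- unique(unlist(sets))
    for (j in seq_len(nrow(v3))) {
      pat <- unlist(v3[j, c("A", "B", "C")])
      oracle <- sum(vapply(universe, function(el) {
        all(c(el %in% sets$A, el %in% sets$B, el %in% sets$C) == pat)
      }, logical(1)))
      expect_equal(v3$count[[j]], oracle)
    }
    expect_equal(sum(v3$count), length(universe))
  }

  expect_error(venn_counts(list(A = "a")), "2 or 3")
  expect_error(venn_counts(list(A = "a", B = "b", C = "c", D = "d")), "2 or 3")
})
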