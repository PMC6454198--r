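mk_tx <- function(id, chrom, strand, starts, ends, gene = paste0(id, "_g"),
                  biotype = "unknown") {
  tibble::tibble(chrom = chrom, start = starts, end = ends, strand = strand,
                 transcript_id = id, gene_id = gene, biotype = biotype)
}

discovery_fixture <- function() {
  reference <- dplyr::bind_rows(
    mk_tx("ref_cod", "chrA", "+", c(1000, 1600), c(1500, 2000),
          gene = "ref_cod_g", biotype = "coding"),
    mk_tx("ref_lnc", "chrA", "+", c(10000, 11000), c(10500, 11400),
          gene = "ref_lnc_g", biotype = "annotated_lncRNA")
  )
  candidates <- dplyr::bind_rows(
    mk_tx("c_exon1", "chrA", "+", 30000, 30800),
    mk_tx("c_short", "chrA", "+", c(31000, 31200), c(31080, 31300)),
    mk_tx("c_coding_same", "chrA", "+", c(1100, 2500), c(1300, 2800)),
    mk_tx("c_coding_anti", "chrA", "-", c(1100, 2500), c(1300, 2800)),
    mk_tx("c_lowexpr", "chrA", "+", c(40000, 41000), c(40400, 41300)),
    mk_tx("c_annotated", "chrA", "+", c(10100, 11050), c(10400, 11300)),
    mk_tx("c_annot_low", "chrA", "+", c(10050, 11100), c(10450, 11350)),
    mk_tx("c_tucp", "chrA", "+", c(50000, 51000), c(50400, 51200)),
    mk_tx("c_tucp2", "chrA", "-", c(52000, 53000), c(52400, 53200)),
    mk_tx("c_novel1", "chrA", "+", c(54000, 55000), c(54400, 55200)),
    mk_tx("c_novel2", "chrB", "-", c(100, 900), c(500, 1400)),
    mk_tx("c_multi", "chrA", "+", 1100, 1180)  # 1 exon, 80 bp, coding overlap
  )
  ids <- unique(candidates$transcript_id)
  fpkm <- tibble::tibble(
    feature_id = ids,
    s1 = ifelse(ids %in% c("c_lowexpr", "c_annot_low"), 0.3, 5),
    s2 = ifelse(ids %in% c("c_lowexpr", "c_annot_low"), 0.1, 1)
  )
  calls <- tibble::tibble(
    transcript_id = ids,
    cpc = ids %in% "c_tucp",
    cnci = ids %in% c("c_tucp", "c_tucp2")
  )
  list(reference = as_annotation(reference),
       candidates = as_annotation(candidates), fpkm = fpkm, calls = calls)
}

test_that("the filtration cascade matches the rule-by-rule oracle", {
  fx <- discovery_fixture()
  res <- filter_lncrna_candidates(fx$candidates, fx$reference, fx$fpkm,
                                  fx$calls)
  oracle <- cascade_oracle(fx$candidates, fx$reference, fx$fpkm, fx$calls)
  got <- dplyr::arrange(res$report, transcript_id)
  exp <- dplyr::arrange(tibble::as_tibble(oracle), transcript_id)
  expect_equal(got$outcome, exp$outcome)
  expect_equal(got$first_failing_step, exp$first_failing_step)

  report <- setNames(res$report$outcome, res$report$transcript_id)
  expect_equal(report[["c_exon1"]], "rejected")
  expect_equal(report[["c_short"]], "rejected")
  expect_equal(report[["c_coding_same"]], "rejected")
  expect_equal(report[["c_coding_anti"]], "novel_lncRNA")
  expect_equal(report[["c_annotated"]], "annotated_lncRNA")
  expect_equal(report[["c_annot_low"]], "rejected")
  expect_equal(report[["c_tucp"]], "TUCP")
  expect_equal(report[["c_tucp2"]], "TUCP")
  expect_equal(report[["c_novel1"]], "novel_lncRNA")

  steps <- setNames(res$report$first_failing_step, res$report$transcript_id)
  expect_equal(steps[["c_exon1"]], "exon_count")
  expect_equal(steps[["c_short"]], "length")
  expect_equal(steps[["c_coding_same"]], "coding_exon_overlap")
  expect_equal(steps[["c_lowexpr"]], "expression")
  # a transcript failing several steps is counted under the first
  expect_equal(steps[["c_multi"]], "exon_count")
})

test_that("cascade outcomes partition the candidates and counts are non-increasing", {
  fx <- discovery_fixture()
  res <- filter_lncrna_candidates(fx$candidates, fx$reference, fx$fpkm,
                                  fx$calls)
  gl <- glance(res)
  expect_equal(gl$n_novel + gl$n_annotated + gl$n_tucp + gl$n_rejected,
               gl$n_candidates)
  expect_true(all(diff(res$steps$survivors) <= 0))
})

test_that("missing inputs are reported as errors", {
  fx <- discovery_fixture()
  expect_error(
    filter_lncrna_candidates(fx$candidates, fx$reference,
                             fx$fpkm[fx$fpkm$feature_id != "c_novel1", ],
                             fx$calls),
    "FPKM")
  expect_error(
    filter_lncrna_candidates(fx$candidates, fx$reference, fx$fpkm,
                             fx$calls[fx$calls$transcript_id != "c_novel1", ]),
    "coding call")
})

test_that("engineered generator failures land on their planted steps", {
  ds <- simulate_dataset(simulation_config(seed = 17, cascade_failures = TRUE))
  tx <- transcript_table(ds$annotation)
  fpkm <- compute_fpkm(ds$counts, setNames(tx$length, tx$transcript_id))
  res <- filter_lncrna_candidates(ds$candidates, ds$reference, fpkm,
                                  ds$coding_calls)
  truth <- ds$truth$cascade
  got <- dplyr::inner_join(res$report, truth, by = "transcript_id")
  expect_equal(nrow(got), nrow(truth))
  expect_equal(got$outcome, got$expected_outcome)
  keep <- !is.na(got$expected_first_failing_step)
  expect_equal(got$first_failing_step[keep],
               got$expected_first_failing_step[keep])
})

test_that("positional classes follow the antisense > intronic > lincRNA rule", {
  reference <- as_annotation(
    mk_tx("cod", "chr1", "+", c(1000, 5000), c(1500, 5500),
          gene = "cod_g", biotype = "coding"))
  # exonic overlap on the opposite strand
  anti <- as_annotation(mk_tx("anti", "chr1", "-", c(1200, 2000),
                              c(1600, 2300)))
  # contained in the intron, same strand, no exonic overlap
  intr <- as_annotation(mk_tx("intr", "chr1", "+", c(2000, 3000),
                              c(2400, 3400)))
  # no overlap with any coding span
  linc <- as_annotation(mk_tx("linc", "chr1", "+", c(100000, 101000),
                              c(100400, 101400)))
  # a chromosome with no coding genes at all
  lonely <- as_annotation(mk_tx("lonely", "chr9", "-", c(10, 500),
                                c(200, 900)))
  all_cls <- classify_lncrna(dplyr::bind_rows(anti, intr, linc, lonely),
                             reference)
  cls <- setNames(all_cls$class, all_cls$transcript_id)
  expect_equal(cls[["anti"]], "antisense")
  expect_equal(cls[["intr"]], "intronic")
  expect_equal(cls[["linc"]], "lincRNA")
  expect_equal(cls[["lonely"]], "lincRNA")

  # same-strand exonic overlap forbids intronic; antisense takes precedence
  both <- as_annotation(mk_tx("both", "chr1", "-", c(1100, 2000),
                              c(1300, 2200)))
  expect_equal(classify_lncrna(both, reference)$class, "antisense")
})

test_that("the ORF heuristic matches its boundary cases and a brute-force scan", {
  non_stop <- strrep("GCT", 99)
  expect_true(orf_coding_heuristic(paste0("ATG", non_stop, "TAA"), 100))
  expect_false(orf_coding_heuristic(paste0("ATG", strrep("GCT", 98), "TAA"), 100))
  expect_false(orf_coding_heuristic(strrep("TAA", 120), 100))
  # ORF may run off the 3' end
  expect_true(orf_coding_heuristic(paste0("ATG", strrep("GCT", 99)), 100))

  set.seed(44)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    for (th in c(20, 50, 100)) {
      expect_identical(orf_coding_heuristic(s, th), orf_oracle(s, th))
    }
  }
})

test_that("feature summaries reflect planted lncRNA/mRNA differences", {
  sim <- simulate_annotation(simulation_config(seed = 19))
  ann <- sim$annotation
  tx <- transcript_table(ann)
  classes <- tibble::tibble(
    transcript_id = tx$transcript_id,
    class = ifelse(tx$biotype == "coding", "mRNA", "lncRNA"))
  sm <- summarize_transcript_features(ann, classes)
  len <- dplyr::filter(sm, metric == "length")
  expect_lt(len$median[len$class == "lncRNA"],
            len$median[len$class == "mRNA"])
  nex <- dplyr::filter(sm, metric == "n_exons")
  expect_lte(nex$median[nex$class == "lncRNA"],
             nex$median[nex$class == "mRNA"])

  # identical inputs give identical summaries; a single transcript collapses
  one <- ann[ann$transcript_id == tx$transcript_id[[1]], ]
  s1 <- summarize_transcript_features(
    one, tibble::tibble(transcript_id = tx$transcript_id[[1]], class = "x"))
  expect_equal(s1$min, s1$max)
  expect_equal(s1$median, s1$mean)
})
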