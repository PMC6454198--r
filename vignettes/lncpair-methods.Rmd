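---
title: "Methods: inferring candidate lncRNA-mRNA interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring candidate lncRNA-mRNA interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpair)
```

# The procedure and its assumptions

`lncpair` nominates candidate *cis*-regulatory lncRNA–mRNA pairs from a
multi-group RNA-seq design by intersecting three kinds of evidence per
two-group comparison: differential expression of both partners,
co-expression across all samples, and genomic co-localization. The
underlying assumptions are the usual ones for this class of analysis:
counts are adequately described by a negative binomial with a smooth
mean–variance relationship; most features are not differential, so
median-of-ratios normalisation is valid; and a cis-acting lncRNA is near
its target and co-varies with it, so correlation plus proximity enriches
for (but does not prove) regulation.

## lncRNA filtration cascade

Candidates pass five filters strictly in order: exon count, length,
comparison with the annotated transcriptome, expression, coding potential.
Three points were genuinely open and were decided as follows.

* **Strandedness of step 3.** Elimination by overlap with annotated coding
  exons is restricted to *same-strand* exonic overlap. Under strand-blind
  elimination no antisense lncRNA could ever survive, yet antisense lncRNAs
  are a standard, non-empty class; a stranded library protocol makes the
  same-strand reading the coherent one. Overlap means ≥ 1 bp of exonic
  intersection, with no minimum-fraction rule. Matching against annotated
  lncRNAs is likewise same-strand: a candidate re-assembling an annotated
  lncRNA is the same stranded molecule.
* **Annotated matches and steps 4–5.** Transcripts matching an annotated
  lncRNA are still required to pass exon-count, length and expression
  filters (an unexpressed transcript is not reported), but skip the coding
  -potential step — that step exists to triage *novel* candidates.
* **The FPKM ≥ 0.5 rule.** "Expressed" is read permissively as max FPKM
  across samples ≥ 0.5; a mean-based variant is available
  (`fpkm_stat = "mean"`).

Positional classes follow the precedence antisense > intronic > lincRNA:
an exon–exon overlap on the opposite strand dominates; containment in a
coding gene's span without exonic overlap is intronic; everything else is
lincRNA. A transcript straddling a gene boundary without exonic overlap is
deliberately *not* intronic (it is not contained) and falls through to
lincRNA.

The built-in coding-potential stand-in is a three-forward-frame longest-ORF
scan (`orf_coding_heuristic()`, default ≥ 100 codons from ATG, stop
excluded, runs off the 3' end allowed). External predictor verdicts can be
supplied instead as a table of booleans, any number of predictors; "coding
by at least one" makes a TUCP.

## Expression

FPKM uses the mature transcript length (sum of exon lengths, in bp) — the
unit normalises per kilobase *of exon* — and the per-sample library size,
which defaults to the column sum of the count matrix since a mapped-fragment
total is not available without alignments; an explicit total can override
it. Gene expression sums member-transcript FPKMs, conserving totals under
grouping.

## Differential expression

The two-group test is a documented negative-binomial Wald test, not a
re-implementation of any particular tool's internals:

* size factors by median-of-ratios (median over features of the log ratio
  to the feature's geometric mean), rescaled to geometric mean 1;
* per-feature dispersion by within-group method of moments
  `max(0, (s² − m)/m²)` on normalised counts, averaged over groups, then
  shrunk toward the across-feature mean with prior weight
  `prior_df = 20` pseudo-degrees of freedom against the
  `d = Σ(n_g − 1)` residual degrees of freedom actually observed. At three
  replicates per group the shared value dominates (w ≈ 0.17 on the
  per-feature estimate); at fifty replicates the feature's own estimate
  does. The shrinkage *target* averages the untruncated moment estimates:
  truncating negative estimates at zero before averaging would bias the
  target upward. Without shrinkage, the raw per-feature estimator at n = 3
  is so noisy that the Wald test's size is far from nominal; the
  package's own acceptance suite checks the type-I error of the shrunk
  test lies in [0.03, 0.08] under a 2000-feature null at 3 vs 3.
* Wald statistic `z = (log(μ̂_B + c) − log(μ̂_A + c))/SE` with
  `SE² = (1/(μ̂_B + c) + φ)/n_B + (1/(μ̂_A + c) + φ)/n_A` (delta method
  under variance μ + φμ²), two-sided normal p-values, BH adjustment,
  α = 0.05. The pseudo-count `c = 1` normalised count keeps fold changes
  finite when a group is unobserved; features all-zero in both groups
  report `log2fc = 0, p = 1` by convention. A DE feature with a fold
  change of exactly zero (possible through ties) is flagged `direction =
  "none"` and excluded from up/down tallies.

In the pipeline, mRNAs are tested at gene level and lncRNAs/TUCPs at
transcript level, and normalisation and dispersion are estimated **once**
across all features entering any DE test: estimating a shared dispersion
target from a ~20-feature lncRNA-only matrix is fragile (one wild
method-of-moments estimate moves the mean), while the pooled feature space
stabilises it. TUCPs are carried through DE but excluded from the
interaction analysis.

## Interaction evidence

* **Co-expression** is computed once per pair over *all* samples (n = 9 in
  the default design), not per comparison — a pair has one correlation;
  only DE status is comparison-specific. The test is the classical
  two-sided t with df = n − 2; `|r| = 1` reports the smallest positive
  double rather than 0. Defaults `|r| ≥ 0.95`, `p ≤ 10⁻⁴` on the raw (not
  adjusted) p; both are prominent knobs, as is the choice to correlate
  log2(FPKM + 1) in the pipeline (correlation on the log scale is the
  scale on which expression noise is approximately additive).
* **Co-localization** measures the gap between the lncRNA *transcript*
  span and the mRNA *gene* span (locus-to-locus, introns included), 0 when
  they overlap, with a 100 kb window by default. Upstream/downstream is
  relative to the mRNA's strand. Abutting intervals (gap 0 without a
  shared base) are reported `overlapping`, keeping the invariant
  "distance 0 ⇔ overlapping" exact.
* Candidates are the intersection of the two edge lists; the
  cross-comparison intersection keeps pairs present in every comparison.

## Enrichment and qPCR

Enrichment is a plain hypergeometric upper tail `P[X ≥ k]` with BH
correction and rich factor k/K; terms with fewer than 2 in-universe members
are untestable and skipped (counted in an attribute). The default universe
in the pipeline is all genes expressed at FPKM ≥ 0.5 in ≥ 1 sample. No
annotation-length bias correction and no ontology-graph propagation is
attempted. qPCR relative expression is the Livak 2^−ΔΔCT form with assumed
amplification efficiency exactly 2, calibrated so the calibrator group's
geometric mean RQ is 1.

# The synthetic-data generator

`simulation_config()` fixes the study conditions; `simulate_dataset()`
emits a reference annotation (coding genes, optionally mirrored annotated
lncRNAs), candidate lncRNA transcripts, transcript-level NB counts for 3
groups × 3 replicates, coding calls, and a truth ledger. Design choices:

* **Layout.** Coding genes (3–8 exons of 120–400 bp, introns 0.5–3 kb) are
  laid out with intergenic gaps of 240–320 kb, wide enough that the *only*
  (lncRNA, gene) pairs within the 100 kb window are the planted pairs and
  near decoys; far decoys sit ≥ 110 kb from every gene. Planted distances
  and orientations are realised exactly and re-derivable with
  `genomic_gap()`. lncRNAs get 2–4 exons of 100–500 bp, so they are
  shorter and less exon-rich than mRNAs by construction.
* **Counts.** NB with `variance = μ + φμ²`; background dispersion φ = 0.1,
  background means lognormal (mRNA meanlog log 300, lncRNA log 60 —
  lncRNAs are expressed lower), mild ±10% per-sample depth variation.
* **Planted pairs** share a per-group log2 offset pattern (0, 3, 1.5) —
  differential in every pairwise comparison — at mean 600 and dispersion
  0.003, mirrored in sign for a negative target correlation. The expected
  log-scale correlation of a pair is `(C + σ²)/√((C + σ² + v₁)(C + σ² +
  v₂))`, where C is the variance of the shared fold-change pattern across
  samples and `v ≈ 1/μ + φ` the member's noise variance; σ², the variance
  of an additional shared per-sample lognormal factor, is solved
  numerically (uniroot) to reach the target r = 0.99. NB noise alone caps
  the achievable correlation, hence the shared factor; when the
  fold-change pattern alone already exceeds the target, σ² = 0 and the
  realised correlation slightly overshoots — raising noise to hit the
  target exactly would degrade the very DE signal the pair must also
  carry.
* **Near decoys** are adjacent (within the window) but get *exactly
  orthogonal* group patterns — the mRNA "up in the middle group only", the
  lncRNA a monotonic gradient, whose group-level correlation is zero — so
  both members can be DE yet proximity alone never produces a
  co-expression edge. This is what makes the zero-geometric-decoy check a
  real test of the correlation filter rather than a vacuous one.
* **Streams.** Annotation, counts and reads each draw from their own RNG
  stream derived from the master seed, so adding read fixtures never
  perturbs counts. Identical configs give byte-identical artifacts.
* **Reads.** The FASTQ fixture emits exactly the configured numbers of
  adapter-bearing, poly-N (20% N), low-quality (60% of bases at Phred ≤ 4)
  and clean reads, category-tagged in the ids; clean reads are verified
  adapter-free at generation.

What the generator does **not** emulate: positional read coverage and
alignment artefacts, isoform switching, GC and length biases, batch
effects, library-preparation chemistry, and any real linkage between
genomic position and expression. Tests passing on this generator therefore
demonstrate the pipeline's internal correctness and its recovery behaviour
under the stated statistical model — not performance on real libraries.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; GTF I/O converts to/from
  1-based inclusive at the boundary. Strand must be `+`/`-`; `.` is
  rejected (filtration and orientation logic require strand).
* Dispersion floor 10⁻⁸; p-value floors at the smallest positive double;
  BH via `p.adjust` (step-up, capped at 1).
* Zero-variance expression vectors are untestable for correlation and are
  dropped from edge screens (an explicit error in `pearson_test()`).
* Empty inputs flow through: empty annotations read/write as zero exon
  records, an empty candidate set yields an empty but well-formed result
  bundle, an empty read stream yields zero counts and `NA` fractions.
* Run manifests contain the effective thresholds and package version but
  no timestamps, so identical inputs give byte-identical persisted
  bundles.

# Problem sizes in the test suite

The suites run at deliberately desk-sized scales, chosen as the smallest
sizes at which each property is statistically meaningful: the type-I check
uses 2000 null features at 3 vs 3; dispersion recovery uses 50 replicates;
correlation planting is checked over 60 single-pair simulations;
end-to-end recovery uses the default configuration (60 genes, 5 planted
pairs, 8 near decoys, 7 far decoys, ≥ 50 decoy features in total) across
20 seeds in the acceptance suite and 10 in the acceptance script.

# Known limitations

* The Wald test with moment-based shrunk dispersions is anticonservative
  for very low counts and has no outlier handling; shrinkage toward a
  single pooled value ignores mean–dispersion trends.
* Correlation thresholds are applied to the raw p-value; with thousands of
  DE×DE pairs the edge list is an enrichment device, not an
  error-controlled discovery set.
* Distance-based cis prediction cannot distinguish co-regulation by a
  shared enhancer from lncRNA-mediated regulation; candidates are
  hypotheses for validation (hence the bundled 2^−ΔΔCT support).
* Trans-acting (different-chromosome) interactions, sequence
  complementarity, and network topology are out of scope.
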