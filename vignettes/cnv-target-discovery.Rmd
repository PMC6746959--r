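---
title: "Trio-based CNV target discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based CNV target discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvtrio)
```

## The problem

Congenital heart defects (CHD) and other severe pediatric phenotypes carry a
substantial burden of rare copy number variants (CNVs). The analytic
difficulty is not detecting CNVs — call sets from exome read-depth callers,
SNP-array intensity callers and WGS structural-variant callers are abundant —
but separating the handful of disease-relevant events from the sea of benign
polymorphic CNVs every genome carries. `cnvtrio` implements a four-layer
prioritization pipeline for family-trio cohorts:

1. **De novo screen.** A proband call is certified de novo only if no call
   from a genotyped first-degree relative (parent or sibling) matches it, and
   no independent family control of the same cohort carries it.
2. **Replication.** Surviving calls must be re-observed in an affected
   individual of at least one independent replication cohort (exome, array or
   WGS), and must not appear in any replication control.
3. **Knowledge screen.** Merged recurrent regions are flagged against prior
   knowledge: genes expressed in embryonic/adult heart, previously reported
   disease loci, and common-variant catalogues of healthy individuals.
4. **Expression validation.** For candidate regions, the expression (FPKM) of
   the genes they disrupt is contrasted between carrier and non-carrier
   probands in the same tissue, after housekeeping-gene normalization.

Each layer only removes calls, every removal is recorded in a filter trace
with a reason code and the IDs of the evidence calls, and the carrier
asymmetry of each recurrent region is quantified with a permutation test
backed by an exact combinatorial oracle.

## Interval algebra and matching thresholds

All coordinates are 1-based and inclusive, the convention in which CNV loci
are printed (`chr2:109363161-109371723`); BED inputs (0-based half-open) are
converted at the parser boundary, so `[s, e)` becomes `[s+1, e]` with length
preserved. Chromosome labels are normalized to a canonical `chr`-prefixed
form (`23` → `chrX`) because array and sequencing callers disagree.

Two calls *match* when their **reciprocal overlap** — the smaller of the two
mutual coverage fractions — reaches a threshold:

* `rho = 0.5` for the de novo and control screens. This is the standard
  CNV-matching convention; at 0.5 a call can match at most one call per
  sample per locus, and breakpoint jitter of a few hundred bp on events of
  tens of kb does not break a match.
* `rho_rep = 0.25` for replication matching, deliberately looser: replication
  platforms differ in breakpoint resolution, and a partial-span event of the
  opposite type (a duplication inside a deletion locus) is accepted as locus
  evidence, which is how multi-platform support at a shared locus presents in
  practice.
* `f_kb = 0.5` *one-way* coverage (of the candidate by the knowledge-base
  record) for the knowledge screens. One-way coverage is used instead of
  reciprocal overlap so that a small candidate inside a megabase syndromic
  record still counts as covered; `f_kb = 0` degrades to "any overlap".

All three are configuration parameters of `pipeline_config()`; the defaults
above are used throughout the tests.

Matching for inheritance and control screening is **type-agnostic**: an
overlapping parental duplication blocks certification of a proband deletion.
This is the conservative choice for a de novo screen — a discordant type more
often reflects a caller's copy-state error than two independent events at one
locus.

## De novo classification semantics

`classify_inheritance()` distinguishes three verdicts:

* `inherited` — some relative call reaches `rho`;
* `de_novo` — relatives are genotyped and none matches;
* `unclassified` — the family has **no genotyped relatives**, so
  non-inheritance is unverifiable. Unclassified calls are excluded from the
  de novo channel but kept in the trace.

Consequently every truth-level comparison in the test suite is against
*recoverable* truth: de novo events of probands in families with at least one
genotyped relative. Probands without relatives cannot be classified by any
method, and the study design this package models restricts its de novo
analysis to families with at least one parent or sibling in the same way.

Siblings are included among the relatives that can block certification; this
is again conservative (a variant shared with an unaffected sibling is
unlikely to be a proband-specific de novo event).

## Recurrent regions

Surviving discovery calls and their supporting replication calls are merged
by single-linkage: calls on one chromosome sharing at least one base are
linked, and regions are the connected components, with the region interval
being the union span. Region IDs are the span itself, so they are
deterministic and independent of input order. Carrier counts are **distinct
samples**, never calls; case carriers are probands, control carriers
everything else. Single-linkage spans on one chromosome can never overlap
each other, and the tests verify the partition against a brute-force
connected-components oracle and against `IRanges::reduce()`.

## The carrier permutation test

For a region with `k_case` case carriers and `k_control` control carriers in
cohorts of `n_case` cases and `n_control` controls, the null hypothesis is
that the `k = k_case + k_control` carrier labels are assigned uniformly
without replacement across all `n_case + n_control` individuals. The test is
one-sided for case excess, because the screen targets case-only regions.

Two routes are computed and cross-checked:

* **Monte Carlo:** `n_perm` label permutations, with the add-one estimator
  `p_mc = (1 + #{case-carrier count >= k_case}) / (n_perm + 1)`, which can
  never return zero, plus its binomial standard error.
* **Exact:** the hypergeometric upper tail `P(X >= k_case)`, computed with
  `stats::phyper` — the closed form of the same null.

The default null population is the combined discovery and exome-replication
cohort, 2,458 probands versus 4,455 family controls, configurable because
region-level denominators are a design choice in any multi-cohort study. Each
region's permutation stream is seeded from the master seed plus a hash of the
region ID, so per-region p-values do not depend on evaluation order. A
Benjamini–Hochberg column is provided for reference but never used for
filtering; region screening in this design rests on replication and carrier
counts, not on a significance cutoff.

**Null calibration.** The test's calibration is checked by simulating regions
whose carrier count `k` is drawn uniformly from 20–200 (carrier frequencies
of roughly 0.3–3%, spanning rare to common polymorphic CNVs) and whose
carriers are assigned uniformly. The carrier-count range matters because the
one-sided hypergeometric tail is discrete: at very small `k` the largest
attainable p-value below 0.05 can be far below 0.05, so the rejection rate of
an exact test is legitimately much smaller than the nominal level. Averaging
over a realistic range of carrier counts, the expected fraction of null
regions with `p < 0.05` is about 0.04, and the suite checks it falls in
[0.03, 0.07] over 2,000 regions.

## Knowledge-based relevance

A region qualifies for the high-confidence list if **any** of three criteria
holds:

1. a gene it overlaps is on the heart-expressed gene list;
2. no previously reported disease-associated CNV region covers at least
   `f_kb` of it (novelty);
3. no common-CNV catalogue record covers at least `f_kb` of it.

Criterion 2 is implemented literally as stated above — novelty *counts
toward* relevance. This direction is debatable (overlap with a known disease
locus could equally be read as supporting evidence), so
`invert_criterion2 = TRUE` flips its contribution while the reported
`novel_vs_chd` flag always keeps its literal value. The separate
catalogue-novel de novo list contains every de novo region absent from the
common-CNV catalogue, with regions carried by two or more distinct cases
marked recurrent.

## Expression validation

FPKM matrices are normalized so that every sample has the same housekeeping
geometric mean (default housekeeping set: *G6PD*, *ACTB*, chosen for stable
expression across cardiac tissue). The normalization target defaults to the
cohort geometric mean, which keeps values on an interpretable FPKM scale, and
the value used is recorded in the returned object. Recording it makes the
procedure exactly invariant to a global rescaling of the raw matrix: a change
of units rescales every sample's housekeeping level by the same factor, and
re-normalizing against the *recorded* reference reproduces the identical
matrix, hence identical contrasts. (If the reference were silently recomputed
from rescaled data it would absorb the unit change into the reported FPKM
scale instead.) Normalization is idempotent, and samples with a zero
housekeeping value are excluded with a warning since they admit no geometric
mean.

Contrasts compare carriers against all non-carrier probands of the same
tissue. Group means are reported on the FPKM scale; the fold change is
`log2((mean_car + 1) / (mean_non + 1))`, with the unit pseudocount bounding
behavior near zero. The p-value is a two-sided Welch t-test on
`log2(FPKM + 1)` when both groups have at least three samples. With one or
two carriers no two-sample test exists, so a clearly labeled one-sample
z-score of the carrier mean against the non-carrier log2 distribution
(`method = "z_outlier"`) is reported instead and never pooled with Welch
results; with fewer than three non-carriers no p-value is reported at all.
This replaces read-level differential-expression machinery (negative-binomial
count models) deliberately: FPKM matrices are the input here, and the
scientific claim is a group-mean contrast, not transcript-level inference.
With three carriers against ten non-carriers and a heterozygous-deletion
effect (0.5×, σ_log2 = 0.5), the contrast recovers a negative fold change
almost always but reaches p < 0.05 only in roughly three of five replicates —
small-sample Welch degrees of freedom are expensive — which is why the
pipeline treats expression as validation evidence, not as a filter.

## The synthetic cohort generator

Restricted genotype data cannot ship with a package, so every stage is
exercised against `simulate_cohort()`, which generates the full
multi-platform study design with known ground truth:

* **Cohorts** (defaults, scaled down so the full pipeline runs in seconds):
  100 discovery trios, 200 exome-replication trios, 150 unrelated array
  samples (75 affected / 75 control), 10 WGS trios. 86% of discovery and
  exome-replication families have genotyped parents (10% of those also a
  genotyped unaffected sibling); WGS trios are always complete. Sample IDs
  are disjoint across datasets, mirroring mutually exclusive cohorts.
* **Benign polymorphic CNVs:** 10 loci, 20–200 kb, population allele
  frequencies uniform on 0.05–0.30, transmitted Mendelianly (each parental
  allele passed with probability 0.5). Frequencies in the common range are
  what make the independent-control filter effective: when a parental call
  drops out, other families' carriers still block the false de novo call.
* **Background de novo events:** Poisson with mean 0.05 per proband,
  10–500 kb, placed away from polymorphic and planted loci.
* **Planted case-only recurrent regions:** five regions with fixed carrier
  rosters across datasets and one dosage-affected gene each (four deletions
  at 0.5×, one synthetic duplication at 1.5×).
* **Platform degradation**, per dataset: detection sensitivity (0.95 exome,
  0.85 array, 0.90 WGS), Gaussian breakpoint jitter (sd 100 / 1000 / 50 bp,
  truncated so intervals stay valid), false calls (rate 0.01–0.02 per sample,
  lengths log-uniform 1 kb–1 Mb), and type miscalls (probability 0.02). WGS
  calls carry read-support fractions; the parser drops calls under 0.5,
  exercising the read-support rule.
* **Expression:** `log2 FPKM ~ Normal(log2(baseline × dosage^carrier),
  σ_log2)` with σ_log2 = 0.5 for the 55-sample RNA cohort; housekeeping genes
  at fixed baselines with a quarter of the noise. All samples default to one
  tissue ("aorta"); per-tissue splits are configurable but shrink the
  contrast groups.

Everything is deterministic given the master seed — identical configuration
and seed give byte-identical output files, which the suite asserts.

What the generator does **not** emulate: linkage disequilibrium between CNV
loci, probe- or target-level detection resolution (sensitivity is a flat
per-call probability), realistic breakpoint microhomology, GC or batch biases
in expression, and multi-allelic copy states. Tests passing on this generator
therefore demonstrate the pipeline's logic — classification, filtering,
merging, counting, statistics — not the behavior of any upstream caller on
real intensities or reads.

## Numerical and engineering choices

* Output tables are TSV with a fixed, documented column order, deterministic
  row sort and `%.6g` numeric formatting; `write → read → write` is
  bit-exact, so runs can be compared with `diff`.
* The run log contains no wall-clock content, so reruns with one seed are
  byte-identical across all outputs.
* "Exact" floating-point assertions (normalization idempotence, scale
  invariance) are verified to 1e-12, i.e. to double-precision rounding.
* Per-region sub-seeds are derived as a 31-bit polynomial hash of the region
  ID added to the master seed, keeping every derived seed a valid R integer.
* Degenerate statistics are pinned: zero carriers give p = 1 with a warning;
  constant expression groups give p = 1; carrier counts exceeding cohort
  sizes are contract violations, as are relative calls from the wrong family
  and replication samples that also appear in discovery.
* Problem sizes in the test suite: the default scaled-down cohort for
  end-to-end runs (10 noisy seeds), 20 seeds for the noisy de novo screen,
  100,000 permutations for the Monte-Carlo-versus-exact grid, 2,000 regions
  for null calibration, 500 replicates for dosage recovery.

## Known limitations

* Breakpoints are taken as called; there is no breakpoint refinement or
  probe-level re-genotyping, so region spans inherit caller jitter.
* The de novo screen cannot classify probands without genotyped relatives
  (reported as `unclassified`), and parental mosaicism is not modeled.
* The carrier permutation test conditions on the observed carrier count; it
  does not model platform-specific detection sensitivity, so cross-platform
  carrier counts mix detection regimes.
* Expression contrasts with one or two carriers are outlier scores, not
  tests, and no multiple-testing correction is applied to the reported
  per-region or per-gene p-values (a BH column is provided for reference).
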