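---
title: "Methods: father-sorted DMR detection, shuffle validation, and cross-factor comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: father-sorted DMR detection, shuffle validation, and cross-factor comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sireDMR)
```

## The design being analysed

The unit of inference is the *father-sorted comparison*: one sire's
offspring split into sons conceived before (control) and after (treated)
the sire's environmental exposure. With five sires per experiment, each
experiment yields five independent comparisons; replication across sires
and concordance across two experiments that differ only in the
environmental factor are the substantive questions downstream of DMR
calling.

Counts enter the pipeline as per-CpG methylated/unmethylated read pairs
(the Bismark coverage dialect). Everything internal is 0-based half-open;
conversion happens only in the readers and writers. Counts are
authoritative — the percentage column on disk is derived, rounded, and
recomputed on load.

## The DMR model

Within one comparison the control and treated counts at a CpG are modelled
as binomial draws with a common (null) or different (alternative)
methylation probability, which the two-sided Fisher exact test on the 2×2
table addresses without any dispersion parameter. Choices, in order of
appearance:

* **Coverage floor** (`min_coverage = 5` per group, after pooling). Ratio
  estimates from fewer than ~5 reads are too unstable to threshold on a
  0.10 ratio difference; 5 is a deliberately permissive floor for pooled
  data, configurable where input is sparser.
* **Pooling.** Counts of one father's offspring are summed per side
  before testing. The pooled ratio is then the coverage-weighted mean of
  per-offspring ratios; a property test asserts this identity. Pooling
  discards inter-offspring variation — see *Limitations*.
* **Per-site test.** The Fisher p-value is computed in-package by
  hypergeometric enumeration, summing all tables whose point probability
  does not exceed the observed one (with a `1 + 1e-7` relative tolerance
  for floating-point ties, the convention of exact-test implementations).
  The test suite requires exact agreement with `stats::fisher.test` on
  random tables; the shipped code path never calls it because a vectorised
  enumeration is orders of magnitude faster over ~20,000 sites × hundreds
  of shuffle re-calls.
* **Multiple testing.** Benjamini–Hochberg across all tested sites of one
  comparison (`q_max = 0.05`). Correcting per comparison, not per
  experiment, keeps each father's call independent — the replication
  filter then works on genuinely independent units.
* **Region merging.** Significant sites (q ≤ 0.05, |Δ| ≥ 0.10) of the
  same sign merge while consecutive significant sites are ≤ `max_gap =
  100` bp apart; runs shorter than `min_cpgs = 3` are dropped. A
  non-significant site between two significant ones does not break a run —
  only distance, sign, or chromosome do. Region summaries are
  deliberately conservative and simple: unweighted mean Δ, direction from
  its sign, minimum site p and q (no combined statistic; combiners would
  need their own calibration).

These thresholds are declared, configurable stand-ins: the DMR definition
space (window sizes, significance rules) is large, and the package treats
the caller as a parameterised component whose defaults are validated by
the planted-truth and null benchmarks below, not as a canonical
definition.

## The shuffle null

"How many DMRs would this comparison produce by chance?" is answered by a
permutation that swaps, independently at each common CpG with probability
½, the (methylated, unmethylated) pairs of the two groups, then re-runs
the caller; 100 shuffles per father. The site-wise swap was chosen over
permuting ratios across positions because it preserves each site's
coverage structure and the marginal ratio distribution — the natural
exchangeable null for a two-group comparison — and over sample-level
permutation because pooled designs offer only one unit per side, leaving
nothing to permute at sample level.

Two facts make the implementation cheap and exactly faithful: under a
site swap the 2×2 table's rows exchange, so the two-sided Fisher p (hence
the BH q) and |Δ| are invariant — only the sign of Δ flips. Site
statistics are therefore computed once and each shuffle re-runs only the
sign-dependent merging step. A test asserts that an all-swap shuffle
equals calling DMRs with the groups exchanged.

On matched null simulations (no planted effect, ~20,000 CpGs, 30× mean
coverage, five pooled comparisons) the mean null count per calculation is
far below the < 2 benchmark — typically 0. Two caveats: first, the
binomial generator has no biological overdispersion, so its null is
cleaner than real RRBS data, where the benchmark value near 2 originates;
second, when the *observed* data contain strong dense differential
regions, the site-wise shuffle fragments them into many short sign-broken
runs, so shuffle counts on signal-bearing data exceed the observed count —
the benchmark is a property of null data, and the workflow's step 3
reports both sides explicitly.

## Annotation and gene-level bookkeeping

Promoters are operational: `[TSS − 2000, TSS + 500)` strand-aware, clipped
at chromosome bounds — a common convention, configurable per call. Overlap
is ≥ 1 bp under half-open semantics, the simplest auditable rule, and the
test oracle is a brute-force O(n·m) scan. A DMR hitting two genes counts
for both (gene sets are unions over DMRs). CGI-only hits mark a DMR as
annotated but attribute no gene; single-label summaries rank
promoter > CDS > CGI.

Replication filtering happens at gene level: a gene passes in a
comparison if any DMR hits its promoter or CDS, hypo- and hypermethylated
regions pooled (the analysis asks which pathways are touched, not in
which direction). The k-of-n rule uses k = 5 of 5 for the pooled
experiment — with pooled DNA, individual-specific DMRs are unobservable,
so only effects present in every father-sorted group are accepted — and
k = 4 of 5 for the individually sequenced one. The 4/5 relaxation is
applied after gene-level aggregation (a gene needs hits in ≥ 4 father
groups), the only reading consistent with gene-count bookkeeping.
Cross-factor sharing is likewise computed on gene sets, with region
classes attached afterwards under the promoter > CDS precedence over both
experiments' hits.

## Network enrichment

The offline enrichment statistic counts interactions (edges with combined
score ≥ a stringency threshold, default 0.5) among the query genes and
compares with uniformly drawn gene sets of the same size from the table's
gene universe; `p = (1 + #{null ≥ obs}) / (n_perm + 1)` with add-one
smoothing so p > 0 always. The null ignores node degree on purpose: it
matches the question "would a random gene set of similar size show this
many interactions". Database-specific analytic p-value models (with their
evidence channels and degree corrections) are out of scope; printed
p-values from such services are not comparable targets for this
statistic, only its shape (observed vs expected count, small p for
planted modules) is tested.

## The synthetic-data generator

The generator emulates: five sires per experiment, three control and
three treated offspring each (matching the emulated cohort sizes of ~15–18
sons over five sires), pooled or individual output, Poisson coverage
truncated at ≥ 1 (mean 30), binomial methylation counts at baseline 0.7,
an RRBS-like grid (25 bp steps inside promoters/CDS, 500 bp background —
~20,000 CpGs for 100 genes on 1 Mb), and region-level planted shifts of
magnitude 0.4 (negative by default so the shifted probability stays in
[0, 1] at baseline 0.7; direction is irrelevant downstream) in whole
promoter or CDS intervals of carrier fathers' treated offspring.
Per-CpG depth and genome-wide CpG counts are free parameters of such a
design; the defaults above were fixed once as a realistic desk-scale
configuration.

It does **not** emulate: read-level artefacts (bisulfite conversion
errors, mapping bias), inter-individual biological variation beyond
binomial noise (no beta-binomial dispersion), SNP interference, sex
chromosomes, or chromatin context. Passing tests therefore demonstrate
the pipeline's correctness and calibration under its stated model, not
performance on overdispersed real data — on real data the Fisher test is
anticonservative relative to a dispersion-aware test, which is why the
shuffle validation exists as an empirical check.

Degenerate inputs are rejected loudly: `mean_coverage` must be positive
(zero-coverage sites cannot exist because truncation guarantees ≥ 1 read;
the coverage floor at load time handles real files); `baseline_meth +
planted_effect` must stay in [0, 1]; gene placement fails with a capacity
error when the requested genes cannot fit without overlap. All generation
is deterministic given the design's seed, to the byte for written files.

## Problem sizes used in the shipped checks

The packaged tests and scripts choose sizes that exercise the full design
while remaining desk-scale: the null benchmark runs 100 genes / 1 Mb
(~19,000–20,000 CpGs) with 100 shuffles × 5 fathers; the end-to-end
recovery study runs 10 replicates of two 40-gene / 0.4 Mb experiments
(~7,500 CpGs) with planted effects carried by 5/5 (pooled arm) and 4/5
(individual arm) sires; oracle-equivalence checks use 100+ random
instances per operation. These sizes are the package's own validation
configuration, and the planted-recovery criterion (all planted shared
genes recovered in ≥ 9 of 10 replicates) passes with margin at 30×
coverage and effect 0.4.

## Known limitations

* Fisher on pooled counts ignores litter and individual effects;
  replication across sires is the compensating design element.
* Minimum-p region statistics overstate region-level significance; they
  are reported for ranking, not inference.
* The permutation unit (site-wise swap) is one of several defensible
  nulls; ratio-permutation across positions would break the
  coverage–ratio coupling and was rejected for that reason.
* The enrichment null ignores degree; for hub-heavy tables it is
  anticonservative for hub-rich query sets.
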