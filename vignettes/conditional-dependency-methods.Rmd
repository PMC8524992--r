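---
title: "Methods: conditional dependency analysis with condep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional dependency analysis with condep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condep)
```

`condep` answers one family of questions over a multi-omic cancer cell line
panel: *which genes change essentiality or expression when the panel is
stratified by a biological condition* — disease, sex, or the presence of a
driver mutation. This vignette documents the statistical procedures, their
assumptions, the tunable parameters, the numerical edge-case rules, and what
the bundled synthetic fixtures do and do not demonstrate.

## Data model and identifier canon

Every analysis operates on canonical identifiers: genes as stable ids,
cell lines as panel line ids. The index tables (`load_gene_index()`,
`load_cell_line_index()`) make translation total over symbols, aliases and
ids — case-insensitively for names, exactly for ids — and fail loudly on
unknown queries, because silent identifier mismatch is the classic failure
mode of multi-source joins. Readers drop untranslatable rows *visibly*
(every reader attaches a report with `rows_in == rows_kept + rows_dropped`).

Sex labels are normalized through an explicit map
(`Male`/`M`/`male` → `male`, analogously for female); anything else becomes
`unknown`. Unknown-sex lines are retained in the store but belong to no
sex partition, so sex-stratified analyses never guess. "Mutant" for a gene
means at least one mutation record in a documented protein-altering class
list (`protein_altering_classes`; missense, nonsense, frameshifts, in-frame
indels, splice site, nonstop, translation start); "wildtype" means no
protein-altering record. With these defaults mutant and wildtype partition
the line universe exactly, which the test suite asserts as an algebraic
property. Disease and lineage matching is exact on lowercased labels — no
fuzzy matching, for reproducibility. All clusters are sorted by line id so
downstream statistics never depend on input order.

## Differential essentiality

Given two disjoint line clusters A and B and a genes × lines CERES matrix:

1. **Hypothesis reduction.** Each gene's scores are discretized into
   equal-frequency bins (default 8) and the plug-in mutual information (in
   nats) with a discrete covariate is computed. Genes with
   MI > median(MI) + 1·sd(MI) are removed; sample (n−1) standard deviation
   and a *strict* inequality, so a zero-spread MI vector removes nothing.
   The estimator is a deterministic histogram plug-in rather than a
   nearest-neighbour estimator: at panel sample sizes the bias is shared
   across genes (only the ranking matters here) and exact reproducibility is
   worth more than asymptotic efficiency.

   **The covariate is a deliberate free parameter.** Filtering against the
   comparison grouping itself removes precisely the genes that differ
   between the groups — the true positives. The filter is intended to strip
   genes dominated by a *confounder* (e.g. lineage in a pan-disease
   comparison), so `mi_covariate` should name that confounder; within a
   single homogeneous disease there is usually no confounder left and the
   workflows default to disabling the filter. The validation fixtures
   exercise recovery with the filter off, and the filter itself is tested
   separately with an analytic planted-MI construction.

2. **Test.** A two-sided Mann–Whitney U test per surviving gene. Two-sided
   is the conservative choice when the direction of a conditional
   dependency is not prespecified. Mode `auto` uses the exact null
   distribution when both groups have ≤ 8 observations and the pooled data
   are tie-free, otherwise a tie-corrected normal approximation with
   continuity correction. The exact path is verified against exhaustive
   rank-configuration enumeration for all n₁, n₂ ≤ 6.

3. **Effect sizes.** The mean CERES difference (A − B), antisymmetric under
   group swap, and Cohen's d with pooled sample sd. d is undefined (flagged
   `NA`, excluded from rankings) when a group has < 2 observations or the
   pooled sd is 0.

4. **Reporting.** Significance is the raw p < α (default α = 0.01), and a
   BH-adjusted column (`p_adj`) is always emitted alongside. Raw-p
   selection is the procedure's operating rule; at genome scale it implies
   ≈ α·G false positives, so the BH column is the honest basis for
   false-discovery statements, and the package's own validation measures
   recall on the raw rule and FDR on the BH column. Results are sorted by
   p, then |mean difference| (descending), then gene id — a total,
   deterministic order.

Missing scores are excluded pairwise per gene; genes with fewer than
`min_n = 2` observations in a group are marked untestable rather than
dropped, so the output always accounts for every input gene.

## Pan-cancer mutation × essentiality screen

Bayes-factor essentiality profiles are binarized at BF > 5, *strictly*: a
BF of exactly 5 is non-essential (the rule is stated as "over 5", so the
boundary goes to the non-essential side and is documented and tested).
Candidate genes are those whose binary profile variance falls in a
percentile band, default [0.85, 0.95): genes are ranked by variance
ascending with ties broken by gene id, and rank r is selected when
(r − 1)/G ∈ [lower, upper), so exactly ⌊0.95·G⌋ − ⌊0.85·G⌋ genes are
selected. The band is a parameter because reasonable variants (e.g.
85th–90th) appear in practice; nesting is monotone by construction.

Each (candidate gene, driver) pair is tested with an uncorrected Pearson
chi-square (df = 1) on the 2×2 table of binarized essentiality against the
driver's mutation indicator, over the lines with non-missing essentiality
for that gene. No continuity correction: the uncorrected statistic matches
the closed form N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)) that the tests verify to
1e−9 relative error, and the smallest expected cell is reported so users
can filter low-count pairs rather than having a correction silently applied.
A zero row or column margin makes the pair untestable (flagged, not an
error). Raw p-values are reported without multiplicity correction across
pairs — the screen is a short-listing device, not an inference — and both
pairs-attempted and pairs-testable are reported because the two differ
whenever sparse essentiality data produce degenerate margins. Drivers come
in two groups: tumor-suppressor nonsense (any nonsense mutation counts) and
oncogene missense (only listed protein changes count). Self-pairs (the
candidate gene is the driver) are retained and labelled rather than
excluded, because driver self-essentiality is itself a finding of interest.
Significant pairs are followed up on the continuous CERES scores
(Mann–Whitney, mean difference, Cohen's d) in three reporting groups:
oncogene pairs, tumor-suppressor pairs, and the combination.

## Differential expression

The engine is a deliberately simple negative-binomial Wald test, written to
be self-contained and validated by simulation rather than by matching a
reference implementation:

* **Normalization**: median-of-ratios size factors against the per-gene
  geometric mean; reference genes are rows with no zero, with an optional
  pseudo-reference fallback for sparse matrices. Size factors are defined
  up to a common scale (the geometric-mean reference moves when a sample is
  rescaled), so the scaling identity that holds *exactly* is relative:
  multiplying one sample's counts by c multiplies its factor by c relative
  to every other sample. A single sample gets factor 1 by convention.
* **Dispersion**: per-gene method of moments on normalized counts
  (Var(q) = μ·mean(1/s) + φμ²), floored at 1e−8, then moderated on the log
  scale toward the panel median with prior weight `prior_df = 4` against
  the within-group degrees of freedom. Moderation stabilizes the noisy
  per-gene estimates at typical group sizes (5–15 samples); `prior_df = 0`
  disables it.
* **Test**: log₂FC is the difference of log₂ group means of normalized
  counts with a symmetric pseudocount of 0.5 (computed as a difference of
  logs, so swapping the condition labels negates log₂FC bitwise exactly);
  the delta-method standard error uses the NB variance; the Wald statistic
  is referred to a t distribution on n − 2 df rather than the normal,
  absorbing the dispersion-estimation noise and keeping null calibration
  at or below nominal. BH adjustment runs over the tested genes;
  all-zero-count genes are excluded beforehand and reported, since they
  carry no information but would inflate the correction denominator.

Known differences from full-featured NB engines (no Cox–Reid adjustment, no
dispersion-trend fitting, no independent filtering, no fold-change
shrinkage) are accepted: the acceptance checks require recall ≥ 0.9 of
planted log₂FC = 2 effects at adjusted p < 0.01 with empirical FDR ≤ 0.05
(10 vs 10 samples, dispersion 0.1), and the test suite additionally
cross-checks log₂FC concordance against an independent NB GLM
implementation on a small fixture. When merged panel and external samples
coincide exactly with the two conditions the engine warns that source and
condition are confounded — inherent to any benign-reference design, but
worth flagging.

## Localization scoring and target nomination

Each of three annotation sources assigns a categorical confidence to a
(gene, compartment) pair; categories map to integer scores 0–4 per source
via a `ConfidenceMap` and are summed (absent source = 0, so totals are
0–12; one record per gene/compartment/source is kept, the highest-scoring
on duplicates). The original sources do not publish a shared category
vocabulary, so the shipped `default_confidence_map()` is a labelled
stand-in (4-tier reliability scales mapped 4/3/2/1) and the map is a
required, swappable input; an unmapped category is a hard error naming the
category and source, never a silent zero. Compartments are lowercased and
"cell membrane" is aliased to "plasma membrane".

Nomination keeps genes with adjusted p < α, log₂FC > 0, plasma-membrane
total score ≥ `min_score` (default 6; a score of exactly 6 is kept), and
not on the user-supplied manual exclusion list (recorded in the output for
provenance — curation is never hard-coded). Every input gene appears
exactly once in the output, nominated or excluded with the first failing
reason in the order: not significant, not upregulated, no membrane
annotation, low score, manual exclusion. The nominated set shrinks
monotonically as `min_score` rises.

## The synthetic fixture generator

`fixture_spec()`/`generate_fixture()` emulate the panel table schemas with
planted signals. The default magnitudes are the generator's study
conditions, fixed once:

* CERES noise sd σ₀ = 0.15 around group means (commonly essential genes at
  −1, 10% of genes; all others at 0) — at this noise a planted shift of
  −0.6 is detectable with ~10–15 lines per group, which matches the group
  sizes of realistic disease-by-mutation strata;
* Bayes factors BF = −10·CERES + N(0, 0.5), so essential genes sit near 10
  and clear the > 5 cutoff while non-essential genes sit near 0;
* counts are NB with log-normal base means (median 200, sdlog 1),
  dispersion φ = 0.1 and log-normal per-sample size factors (sdlog 0.2);
* mutations arise per driver as Bernoulli(rate) per line, plus low-rate
  missense passengers outside the driver genes;
* localization draws per-source annotations with probability 0.7 for
  membrane genes; planted membrane targets get deterministic categories
  that sum to a requested score.

One global seed drives everything through a fixed stream-splitting scheme
(one derived seed per table), so identical spec + seed yields byte-identical
files, and planted effects are always enumerated in a truth table. Planted
effects name explicit genes or a count `n`, in which case the generator
assigns the first unused non-essential genes deterministically.

The generator makes **no** attempt to mimic real panel covariance: genes
are independent, there is no gene–gene correlation or co-essentiality
structure, no copy-number artefacts, no mutation spectra, no batch
structure beyond per-sample size factors. Passing the recovery and
calibration checks therefore demonstrates that the statistical machinery is
correct and calibrated under its stated model — not that real-panel
discoveries at these thresholds enjoy the same operating characteristics.

## Validation problem sizes

The test suite and the acceptance script validate at these scales, chosen
to give stable empirical rates while keeping a full run interactive:
exhaustive Mann–Whitney enumeration for all group sizes up to 6 (3,418
rank configurations); 1,000 random chi-square tables; essentiality recovery
and null calibration on 2,000-gene × 60-line fixtures with 50 planted
−0.6 shifts, compared 15 vs 15 lines; expression recovery on a 3,000-gene
fixture with 100 planted log₂FC = 2 effects, 10 vs 10 samples; 500
randomized entity queries against brute-force scans; and double-run
byte-identity of workflow tables.

## Known limitations

* The MI filter's covariate must be chosen by the analyst; there is no
  automatic confounder detection.
* The screen's raw chi-square p-values are short-listing scores; expected
  cell counts below ~5 make the asymptotic p unreliable, which is why
  `expected_min` is reported per pair.
* The expression engine models a single two-level condition; no covariates,
  no multi-factor designs, and merged external data are not batch-corrected.
* Localization scoring is only as good as the supplied confidence map; the
  shipped default is a stand-in vocabulary, not a published scale.
* Live release retrieval, read-level quantification and co-essentiality
  network inference are out of scope.
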