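# condep

Conditional dependency analysis across cancer cell line panels.

Genome-scale CRISPR knockout screens assign every gene, in every profiled
cancer cell line, a fitness effect (a CERES gene effect score; more negative
means more essential). A gene that is dispensable on average but essential in
a *subset* of lines — lines of one disease, one sex, or lines carrying a
particular driver mutation — is a **conditional dependency**, and when the
condition is another genetic lesion it is a candidate **synthetic-lethal**
interaction and hence a candidate drug target. Finding such genes requires
joining the screen data with mutation calls, expression, sample annotations,
protein localization and complex membership — tables that ship with
inconsistent identifiers and no common query layer.

`condep` is for cancer functional genomicists who want to run these
stratified queries and tests on DepMap/CCLE-style tables (or on their own
bespoke datasets) without standing up a database. It provides:

* **Index tables and readers** — gene and cell-line identifier translation
  (symbols/aliases to stable ids, panel names to line ids), CSV readers for
  gene-effect matrices, Bayes-factor matrices, raw RNA-seq counts, MAF-like
  mutation tables, localization annotations and complex membership, all with
  load reports (`rows_in == rows_kept + rows_dropped`).
* **A query layer** — `filter_lines()`, `split_lines_by()`,
  `gene_essentiality()`, `gene_complexes()`, `gene_locations()`,
  `organelle_genes()` compose conjunctive predicates (lineage, disease, sex,
  mutated/wildtype with variant class and protein change) over a
  `condep_store`.
* **Four analysis procedures**
  1. *Stratified differential essentiality*: a mutual-information
     hypothesis-reduction filter (remove genes with
     MI > median(MI) + 1 sd), then a two-sided Mann–Whitney U test per gene
     between two line clusters, with the mean CERES difference
     Δ = x̄₁ − x̄₂ and Cohen's d = (x̄₁ − x̄₂)/s_pooled as effect sizes;
     significant at raw p < 0.01, with a BH-adjusted column emitted
     alongside.
  2. *Pan-cancer mutation × essentiality screen*: binarize Bayes factors at
     BF > 5 (strict), keep genes in the 85th–95th variance percentile band,
     and test every (gene, driver) pair with an uncorrected Pearson
     chi-square on the 2×2 essential × mutant table,
     χ² = N(ad − bc)²/((a+b)(c+d)(a+c)(b+d)); significant pairs are followed
     up on the continuous scores with Mann–Whitney and Cohen's d.
  3. *Differential expression*: a negative-binomial Wald engine with
     median-of-ratios size factors s_j = median_g (K_gj / (∏_k K_gk)^{1/m}),
     method-of-moments dispersion, Wald statistic z = log₂FC / SE and
     Benjamini–Hochberg adjustment; significant at adjusted p < 0.01.
  4. *Surface-target nomination*: per-source categorical localization
     confidences mapped to 0–4 and summed across three sources (max 12);
     nominate genes that are significantly upregulated, plasma-membrane
     annotated with total score ≥ 6, and not manually excluded — every input
     gene is either nominated or excluded with a stated reason.
* **A seeded fixture generator** (`fixture_spec()` / `generate_fixture()`)
  that emulates all of the above schemas with planted signals and a truth
  table, so every procedure is testable end to end without downloading any
  release.

Results are tibbles (with `tidy()` / `glance()` / `autoplot()` methods on the
fitted objects) and compose with the pipe. A thin command-line wrapper ships
in `inst/scripts/condep-cli.R` (`validate-config`, `make-fixture`, `query`,
`diff-ess`, `pan-screen`, `diff-exp`, `surface-targets`).

Live retrieval of panel releases is out of scope by design: the retrieval
layer is a registry stub (`release_registry()`), and you point the
configuration at local files. Note that public dependency-screen releases
are distributed under their own licenses (e.g. CC BY 4.0).

## Worked example

Generate a synthetic panel (500 genes × 60 lines) with a G12D-missense
driver mutated in ~40% of lines and five genes made 0.6 CERES units more
essential in the driver-mutant lines, then ask which genes are
differentially essential between mutant and wildtype NSCLC models:

```r
library(condep)

fx <- generate_fixture(fixture_spec(
  n_genes = 500, n_lines = 60, seed = 42,
  drivers = tibble::tibble(gene = fixture_gene_id(10), rate = 0.4,
                           variant_class = "Missense_Mutation",
                           protein_change = "G12D"),
  planted_essentiality = list(list(n = 5,
                                   where = list(mutated = fixture_gene_id(10)),
                                   delta = -0.6))))

mut <- filter_lines(fx$store, disease = "nsclc", mutated = fixture_gene_id(10))
wt  <- filter_lines(fx$store, disease = "nsclc", wildtype = fixture_gene_id(10))
res <- differential_essentiality(fx$store$ceres, mut, wt,
                                 alpha = 0.01, mi_filter = FALSE)
res
#> <diff_ess> 500 genes (0 removed by MI filter); 6 significant at p < 0.01
#> # A tibble: 5 × 12
#>   gene      mi mi_pass     u         p mean_diff cohens_d    n1    n2 testable
#>   <chr>  <dbl> <lgl>   <dbl>     <dbl>     <dbl>    <dbl> <int> <int> <lgl>
#> 1 100054 0.669 TRUE        0 0.0000825    -0.686    -4.99     9    14 TRUE
#> 2 100052 0.669 TRUE        0 0.0000825    -0.506    -3.34     9    14 TRUE
#> 3 100053 0.503 TRUE        1 0.000107     -0.511    -3.20     9    14 TRUE
#> 4 100051 0.503 TRUE        3 0.000178     -0.565    -2.74     9    14 TRUE
#> 5 100055 0.503 TRUE        6 0.000372     -0.491    -3.54     9    14 TRUE
```

The nine mutant NSCLC lines are compared with the fourteen wildtype ones;
the five planted genes (`100051`–`100055`, see `fx$truth`) rank first with
negative mean CERES differences around the planted −0.6 (mutant lines more
essential) and U statistics near 0. `tidy(res)` returns the full per-gene
table (including the BH-adjusted column), `glance(res)` the one-row summary,
`autoplot(res)` a volcano view. The workflows `wf_strata_heatmap()`,
`wf_driver_sl()`, `wf_sex_disparity()` and `wf_surface_targets()` chain the
same pieces end to end and return tables plus exact group-size accounting.

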