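# End-to-end workflows on planted fixtures.

wf_fixture <- function(seed = 41) {
  generate_fixture(fixture_spec(
    n_genes = 120, n_lines = 50, seed = seed,
    sex_props = c(male = 0.5, female = 0.5, unknown = 0),
    drivers = tibble::tibble(
      gene = fixture_gene_id(c(5, 6)),
      rate = c(0.45, 0.5),
      variant_class = c("Missense_Mutation", "Missense_Mutation"),
      protein_change = c("G12D", "L858R")),
    planted_essentiality = list(
      list(n = 3, where = list(disease = "ovarian cancer",
                               mutated = fixture_gene_id(6)), delta = -1.2),
      list(genes = fixture_gene_id(5),
           where = list(mutated = fixture_gene_id(5)), delta = -1.5)),
    n_external = 4))
}

test_that("stratified heat-map workflow surfaces the planted conditional dependency", {
  fx <- wf_fixture()
  planted <- fx$truth$gene[fx$truth$group_def ==
                             paste0("disease=ovarian cancer&mutated=",
                                    fixture_gene_id(6))]
  symbols <- fx$tables$gene_index$symbol[match(c(planted, fixture_gene_id(30:33)),
                                               fx$tables$gene_index$stable_id)]
  wf <- wf_strata_heatmap(fx$store, symbols, "ovarian cancer",
                          stratify_gene = fixture_gene_id(6))
  gm <- wf$tables$group_means
  mut_col <- gm[["mean_ovarian cancer/mutant"]]
  wt_col <- gm[["mean_ovarian cancer/wildtype"]]
  # planted genes are most essential exactly in the mutant stratum
  for (g in planted) {
    i <- match(g, gm$gene)
    expect_lt(mut_col[i], wt_col[i] - 0.5)
  }
  expect_equal(sum(unlist(wf$group_sizes)),
               length(filter_lines(fx$store, disease = "ovarian cancer",
                                   quiet = TRUE)))

  # one bad symbol: warned, workflow continues with the rest
  expect_warning(
    wf2 <- wf_strata_heatmap(fx$store, c(symbols[1], "NOSUCH"),
                             "ovarian cancer"),
    regexp = "NOSUCH")
  expect_equal(nrow(wf2$tables$group_means), 1)

  # no stratification: one group per disease
  wf3 <- wf_strata_heatmap(fx$store, symbols[1], "ovarian cancer")
  expect_named(wf3$group_sizes, "ovarian cancer")
})

test_that("driver workflow ranks the self-essential driver first with negative deviation", {
  fx <- wf_fixture()
  # restrict to the disease with most lines to mirror a stratified panel
  wf <- wf_driver_sl(fx$store, "nsclc", fixture_gene_id(5))
  means <- wf$tables$means
  expect_equal(means$gene[1], fixture_gene_id(5))
  expect_lt(means$deviation[1], -1)
  expect_equal(wf$group_sizes$mutant + wf$group_sizes$wildtype,
               length(filter_lines(fx$store, disease = "nsclc", quiet = TRUE)))

  # excluding a driver with no mutants in scope changes nothing
  fx2 <- generate_fixture(fixture_spec(
    n_genes = 60, n_lines = 30, seed = 43,
    drivers = tibble::tibble(gene = fixture_gene_id(5), rate = 0.5,
                             variant_class = "Missense_Mutation",
                             protein_change = "G12D"),
    planted_essentiality = list(list(
      genes = fixture_gene_id(5), where = list(mutated = fixture_gene_id(5)),
      delta = -1.5))))
  w1 <- wf_driver_sl(fx2$store, "nsclc", fixture_gene_id(5))
  w2 <- wf_driver_sl(fx2$store, "nsclc", fixture_gene_id(5),
                     exclude_other = fixture_gene_id(40))
  expect_equal(w1$tables$means, w2$tables$means)

  expect_error(wf_driver_sl(fx2$store, "nsclc", fixture_gene_id(41)),
               class = "condep_argument_error")
})

test_that("sex-disparity workflow recovers planted sex-differential genes and reports both N's", {
  fx <- generate_fixture(fixture_spec(
    n_genes = 150, n_lines = 60, seed = 44,
    sex_props = c(male = 0.5, female = 0.5, unknown = 0),
    tissues = tibble::tibble(lineage = "colon", disease = "crc", prop = 1),
    drivers = tibble::tibble(gene = fixture_gene_id(5), rate = 0.8,
                             variant_class = "Missense_Mutation",
                             protein_change = "G12D"),
    planted_essentiality = list(list(n = 5, where = list(sex = "female"),
                                     delta = -0.8))))
  wf <- wf_sex_disparity(fx$store, "crc", require_mutated = fixture_gene_id(5))
  planted <- fx$truth$gene[fx$truth$module == "essentiality"]
  top <- unique(wf$tables$top_bottom$gene[wf$tables$top_bottom$rank_group == "top"])
  expect_gte(length(intersect(planted, top)), 4)
  # bottom genes are negative controls: large p
  bottom <- unique(wf$tables$top_bottom$gene[wf$tables$top_bottom$rank_group == "bottom"])
  ess <- wf$tables$ess
  expect_gte(min(ess$p[ess$gene %in% bottom], na.rm = TRUE), 0.5)
  expect_named(wf$group_sizes, c("de_male", "de_female", "ess_male",
                                 "ess_female", "sex_unknown"))

  # a single-sex disease is fatal with counts in the message
  fx_m <- generate_fixture(fixture_spec(
    n_genes = 30, n_lines = 12, seed = 45,
    sex_props = c(male = 1, female = 0, unknown = 0),
    tissues = tibble::tibble(lineage = "colon", disease = "crc", prop = 1)))
  expect_error(wf_sex_disparity(fx_m$store, "crc"),
               class = "condep_argument_error")
})

test_that("surface-target workflow nominates exactly the planted membrane genes", {
  mem_genes <- fixture_gene_id(96:98)
  fx <- generate_fixture(fixture_spec(
    n_genes = 100, n_lines = 30, seed = 46,
    tissues = tibble::tibble(lineage = "lung", disease = "nsclc", prop = 1),
    membrane_frac = 0,  # membrane annotations only where planted
    planted_expression = list(list(genes = mem_genes,
                                   where = list(source = "panel"), lfc = 3)),
    planted_membrane = list(list(genes = mem_genes, score = 8)),
    n_external = 4))
  wf <- suppressWarnings(wf_surface_targets(
    fx$store, fx$external_counts, filter = list(disease = "nsclc")))
  nom <- wf$tables$nominations
  expect_setequal(nom$gene[nom$nominated], mem_genes)
  expect_equal(wf$group_sizes$malignant, 30)
  expect_equal(wf$group_sizes$benign, 4)
  # conservation: nominations plus reasoned exclusions cover all tested genes
  expect_setequal(nom$gene, wf$tables$de$gene)
  expect_true(all(!is.na(nom$reason[!nom$nominated])))

  # raising the bar above every planted score empties the list
  wf_hi <- suppressWarnings(wf_surface_targets(
    fx$store, fx$external_counts, filter = list(disease = "nsclc"),
    min_score = 9))
  expect_equal(sum(wf_hi$tables$nominations$nominated), 0)
})

test_that("workflows re-run identically: same inputs, byte-identical tables", {
  fx <- wf_fixture()
  w1 <- wf_driver_sl(fx$store, "nsclc", fixture_gene_id(5))
  w2 <- wf_driver_sl(fx$store, "nsclc", fixture_gene_id(5))
  expect_identical(w1$tables, w2$tables)

  d1 <- withr::local_tempdir()
  f1 <- file.path(d1, "a.csv"); f2 <- file.path(d1, "b.csv")
  readr::write_csv(w1$tables$means, f1)
  readr::write_csv(w2$tables$means, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # regenerating the fixture reproduces the workflow tables exactly
  fx_again <- wf_fixture()
  w3 <- wf_driver_sl(fx_again$store, "nsclc", fixture_gene_id(5))
  expect_identical(w1$tables, w3$tables)
})
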