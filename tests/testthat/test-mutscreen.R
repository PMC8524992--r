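# Pan-cancer mutation x essentiality screen.

test_that("Bayes-factor binarization uses a strict cutoff and keeps missing values", {
  m <- matrix(c(5.1, 5.0, 4.9, NA), 2, dimnames = list(c("g1", "g2"),
                                                       c("l1", "l2")))
  b <- binarize_bayes_factors(m)
  expect_equal(unname(b[, ]), matrix(c(1L, 0L, 0L, NA), 2))
  expect_equal(attr(b, "bf_cutoff"), 5)
  # all-missing row stays all-missing
  m2 <- matrix(NA_real_, 1, 3, dimnames = list("g", paste0("l", 1:3)))
  expect_true(all(is.na(binarize_bayes_factors(m2))))
})

test_that("variance-band selection sizes follow the floor arithmetic and nest monotonically", {
  set.seed(12)
  G <- 1000
  bm <- matrix(rbinom(G * 20, 1, runif(G * 20)), G,
               dimnames = list(sprintf("g%04d", 1:G), paste0("l", 1:20)))
  sel <- select_variable_genes(bm, c(0.85, 0.95))
  expect_length(sel, floor(0.95 * G) - floor(0.85 * G))
  expect_length(sel, 100)

  # widening the band only adds genes
  sel_wide <- select_variable_genes(bm, c(0.80, 0.95))
  expect_true(all(sel %in% sel_wide))
  sel_wider <- select_variable_genes(bm, c(0.80, 1.00))
  expect_true(all(sel_wide %in% sel_wider))

  # planted maximal-variance genes land in the top band
  bm2 <- matrix(0L, 100, 20, dimnames = list(sprintf("h%03d", 1:100),
                                             paste0("l", 1:20)))
  planted <- sprintf("h%03d", 91:100)
  bm2[planted, seq(1, 20, 2)] <- 1L
  top <- select_variable_genes(bm2, c(0.90, 1.00))
  expect_setequal(top, planted)

  # all-constant genes: the band is still returned by rank with id tie-break
  bm3 <- matrix(1L, 50, 10, dimnames = list(sprintf("c%02d", 1:50),
                                            paste0("l", 1:10)))
  sel3 <- select_variable_genes(bm3, c(0.5, 0.7))
  expect_length(sel3, floor(0.7 * 50) - floor(0.5 * 50))
  expect_identical(as.character(sel3), sort(rownames(bm3))[26:35])

  expect_error(select_variable_genes(bm, c(0.9, 0.2)),
               class = "condep_argument_error")
})

test_that("driver specs validate their group semantics", {
  ok <- driver_spec(tibble::tibble(
    gene = c("3845", "7157"), group = c("onco_missense", "tsg_nonsense"),
    protein_changes = c("G12D;G12V", "")))
  expect_s3_class(ok, "driver_spec")
  expect_error(driver_spec(tibble::tibble(gene = "x", group = "onco_missense",
                                          protein_changes = "")),
               class = "condep_schema_error")
  expect_error(driver_spec(tibble::tibble(gene = "x", group = "tsg_nonsense",
                                          protein_changes = "G12D")),
               class = "condep_schema_error")
  expect_error(driver_spec(tibble::tibble(gene = "x", group = "weird",
                                          protein_changes = "")),
               class = "condep_schema_error")
})

test_that("mutation indicators respect class and protein-change semantics", {
  mut <- tibble::tibble(
    gene = c("3845", "3845", "7157"),
    line_id = c("L1", "L2", "L3"),
    variant_class = c("Missense_Mutation", "Missense_Mutation",
                      "Nonsense_Mutation"),
    protein_change = c("G12D", "G13D", ""))
  lines <- c("L1", "L2", "L3", "L4")
  onco <- list(gene = "3845", group = "onco_missense", protein_changes = "G12D")
  expect_equal(unname(mutation_indicator(mut, onco, lines)), c(1L, 0L, 0L, 0L))
  tsg <- list(gene = "7157", group = "tsg_nonsense", protein_changes = "")
  expect_equal(unname(mutation_indicator(mut, tsg, lines)), c(0L, 0L, 1L, 0L))
})

test_that("chi-square matches the closed 2x2 form and flags zero margins", {
  got <- chi_square_2x2(matrix(c(20, 5, 5, 20), 2))
  expect_equal(got$chi2, 18)
  expect_equal(got$expected_min, 12.5)

  flat <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  degen <- chi_square_2x2(matrix(c(5, 0, 0, 0), 2))
  expect_false(degen$testable)
  expect_true(is.na(degen$p))

  set.seed(13)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    got <- chi_square_2x2(tab)
    want <- chi2_closed(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(got$chi2, want, tolerance = 1e-9)
  }
})

test_that("the vectorized screen equals the per-table test and flags planted pairs", {
  set.seed(14)
  n_l <- 40
  lines <- sprintf("L%02d", 1:n_l)
  genes <- sprintf("e%02d", 1:10)
  bm <- matrix(rbinom(10 * n_l, 1, 0.5), 10, dimnames = list(genes, lines))
  mut_lines <- lines[1:20]
  # planted: e05 essential exactly in driver-mutant lines
  bm["e05", ] <- as.integer(lines %in% mut_lines)
  mut <- tibble::tibble(gene = "DRV", line_id = mut_lines,
                        variant_class = "Nonsense_Mutation", protein_change = "")
  drivers <- driver_spec(tibble::tibble(gene = "DRV", group = "tsg_nonsense",
                                        protein_changes = ""))
  scr <- run_pair_screen(bm, drivers, genes, mut)
  res <- tidy(scr)
  expect_equal(nrow(res), 10)          # genes x drivers
  expect_equal(res$chi2[res$ess_gene == "e05"], 40)  # perfect 20/20 table
  expect_equal(res$ess_gene[which.min(res$p)], "e05")

  # route equality: vectorized cells vs chisq.test per pair
  for (i in seq_len(nrow(res))) {
    tab <- matrix(c(res$n_ess_mut[i], res$n_ess_wt[i],
                    res$n_noness_mut[i], res$n_noness_wt[i]), 2, byrow = TRUE)
    ref <- chi_square_2x2(tab)
    expect_equal(res$testable[i], ref$testable)
    if (ref$testable) {
      expect_equal(res$chi2[i], ref$chi2, tolerance = 1e-9)
      expect_equal(res$p[i], ref$p, tolerance = 1e-12)
      expect_equal(res$expected_min[i], ref$expected_min, tolerance = 1e-9)
    }
  }

  # alpha = 0 flags nothing; screen invariant under line permutation
  scr0 <- run_pair_screen(bm, drivers, genes, mut, alpha = 0)
  expect_equal(sum(tidy(scr0)$significant), 0)
  perm <- bm[sample(nrow(bm)), sample(ncol(bm))]
  expect_equal(dplyr::arrange(tidy(run_pair_screen(perm, drivers, genes, mut)),
                              ess_gene),
               dplyr::arrange(res, ess_gene))
})

test_that("perfect association achieves chi2 = N among same-margin tables", {
  for (k in 1:10) {
    tab <- matrix(c(k, 0, 0, k), 2)
    expect_equal(chi_square_2x2(tab)$chi2, 2 * k)
  }
  # enumeration: no same-margin table beats the diagonal one
  N <- 16; r1 <- 8; c1 <- 8
  best <- max(sapply(0:8, function(a) {
    tab <- matrix(c(a, r1 - a, c1 - a, N - r1 - c1 + a), 2)
    if (any(tab < 0)) return(-Inf)
    chi_square_2x2(tab)$chi2
  }))
  expect_equal(best, N)
})

test_that("effect-size follow-up recovers the planted CERES shift and labels self pairs", {
  set.seed(15)
  n_l <- 200
  lines <- sprintf("L%03d", 1:n_l)
  mut_lines <- lines[1:100]
  genes <- c("e01", "e02", "DRV")
  ceres <- matrix(rnorm(3 * n_l, sd = 0.3), 3, dimnames = list(genes, lines))
  ceres["e01", mut_lines] <- ceres["e01", mut_lines] - 0.8
  ceres["DRV", mut_lines] <- ceres["DRV", mut_lines] - 1.0  # self-essential driver
  bm <- (ceres < -0.4) * 1L
  mut <- tibble::tibble(gene = "DRV", line_id = mut_lines,
                        variant_class = "Missense_Mutation",
                        protein_change = "G12D")
  drivers <- driver_spec(tibble::tibble(gene = "DRV", group = "onco_missense",
                                        protein_changes = "G12D"))
  scr <- run_pair_screen(bm, drivers, genes, mut)
  fu <- followup_effect_sizes(scr, ceres, mut, drivers)
  res <- tidy(fu)
  expect_gte(abs(res$cohens_d[res$ess_gene == "e01"]), 2)
  expect_lt(res$mean_diff[res$ess_gene == "e01"], 0)
  self_row <- res[res$self_pair, ]
  expect_equal(self_row$ess_gene, "DRV")
  expect_lt(self_row$mean_diff, 0)
  expect_equal(nrow(fu$groups$onco), nrow(res))
  expect_equal(nrow(fu$groups$tsg), 0)

  # identical mutant/wildtype scores give d = 0 and p near 1
  flat <- matrix(rep(c(0, -1), n_l / 2), 1,
                 dimnames = list("e09", lines))
  bm2 <- matrix(as.integer(lines %in% mut_lines), 1,
                dimnames = list("e09", lines))
  scr2 <- run_pair_screen(bm2, drivers, "e09", mut)
  fu2 <- tidy(followup_effect_sizes(scr2, flat, mut, drivers))
  expect_equal(fu2$cohens_d, 0, tolerance = 1e-12)
  expect_gte(fu2$mw_p, 0.9)
})
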