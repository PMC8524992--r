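# Differential essentiality: MI filter, Mann-Whitney, effect sizes.

test_that("mutual information handles degenerate and perfectly separated inputs", {
  # constant vector carries no information
  expect_equal(as.numeric(mutual_information(rep(1, 10), rep(c("a", "b"), 5))), 0)
  expect_true(attr(mutual_information(rep(1, 10), rep(c("a", "b"), 5)), "degenerate"))
  # two value clusters aligned with a balanced binary covariate: ln 2
  mi <- mutual_information(c(1, 2, 3, 10, 11, 12),
                           rep(c("a", "b"), each = 3), bins = 2)
  expect_equal(as.numeric(mi), log(2), tolerance = 1e-12)
  # constant covariate is degenerate
  expect_equal(as.numeric(mutual_information(1:10, rep("a", 10))), 0)
})

test_that("MI of permuted values sits in the simulation null band near zero", {
  set.seed(7)
  v <- rnorm(40)
  cov <- rep(c("a", "b"), 20)
  null_mi <- replicate(1000, as.numeric(mutual_information(sample(v), cov, bins = 4)))
  obs <- as.numeric(mutual_information(sample(v), cov, bins = 4))
  expect_lt(obs, quantile(null_mi, 0.999))
  # separated data clear the whole null distribution
  sep <- as.numeric(mutual_information(c(rnorm(20), rnorm(20) + 50),
                                       rep(c("a", "b"), each = 20), bins = 4))
  expect_gt(sep, max(null_mi))
})

test_that("MI is invariant under strictly monotone transforms given quantile binning", {
  set.seed(8)
  v <- rnorm(30)
  cov <- sample(c("a", "b"), 30, replace = TRUE)
  m1 <- as.numeric(mutual_information(v, cov, bins = 4))
  m2 <- as.numeric(mutual_information(exp(v), cov, bins = 4))
  m3 <- as.numeric(mutual_information(2 * v + 5, cov, bins = 4))
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_equal(m1, m3, tolerance = 1e-12)
  expect_gte(m1, 0)
})

test_that("MI filter removes exactly the planted high-MI genes and honours the strict rule", {
  n_lines <- 40
  cov <- rep(c("a", "b"), n_lines / 2)  # alternating labels
  # 95 null genes with analytically zero MI: strictly increasing values,
  # so every quantile bin holds an equal number of a- and b-lines.
  # 5 planted genes perfectly separated by the covariate: MI = ln 2.
  mat <- rbind(
    t(sapply(1:95, function(i) seq_len(n_lines) + i / 1000)),
    t(sapply(1:5, function(i) ifelse(cov == "a", i, 50 + i))))
  rownames(mat) <- sprintf("g%03d", 1:100)
  flt <- mi_filter(mat, cov, bins = 4)
  # median MI = 0, sample sd = sqrt(5 ln(2)^2 / 99) ~ 0.156 < ln 2
  expect_setequal(flt$removed, sprintf("g%03d", 96:100))
  expect_equal(flt$threshold, sd(c(rep(0, 95), rep(log(2), 5))),
               tolerance = 1e-12)

  # identical MI for every gene: sd contribution 0, strict '>' removes none
  same <- matrix(rep(c(1, 2, 3, 4), each = 10), nrow = 10, byrow = FALSE)
  rownames(same) <- paste0("s", 1:10)
  flt2 <- mi_filter(same, rep(c("a", "b"), each = 2))
  expect_length(flt2$removed, 0)

  # disabled filter keeps everything but still scores
  flt3 <- mi_filter(mat, cov, bins = 4, enabled = FALSE)
  expect_length(flt3$removed, 0)
  expect_equal(flt3$scores$mi, flt$scores$mi)
})

test_that("Mann-Whitney matches exhaustive enumeration on small tie-free samples", {
  got <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$u, 0)
  expect_equal(got$p, 0.1)  # 2/20 assignments are as extreme

  set.seed(10)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      v <- sample(seq_len(50), n1 + n2)
      x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
      want <- mw_enum(x, y)
      got <- mann_whitney(x, y)
      expect_equal(got$u, want$u)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney symmetry, tie handling and missing-group flags", {
  x <- c(1.2, 3.4, 2.2, 8.1); y <- c(0.3, 5.5, 9.9)
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(a$p, b$p)
  expect_equal(b$u, length(x) * length(y) - a$u)

  ident <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gte(ident$p, 0.99)

  none <- mann_whitney(numeric(0), c(1, 2))
  expect_false(none$testable)
  expect_true(is.na(none$p))
})

test_that("Cohen's d uses the pooled sample sd and flags degenerate inputs", {
  expect_equal(as.numeric(cohens_d(c(1, 2, 3), c(3, 4, 5))), -2)
  expect_equal(as.numeric(cohens_d(c(1, 2, 3), c(1, 2, 3) + 0)), 0)
  und <- cohens_d(c(2, 2), c(2, 2))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  expect_true(is.na(cohens_d(1, c(1, 2, 3))))
})

test_that("differential essentiality recovers planted effects and rejects bad groups", {
  fx <- generate_fixture(fixture_spec(
    n_genes = 200, n_lines = 30, seed = 21,
    drivers = tibble::tibble(gene = fixture_gene_id(5), rate = 0.5,
                             variant_class = "Missense_Mutation",
                             protein_change = "G12D"),
    planted_essentiality = list(list(n = 10,
                                     where = list(mutated = fixture_gene_id(5)),
                                     delta = -0.6))))
  mut <- filter_lines(fx$store, mutated = fixture_gene_id(5), quiet = TRUE)
  wt <- filter_lines(fx$store, wildtype = fixture_gene_id(5), quiet = TRUE)
  res <- differential_essentiality(fx$store$ceres, mut, wt, mi_filter = FALSE)
  planted <- fx$truth$gene
  hits <- tidy(res)$gene[tidy(res)$significant]
  expect_gte(length(intersect(planted, hits)) / length(planted), 0.9)
  # planted direction: group A (mutant) more essential, mean_diff < 0
  expect_true(all(tidy(res)$mean_diff[tidy(res)$gene %in% planted] < 0))

  expect_error(differential_essentiality(fx$store$ceres, mut, mut),
               class = "condep_argument_error")
  expect_error(differential_essentiality(fx$store$ceres, mut, c(wt, mut[1])),
               class = "condep_argument_error")
})

test_that("differential essentiality is invariant to row/column ordering of the matrix", {
  fx <- make_query_fixture(seed = 31)
  mat <- fx$store$ceres
  g_a <- filter_lines(fx$store, sex = "female", quiet = TRUE)
  g_b <- filter_lines(fx$store, sex = "male", quiet = TRUE)
  r1 <- tidy(differential_essentiality(mat, g_a, g_b, mi_filter = FALSE))
  set.seed(1)
  shuf <- mat[sample(nrow(mat)), sample(ncol(mat))]
  r2 <- tidy(differential_essentiality(shuf, g_a, g_b, mi_filter = FALSE))
  expect_equal(r1, r2)
})

test_that("mean essentiality by group reduces to raw values for singleton groups and is antisymmetric", {
  fx <- make_query_fixture(seed = 32)
  mat <- fx$store$ceres
  l1 <- colnames(mat)[1]; l2 <- colnames(mat)[2]
  m <- mean_essentiality_by_group(mat, list(a = l1, b = l2))
  expect_equal(m$mean_a, unname(mat[, l1]))
  expect_equal(m$deviation, unname(mat[, l1] - mat[, l2]))
  m_swap <- mean_essentiality_by_group(mat, list(b = l2, a = l1))
  expect_equal(m_swap$deviation, -m$deviation)

  # a gene shifted only in one group dominates the deviation
  mat2 <- matrix(rnorm(50 * 10, sd = 0.1), 50,
                 dimnames = list(paste0("g", 1:50), paste0("l", 1:10)))
  mat2["g7", 1:5] <- mat2["g7", 1:5] - 3
  dev <- mean_essentiality_by_group(mat2, list(x = paste0("l", 1:5),
                                               y = paste0("l", 6:10)))
  expect_equal(dev$gene[which.max(abs(dev$deviation))], "g7")
})
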