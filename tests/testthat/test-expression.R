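# Counts merging, normalization and the NB Wald engine.

test_that("merge_counts inner-joins genes, tags sources and rejects disjoint inputs", {
  set.seed(16)
  panel <- matrix(rpois(100 * 4, 50), 100,
                  dimnames = list(sprintf("g%03d", 1:100), paste0("P", 1:4)))
  ext <- matrix(rpois(80 * 3, 50), 80,
                dimnames = list(sprintf("g%03d", 41:120), paste0("E", 1:3)))
  merged <- merge_counts(panel, ext)
  rep <- attr(merged, "merge_report")
  expect_equal(rep$genes_shared, 60)
  expect_equal(rep$genes_dropped_panel, 40)
  expect_equal(rep$genes_dropped_external, 20)
  expect_equal(ncol(merged), 7)
  expect_equal(unname(attr(merged, "sources")),
               rep(c("panel", "external"), c(4, 3)))

  same <- merge_counts(panel, `colnames<-`(panel, paste0("Q", 1:4)))
  expect_equal(attr(same, "merge_report")$genes_dropped_panel, 0)

  disjoint <- matrix(rpois(10 * 2, 5), 10,
                     dimnames = list(sprintf("x%02d", 1:10), c("E1", "E2")))
  expect_error(merge_counts(panel, disjoint), class = "condep_merge_error")
})

test_that("size factors follow the median-of-ratios definition", {
  c1 <- c(10, 20, 30, 40)
  m <- cbind(s1 = c1, s2 = 2 * c1)
  rownames(m) <- paste0("g", 1:4)
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  ident <- cbind(a = c1, b = c1, c = c1)
  rownames(ident) <- paste0("g", 1:4)
  expect_equal(unname(size_factors(ident)), c(1, 1, 1))

  single <- matrix(c1, ncol = 1, dimnames = list(paste0("g", 1:4), "only"))
  expect_equal(unname(size_factors(single)), 1)

  # scale equivariance: factors are defined up to a common scale (the
  # per-gene geometric-mean reference moves too), so scaling one sample
  # by c scales its factor by c relative to every other sample, exactly
  set.seed(17)
  mm <- matrix(rpois(50 * 5, 100) + 1, 50,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:5)))
  f0 <- size_factors(mm)
  mm2 <- mm; mm2[, 3] <- mm2[, 3] * 4
  f1 <- size_factors(mm2)
  expect_equal(unname(f1[3] / f1[-3]), unname(4 * f0[3] / f0[-3]),
               tolerance = 1e-12)
  expect_equal(unname(f1[-3] / f1[1]), unname(f0[-3] / f0[1]),
               tolerance = 1e-12)

  # no all-positive gene: error suggesting the fallback, which then works
  sp <- mm; sp[cbind(1:50, rep(1:5, 10))] <- 0
  expect_error(size_factors(sp), regexp = "pseudo",
               class = "condep_argument_error")
  expect_true(all(size_factors(sp, pseudo_reference = TRUE) > 0))
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(18)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_manual(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "condep_argument_error")
})

test_that("NB Wald engine recovers planted fold changes with controlled FDR", {
  spec <- fixture_spec(
    n_genes = 600, n_lines = 20, seed = 22,
    sex_props = c(male = 0.5, female = 0.5, unknown = 0),
    planted_expression = list(list(n = 30, where = list(sex = "female"),
                                   lfc = 2)))
  fx <- generate_fixture(spec)
  sex <- setNames(fx$store$line_index$sex, fx$store$line_index$line_id)
  cond <- factor(sex[colnames(fx$store$counts)], levels = c("male", "female"))
  de <- nb_wald_test(fx$store$counts, cond)
  res <- tidy(de)
  planted <- fx$truth$gene[fx$truth$module == "expression"]
  hits <- res$gene[res$significant]
  recall <- length(intersect(hits, planted)) / length(planted)
  fdr <- if (length(hits) > 0) length(setdiff(hits, planted)) / length(hits) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.05)
  expect_gt(median(res$log2fc[res$gene %in% planted]), 1.5)
})

test_that("NB Wald engine is label-antisymmetric and null on duplicated groups", {
  set.seed(19)
  counts <- matrix(rnbinom(200 * 8, mu = 100, size = 10), 200,
                   dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:8)))
  cond <- factor(rep(c("a", "b"), each = 4))
  d1 <- tidy(nb_wald_test(counts, cond))
  d2 <- tidy(nb_wald_test(counts, factor(rep(c("a", "b"), each = 4),
                                         levels = c("b", "a"))))
  d2m <- d2[match(d1$gene, d2$gene), ]
  expect_equal(d1$log2fc, -d2m$log2fc, tolerance = 1e-12)
  expect_equal(d1$p, d2m$p, tolerance = 1e-12)

  dup <- cbind(counts[, 1:4], counts[, 1:4])
  colnames(dup) <- paste0("s", 1:8)
  d3 <- tidy(nb_wald_test(dup, cond, sf = rep(1, 8)))
  expect_true(all(d3$log2fc == 0))

  # zero-count genes are excluded and reported
  z <- counts; z[5, ] <- 0
  dz <- nb_wald_test(z, cond)
  expect_equal(dz$zero_genes, rownames(counts)[5])
  expect_equal(nrow(tidy(dz)), 199)

  expect_error(nb_wald_test(counts, factor(rep(c("a", "b"), c(1, 7)))),
               class = "condep_argument_error")
  expect_error(nb_wald_test(counts, factor(rep("a", 8))),
               class = "condep_argument_error")
})

test_that("DE results are invariant to gene and sample ordering", {
  set.seed(20)
  counts <- matrix(rnbinom(100 * 10, mu = 80, size = 10), 100,
                   dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:10)))
  cond <- rep(c("a", "b"), each = 5)
  r1 <- tidy(nb_wald_test(counts, cond))
  perm_g <- sample(nrow(counts)); perm_s <- sample(ncol(counts))
  r2 <- tidy(nb_wald_test(counts[perm_g, perm_s], cond[perm_s]))
  expect_equal(r1, r2[match(r1$gene, r2$gene), ], ignore_attr = TRUE)
})

test_that("log2 fold changes agree with an independent NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(23)
  n_g <- 150
  mu <- rlnorm(n_g, log(150), 0.8)
  lfc <- c(rep(2, 15), rep(0, n_g - 15))
  counts <- cbind(
    matrix(rnbinom(n_g * 8, mu = mu, size = 10), n_g),
    matrix(rnbinom(n_g * 8, mu = mu * 2^lfc, size = 10), n_g))
  dimnames(counts) <- list(sprintf("g%03d", 1:n_g), paste0("s", 1:16))
  cond <- factor(rep(c("a", "b"), each = 8))
  mine <- tidy(nb_wald_test(counts, cond))

  dds <- DESeq2::DESeqDataSetFromMatrix(counts, S4Vectors::DataFrame(cond = cond),
                                        ~cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- as.data.frame(DESeq2::results(dds))
  m <- match(mine$gene, rownames(ref))
  ok <- is.finite(ref$log2FoldChange[m])
  expect_gt(cor(mine$log2fc[ok], ref$log2FoldChange[m][ok]), 0.98)
  # nearly all strongly planted genes are significant under both engines
  strong <- sprintf("g%03d", 1:15)
  expect_gte(mean(mine$padj[mine$gene %in% strong] < 0.01), 0.8)
  expect_gte(mean(ref[strong, "padj"] < 0.01, na.rm = TRUE), 0.8)
})
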