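# Stratified differential essentiality.
#
# Procedure: (1) a mutual-information hypothesis-reduction filter drops
# genes whose quantile-binned CERES profile carries high information about
# a discrete covariate (removal rule: MI > median(MI) + 1 sample sd,
# strict); (2) each surviving gene is tested with a two-sided Mann-Whitney
# U test between the two line clusters; (3) effect sizes are the
# difference in mean CERES scores and Cohen's d. Significance is the raw
# p < alpha (default 0.01); a BH-adjusted column is emitted alongside.

#' Plug-in mutual information between a numeric vector and discrete labels
#'
#' Values are discretized into equal-frequency (quantile) bins, the joint
#' histogram with the covariate labels is formed, and the plug-in mutual
#' information is returned in nats. The estimator is fully deterministic.
#' Degenerate inputs (constant values, a single represented label, fewer
#' than two complete observations) score 0 and are flagged via the
#' `degenerate` attribute.
#'
#' @param values Numeric vector (missing values dropped pairwise with
#'   their labels).
#' @param covariate Discrete labels, same length as `values`.
#' @param bins Number of quantile bins (default 8).
#' @return Non-negative MI in nats, with attribute `degenerate`.
#' @examples
#' mutual_information(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3), bins = 2)
#' @export
mutual_information <- function(values, covariate, bins = 8) {
  stopifnot(length(values) == length(covariate), bins >= 2)
  ok <- !is.na(values) & !is.na(covariate)
  values <- values[ok]
  covariate <- as.character(covariate[ok])
  degenerate <- length(values) < 2 || length(unique(covariate)) < 2 ||
    diff(range(values)) == 0
  if (degenerate) return(structure(0, degenerate = TRUE))
  brk <- unique(quantile(values, probs = seq(0, 1, length.out = bins + 1),
                         names = FALSE, type = 7))
  if (length(brk) < 2) return(structure(0, degenerate = TRUE))
  binned <- cut(values, breaks = brk, include.lowest = TRUE)
  joint <- table(binned, covariate)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  structure(max(mi, 0), degenerate = FALSE)
}

#' Mutual-information hypothesis-reduction filter
#'
#' Computes the MI of each gene's row against a discrete covariate and
#' removes the genes whose MI exceeds `median(MI) + 1 * sd(MI)` (sample
#' standard deviation, strict inequality). With a zero spread nothing is
#' removed. The covariate is a free choice: filtering against the
#' comparison grouping itself removes precisely the genes that differ
#' between the groups, so a confounder (e.g. lineage) is usually the
#' intended covariate; see the methods vignette.
#'
#' @param mat Genes × lines numeric matrix.
#' @param covariate Discrete labels, one per column of `mat`.
#' @param bins Quantile bins for [mutual_information()].
#' @param enabled If `FALSE`, keep every gene (scores still computed).
#' @return List with `kept`, `removed` (character vectors of gene ids) and
#'   `scores` (tibble `gene`, `mi`, `removed`).
#' @export
mi_filter <- function(mat, covariate, bins = 8, enabled = TRUE) {
  stopifnot(length(covariate) == ncol(mat))
  mi <- apply(mat, 1, function(v) as.numeric(mutual_information(v, covariate, bins)))
  cut_at <- median(mi) + sd(mi)
  removed_flag <- enabled & !is.na(mi) & mi > cut_at
  scores <- tibble::tibble(gene = rownames(mat), mi = unname(mi),
                           removed = unname(removed_flag))
  list(kept = scores$gene[!scores$removed],
       removed = scores$gene[scores$removed],
       scores = scores, threshold = cut_at)
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum test. In `"auto"` mode the exact null distribution is
#' used when both groups have at most 8 observations and the pooled data
#' are tie-free; otherwise a tie-corrected normal approximation with
#' continuity correction is used. The U statistic is reported for the
#' first group, so swapping groups maps U to `n1 * n2 - U` and preserves p.
#'
#' @param x,y Numeric vectors (missing values dropped).
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return Tibble with `u`, `p`, `n1`, `n2`, `method`, `testable`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) {
    return(tibble::tibble(u = NA_real_, p = NA_real_, n1 = n1, n2 = n2,
                          method = NA_character_, testable = FALSE))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = n1 <= 8 && n2 <= 8 && !ties
  )
  if (exact && ties) {
    cd_abort("exact Mann-Whitney mode requires tie-free data",
             class = "condep_argument_error")
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  tibble::tibble(u = unname(wt$statistic), p = wt$p.value, n1 = n1, n2 = n2,
                 method = if (exact) "exact" else "normal_approx",
                 testable = TRUE)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / sd_pooled` with
#' `sd_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))` using
#' sample variances. Undefined (returned as `NA`) when either group has
#' fewer than two observations or the pooled sd is zero.
#'
#' @param x,y Numeric vectors (missing values dropped).
#' @return A single number, or `NA` with attribute `undefined = TRUE`.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) return(structure(NA_real_, undefined = TRUE))
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) return(structure(NA_real_, undefined = TRUE))
  (mean(x) - mean(y)) / sp
}

#' Differential essentiality between two cell-line clusters
#'
#' Runs the full procedure on a CERES genes × lines matrix: MI filter,
#' per-gene Mann-Whitney test, mean CERES difference (group A − group B)
#' and Cohen's d. Missing scores are excluded pairwise per gene; genes with
#' fewer than `min_n` non-missing observations in either group are marked
#' untestable. Significance is the raw p < `alpha` (the procedure's
#' published operating rule); a BH-adjusted column (`p_adj`, computed over
#' the tested genes) is emitted alongside for false-discovery control.
#'
#' @param mat Genes × lines CERES matrix.
#' @param group_a,group_b Disjoint character vectors of line_ids present in
#'   `mat`.
#' @param alpha Raw significance level (default 0.01).
#' @param mi_filter Apply the MI hypothesis-reduction filter (default
#'   `TRUE`).
#' @param mi_covariate Discrete covariate per analyzed line (ordered as
#'   `c(group_a, group_b)` after sorting each group). Default: the group
#'   label itself — note the caveat in [mi_filter()].
#' @param mi_bins Quantile bins for the MI estimator.
#' @param min_n Minimum non-missing observations per group (default 2).
#' @return A `diff_ess` object; `tidy()` returns the per-gene results
#'   tibble sorted by p, then |mean difference|, then gene id.
#' @export
differential_essentiality <- function(mat, group_a, group_b, alpha = 0.01,
                                      mi_filter = TRUE, mi_covariate = NULL,
                                      mi_bins = 8, min_n = 2) {
  group_a <- sort(unique(group_a)); group_b <- sort(unique(group_b))
  if (length(intersect(group_a, group_b)) > 0) {
    cd_abort("group_a and group_b must be disjoint", class = "condep_argument_error")
  }
  group_a <- group_a[group_a %in% colnames(mat)]
  group_b <- group_b[group_b %in% colnames(mat)]
  if (length(group_a) < 1 || length(group_b) < 1) {
    cd_abort("each group needs at least one line present in the matrix",
             class = "condep_argument_error")
  }
  lines <- c(group_a, group_b)
  labels <- c(rep("A", length(group_a)), rep("B", length(group_b)))
  sub <- mat[, lines, drop = FALSE]
  sub <- sub[order(rownames(sub)), , drop = FALSE]

  covariate <- mi_covariate %||% labels
  flt <- mi_filter(sub, covariate, bins = mi_bins, enabled = isTRUE(mi_filter))
  mi_scores <- setNames(flt$scores$mi, flt$scores$gene)

  res <- purrr::map_dfr(rownames(sub), function(g) {
    a <- sub[g, group_a]; b <- sub[g, group_b]
    mi_pass <- g %in% flt$kept
    na <- sum(!is.na(a)); nb <- sum(!is.na(b))
    if (!mi_pass || na < min_n || nb < min_n) {
      return(tibble::tibble(gene = g, mi = mi_scores[[g]], mi_pass = mi_pass,
                            u = NA_real_, p = NA_real_,
                            mean_diff = mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE),
                            cohens_d = NA_real_, n1 = na, n2 = nb,
                            testable = FALSE))
    }
    mw <- mann_whitney(a, b)
    tibble::tibble(gene = g, mi = mi_scores[[g]], mi_pass = TRUE,
                   u = mw$u, p = mw$p,
                   mean_diff = mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE),
                   cohens_d = as.numeric(cohens_d(a, b)),
                   n1 = na, n2 = nb, testable = TRUE)
  })
  res$p_adj <- NA_real_
  tested <- res$testable & !is.na(res$p)
  res$p_adj[tested] <- bh_adjust(res$p[tested])
  res$significant <- !is.na(res$p) & res$p < alpha
  res <- dplyr::arrange(res, .data$p, dplyr::desc(abs(.data$mean_diff)), .data$gene)

  structure(list(
    results = res,
    params = list(alpha = alpha, mi_filter = isTRUE(mi_filter),
                  mi_bins = mi_bins, mi_threshold = flt$threshold,
                  min_n = min_n,
                  n_group_a = length(group_a), n_group_b = length(group_b)),
    groups = list(a = group_a, b = group_b),
    removed = flt$removed
  ), class = "diff_ess")
}

#' @export
print.diff_ess <- function(x, ...) {
  cat("<diff_ess> ", nrow(x$results), " genes (",
      length(x$removed), " removed by MI filter); ",
      sum(x$results$significant), " significant at p < ", x$params$alpha,
      "\n", sep = "")
  print(head(x$results, 5))
  invisible(x)
}

#' @method tidy diff_ess
#' @export
tidy.diff_ess <- function(x, ...) x$results

#' @method glance diff_ess
#' @export
glance.diff_ess <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_removed_mi = length(x$removed),
    n_tested = sum(x$results$testable),
    n_significant = sum(x$results$significant),
    alpha = x$params$alpha,
    n_group_a = x$params$n_group_a,
    n_group_b = x$params$n_group_b
  )
}

#' Mean essentiality per group of cell lines
#'
#' Arithmetic mean of non-missing CERES scores per gene within each named
#' cluster. With exactly two groups a `deviation` column (first group mean
#' − second group mean) is appended: the per-gene shift off the y = x
#' diagonal of a mutant-vs-wildtype mean-essentiality scatter.
#'
#' @param mat Genes × lines CERES matrix.
#' @param groups Named list of line_id clusters; each must overlap `mat`.
#' @return Tibble with `gene`, one mean column per group, and `deviation`
#'   when there are exactly two groups.
#' @export
mean_essentiality_by_group <- function(mat, groups) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  cols <- lapply(groups, function(ls) {
    ls <- intersect(ls, colnames(mat))
    if (length(ls) == 0) {
      cd_abort("a group has no line present in the matrix",
               class = "condep_argument_error")
    }
    mm <- rowMeans(mat[, ls, drop = FALSE], na.rm = TRUE)
    mm[is.nan(mm)] <- NA_real_
    mm
  })
  out <- tibble::tibble(gene = rownames(mat))
  for (nm in names(groups)) out[[paste0("mean_", nm)]] <- unname(cols[[nm]])
  if (length(groups) == 2) {
    out$deviation <- out[[2]] - out[[3]]
  }
  out
}
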