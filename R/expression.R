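# Negative-binomial Wald differential expression.
#
# Engine: median-of-ratios size factors; per-gene method-of-moments
# dispersion on normalized counts (floor 1e-8) with log-scale moderation
# toward the panel-wide median; per-condition NB means; delta-method
# standard error of the log2 fold change; Wald statistic referred to a t
# distribution on n - 2 df; BH adjustment over the tested genes. This is a
# deliberately simple engine (no Cox-Reid adjustment, no dispersion trend
# fitting, no independent filtering, no fold-change shrinkage); it is
# validated by recovery/calibration simulation rather than by matching any
# external implementation.

#' Merge two counts matrices on shared genes
#'
#' Inner join on gene ids: the merged matrix covers the intersection, with
#' samples of both inputs side by side and per-sample source tags
#' preserved in the `sources` attribute. Genes dropped from each side are
#' counted in the `merge_report` attribute.
#'
#' @param panel,external Genes × samples counts matrices.
#' @param tags Length-2 character: source tags for panel and external
#'   samples.
#' @return Merged counts matrix with attributes `sources` (named character
#'   per sample) and `merge_report`.
#' @export
merge_counts <- function(panel, external, tags = c("panel", "external")) {
  shared <- intersect(rownames(panel), rownames(external))
  if (length(shared) == 0) {
    cd_abort("counts matrices share no genes; cannot merge",
             class = "condep_merge_error")
  }
  if (length(intersect(colnames(panel), colnames(external))) > 0) {
    cd_abort("panel and external sample names overlap", class = "condep_merge_error")
  }
  shared <- sort(shared)
  out <- cbind(panel[shared, , drop = FALSE], external[shared, , drop = FALSE])
  attr(out, "kind") <- "counts"
  attr(out, "sources") <- setNames(
    rep(tags, c(ncol(panel), ncol(external))),
    c(colnames(panel), colnames(external)))
  attr(out, "merge_report") <- tibble::tibble(
    genes_shared = length(shared),
    genes_dropped_panel = nrow(panel) - length(shared),
    genes_dropped_external = nrow(external) - length(shared))
  out
}

#' Median-of-ratios size factors
#'
#' The size factor of sample j is the median over reference genes of
#' `count[g, j] / geometric_mean(count[g, ])`; reference genes are the
#' rows with no zero count. With `pseudo_reference = TRUE` the reference
#' is instead every gene with a positive geometric mean computed over the
#' positive entries, a fallback for sparse matrices with no all-positive
#' row.
#'
#' @param counts Genes × samples non-negative counts matrix.
#' @param pseudo_reference Enable the sparse-matrix fallback.
#' @return Positive numeric vector, one factor per sample. A single-sample
#'   matrix gets factor 1 by convention.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  logc <- log(counts)
  if (pseudo_reference) {
    loggeo <- apply(logc, 1, function(r) mean(r[is.finite(r)]))
    ref <- is.finite(loggeo)
  } else {
    ref <- rowSums(counts > 0) == ncol(counts)
    loggeo <- rowMeans(logc)
  }
  if (!any(ref)) {
    cd_abort(paste0("no gene has all-positive counts; re-run with ",
                    "pseudo_reference = TRUE to use a pseudo-reference"),
             class = "condep_argument_error")
  }
  sf <- apply(logc[ref, , drop = FALSE], 2, function(col) {
    ok <- is.finite(col) & is.finite(loggeo[ref])
    exp(median(col[ok] - loggeo[ref][ok]))
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    cd_abort("size factor estimation failed (non-positive factor)",
             class = "condep_argument_error")
  }
  sf
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   returned as `NA`).
#' @return Adjusted p-values, order-aligned with the input; never smaller
#'   than the input.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    cd_abort("p-values must lie in [0, 1]", class = "condep_argument_error")
  }
  p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test for two-condition differential expression
#'
#' Tests each gene for a difference in normalized mean expression between
#' the two levels of `condition`. The reported `log2fc` is the second
#' level versus the first (reference) level, computed on group means of
#' normalized counts with a symmetric pseudocount of 0.5, so swapping the
#' condition labels negates `log2fc` exactly. Genes with all-zero counts
#' are excluded before testing (and before BH adjustment) and reported in
#' the `zero_genes` element.
#'
#' @param counts Genes × samples non-negative integer matrix.
#' @param condition Factor (or coercible) of length `ncol(counts)` with
#'   exactly two levels, each represented by at least two samples.
#' @param alpha Significance level on the BH-adjusted p (default 0.01).
#' @param sf Optional size factors (default [size_factors()] with
#'   pseudo-reference fallback).
#' @param prior_df Moderation weight for the dispersion shrinkage toward
#'   the panel median on the log scale (default 4; 0 disables).
#' @return An `nb_de` object; `tidy()` returns a tibble with `gene`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `p`, `padj`, `significant`,
#'   sorted by `p`.
#' @export
nb_wald_test <- function(counts, condition, alpha = 0.01, sf = NULL,
                         prior_df = 4) {
  condition <- factor(condition)
  if (nlevels(condition) != 2) {
    cd_abort("condition must have exactly two levels", class = "condep_argument_error")
  }
  if (length(condition) != ncol(counts)) {
    cd_abort("condition length must equal the number of samples",
             class = "condep_argument_error")
  }
  if (any(table(condition) < 2)) {
    cd_abort("each condition needs at least two samples",
             class = "condep_argument_error")
  }
  src <- attr(counts, "sources")
  if (!is.null(src) && all(table(condition, src[colnames(counts)]) %in%
                           c(0, table(condition)))) {
    rlang::warn(paste0("condition coincides with data source; source and ",
                       "condition effects are confounded by design"))
  }
  sf <- sf %||% tryCatch(size_factors(counts),
                         condep_argument_error = function(e)
                           size_factors(counts, pseudo_reference = TRUE))

  zero <- rowSums(counts) == 0
  zero_genes <- rownames(counts)[zero]
  counts <- counts[!zero, , drop = FALSE]
  q <- sweep(counts, 2, sf, "/")
  ia <- condition == levels(condition)[1]
  ib <- condition == levels(condition)[2]
  na <- sum(ia); nb <- sum(ib)
  mu_a <- rowMeans(q[, ia, drop = FALSE])
  mu_b <- rowMeans(q[, ib, drop = FALSE])
  base_mean <- rowMeans(q)

  # method-of-moments dispersion: Var(q_j) = mu / s_j + disp * mu^2
  var_a <- apply(q[, ia, drop = FALSE], 1, var)
  var_b <- apply(q[, ib, drop = FALSE], 1, var)
  var_w <- ((na - 1) * var_a + (nb - 1) * var_b) / (na + nb - 2)
  mu_bar <- (na * mu_a + nb * mu_b) / (na + nb)
  m1s <- mean(1 / sf)
  disp_floor <- 1e-8
  disp_raw <- pmax((var_w - mu_bar * m1s) / mu_bar^2, disp_floor)
  if (prior_df > 0) {
    d <- na + nb - 2
    disp_mid <- exp(median(log(disp_raw)))
    disp <- exp((d * log(disp_raw) + prior_df * log(disp_mid)) / (d + prior_df))
  } else {
    disp <- disp_raw
  }

  pseudo <- 0.5
  # difference of logs, so swapping the condition labels negates log2fc
  # bitwise exactly
  log2fc <- log2(mu_b + pseudo) - log2(mu_a + pseudo)
  # delta-method variance of log2 of a group mean of normalized NB counts
  var_mu_a <- (mu_a * m1s + disp * mu_a^2) / na
  var_mu_b <- (mu_b * m1s + disp * mu_b^2) / nb
  se <- sqrt(var_mu_a / (mu_a + pseudo)^2 + var_mu_b / (mu_b + pseudo)^2) / log(2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pt(-abs(stat), df = na + nb - 2)
  padj <- bh_adjust(p)

  res <- tibble::tibble(
    gene = rownames(counts), base_mean = unname(base_mean),
    log2fc = unname(log2fc), se = unname(se), stat = unname(stat),
    p = unname(p), padj = unname(padj),
    significant = !is.na(padj) & padj < alpha
  ) |>
    dplyr::arrange(.data$p, .data$gene)

  structure(list(
    results = res, zero_genes = zero_genes,
    params = list(alpha = alpha, prior_df = prior_df,
                  condition_levels = levels(condition),
                  n_per_level = c(na, nb), size_factors = sf)
  ), class = "nb_de")
}

#' @export
print.nb_de <- function(x, ...) {
  cat("<nb_de> ", nrow(x$results), " genes tested (",
      length(x$zero_genes), " all-zero excluded); ",
      sum(x$results$significant), " significant at padj < ", x$params$alpha,
      "; contrast ", x$params$condition_levels[2], " vs ",
      x$params$condition_levels[1], "\n", sep = "")
  print(head(x$results, 5))
  invisible(x)
}

#' @method tidy nb_de
#' @export
tidy.nb_de <- function(x, ...) x$results

#' @method glance nb_de
#' @export
glance.nb_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_zero_excluded = length(x$zero_genes),
    n_significant = sum(x$results$significant),
    alpha = x$params$alpha,
    n_level_a = x$params$n_per_level[1],
    n_level_b = x$params$n_per_level[2]
  )
}
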