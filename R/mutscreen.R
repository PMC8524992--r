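# Pan-cancer conditional-essentiality screen.
#
# Bayes-factor essentiality profiles are binarized (BF > 5 = essential,
# strict), genes in a chosen variance-percentile band (default the 85th to
# 95th) form the conditionally essential candidate set, and every
# (candidate gene, driver mutation) pair is tested for association with a
# Pearson chi-square on the 2x2 essential × mutant table. Significant
# pairs are followed up on the continuous CERES scores with Mann-Whitney
# tests, mean differences and Cohen's d.

#' Binarize a Bayes-factor essentiality matrix
#'
#' Value 1 (essential) iff the Bayes factor strictly exceeds `cutoff`
#' (default 5); a BF exactly at the cutoff is non-essential. Missing
#' values stay missing.
#'
#' @param mat Genes × lines Bayes-factor matrix.
#' @param cutoff Strict threshold (default 5).
#' @return 0/1 matrix with attributes `kind = "binary_essentiality"` and
#'   `bf_cutoff`.
#' @export
binarize_bayes_factors <- function(mat, cutoff = 5.0) {
  out <- (mat > cutoff) * 1L
  attr(out, "kind") <- "binary_essentiality"
  attr(out, "bf_cutoff") <- cutoff
  out
}

#' Select genes in a variance-percentile band
#'
#' Per-gene variance of the binary essentiality vector is computed over
#' non-missing entries (genes with fewer than two observations are not
#' testable and are excluded from the ranking universe). Genes are ranked
#' by variance ascending with ties broken by gene id, and the ranks whose
#' percentile `(rank - 1) / G` falls in `[lower, upper)` are selected, so
#' the selection size is `floor(upper * G) - floor(lower * G)`.
#'
#' @param bin_mat 0/1 genes × lines matrix ([binarize_bayes_factors()]).
#' @param band Numeric `c(lower, upper)` in `[0, 1]`, default
#'   `c(0.85, 0.95)`.
#' @return Character vector of selected gene ids (in rank order), with
#'   attribute `variances` (named vector over the testable universe).
#' @export
select_variable_genes <- function(bin_mat, band = c(0.85, 0.95)) {
  if (length(band) != 2 || any(!is.finite(band)) || any(band < 0) ||
      any(band > 1) || band[1] >= band[2]) {
    cd_abort("band must be c(lower, upper) with 0 <= lower < upper <= 1",
             class = "condep_argument_error")
  }
  n_obs <- rowSums(!is.na(bin_mat))
  testable <- rownames(bin_mat)[n_obs >= 2]
  v <- apply(bin_mat[testable, , drop = FALSE], 1, var, na.rm = TRUE)
  G <- length(v)
  ord <- order(v, names(v))
  ranks <- seq_len(G)
  lo <- floor(band[1] * G) + 1
  hi <- floor(band[2] * G)
  sel <- names(v)[ord][ranks >= lo & ranks <= hi]
  structure(sel, variances = v)
}

#' Driver-mutation specifications
#'
#' A driver list has one row per driver: tumor-suppressor drivers are
#' defined by nonsense mutations (`group = "tsg_nonsense"`, no protein
#' changes), oncogene drivers by missense mutations at specific protein
#' changes (`group = "onco_missense"`, `protein_changes` a
#' semicolon-separated list, required).
#'
#' @param x Data frame or CSV path with columns `gene`, `group`,
#'   `protein_changes`.
#' @return Validated `driver_spec` tibble.
#' @export
driver_spec <- function(x) {
  df <- if (is.data.frame(x)) tibble::as_tibble(x) else {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()))
  }
  req <- c("gene", "group")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    cd_abort(paste0("driver list is missing column(s): ", paste(miss, collapse = ", ")),
             class = "condep_schema_error")
  }
  if (!"protein_changes" %in% names(df)) df$protein_changes <- ""
  df$protein_changes[is.na(df$protein_changes)] <- ""
  bad_group <- df$group %notin% c("tsg_nonsense", "onco_missense")
  if (any(bad_group)) {
    cd_abort(paste0("invalid driver group: ", paste(unique(df$group[bad_group]),
                                                    collapse = ", ")),
             class = "condep_schema_error")
  }
  onco_empty <- df$group == "onco_missense" & df$protein_changes == ""
  if (any(onco_empty)) {
    cd_abort(paste0("onco_missense drivers need protein_changes: ",
                    paste(df$gene[onco_empty], collapse = ", ")),
             class = "condep_schema_error")
  }
  tsg_nonempty <- df$group == "tsg_nonsense" & df$protein_changes != ""
  if (any(tsg_nonempty)) {
    cd_abort("tsg_nonsense drivers must have empty protein_changes",
             class = "condep_schema_error")
  }
  structure(df[, c("gene", "group", "protein_changes")],
            class = c("driver_spec", class(tibble::tibble())))
}

#' Per-line mutation indicator for a driver
#'
#' Tumor-suppressor drivers: 1 iff the line carries a nonsense mutation in
#' the driver gene. Oncogene drivers: 1 iff the line carries a missense
#' mutation whose normalized protein change is in the driver's list.
#'
#' @param mutations Mutation tibble ([read_mutation_table()]).
#' @param driver One row of a [driver_spec()] (data frame or list with
#'   `gene`, `group`, `protein_changes`).
#' @param lines Character vector of line_ids to score.
#' @return Named 0/1 integer vector over `lines`.
#' @export
mutation_indicator <- function(mutations, driver, lines) {
  gene <- driver$gene; group <- driver$group
  rec <- mutations[mutations$gene == gene, , drop = FALSE]
  if (group == "tsg_nonsense") {
    hit <- rec$line_id[rec$variant_class == "Nonsense_Mutation"]
  } else {
    changes <- normalize_protein_change(
      strsplit(driver$protein_changes, ";", fixed = TRUE)[[1]])
    hit <- rec$line_id[rec$variant_class == "Missense_Mutation" &
                         rec$protein_change %in% changes]
  }
  setNames(as.integer(lines %in% hit), lines)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson test with 1 df; the
#' smallest expected cell is reported so low-count pairs can be filtered
#' downstream. A table with a zero row or column margin is untestable.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return Tibble with `chi2`, `p`, `expected_min`, `testable`.
#' @examples
#' chi_square_2x2(matrix(c(20, 5, 5, 20), 2))
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), sum(tab) > 0)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(chi2 = NA_real_, p = NA_real_,
                          expected_min = NA_real_, testable = FALSE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(chi2 = unname(ct$statistic), p = ct$p.value,
                 expected_min = min(ct$expected), testable = TRUE)
}

# Vectorized Pearson chi-square over per-gene 2x2 cell counts; equals
# chi_square_2x2 on every testable table (asserted in the test suite).
chi2_cells <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  r1 <- n11 + n10; r0 <- n01 + n00
  c1 <- n11 + n01; c0 <- n10 + n00
  testable <- r1 > 0 & r0 > 0 & c1 > 0 & c0 > 0
  chi2 <- ifelse(testable, n * (n11 * n00 - n10 * n01)^2 / (r1 * r0 * c1 * c0),
                 NA_real_)
  exp_min <- ifelse(testable,
                    pmin(r1 * c1, r1 * c0, r0 * c1, r0 * c0) / n, NA_real_)
  tibble::tibble(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 expected_min = exp_min, testable = testable)
}

#' Pan-cancer gene × driver association screen
#'
#' For every (candidate essentiality gene, driver) pair, forms the 2x2
#' table of binarized essentiality against the driver's mutation indicator
#' over the lines with non-missing essentiality for that gene, and applies
#' the uncorrected Pearson chi-square test. Self-pairs (the candidate gene
#' is the driver gene) are retained and labelled `self_pair` because
#' oncogene self-essentiality is itself a finding of interest.
#'
#' @param bin_mat 0/1 genes × lines matrix ([binarize_bayes_factors()]).
#' @param drivers A [driver_spec()].
#' @param genes Candidate gene ids (subset of `rownames(bin_mat)`),
#'   typically [select_variable_genes()].
#' @param mutations Mutation tibble.
#' @param alpha Significance level for flagging pairs (default 0.01; raw
#'   chi-square p, uncorrected across pairs).
#' @return A `pair_screen` object; `tidy()` gives one row per pair with
#'   the 2x2 cell counts (`n_ess_mut`, `n_ess_wt`, `n_noness_mut`,
#'   `n_noness_wt`), `chi2`, `p`, `expected_min`, `testable`,
#'   `significant`, `self_pair`.
#' @export
run_pair_screen <- function(bin_mat, drivers, genes, mutations, alpha = 0.01) {
  drivers <- if (inherits(drivers, "driver_spec")) drivers else driver_spec(drivers)
  bad <- setdiff(genes, rownames(bin_mat))
  if (length(bad) > 0) {
    cd_abort(paste0("candidate genes absent from matrix: ",
                    paste(head(bad, 5), collapse = ", ")),
             class = "condep_argument_error")
  }
  genes <- sort(genes)
  E <- bin_mat[genes, , drop = FALSE]
  lines <- colnames(E)
  obs <- !is.na(E)
  E0 <- E; E0[!obs] <- 0L

  res <- purrr::map_dfr(seq_len(nrow(drivers)), function(i) {
    drv <- drivers[i, ]
    m <- mutation_indicator(mutations, drv, lines)
    n11 <- as.vector(E0 %*% m)                   # essential & mutant
    n1dot <- unname(rowSums(E0))                  # essential total
    ndot1 <- as.vector(obs %*% m)                 # mutant with data
    N <- unname(rowSums(obs))
    cells <- chi2_cells(n11, n1dot - n11, ndot1 - n11, N - n1dot - ndot1 + n11)
    tibble::tibble(
      ess_gene = genes, driver_gene = drv$gene, driver_group = drv$group,
      n_ess_mut = n11, n_ess_wt = n1dot - n11,
      n_noness_mut = ndot1 - n11, n_noness_wt = N - n1dot - ndot1 + n11,
      chi2 = cells$chi2, p = cells$p, expected_min = cells$expected_min,
      testable = cells$testable,
      significant = cells$testable & cells$p < alpha,
      self_pair = genes == drv$gene
    )
  })
  structure(list(
    results = res,
    params = list(alpha = alpha, bf_cutoff = attr(bin_mat, "bf_cutoff"),
                  pairs_attempted = nrow(res),
                  pairs_testable = sum(res$testable),
                  n_candidate_genes = length(genes),
                  n_drivers = nrow(drivers))
  ), class = "pair_screen")
}

#' @export
print.pair_screen <- function(x, ...) {
  cat("<pair_screen> ", x$params$pairs_attempted, " pairs attempted, ",
      x$params$pairs_testable, " testable, ",
      sum(x$results$significant), " significant at p < ", x$params$alpha,
      "\n", sep = "")
  invisible(x)
}

#' @method tidy pair_screen
#' @export
tidy.pair_screen <- function(x, ...) x$results

#' @method glance pair_screen
#' @export
glance.pair_screen <- function(x, ...) {
  tibble::tibble(
    pairs_attempted = x$params$pairs_attempted,
    pairs_testable = x$params$pairs_testable,
    n_significant = sum(x$results$significant),
    n_self_pairs = sum(x$results$self_pair),
    alpha = x$params$alpha
  )
}

#' Effect-size follow-up on significant screen pairs
#'
#' For each significant pair, compares the continuous CERES scores of
#' mutant vs wildtype lines with a Mann-Whitney test, the mean difference
#' (mutant − wildtype) and Cohen's d. Three reporting groups are emitted:
#' the oncogene-missense pairs, the tumor-suppressor-nonsense pairs, and
#' the combination of both.
#'
#' @param screen A `pair_screen` from [run_pair_screen()].
#' @param ceres_mat Genes × lines CERES matrix covering the pairs' genes.
#' @param mutations Mutation tibble.
#' @param drivers The [driver_spec()] used for the screen.
#' @return A `pair_followup` object; `tidy()` gives the augmented pair
#'   table (`mw_p`, `mean_diff`, `cohens_d`, `n_mut`, `n_wt`), and the
#'   `groups` element lists the `onco`, `tsg` and `combined` views.
#' @export
followup_effect_sizes <- function(screen, ceres_mat, mutations, drivers) {
  stopifnot(inherits(screen, "pair_screen"))
  drivers <- if (inherits(drivers, "driver_spec")) drivers else driver_spec(drivers)
  sig <- screen$results[screen$results$significant, , drop = FALSE]
  lines <- colnames(ceres_mat)
  out <- purrr::map_dfr(seq_len(nrow(sig)), function(i) {
    row <- sig[i, ]
    drv <- drivers[drivers$gene == row$driver_gene &
                     drivers$group == row$driver_group, ][1, ]
    if (row$ess_gene %notin% rownames(ceres_mat)) {
      return(dplyr::mutate(row, mw_p = NA_real_, mean_diff = NA_real_,
                           cohens_d = NA_real_, n_mut = 0L, n_wt = 0L))
    }
    m <- mutation_indicator(mutations, drv, lines)
    v <- ceres_mat[row$ess_gene, ]
    mut_v <- v[m == 1]; wt_v <- v[m == 0]
    mw <- mann_whitney(mut_v, wt_v)
    dplyr::mutate(row,
      mw_p = mw$p,
      mean_diff = mean(mut_v, na.rm = TRUE) - mean(wt_v, na.rm = TRUE),
      cohens_d = as.numeric(cohens_d(mut_v, wt_v)),
      n_mut = sum(!is.na(mut_v)), n_wt = sum(!is.na(wt_v)))
  })
  if (nrow(sig) == 0) {
    out <- dplyr::mutate(sig, mw_p = numeric(), mean_diff = numeric(),
                         cohens_d = numeric(), n_mut = integer(), n_wt = integer())
  }
  structure(list(
    results = out,
    groups = list(
      onco = out[out$driver_group == "onco_missense", , drop = FALSE],
      tsg = out[out$driver_group == "tsg_nonsense", , drop = FALSE],
      combined = out
    )
  ), class = "pair_followup")
}

#' @method tidy pair_followup
#' @export
tidy.pair_followup <- function(x, ...) x$results
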