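# End-to-end analysis workflows composed from the query layer and the
# statistical modules. Workflows are pure compositions: given the same
# store and parameters they return identical tables, and each report
# carries the thresholds applied and exact group-size accounting.

wf_report <- function(workflow, params, group_sizes, tables) {
  structure(list(workflow = workflow, params = params,
                 group_sizes = group_sizes, tables = tables),
            class = "condep_workflow")
}

#' @export
print.condep_workflow <- function(x, ...) {
  cat("<condep_workflow:", x$workflow, ">\n")
  cat("  groups:",
      paste(names(x$group_sizes), unlist(x$group_sizes), sep = "=",
            collapse = " "), "\n")
  cat("  tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' Stratified essentiality heat-map table
#'
#' CERES scores for a list of genes across the cell lines of one or more
#' diseases, with lines grouped by disease and (optionally) by
#' mutant/wildtype status of a stratifying gene, plus per-group per-gene
#' mean scores. Symbols that do not resolve through the gene index are
#' reported and skipped, and the workflow continues with the rest.
#'
#' @param store A `condep_store`.
#' @param genes Gene symbols, aliases or stable_ids.
#' @param diseases Disease labels resolving to nonempty clusters.
#' @param stratify_gene Optional gene stable_id to stratify
#'   mutant/wildtype within each disease.
#' @param stratify_class Optional variant class required for "mutant"
#'   status.
#' @return A `condep_workflow` with tables `scores` (long: `gene`,
#'   `line_id`, `group`, `score`) and `group_means` (`gene`, one column
#'   per group).
#' @export
wf_strata_heatmap <- function(store, genes, diseases, stratify_gene = NULL,
                              stratify_class = NULL) {
  stopifnot(length(genes) >= 1, length(diseases) >= 1)
  mat <- store_require(store, "ceres")
  ids <- if (is.null(store$gene_index)) genes else {
    translate_gene(store$gene_index, genes, strict = FALSE)
  }
  unresolved <- genes[is.na(ids) | ids %notin% rownames(mat)]
  if (length(unresolved) > 0) {
    rlang::warn(paste0("skipping unresolvable gene(s): ",
                       paste(unresolved, collapse = ", ")))
  }
  ids <- ids[!is.na(ids) & ids %in% rownames(mat)]
  if (length(ids) == 0) {
    cd_abort("no queried gene resolves into the essentiality matrix",
             class = "condep_argument_error")
  }

  groups <- list()
  for (d in diseases) {
    cl <- filter_lines(store, disease = d, quiet = TRUE)
    if (length(cl) == 0) {
      cd_abort(paste0("disease resolves to an empty cluster: ", d),
               class = "condep_argument_error")
    }
    if (is.null(stratify_gene)) {
      groups[[d]] <- cl
    } else {
      mut <- filter_lines(store, lines = cl, quiet = TRUE,
                          mutated = list(gene = stratify_gene,
                                         variant_class = stratify_class))
      groups[[paste0(d, "/mutant")]] <- mut
      groups[[paste0(d, "/wildtype")]] <- setdiff(cl, mut)
    }
  }
  groups <- groups[vapply(groups, length, 1L) > 0]

  scores <- purrr::imap_dfr(groups, function(cl, label) {
    cl <- intersect(cl, colnames(mat))
    sub <- mat[ids, cl, drop = FALSE]
    tibble::tibble(gene = rep(ids, times = length(cl)),
                   line_id = rep(cl, each = length(ids)),
                   group = label, score = as.vector(sub))
  })
  group_means <- mean_essentiality_by_group(mat[ids, , drop = FALSE], groups)

  wf_report("strata_heatmap",
            params = list(stratify_gene = stratify_gene,
                          stratify_class = stratify_class,
                          unresolved = unresolved),
            group_sizes = lapply(groups, length),
            tables = list(scores = scores, group_means = group_means))
}

#' Driver synthetic-lethality mean-essentiality scatter
#'
#' Splits the cell lines of one disease into driver-mutant and
#' driver-wildtype groups (optionally removing lines mutant for a second
#' driver first) and computes, for every gene in the essentiality matrix,
#' the mean CERES score per group and the deviation (mutant − wildtype):
#' the shift off the y = x diagonal. Genes untestable in a group keep a
#' missing mean rather than being dropped.
#'
#' @param store A `condep_store`.
#' @param disease Disease label.
#' @param driver Driver gene stable_id to stratify on.
#' @param exclude_other Optional second driver: lines mutant for it are
#'   removed before grouping.
#' @return A `condep_workflow` with table `means` (`gene`, `mean_mutant`,
#'   `mean_wildtype`, `deviation`), sorted by |deviation| descending.
#' @export
wf_driver_sl <- function(store, disease, driver, exclude_other = NULL) {
  mat <- store_require(store, "ceres")
  cl <- filter_lines(store, disease = disease, quiet = TRUE)
  if (!is.null(exclude_other)) {
    cl <- setdiff(cl, lines_mutated(store, exclude_other))
  }
  mutant <- intersect(cl, lines_mutated(store, driver))
  wildtype <- setdiff(cl, mutant)
  if (length(mutant) == 0) {
    cd_abort(paste0("no ", driver, "-mutant line in '", disease,
                    "' (disease cluster: ", length(cl), " lines, wildtype: ",
                    length(wildtype), ")"),
             class = "condep_argument_error")
  }
  means <- mean_essentiality_by_group(mat, list(mutant = mutant,
                                                wildtype = wildtype))
  means <- dplyr::arrange(means, dplyr::desc(abs(.data$deviation)))
  wf_report("driver_sl",
            params = list(disease = disease, driver = driver,
                          exclude_other = exclude_other),
            group_sizes = list(mutant = length(mutant),
                               wildtype = length(wildtype)),
            tables = list(means = means))
}

#' Sex-disparity differential expression and essentiality
#'
#' Restricts one disease to lines carrying a required driver mutation,
#' splits by sex, and runs (1) differential expression on the counts
#' matrix at `de_alpha` (BH-adjusted) and (2) differential essentiality
#' on the CERES matrix at `ess_alpha` (raw p). The top 7 most significant
#' differentially essential genes are reported together with the bottom 3
#' (least significant) as negative controls, with per-sex score
#' distributions, and the overlap between the significant expression and
#' essentiality gene sets is reported. The two analyses use the lines
#' available in their respective matrices, so their group sizes may
#' differ; both are reported.
#'
#' @param store A `condep_store`.
#' @param disease Disease label.
#' @param require_mutated Driver gene stable_id that every analyzed line
#'   must carry (default `NULL`: no mutation requirement).
#' @param de_alpha Adjusted-p threshold for expression (default 0.01).
#' @param ess_alpha Raw-p threshold for essentiality (default 0.05).
#' @param mi_filter Passed to [differential_essentiality()]; default
#'   `FALSE` within a single disease (see the methods vignette).
#' @param n_top,n_bottom Sizes of the highlighted and negative-control
#'   gene sets (defaults 7 and 3).
#' @return A `condep_workflow` with tables `de` (expression results),
#'   `ess` (essentiality results), `top_bottom` (gene, rank_group,
#'   per-line scores long), and `overlap` (genes significant in both).
#' @export
wf_sex_disparity <- function(store, disease, require_mutated = NULL,
                             de_alpha = 0.01, ess_alpha = 0.05,
                             mi_filter = FALSE, n_top = 7, n_bottom = 3) {
  ceres <- store_require(store, "ceres")
  counts <- store_require(store, "counts")
  cl <- filter_lines(store, disease = disease,
                     mutated = require_mutated, quiet = TRUE)
  parts <- split_lines_by(store, "sex", lines = cl)
  males <- parts$clusters$male %||% character()
  females <- parts$clusters$female %||% character()
  if (length(males) == 0 || length(females) == 0) {
    cd_abort(paste0("both sexes must be represented in '", disease, "': ",
                    length(males), " male, ", length(females), " female, ",
                    length(parts$unknown), " unknown"),
             class = "condep_argument_error")
  }

  de_lines <- intersect(c(males, females), colnames(counts))
  de_sex <- setNames(store$line_index$sex, store$line_index$line_id)[de_lines]
  de <- nb_wald_test(counts[, de_lines, drop = FALSE],
                     factor(de_sex, levels = c("male", "female")),
                     alpha = de_alpha)

  ess_m <- intersect(males, colnames(ceres))
  ess_f <- intersect(females, colnames(ceres))
  ess <- differential_essentiality(ceres, ess_f, ess_m, alpha = ess_alpha,
                                   mi_filter = mi_filter)

  ranked <- ess$results[ess$results$testable & !is.na(ess$results$p), ]
  top <- head(ranked$gene, n_top)
  bottom <- utils::tail(ranked$gene, n_bottom)
  tb_genes <- c(top, bottom)
  tb <- purrr::map_dfr(tb_genes, function(g) {
    tibble::tibble(
      gene = g,
      rank_group = if (g %in% top) "top" else "bottom",
      line_id = c(ess_f, ess_m),
      sex = rep(c("female", "male"), c(length(ess_f), length(ess_m))),
      score = ceres[g, c(ess_f, ess_m)])
  })
  de_sig <- de$results$gene[de$results$significant]
  ess_sig <- ranked$gene[ranked$significant]

  wf_report("sex_disparity",
            params = list(disease = disease, require_mutated = require_mutated,
                          de_alpha = de_alpha, ess_alpha = ess_alpha,
                          n_top = n_top, n_bottom = n_bottom),
            group_sizes = list(de_male = sum(de_sex == "male"),
                               de_female = sum(de_sex == "female"),
                               ess_male = length(ess_m),
                               ess_female = length(ess_f),
                               sex_unknown = length(parts$unknown)),
            tables = list(de = de$results, ess = ess$results,
                          top_bottom = tb,
                          overlap = tibble::tibble(
                            gene = sort(intersect(de_sig, ess_sig)))))
}

#' Surface-target nomination against an external benign reference
#'
#' Merges the panel counts of a filtered malignant group with an external
#' benign counts matrix, tests malignant vs benign differential
#' expression, and nominates upregulated plasma-membrane targets using
#' the localization confidence scores.
#'
#' @param store A `condep_store`.
#' @param external_counts Genes × samples benign counts matrix.
#' @param filter Named list of [filter_lines()] predicates selecting the
#'   malignant group (e.g. `list(disease = "nsclc", mutated = "...")`).
#' @param min_score,exclusions,de_alpha Passed to
#'   [nominate_surface_targets()].
#' @return A `condep_workflow` with tables `de` (malignant vs benign) and
#'   `nominations`.
#' @export
wf_surface_targets <- function(store, external_counts, filter = list(),
                               min_score = 6, exclusions = character(),
                               de_alpha = 0.01) {
  counts <- store_require(store, "counts")
  loc <- store_require(store, "localization")
  cl <- rlang::exec(filter_lines, store, !!!filter, quiet = TRUE)
  cl <- intersect(cl, colnames(counts))
  if (length(cl) < 2) {
    cd_abort("malignant group has fewer than two lines with counts",
             class = "condep_argument_error")
  }
  merged <- merge_counts(counts[, cl, drop = FALSE], external_counts,
                         tags = c("malignant", "benign"))
  src <- attr(merged, "sources")
  condition <- factor(unname(src[colnames(merged)]),
                      levels = c("benign", "malignant"))
  de <- nb_wald_test(merged, condition, alpha = de_alpha)
  nom <- nominate_surface_targets(de$results, loc, min_score = min_score,
                                  exclusions = exclusions, de_alpha = de_alpha)
  wf_report("surface_targets",
            params = list(filter = filter, min_score = min_score,
                          exclusions = exclusions, de_alpha = de_alpha,
                          merge_report = attr(merged, "merge_report")),
            group_sizes = list(malignant = length(cl),
                               benign = ncol(external_counts)),
            tables = list(de = de$results, nominations = nom$results))
}
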