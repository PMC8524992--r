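# Protein localization confidence scoring and surface-target nomination.
#
# Each of three annotation sources assigns a categorical confidence to a
# (gene, compartment) annotation; categories map to an integer 0-4 score
# per source and the per-source scores are summed into a total confidence
# score (maximum 12). Surface-target nomination keeps the genes that are
# significantly upregulated and plasma-membrane annotated with total
# score >= 6, minus a user-supplied manual exclusion list.

.localization_sources <- c("cell_atlas", "map_of_cell", "surfaceome")

#' Default category-to-score confidence map
#'
#' The published sources do not print their category scales in a single
#' shared vocabulary, so the shipped default is a stand-in covering common
#' 4-level reliability tiers (scored 4/3/2/1; absent source contributes
#' 0). Supply your own map whenever your annotation files use a different
#' vocabulary: the map is a required, swappable input and unknown
#' categories are a hard error, never a silent zero.
#'
#' @return Named list (one element per source) of named integer vectors
#'   mapping category labels to scores in 0..4.
#' @export
default_confidence_map <- function() {
  list(
    cell_atlas = c(enhanced = 4L, supported = 3L, approved = 2L,
                   uncertain = 1L),
    map_of_cell = c(validated = 4L, high = 3L, medium = 2L, low = 1L),
    surfaceome = c("high confidence" = 4L, confident = 3L, putative = 2L,
                   candidate = 1L)
  )
}

#' Score raw localization annotations with a confidence map
#'
#' @param raw Raw annotation tibble ([read_localization_table()]): columns
#'   `gene`, `compartment`, `source`, `category`.
#' @param map Confidence map, as [default_confidence_map()].
#' @return Tibble of localization records: `gene`, `compartment`,
#'   `source`, `category`, `score` (integer 0-4), deduplicated to one
#'   record per (gene, compartment, source) keeping the highest score.
#' @export
apply_confidence_map <- function(raw, map = default_confidence_map()) {
  req <- c("gene", "compartment", "source", "category")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    cd_abort(paste0("localization input is missing column(s): ",
                    paste(miss, collapse = ", ")),
             class = "condep_schema_error")
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(gene = character(), compartment = character(),
                          source = character(), category = character(),
                          score = integer()))
  }
  bad_src <- setdiff(unique(raw$source), names(map))
  if (length(bad_src) > 0) {
    cd_abort(paste0("no confidence map for source(s): ",
                    paste(bad_src, collapse = ", ")),
             class = "condep_confidence_error")
  }
  score <- purrr::map2_int(raw$source, raw$category, function(s, cat) {
    v <- unname(map[[s]][cat])
    if (is.na(v)) {
      cd_abort(paste0("unmapped confidence category '", cat,
                      "' for source '", s, "'"),
               class = "condep_confidence_error")
    }
    as.integer(v)
  })
  if (any(score < 0 | score > 4)) {
    cd_abort("confidence map scores must lie in 0..4",
             class = "condep_confidence_error")
  }
  out <- tibble::tibble(gene = raw$gene, compartment = tolower(raw$compartment),
                        source = raw$source, category = raw$category,
                        score = score)
  out |>
    dplyr::group_by(.data$gene, .data$compartment, .data$source) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene, .data$compartment, .data$source)
}

#' Total localization confidence scores
#'
#' Sums the per-source scores for each (gene, compartment) pair; a source
#' with no annotation contributes 0, so totals lie in 0..12 for three
#' sources.
#'
#' @param records Scored localization records ([apply_confidence_map()]).
#' @return Tibble with `gene`, `compartment`, `total_score`, `n_sources`.
#' @export
localization_scores <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(gene = character(), compartment = character(),
                          total_score = integer(), n_sources = integer()))
  }
  records |>
    dplyr::group_by(.data$gene, .data$compartment) |>
    dplyr::summarise(total_score = sum(.data$score),
                     n_sources = dplyr::n_distinct(.data$source),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene, .data$compartment)
}

#' @rdname localization_scores
#' @param gene,compartment Single gene id and compartment label; returns
#'   the scalar total (0 for an unannotated pair).
#' @export
total_score <- function(records, gene, compartment) {
  sc <- localization_scores(records)
  hit <- sc$total_score[sc$gene == gene & sc$compartment == tolower(compartment)]
  if (length(hit) == 0) 0L else hit
}

#' Nominate upregulated cell-surface targets
#'
#' Keeps the genes of a differential-expression result that are
#' significant (`padj < de_alpha`), upregulated (`log2fc > 0`),
#' plasma-membrane annotated with total confidence score >= `min_score`
#' (a score of exactly `min_score` is kept), and not manually excluded.
#' Every input gene appears exactly once in the output, either nominated
#' or excluded with a reason (`not_significant`, `not_upregulated`,
#' `no_membrane_annotation`, `low_score`, `manual_exclusion` — first
#' failing check in that order, manual exclusion checked last).
#'
#' @param de_results Tibble with columns `gene`, `log2fc`, `padj` (e.g.
#'   `tidy()` of an [nb_wald_test()] result).
#' @param records Scored localization records.
#' @param min_score Minimum total plasma-membrane score (default 6).
#' @param exclusions Character vector of manually excluded gene ids
#'   (recorded in the `exclusions` element for provenance).
#' @param de_alpha Adjusted-p significance threshold (default 0.01).
#' @param compartment Membrane compartment label (default
#'   `"plasma membrane"`).
#' @return A `target_nomination` object; `tidy()` gives one row per input
#'   gene: `gene`, `log2fc`, `padj`, `total_membrane_score`, `nominated`,
#'   `reason` (`NA` when nominated), nominated genes first sorted by
#'   `log2fc` descending.
#' @export
nominate_surface_targets <- function(de_results, records, min_score = 6,
                                     exclusions = character(),
                                     de_alpha = 0.01,
                                     compartment = "plasma membrane") {
  req <- c("gene", "log2fc", "padj")
  miss <- setdiff(req, names(de_results))
  if (length(miss) > 0) {
    cd_abort(paste0("de_results is missing column(s): ",
                    paste(miss, collapse = ", ")),
             class = "condep_schema_error")
  }
  sc <- localization_scores(records)
  sc <- sc[sc$compartment == tolower(compartment), c("gene", "total_score")]
  out <- tibble::tibble(gene = de_results$gene,
                        log2fc = de_results$log2fc,
                        padj = de_results$padj) |>
    dplyr::left_join(sc, by = "gene") |>
    dplyr::rename(total_membrane_score = "total_score")
  annotated <- !is.na(out$total_membrane_score)
  out$total_membrane_score[!annotated] <- 0L

  reason <- rep(NA_character_, nrow(out))
  reason[is.na(out$padj) | out$padj >= de_alpha] <- "not_significant"
  need <- is.na(reason)
  reason[need & out$log2fc <= 0] <- "not_upregulated"
  need <- is.na(reason)
  reason[need & !annotated] <- "no_membrane_annotation"
  need <- is.na(reason)
  reason[need & out$total_membrane_score < min_score] <- "low_score"
  need <- is.na(reason)
  reason[need & out$gene %in% exclusions] <- "manual_exclusion"

  out$nominated <- is.na(reason)
  out$reason <- reason
  out <- dplyr::arrange(out, dplyr::desc(.data$nominated),
                        dplyr::desc(.data$log2fc), .data$gene)
  structure(list(
    results = out,
    params = list(min_score = min_score, de_alpha = de_alpha,
                  compartment = tolower(compartment)),
    exclusions = exclusions
  ), class = "target_nomination")
}

#' @export
print.target_nomination <- function(x, ...) {
  cat("<target_nomination> ", sum(x$results$nominated), " nominated of ",
      nrow(x$results), " genes (min plasma-membrane score ",
      x$params$min_score, ", padj < ", x$params$de_alpha, ")\n", sep = "")
  print(head(x$results[x$results$nominated, ], 10))
  invisible(x)
}

#' @method tidy target_nomination
#' @export
tidy.target_nomination <- function(x, ...) x$results

#' @method glance target_nomination
#' @export
glance.target_nomination <- function(x, ...) {
  tibble::tibble(
    n_input = nrow(x$results),
    n_nominated = sum(x$results$nominated),
    n_excluded = sum(!x$results$nominated),
    min_score = x$params$min_score,
    de_alpha = x$params$de_alpha
  )
}
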