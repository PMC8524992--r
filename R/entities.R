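# Entity-level query verbs. Each verb restricts the underlying tables to a
# biological scope (one gene, one compartment, a cluster of cell lines) and
# is contractually equal to a direct subset of those tables; the test suite
# checks that equivalence against brute-force scans.

#' Variant classes counted as protein-altering
#'
#' "Mutant" for a gene means at least one record in this list (or in the
#' explicitly requested class); "wildtype" means no protein-altering
#' record, so mutant/wildtype partition the line universe.
#' @format Character vector of variant classifications.
#' @export
protein_altering_classes <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
  "Nonstop_Mutation", "Translation_Start_Site"
)

#' Cell lines carrying (or lacking) a mutation in a gene
#'
#' `lines_mutated()` returns the lines with at least one qualifying
#' mutation record for `gene`; `lines_wildtype()` returns the lines with no
#' protein-altering record for `gene`. With the default class list the two
#' sets partition the cell-line universe.
#'
#' @param store A `condep_store`.
#' @param gene Canonical gene stable_id (use [translate_gene()] first for
#'   symbols).
#' @param variant_class Optional variant classification to require
#'   (e.g. `"Missense_Mutation"`); default: any protein-altering class.
#' @param protein_change Optional normalized protein change to require
#'   (e.g. `"G12D"`).
#' @return Sorted character vector of line_ids.
#' @export
lines_mutated <- function(store, gene, variant_class = NULL, protein_change = NULL) {
  mut <- store_require(store, "mutations")
  rec <- mut[mut$gene == gene, , drop = FALSE]
  if (is.null(variant_class)) {
    rec <- rec[rec$variant_class %in% protein_altering_classes, , drop = FALSE]
  } else {
    rec <- rec[rec$variant_class == variant_class, , drop = FALSE]
  }
  if (!is.null(protein_change)) {
    rec <- rec[rec$protein_change == normalize_protein_change(protein_change), ,
               drop = FALSE]
  }
  sort(intersect(unique(rec$line_id), store$line_index$line_id))
}

#' @rdname lines_mutated
#' @export
lines_wildtype <- function(store, gene) {
  mut <- store_require(store, "mutations")
  rec <- mut[mut$gene == gene &
               mut$variant_class %in% protein_altering_classes, , drop = FALSE]
  sort(setdiff(store$line_index$line_id, unique(rec$line_id)))
}

#' Filter cell lines by conjunction of annotation and mutation predicates
#'
#' All supplied predicates are combined with AND. Lineage/disease matching
#' is exact on normalized lowercase labels. `mutated` takes a gene
#' stable_id, or a list `list(gene =, variant_class =, protein_change =)`;
#' `wildtype` takes a gene stable_id. The result is sorted by line_id so
#' downstream statistics are deterministic; an empty result is an empty
#' cluster with a warning, not an error.
#'
#' @param store A `condep_store`.
#' @param lineage,disease,sex Optional exact-match annotation filters.
#' @param mutated,wildtype Optional mutation-status filters (see Details).
#' @param lines Optional starting cluster (default: all lines).
#' @param quiet Suppress the empty-result warning.
#' @return Sorted character vector of line_ids.
#' @examples
#' store <- generate_fixture(fixture_spec(n_genes = 40, n_lines = 20, seed = 1))$store
#' length(filter_lines(store, sex = "female"))
#' @export
filter_lines <- function(store, lineage = NULL, disease = NULL, sex = NULL,
                         mutated = NULL, wildtype = NULL, lines = NULL,
                         quiet = FALSE) {
  li <- store$line_index
  keep <- li$line_id
  if (!is.null(lines)) keep <- intersect(keep, lines)
  if (!is.null(lineage)) {
    keep <- intersect(keep, li$line_id[li$lineage %in% tolower(lineage)])
  }
  if (!is.null(disease)) {
    keep <- intersect(keep, li$line_id[li$disease %in% tolower(disease)])
  }
  if (!is.null(sex)) {
    sex <- normalize_sex(sex)
    keep <- intersect(keep, li$line_id[li$sex %in% sex])
  }
  if (!is.null(mutated)) {
    if (!is.list(mutated)) mutated <- list(gene = mutated)
    keep <- intersect(keep, lines_mutated(store, mutated$gene,
                                          mutated$variant_class,
                                          mutated$protein_change))
  }
  if (!is.null(wildtype)) {
    if (is.list(wildtype)) wildtype <- wildtype$gene
    keep <- intersect(keep, lines_wildtype(store, wildtype))
  }
  out <- sort(keep)
  if (length(out) == 0 && !quiet) {
    rlang::warn("filter_lines: no cell line matches all predicates")
  }
  out
}

#' Partition a cluster of cell lines by an attribute
#'
#' Splits `lines` by `sex`, `lineage`, `disease`, or mutant/wildtype status
#' of a gene (`attribute = "mutation"` with `gene =`). Partitions are
#' disjoint and cover all lines whose attribute is known; lines with
#' unknown attribute (e.g. sex `"unknown"`) are reported under `unknown`
#' and belong to no partition.
#'
#' @param store A `condep_store`.
#' @param attribute One of `"sex"`, `"lineage"`, `"disease"`, `"mutation"`.
#' @param gene Gene stable_id, required when `attribute = "mutation"`.
#' @param lines Cluster to split (default: all lines).
#' @return List with `clusters` (named list of sorted line_id vectors) and
#'   `unknown` (sorted line_ids with no known attribute value).
#' @export
split_lines_by <- function(store, attribute = c("sex", "lineage", "disease", "mutation"),
                           gene = NULL, lines = NULL) {
  attribute <- match.arg(attribute)
  li <- store$line_index
  lines <- lines %||% li$line_id
  lines <- sort(intersect(lines, li$line_id))
  if (attribute == "mutation") {
    if (is.null(gene)) {
      cd_abort("split_lines_by(attribute = 'mutation') requires `gene`",
               class = "condep_argument_error")
    }
    mutant <- intersect(lines, lines_mutated(store, gene))
    return(list(clusters = list(mutant = sort(mutant),
                                wildtype = sort(setdiff(lines, mutant))),
                unknown = character()))
  }
  vals <- setNames(li[[attribute]], li$line_id)[lines]
  is_unknown <- is.na(vals) | vals == "" | (attribute == "sex" & vals == "unknown")
  known <- vals[!is_unknown]
  clusters <- lapply(split(names(known), known), sort)
  list(clusters = clusters, unknown = sort(names(vals)[is_unknown]))
}

#' CERES essentiality profile of one gene
#'
#' Returns the gene's row of the essentiality matrix restricted to a
#' cluster of lines. Missing entries are flagged, not dropped.
#'
#' @param store A `condep_store`.
#' @param gene Gene stable_id.
#' @param lines Optional cluster of line_ids (default: all columns).
#' @return Tibble with columns `line_id`, `score`, `missing`.
#' @export
gene_essentiality <- function(store, gene, lines = NULL) {
  mat <- store_require(store, "ceres")
  if (gene %notin% rownames(mat)) {
    cd_abort(paste0("gene not present in essentiality matrix: ", gene),
             class = "condep_notfound_error")
  }
  lines <- lines %||% colnames(mat)
  lines <- lines[lines %in% colnames(mat)]
  v <- mat[gene, lines]
  tibble::tibble(line_id = lines, score = unname(v), missing = is.na(unname(v)))
}

#' Protein complexes containing a gene
#'
#' @param store A `condep_store`.
#' @param gene Gene stable_id.
#' @return Tibble with one row per complex containing the gene:
#'   `complex_id`, `complex_name`, `members` (list column of member gene
#'   ids).
#' @export
gene_complexes <- function(store, gene) {
  cpx <- store_require(store, "complexes")
  ids <- unique(cpx$complex_id[cpx$gene == gene])
  sub <- cpx[cpx$complex_id %in% ids, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble::tibble(complex_id = character(), complex_name = character(),
                          members = list()))
  }
  sub |>
    dplyr::group_by(.data$complex_id, .data$complex_name) |>
    dplyr::summarise(members = list(sort(unique(.data$gene))), .groups = "drop") |>
    dplyr::arrange(.data$complex_id)
}

#' Localization annotations of one gene / genes of one compartment
#'
#' `gene_locations()` returns all scored localization records for a gene;
#' `organelle_genes()` returns the (sorted, deduplicated) genes annotated
#' to a compartment. The two views are mutually consistent: `g` is in
#' `organelle_genes(store, c)` exactly when `c` appears among
#' `gene_locations(store, g)$compartment`.
#'
#' @param store A `condep_store`.
#' @param gene Gene stable_id.
#' @param compartment Normalized compartment label (e.g.
#'   `"plasma membrane"`).
#' @return `gene_locations()`: tibble of localization records;
#'   `organelle_genes()`: character vector of gene ids.
#' @export
gene_locations <- function(store, gene) {
  loc <- store_require(store, "localization")
  tibble::as_tibble(loc[loc$gene == gene, , drop = FALSE])
}

#' @rdname gene_locations
#' @export
organelle_genes <- function(store, compartment) {
  loc <- store_require(store, "localization")
  sort(unique(loc$gene[loc$compartment == tolower(compartment)]))
}
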