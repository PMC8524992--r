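# Index tables: the identifier-translation layer that lets heterogeneous
# panel datasets be joined on canonical keys. Canonical form throughout the
# package: genes are stable_ids, cell lines are line_ids; every analysis
# module operates on canonical identifiers only.

.sex_map <- c(
  "male" = "male", "m" = "male",
  "female" = "female", "f" = "female",
  "unknown" = "unknown", "na" = "unknown"
)

normalize_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key[is.na(key) | key == ""] <- "unknown"
  out <- unname(.sex_map[key])
  out[is.na(out)] <- "unknown"
  out
}

#' Load a gene index table
#'
#' The gene index maps every symbol, alias and stable identifier to one
#' canonical `stable_id`. Symbol and alias lookup is case-insensitive;
#' stable_id lookup is exact.
#'
#' @param x Path to a CSV with columns `symbol`, `stable_id`, `aliases`
#'   (pipe-separated, may be empty), or a data frame with those columns.
#' @return A `gene_index` tibble.
#' @seealso [translate_gene()]
#' @export
load_gene_index <- function(x) {
  idx <- if (is.data.frame(x)) tibble::as_tibble(x) else {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()))
  }
  req <- c("symbol", "stable_id")
  miss <- setdiff(req, names(idx))
  if (length(miss) > 0) {
    cd_abort(paste0("gene index is missing column(s): ", paste(miss, collapse = ", ")),
             class = "condep_schema_error")
  }
  if (!"aliases" %in% names(idx)) idx$aliases <- ""
  idx$aliases[is.na(idx$aliases)] <- ""
  idx$stable_id <- as.character(idx$stable_id)
  if (any(is.na(idx$symbol) | idx$symbol == "")) {
    cd_abort("gene index contains empty symbols", class = "condep_schema_error")
  }
  dup <- idx$stable_id[duplicated(idx$stable_id)]
  if (length(dup) > 0) {
    cd_abort(paste0("duplicate stable_id in gene index: ",
                    paste(unique(dup), collapse = ", ")),
             class = "condep_schema_error")
  }
  idx <- idx[, c("symbol", "stable_id", "aliases")]
  attr(idx, "lookup") <- build_gene_lookup(idx)
  structure(idx, class = c("gene_index", class(tibble::tibble())))
}

build_gene_lookup <- function(idx) {
  alias_list <- strsplit(idx$aliases, "|", fixed = TRUE)
  keys <- c(tolower(idx$symbol), idx$stable_id,
            tolower(unlist(alias_list)))
  vals <- c(idx$stable_id, idx$stable_id,
            rep(idx$stable_id, lengths(alias_list)))
  keep <- nzchar(keys)
  # first mapping wins for ambiguous aliases
  keys <- keys[keep]; vals <- vals[keep]
  vals[!duplicated(keys)] -> v
  setNames(v, keys[!duplicated(keys)])
}

#' Translate gene queries to canonical stable identifiers
#'
#' Accepts symbols or aliases (case-insensitively) or stable identifiers
#' (exactly). Translation is idempotent: translating a stable_id returns it.
#'
#' @param index A `gene_index` from [load_gene_index()].
#' @param query Character vector of symbols, aliases or stable_ids.
#' @param strict If `TRUE` (default) an unknown query is an error listing
#'   exact-prefix near-matches; if `FALSE` unknown queries yield `NA`.
#' @return Character vector of stable_ids, same length as `query`.
#' @export
translate_gene <- function(index, query, strict = TRUE) {
  lookup <- attr(index, "lookup") %||% build_gene_lookup(index)
  key <- ifelse(query %in% index$stable_id, query, tolower(query))
  out <- unname(lookup[key])
  if (strict && anyNA(out)) {
    bad <- query[is.na(out)][1]
    near <- names(lookup)[startsWith(names(lookup), tolower(bad))]
    cd_abort(paste0("gene not found in index: '", bad, "'",
                    if (length(near) > 0)
                      paste0(" (nearest prefix matches: ",
                             paste(head(near, 5), collapse = ", "), ")")
                    else ""),
             class = "condep_notfound_error")
  }
  out
}

#' Load a cell-line index table
#'
#' One row per cell line with canonical `line_id`, panel name, lineage,
#' disease, subtype and sex. Sex labels are normalized to
#' `male`/`female`/`unknown` via an explicit mapping
#' (`Male`/`M`/`male` -> `male`, similarly for female; anything else,
#' including missing values, becomes `unknown`). Lines of unknown sex are
#' retained but excluded from sex-stratified analyses.
#'
#' @param x Path to a CSV with columns `line_id`, `ccle_name`, `lineage`,
#'   `disease`, and optionally `subtype` and `sex`, or a data frame.
#' @return A `line_index` tibble.
#' @seealso [translate_line()]
#' @export
load_cell_line_index <- function(x) {
  idx <- if (is.data.frame(x)) tibble::as_tibble(x) else {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()))
  }
  req <- c("line_id", "ccle_name", "lineage", "disease")
  miss <- setdiff(req, names(idx))
  if (length(miss) > 0) {
    cd_abort(paste0("cell-line index is missing column(s): ",
                    paste(miss, collapse = ", ")),
             class = "condep_schema_error")
  }
  if (!"subtype" %in% names(idx)) idx$subtype <- NA_character_
  if (!"sex" %in% names(idx)) idx$sex <- "unknown"
  dup <- idx$line_id[duplicated(idx$line_id)]
  if (length(dup) > 0) {
    cd_abort(paste0("duplicate line_id in cell-line index: ",
                    paste(unique(dup), collapse = ", ")),
             class = "condep_schema_error")
  }
  idx$sex <- normalize_sex(idx$sex)
  idx$lineage <- tolower(trimws(idx$lineage))
  idx$disease <- tolower(trimws(idx$disease))
  idx <- idx[, c("line_id", "ccle_name", "lineage", "disease", "subtype", "sex")]
  structure(tibble::as_tibble(idx), class = c("line_index", class(tibble::tibble())))
}

#' Translate cell-line queries to canonical line identifiers
#'
#' @param index A `line_index` from [load_cell_line_index()].
#' @param query Character vector of line_ids (exact) or panel names
#'   (case-insensitive).
#' @param strict As in [translate_gene()].
#' @return Character vector of line_ids.
#' @export
translate_line <- function(index, query, strict = TRUE) {
  lookup <- setNames(c(index$line_id, index$line_id),
                     c(index$line_id, tolower(index$ccle_name)))
  key <- ifelse(query %in% index$line_id, query, tolower(query))
  out <- unname(lookup[key])
  if (strict && anyNA(out)) {
    bad <- query[is.na(out)][1]
    near <- names(lookup)[startsWith(names(lookup), tolower(bad))]
    cd_abort(paste0("cell line not found in index: '", bad, "'",
                    if (length(near) > 0)
                      paste0(" (nearest prefix matches: ",
                             paste(head(near, 5), collapse = ", "), ")")
                    else ""),
             class = "condep_notfound_error")
  }
  out
}
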