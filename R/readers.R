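# CSV readers for the panel schemas. All readers translate identifiers to
# canonical form when an index is supplied, drop untranslatable rows/columns,
# and attach a load report (rows_in == rows_kept + rows_dropped).

load_report <- function(rows_in, rows_kept, cols_in = NA_integer_,
                        cols_kept = NA_integer_) {
  tibble::tibble(
    rows_in = rows_in, rows_kept = rows_kept, rows_dropped = rows_in - rows_kept,
    cols_in = cols_in, cols_kept = cols_kept, cols_dropped = cols_in - cols_kept
  )
}

#' Read a genes-by-lines numeric matrix
#'
#' Reads a CSV whose first column holds row identifiers and whose header
#' holds column identifiers, and returns a numeric matrix oriented genes ×
#' lines (set `orientation = "lines_by_genes"` for transposed files). When
#' index tables are supplied, identifiers are translated to canonical form
#' and rows/columns that fail translation are dropped and counted in the
#' attached load report (`attr(x, "load_report")`).
#'
#' @param path CSV path.
#' @param kind One of `"ceres"`, `"bayes_factor"`, `"counts"`, `"tpm"`.
#'   Counts matrices must be non-negative integers with no missing values.
#' @param orientation `"genes_by_lines"` (default) or `"lines_by_genes"`.
#' @param gene_index,line_index Optional index tables for identifier
#'   translation ([load_gene_index()], [load_cell_line_index()]).
#' @return Numeric matrix with `rownames` = gene ids, `colnames` = line or
#'   sample ids, and attributes `kind` and `load_report`.
#' @export
read_omics_matrix <- function(path, kind = c("ceres", "bayes_factor", "counts", "tpm"),
                              orientation = c("genes_by_lines", "lines_by_genes"),
                              gene_index = NULL, line_index = NULL) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  df <- readr::read_csv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), name_repair = "minimal")
  if (ncol(df) < 2) {
    cd_abort("matrix file must have an id column plus at least one value column",
             class = "condep_schema_error")
  }
  row_ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(row_ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals) & vals != "" & toupper(vals) != "NA",
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cd_abort(sprintf("non-numeric cell at row %d ('%s'), column %d ('%s'): '%s'",
                     bad[1, 1], row_ids[bad[1, 1]], bad[1, 2],
                     colnames(vals)[bad[1, 2]], vals[bad[1, 1], bad[1, 2]]),
             class = "condep_parse_error")
  }
  if (orientation == "lines_by_genes") num <- t(num)

  if (kind == "counts") {
    if (anyNA(num)) {
      cd_abort("counts matrix contains missing values", class = "condep_parse_error")
    }
    frac <- which(num %% 1 != 0 | num < 0, arr.ind = TRUE)
    if (nrow(frac) > 0) {
      cd_abort(sprintf("counts matrix has a non-integer or negative value at row '%s', column '%s': %s",
                       rownames(num)[frac[1, 1]], colnames(num)[frac[1, 2]],
                       num[frac[1, 1], frac[1, 2]]),
               class = "condep_parse_error")
    }
  }

  rows_in <- nrow(num); cols_in <- ncol(num)
  if (!is.null(gene_index)) {
    tr <- translate_gene(gene_index, rownames(num), strict = FALSE)
    keep <- !is.na(tr)
    num <- num[keep, , drop = FALSE]
    rownames(num) <- tr[keep]
  }
  if (!is.null(line_index)) {
    tr <- translate_line(line_index, colnames(num), strict = FALSE)
    keep <- !is.na(tr)
    num <- num[, keep, drop = FALSE]
    colnames(num) <- tr[keep]
  }
  if (anyDuplicated(rownames(num)) || anyDuplicated(colnames(num))) {
    cd_abort("matrix identifiers are not unique after translation",
             class = "condep_schema_error")
  }
  attr(num, "kind") <- kind
  attr(num, "load_report") <- load_report(rows_in, nrow(num), cols_in, ncol(num))
  num
}

#' Write a matrix back to the on-disk CSV schema
#'
#' Inverse of [read_omics_matrix()]: first column `gene`, one column per
#' line/sample. Numeric values are written at full precision so a read /
#' write / read round trip reproduces identifiers and values exactly.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(mat, path) {
  df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_csv(df, path)
  invisible(path)
}

.mutation_required <- c("gene", "variant_class", "protein_change")

#' Read a long-format somatic mutation table
#'
#' One row per variant call. Protein changes are normalized by stripping a
#' leading `p.` prefix and upper-casing (`p.G12d` -> `G12D`); cell-line
#' names are translated to canonical line_ids when an index is supplied.
#'
#' @param x CSV path or data frame with columns `gene`, `line_id` (or
#'   `ccle_name`), `variant_class`, `protein_change`.
#' @param gene_index,line_index Optional index tables.
#' @return Tibble of mutation records with a `load_report` attribute.
#' @export
read_mutation_table <- function(x, gene_index = NULL, line_index = NULL) {
  df <- if (is.data.frame(x)) tibble::as_tibble(x) else {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()))
  }
  has_line <- "line_id" %in% names(df) || "ccle_name" %in% names(df)
  miss <- setdiff(.mutation_required, names(df))
  if (length(miss) > 0 || !has_line) {
    if (!has_line) miss <- c("line_id", miss)
    cd_abort(paste0("mutation table is missing column(s): ",
                    paste(miss, collapse = ", ")),
             class = "condep_schema_error")
  }
  rows_in <- nrow(df)
  if (rows_in == 0) {
    out <- tibble::tibble(gene = character(), line_id = character(),
                          variant_class = character(), protein_change = character())
    attr(out, "load_report") <- load_report(0L, 0L)
    return(out)
  }
  if (!"line_id" %in% names(df)) {
    if (is.null(line_index)) {
      cd_abort("mutation table uses ccle_name but no line index was supplied",
               class = "condep_schema_error")
    }
    df$line_id <- translate_line(line_index, df$ccle_name, strict = FALSE)
  } else if (!is.null(line_index)) {
    df$line_id <- translate_line(line_index, df$line_id, strict = FALSE)
  }
  if (!is.null(gene_index)) {
    df$gene <- translate_gene(gene_index, df$gene, strict = FALSE)
  }
  df$protein_change <- normalize_protein_change(df$protein_change)
  keep <- !is.na(df$gene) & !is.na(df$line_id) &
    !is.na(df$variant_class) & df$variant_class != ""
  out <- tibble::as_tibble(df[keep, c("gene", "line_id", "variant_class",
                                      "protein_change")])
  attr(out, "load_report") <- load_report(rows_in, nrow(out))
  out
}

normalize_protein_change <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  toupper(sub("^p\\.", "", trimws(x)))
}

#' Read a localization annotation table
#'
#' Long format: one row per (gene, compartment, source, category)
#' annotation. Compartment labels are normalized to lowercase and
#' "cell membrane" is aliased to "plasma membrane".
#'
#' @param x CSV path or data frame with columns `gene`, `compartment`,
#'   `source`, `category`.
#' @param gene_index Optional gene index for translation.
#' @param compartment_aliases Named character vector mapping alternative
#'   labels to canonical ones.
#' @return Tibble of raw annotations with a `load_report` attribute.
#' @export
read_localization_table <- function(x, gene_index = NULL,
                                    compartment_aliases = c("cell membrane" = "plasma membrane")) {
  df <- if (is.data.frame(x)) tibble::as_tibble(x) else {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()))
  }
  req <- c("gene", "compartment", "source", "category")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    cd_abort(paste0("localization table is missing column(s): ",
                    paste(miss, collapse = ", ")),
             class = "condep_schema_error")
  }
  rows_in <- nrow(df)
  df$compartment <- tolower(trimws(df$compartment))
  hit <- df$compartment %in% names(compartment_aliases)
  df$compartment[hit] <- unname(compartment_aliases[df$compartment[hit]])
  if (!is.null(gene_index)) {
    df$gene <- translate_gene(gene_index, df$gene, strict = FALSE)
  }
  keep <- !is.na(df$gene)
  out <- tibble::as_tibble(df[keep, req])
  attr(out, "load_report") <- load_report(rows_in, nrow(out))
  out
}

#' Read a protein-complex membership table
#'
#' Long format: one row per (complex, member gene).
#'
#' @param x CSV path or data frame with columns `complex_id`,
#'   `complex_name`, `gene`.
#' @param gene_index Optional gene index for translation.
#' @return Tibble of complex memberships with a `load_report` attribute.
#' @export
read_complex_table <- function(x, gene_index = NULL) {
  df <- if (is.data.frame(x)) tibble::as_tibble(x) else {
    readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()))
  }
  req <- c("complex_id", "complex_name", "gene")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    cd_abort(paste0("complex table is missing column(s): ",
                    paste(miss, collapse = ", ")),
             class = "condep_schema_error")
  }
  rows_in <- nrow(df)
  if (!is.null(gene_index)) {
    df$gene <- translate_gene(gene_index, df$gene, strict = FALSE)
  }
  keep <- !is.na(df$gene)
  out <- tibble::as_tibble(df[keep, req])
  attr(out, "load_report") <- load_report(rows_in, nrow(out))
  out
}
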