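# The store bundles every loaded dataset behind one handle; entity-level
# query verbs (entities.R) operate on it. Accessors only ever read.

#' Assemble a data store from loaded tables
#'
#' @param line_index A `line_index` ([load_cell_line_index()]). Required:
#'   it defines the cell-line universe.
#' @param gene_index Optional `gene_index` ([load_gene_index()]).
#' @param ceres,bayes Optional genes × lines numeric matrices (CERES gene
#'   effect scores; Bayes-factor essentiality).
#' @param counts Optional genes × lines RNA-seq counts matrix.
#' @param mutations Optional mutation tibble ([read_mutation_table()]).
#' @param localization Optional scored localization records
#'   ([apply_confidence_map()]) or raw annotations.
#' @param complexes Optional complex-membership tibble
#'   ([read_complex_table()]).
#' @param thresholds Named list of analysis thresholds; defaults to the
#'   package defaults (see [load_config()]).
#' @return A `condep_store` object.
#' @export
build_store <- function(line_index, gene_index = NULL, ceres = NULL,
                        bayes = NULL, counts = NULL, mutations = NULL,
                        localization = NULL, complexes = NULL,
                        thresholds = NULL) {
  stopifnot(inherits(line_index, "line_index"))
  th <- .default_thresholds
  for (k in names(thresholds %||% list())) th[[k]] <- thresholds[[k]]
  validate_thresholds(th)
  structure(list(
    line_index = line_index, gene_index = gene_index,
    ceres = ceres, bayes = bayes, counts = counts,
    mutations = mutations, localization = localization,
    complexes = complexes, thresholds = th
  ), class = "condep_store")
}

#' Load a complete store from a configuration
#'
#' Reads every dataset registered in a [load_config()] configuration.
#' Dataset names are interpreted by convention: `gene_index`, `line_index`
#' (or `sample_info`), `ceres`, `bayes`, `counts`, `mutations`,
#' `localization`, `complexes`.
#'
#' @param config A `condep_config` or a path to a YAML configuration.
#' @param confidence_map Confidence map used to score localization
#'   annotations; defaults to [default_confidence_map()].
#' @return A `condep_store`.
#' @export
load_store <- function(config, confidence_map = default_confidence_map()) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "condep_config"))
  ds <- config$datasets
  path_of <- function(nm) if (nm %in% ds$name) ds$path[ds$name == nm] else NULL

  li_path <- path_of("line_index") %||% path_of("sample_info")
  if (is.null(li_path)) {
    cd_abort("configuration must register a 'line_index' or 'sample_info' dataset",
             class = "condep_config_error")
  }
  line_index <- load_cell_line_index(li_path)
  gi_path <- path_of("gene_index")
  gene_index <- if (!is.null(gi_path)) load_gene_index(gi_path) else NULL

  rd_mat <- function(nm, kind) {
    p <- path_of(nm)
    if (is.null(p)) return(NULL)
    read_omics_matrix(p, kind = kind, gene_index = gene_index,
                      line_index = line_index)
  }
  loc <- NULL
  if (!is.null(path_of("localization"))) {
    raw <- read_localization_table(path_of("localization"), gene_index = gene_index)
    loc <- apply_confidence_map(raw, confidence_map)
  }
  mut <- NULL
  if (!is.null(path_of("mutations"))) {
    mut <- read_mutation_table(path_of("mutations"), gene_index = gene_index,
                               line_index = line_index)
  }
  cpx <- NULL
  if (!is.null(path_of("complexes"))) {
    cpx <- read_complex_table(path_of("complexes"), gene_index = gene_index)
  }
  build_store(line_index = line_index, gene_index = gene_index,
              ceres = rd_mat("ceres", "ceres"),
              bayes = rd_mat("bayes", "bayes_factor"),
              counts = rd_mat("counts", "counts"),
              mutations = mut, localization = loc, complexes = cpx,
              thresholds = config$thresholds)
}

#' @export
print.condep_store <- function(x, ...) {
  dim_of <- function(m) if (is.null(m)) "absent" else paste(dim(m), collapse = " x ")
  n_of <- function(d) if (is.null(d)) "absent" else paste0(nrow(d), " rows")
  cat("<condep_store>\n")
  cat("  cell lines:   ", nrow(x$line_index), "\n")
  cat("  ceres:        ", dim_of(x$ceres), "\n")
  cat("  bayes:        ", dim_of(x$bayes), "\n")
  cat("  counts:       ", dim_of(x$counts), "\n")
  cat("  mutations:    ", n_of(x$mutations), "\n")
  cat("  localization: ", n_of(x$localization), "\n")
  cat("  complexes:    ", n_of(x$complexes), "\n")
  invisible(x)
}

store_require <- function(store, what) {
  if (is.null(store[[what]])) {
    cd_abort(paste0("store has no '", what, "' dataset loaded"),
             class = "condep_capability_error")
  }
  store[[what]]
}
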