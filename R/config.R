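# Configuration: dataset registry + analysis thresholds.
#
# Threshold defaults are the published operating points of the analysis
# procedures: adjusted p < 0.01 for differential expression, raw p < 0.01
# for differential essentiality, p < 0.05 for the sex-stratified
# essentiality comparison, Bayes factor > 5 for binarized essentiality,
# localization confidence score >= 6 for surface-target nomination, and
# the 85th-95th variance percentile band for the pan-cancer screen.

.default_thresholds <- list(
  de_alpha      = 0.01,
  ess_alpha     = 0.01,
  sex_ess_alpha = 0.05,
  bf_cutoff     = 5.0,
  loc_min_score = 6L,
  var_band      = c(0.85, 0.95)
)

.schema_kinds <- c("matrix", "mutations", "sample_info", "localization", "complexes")

#' Load and validate an analysis configuration
#'
#' Reads a YAML configuration describing where each dataset lives
#' (`data_root`, `datasets:`) and which significance / score thresholds to
#' apply (`thresholds:`). Any threshold omitted from the file is filled with
#' the package default; dataset paths are resolved relative to `data_root`.
#'
#' @param path Path to a YAML configuration file.
#' @param check_files If `TRUE` (default) every dataset path must point to a
#'   readable file.
#' @return An object of class `condep_config`: a list with elements
#'   `data_root`, `datasets` (tibble with columns `name`, `path`,
#'   `schema_kind`, `release_label`) and `thresholds`.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("data_root: .", "datasets: {}"), cfg_file)
#' cfg <- load_config(cfg_file)
#' cfg$thresholds$de_alpha
#' @export
load_config <- function(path, check_files = TRUE) {
  if (!file.exists(path)) {
    cd_abort(paste0("config file not found: ", path), class = "condep_config_error")
  }
  raw <- yaml::read_yaml(path)
  data_root <- raw$data_root %||% dirname(path)

  thresholds <- .default_thresholds
  for (key in names(raw$thresholds %||% list())) {
    if (key %notin% names(.default_thresholds)) {
      cd_abort(paste0("unknown threshold key: ", key), class = "condep_config_error")
    }
    val <- raw$thresholds[[key]]
    if (!is.numeric(unlist(val))) {
      cd_abort(paste0("threshold '", key, "' is not numeric"),
               class = "condep_config_error")
    }
    thresholds[[key]] <- unlist(val)
  }
  validate_thresholds(thresholds)

  ds <- raw$datasets %||% list()
  datasets <- purrr::imap_dfr(ds, function(entry, nm) {
    kind <- entry$schema_kind %||% NA_character_
    if (is.na(kind) || kind %notin% .schema_kinds) {
      cd_abort(paste0("dataset '", nm, "' has invalid schema_kind: ", kind),
               class = "condep_config_error")
    }
    p <- entry$path
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(data_root, p)
    tibble::tibble(name = nm, path = p, schema_kind = kind,
                   release_label = entry$release_label %||% NA_character_)
  })
  if (check_files && nrow(datasets) > 0) {
    missing <- datasets$path[!file.exists(datasets$path)]
    if (length(missing) > 0) {
      cd_abort(paste0("dataset file(s) not found: ", paste(missing, collapse = ", ")),
               class = "condep_config_error")
    }
  }

  structure(list(data_root = data_root, datasets = datasets,
                 thresholds = thresholds),
            class = "condep_config")
}

validate_thresholds <- function(th) {
  for (key in c("de_alpha", "ess_alpha", "sex_ess_alpha")) {
    v <- th[[key]]
    if (length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      cd_abort(paste0("threshold '", key, "' must be a single value in [0,1]"),
               class = "condep_config_error")
    }
  }
  if (length(th$bf_cutoff) != 1 || !is.finite(th$bf_cutoff)) {
    cd_abort("threshold 'bf_cutoff' must be a single finite number",
             class = "condep_config_error")
  }
  if (length(th$loc_min_score) != 1 || th$loc_min_score < 0) {
    cd_abort("threshold 'loc_min_score' must be a single non-negative number",
             class = "condep_config_error")
  }
  band <- th$var_band
  if (length(band) != 2 || any(!is.finite(band)) || any(band < 0) || any(band > 1)) {
    cd_abort("threshold 'var_band' must be two values in [0,1]",
             class = "condep_config_error")
  }
  if (band[1] >= band[2]) {
    cd_abort("threshold 'var_band' is reversed: lower must be < upper",
             class = "condep_config_error")
  }
  invisible(th)
}

#' @export
print.condep_config <- function(x, ...) {
  cat("<condep_config>\n")
  cat("  data_root:", x$data_root, "\n")
  cat("  datasets: ", nrow(x$datasets), "\n")
  cat("  thresholds:",
      paste(names(x$thresholds)[1:5],
            vapply(x$thresholds[1:5], function(v) paste(v, collapse = "-"), ""),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Registry of upstream data releases
#'
#' The retrieval layer for live panel releases is deliberately a stub: this
#' registry records, per dataset, a URL template, a release label and an
#' expected checksum, and [validate_registry()] checks the contract without
#' touching the network. Actual downloads are out of scope (release data are
#' distributed under their own licenses and the analysis layer is
#' release-agnostic); users point the configuration at local files instead.
#'
#' @param entries A data frame / tibble with columns `name`, `url`,
#'   `release_label` and optionally `sha256`.
#' @return A `condep_registry` tibble.
#' @export
release_registry <- function(entries) {
  entries <- tibble::as_tibble(entries)
  req <- c("name", "url", "release_label")
  miss <- setdiff(req, names(entries))
  if (length(miss) > 0) {
    cd_abort(paste0("registry is missing column(s): ", paste(miss, collapse = ", ")),
             class = "condep_schema_error")
  }
  if (!"sha256" %in% names(entries)) entries$sha256 <- NA_character_
  if (anyDuplicated(entries$name) > 0) {
    cd_abort("registry dataset names must be unique", class = "condep_schema_error")
  }
  structure(entries, class = c("condep_registry", class(entries)))
}

#' @rdname release_registry
#' @param registry A `condep_registry`.
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "condep_registry"))
  ok_url <- grepl("^https?://", registry$url)
  if (!all(ok_url)) {
    cd_abort(paste0("registry entries with invalid url: ",
                    paste(registry$name[!ok_url], collapse = ", ")),
             class = "condep_schema_error")
  }
  invisible(registry)
}
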