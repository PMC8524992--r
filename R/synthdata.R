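# Seeded generator of panel-schema fixtures with planted signals.
#
# The generator emulates the table schemas of a dependency-screen panel
# (gene/line index tables, CERES and Bayes-factor matrices, RNA-seq
# counts, somatic mutation calls, localization annotations, complex
# membership) with known planted effects, so every analysis procedure can
# be tested for recovery and calibration without any release download.
# One global seed governs all draws through a fixed stream-splitting
# scheme (one derived seed per component), so components are reproducible
# independently and identical spec + seed yields byte-identical files.
# It makes no attempt to mimic real panel covariance structure, gene-gene
# correlation, or real mutation spectra.

.fixture_components <- c("sample_info", "mutations", "ceres", "bayes",
                         "counts", "localization", "complexes", "external")

component_seed <- function(seed, component) {
  k <- match(component, .fixture_components)
  (as.integer(seed) %% 1000000L) * 1009L + k * 101L
}

#' Canonical fixture identifiers
#'
#' The generator assigns gene stable_ids `100001, 100002, ...` with
#' symbols `GENE0001, ...`, and line_ids `ACH-000001, ...`. These helpers
#' let tests and planted-effect specs refer to them by index.
#'
#' @param i Integer index (1-based).
#' @return Character identifier.
#' @export
fixture_gene_id <- function(i) as.character(100000L + as.integer(i))

#' @rdname fixture_gene_id
#' @export
fixture_line_id <- function(i) sprintf("ACH-%06d", as.integer(i))

.default_tissues <- tibble::tibble(
  lineage = c("lung", "ovary", "pancreas", "colon"),
  disease = c("nsclc", "ovarian cancer", "pdac", "crc"),
  prop = c(0.4, 0.2, 0.2, 0.2)
)

#' Specification of a synthetic panel fixture
#'
#' Default magnitudes are the study conditions under which the analysis
#' procedures are validated: CERES noise sd 0.15 around group means
#' (essential genes at -1, others at 0), Bayes factors proportional to
#' negated CERES (scale 10, so essential genes sit near BF 10 and clear
#' the >5 cutoff), NB counts with dispersion 0.1 around log-normal base
#' means, and sample sizes set per fixture. Planted effects are lists of
#' `list(genes = NULL, n =, where = list(...), delta/lfc =)`; when
#' `genes` is `NULL` the generator deterministically assigns the first
#' `n` unused non-essential genes. `where` predicates may combine
#' `lineage`, `disease`, `sex`, `mutated` (a driver gene id) and
#' `source = "panel"` (expression effects applied to all panel samples,
#' for panel-vs-external contrasts).
#'
#' @param n_genes,n_lines Panel dimensions.
#' @param seed Global integer seed.
#' @param tissues Tibble `lineage`, `disease`, `prop` (proportions are
#'   normalized).
#' @param sex_props Named proportions for `male`, `female`, `unknown`.
#' @param frac_essential Fraction of genes commonly essential (CERES mean
#'   -1).
#' @param ceres_sd CERES noise sd (default 0.15).
#' @param missing_rate Fraction of CERES entries set missing.
#' @param bf_scale,bf_noise_sd Bayes-factor model `BF = -bf_scale * ceres
#'   + N(0, bf_noise_sd)`.
#' @param counts_meanlog,counts_sdlog Log-normal base-mean model for
#'   counts.
#' @param nb_dispersion NB dispersion of counts (default 0.1).
#' @param sf_sdlog Log-normal sd of per-sample size factors.
#' @param drivers Tibble `gene`, `rate`, `variant_class`,
#'   `protein_change`: per-line Bernoulli mutation rates for driver
#'   genes.
#' @param passenger_rate Per-(gene, line) rate of random missense
#'   passenger mutations (driver genes excluded).
#' @param membrane_frac Fraction of genes annotated to the plasma
#'   membrane.
#' @param loc_source_prob Probability each source annotates a membrane
#'   gene.
#' @param n_complexes Number of random protein complexes.
#' @param planted_essentiality,planted_expression,planted_membrane Lists
#'   of planted effects (see Details).
#' @param n_external Number of external (benign reference) RNA-seq
#'   samples; 0 disables the external matrix.
#' @param external_prefix Sample-name prefix for external samples.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 400, n_lines = 60, seed = 1,
                         tissues = .default_tissues,
                         sex_props = c(male = 0.45, female = 0.45, unknown = 0.10),
                         frac_essential = 0.1, ceres_sd = 0.15,
                         missing_rate = 0, bf_scale = 10, bf_noise_sd = 0.5,
                         counts_meanlog = log(200), counts_sdlog = 1,
                         nb_dispersion = 0.1, sf_sdlog = 0.2,
                         drivers = NULL, passenger_rate = 0.01,
                         membrane_frac = 0.15, loc_source_prob = 0.7,
                         n_complexes = 10,
                         planted_essentiality = list(),
                         planted_expression = list(),
                         planted_membrane = list(),
                         n_external = 0, external_prefix = "HBE") {
  spec <- list(
    n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
    seed = as.integer(seed), tissues = tibble::as_tibble(tissues),
    sex_props = sex_props, frac_essential = frac_essential,
    ceres_sd = ceres_sd, missing_rate = missing_rate,
    bf_scale = bf_scale, bf_noise_sd = bf_noise_sd,
    counts_meanlog = counts_meanlog, counts_sdlog = counts_sdlog,
    nb_dispersion = nb_dispersion, sf_sdlog = sf_sdlog,
    drivers = if (is.null(drivers)) {
      tibble::tibble(gene = character(), rate = numeric(),
                     variant_class = character(), protein_change = character())
    } else tibble::as_tibble(drivers),
    passenger_rate = passenger_rate, membrane_frac = membrane_frac,
    loc_source_prob = loc_source_prob, n_complexes = as.integer(n_complexes),
    planted_essentiality = planted_essentiality,
    planted_expression = planted_expression,
    planted_membrane = planted_membrane,
    n_external = as.integer(n_external), external_prefix = external_prefix
  )
  validate_fixture_spec(spec)
  structure(spec, class = "fixture_spec")
}

validate_fixture_spec <- function(spec) {
  if (spec$n_genes < 1 || spec$n_lines < 1) {
    cd_abort("fixture dimensions must be positive", class = "condep_argument_error")
  }
  probs <- c(spec$sex_props, spec$frac_essential, spec$missing_rate,
             spec$passenger_rate, spec$membrane_frac, spec$loc_source_prob,
             spec$drivers$rate, spec$tissues$prop)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    cd_abort("fixture probabilities must lie in [0, 1]",
             class = "condep_argument_error")
  }
  if (spec$ceres_sd <= 0 || spec$nb_dispersion <= 0) {
    cd_abort("fixture noise parameters must be positive",
             class = "condep_argument_error")
  }
  for (pe in c(spec$planted_essentiality, spec$planted_expression)) {
    if (is.null(pe$genes) && is.null(pe$n)) {
      cd_abort("each planted effect needs `genes` or `n`",
               class = "condep_argument_error")
    }
  }
  invisible(spec)
}

resolve_where <- function(where, sample_info, mutations) {
  ids <- sample_info$line_id
  if (is.null(where)) return(ids)
  if (!is.null(where$lineage)) {
    ids <- intersect(ids, sample_info$line_id[sample_info$lineage %in% tolower(where$lineage)])
  }
  if (!is.null(where$disease)) {
    ids <- intersect(ids, sample_info$line_id[sample_info$disease %in% tolower(where$disease)])
  }
  if (!is.null(where$sex)) {
    ids <- intersect(ids, sample_info$line_id[sample_info$sex %in% normalize_sex(where$sex)])
  }
  if (!is.null(where$mutated)) {
    hit <- unique(mutations$line_id[mutations$gene == where$mutated &
                                      mutations$variant_class %in% protein_altering_classes])
    ids <- intersect(ids, hit)
  }
  sort(ids)
}

where_label <- function(where) {
  if (is.null(where) || length(where) == 0) return("all")
  paste(vapply(names(where), function(k) paste0(k, "=", paste(where[[k]], collapse = "|")),
               ""), collapse = "&")
}

# Assign explicit gene ids to planted effects that only give `n`,
# drawing deterministically from unused non-essential genes.
assign_planted_genes <- function(effects, pool) {
  used <- unlist(lapply(effects, function(e) e$genes))
  pool <- setdiff(pool, used)
  for (i in seq_along(effects)) {
    if (is.null(effects[[i]]$genes)) {
      n <- effects[[i]]$n
      if (n > length(pool)) {
        cd_abort("not enough unused genes for planted effects",
                 class = "condep_argument_error")
      }
      effects[[i]]$genes <- pool[seq_len(n)]
      pool <- pool[-seq_len(n)]
    }
  }
  effects
}

#' Generate a synthetic panel fixture
#'
#' Builds every table of the panel schema from a [fixture_spec()], in
#' memory and (optionally) as CSV files that load through the package
#' readers without any dropped rows. All planted effects are enumerated
#' in the returned `truth` tibble.
#'
#' @param spec A `fixture_spec`.
#' @param out_dir Optional directory; when given, writes `gene_index.csv`,
#'   `sample_info.csv`, `ceres.csv`, `bayes.csv`, `counts.csv`,
#'   `mutations.csv`, `localization.csv`, `complexes.csv`, `truth.csv`
#'   and (if `n_external > 0`) `external_counts.csv`.
#' @return List with `store` (a ready [build_store()] handle), `tables`
#'   (all generated tibbles/matrices), `truth`, `external_counts`
#'   (or `NULL`), and `paths` (when `out_dir` was given).
#' @examples
#' fx <- generate_fixture(fixture_spec(n_genes = 50, n_lines = 12, seed = 7))
#' fx$store
#' @export
generate_fixture <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  validate_fixture_spec(spec)
  n_g <- spec$n_genes; n_l <- spec$n_lines
  gene_ids <- fixture_gene_id(seq_len(n_g))
  line_ids <- fixture_line_id(seq_len(n_l))

  gene_index <- tibble::tibble(
    symbol = sprintf("GENE%04d", seq_len(n_g)),
    stable_id = gene_ids,
    aliases = ifelse(seq_len(n_g) <= 5, sprintf("ALIAS%04d", seq_len(n_g)), "")
  )

  # --- sample info ------------------------------------------------------
  set.seed(component_seed(spec$seed, "sample_info"))
  tis <- spec$tissues
  tis$prop <- tis$prop / sum(tis$prop)
  t_idx <- sample(nrow(tis), n_l, replace = TRUE, prob = tis$prop)
  sexes <- sample(names(spec$sex_props), n_l, replace = TRUE,
                  prob = spec$sex_props / sum(spec$sex_props))
  sample_info <- tibble::tibble(
    line_id = line_ids,
    ccle_name = paste0("LINE", seq_len(n_l), "_", toupper(tis$lineage[t_idx])),
    lineage = tis$lineage[t_idx],
    disease = tis$disease[t_idx],
    subtype = NA_character_,
    sex = sexes
  )

  # --- mutations --------------------------------------------------------
  set.seed(component_seed(spec$seed, "mutations"))
  mut_rows <- list()
  if (nrow(spec$drivers) > 0) {
    for (i in seq_len(nrow(spec$drivers))) {
      drv <- spec$drivers[i, ]
      hit <- line_ids[runif(n_l) < drv$rate]
      if (length(hit) > 0) {
        mut_rows[[length(mut_rows) + 1]] <- tibble::tibble(
          gene = drv$gene, line_id = hit,
          variant_class = drv$variant_class,
          protein_change = normalize_protein_change(drv$protein_change))
      }
    }
  }
  if (spec$passenger_rate > 0) {
    pool <- setdiff(gene_ids, spec$drivers$gene)
    hit <- which(matrix(runif(length(pool) * n_l), length(pool)) < spec$passenger_rate,
                 arr.ind = TRUE)
    if (nrow(hit) > 0) {
      mut_rows[[length(mut_rows) + 1]] <- tibble::tibble(
        gene = pool[hit[, 1]], line_id = line_ids[hit[, 2]],
        variant_class = "Missense_Mutation",
        protein_change = paste0("A", hit[, 1], "V"))
    }
  }
  mutations <- if (length(mut_rows) > 0) {
    dplyr::arrange(dplyr::bind_rows(mut_rows), .data$gene, .data$line_id)
  } else {
    tibble::tibble(gene = character(), line_id = character(),
                   variant_class = character(), protein_change = character())
  }

  # --- planted-effect gene assignment ----------------------------------
  n_ess <- floor(spec$frac_essential * n_g)
  essential_genes <- gene_ids[seq_len(n_ess)]
  pool <- setdiff(gene_ids, c(essential_genes, spec$drivers$gene))
  ess_effects <- assign_planted_genes(spec$planted_essentiality, pool)
  used <- unlist(lapply(ess_effects, function(e) e$genes))
  expr_effects <- assign_planted_genes(spec$planted_expression,
                                       setdiff(pool, used))

  truth <- list()

  # --- CERES ------------------------------------------------------------
  set.seed(component_seed(spec$seed, "ceres"))
  base_mean <- ifelse(gene_ids %in% essential_genes, -1, 0)
  ceres <- matrix(rnorm(n_g * n_l, mean = base_mean, sd = spec$ceres_sd),
                  nrow = n_g, dimnames = list(gene_ids, line_ids))
  for (eff in ess_effects) {
    grp <- resolve_where(eff$where, sample_info, mutations)
    if (length(grp) > 0) {
      ceres[eff$genes, grp] <- ceres[eff$genes, grp] + eff$delta
    }
    truth[[length(truth) + 1]] <- tibble::tibble(
      module = "essentiality", gene = eff$genes,
      group_def = where_label(eff$where), parameter = "delta",
      value = eff$delta, n_lines = length(grp))
  }
  if (spec$missing_rate > 0) {
    ceres[runif(n_g * n_l) < spec$missing_rate] <- NA_real_
  }
  attr(ceres, "kind") <- "ceres"

  # --- Bayes factors ----------------------------------------------------
  set.seed(component_seed(spec$seed, "bayes"))
  bayes <- -spec$bf_scale * ifelse(is.na(ceres), 0, ceres) +
    matrix(rnorm(n_g * n_l, sd = spec$bf_noise_sd), nrow = n_g)
  bayes[is.na(ceres)] <- NA_real_
  dimnames(bayes) <- dimnames(ceres)
  attr(bayes, "kind") <- "bayes_factor"

  # --- counts -----------------------------------------------------------
  set.seed(component_seed(spec$seed, "counts"))
  mu0 <- rlnorm(n_g, meanlog = spec$counts_meanlog, sdlog = spec$counts_sdlog)
  names(mu0) <- gene_ids
  sf <- rlnorm(n_l, meanlog = 0, sdlog = spec$sf_sdlog)
  lfc_mat <- matrix(0, n_g, n_l, dimnames = list(gene_ids, line_ids))
  for (eff in expr_effects) {
    grp <- if (!is.null(eff$where$source) && eff$where$source == "panel") {
      line_ids
    } else resolve_where(eff$where, sample_info, mutations)
    if (length(grp) > 0) lfc_mat[eff$genes, grp] <- eff$lfc
    truth[[length(truth) + 1]] <- tibble::tibble(
      module = "expression", gene = eff$genes,
      group_def = where_label(eff$where), parameter = "log2fc",
      value = eff$lfc, n_lines = length(grp))
  }
  mu <- (mu0 %o% sf) * 2^lfc_mat
  counts <- matrix(rnbinom(n_g * n_l, mu = mu, size = 1 / spec$nb_dispersion),
                   nrow = n_g, dimnames = list(gene_ids, line_ids))
  attr(counts, "kind") <- "counts"

  # --- external counts --------------------------------------------------
  external_counts <- NULL
  if (spec$n_external > 0) {
    set.seed(component_seed(spec$seed, "external"))
    ext_names <- paste0(spec$external_prefix, "_", seq_len(spec$n_external))
    ext_sf <- rlnorm(spec$n_external, meanlog = 0, sdlog = spec$sf_sdlog)
    ext_mu <- mu0 %o% ext_sf
    external_counts <- matrix(
      rnbinom(n_g * spec$n_external, mu = ext_mu, size = 1 / spec$nb_dispersion),
      nrow = n_g, dimnames = list(gene_ids, ext_names))
    attr(external_counts, "kind") <- "counts"
  }

  # --- localization -----------------------------------------------------
  set.seed(component_seed(spec$seed, "localization"))
  planted_mem_genes <- unlist(lapply(spec$planted_membrane, function(e) e$genes))
  n_mem <- max(0, floor(spec$membrane_frac * n_g) - length(planted_mem_genes))
  mem_random <- sample(setdiff(gene_ids, planted_mem_genes), n_mem)
  cmap <- default_confidence_map()
  loc_rows <- list()
  if (length(mem_random) > 0) {
    grid <- expand.grid(gene = mem_random, source = .localization_sources,
                        stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < spec$loc_source_prob, , drop = FALSE]
    if (nrow(grid) > 0) {
      cat_idx <- sample.int(4, nrow(grid), replace = TRUE)
      loc_rows[[1]] <- tibble::tibble(
        gene = grid$gene, compartment = "plasma membrane",
        source = grid$source,
        category = vapply(seq_len(nrow(grid)), function(i)
          names(cmap[[grid$source[i]]])[cat_idx[i]], ""))
    }
  }
  for (eff in spec$planted_membrane) {
    parts <- score_partition(eff$score)
    for (g in eff$genes) {
      for (k in seq_along(parts)) {
        if (parts[k] > 0) {
          s <- .localization_sources[k]
          loc_rows[[length(loc_rows) + 1]] <- tibble::tibble(
            gene = g, compartment = "plasma membrane", source = s,
            category = names(cmap[[s]])[5L - parts[k]])
        }
      }
      truth[[length(truth) + 1]] <- tibble::tibble(
        module = "membrane", gene = g, group_def = "plasma membrane",
        parameter = "total_score", value = eff$score, n_lines = NA_integer_)
    }
  }
  other_comp <- c("nucleus", "cytosol", "mitochondria", "endoplasmic reticulum",
                  "golgi apparatus")
  non_mem <- setdiff(gene_ids, c(mem_random, planted_mem_genes))
  if (length(non_mem) > 0) {
    s <- sample(.localization_sources, length(non_mem), replace = TRUE)
    cat_idx <- sample.int(4, length(non_mem), replace = TRUE)
    loc_rows[[length(loc_rows) + 1]] <- tibble::tibble(
      gene = non_mem,
      compartment = sample(other_comp, length(non_mem), replace = TRUE),
      source = s,
      category = vapply(seq_along(non_mem), function(i)
        names(cmap[[s[i]]])[cat_idx[i]], ""))
  }
  localization_raw <- dplyr::arrange(dplyr::bind_rows(loc_rows),
                                     .data$gene, .data$compartment, .data$source)

  # --- complexes --------------------------------------------------------
  set.seed(component_seed(spec$seed, "complexes"))
  cpx_rows <- list()
  for (k in seq_len(spec$n_complexes)) {
    members <- sample(gene_ids, sample(2:4, 1))
    cpx_rows[[k]] <- tibble::tibble(
      complex_id = sprintf("CPX%03d", k),
      complex_name = sprintf("complex %03d", k),
      gene = sort(members))
  }
  complexes <- if (length(cpx_rows) > 0) dplyr::bind_rows(cpx_rows) else {
    tibble::tibble(complex_id = character(), complex_name = character(),
                   gene = character())
  }

  truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else {
    tibble::tibble(module = character(), gene = character(),
                   group_def = character(), parameter = character(),
                   value = numeric(), n_lines = integer())
  }

  gi <- load_gene_index(gene_index)
  li <- load_cell_line_index(sample_info)
  store <- build_store(
    line_index = li, gene_index = gi, ceres = ceres, bayes = bayes,
    counts = counts, mutations = mutations,
    localization = apply_confidence_map(localization_raw),
    complexes = complexes)

  tables <- list(gene_index = gene_index, sample_info = sample_info,
                 ceres = ceres, bayes = bayes, counts = counts,
                 mutations = mutations, localization = localization_raw,
                 complexes = complexes, truth = truth)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      gene_index = file.path(out_dir, "gene_index.csv"),
      sample_info = file.path(out_dir, "sample_info.csv"),
      ceres = file.path(out_dir, "ceres.csv"),
      bayes = file.path(out_dir, "bayes.csv"),
      counts = file.path(out_dir, "counts.csv"),
      mutations = file.path(out_dir, "mutations.csv"),
      localization = file.path(out_dir, "localization.csv"),
      complexes = file.path(out_dir, "complexes.csv"),
      truth = file.path(out_dir, "truth.csv")
    )
    readr::write_csv(gene_index, paths[["gene_index"]])
    readr::write_csv(sample_info, paths[["sample_info"]])
    write_omics_matrix(ceres, paths[["ceres"]])
    write_omics_matrix(bayes, paths[["bayes"]])
    write_omics_matrix(counts, paths[["counts"]])
    readr::write_csv(mutations, paths[["mutations"]])
    readr::write_csv(localization_raw, paths[["localization"]])
    readr::write_csv(complexes, paths[["complexes"]])
    readr::write_csv(truth, paths[["truth"]])
    if (!is.null(external_counts)) {
      paths[["external_counts"]] <- file.path(out_dir, "external_counts.csv")
      write_omics_matrix(external_counts, paths[["external_counts"]])
    }
  }

  list(store = store, tables = tables, truth = truth,
       external_counts = external_counts, paths = paths)
}

# Decompose a total confidence score (0..12) into three per-source scores,
# each in 0..4, greedily from the first source.
score_partition <- function(score) {
  stopifnot(score >= 0, score <= 12)
  parts <- integer(3)
  for (k in 1:3) {
    parts[k] <- min(4L, score)
    score <- score - parts[k]
  }
  parts
}

#' Null fixture: the same spec with every planted effect removed
#'
#' @param spec A `fixture_spec`.
#' @param out_dir As in [generate_fixture()].
#' @return As [generate_fixture()]; `truth` has zero rows.
#' @export
null_fixture <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  spec$planted_essentiality <- list()
  spec$planted_expression <- list()
  spec$planted_membrane <- list()
  generate_fixture(spec, out_dir = out_dir)
}
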