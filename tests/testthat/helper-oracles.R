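# Independent oracles, written from first principles and kept free of any
# package internals.

# Exhaustive Mann-Whitney: enumerate every assignment of the pooled ranks
# to group 1, build the exact null distribution of U, and return the
# two-sided p (doubled smaller tail, capped at 1). Tie-free inputs only.
mw_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(anyDuplicated(pooled) == 0)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Closed-form 2x2 Pearson chi-square.
chi2_closed <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Hand-written BH step-up rule.
bh_manual <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * n / seq(n, 1)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force cell-line filter: a direct row scan over the index and
# mutation tables, independent of the query layer.
brute_filter <- function(sample_info, mutations, altering,
                         lineage = NULL, disease = NULL, sex = NULL,
                         mutated_gene = NULL, mutated_class = NULL,
                         wildtype_gene = NULL) {
  keep <- rep(TRUE, nrow(sample_info))
  if (!is.null(lineage)) keep <- keep & sample_info$lineage %in% lineage
  if (!is.null(disease)) keep <- keep & sample_info$disease %in% disease
  if (!is.null(sex)) keep <- keep & sample_info$sex %in% sex
  if (!is.null(mutated_gene)) {
    cls <- if (is.null(mutated_class)) altering else mutated_class
    hit <- unique(mutations$line_id[mutations$gene == mutated_gene &
                                      mutations$variant_class %in% cls])
    keep <- keep & sample_info$line_id %in% hit
  }
  if (!is.null(wildtype_gene)) {
    hit <- unique(mutations$line_id[mutations$gene == wildtype_gene &
                                      mutations$variant_class %in% altering])
    keep <- keep & !(sample_info$line_id %in% hit)
  }
  sort(sample_info$line_id[keep])
}

# Shared small fixture for the query-layer tests.
make_query_fixture <- function(seed = 11) {
  generate_fixture(fixture_spec(
    n_genes = 60, n_lines = 40, seed = seed,
    drivers = tibble::tibble(
      gene = fixture_gene_id(c(10, 11)),
      rate = c(0.4, 0.25),
      variant_class = c("Missense_Mutation", "Nonsense_Mutation"),
      protein_change = c("p.G12D", "")),
    passenger_rate = 0.02))
}

write_minimal_config <- function(dir, datasets, thresholds = NULL) {
  lines <- c(paste0("data_root: ", dir), "datasets:")
  for (nm in names(datasets)) {
    lines <- c(lines, paste0("  ", nm, ":"),
               paste0("    path: ", basename(datasets[[nm]]$path)),
               paste0("    schema_kind: ", datasets[[nm]]$schema_kind),
               "    release_label: synthetic-v1")
  }
  if (!is.null(thresholds)) {
    lines <- c(lines, "thresholds:",
               paste0("  ", names(thresholds), ": ",
                      vapply(thresholds, function(v)
                        if (length(v) > 1) paste0("[", paste(v, collapse = ", "), "]")
                        else as.character(v), "")))
  }
  path <- file.path(dir, "config.yaml")
  writeLines(lines, path)
  path
}
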