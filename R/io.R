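#' @title Table readers/writers and the full analysis pipeline
#' @description All tables are plain comma-delimited text. Every file the
#'   package writes starts with comment lines (`#`) recording the package
#'   version, the configuration hash and the seed, so a result bundle can
#'   be traced back to the run that produced it. Readers validate the
#'   documented schema and report offending rows by number.
#' @name io
NULL

# FNV-1a 32-bit hash of a character string; used to fingerprint configs
# in output headers without external dependencies.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keep h a double
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Fingerprint of a configuration object
#' @param config Any R object (typically a [scenario_config] or
#'   [analysis_config]).
#' @return 8-hex-digit hash string.
#' @export
config_hash <- function(config) {
  fnv1a_hash(paste(deparse(config), collapse = "\n"))
}

# Write a data.frame as CSV with provenance header lines.
write_table_with_header <- function(df, path, seed = NA, hash = NA) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# gelflux %s",
                     as.character(utils::packageVersion("gelflux"))), con)
  if (!is.na(hash)) writeLines(sprintf("# config_hash: %s", hash), con)
  if (!is.na(seed)) writeLines(sprintf("# seed: %s", seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_skip_comments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Generic schema check: required columns present, no NA in them, and
# per-column predicates reported with row numbers.
check_schema <- function(df, required, checks = list(), what = "table") {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in names(checks)) {
    bad <- which(!checks[[col]](df[[col]]))
    if (length(bad)) {
      stop(what, ": invalid values in column '", col, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "")
    }
  }
  invisible(df)
}

#' Read a taxon counts table
#'
#' Expected columns: `sample_id`, `taxon`, `tier`, `count` (non-negative
#' integer), `surveyed_area_m2` (> 0), `duration_d` (> 0). Comment lines
#' beginning with `#` are ignored. An empty-but-headered file returns an
#' empty table with a warning.
#'
#' @param path Path to a CSV file.
#' @return Validated data.frame.
#' @export
read_counts_table <- function(path) {
  df <- read_table_skip_comments(path)
  if (nrow(df) == 0) {
    check_schema(df, c("sample_id", "taxon", "count", "surveyed_area_m2",
                       "duration_d"), what = "counts table")
    warning("counts table is empty: ", path)
    return(df)
  }
  check_schema(df,
               c("sample_id", "taxon", "count", "surveyed_area_m2",
                 "duration_d"),
               checks = list(
                 count = function(x) !is.na(x) & x >= 0 &
                   abs(x - round(x)) < 1e-8,
                 surveyed_area_m2 = function(x) !is.na(x) & x > 0,
                 duration_d = function(x) !is.na(x) & x > 0),
               what = "counts table")
}

#' Read a trap-sample metadata table
#' @param path Path to a CSV file with columns `sample_id`, `site`,
#'   `deployment`, `platform`, `depth_m`, `duration_d`, `tube_area_m2`,
#'   `combined_area_m2`.
#' @return Validated data.frame.
#' @export
read_trap_samples <- function(path) {
  df <- read_table_skip_comments(path)
  check_schema(df,
               c("sample_id", "site", "deployment", "platform", "depth_m",
                 "duration_d", "tube_area_m2", "combined_area_m2"),
               checks = list(
                 depth_m = function(x) !is.na(x) & x > 0,
                 duration_d = function(x) !is.na(x) & x > 0,
                 tube_area_m2 = function(x) !is.na(x) & x > 0),
               what = "trap sample table")
}

#' Read a bulk replicate-split mass table
#' @param path CSV with columns `sample_id`, `replicate`, `mass_umolC`,
#'   `split_fraction`.
#' @return Validated data.frame.
#' @export
read_bulk_masses <- function(path) {
  df <- read_table_skip_comments(path)
  check_schema(df, c("sample_id", "replicate", "mass_umolC", "split_fraction"),
               checks = list(
                 mass_umolC = function(x) !is.na(x) & x >= 0,
                 split_fraction = function(x) !is.na(x) & x > 0 & x <= 1),
               what = "bulk mass table")
}

#' Read a detrital particle-class POC flux table
#' @param path CSV with columns `sample_id`, `particle_class`,
#'   `poc_flux_mmolC_m2_d`.
#' @return Validated data.frame.
#' @export
read_detrital_fluxes <- function(path) {
  df <- read_table_skip_comments(path)
  check_schema(df, c("sample_id", "particle_class", "poc_flux_mmolC_m2_d"),
               checks = list(
                 poc_flux_mmolC_m2_d = function(x) !is.na(x) & x >= 0),
               what = "detrital flux table")
}

#' Write a synthetic dataset as its four input tables plus a truth sidecar
#'
#' Writes `trap_samples.csv`, `counts.csv`, `bulk_masses.csv`,
#' `detrital_fluxes.csv` (the four analysis inputs) and
#' `truth_flux.csv` + `truth_meta.csv` (the generator's noise-free
#' record), each with a provenance header.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- dataset$truth$config
  h <- config_hash(cfg)
  s <- cfg$seed
  write_table_with_header(dataset$trap_samples,
                          file.path(dir, "trap_samples.csv"), s, h)
  write_table_with_header(dataset$counts, file.path(dir, "counts.csv"), s, h)
  write_table_with_header(dataset$bulk_masses,
                          file.path(dir, "bulk_masses.csv"), s, h)
  write_table_with_header(dataset$detrital_fluxes,
                          file.path(dir, "detrital_fluxes.csv"), s, h)
  write_table_with_header(dataset$truth$flux,
                          file.path(dir, "truth_flux.csv"), s, h)
  meta <- data.frame(key = c("layer_speed_m_d", "site_label", "seed",
                             "platform_cv", "detrital_coupling"),
                     value = c(dataset$truth$layer_speed_m_d,
                               cfg$site_label, cfg$seed, cfg$platform_cv,
                               cfg$detrital_coupling),
                     stringsAsFactors = FALSE)
  write_table_with_header(meta, file.path(dir, "truth_meta.csv"), s, h)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset]
#' @param dir Directory containing the four input tables.
#' @return List with `trap_samples`, `counts`, `bulk_masses`,
#'   `detrital_fluxes` data.frames.
#' @export
read_dataset <- function(dir) {
  list(trap_samples = read_trap_samples(file.path(dir, "trap_samples.csv")),
       counts = read_counts_table(file.path(dir, "counts.csv")),
       bulk_masses = read_bulk_masses(file.path(dir, "bulk_masses.csv")),
       detrital_fluxes = read_detrital_fluxes(
         file.path(dir, "detrital_fluxes.csv")))
}

#' Analysis configuration for the full pipeline
#'
#' @param network_threshold Bray-Curtis edge threshold (default 0.25).
#' @param display_min Minimum mean share for a taxon to be shown in
#'   cluster compositions (default 0.05).
#' @param diameter_um Cell diameter midpoint for the carbon model
#'   (default 45).
#' @param n_perm Permutations for PERMANOVA and Spearman tests (default
#'   9999).
#' @param seed Integer seed for all permutation streams.
#' @param sinking_taxon Taxon whose profile translation is inverted for a
#'   sinking speed (default `"Fragilariopsis"`).
#' @param sinking_deployments Length-2 vector: the earlier and later
#'   deployment compared (default `c(2, 3)`).
#' @param delta_t_d Days between the two deployments (default 7).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(network_threshold = 0.25, display_min = 0.05,
                            diameter_um = 45, n_perm = 9999L, seed = 1L,
                            sinking_taxon = "Fragilariopsis",
                            sinking_deployments = c(2L, 3L),
                            delta_t_d = 7) {
  if (network_threshold <= 0 || network_threshold > 1) {
    stop("network_threshold must be in (0, 1]")
  }
  if (display_min < 0 || display_min >= 1) stop("display_min must be in [0, 1)")
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full analysis pipeline on a dataset
#'
#' Chains the stages in the order fluxes -> composition -> covariation ->
#' sinking speed, writing every result table to `out_dir` with
#' provenance headers. Deterministic under fixed seeds: the same dataset
#' and config produce byte-identical outputs. Any stage failure removes
#' partial outputs and re-raises with the stage name.
#'
#' @param data List with `trap_samples`, `counts`, `bulk_masses`,
#'   `detrital_fluxes` (e.g. from [read_dataset] or a
#'   `synthetic_dataset`).
#' @param out_dir Output directory.
#' @param config An [analysis_config].
#' @return Invisibly, a list with all computed results.
#' @export
run_pipeline <- function(data, out_dir, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (inherits(data, "synthetic_dataset")) {
    data <- list(trap_samples = data$trap_samples, counts = data$counts,
                 bulk_masses = data$bulk_masses,
                 detrital_fluxes = data$detrital_fluxes)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(config)
  s <- config$seed
  written <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table_with_header(df, p, s, h)
    written <<- c(written, p)
  }
  stage <- "setup"
  res <- tryCatch({
    stage <- "fluxes"
    ft <- cell_flux_table(data$counts)
    bt <- bulk_flux_table(data$bulk_masses, data$trap_samples)
    emit(ft, "cell_fluxes.csv")
    emit(bt, "bulk_fluxes.csv")

    stage <- "community"
    cm <- community_matrix(ft, data$trap_samples)
    nonzero <- rowSums(cm$matrix) > 0
    M <- cm$matrix[nonzero, , drop = FALSE]
    meta <- cm$meta[nonzero, , drop = FALSE]
    D <- community_dissimilarity(M)
    perm <- permanova(D, meta$deployment, n_perm = config$n_perm,
                      seed = config$seed)
    net <- build_similarity_network(D, config$network_threshold, meta)
    comp <- network_cluster_composition(net, M, config$display_min)
    emit(data.frame(sample_id = rownames(D), D,
                    check.names = FALSE), "dissimilarity.csv")
    emit(net$edges, "network_edges.csv")
    emit(data.frame(sample_id = names(net$membership),
                    cluster = unname(net$membership)),
         "network_membership.csv")
    emit(data.frame(cluster = rownames(comp), comp, check.names = FALSE),
         "cluster_composition.csv")
    emit(data.frame(statistic = c("pseudo_F", "p_value", "n_perm"),
                    value = c(perm$pseudo_F, perm$p_value, perm$n_perm)),
         "permanova.csv")

    stage <- "covariation"
    X <- flux_feature_table(ft, data$detrital_fluxes,
                            cell_carbon_model(diameter_um = config$diameter_um))
    pca <- pca_first_two_loadings(X)
    sp <- spearman_rho(X[, "cell_poc"], X[, "small_detrital"],
                       n_perm = config$n_perm, seed = config$seed)
    emit(data.frame(variable = rownames(pca$loadings), pca$loadings,
                    check.names = FALSE), "pca_loadings.csv")
    emit(data.frame(statistic = c("spearman_rho", "p_value", "n"),
                    value = c(sp$rho, sp$p_value, sp$n)),
         "spearman_cell_vs_small_detrital.csv")

    stage <- "sinking"
    sink_rec <- pipeline_sinking(ft, data$trap_samples, config)
    emit(sink_rec, "sinking_speed.csv")

    stage <- "manifest"
    manifest <- data.frame(
      key = c("package", "version", "config_hash", "seed",
              "network_threshold", "n_perm"),
      value = c("gelflux",
                as.character(utils::packageVersion("gelflux")),
                h, s, config$network_threshold, config$n_perm),
      stringsAsFactors = FALSE)
    emit(manifest, "manifest.csv")
    list(flux_table = ft, bulk_table = bt, dissimilarity = D,
         permanova = perm, network = net, cluster_composition = comp,
         pca = pca, spearman = sp, sinking = sink_rec)
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# One-row sinking-speed record for the configured taxon and deployment
# pair; averages platform replicates at each depth first.
pipeline_sinking <- function(flux_table, trap_samples, config) {
  tx <- config$sinking_taxon
  make_profile <- function(dep) {
    ids <- trap_samples$sample_id[trap_samples$deployment == dep]
    sub <- flux_table[flux_table$sample_id %in% ids &
                        flux_table$taxon == tx, ]
    if (nrow(sub) == 0) return(NULL)
    depth <- trap_samples$depth_m[match(sub$sample_id, trap_samples$sample_id)]
    agg <- tapply(sub$flux_cells_m2_d, depth, mean)
    z <- as.numeric(names(agg))
    ord <- order(z)
    if (length(z) < 2) return(NULL)
    flux_profile(z[ord], as.numeric(agg)[ord], taxon = tx, deployment = dep)
  }
  early <- make_profile(config$sinking_deployments[1])
  late <- make_profile(config$sinking_deployments[2])
  if (is.null(early) || is.null(late)) {
    return(data.frame(taxon = tx, speed_m_d = NA_real_,
                      sink_depth_m = NA_real_, delta_t_d = config$delta_t_d,
                      no_loss = NA, note = "insufficient profile data"))
  }
  est <- infer_translation_speed(early, late, delta_t_d = config$delta_t_d)
  data.frame(taxon = tx, speed_m_d = est$speed_m_d,
             sink_depth_m = est$sink_depth_m, delta_t_d = est$delta_t_d,
             no_loss = est$no_loss,
             note = paste(est$assumptions, collapse = ";"),
             stringsAsFactors = FALSE)
}
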