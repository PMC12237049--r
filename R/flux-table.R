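#' @title Tidy flux tables and community matrices
#' @name flux-table
NULL

#' Estimated number fluxes per sample and taxon
#'
#' Applies [number_flux] to every counted taxon of every sample. When a
#' taxon was counted at more than one detection tier (different surveyed
#' areas), the tier fluxes are summed and their sigmas combined in
#' quadrature.
#'
#' @param counts Counts table with columns `sample_id`, `taxon`, `tier`,
#'   `count`, `surveyed_area_m2`, `duration_d`.
#' @return data.frame `sample_id`, `taxon`, `flux_cells_m2_d`, `sigma`,
#'   `n_counted`, one row per sample x taxon.
#' @export
cell_flux_table <- function(counts) {
  req <- c("sample_id", "taxon", "count", "surveyed_area_m2", "duration_d")
  missing_cols <- setdiff(req, names(counts))
  if (length(missing_cols)) {
    stop("counts table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- interaction(counts$sample_id, counts$taxon, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(counts)), key), function(idx) {
    recs <- lapply(idx, function(i) {
      number_flux(counts$count[i], counts$surveyed_area_m2[i],
                  counts$duration_d[i])
    })
    data.frame(sample_id = counts$sample_id[idx[1]],
               taxon = counts$taxon[idx[1]],
               flux_cells_m2_d = sum(vapply(recs, `[[`, numeric(1), "value")),
               sigma = sqrt(sum(vapply(recs, `[[`, numeric(1), "sigma")^2)),
               n_counted = sum(counts$count[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$taxon), ]
  rownames(out) <- NULL
  out
}

#' Samples x taxa community matrix from a tidy flux table
#'
#' @param flux_table Output of [cell_flux_table].
#' @param trap_samples Trap metadata with `sample_id`, `deployment`,
#'   `depth_m` (used to order rows and returned as row metadata).
#' @return List with `matrix` (samples x taxa number fluxes) and `meta`
#'   (one metadata row per matrix row, same order).
#' @export
community_matrix <- function(flux_table, trap_samples) {
  ids <- trap_samples$sample_id
  taxa <- sort(unique(flux_table$taxon))
  M <- matrix(0, length(ids), length(taxa), dimnames = list(ids, taxa))
  idx <- cbind(match(flux_table$sample_id, ids),
               match(flux_table$taxon, taxa))
  keep <- !is.na(idx[, 1])
  M[idx[keep, , drop = FALSE]] <- flux_table$flux_cells_m2_d[keep]
  list(matrix = M, meta = trap_samples)
}

#' Bulk POC fluxes per sample from replicate split masses
#'
#' @param bulk_masses Table with `sample_id`, `replicate`, `mass_umolC`,
#'   `split_fraction`.
#' @param trap_samples Trap metadata providing `duration_d` and
#'   `combined_area_m2` per sample.
#' @return data.frame `sample_id`, `poc_flux_mmolC_m2_d`, `sigma`.
#' @export
bulk_flux_table <- function(bulk_masses, trap_samples) {
  rows <- lapply(split(bulk_masses, bulk_masses$sample_id), function(bm) {
    ts <- trap_samples[trap_samples$sample_id == bm$sample_id[1], ]
    if (nrow(ts) != 1) stop("sample metadata missing for ", bm$sample_id[1])
    rec <- bulk_poc_flux(bm$mass_umolC, bm$split_fraction[1],
                         ts$duration_d, ts$combined_area_m2)
    data.frame(sample_id = bm$sample_id[1],
               poc_flux_mmolC_m2_d = rec$value / 1000,
               sigma = rec$sigma / 1000,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id), ]
  rownames(out) <- NULL
  out
}

#' Per-sample flux feature table for covariation analysis
#'
#' Combines the solitary-cell POC flux (cell number flux times per-cell
#' carbon) with the detrital particle-class POC fluxes into one
#' samples x variables matrix, mmol C m^-2 d^-1.
#'
#' @param flux_table Output of [cell_flux_table].
#' @param detrital_fluxes Table with `sample_id`, `particle_class`,
#'   `poc_flux_mmolC_m2_d`.
#' @param model [cell_carbon_model] used for the per-cell carbon.
#' @return Samples x variables numeric matrix; first column
#'   `cell_poc`.
#' @export
flux_feature_table <- function(flux_table, detrital_fluxes,
                               model = cell_carbon_model()) {
  pg <- cell_carbon(sphere_volume(model$diameter_um), model)
  cell_tot <- tapply(flux_table$flux_cells_m2_d, flux_table$sample_id, sum)
  cell_poc <- cell_tot * pg / PG_PER_MMOL_C
  ids <- sort(unique(detrital_fluxes$sample_id))
  ids <- ids[ids %in% names(cell_poc)]
  classes <- sort(unique(detrital_fluxes$particle_class))
  X <- matrix(0, length(ids), length(classes) + 1,
              dimnames = list(ids, c("cell_poc", classes)))
  X[, "cell_poc"] <- cell_poc[ids]
  for (cl in classes) {
    sub <- detrital_fluxes[detrital_fluxes$particle_class == cl, ]
    X[sub$sample_id[sub$sample_id %in% ids], cl] <-
      sub$poc_flux_mmolC_m2_d[sub$sample_id %in% ids]
  }
  X
}
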