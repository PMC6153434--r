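#' Export a spheroid snapshot as CSV
#'
#' One row per cell: position (um), lineage name, volume, life state,
#' severe-hypoxia clock and accumulated log survival.
#'
#' @param sph spheroid state.
#' @param path output CSV; `NULL` returns the data.frame.
#' @return the data.frame (invisibly when written).
#' @export
export_spheroid_snapshot <- function(sph, path = NULL) {
  grid <- sph$grid; cells <- sph$cells
  xyz <- (grid$ijk[cells$site, , drop = FALSE] + 0.5) * grid$dx
  lname <- vapply(sph$lines, `[[`, "", "name")
  d <- data.frame(
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    lineage = lname[cells$line], volume = cells$volume,
    state = c("viable", "death_tagged")[cells$state + 1L],
    severe_hypoxia_h = cells$hypoxia_h,
    log_survival = cells$log_survival)
  if (!is.null(path)) {
    utils::write.csv(d, path, row.names = FALSE)
    return(invisible(d))
  }
  d
}

#' Run manifest
#'
#' JSON-serializable record of a simulation run: every parameter with
#' its provenance, the seeds used, and the ASSUMED entries the run
#' depended on (a run whose registry holds only PAPER and FITTED
#' entries is flagged fully constrained).
#'
#' @param model `hap_prodrug_model`.
#' @param seeds integer vector of RNG seeds used.
#' @param extra named list folded into the manifest.
#' @param path optional JSON output path.
#' @return the manifest list (invisibly when written).
#' @export
run_manifest <- function(model, seeds = integer(0), extra = list(),
                         path = NULL) {
  prov <- registry_provenance(model$registry)
  man <- c(list(
    model = model$name,
    seeds = seeds,
    parameters = model$registry,
    assumed_parameters = prov$assumed,
    fully_constrained = prov$fully_constrained), extra)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(man))
  }
  man
}
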