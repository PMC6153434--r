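#' Exposure protocol
#'
#' Bundles the drug-exposure conditions of one in-silico experiment.
#'
#' @param concentrations prodrug concentrations (uM), >= 0.
#' @param duration_h exposure duration (h), > 0.
#' @param o2_bolus dissolved-O2 contamination introduced with the drug
#'   (uM).
#' @param mixing_ratios activator fractions of the co-cultures.
#' @param replicates spheroids (or wells) pooled per concentration.
#' @param seed base RNG seed; replicate r uses `seed + r`.
#' @return object of class `hap_protocol`.
#' @export
exposure_protocol <- function(concentrations, duration_h = 1,
                              o2_bolus = 0, mixing_ratios = c(0, 0.1, 0.5),
                              replicates = 1, seed = 1L) {
  if (duration_h <= 0) stop("duration must be > 0", call. = FALSE)
  if (any(concentrations < 0)) stop("concentrations must be >= 0",
                                    call. = FALSE)
  if (any(mixing_ratios < 0 | mixing_ratios > 1)) {
    stop("mixing ratios must lie in [0, 1]", call. = FALSE)
  }
  structure(list(concentrations = concentrations, duration_h = duration_h,
                 o2_bolus = o2_bolus, mixing_ratios = mixing_ratios,
                 replicates = replicates, seed = seed),
            class = "hap_protocol")
}

#' Monolayer clonogenic assay
#'
#' Simulates the 1-h anoxic monolayer exposure for each lineage in its
#' own well (selective plating idealized as perfect lineage separation)
#' across a concentration grid, including prodrug depletion by cellular
#' metabolism and any dissolved-O2 bolus.
#'
#' @param model `hap_prodrug_model`.
#' @param lines line pair from [model_cell_lines()].
#' @param protocol an [exposure_protocol()].
#' @param n_cells,volume_mL monolayer density (default 1e5 cells /
#'   0.15 mL).
#' @param ... passed to [simulate_monolayer()].
#' @return `DoseResponse` data.frame: `prodrug_uM`, `lineage`, `SF`,
#'   `log10_SF`.
#' @export
run_monolayer_assay <- function(model, lines, protocol,
                                n_cells = NULL, volume_mL = NULL, ...) {
  reg <- model$registry
  n_cells <- n_cells %||% registry_get(reg, "monolayer_n_cells")
  volume_mL <- volume_mL %||% registry_get(reg, "monolayer_volume")
  rows <- list()
  for (ln in lines) {
    for (conc in protocol$concentrations) {
      if (conc == 0) {
        sf <- 1
      } else {
        sim <- simulate_monolayer(model, list(ln), fractions = 1,
                                  concentration = conc,
                                  duration = protocol$duration_h * 3600,
                                  o2_bolus = protocol$o2_bolus,
                                  n_cells = n_cells, volume_mL = volume_mL,
                                  ...)
        sf <- unname(sim$SF[1])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        prodrug_uM = conc, lineage = ln$name, SF = sf,
        log10_SF = log10(sf))
    }
  }
  structure(do.call(rbind, rows), class = c("hap_dose_response",
                                            "data.frame"))
}

#' Spheroid co-culture clonogenic assay
#'
#' For each mixing ratio, exposes pre-grown spheroids to each prodrug
#' concentration for the protocol duration (anoxic unless an O2 bolus is
#' set) and reads per-lineage surviving fractions; replicate spheroids
#' are pooled (averaged), mirroring the pooling of four spheroids per
#' concentration in the wet protocol.
#'
#' @param model `hap_prodrug_model`.
#' @param spheroids named list: one grown spheroid (or list of replicate
#'   spheroids) per mixing ratio; names are the activator fractions.
#' @param protocol an [exposure_protocol()].
#' @param ... passed to [simulate_spheroid_exposure()].
#' @return data.frame: `mixing_ratio`, `prodrug_uM`, `lineage`, `SF`,
#'   `log10_SF`.
#' @export
run_spheroid_assay <- function(model, spheroids, protocol, ...) {
  rows <- list()
  for (mr_name in names(spheroids)) {
    sph_set <- spheroids[[mr_name]]
    if (inherits(sph_set, "hap_spheroid")) sph_set <- list(sph_set)
    mr <- as.numeric(mr_name)
    for (conc in protocol$concentrations) {
      sf_acc <- c(activator = 0, target = 0)
      n_acc <- c(activator = 0, target = 0)
      for (sph in sph_set) {
        if (conc == 0) {
          sf <- c(activator = 1, target = 1)
          have <- c(activator = any(sph$cells$line == 1L & sph$cells$state == 0L),
                    target = any(sph$cells$line == 2L & sph$cells$state == 0L))
        } else {
          ex <- simulate_spheroid_exposure(
            sph, model, concentration = conc,
            duration = protocol$duration_h * 3600,
            o2_bolus = protocol$o2_bolus, ...)
          sf <- c(activator = NA_real_, target = NA_real_)
          have <- c(activator = FALSE, target = FALSE)
          for (li in 1:2) {
            nm <- c("activator", "target")[li]
            ok <- any(ex$cells$line == li & ex$cells$state == 0L)
            have[nm] <- ok
            if (ok) sf[nm] <- surviving_fraction(ex$cells, lineage = li)
          }
        }
        for (nm in c("activator", "target")) {
          if (have[nm]) {
            sf_acc[nm] <- sf_acc[nm] + sf[nm]
            n_acc[nm] <- n_acc[nm] + 1
          }
        }
      }
      for (nm in c("activator", "target")) {
        if (n_acc[nm] > 0) {
          sfm <- sf_acc[nm] / n_acc[nm]
          rows[[length(rows) + 1L]] <- data.frame(
            mixing_ratio = mr, prodrug_uM = conc, lineage = nm,
            SF = sfm, log10_SF = log10(sfm))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' MCL diffusion assay across activator fractions
#'
#' @param model `hap_prodrug_model`.
#' @param lines line pair.
#' @param fractions activator fractions (default the published 0, 10,
#'   50, 100%).
#' @param donor_bolus donor prodrug bolus (uM).
#' @param duration_h assay duration (h).
#' @param ... passed to [simulate_mcl()].
#' @return list with `summary` (data.frame: activator_fraction,
#'   receiver_auc, final_metabolite_umol) and `runs` (per-fraction
#'   [simulate_mcl()] results).
#' @export
run_mcl_assay <- function(model, lines, fractions = c(0, 0.1, 0.5, 1),
                          donor_bolus = NULL, duration_h = 5, ...) {
  donor_bolus <- donor_bolus %||% registry_get(model$registry,
                                               "mcl_donor_bolus")
  runs <- list()
  rows <- list()
  for (f in fractions) {
    r <- simulate_mcl(model, lines, activator_fraction = f,
                      donor_bolus = donor_bolus,
                      duration = duration_h * 3600, ...)
    runs[[as.character(f)]] <- r
    rows[[length(rows) + 1L]] <- data.frame(
      activator_fraction = f, receiver_auc = r$receiver_auc,
      final_metabolite_umol = r$metabolite_umol$umol[
        nrow(r$metabolite_umol)])
  }
  list(summary = do.call(rbind, rows), runs = runs)
}

#' Decompose metabolite contributions to cell kill
#'
#' Runs the dichloro-metabolites model, then counterfactuals with each
#' kill model's potency zeroed (transport unchanged), and attributes
#' log kill to each metabolite class; contributions are normalized to
#' sum to one per lineage.
#'
#' @param model a `hap_prodrug_model` with two kill models (the
#'   dichloro model).
#' @param simulate function(model) returning a per-lineage named vector
#'   of SF (e.g. a closure around [run_monolayer_assay()] or a spheroid
#'   exposure at the lineage-specific test concentration).
#' @return data.frame: `lineage`, `metabolite`, `log_kill`,
#'   `relative_contribution`.
#' @export
decompose_metabolite_contributions <- function(model, simulate) {
  K <- length(model$kill_models)
  stopifnot(K >= 2)
  sf_full <- simulate(model)
  res <- list()
  for (k in seq_len(K)) {
    m_k <- model
    for (j in setdiff(seq_len(K), k)) m_k$kill_models[[j]]$K_c <- 0
    sf_k <- simulate(m_k)
    res[[k]] <- -log10(sf_k)     # log kill by metabolite k alone
  }
  lineages <- names(sf_full)
  rows <- list()
  for (ln in lineages) {
    lk <- vapply(res, `[[`, 0, ln)
    tot <- sum(lk)
    for (k in seq_len(K)) {
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = ln, metabolite = model$kill_models[[k]]$label,
        log_kill = lk[k],
        relative_contribution = if (tot > 0) lk[k] / tot else 0)
    }
  }
  do.call(rbind, rows)
}

#' Spatial-heterogeneity seeding experiment
#'
#' Grows spheroids from different initial cell numbers (same activator
#' fraction) to a common diameter with equal doubling times and
#' hypoxia-driven death disabled, then treats each with the prodrug and
#' reports per-seed target log kill. Sparse seedings develop patchy
#' activator distributions, which lowers and destabilizes bystander
#' killing of targets.
#'
#' @param model `hap_prodrug_model` (dichloro model in the reference
#'   experiment).
#' @param lines line pair.
#' @param n_init vector of initial cell numbers.
#' @param activator_fraction seeded activator fraction.
#' @param concentration prodrug concentration (uM).
#' @param n_seeds replicate seedings per size.
#' @param target_diameter grow until this equivalent diameter (um).
#' @param doubling_time_h common doubling time (h).
#' @param duration_h exposure (h).
#' @param max_days growth cut-off (days).
#' @param ... passed to [simulate_spheroid_exposure()].
#' @return list with `per_seed` (data.frame: n_init, seed,
#'   target_log_kill, diameter) and `summary` (mean, SD, SE per size).
#' @export
run_heterogeneity_experiment <- function(model, lines,
                                         n_init = c(20, 2000, 20000),
                                         activator_fraction = 0.10,
                                         concentration = 40,
                                         n_seeds = 6,
                                         target_diameter = 430,
                                         doubling_time_h = 16,
                                         duration_h = 1, max_days = 14,
                                         ...) {
  lines_eq <- lines
  for (i in seq_along(lines_eq)) lines_eq[[i]]$doubling_time <- doubling_time_h
  params <- growth_params(hypoxic_death = FALSE)
  rows <- list()
  for (n0 in n_init) {
    for (s in seq_len(n_seeds)) {
      seed <- 1000L * match(n0, n_init) + s
      sph <- seed_spheroid(n0, activator_fraction, lines_eq, seed = seed,
                           max_radius = target_diameter / 2 + 40)
      hours <- 0
      while (lattice_diameter(sph$grid) < target_diameter &&
             hours < max_days * 24) {
        # abundant-O2 growth (death disabled; O2 limitation immaterial
        # for the diameters used here)
        sph <- grow_step(sph, O2 = 100, params = params, dt_h = 1,
                         seed = seed + hours)
        hours <- hours + 1
      }
      ex <- simulate_spheroid_exposure(sph, model,
                                       concentration = concentration,
                                       duration = duration_h * 3600, ...)
      tlk <- -log10(surviving_fraction(ex$cells, lineage = 2L))
      rows[[length(rows) + 1L]] <- data.frame(
        n_init = n0, seed = s, target_log_kill = tlk,
        diameter = lattice_diameter(sph$grid), hours_grown = hours)
    }
  }
  per_seed <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_seed, per_seed$n_init), function(d) {
    data.frame(n_init = d$n_init[1], mean_log_kill = mean(d$target_log_kill),
               sd_log_kill = stats::sd(d$target_log_kill),
               se_log_kill = stats::sd(d$target_log_kill) / sqrt(nrow(d)))
  }))
  list(per_seed = per_seed, summary = agg)
}

#' Interpolate the IC90 from a dose-response table
#'
#' Concentration at which the surviving fraction crosses 0.1 (90%
#' kill), by linear interpolation of `log10(SF)` against concentration,
#' consistent with the log-linear treatment of clonogenic survival
#' curves.
#'
#' @param dose_response a `DoseResponse` data.frame
#'   (see [run_monolayer_assay()]).
#' @param lineage lineage name to filter on.
#' @return list of class `hap_ic90`: `lineage`, `ic90_uM`, `bracket`
#'   (the two concentrations around the crossing).
#' @export
ic90 <- function(dose_response, lineage) {
  d <- dose_response[dose_response$lineage == lineage, ]
  if (!nrow(d)) stop("no rows for lineage '", lineage, "'", call. = FALSE)
  d <- d[order(d$prodrug_uM), ]
  if (any(diff(d$SF) > 1e-9)) {
    stop("SF must be non-increasing in concentration to interpolate an IC90",
         call. = FALSE)
  }
  y <- d$log10_SF
  target <- -1
  hit <- which(abs(y - target) < 1e-12)
  if (length(hit)) {
    c_star <- d$prodrug_uM[hit[1]]
    br <- rep(d$prodrug_uM[hit[1]], 2)
  } else {
    below <- which(y < target)
    if (!length(below) || below[1] == 1L) {
      stop(sprintf(
        "SF grid does not bracket 0.1 (achieved SF range %.3g..%.3g)",
        min(d$SF), max(d$SF)), call. = FALSE)
    }
    j <- below[1]
    i <- j - 1L
    w <- (target - y[i]) / (y[j] - y[i])
    c_star <- d$prodrug_uM[i] + w * (d$prodrug_uM[j] - d$prodrug_uM[i])
    br <- c(d$prodrug_uM[i], d$prodrug_uM[j])
  }
  structure(list(lineage = lineage, ic90_uM = c_star, bracket = br),
            class = "hap_ic90")
}
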