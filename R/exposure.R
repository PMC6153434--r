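# drop solutes that neither drive a kill model nor lead to one through
# the chain (keeps the prodrug and every acts_on solute plus ancestors)
.prune_inert <- function(model) {
  keep <- unique(c(model$prodrug,
                   vapply(model$kill_models, `[[`, "", "acts_on")))
  repeat {
    parents <- unlist(lapply(keep, function(nm)
      .parent_of(model$solutes, nm)))
    new <- union(keep, parents)
    if (length(new) == length(keep)) break
    keep <- new
  }
  model$solutes <- model$solutes[intersect(names(model$solutes), keep)]
  for (nm in names(model$solutes)) {
    ch <- model$solutes[[nm]]$child
    if (!is.null(ch) && !ch %in% keep) model$solutes[[nm]]$child <- NULL
  }
  model
}

#' Simulate a drug exposure on a grown spheroid
#'
#' Couples the 3D fine-grid transport of the prodrug model's solute
#' chain to the 1D unstirred medium column of the exposure well
#' ([culture_geometry()], default 80 uL). The medium is well-mixed at
#' time zero (drug addition) and unmixed thereafter. Oxygen is zero
#' throughout (anoxic chamber) unless `o2_bolus > 0`, in which case a
#' dissolved-oxygen contamination bolus is tracked: the medium column
#' carries transient O2 with the gas interface held at `gas_O2`, the
#' fine-grid O2 field is solved quasi-steadily against the bath, and the
#' oxygen-dependent metabolism constants are refreshed as the bolus is
#' consumed.
#'
#' Kill hazards accumulate per cell and kill model as the exact
#' trapezoidal integral of the hazard rate; on return each cell's
#' `log_survival` is decremented by its total hazard.
#'
#' @param sph grown spheroid state ([grow_spheroid()]).
#' @param model `hap_prodrug_model`.
#' @param concentration prodrug concentration at t = 0 (uM), uniform in
#'   the medium.
#' @param duration exposure (s), default 1 h.
#' @param o2_bolus initial dissolved O2 (uM) introduced with the drug.
#' @param geometry exposure-well geometry; default 80 uL in the growth
#'   well footprint, anoxic gas phase.
#' @param dt inner transport step (s).
#' @param dt_out outer step (s) for medium-column and O2 updates.
#' @param theta implicitness of the fine-grid stepper.
#' @param n_column medium-column nodes.
#' @param record_timecourse keep an outer-step time course.
#' @param track_inert also transport inert terminal metabolites (the
#'   SN30000 oxide pool); they do not influence kill, so clonogenic
#'   assays skip them by default.
#' @return list with `cells` (log_survival updated), `hazard` (cells x
#'   kill models), `kill_labels`, `o2_surface` (uM, final), `timecourse`
#'   (data.frame or NULL), `conservation` (relative mole balance error
#'   for the solute chain), `clip_events`.
#' @export
simulate_spheroid_exposure <- function(sph, model, concentration,
                                       duration = 3600, o2_bolus = 0,
                                       geometry = NULL, dt = 2,
                                       dt_out = 60, theta = 0.5,
                                       n_column = 12,
                                       record_timecourse = FALSE,
                                       track_inert = FALSE) {
  stopifnot(concentration >= 0, duration > 0)
  if (!track_inert) model <- .prune_inert(model)
  reg <- model$registry
  g <- function(nm) registry_get(reg, nm)
  geom <- geometry %||% culture_geometry(
    "spheroid",
    medium_volume = g("exposure_volume"),
    medium_depth = g("exposure_volume") * 1e3 / (g("well_area") / 1e6),
    well_area = g("well_area") / 1e6,
    gas_O2 = 0, initial_O2 = o2_bolus)
  grid <- sph$grid; cells <- sph$cells
  lines <- sph$lines

  ctx <- .make_transport_ctx(grid, model, lines, theta = theta, dt = dt)
  ctx$line_of <- cells$line[ctx$cell_rows]

  # initial fields: medium at `concentration`, spheroid interstitium 0
  occ <- grid$occupancy > 0L
  r_hull <- if (any(occ)) max(grid$r[occ]) else -1
  prodrug <- model$prodrug
  ce0 <- ifelse(grid$r > r_hull, concentration, 0)
  ctx$Ce[[prodrug]] <- ce0

  # medium column above/around the fine grid
  A <- geom$well_area * 1e6                 # mm2 -> um2
  depth <- geom$medium_depth * 1e3
  dz <- depth / n_column
  node_vol <- rep(A * dz, n_column)
  node_vol[1] <- node_vol[1] - grid$n_sites * grid$site_volume
  stopifnot(node_vol[1] > 0)
  diffusible <- names(which(vapply(model$solutes, `[[`, TRUE, "diffusible")))
  Ccol <- lapply(model$solutes, function(s) rep(0, n_column))
  Ccol[[prodrug]] <- rep(concentration, n_column)

  # oxygen machinery (only exercised when a bolus is present)
  o2_on <- o2_bolus > 0
  o2p <- list(Dm = g("O2_D_medium"), Dt = g("O2_D_tissue"),
              Vmax = g("O2_Vmax") * 1e21, Km = g("O2_Km"))
  O2_field <- rep(if (o2_on) o2_bolus else 0, grid$n_sites)
  Ccol_O2 <- rep(if (o2_on) o2_bolus else 0, n_column)
  if (o2_on) {
    O2_field <- .solve_o2_field(grid, o2p, C_bath = Ccol_O2[1],
                                C0 = O2_field)
  }
  occ <- grid$occupancy > 0L
  surf_sel <- which(occ & grid$r > r_hull - 1.5 * grid$dx)
  o2_surface_initial <- if (length(surf_sel)) mean(O2_field[surf_sel]) else NA_real_
  ctx$O2_cell <- O2_field[ctx$cell_sites]
  kmet_at_factor <- NULL
  .prepare_all(ctx)

  # mole budget over the tracked chain (decay removed is accounted)
  amount_total <- function() {
    grid_amt <- sum(vapply(ctx$order, function(nm) .grid_amount(ctx, nm), 0))
    col_amt <- sum(vapply(diffusible, function(nm)
      sum(Ccol[[nm]] * node_vol), 0))
    grid_amt + col_amt
  }
  decayed <- 0
  initial_amount <- amount_total()

  n_outer <- max(1L, round(duration / dt_out))
  n_inner <- max(1L, round(dt_out / dt))
  tc <- if (record_timecourse) vector("list", n_outer) else NULL

  for (o in seq_len(n_outer)) {
    if (o2_on) {
      cons <- sum(o2p$Vmax * O2_field[occ] / (o2p$Km + O2_field[occ]))
      Ccol_O2 <- .step_column(Ccol_O2, o2p$Dm, dz, dt_out,
                              gas_value = geom$gas_O2, sink_bottom = cons,
                              node_volume = node_vol, area = A)
      O2_field <- .solve_o2_field(grid, o2p, C_bath = Ccol_O2[1],
                                  C0 = O2_field)
      ctx$O2_cell <- O2_field[ctx$cell_sites]
      kmet_now <- .cell_conversion(ctx, prodrug)
      if (is.null(kmet_at_factor) ||
          max(abs(kmet_now - kmet_at_factor)) >
            0.05 * max(kmet_at_factor, 1e-12)) {
        .prepare_solute(ctx, prodrug)
        kmet_at_factor <- ctx$coef[[prodrug]]$conv
      }
    }
    bath <- lapply(Ccol, `[[`, 1)
    ctx$bath_influx[] <- 0
    for (i in seq_len(n_inner)) .step_once(ctx, bath)
    # return boundary fluxes to the bottom node, then diffuse the column
    for (nm in diffusible) {
      Ccol[[nm]][1] <- max(0, Ccol[[nm]][1] -
                             ctx$bath_influx[[nm]] / node_vol[1])
      kdec <- model$solutes[[nm]]$k_decay_medium
      if (kdec > 0) {
        decayed <- decayed + sum(Ccol[[nm]] * node_vol) *
          (1 - exp(-kdec * dt_out))
        Ccol[[nm]] <- Ccol[[nm]] * exp(-kdec * dt_out)
      }
      Ccol[[nm]] <- .step_column(Ccol[[nm]], model$solutes[[nm]]$D_medium,
                                 dz, dt_out, gas_value = NULL,
                                 sink_bottom = 0, node_volume = node_vol,
                                 area = A)
    }
    if (record_timecourse) {
      tc[[o]] <- data.frame(
        t_s = o * dt_out,
        bath_prodrug_uM = Ccol[[prodrug]][1],
        o2_bath_uM = if (o2_on) Ccol_O2[1] else 0,
        o2_surface_uM = if (length(surf_sel)) mean(O2_field[surf_sel]) else 0)
    }
  }

  haz <- rowSums(ctx$hazard)
  cells$log_survival[ctx$cell_rows] <- cells$log_survival[ctx$cell_rows] - haz
  # conservation: decay and intracellular losses are legitimate sinks;
  # report the balance including decayed moles (loss terms other than
  # k_decay_medium are only diagnosable per run)
  final_amount <- amount_total() + decayed
  cons_err <- if (initial_amount > 0)
    abs(final_amount - initial_amount) / initial_amount else 0

  list(cells = cells,
       hazard = ctx$hazard,
       kill_labels = vapply(model$kill_models, `[[`, "", "label"),
       o2_surface = if (length(surf_sel)) mean(O2_field[surf_sel]) else NA_real_,
       o2_surface_initial = o2_surface_initial,
       timecourse = if (record_timecourse) do.call(rbind, tc) else NULL,
       conservation = cons_err,
       clip_events = ctx$clip_events)
}
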