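#' Simulate a multicellular-layer (MCL) diffusion assay
#'
#' A planar tissue slab of thickness `mcl_thickness` (cell volume
#' fraction 0.5, activator/target mixture) separates two well-stirred
#' compartments. Drug is added to the donor compartment and
#' drug/metabolite amounts in both compartments are followed, as in the
#' diffusion-chamber experiment. The slab is discretized axially; every
#' node carries an extracellular equation (diffusivity `D_tissue`) and
#' one intracellular compartment per lineage; the support membrane is
#' treated as transparent. The chamber runs in the anoxic gas stream, so
#' metabolism proceeds at its anoxic rate.
#'
#' @param model `hap_prodrug_model`.
#' @param lines list with `activator`, `target` [cell_line_spec()]s.
#' @param activator_fraction fraction of slab cells that are activators
#'   in `[0, 1]`.
#' @param donor_bolus prodrug added to the donor at t = 0 (uM).
#' @param duration assay duration (s).
#' @param geometry a [culture_geometry()] of kind `"mcl"`.
#' @param acellular simulate a cell-free slab (pure tissue diffusion).
#' @param n_nodes slab nodes.
#' @param cell_volume cell volume (um^3).
#' @param times output times (s); default 13 evenly spaced samples.
#' @param rtol,atol solver tolerances.
#' @return list with `timecourse` (long data.frame: t_s, compartment,
#'   solute, concentration_uM, amount_umol), `receiver_norm` (receiver
#'   prodrug C/C0 vs time), `metabolite_umol` (donor+receiver tracked
#'   metabolite amounts vs time), `receiver_auc` (uM s, prodrug).
#' @export
simulate_mcl <- function(model, lines, activator_fraction,
                         donor_bolus = 100, duration = 5 * 3600,
                         geometry = NULL, acellular = FALSE,
                         n_nodes = 10, cell_volume = 2500,
                         times = NULL, rtol = 1e-7, atol = 1e-9) {
  stopifnot(activator_fraction >= 0, activator_fraction <= 1,
            donor_bolus >= 0, duration > 0)
  reg <- model$registry
  g <- function(nm) registry_get(reg, nm)
  geom <- geometry %||% culture_geometry(
    "mcl", medium_volume = g("mcl_compartment_volume"), medium_depth = 10,
    well_area = g("mcl_compartment_volume") * 100,
    donor_volume = g("mcl_compartment_volume"),
    receiver_volume = g("mcl_compartment_volume"),
    mcl_thickness = g("mcl_thickness"), mcl_area = g("mcl_area") / 1e6)
  sol <- model$solutes
  order <- validate_chain(sol)
  S <- length(order)
  diff_s <- vapply(sol[order], `[[`, TRUE, "diffusible")
  L <- 2L
  fr <- c(activator_fraction, 1 - activator_fraction)

  M <- n_nodes
  A <- geom$mcl_area * 1e6                  # mm2 -> um2
  th <- geom$mcl_thickness                  # um
  dz <- th / M
  node_vol <- A * dz
  Ve <- if (acellular) node_vol else node_vol / 2
  Vi_l <- if (acellular) c(0, 0) else (node_vol / 2) * fr
  Vd <- geom$donor_volume * 1e12            # mL -> um^3
  Vr <- geom$receiver_volume * 1e12

  # state: donor (S_d), receiver (S_d), Ce (M x S_d), Ci (M x L x S)
  sdx <- which(diff_s)
  nSd <- length(sdx)
  d_idx <- seq_len(nSd)
  r_idx <- nSd + seq_len(nSd)
  ce_idx <- array(0L, c(M, S))
  ce_idx[, sdx] <- 2 * nSd + seq_len(M * nSd)
  ci_idx <- array(seq_len(M * L * S), c(M, L, S)) + 2 * nSd + M * nSd
  ny <- 2 * nSd + M * nSd + M * L * S

  conv_l <- vapply(order, function(nm) {
    vapply(seq_len(L), function(l) {
      ms <- lines[[l]]$metabolism[[nm]]
      if (!is.null(ms)) oxygen_dependent_kmet(ms, 0) else sol[[nm]]$k_convert
    }, 0)
  }, numeric(L))                             # L x S

  y0 <- numeric(ny)
  y0[d_idx[match(model$prodrug, order[sdx])]] <- donor_bolus

  rhs <- function(t, y, p) {
    dy <- numeric(ny)
    for (si in seq_along(sdx)) {
      s <- sdx[si]
      nm <- order[s]
      sp <- sol[[nm]]
      Cd <- y[d_idx[si]]; Cr <- y[r_idx[si]]
      Ce <- y[ce_idx[, s]]
      lam <- sp$D_tissue / dz^2
      d <- numeric(M)
      if (M > 1) {
        d[1] <- lam * (Ce[2] - Ce[1])
        d[M] <- lam * (Ce[M - 1] - Ce[M])
        if (M > 2) {
          i <- 2:(M - 1)
          d[i] <- lam * (Ce[i - 1] - 2 * Ce[i] + Ce[i + 1])
        }
      }
      # stirred-compartment interfaces through a half node
      jin <- sp$D_tissue * A * (Cd - Ce[1]) / (dz / 2)   # um^3 uM / s
      jout <- sp$D_tissue * A * (Ce[M] - Cr) / (dz / 2)
      d[1] <- d[1] + jin / Ve
      d[M] <- d[M] - jout / Ve
      if (!acellular) {
        for (l in 1:2) {
          if (fr[l] == 0) next
          Cil <- y[ci_idx[, l, s]]
          ex <- sp$K_in * Ce - sp$K_out * Cil
          d <- d - ex * (Vi_l[l] / Ve)
          parent <- .parent_of(sol, nm)
          src <- if (!is.null(parent))
            conv_l[l, match(parent, order)] * y[ci_idx[, l, match(parent, order)]]
          else 0
          dy[ci_idx[, l, s]] <- ex - (conv_l[l, s] + sp$k_loss_cell) * Cil + src
        }
      }
      dy[ce_idx[, s]] <- d - sp$k_decay_medium * Ce
      dy[d_idx[si]] <- -jin / Vd - sp$k_decay_medium * Cd
      dy[r_idx[si]] <- jout / Vr - sp$k_decay_medium * Cr
    }
    # non-diffusing chain members live only inside cells
    if (!acellular) {
      for (s in which(!diff_s)) {
        nm <- order[s]; sp <- sol[[nm]]
        parent <- .parent_of(sol, nm)
        for (l in 1:2) {
          if (fr[l] == 0) next
          Cil <- y[ci_idx[, l, s]]
          src <- if (!is.null(parent))
            conv_l[l, match(parent, order)] * y[ci_idx[, l, match(parent, order)]]
          else 0
          dy[ci_idx[, l, s]] <- -(conv_l[l, s] + sp$k_loss_cell) * Cil + src
        }
      }
    }
    list(dy)
  }

  tt <- times %||% seq(0, duration, length.out = 13)
  out <- deSolve::lsoda(y0, tt, rhs, parms = NULL, rtol = rtol, atol = atol)

  umol <- function(C_uM, V_um3) C_uM * V_um3 * 1e-15 * 1e-3  # uM um^3 -> umol
  rows <- list()
  for (si in seq_along(sdx)) {
    nm <- order[sdx[si]]
    rows[[length(rows) + 1L]] <- data.frame(
      t_s = out[, 1], compartment = "donor", solute = nm,
      concentration_uM = out[, 1 + d_idx[si]],
      amount_umol = umol(out[, 1 + d_idx[si]], Vd))
    rows[[length(rows) + 1L]] <- data.frame(
      t_s = out[, 1], compartment = "receiver", solute = nm,
      concentration_uM = out[, 1 + r_idx[si]],
      amount_umol = umol(out[, 1 + r_idx[si]], Vr))
  }
  tc <- do.call(rbind, rows)
  p_si <- match(model$prodrug, order[sdx])
  recv <- out[, 1 + r_idx[p_si]]
  recv_norm <- data.frame(t_s = out[, 1],
                          C_over_C0 = if (donor_bolus > 0)
                            recv / donor_bolus else recv * 0)
  # tracked terminal metabolite pool(s): every diffusible non-prodrug
  met_s <- setdiff(order[sdx], model$prodrug)
  met_amt <- rep(0, nrow(out))
  for (nm in met_s) {
    si <- match(nm, order[sdx])
    met_amt <- met_amt + umol(out[, 1 + d_idx[si]], Vd) +
      umol(out[, 1 + r_idx[si]], Vr)
  }
  auc <- sum(diff(out[, 1]) * (head(recv, -1) + tail(recv, -1)) / 2)
  list(timecourse = tc,
       receiver_norm = recv_norm,
       metabolite_umol = data.frame(t_s = out[, 1], umol = met_amt),
       receiver_auc = auc,
       slab_state = out[nrow(out), -1])
}
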