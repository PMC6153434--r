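#' Simulate a monolayer drug exposure (1D depth model)
#'
#' Concentrations in a monolayer culture depend only on depth: the
#' medium column is discretized into `n_nodes` axial nodes and the cell
#' layer sits in the bottom node, giving a Method-of-Lines ODE system
#' (diffusion, membrane exchange, intracellular metabolism chain, medium
#' decay, Michaelis-Menten O2 consumption) solved with an adaptive
#' stiff/non-stiff integrator ([deSolve::lsoda()]). Several lineages can
#' share the well (co-culture); the wet protocol's single-line wells are
#' the `fractions = 1` special case.
#'
#' @param model `hap_prodrug_model`.
#' @param lines list of [cell_line_spec()] present in the well.
#' @param fractions numeric, same length as `lines`: fraction of
#'   `n_cells` belonging to each line.
#' @param concentration prodrug bolus (uM), uniform at t = 0.
#' @param duration exposure (s).
#' @param o2_bolus dissolved O2 introduced with the drug (uM).
#' @param gas_O2 O2 held at the medium-air interface (uM); 0 in the
#'   anoxic chamber.
#' @param n_cells cells in the well.
#' @param volume_mL medium volume (mL).
#' @param area_mm2 well cross-section (mm^2).
#' @param cell_volume cell volume (um^3).
#' @param n_nodes axial nodes.
#' @param rtol,atol solver tolerances.
#' @param times optional output times (s); default start/end.
#' @return list with `SF` (named per line), `hazard` (lines x kill
#'   models), `kill_labels`, `timecourse` (data.frame: t_s, bottom/top
#'   medium prodrug, bottom O2, per-line intracellular prodrug),
#'   `depth_profile` (final extracellular concentrations vs depth).
#' @export
simulate_monolayer <- function(model, lines, fractions = 1,
                               concentration, duration = 3600,
                               o2_bolus = 0, gas_O2 = 0,
                               n_cells = 1e5, volume_mL = 0.15,
                               area_mm2 = 32.8, cell_volume = 2500,
                               n_nodes = 20, rtol = 1e-7, atol = 1e-9,
                               times = NULL) {
  stopifnot(duration > 0, concentration >= 0)
  L <- length(lines)
  fractions <- rep_len(fractions, L)
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  sol <- model$solutes
  order <- validate_chain(sol)
  S <- length(order)
  diff_s <- vapply(sol[order], `[[`, TRUE, "diffusible")
  kills <- model$kill_models
  K <- length(kills)
  if (n_cells <= 0 && any(vapply(kills, `[[`, "", "mode") ==
                            "metabolism_rate")) {
    warning("zero cell density with a metabolism-rate kill model: ",
            "no killing possible")
  }

  A <- area_mm2 * 1e6                      # um^2
  depth <- volume_mL * 1e12 / A            # um
  N <- n_nodes
  dz <- depth / N
  node_vol <- A * dz
  Vl <- n_cells * fractions * cell_volume  # intracellular volume per line
  Ve1 <- node_vol - sum(Vl)
  stopifnot(Ve1 > 0)
  o2_on <- o2_bolus > 0 || gas_O2 > 0
  reg <- model$registry
  o2p <- list(Vmax = registry_get(reg, "O2_Vmax") * 1e21,
              Km = registry_get(reg, "O2_Km"),
              D = registry_get(reg, "O2_D_medium"))

  # per-line, per-solute conversion at a given O2 (prodrug: enzymatic)
  conv_fun <- function(nm, O2) {
    vapply(seq_len(L), function(l) {
      ms <- lines[[l]]$metabolism[[nm]]
      if (!is.null(ms)) oxygen_dependent_kmet(ms, O2)
      else sol[[nm]]$k_convert
    }, 0)
  }

  nCe <- N * sum(diff_s)
  ce_idx <- matrix(0L, N, S)
  ce_idx[, diff_s] <- seq_len(nCe)
  ci_idx <- matrix(seq_len(L * S), L, S) + nCe
  hz_idx <- matrix(seq_len(L * K), L, K) + nCe + L * S
  o2_idx <- if (o2_on) seq_len(N) + nCe + L * S + L * K else integer(0)
  ny <- nCe + L * S + L * K + length(o2_idx)

  y0 <- numeric(ny)
  for (s in which(diff_s)) y0[ce_idx[, s]] <- concentration *
    (order[s] == model$prodrug)
  if (o2_on) y0[o2_idx] <- o2_bolus

  lap1d <- function(C, D) {
    # no-flux ends unless overridden by the caller
    d <- numeric(length(C))
    d[1] <- D * (C[2] - C[1]) / dz^2
    d[N] <- D * (C[N - 1] - C[N]) / dz^2
    if (N > 2) {
      i <- 2:(N - 1)
      d[i] <- D * (C[i - 1] - 2 * C[i] + C[i + 1]) / dz^2
    }
    d
  }

  rhs <- function(t, y, p) {
    dy <- numeric(ny)
    O2_1 <- if (o2_on) max(y[o2_idx[1]], 0) else 0
    Ci <- matrix(y[ci_idx], L, S)
    for (s in seq_len(S)) {
      nm <- order[s]
      sp <- sol[[nm]]
      conv <- conv_fun(nm, O2_1)
      parent <- .parent_of(sol, nm)
      src <- if (!is.null(parent)) {
        p_ix <- match(parent, order)
        conv_fun(parent, O2_1) * Ci[, p_ix]
      } else rep(0, L)
      if (diff_s[s]) {
        Ce <- y[ce_idx[, s]]
        d <- lap1d(Ce, sp$D_medium) - sp$k_decay_medium * Ce
        ex <- sp$K_in * Ce[1] - sp$K_out * Ci[, s]   # per line, uM/s
        d[1] <- d[1] - sum(Vl * ex) / Ve1
        dy[ce_idx[, s]] <- d
        dy[ci_idx[, s]] <- ex - (conv + sp$k_loss_cell) * Ci[, s] + src
      } else {
        dy[ci_idx[, s]] <- -(conv + sp$k_loss_cell) * Ci[, s] + src
      }
    }
    for (k in seq_len(K)) {
      km <- kills[[k]]
      s <- match(km$acts_on, order)
      if (km$mode == "concentration") {
        dy[hz_idx[, k]] <- km$K_c * Ci[, s]
      } else {
        dy[hz_idx[, k]] <- km$K_c * conv_fun(km$acts_on, O2_1) * Ci[, s]
      }
    }
    if (o2_on) {
      Co2 <- pmax(y[o2_idx], 0)
      d <- lap1d(Co2, o2p$D)
      cons <- sum(n_cells * fractions *
                    michaelis_menten_O2_rate(Co2[1], o2p$Vmax, o2p$Km))
      d[1] <- d[1] - cons / Ve1
      # half-cell exchange with the gas phase at the top
      d[N] <- d[N] + o2p$D * (gas_O2 - Co2[N]) / (dz * dz / 2)
      dy[o2_idx] <- d
    }
    list(dy)
  }

  tt <- times %||% seq(0, duration, length.out = 25)
  out <- deSolve::lsoda(y0, tt, rhs, parms = NULL, rtol = rtol, atol = atol)
  yT <- out[nrow(out), -1]
  haz <- matrix(yT[hz_idx], L, K)
  SF <- exp(-rowSums(haz))
  names(SF) <- vapply(lines, `[[`, "", "name")
  p_ix <- match(model$prodrug, order)
  tc <- data.frame(
    t_s = out[, 1],
    bottom_uM = out[, 1 + ce_idx[1, p_ix]],
    top_uM = out[, 1 + ce_idx[N, p_ix]],
    o2_bottom_uM = if (o2_on) out[, 1 + o2_idx[1]] else 0)
  for (l in seq_len(L)) {
    tc[[paste0("Ci_", names(SF)[l])]] <- out[, 1 + ci_idx[l, p_ix]]
  }
  depth_profile <- data.frame(
    depth_um = (seq_len(N) - 0.5) * dz,
    prodrug_uM = yT[ce_idx[, p_ix]])
  list(SF = SF, hazard = haz,
       kill_labels = vapply(kills, `[[`, "", "label"),
       timecourse = tc, depth_profile = depth_profile)
}
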