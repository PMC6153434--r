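#' Membrane exchange rates
#'
#' First-order trans-membrane flux: `dC_i/dt = K_in C_e - K_out C_i`,
#' with the extracellular compartment losing the same moles,
#' `dC_e/dt = -(dC_i/dt) / vol_ratio`. At steady state
#' `C_i / C_e = K_in / K_out` (lipophilic partitioning when > 1).
#'
#' @param C_e,C_i extracellular / intracellular concentrations (uM).
#' @param K_in,K_out uptake/efflux rate constants (1/s), >= 0.
#' @param vol_ratio extracellular : intracellular volume ratio of the
#'   site, > 0.
#' @return list with `dCi_dt` and `dCe_dt` (uM/s).
#' @export
membrane_exchange <- function(C_e, C_i, K_in, K_out, vol_ratio) {
  if (any(K_in < 0) || any(K_out < 0)) stop("rates must be >= 0",
                                            call. = FALSE)
  if (any(vol_ratio <= 0)) stop("vol_ratio must be > 0", call. = FALSE)
  dCi <- K_in * C_e - K_out * C_i
  list(dCi_dt = dCi, dCe_dt = -dCi / vol_ratio)
}

# Symmetric mole-flux matrix G (entries um^3/s): row i of G %*% Ce is the
# net diffusive mole inflow (uM um^3/s) into site i. Face conductance
# D_f * dx with D_f = D_tissue (both sites occupied), D_medium (both
# vacant) or the harmonic mean at the interface. Rows sum to zero.
.flux_matrix <- function(grid, D_medium, D_tissue) {
  occ <- grid$occupancy > 0L
  dx <- grid$dx
  ii <- integer(0); jj <- integer(0)
  for (ax in c(2L, 4L, 6L)) {          # +x, +y, +z faces once each
    nb <- grid$nbr[, ax]
    keep <- !is.na(nb)
    ii <- c(ii, which(keep)); jj <- c(jj, nb[keep])
  }
  both_occ <- occ[ii] & occ[jj]
  none_occ <- !occ[ii] & !occ[jj]
  Df <- numeric(length(ii))
  Df[both_occ] <- D_tissue
  Df[none_occ] <- D_medium
  mixed <- !both_occ & !none_occ
  Df[mixed] <- if (D_tissue + D_medium > 0)
    2 * D_tissue * D_medium / (D_tissue + D_medium) else 0
  w <- Df * dx
  G <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = rep(w, 2),
                            dims = c(grid$n_sites, grid$n_sites))
  G - Matrix::Diagonal(grid$n_sites, Matrix::rowSums(G))
}

# conductance (um^3/s) of each boundary site to the surrounding bath:
# exposed outer faces times D_medium * dx
.bath_conductance <- function(grid, D_medium) {
  n_outer <- rowSums(is.na(grid$nbr))
  n_outer * D_medium * grid$dx
}

# ---------------------------------------------------------------------
# Fine-grid transport context: per-solute theta-scheme with algebraic
# elimination of the intracellular compartments (Schur complement), so
# each step per diffusible solute is one SPD sparse triangular solve.
# ---------------------------------------------------------------------

# grid: hap_grid with occupancy set; cells: population (site, line, ...)
# model: hap_prodrug_model; lines: list(activator, target) cell lines
# O2: per-site oxygen field (uM) fixing the prodrug K_met values
.make_transport_ctx <- function(grid, model, lines = NULL, O2 = 0,
                                theta = 0.5, dt = 2) {
  ctx <- new.env(parent = emptyenv())
  ctx$grid <- grid
  ctx$theta <- theta; ctx$dt <- dt
  ctx$order <- validate_chain(model$solutes)
  ctx$model <- model
  ctx$lines <- lines
  occ_sites <- which(grid$occupancy > 0L)
  ctx$cell_sites <- occ_sites                     # site of cell row c
  ctx$cell_rows <- grid$occupancy[occ_sites]      # population row ids
  ctx$n_cells <- length(occ_sites)
  V <- grid$site_volume
  ctx$Vi <- V / 2
  ctx$Ve <- ifelse(grid$occupancy > 0L, V / 2, V)
  ctx$line_of <- integer(ctx$n_cells)             # filled by caller
  ctx$G <- list(); ctx$gb <- list()
  ctx$fac <- list(); ctx$coef <- list()
  ctx$Ce <- list(); ctx$Ci <- list()
  ctx$clip_events <- 0L; ctx$n_steps <- 0L
  for (nm in ctx$order) {
    s <- model$solutes[[nm]]
    if (s$diffusible) {
      key <- paste(s$D_medium, s$D_tissue)
      if (is.null(ctx$G[[key]])) {
        ctx$G[[key]] <- .flux_matrix(grid, s$D_medium, s$D_tissue)
        ctx$gb[[key]] <- .bath_conductance(grid, s$D_medium)
      }
    }
    ctx$Ce[[nm]] <- numeric(grid$n_sites)
    ctx$Ci[[nm]] <- numeric(ctx$n_cells)
  }
  ctx$O2_cell <- rep_len(0, ctx$n_cells)
  ctx$hazard <- matrix(0, ctx$n_cells, length(model$kill_models))
  ctx$bath_influx <- setNames(numeric(length(ctx$order)), ctx$order)
  ctx
}

# conversion rate constant (1/s) of solute `nm` into its child, per cell
.cell_conversion <- function(ctx, nm) {
  s <- ctx$model$solutes[[nm]]
  if (ctx$n_cells == 0L) return(numeric(0))
  # enzymatic (cell-line and O2 dependent) if any line has a spec
  enz <- any(vapply(ctx$lines, function(l) !is.null(l$metabolism[[nm]]),
                    TRUE))
  if (enz) {
    k <- numeric(ctx$n_cells)
    for (li in seq_along(ctx$lines)) {
      sel <- ctx$line_of == li
      if (any(sel)) k[sel] <- .line_kmet(ctx$lines[[li]], nm,
                                         ctx$O2_cell[sel])
    }
    k
  } else rep_len(s$k_convert, ctx$n_cells)
}

# (re)build the factorization and step coefficients for one solute
.prepare_solute <- function(ctx, nm) {
  s <- ctx$model$solutes[[nm]]
  th <- ctx$theta; dt <- ctx$dt
  conv <- .cell_conversion(ctx, nm)
  a <- s$K_out + conv + s$k_loss_cell
  denom <- 1 + th * dt * a
  coef <- list(
    conv = conv, a = a,
    alpha = (1 - (1 - th) * dt * a) / denom,
    beta = dt * s$K_in / denom,
    gamma = dt / denom)
  if (s$diffusible) {
    key <- paste(s$D_medium, s$D_tissue)
    G <- ctx$G[[key]]; gb <- ctx$gb[[key]]
    Vi <- ctx$Vi; Ve <- ctx$Ve
    m <- Ve * (1 + th * dt * s$k_decay_medium) + th * dt * gb
    # beta already carries one power of dt
    exch <- Vi * (th * dt * s$K_in - th^2 * dt * s$K_out * coef$beta)
    m[ctx$cell_sites] <- m[ctx$cell_sites] + exch
    M <- Matrix::Diagonal(ctx$grid$n_sites, m) - th * dt * G
    ctx$fac[[nm]] <- Matrix::Cholesky(Matrix::forceSymmetric(M),
                                      LDL = FALSE, perm = TRUE, super = TRUE)
    coef$G <- G; coef$gb <- gb
  }
  ctx$coef[[nm]] <- coef
  invisible(ctx)
}

.prepare_all <- function(ctx) {
  for (nm in ctx$order) .prepare_solute(ctx, nm)
  invisible(ctx)
}

# advance every solute by one theta step; C_bath: named bath
# concentrations (uM). Accumulates kill hazards and bath flux bookkeeping.
.step_once <- function(ctx, C_bath) {
  th <- ctx$theta; dt <- ctx$dt
  Vi <- ctx$Vi; Ve <- ctx$Ve
  cs <- ctx$cell_sites
  avg_Ci <- list()   # theta-averaged intracellular concentrations
  for (nm in ctx$order) {
    s <- ctx$model$solutes[[nm]]
    co <- ctx$coef[[nm]]
    Ce <- ctx$Ce[[nm]]; Ci <- ctx$Ci[[nm]]
    parent <- .parent_of(ctx$model$solutes, nm)
    shat <- if (!is.null(parent))
      ctx$coef[[parent]]$conv * avg_Ci[[parent]] else 0
    if (s$diffusible) {
      cb <- C_bath[[nm]] %||% 0
      r <- (Ve - (1 - th) * dt * (co$gb + Ve * s$k_decay_medium)) * Ce +
        (1 - th) * dt * as.numeric(co$G %*% Ce) + dt * co$gb * cb
      if (ctx$n_cells > 0L) {
        contrib <- -(1 - th) * dt * Vi * s$K_in * Ce[cs] +
          dt * Vi * s$K_out * ((th * co$alpha + 1 - th) * Ci +
                                 th * co$beta * (1 - th) * Ce[cs] +
                                 th * co$gamma * shat)
        r[cs] <- r[cs] + contrib
      }
      Ce_new <- as.numeric(Matrix::solve(ctx$fac[[nm]], r))
      if (ctx$n_cells > 0L) {
        Ci_new <- co$alpha * Ci +
          co$beta * (th * Ce_new[cs] + (1 - th) * Ce[cs]) +
          co$gamma * shat
      } else Ci_new <- Ci
      # bath bookkeeping: moles entering the grid across the boundary
      ctx$bath_influx[[nm]] <- ctx$bath_influx[[nm]] +
        dt * sum(co$gb * (cb - (th * Ce_new + (1 - th) * Ce)))
      neg <- Ce_new < 0
      if (any(neg)) {
        ctx$clip_events <- ctx$clip_events + sum(Ce_new < -1e-12)
        Ce_new[neg] <- 0
      }
      neg <- Ci_new < 0
      if (any(neg)) {
        ctx$clip_events <- ctx$clip_events + sum(Ci_new < -1e-12)
        Ci_new[neg] <- 0
      }
      ctx$Ce[[nm]] <- Ce_new
    } else {
      # confined to the cell of origin: intracellular ODE only
      Ci_new <- co$alpha * Ci + co$gamma * shat
      Ci_new[Ci_new < 0] <- 0
    }
    avg_Ci[[nm]] <- th * Ci_new + (1 - th) * Ci
    ctx$Ci[[nm]] <- Ci_new
  }
  # kill hazards (exact trapezoidal hazard integral over the step)
  for (k in seq_along(ctx$model$kill_models)) {
    km <- ctx$model$kill_models[[k]]
    if (km$mode == "concentration") {
      ctx$hazard[, k] <- ctx$hazard[, k] + km$K_c * dt * avg_Ci[[km$acts_on]]
    } else {
      ctx$hazard[, k] <- ctx$hazard[, k] +
        km$K_c * dt * ctx$coef[[km$acts_on]]$conv * avg_Ci[[km$acts_on]]
    }
  }
  ctx$n_steps <- ctx$n_steps + 1L
  invisible(ctx)
}

# total amount (uM um^3) of one solute on the fine grid
.grid_amount <- function(ctx, nm) {
  amt <- sum(ctx$Ve * ctx$Ce[[nm]])
  if (ctx$n_cells > 0L) amt <- amt + sum(ctx$Vi * ctx$Ci[[nm]])
  amt
}

#' Advance a fine-grid transport state
#'
#' Low-level Method-of-Lines integrator for the 3D lattice: diffusion on
#' the extracellular field (6-point stencil, `D_tissue` inside the
#' occupied hull, `D_medium` outside), membrane exchange, intracellular
#' metabolism chain and medium decay, advanced with a one-step
#' theta-scheme (Crank-Nicolson by default) in which the whole linear
#' transport operator is treated as a single right-hand side. Vacant
#' sites carry only the extracellular equation. Intended for transport
#' verification and as the kernel of [simulate_spheroid_exposure()].
#'
#' @param grid `hap_grid` with occupancy set (all-vacant is allowed).
#' @param model `hap_prodrug_model` (or any list with `solutes` and
#'   `kill_models`).
#' @param lines cell-line pair (see [model_cell_lines()]); needed only
#'   when occupied sites metabolize.
#' @param line_of integer vector: line index (into `lines`) of each
#'   occupied site, in `which(grid$occupancy > 0)` order.
#' @param init named list of initial extracellular fields (per solute,
#'   scalar or length `n_sites`).
#' @param C_bath named bath concentrations at the grid boundary (uM).
#' @param O2 per-site oxygen (uM), scalar or vector.
#' @param duration simulated time (s).
#' @param dt step (s).
#' @param theta implicitness (0.5 = Crank-Nicolson).
#' @param closed seal the grid boundary (no bath exchange); used for
#'   conservation checks.
#' @return list with `Ce`, `Ci` (named lists), `hazard` (cells x kill
#'   models), `amounts` (named, uM um^3 on the grid), `bath_influx`
#'   (moles entered from the bath, uM um^3), `clip_events`.
#' @export
step_fine_grid <- function(grid, model, lines = NULL, line_of = NULL,
                           init = list(), C_bath = list(), O2 = 0,
                           duration, dt = 2, theta = 0.5, closed = FALSE) {
  stopifnot(duration > 0, dt > 0)
  ctx <- .make_transport_ctx(grid, model, lines, theta = theta, dt = dt)
  if (closed) for (key in names(ctx$gb)) ctx$gb[[key]][] <- 0
  if (ctx$n_cells > 0L) {
    if (is.null(line_of)) stop("line_of required when sites are occupied",
                               call. = FALSE)
    ctx$line_of <- line_of
    ctx$O2_cell <- rep_len(O2, ctx$n_cells)
  }
  for (nm in names(init)) ctx$Ce[[nm]] <- rep_len(init[[nm]], grid$n_sites)
  .prepare_all(ctx)
  n <- max(1L, round(duration / dt))
  for (i in seq_len(n)) .step_once(ctx, C_bath)
  amounts <- vapply(ctx$order, function(nm) .grid_amount(ctx, nm), 0)
  list(Ce = ctx$Ce, Ci = ctx$Ci, hazard = ctx$hazard, amounts = amounts,
       bath_influx = ctx$bath_influx, clip_events = ctx$clip_events,
       n_steps = ctx$n_steps)
}

# ---------------------------------------------------------------------
# Quasi-steady oxygen field: Newton iteration on the steady
# reaction-diffusion balance G C - q(C) - gb (C - C_bath) = 0 with
# Michaelis-Menten consumption q at occupied sites. Oxygen is treated as
# a single well-equilibrated compartment per site (no membrane barrier).
# ---------------------------------------------------------------------

# solve the quasi-steady O2 field on the subdomain within `margin`
# shells of the occupied hull (the medium depletion boundary layer
# around a consuming spheroid needs ~8 shells to converge); outside it
# the field is taken at the bath value
.solve_o2_field <- function(grid, o2p, C_bath, C0 = NULL, margin = 8) {
  occ <- grid$occupancy > 0L
  if (!any(occ) || C_bath <= 0) return(rep(max(C_bath, 0), grid$n_sites))
  r_hull <- max(grid$r[occ])
  active <- grid$r <= r_hull + margin * grid$dx & !grid$boundary
  idx <- which(active)
  map <- integer(grid$n_sites); map[idx] <- seq_along(idx)
  dx <- grid$dx
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  gb_a <- numeric(length(idx))
  for (ax in 1:6) {
    nb <- grid$nbr[idx, ax]
    in_sub <- !is.na(nb) & active[nb]
    w <- numeric(length(idx))
    both_occ <- in_sub & occ[idx] & occ[nb]
    # tissue/medium face diffusivities as in .flux_matrix
    Dm <- o2p$Dm; Dt <- o2p$Dt
    Dh <- 2 * Dt * Dm / (Dt + Dm)
    w[in_sub] <- ifelse(occ[idx[in_sub]] & occ[nb[in_sub]], Dt,
                        ifelse(!occ[idx[in_sub]] & !occ[nb[in_sub]], Dm, Dh))
    ii <- c(ii, which(in_sub)); jj <- c(jj, map[nb[in_sub]])
    xx <- c(xx, w[in_sub] * dx)
    ext <- !in_sub            # face to outside-subdomain (bath) or grid edge
    gb_a[ext] <- gb_a[ext] + Dm * dx
  }
  n_a <- length(idx)
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_a, n_a))
  G <- G - Matrix::Diagonal(n_a, Matrix::rowSums(G))
  vmax <- ifelse(occ[idx], o2p$Vmax, 0)
  C <- if (is.null(C0)) rep(C_bath, n_a) else pmax(C0[idx], 0)
  scale <- max(C_bath, 1e-6)
  for (it in 1:40) {
    q <- vmax * C / (o2p$Km + C)
    F <- as.numeric(G %*% C) - q - gb_a * (C - C_bath)
    if (max(abs(F)) < 1e-9 * max(sum(gb_a) * scale, 1)) break
    qp <- vmax * o2p$Km / (o2p$Km + C)^2
    J <- Matrix::Diagonal(n_a, qp + gb_a) - G
    Ch <- Matrix::Cholesky(Matrix::forceSymmetric(J), LDL = FALSE,
                           perm = TRUE, super = TRUE)
    dC <- as.numeric(Matrix::solve(Ch, F))
    C_new <- C + dC
    neg <- C_new < 0
    if (any(neg)) C_new[neg] <- C[neg] / 2
    if (max(abs(C_new - C)) < 1e-10 * scale) { C <- C_new; break }
    C <- C_new
  }
  out <- rep(C_bath, grid$n_sites)
  out[idx] <- C
  out
}
#' Steady-state spherical diffusion-consumption profile on the lattice
#'
#' Solves the steady reaction-diffusion balance for a sphere of radius
#' `R` with uniform first-order consumption `k = D / lambda^2` inside
#' and the boundary held at `C_R`, on the cubic lattice. The continuum
#' solution is `C(r)/C_R = (R/r) sinh(r/lambda) / sinh(R/lambda)` with
#' center ratio `(R/lambda) / sinh(R/lambda)`.
#'
#' @param R sphere radius (um).
#' @param lambda penetration depth `sqrt(D/k)` (um).
#' @param D diffusivity (um^2/s).
#' @param mean_cell_volume cell volume fixing the lattice spacing
#'   (um^3); `dx = (2 * mean_cell_volume)^(1/3)`.
#' @param dx optional explicit lattice spacing (um), overriding
#'   `mean_cell_volume`.
#' @return data.frame with `r` (um), `ratio` (simulated `C/C_R`) and
#'   `analytic` for every lattice site inside the sphere.
#' @export
steady_state_sphere <- function(R, lambda, D = 100,
                                mean_cell_volume = 2500, dx = NULL) {
  stopifnot(R > 0, lambda > 0, D > 0)
  if (!is.null(dx)) mean_cell_volume <- dx^3 / 2
  grid <- build_lattice(mean_cell_volume, R)
  k <- D / lambda^2
  dxg <- grid$dx
  inside <- grid$r <= R & !grid$boundary
  V <- grid$site_volume
  idx_in <- which(inside)
  map <- integer(grid$n_sites); map[idx_in] <- seq_along(idx_in)
  # assemble the interior operator; the boundary value C_R is applied on
  # the faces separating inside from outside sites (half-cell Dirichlet),
  # putting the effective surface at the sphere radius
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_add <- numeric(length(idx_in)); b <- numeric(length(idx_in))
  w <- D * dxg
  for (ax in 1:6) {
    nb <- grid$nbr[idx_in, ax]
    nb_in <- !is.na(nb) & inside[nb]
    ii <- c(ii, which(nb_in)); jj <- c(jj, map[nb[nb_in]])
    xx <- c(xx, rep(w, sum(nb_in)))
    diag_add[nb_in] <- diag_add[nb_in] + w
    out_face <- is.na(nb) | !inside[nb]
    diag_add[out_face] <- diag_add[out_face] + 2 * w
    b[out_face] <- b[out_face] + 2 * w      # times C_R = 1
  }
  Gi <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                             dims = rep(length(idx_in), 2))
  A <- Matrix::Diagonal(length(idx_in), diag_add + k * V) - Gi
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE,
                         perm = TRUE, super = TRUE)
  Cin <- as.numeric(Matrix::solve(Ch, b))
  r <- grid$r[idx_in]
  analytic <- ifelse(r < 1e-9, (R / lambda) / sinh(R / lambda),
                     (R / r) * sinh(r / lambda) / sinh(R / lambda))
  out <- data.frame(r = r, ratio = Cin, analytic = analytic)
  out <- out[order(out$r), ]
  # radial profile: shell means over sites of equal radius (sites in one
  # shell differ only by lattice stair-casing, the continuum profile is
  # a function of r alone)
  key <- round(out$r, 6)
  prof <- data.frame(
    r = tapply(out$r, key, mean),
    ratio = tapply(out$ratio, key, mean),
    analytic = tapply(out$analytic, key, mean))
  rownames(prof) <- NULL
  attr(out, "profile") <- prof
  out
}

# ---------------------------------------------------------------------
# 1D unstirred medium column (Crank-Nicolson, dense tridiagonal solve).
# Node 1 is the bottom (bath around the fine grid); node N the
# medium-air interface where a gas-phase boundary condition may apply.
# ---------------------------------------------------------------------
.step_column <- function(C, D, dz, dt, gas_value = NULL, sink_bottom = 0,
                         node_volume, area) {
  N <- length(C)
  lam <- D * area / dz                    # face conductance, um^3/s
  lo <- rep(lam, N - 1)
  dg <- numeric(N)
  dg[1] <- lam; dg[N] <- lam; if (N > 2) dg[2:(N - 1)] <- 2 * lam
  if (!is.null(gas_value)) dg[N] <- dg[N] + 2 * lam  # half-cell to interface
  A <- diag(node_volume / dt + 0.5 * dg, N)
  for (i in seq_len(N - 1)) {
    A[i, i + 1] <- -0.5 * lam
    A[i + 1, i] <- -0.5 * lam
  }
  GC <- numeric(N)                        # explicit half of the operator
  GC[1] <- lam * (C[2] - C[1])
  GC[N] <- lam * (C[N - 1] - C[N])
  if (N > 2) {
    idx <- 2:(N - 1)
    GC[idx] <- lam * (C[idx - 1] - 2 * C[idx] + C[idx + 1])
  }
  b <- node_volume * C / dt + 0.5 * GC
  b[1] <- b[1] - sink_bottom
  if (!is.null(gas_value)) {
    Gtop <- 2 * lam * (gas_value - C[N])
    b[N] <- b[N] + 0.5 * Gtop + 0.5 * 2 * lam * gas_value
  }
  out <- solve(A, b)
  pmax(out, 0)
}
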