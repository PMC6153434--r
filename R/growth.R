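#' Growth-model parameters
#'
#' @param mean_cell_volume mean cell volume (um^3); birth volume is
#'   `mean_cell_volume * log(2)` so the time-average volume of an
#'   exponentially growing cell equals the mean, and the division
#'   trigger is twice the birth volume.
#' @param O2_half_sat oxygen half-saturation of the growth-rate scaling
#'   (uM); local growth rate is scaled by `O2 / (O2 + O2_half_sat)`.
#' @param hypoxia_threshold reporting threshold for hypoxia (uM).
#' @param severe_hypoxia_threshold O2 below which the death clock runs
#'   (uM); must be below `hypoxia_threshold`.
#' @param death_tag_delay continuous severe hypoxia (h) after which a
#'   cell is tagged for death.
#' @param lysis_delay time (h) from death tagging to necrosis (site
#'   reverts to vacant).
#' @param hypoxic_death disable to grow without hypoxia-driven death
#'   (used by the spatial-heterogeneity experiment).
#' @return object of class `hap_growth_params`.
#' @export
growth_params <- function(mean_cell_volume = 2500, O2_half_sat = 1,
                          hypoxia_threshold = 4,
                          severe_hypoxia_threshold = 0.15,
                          death_tag_delay = 24, lysis_delay = 24,
                          hypoxic_death = TRUE) {
  stopifnot(severe_hypoxia_threshold < hypoxia_threshold,
            death_tag_delay >= 0, lysis_delay >= 0)
  birth <- mean_cell_volume * log(2)
  structure(list(mean_cell_volume = mean_cell_volume,
                 birth_volume = birth, divide_volume = 2 * birth,
                 O2_half_sat = O2_half_sat,
                 hypoxia_threshold = hypoxia_threshold,
                 severe_hypoxia_threshold = severe_hypoxia_threshold,
                 death_tag_delay = death_tag_delay,
                 lysis_delay = lysis_delay, hypoxic_death = hypoxic_death),
            class = "hap_growth_params")
}

# cell population: parallel vectors; state 0 = viable, 1 = death-tagged
.new_cells <- function(sites, line, volume) {
  n <- length(sites)
  list(site = as.integer(sites), line = as.integer(rep_len(line, n)),
       volume = rep_len(volume, n), state = integer(n),
       hypoxia_h = numeric(n), tagged_h = numeric(n),
       log_survival = numeric(n), n_necrotic = c(0L, 0L))
}

#' Seed a compact spheroid on the lattice
#'
#' Places `n_cells` in the most central lattice sites and assigns each
#' independently to the activator lineage with probability
#' `activator_fraction` (seeded Bernoulli draws).
#'
#' @param n_cells number of cells to seed (>= 1).
#' @param activator_fraction probability a seeded cell is an activator.
#' @param lines list with `activator` and `target` [cell_line_spec()]s.
#' @param seed RNG seed.
#' @param grid optional pre-built [build_lattice()] grid; by default a
#'   grid is sized generously for the seeded population.
#' @param max_radius grid radius (um) when `grid` is not supplied.
#' @param mean_cell_volume cell volume for a default grid (um^3).
#' @return a spheroid state: list with `grid`, `cells`, `lines`.
#' @export
seed_spheroid <- function(n_cells, activator_fraction, lines, seed = 1L,
                          grid = NULL, max_radius = NULL,
                          mean_cell_volume = 2500) {
  stopifnot(n_cells >= 1, activator_fraction >= 0, activator_fraction <= 1)
  if (is.null(grid)) {
    if (is.null(max_radius)) {
      # radius holding the seeded sphere with ample room
      max_radius <- 2 * (3 * n_cells * 2 * mean_cell_volume /
                           (4 * pi))^(1 / 3) + 4 * (2 * mean_cell_volume)^(1 / 3)
    }
    grid <- build_lattice(mean_cell_volume, max_radius)
  }
  open <- which(!grid$boundary)
  if (n_cells > length(open)) stop("n_cells exceeds grid capacity",
                                   call. = FALSE)
  sites <- open[order(grid$r[open])][seq_len(n_cells)]
  line <- with_seed(seed, ifelse(stats::runif(n_cells) < activator_fraction,
                                 1L, 2L))
  bp <- growth_params(mean_cell_volume = grid$mean_cell_volume)
  cells <- .new_cells(sites, line, bp$birth_volume)
  # randomize birth volumes so seeded cells are desynchronized
  cells$volume <- with_seed(seed + 1L,
    bp$birth_volume * 2^stats::runif(n_cells))
  grid$occupancy[sites] <- seq_len(n_cells)
  structure(list(grid = grid, cells = cells, lines = lines),
            class = "hap_spheroid")
}

#' One growth step
#'
#' Advances every viable cell's volume at rate
#' `(ln 2 / doubling_time) * volume * O2_scaling(O2_local)`, divides
#' cells reaching the division volume, updates severe-hypoxia clocks,
#' tags cells exceeding the death-tag delay and converts tagged cells to
#' necrosis (vacating their site) after the lysis delay.
#'
#' @param sph a spheroid state (see [seed_spheroid()]).
#' @param O2 per-cell oxygen (uM), scalar or vector over cells.
#' @param params a [growth_params()].
#' @param dt_h step (h), at most 1.
#' @param seed RNG seed for division-vacancy choices.
#' @return the advanced spheroid state.
#' @export
grow_step <- function(sph, O2, params = growth_params(), dt_h = 1,
                      seed = NULL) {
  stopifnot(dt_h <= 1, dt_h > 0)
  grid <- sph$grid; cells <- sph$cells
  n <- length(cells$site)
  if (n == 0L) return(sph)
  O2 <- rep_len(O2, n)
  Td <- vapply(sph$lines, `[[`, 0, "doubling_time")[cells$line]
  scale <- O2 / (O2 + params$O2_half_sat)
  viable <- cells$state == 0L
  cells$volume[viable] <- cells$volume[viable] *
    2^(dt_h * scale[viable] / Td[viable])

  # severe-hypoxia death clock
  sev <- O2 < params$severe_hypoxia_threshold
  cells$hypoxia_h[sev] <- cells$hypoxia_h[sev] + dt_h
  cells$hypoxia_h[!sev] <- 0
  if (params$hypoxic_death) {
    newly <- viable & cells$hypoxia_h > params$death_tag_delay
    cells$state[newly] <- 1L
    tagged <- cells$state == 1L
    cells$tagged_h[tagged] <- cells$tagged_h[tagged] + dt_h
    lyse <- which(tagged & cells$tagged_h > params$lysis_delay)
    if (length(lyse)) {
      grid$occupancy[cells$site[lyse]] <- 0L
      nec <- tabulate(cells$line[lyse], 2L)
      keep <- setdiff(seq_len(n), lyse)
      for (f in c("site", "line", "volume", "state", "hypoxia_h",
                  "tagged_h", "log_survival")) {
        cells[[f]] <- cells[[f]][keep]
      }
      cells$n_necrotic <- cells$n_necrotic + nec
      grid$occupancy[cells$site] <- seq_along(cells$site)
      n <- length(cells$site)
    }
  }

  # divisions (volume-triggered, deterministic; vacancy choice seeded)
  sph$grid <- grid; sph$cells <- cells
  # trigger with a relative tolerance so an exact doubling in real time
  # is not missed to floating-point rounding
  div <- which(cells$state == 0L &
                 cells$volume >= params$divide_volume * (1 - 1e-9))
  if (length(div)) {
    sph <- with_seed(seed, {
      for (row in div) sph <- divide(sph, row)
      sph
    })
  }
  sph
}

#' Divide one cell
#'
#' The daughter occupies an adjacent (26-neighborhood) vacancy; if none
#' exists, the chain of cells along the most-radial lattice direction is
#' shifted outward one site and the freed neighbor is used. Mother and
#' daughter each receive half the mother's volume and the daughter
#' inherits the lineage.
#'
#' @param sph spheroid state.
#' @param row row index of the dividing cell in `sph$cells`.
#' @return the modified spheroid state.
#' @export
divide <- function(sph, row) {
  grid <- sph$grid; cells <- sph$cells
  s <- cells$site[row]
  nb <- .moore_neighbors(grid, s)
  vac <- nb[grid$occupancy[nb] == 0L & !grid$boundary[nb]]
  if (length(vac)) {
    # most compact vacancy (closest to the spheroid center); random
    # among ties, keeping the aggregate near-spherical
    rv <- grid$r[vac]
    vac <- vac[abs(rv - min(rv)) < 1e-9]
    d_site <- if (length(vac) == 1L) vac else vac[sample.int(length(vac), 1L)]
  } else {
    d_site <- .push_radial(grid, cells, s)
    grid <- d_site$grid; cells <- d_site$cells; d_site <- d_site$site
  }
  half <- cells$volume[row] / 2
  cells$volume[row] <- half
  m <- length(cells$site) + 1L
  cells$site <- c(cells$site, d_site)
  cells$line <- c(cells$line, cells$line[row])
  cells$volume <- c(cells$volume, half)
  cells$state <- c(cells$state, 0L)
  cells$hypoxia_h <- c(cells$hypoxia_h, 0)
  cells$tagged_h <- c(cells$tagged_h, 0)
  cells$log_survival <- c(cells$log_survival, 0)
  grid$occupancy[d_site] <- m
  sph$grid <- grid; sph$cells <- cells
  sph
}

# shift the chain of cells along the most-radial 26-direction outward by
# one site; returns the freed adjacent site
.push_radial <- function(grid, cells, s) {
  n1 <- grid$dims[1]
  ijk <- grid$ijk[s, ]
  u <- (ijk - grid$c0)
  nu <- sqrt(sum(u^2))
  u <- if (nu > 0) u / nu else c(1, 0, 0)
  di <- rep(-1:1, 9); dj <- rep(rep(-1:1, each = 3), 3)
  dk <- rep(-1:1, each = 9)
  keep <- !(di == 0 & dj == 0 & dk == 0)
  dirs <- cbind(di, dj, dk)[keep, , drop = FALSE]
  dn <- dirs / sqrt(rowSums(dirs^2))
  score <- as.numeric(dn %*% u)
  # outward direction sampled with alignment-weighted probability: a
  # deterministic best-aligned ray would focus all interior pushes onto
  # 26 rays and grow spikes; spreading the flux over the outward solid
  # angle keeps the aggregate near-spherical
  w <- pmax(score, 0)^4
  best <- sample.int(nrow(dirs), 1L, prob = w + 1e-12)
  d <- dirs[best, ]
  # walk outward; stop as soon as any adjacent vacancy appears (fills
  # surface concavities instead of tunneling past them)
  chain <- integer(0)
  p <- ijk
  repeat {
    # vacancy adjacent to the current position?
    here <- if (length(chain)) chain[length(chain)] else s
    nbv <- .moore_neighbors(grid, here)
    nbv <- nbv[grid$occupancy[nbv] == 0L & !grid$boundary[nbv]]
    if (length(nbv)) {
      rv <- grid$r[nbv]
      nbv <- nbv[abs(rv - min(rv)) < 1e-9]
      v <- if (length(nbv) == 1L) nbv else nbv[sample.int(length(nbv), 1L)]
      chain <- c(chain, v)
      break
    }
    p <- p + d
    if (any(p < 1L) || any(p > n1 - 2L)) {
      stop("no path to a vacancy: grid full along the radial direction",
           call. = FALSE)
    }
    q <- .lin_idx(grid, p[1], p[2], p[3])
    chain <- c(chain, q)
    if (grid$occupancy[q] == 0L) break
  }
  # shift occupants outward, starting from the vacancy
  for (i in rev(seq_len(length(chain) - 1L))) {
    mover <- grid$occupancy[chain[i]]
    grid$occupancy[chain[i + 1L]] <- mover
    cells$site[mover] <- chain[i + 1L]
  }
  grid$occupancy[chain[1L]] <- 0L
  list(grid = grid, cells = cells, site = chain[1L])
}

#' Grow a spheroid for a number of days
#'
#' Alternates hourly growth steps with quasi-steady oxygen solves on the
#' fine grid coupled to the transient unstirred medium column (gas-phase
#' O2 boundary at the medium-air interface). Transport operators are
#' refreshed whenever the population has grown materially since the last
#' solve; while the population is small (< 500 cells) oxygen is taken as
#' the bath value, which it equals to within solver tolerance at those
#' sizes.
#'
#' @param sph spheroid state from [seed_spheroid()].
#' @param days duration (days), > 0.
#' @param params a [growth_params()].
#' @param registry parameter registry supplying oxygen and geometry
#'   defaults.
#' @param geometry a [culture_geometry()]; default: growth medium 0.2
#'   mL / 6.1 mm deep, air-equilibrated gas interface.
#' @param seed RNG seed for division-vacancy choices.
#' @param n_column nodes in the 1D medium column.
#' @param o2_update_frac refresh transport when the cell count has grown
#'   by this fraction since the last refresh.
#' @return spheroid state with extra fields `diameter` (um), `counts`
#'   (viable per lineage), `o2` (last per-cell O2 field), `history`
#'   (hourly data.frame).
#' @export
grow_spheroid <- function(sph, days, params = growth_params(),
                          registry = NULL, geometry = NULL, seed = 1L,
                          n_column = 16, o2_update_frac = 0.05) {
  stopifnot(days > 0)
  reg <- registry %||% default_registry("sn30000")
  g <- function(nm) registry_get(reg, nm)
  geom <- geometry %||% culture_geometry(
    "spheroid", medium_volume = g("medium_volume"),
    medium_depth = g("medium_depth") / 1e3,   # um -> mm
    gas_O2 = g("gas_O2_growth"), initial_O2 = g("gas_O2_growth"))
  o2p <- list(Dm = g("O2_D_medium"), Dt = g("O2_D_tissue"),
              Vmax = g("O2_Vmax") * 1e21, Km = g("O2_Km"))
  # medium column (um-based amounts)
  A <- geom$well_area * 1e6                 # mm2 -> um2
  depth <- geom$medium_depth * 1e3          # mm -> um
  dz <- depth / n_column
  node_vol <- rep(A * dz, n_column)
  node_vol[1] <- node_vol[1] - sph$grid$n_sites * sph$grid$site_volume
  stopifnot(node_vol[1] > 0)
  Ccol <- rep(geom$initial_O2, n_column)

  n_hours <- round(days * 24)
  last_n <- -Inf
  O2_field <- rep(Ccol[1], sph$grid$n_sites)
  cons_rate <- 0
  hist <- vector("list", n_hours)
  for (h in seq_len(n_hours)) {
    n_now <- length(sph$cells$site)
    if (n_now >= 500 && n_now > last_n * (1 + o2_update_frac)) {
      O2_field <- .solve_o2_field(sph$grid, o2p, C_bath = Ccol[1],
                                  C0 = O2_field)
      occ <- sph$grid$occupancy > 0L
      cons_rate <- sum(o2p$Vmax * O2_field[occ] / (o2p$Km + O2_field[occ]))
      last_n <- n_now
    } else if (n_now < 500) {
      O2_field <- rep(Ccol[1], sph$grid$n_sites)
      cons_rate <- n_now * o2p$Vmax * Ccol[1] / (o2p$Km + Ccol[1])
    }
    # transient medium column over one hour (O2 only; sink = spheroid)
    for (sub in 1:6) {
      Ccol <- .step_column(Ccol, o2p$Dm, dz, 600, gas_value = geom$gas_O2,
                           sink_bottom = cons_rate, node_volume = node_vol,
                           area = A)
    }
    O2_cell <- O2_field[sph$cells$site]
    sph <- grow_step(sph, O2_cell, params, dt_h = 1, seed = seed + h)
    hist[[h]] <- data.frame(
      hour = h, n_cells = length(sph$cells$site),
      n_tagged = sum(sph$cells$state == 1L),
      n_necrotic = sum(sph$cells$n_necrotic),
      diameter = lattice_diameter(sph$grid),
      bath_O2 = Ccol[1])
  }
  sph$o2 <- O2_field[sph$cells$site]
  sph$diameter <- lattice_diameter(sph$grid)
  sph$counts <- c(activator = sum(sph$cells$line == 1L & sph$cells$state == 0L),
                  target = sum(sph$cells$line == 2L & sph$cells$state == 0L))
  sph$history <- do.call(rbind, hist)
  sph
}

#' Grow a spheroid from a seeding specification to a target day
#'
#' Convenience wrapper: seeds, grows, and reports the equivalent-sphere
#' diameter `(6 V_occupied / pi)^(1/3)` and per-lineage viable counts.
#'
#' @param n_days days of growth.
#' @param n_cells,activator_fraction,lines,seed seeding specification
#'   (see [seed_spheroid()]).
#' @param ... passed to [grow_spheroid()].
#' @return grown spheroid state (with `diameter` and `counts`).
#' @export
grow_to_day <- function(n_days, n_cells, activator_fraction, lines,
                        seed = 1L, ...) {
  stopifnot(n_days > 0)
  args <- list(...)
  max_radius <- args$max_radius
  args$max_radius <- NULL
  if (is.null(max_radius)) {
    # size the grid for the projected final population (unconstrained
    # exponential growth at the faster doubling time, plus margin)
    Td <- min(vapply(lines, `[[`, 0, "doubling_time"))
    n_final <- n_cells * 2^(n_days * 24 / Td)
    max_radius <- 1.3 * (3 * n_final * 5000 / (4 * pi))^(1 / 3) + 35
  }
  sph <- seed_spheroid(n_cells, activator_fraction, lines, seed = seed,
                       max_radius = max_radius)
  do.call(grow_spheroid, c(list(sph = sph, days = n_days, seed = seed), args))
}
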