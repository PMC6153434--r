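.lin_idx_test <- function(grid, i, j, k) {
  n1 <- grid$dims[1]
  i + n1 * j + n1 * n1 * k + 1L
}

test_that("membrane exchange conserves moles and finds partitioning", {
  ex <- membrane_exchange(10, 0, 0.1, 0.05, vol_ratio = 2)
  expect_equal(ex$dCi_dt, 1)
  expect_equal(ex$dCe_dt, -0.5)
  # equilibrium: equal concentrations with symmetric rates
  eq <- membrane_exchange(5, 5, 0.1, 0.1, 1)
  expect_identical(eq$dCi_dt, 0)
  expect_identical(eq$dCe_dt, 0)
  # K_in/K_out = 2 -> steady state C_i/C_e = 2
  eq2 <- membrane_exchange(5, 10, 0.2, 0.1, 1)
  expect_equal(eq2$dCi_dt, 0)
  expect_error(membrane_exchange(1, 1, -0.1, 0.1, 1), ">= 0")
  expect_error(membrane_exchange(1, 1, 0.1, 0.1, 0), "> 0")
})

test_that("steady spherical diffusion-consumption matches the analytic profile", {
  ss <- steady_state_sphere(R = 200, lambda = 100, D = 100)
  prof <- attr(ss, "profile")
  expect_equal(prof$analytic[1], 2 / sinh(2), tolerance = 1e-3)
  rel <- abs(prof$ratio - prof$analytic) / prof$analytic
  expect_lt(max(rel), 0.02)
  # error decreases under grid refinement
  ss_f <- steady_state_sphere(R = 200, lambda = 100, D = 100, dx = 10)
  prof_f <- attr(ss_f, "profile")
  rel_f <- abs(prof_f$ratio - prof_f$analytic) / prof_f$analytic
  expect_lt(max(rel_f), max(rel))
})

test_that("a uniform field with matched bath stays uniform", {
  m <- prodrug_model("sn30000")
  g <- build_lattice(2500, 50)
  st <- step_fine_grid(g, m, init = list(SN30000 = 10),
                       C_bath = list(SN30000 = 10), duration = 120, dt = 2)
  expect_equal(range(st$Ce$SN30000), c(10, 10), tolerance = 1e-9)
})

test_that("first-order medium decay follows exp(-kt)", {
  m <- prodrug_model("sn30000")
  m$solutes$SN30000$k_decay_medium <- 1e-3
  g <- build_lattice(2500, 50)
  amt0 <- 10 * g$site_volume * g$n_sites
  st <- step_fine_grid(g, m, init = list(SN30000 = 10), duration = 600,
                       dt = 2, closed = TRUE)
  expect_equal(unname(st$amounts["SN30000"]), amt0 * exp(-0.6),
               tolerance = 1e-4)
})

# a small densely occupied ball shared by the conservation tests
.make_ball <- function(radius = 60, fill_to = 40) {
  g <- build_lattice(2500, radius)
  open <- which(!g$boundary & g$r < fill_to)
  g$occupancy[open] <- seq_along(open)
  g
}

test_that("closed-system transport conserves the solute chain exactly", {
  m <- prodrug_model("sn30000")
  ll <- model_cell_lines(m)
  g <- .make_ball()
  n_c <- sum(g$occupancy > 0)
  st <- step_fine_grid(g, m, lines = list(ll$activator, ll$target),
                       line_of = rep(1:2, length.out = n_c),
                       init = list(SN30000 = 20), O2 = 0,
                       duration = 3600, dt = 2, closed = TRUE)
  tot0 <- 20 * sum(ifelse(g$occupancy > 0, 0.5, 1) * g$site_volume)
  expect_equal(sum(st$amounts), tot0, tolerance = 1e-6)
  # stoichiometry: prodrug consumed reappears in the metabolite chain
  consumed <- tot0 - st$amounts[["SN30000"]]
  formed <- st$amounts[["radical"]] + st$amounts[["oxide"]]
  expect_equal(formed, consumed, tolerance = 1e-6 * tot0)
  expect_identical(st$clip_events, 0L)
})

test_that("fields remain non-negative through sharp gradients", {
  m <- prodrug_model("pr104a_dichloro")
  ll <- model_cell_lines(m)
  g <- .make_ball()
  n_c <- sum(g$occupancy > 0)
  init <- ifelse(g$r > 40, 30, 0)
  st <- step_fine_grid(g, m, lines = list(ll$activator, ll$target),
                       line_of = rep(1L, n_c),
                       init = list(PR104A = init),
                       C_bath = list(PR104A = 30), O2 = 0,
                       duration = 900, dt = 2)
  for (nm in names(st$Ce)) {
    expect_true(all(st$Ce[[nm]] >= 0))
    expect_true(all(st$Ci[[nm]] >= 0))
  }
})

test_that("fine-grid fields inherit the octant symmetry of the problem", {
  m <- prodrug_model("sn30000")
  ll <- model_cell_lines(m)
  g <- build_lattice(2500, 60)
  open <- which(!g$boundary & g$r < 40)
  g$occupancy[open] <- seq_along(open)
  n_c <- length(open)
  st <- step_fine_grid(g, m, lines = list(ll$activator, ll$target),
                       line_of = rep(1L, n_c),   # uniform lineage
                       init = list(SN30000 = 10),
                       C_bath = list(SN30000 = 10), O2 = 0,
                       duration = 300, dt = 2)
  ce <- st$Ce$SN30000
  # mirror the x-axis: site (i,j,k) <-> (n-1-i,j,k)
  n1 <- g$dims[1]
  mirror <- .lin_idx_test(g, (n1 - 1L) - g$ijk[, 1], g$ijk[, 2], g$ijk[, 3])
  expect_equal(ce, ce[mirror], tolerance = 1e-9)
})

test_that("the unstirred column equilibrates to its gas boundary", {
  # gas-phase O2 held at 0 drains an initial bolus monotonically
  N <- 20; dz <- 300; A <- 3e7
  nv <- rep(A * dz, N)
  C <- rep(2.5, N)
  tot <- numeric(40)
  for (i in 1:40) {
    C <- hapabm:::.step_column(C, 2000, dz, 30, gas_value = 0,
                               sink_bottom = 0, node_volume = nv, area = A)
    tot[i] <- sum(C * nv)
  }
  expect_true(all(diff(tot) < 0))
  expect_lt(C[N], 2.5)   # surface node drains first
  # and with gas == initial, nothing changes
  C2 <- rep(2.5, N)
  C2 <- hapabm:::.step_column(C2, 2000, dz, 30, gas_value = 2.5,
                              sink_bottom = 0, node_volume = nv, area = A)
  expect_equal(C2, rep(2.5, N), tolerance = 1e-9)
})
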