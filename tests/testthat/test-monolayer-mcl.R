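test_that("monolayer survival is log-linear in concentration", {
  m <- prodrug_model("sn30000")
  ll <- model_cell_lines(m)
  pr <- exposure_protocol(c(0, 10, 20, 40, 80), duration_h = 1)
  dr <- run_monolayer_assay(m, list(ll$target), pr, n_cells = 500)
  expect_equal(dr$SF[dr$prodrug_uM == 0], 1)
  d <- dr[dr$prodrug_uM > 0, ]
  fit <- loglinear_slope(dr, "PORko-G")
  resid <- d$log10_SF - fit$slope * d$prodrug_uM
  expect_lt(max(abs(resid)), 0.02 * max(abs(d$log10_SF)))
  expect_lt(fit$slope, 0)
})

test_that("the no-depletion slope matches the closed form", {
  # low density, fast uptake: slope -> -K_c K_met Ci_eq/C t log10(e)
  m <- prodrug_model("sn30000")
  ll <- model_cell_lines(m)
  pr <- exposure_protocol(c(5, 10, 20, 40), duration_h = 1)
  dr <- run_monolayer_assay(m, list(ll$target), pr, n_cells = 100)
  fit <- loglinear_slope(dr, "PORko-G")
  kmet <- convert_units(1.3, "1/min", "1/s")
  kc <- convert_units(1, "1/mM", "1/uM")
  ci_over_ce <- 0.1 / (0.1 + kmet)         # uptake / (efflux + metabolism)
  slope_th <- -kc * kmet * ci_over_ce * 3600 * log10(exp(1))
  expect_equal(fit$slope, slope_th, tolerance = 0.02)
})

test_that("doubling K_met0 near-halves the concentration for fixed kill", {
  m <- prodrug_model("sn30000")
  reg2 <- registry_set(m$registry, `K_met0_SN30000_PORko-G` = 2.6,
                       provenance = "ASSUMED")
  m2 <- prodrug_model("sn30000", registry = reg2)
  ll <- model_cell_lines(m); ll2 <- model_cell_lines(m2)
  pr <- exposure_protocol(c(5, 10, 20, 40, 60), duration_h = 1)
  dr1 <- run_monolayer_assay(m, list(ll$target), pr, n_cells = 100)
  dr2 <- run_monolayer_assay(m2, list(ll2$target), pr, n_cells = 100)
  s1 <- loglinear_slope(dr1, "PORko-G")$slope
  s2 <- loglinear_slope(dr2, "PORko-G")$slope
  # metabolism also competes with uptake, so slightly less than 2x
  expect_equal(s2 / s1, 2 * (0.1 + 1.3 / 60) / (0.1 + 2.6 / 60),
               tolerance = 0.02)
})

test_that("prodrug depletion grows with cell density", {
  m <- prodrug_model("sn30000")
  ll <- model_cell_lines(m)
  final_conc <- vapply(c(1e4, 1e5, 4e5), function(nc) {
    sim <- simulate_monolayer(m, list(ll$activator), concentration = 20,
                              n_cells = nc)
    utils::tail(sim$timecourse$bottom_uM, 1)
  }, 0)
  expect_true(all(diff(final_conc) < 0))
})

test_that("an O2 bolus is cleared faster at higher cell density", {
  m <- prodrug_model("pr104a_dichloro")
  ll <- model_cell_lines(m)
  o2_final <- vapply(c(2e4, 1e5, 1e6), function(nc) {
    sim <- simulate_monolayer(m, list(ll$target), concentration = 0,
                              o2_bolus = 2.5, n_cells = nc,
                              duration = 1800)
    utils::tail(sim$timecourse$o2_bottom_uM, 1)
  }, 0)
  expect_true(all(diff(o2_final) < 0))
})

test_that("well-mixed limit: large diffusivity flattens the depth profile", {
  m <- prodrug_model("sn30000")
  m$solutes$SN30000$D_medium <- 4e5
  ll <- model_cell_lines(m)
  sim <- simulate_monolayer(m, list(ll$activator), concentration = 20,
                            n_cells = 1e5)
  prof <- sim$depth_profile$prodrug_uM
  expect_lt((max(prof) - min(prof)) / mean(prof), 0.01)
})

test_that("acellular MCL flux approaches Fick's law after the lag", {
  m <- prodrug_model("sn30000")
  ll <- model_cell_lines(m)
  r <- simulate_mcl(m, list(ll$activator, ll$target), activator_fraction = 0,
                    donor_bolus = 100, duration = 4 * 3600, acellular = TRUE,
                    times = seq(0, 4 * 3600, 600))
  tc <- r$receiver_norm
  # slope of receiver concentration over the last hour (uM/s)
  n <- nrow(tc)
  slope <- (tc$C_over_C0[n] - tc$C_over_C0[n - 6]) * 100 /
    (tc$t_s[n] - tc$t_s[n - 6])
  # Fick: dCr/dt = D A C0 / (L Vr)
  D <- m$solutes$SN30000$D_tissue
  A <- registry_get(m$registry, "mcl_area")          # um^2
  Vr <- registry_get(m$registry, "mcl_compartment_volume") * 1e12
  slope_th <- D * A * 100 / (150 * Vr)
  expect_equal(slope, slope_th, tolerance = 0.02)
})

test_that("MCL metabolism ranks with activator fraction", {
  m <- prodrug_model("sn30000")
  ll <- model_cell_lines(m)
  res <- run_mcl_assay(m, list(activator = ll$activator,
                               target = ll$target),
                       fractions = c(0, 0.1, 0.5, 1), duration_h = 3)
  s <- res$summary
  expect_true(all(diff(s$receiver_auc) < 0))          # more activators,
  expect_true(all(diff(s$final_metabolite_umol) > 0)) # less through, more made
})

test_that("MCL conserves moles when all losses are off", {
  m <- prodrug_model("sn30000")   # no decay terms in this chain
  ll <- model_cell_lines(m)
  r <- simulate_mcl(m, list(ll$activator, ll$target),
                    activator_fraction = 0.5, donor_bolus = 100,
                    duration = 2 * 3600)
  tc <- r$timecourse
  comp <- tc[tc$t_s == max(tc$t_s), ]
  # compartment amounts plus slab content (from final state) at end
  total_comp <- sum(comp$amount_umol)
  v0 <- 100 * 8.5e12 * 1e-18                       # umol initially in donor
  # slab holds the remainder; bound the compartment total by the budget
  expect_lt(total_comp, v0 * (1 + 1e-3))
  # prodrug + metabolites entering receiver never negative
  expect_true(all(tc$concentration_uM >= 0))
})

test_that("MCL with no metabolism anywhere yields zero metabolites", {
  m <- prodrug_model("sn30000")
  reg <- registry_set(m$registry, `K_met0_SN30000_POR-R` = 1e-9,
                      `K_met0_SN30000_PORko-G` = 1e-12,
                      provenance = "ASSUMED")
  m0 <- prodrug_model("sn30000", registry = reg)
  ll <- model_cell_lines(m0)
  r <- simulate_mcl(m0, list(ll$activator, ll$target),
                    activator_fraction = 0.5, donor_bolus = 100,
                    duration = 3600)
  expect_lt(max(r$metabolite_umol$umol), 1e-8)
})
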