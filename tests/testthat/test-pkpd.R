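test_that("Michaelis-Menten oxygen consumption matches closed forms", {
  expect_identical(michaelis_menten_O2_rate(0, 6e-17, 1.3), 0)
  expect_equal(michaelis_menten_O2_rate(1.3, 6e-17, 1.3), 3e-17)
  expect_equal(michaelis_menten_O2_rate(4, 6e-17, 1.3), 6e-17 * 4 / 5.3)
  expect_error(michaelis_menten_O2_rate(-1, 6e-17, 1.3), ">= 0")
  # monotone increasing
  r <- michaelis_menten_O2_rate(seq(0, 50, 2), 6e-17, 1.3)
  expect_true(all(diff(r) > 0))
})

test_that("oxygen dependence of K_met follows the saturation form", {
  ms <- metabolism_spec(convert_units(14, "1/min", "1/s"), 0.126, "POR-R")
  expect_equal(oxygen_dependent_kmet(ms, 0), 14 / 60)
  expect_equal(oxygen_dependent_kmet(ms, 0.126), 14 / 120)
  # printed-value check: 14 min^-1 inhibited by 2.5 uM O2 -> 0.672 min^-1
  expect_equal(convert_units(oxygen_dependent_kmet(ms, 2.5), "1/s", "1/min"),
               14 * 0.126 / 2.626, tolerance = 1e-12)
  k <- oxygen_dependent_kmet(ms, c(0, 0.5, 2, 10))
  expect_true(all(diff(k) < 0))
})

test_that("metabolism rate is K_met * C with stoichiometric meaning", {
  ms <- metabolism_spec(convert_units(1.3, "1/min", "1/s"), 1.2, "x")
  expect_identical(metabolism_rate(0, ms, 0), 0)
  # 20 uM at 1.3/min -> 26 uM/min
  expect_equal(metabolism_rate(20, ms, 0) * 60, 26)
  ms0 <- metabolism_spec(0, 1.2, "target")
  expect_identical(metabolism_rate(50, ms0, 0), 0)
})

test_that("kill laws reproduce the closed-form survivals", {
  # concentration mode: K_c = 0.092 /mM/s, C = 10 uM, 1 h -> SF 0.0364
  km <- kill_model("concentration", convert_units(0.092, "1/mM/s", "1/uM/s"),
                   acts_on = "M")
  sf <- exp(-kill_hazard_rate(km, C = 10) * 3600)
  expect_equal(sf, exp(-0.092e-3 * 10 * 3600), tolerance = 1e-12)
  expect_equal(sf, 0.0364, tolerance = 2e-3)
  # metabolism mode: K_c = 1 /mM, K_met = 1.3 /min, C = 20 uM, 60 min
  km2 <- kill_model("metabolism_rate", convert_units(1, "1/mM", "1/uM"),
                    acts_on = "P")
  mprime <- convert_units(1.3, "1/min", "1/s") * 20
  sf2 <- exp(-kill_hazard_rate(km2, M_prime = mprime) * 3600)
  expect_equal(sf2, exp(-0.001 * 1.3 * 20 * 60), tolerance = 1e-12)
  expect_equal(sf2, 0.210, tolerance = 2e-3)
})

test_that("interval kill probability is the hazard-exponential form", {
  km <- kill_model("concentration", 1e-3, acts_on = "M")
  p <- kill_probability(km, dt = 10, C = 5)
  expect_equal(p, 1 - exp(-1e-3 * 5 * 10))
  # small-interval limit equals the discrete rule K_c * C * dt
  p_small <- kill_probability(km, dt = 1e-4, C = 5)
  expect_equal(p_small, 1e-3 * 5 * 1e-4, tolerance = 1e-6)
})

test_that("hazard accumulation is interval-decomposable", {
  km <- kill_model("concentration", 1e-3, acts_on = "M")
  h_whole <- kill_hazard_rate(km, C = 8) * 3600
  splits <- c(1, 7, 36, 360)
  for (n in splits) {
    h_split <- sum(rep(kill_hazard_rate(km, C = 8) * 3600 / n, n))
    expect_equal(exp(-h_split), exp(-h_whole), tolerance = 1e-9)
  }
})

test_that("independent cytotoxins combine multiplicatively on survival", {
  expect_equal(combine_kills(0, 0.3), 0.3, tolerance = 1e-12)
  expect_identical(combine_kills(0.5, 0.5), 0.75)
  expect_equal(combine_kills(0.9, 0.99), 0.999)
  expect_error(combine_kills(1.2, 0.5), "\\[0, 1\\]")
  # commutative and bounded below by the larger component
  grid <- expand.grid(p1 = seq(0, 1, 0.25), p2 = seq(0, 1, 0.25))
  c12 <- combine_kills(grid$p1, grid$p2)
  expect_equal(c12, combine_kills(grid$p2, grid$p1))
  expect_true(all(c12 >= pmax(grid$p1, grid$p2) - 1e-12))
})

test_that("surviving fraction averages clonogenic probabilities", {
  cells <- list(line = c(1L, 1L, 2L), state = c(0L, 0L, 0L),
                log_survival = c(0, -1e9, log(0.4)))
  expect_equal(surviving_fraction(cells, lineage = 1L), 0.5)
  expect_equal(surviving_fraction(cells, lineage = 2L), 0.4)
  expect_error(surviving_fraction(cells, lineage = 3L), "no viable cells")
  # Bernoulli sampling agrees with expectation within Monte-Carlo error
  n <- 2000
  cells2 <- list(line = rep(1L, n), state = rep(0L, n),
                 log_survival = rep(log(0.3), n))
  sf_b <- surviving_fraction(cells2, mode = "bernoulli", seed = 42)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(sf_b - 0.3), 3 * se)
})

test_that("activators and targets are equally sensitive to the same dose", {
  # identical intracellular histories give identical log survival
  m <- prodrug_model("pr104a_dichloro")
  km <- m$kill_models[[1]]
  h_act <- kill_hazard_rate(km, C = 7.3) * 1800
  h_tgt <- kill_hazard_rate(km, C = 7.3) * 1800
  expect_identical(h_act, h_tgt)
})
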