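.test_lines <- function(Td_act = 31, Td_tgt = 31) {
  list(activator = cell_line_spec("ACT", "activator", Td_act),
       target = cell_line_spec("TGT", "target", Td_tgt))
}

test_that("seeding composition follows the Bernoulli draw", {
  ll <- .test_lines()
  sph <- seed_spheroid(500, 0, ll, seed = 3)
  expect_true(all(sph$cells$line == 2L))
  sph2 <- seed_spheroid(2000, 0.5, ll, seed = 3)
  frac <- mean(sph2$cells$line == 1L)
  expect_lt(abs(frac - 0.5), 0.029)   # binomial 99% CI at n = 2000
  # occupancy bookkeeping: one agent per occupied site
  expect_equal(sum(sph2$grid$occupancy > 0), length(sph2$cells$site))
  expect_error(seed_spheroid(1e7, 0.5, ll, seed = 1, max_radius = 30),
               "capacity")
})

test_that("one isolated cell doubles after one doubling time", {
  ll <- .test_lines(Td_act = 16, Td_tgt = 16)
  sph <- seed_spheroid(1, 0, ll, seed = 1, max_radius = 40)
  p <- growth_params(O2_half_sat = 0)    # exact unit growth scaling
  sph$cells$volume <- p$birth_volume      # deterministic start
  for (h in 1:16) sph <- grow_step(sph, O2 = 1e6, params = p, dt_h = 1,
                                   seed = h)
  expect_length(sph$cells$site, 2L)
  # both daughters carry half the division volume, i.e. the birth volume
  expect_equal(sph$cells$volume, rep(p$birth_volume, 2), tolerance = 1e-9)
})

test_that("zero oxygen freezes growth and eventually kills", {
  ll <- .test_lines()
  sph <- seed_spheroid(10, 0, ll, seed = 2, max_radius = 60)
  v0 <- sph$cells$volume
  p <- growth_params()
  sph1 <- grow_step(sph, O2 = 0, params = p, dt_h = 1)
  expect_equal(sph1$cells$volume, v0)     # scaling 0: volumes unchanged
  # 24 h severe hypoxia tags, lysis_delay later necrotic (site vacated)
  for (h in 1:(24 + 24 + 2)) sph <- grow_step(sph, O2 = 0, params = p,
                                              dt_h = 1, seed = h)
  expect_length(sph$cells$site, 0L)
  expect_equal(sum(sph$cells$n_necrotic), 10)
  expect_equal(sum(sph$grid$occupancy > 0), 0L)
})

test_that("division inherits lineage and displacement conserves counts", {
  ll <- .test_lines()
  sph <- seed_spheroid(150, 0.4, ll, seed = 9, max_radius = 100)
  n_by_line <- table(sph$cells$line)
  p <- growth_params()
  sph$cells$volume[] <- p$divide_volume    # force everyone to divide
  sph2 <- with_seed(5, {
    s <- sph
    for (row in seq_len(150)) s <- divide(s, row)
    s
  })
  expect_length(sph2$cells$site, 300L)
  n_by_line2 <- table(sph2$cells$line)
  expect_equal(as.numeric(n_by_line2), 2 * as.numeric(n_by_line))
  # occupancy consistent after chains of displacements
  expect_equal(sum(sph2$grid$occupancy > 0), 300L)
  expect_true(all(sph2$grid$occupancy[sph2$cells$site] ==
                    seq_along(sph2$cells$site)))
  # no two cells share a site
  expect_false(any(duplicated(sph2$cells$site)))
})

test_that("uniform-oxygen growth matches the exponential law", {
  ll <- .test_lines(Td_act = 16, Td_tgt = 16)
  sph <- seed_spheroid(100, 0.5, ll, seed = 4, max_radius = 150)
  p <- growth_params(hypoxic_death = FALSE)
  for (h in 1:48) sph <- grow_step(sph, O2 = 1e6, params = p, dt_h = 1,
                                   seed = h)
  expected <- 100 * 2^(48 / 16)
  expect_lt(abs(length(sph$cells$site) - expected) / expected, 0.02)
})

test_that("slower-doubling lineage loses ground in co-culture", {
  # 38 h vs 31 h over 96 h: expected fraction falls below the seeded 0.5
  ll <- .test_lines(Td_act = 38, Td_tgt = 31)
  sph <- seed_spheroid(300, 0.5, ll, seed = 8, max_radius = 160)
  p <- growth_params(hypoxic_death = FALSE)
  for (h in 1:96) sph <- grow_step(sph, O2 = 1e6, params = p, dt_h = 1,
                                   seed = h)
  frac_act <- mean(sph$cells$line == 1L)
  expect_lt(frac_act, 0.5)
  # magnitude roughly the ratio-of-exponentials prediction
  pred <- 2^(96 / 38) / (2^(96 / 38) + 2^(96 / 31))
  expect_lt(abs(frac_act - pred), 0.08)
})

test_that("seeded diameter matches the occupied-volume geometry", {
  ll <- .test_lines()
  sph <- seed_spheroid(3000, 0.5, ll, seed = 1)
  d <- lattice_diameter(sph$grid)
  expect_equal(d, (6 * 3000 * sph$grid$site_volume / pi)^(1 / 3),
               tolerance = 1e-9)
})

test_that("lattice trimming preserves the population and its geometry", {
  ll <- .test_lines()
  sph <- seed_spheroid(400, 0.3, ll, seed = 6, max_radius = 300)
  d0 <- lattice_diameter(sph$grid)
  lines0 <- sph$cells$line
  r0 <- sort(sph$grid$r[sph$cells$site])
  sph2 <- trim_lattice(sph)
  expect_lt(sph2$grid$dims[1], sph$grid$dims[1])
  expect_equal(lattice_diameter(sph2$grid), d0)
  expect_identical(sph2$cells$line, lines0)
  expect_equal(sort(sph2$grid$r[sph2$cells$site]), r0, tolerance = 1e-9)
})

test_that("sparse seeding produces patchier activator neighborhoods", {
  ll <- .test_lines(16, 16)
  p <- growth_params(hypoxic_death = FALSE)
  local_sd <- function(n0, seeds) {
    vapply(seeds, function(s) {
      sph <- seed_spheroid(n0, 0.1, ll, seed = s, max_radius = 120)
      while (length(sph$cells$site) < 800) {
        sph <- grow_step(sph, O2 = 1e6, params = p, dt_h = 1, seed = s)
      }
      mean(sph$cells$line == 1L)
    }, 0)
  }
  f20 <- local_sd(20, 1:6)
  f2000 <- local_sd(800, 1:6)
  expect_gt(stats::sd(f20), stats::sd(f2000))
})
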