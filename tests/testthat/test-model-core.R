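test_that("unit conversions are exact and round-trip", {
  expect_equal(convert_units(1.88, "1/min", "1/s"), 1.88 / 60)
  expect_equal(convert_units(0.05, "1/mM/s", "1/uM/s"), 5e-5)
  expect_equal(convert_units(6.1, "mm", "um"), 6100)
  x <- c(0.126, 1.3, 14)
  back <- convert_units(convert_units(x, "1/min", "1/s"), "1/s", "1/min")
  expect_lt(max(abs(back - x) / x), 1e-12)
  expect_error(convert_units(1, "furlong", "um"), "unknown units")
})

test_that("lattice geometry follows the two-cells-per-site rule", {
  g <- build_lattice(2500, 100)
  expect_equal(g$dx, 5000^(1 / 3), tolerance = 1e-12)
  expect_equal(round(g$dx, 1), 17.1)
  expect_equal(g$site_volume / 2500, 2, tolerance = 1e-12)
  expect_error(build_lattice(-5, 100), "must be > 0")
})

test_that("degenerate zero-radius lattice is one site plus vacant shell", {
  g <- build_lattice(2500, 0)
  expect_equal(g$dims, c(3L, 3L, 3L))
  expect_equal(sum(!g$boundary), 1L)
})

test_that("face neighbors are clipped at boundaries", {
  g <- build_lattice(2500, 40)   # dims 9
  n1 <- g$dims[1]
  interior <- which(g$ijk[, 1] == 4 & g$ijk[, 2] == 4 & g$ijk[, 3] == 4)
  expect_length(neighbors(g, interior), 6L)
  corner <- which(g$ijk[, 1] == 0 & g$ijk[, 2] == 0 & g$ijk[, 3] == 0)
  expect_length(neighbors(g, corner), 3L)
  face <- which(g$ijk[, 1] == 0 & g$ijk[, 2] == 4 & g$ijk[, 3] == 4)
  expect_length(neighbors(g, face), 5L)
  expect_error(neighbors(g, g$n_sites + 1), "out of grid")
})

test_that("default registry carries the published constants", {
  reg <- default_registry("sn30000")
  expect_equal(registry_get(reg, "K_met0_SN30000_HCT116", internal = FALSE),
               1.88)
  expect_equal(registry_get(reg, "K_met0_SN30000_HCT116"), 1.88 / 60)
  reg2 <- default_registry("pr104a_dichloro")
  expect_equal(registry_get(reg2, "K_O2_PR104A"), 0.126)
  expect_equal(registry_get(reg2, "K_c_dichloro"), 5e-5) # 0.05 / mM / s
  expect_error(registry_get(reg, "D_tissue_of_nothing"), "missing")
})

test_that("registry validation rejects bad input and reports provenance", {
  expect_error(parameter_registry(c("a", "a"), c(1, 2), c("uM", "uM"),
                                  c("ASSUMED", "ASSUMED")),
               "duplicate")
  expect_error(parameter_registry("a", 1, "parsec", "ASSUMED"),
               "unknown units")
  expect_error(parameter_registry("a", 1, "uM", "PAPER", cite = ""),
               "citation")
  reg <- default_registry("sn30000")
  prov <- registry_provenance(reg)
  expect_false(prov$fully_constrained)
  expect_true("O2_Vmax" %in% prov$assumed)
  expect_error(registry_require(reg, c("K_O2_SN30000", "D_tissue_xyz")),
               "D_tissue_xyz")
})

test_that("registry YAML round-trips with explicit units", {
  reg <- default_registry("pr104a_hm")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_registry(reg, f)
  reg2 <- load_parameter_registry(f)
  expect_equal(reg2$value, reg$value, tolerance = 1e-12)
  expect_identical(reg2$units, reg$units)
  expect_identical(reg2$provenance, reg$provenance)
  # a file with a bare number (no units) is rejected
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(parameters = list(x = list(value = 3))), bad)
  expect_error(load_parameter_registry(bad), "units")
})

test_that("solute and chain invariants are enforced", {
  expect_error(solute_spec("x", D_medium = 100, D_tissue = 200),
               "D_tissue")
  expect_error(solute_spec("x", 100, 50, K_in = -1), ">= 0")
  expect_error(solute_spec("x", 0, 0, K_in = 0.1, diffusible = FALSE),
               "non-diffusing")
  a <- solute_spec("a", 100, 50, child = "b")
  b <- solute_spec("b", 100, 50, child = "a")
  expect_error(validate_chain(list(a = a, b = b)), "cyclic")
  expect_error(validate_chain(list(a = solute_spec("a", 100, 50,
                                                   child = "zz"))),
               "not defined")
})

test_that("model construction enforces the pharmacology contracts", {
  m <- prodrug_model("sn30000")
  expect_identical(m$kill_models[[1]]$mode, "metabolism_rate")
  expect_false(m$solutes$radical$diffusible)
  m2 <- prodrug_model("pr104a_dichloro")
  expect_length(m2$kill_models, 2L)
  expect_true(all(vapply(m2$kill_models, `[[`, "", "mode") ==
                    "concentration"))
  ll <- model_cell_lines(m)
  expect_gt(ll$activator$metabolism$SN30000$K_met0,
            ll$target$metabolism$SN30000$K_met0)
})

test_that("the shipped example registry loads and drives a model", {
  f <- system.file("extdata", "pr104a_dichloro_registry.yaml",
                   package = "hapabm")
  reg <- load_parameter_registry(f)
  expect_equal(registry_get(reg, "K_O2_PR104A"), 0.126)
  m <- prodrug_model("pr104a_dichloro", registry = reg)
  expect_length(m$kill_models, 2L)
})
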