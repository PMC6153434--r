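test_that("IC90 interpolation handles exact hits, brackets and bad input", {
  d <- data.frame(prodrug_uM = c(1, 5, 10, 20),
                  lineage = "L", SF = c(0.9, 0.4, 0.1, 0.01))
  d$log10_SF <- log10(d$SF)
  expect_equal(ic90(d, "L")$ic90_uM, 10)
  # log10 SF = -C/10 -> IC90 at 10 uM by construction
  d2 <- data.frame(prodrug_uM = c(2, 6, 12, 18), lineage = "L",
                   SF = 10^(-c(2, 6, 12, 18) / 10))
  d2$log10_SF <- log10(d2$SF)
  expect_equal(ic90(d2, "L")$ic90_uM, 10, tolerance = 1e-9)
  # not bracketed: reports the achieved range
  d3 <- data.frame(prodrug_uM = c(1, 2), lineage = "L", SF = c(0.9, 0.8),
                   log10_SF = log10(c(0.9, 0.8)))
  expect_error(ic90(d3, "L"), "does not bracket")
  # monotone-increasing SF is invalid input
  d4 <- data.frame(prodrug_uM = c(1, 2, 3), lineage = "L",
                   SF = c(0.1, 0.5, 0.9), log10_SF = log10(c(0.1, 0.5, 0.9)))
  expect_error(ic90(d4, "L"), "non-increasing")
  expect_error(ic90(d, "M"), "no rows")
})

test_that("zero-dose arms and empty protocols behave trivially", {
  m <- prodrug_model("sn30000")
  ll <- model_cell_lines(m)
  pr <- exposure_protocol(c(0, 20), duration_h = 1)
  dr <- run_monolayer_assay(m, list(ll$activator, ll$target), pr,
                            n_cells = 1000)
  expect_true(all(dr$SF[dr$prodrug_uM == 0] == 1))
  expect_true(all(dr$SF[dr$prodrug_uM == 20] < 1))
  expect_error(exposure_protocol(c(-1, 5)), ">= 0")
})

test_that("metabolite decomposition attributes kill and sums to one", {
  m <- prodrug_model("pr104a_dichloro")
  ll <- model_cell_lines(m)
  sim_fun <- function(mod) {
    pr <- exposure_protocol(17, duration_h = 1)
    dr <- run_monolayer_assay(mod, list(ll$activator, ll$target), pr,
                              n_nodes = 6)
    stats::setNames(dr$SF, dr$lineage)
  }
  dec <- decompose_metabolite_contributions(m, sim_fun)
  expect_equal(unique(dec$lineage), c("POR-G", "PORko-R"))
  for (ln in unique(dec$lineage)) {
    expect_equal(sum(dec$relative_contribution[dec$lineage == ln]), 1)
  }
  # monolayer: the proximal mustards dominate killing for both lineages
  for (ln in unique(dec$lineage)) {
    hm <- dec$log_kill[dec$lineage == ln & dec$metabolite == "PR104H+M"]
    ab <- dec$log_kill[dec$lineage == ln &
                         dec$metabolite == "Metabolites A+B"]
    expect_gt(hm, ab)
  }
  # both potencies zeroed -> no kill at all
  m0 <- m
  for (k in 1:2) m0$kill_models[[k]]$K_c <- 0
  sf0 <- sim_fun(m0)
  expect_equal(unname(sf0), c(1, 1), tolerance = 1e-9)
})

test_that("monolayer IC90s sit at the calibration anchors", {
  m <- prodrug_model("pr104a_dichloro")
  ll <- model_cell_lines(m)
  dr_a <- run_monolayer_assay(m, list(ll$activator),
                              exposure_protocol(c(0.4, 0.7, 1, 1.5, 2.5)))
  dr_t <- run_monolayer_assay(m, list(ll$target),
                              exposure_protocol(c(8, 12, 17, 24, 34)))
  expect_equal(ic90(dr_a, "POR-G")$ic90_uM, 1, tolerance = 0.1)
  expect_equal(ic90(dr_t, "PORko-R")$ic90_uM, 17, tolerance = 0.1 * 17)
})

test_that("spheroid assay pools replicates and handles zero-dose arms", {
  m <- prodrug_model("sn30000")
  ll <- model_cell_lines(m)
  pair <- list(activator = ll$activator, target = ll$target)
  mk <- function(seed) {
    sph <- seed_spheroid(120, 0.5, pair, seed = seed, max_radius = 80)
    sph$lines <- pair
    sph
  }
  sphs <- list("0.5" = list(mk(1), mk(2)))
  dr <- run_spheroid_assay(m, sphs, exposure_protocol(c(0, 40)), dt = 4)
  expect_true(all(dr$SF[dr$prodrug_uM == 0] == 1))
  dosed <- dr[dr$prodrug_uM == 40, ]
  expect_true(all(dosed$SF < 1))
  # activators are killed more than targets under the no-bystander law
  expect_lt(dosed$SF[dosed$lineage == "activator"],
            dosed$SF[dosed$lineage == "target"])
  expect_setequal(dr$mixing_ratio, 0.5)
})
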