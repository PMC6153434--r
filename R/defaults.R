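#' Default parameter registry
#'
#' Assembles the package's default parameter set for one prodrug model.
#' Values printed in the source literature carry provenance `PAPER` with
#' a quote-bearing citation; parameters the original study estimated
#' from data carry `FITTED`; everything else is an `ASSUMED`,
#' overridable default (see the methods vignette for the reasoning
#' behind each).
#'
#' @param model `"sn30000"`, `"pr104a_hm"` (PR104H+M model) or
#'   `"pr104a_dichloro"` (dichloro-metabolites model).
#' @return a `hap_registry` containing every parameter the
#'   corresponding simulations consume.
#' @export
default_registry <- function(model = c("sn30000", "pr104a_hm",
                                       "pr104a_dichloro")) {
  model <- match.arg(model)
  rows <- list()
  add <- function(name, value, units, prov, cite = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, value = value, units = units, provenance = prov,
      cite = cite, stringsAsFactors = FALSE)
  }

  ## -- lattice / growth -------------------------------------------------
  add("mean_cell_volume", 2500, "um3", "ASSUMED",
      "typical HCT116 cell size; lattice site volume is twice this")
  add("hypoxia_threshold", 4, "uM", "PAPER",
      "fraction of hypoxia (O2 < 4 uM)")
  add("severe_hypoxia_threshold", 0.15, "uM", "PAPER",
      "severe hypoxia (O2 < 0.15 uM)")
  add("death_tag_delay", 24, "h", "PAPER",
      "persists for more than 24 h, cells are 'tagged' for death")
  add("lysis_delay", 24, "h", "ASSUMED",
      "cells starved of oxygen eventually undergo cytolysis; delay not printed")
  add("growth_O2_half_sat", 1, "uM", "ASSUMED",
      "half-saturation of the O2-dependent growth-rate scaling")

  ## -- culture geometry -------------------------------------------------
  add("medium_volume", 0.2, "mL", "PAPER", "typically 0.2 mL")
  add("medium_depth", 6.1, "mm", "PAPER", "and 6.1 mm, respectively")
  add("exposure_volume", 80, "uL", "PAPER", "final volume of 80 uL/well")
  add("well_area", 32.8, "mm2", "ASSUMED",
      "medium_volume / medium_depth; 96-well footprint")
  add("monolayer_n_cells", 1e5, "cells", "PAPER", "seeded at 10^5 cells/0.15 mL")
  add("monolayer_volume", 0.15, "mL", "PAPER", "seeded at 10^5 cells/0.15 mL")
  add("gas_O2_growth", 200, "uM", "ASSUMED",
      "air-equilibrated medium under 5% CO2")
  add("o2_bolus", 2.5, "uM", "PAPER",
      "initial average oxygen concentration ... was 2.5 uM")
  add("mcl_thickness", 150, "um", "ASSUMED", "chamber dimensions not printed")
  add("mcl_compartment_volume", 8.5, "mL", "ASSUMED",
      "donor/receiver volumes not printed")
  add("mcl_area", 0.3, "cm2", "ASSUMED", "exposed MCL area not printed")
  add("mcl_donor_bolus", 100, "uM", "PAPER",
      "SN30000 (100 uM) ... added to the donor compartment")

  ## -- oxygen -----------------------------------------------------------
  add("O2_D_medium", 2000, "um2/s", "ASSUMED", "O2 diffusivity in medium")
  add("O2_D_tissue", 1700, "um2/s", "ASSUMED", "O2 diffusivity in tissue")
  add("O2_Vmax", 6e-17, "mol/cell/s", "ASSUMED",
      "maximal per-cell O2 consumption")
  add("O2_Km", 1.3, "uM", "ASSUMED", "O2 consumption half-saturation")

  ## -- doubling times ---------------------------------------------------
  add("doubling_time_POR-G", 38, "h", "PAPER", "doubling times of 38 h for POR-G")
  for (ln in c("POR-R", "PORko-R", "PORko-G", "HCT116")) {
    add(paste0("doubling_time_", ln), 31, "h", "PAPER",
        "31 h for the other cell lines")
  }

  if (model == "sn30000") {
    add("SN30000_D_medium", 400, "um2/s", "ASSUMED", "prodrug diffusivity, medium")
    add("SN30000_D_tissue", 100, "um2/s", "ASSUMED", "prodrug diffusivity, tissue")
    add("SN30000_K_in", 0.1, "1/s", "ASSUMED", "membrane exchange")
    add("SN30000_K_out", 0.1, "1/s", "ASSUMED", "membrane exchange")
    add("K_met0_SN30000_HCT116", 1.88, "1/min", "PAPER",
        "SN30000 metabolism (K_met, 0) in parental HCT116 cells (1.88 min-1)")
    add("K_met0_SN30000_PORko-G", 1.3, "1/min", "FITTED",
        "adjusted to 1.3 min-1 for PORko-G targets")
    add("K_met0_SN30000_POR-R", 14, "1/min", "FITTED",
        "and 14 min-1 for POR-R activators")
    add("K_O2_SN30000", 1.2, "uM", "ASSUMED",
        "half-maximal O2 inhibition of SN30000 metabolism; only the PR104A value is printed")
    add("K_c_SN30000", 1.0, "1/mM", "FITTED",
        "placeholder potency; calibrated from monolayer survival curves")
    add("radical_k_convert", 1, "1/s", "ASSUMED",
        "fast conversion of the free radical to the inert oxide pool")
    add("oxide_D_medium", 400, "um2/s", "ASSUMED", "inert oxide pool diffusivity")
    add("oxide_D_tissue", 100, "um2/s", "ASSUMED", "inert oxide pool diffusivity")
    add("oxide_K_in", 0.1, "1/s", "ASSUMED", "membrane exchange")
    add("oxide_K_out", 0.1, "1/s", "ASSUMED", "membrane exchange")
  } else {
    add("PR104A_D_medium", 400, "um2/s", "ASSUMED", "prodrug diffusivity, medium")
    add("PR104A_D_tissue", 100, "um2/s", "ASSUMED", "prodrug diffusivity, tissue")
    add("PR104A_K_in", 0.2, "1/s", "ASSUMED", "membrane exchange")
    add("PR104A_K_out", 0.2, "1/s", "ASSUMED", "membrane exchange")
    add("K_O2_PR104A", 0.126, "uM", "PAPER", "(K_O2 = 0.126 uM)")
    add("K_met0_PR104A_POR-G", 9.3, "1/min", "FITTED",
        "calibrated so the monolayer IC90 of pure activators is ~1 uM")
    add("K_met0_PR104A_PORko-R", 0.13, "1/min", "FITTED",
        "calibrated so the monolayer IC90 of pure targets is ~17 uM")
    add("PR104HM_D_medium", 400, "um2/s", "ASSUMED", "metabolite 1 diffusivity")
    add("PR104HM_D_tissue", 100, "um2/s", "ASSUMED", "metabolite 1 diffusivity")
    add("PR104HM_K_in", 0.003, "1/s", "ASSUMED", "metabolite 1 membrane exchange")
    add("PR104HM_K_out", 0.003, "1/s", "ASSUMED", "metabolite 1 membrane exchange")
    add("PR104HM_k_loss_cell", 1e-3, "1/s", "ASSUMED",
        "intracellular reactions of the Br/mesylate mustards")
    add("PR104HM_k_decay_medium", 5e-4, "1/s", "ASSUMED",
        "instability of PR104H in medium (t1/2 ~ 23 min)")
    add("K_c_PR104HM", 0.092, "1/mM/s", "PAPER", "(0.092 mM-1s-1 for PR104H)")
    if (model == "pr104a_dichloro") {
      add("PR104HM_k_convert", 1e-3, "1/s", "ASSUMED",
          "chloride displacement of the mustard leaving groups")
      add("dichloro_D_medium", 400, "um2/s", "ASSUMED", "metabolite 2 diffusivity")
      add("dichloro_D_tissue", 150, "um2/s", "ASSUMED",
          "greater tissue diffusion range of the dichloro mustards")
      add("dichloro_K_in", 0.1, "1/s", "ASSUMED",
          "lipophilic partitioning (K_in/K_out = 2)")
      add("dichloro_K_out", 0.05, "1/s", "ASSUMED",
          "lipophilic partitioning (K_in/K_out = 2)")
      add("dichloro_k_loss_cell", 5e-4, "1/s", "ASSUMED",
          "fourfold longer half-life than PR104H")
      add("dichloro_k_decay_medium", 1.25e-4, "1/s", "ASSUMED",
          "fourfold longer half-life than PR104H")
      add("K_c_dichloro", 0.05, "1/mM/s", "PAPER",
          "Fitting the potency parameter K_c for metabolite 2 gave an estimate of 0.05 mM-1s-1")
    }
  }

  df <- do.call(rbind, rows)
  parameter_registry(df$name, df$value, df$units, df$provenance, df$cite)
}
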