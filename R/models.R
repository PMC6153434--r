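#' Build a prodrug model from a registry
#'
#' Instantiates the solute chain and kill model(s) of one of the three
#' HAP pharmacology models:
#' \describe{
#'   \item{`sn30000`}{"no bystander" model: SN30000 -> intracellular
#'     free radical (non-diffusing, cytotoxic via the metabolism-rate
#'     kill law) -> inert diffusible 1-oxide/nor-oxide pool.}
#'   \item{`pr104a_hm`}{PR104A -> PR104H+M (lumped metabolite 1,
#'     diffusible, concentration kill law) -> untracked products.}
#'   \item{`pr104a_dichloro`}{PR104A -> PR104H+M -> Metabolites A+B
#'     (lumped dichloro mustards, more stable and lipophilic), both
#'     metabolite classes cytotoxic with independent concentration kill
#'     laws combined multiplicatively on survival.}
#' }
#'
#' @param model model name.
#' @param registry a `hap_registry`; defaults to
#'   [default_registry()] for the model.
#' @return object of class `hap_prodrug_model`: list with `name`,
#'   `prodrug` (name of the administered species), `solutes` (named
#'   list of [solute_spec()]), `kill_models` (list of [kill_model()]),
#'   `registry`.
#' @export
prodrug_model <- function(model = c("sn30000", "pr104a_hm", "pr104a_dichloro"),
                          registry = NULL) {
  model <- match.arg(model)
  reg <- registry %||% default_registry(model)
  g <- function(nm) registry_get(reg, nm)

  if (model == "sn30000") {
    solutes <- list(
      SN30000 = solute_spec("SN30000",
        D_medium = g("SN30000_D_medium"), D_tissue = g("SN30000_D_tissue"),
        K_in = g("SN30000_K_in"), K_out = g("SN30000_K_out"),
        child = "radical"),
      radical = solute_spec("radical", D_medium = 0, D_tissue = 0,
        K_in = 0, K_out = 0, k_convert = g("radical_k_convert"),
        child = "oxide", diffusible = FALSE),
      oxide = solute_spec("oxide",
        D_medium = g("oxide_D_medium"), D_tissue = g("oxide_D_tissue"),
        K_in = g("oxide_K_in"), K_out = g("oxide_K_out"))
    )
    kills <- list(kill_model("metabolism_rate", K_c = g("K_c_SN30000"),
                             acts_on = "SN30000", label = "SN30000 radical"))
  } else if (model == "pr104a_hm") {
    solutes <- list(
      PR104A = solute_spec("PR104A",
        D_medium = g("PR104A_D_medium"), D_tissue = g("PR104A_D_tissue"),
        K_in = g("PR104A_K_in"), K_out = g("PR104A_K_out"),
        child = "PR104HM"),
      PR104HM = solute_spec("PR104HM",
        D_medium = g("PR104HM_D_medium"), D_tissue = g("PR104HM_D_tissue"),
        K_in = g("PR104HM_K_in"), K_out = g("PR104HM_K_out"),
        k_loss_cell = g("PR104HM_k_loss_cell"),
        k_decay_medium = g("PR104HM_k_decay_medium"))
    )
    kills <- list(kill_model("concentration", K_c = g("K_c_PR104HM"),
                             acts_on = "PR104HM", label = "PR104H+M"))
  } else {
    solutes <- list(
      PR104A = solute_spec("PR104A",
        D_medium = g("PR104A_D_medium"), D_tissue = g("PR104A_D_tissue"),
        K_in = g("PR104A_K_in"), K_out = g("PR104A_K_out"),
        child = "PR104HM"),
      PR104HM = solute_spec("PR104HM",
        D_medium = g("PR104HM_D_medium"), D_tissue = g("PR104HM_D_tissue"),
        K_in = g("PR104HM_K_in"), K_out = g("PR104HM_K_out"),
        k_convert = g("PR104HM_k_convert"),
        k_loss_cell = g("PR104HM_k_loss_cell"),
        k_decay_medium = g("PR104HM_k_decay_medium"),
        child = "dichloro"),
      dichloro = solute_spec("dichloro",
        D_medium = g("dichloro_D_medium"), D_tissue = g("dichloro_D_tissue"),
        K_in = g("dichloro_K_in"), K_out = g("dichloro_K_out"),
        k_loss_cell = g("dichloro_k_loss_cell"),
        k_decay_medium = g("dichloro_k_decay_medium"))
    )
    kills <- list(
      kill_model("concentration", K_c = g("K_c_PR104HM"),
                 acts_on = "PR104HM", label = "PR104H+M"),
      kill_model("concentration", K_c = g("K_c_dichloro"),
                 acts_on = "dichloro", label = "Metabolites A+B")
    )
  }
  validate_chain(solutes)
  # the no-bystander contract: a metabolism-rate kill law requires a
  # non-diffusing proximal cytotoxin
  for (km in kills) {
    if (km$mode == "metabolism_rate") {
      child <- solutes[[km$acts_on]]$child
      if (!is.null(child) && solutes[[child]]$diffusible) {
        stop("metabolism_rate kill law requires a non-diffusing proximal ",
             "metabolite", call. = FALSE)
      }
    }
  }
  structure(list(name = model, prodrug = names(solutes)[1],
                 solutes = solutes, kill_models = kills, registry = reg),
            class = "hap_prodrug_model")
}

#' Build the activator/target cell-line pair for a prodrug model
#'
#' SN30000 experiments use POR-R activators with PORko-G targets;
#' PR104A experiments use POR-G activators with PORko-R targets.
#'
#' @param model a `hap_prodrug_model`.
#' @param registry optional registry override (defaults to the model's).
#' @return list of two [cell_line_spec()]: `activator`, `target`.
#' @export
model_cell_lines <- function(model, registry = NULL) {
  reg <- registry %||% model$registry
  g <- function(nm) registry_get(reg, nm)
  if (model$name == "sn30000") {
    act_nm <- "POR-R"; tgt_nm <- "PORko-G"
    mk_ms <- function(line) metabolism_spec(
      K_met0 = g(paste0("K_met0_SN30000_", line)),
      K_O2 = g("K_O2_SN30000"), cell_line = line)
    act <- cell_line_spec(act_nm, "activator", g("doubling_time_POR-R") / 3600,
                          metabolism = list(SN30000 = mk_ms(act_nm)))
    tgt <- cell_line_spec(tgt_nm, "target", g("doubling_time_PORko-G") / 3600,
                          metabolism = list(SN30000 = mk_ms(tgt_nm)))
  } else {
    act_nm <- "POR-G"; tgt_nm <- "PORko-R"
    mk_ms <- function(line) metabolism_spec(
      K_met0 = g(paste0("K_met0_PR104A_", line)),
      K_O2 = g("K_O2_PR104A"), cell_line = line)
    act <- cell_line_spec(act_nm, "activator", g("doubling_time_POR-G") / 3600,
                          metabolism = list(PR104A = mk_ms(act_nm)))
    tgt <- cell_line_spec(tgt_nm, "target", g("doubling_time_PORko-R") / 3600,
                          metabolism = list(PR104A = mk_ms(tgt_nm)))
  }
  a_k <- act$metabolism[[model$prodrug]]$K_met0
  t_k <- tgt$metabolism[[model$prodrug]]$K_met0
  if (a_k <= t_k) {
    stop("activator K_met0 must exceed target K_met0 for the same prodrug",
         call. = FALSE)
  }
  list(activator = act, target = tgt)
}

#' Culture geometry
#'
#' Well/medium/lattice description for spheroid, monolayer or MCL
#' (multicellular layer) configurations. Depth and volume/area must be
#' consistent to 1%.
#'
#' @param kind `"spheroid"`, `"monolayer"` or `"mcl"`.
#' @param medium_volume medium volume (mL).
#' @param medium_depth depth of the unstirred medium column (mm).
#' @param well_area well cross-section (mm^2); default derived from
#'   volume and depth.
#' @param gas_O2 O2 concentration maintained at the medium-air
#'   interface (uM).
#' @param initial_O2 uniform O2 at t = 0 (uM).
#' @param donor_volume,receiver_volume,mcl_thickness,mcl_area MCL-only
#'   fields: compartment volumes (mL), layer thickness (um) and exposed
#'   area (mm^2).
#' @return object of class `hap_geometry`.
#' @export
culture_geometry <- function(kind = c("spheroid", "monolayer", "mcl"),
                             medium_volume = 0.2, medium_depth = 6.1,
                             well_area = NULL, gas_O2 = 0, initial_O2 = 0,
                             donor_volume = 8.5, receiver_volume = 8.5,
                             mcl_thickness = 150, mcl_area = 30) {
  kind <- match.arg(kind)
  stopifnot(medium_volume > 0, medium_depth > 0)
  # 1 mL / 1 mm of depth = 100 mm^2
  derived_area <- medium_volume * 1000 / medium_depth
  if (is.null(well_area)) well_area <- derived_area
  if (abs(well_area - derived_area) / derived_area > 0.01) {
    stop("medium_depth inconsistent with medium_volume / well_area",
         call. = FALSE)
  }
  if (kind == "mcl") stopifnot(donor_volume > 0, receiver_volume > 0,
                               mcl_thickness > 0, mcl_area > 0)
  structure(list(kind = kind, medium_volume = medium_volume,
                 medium_depth = medium_depth, well_area = well_area,
                 gas_O2 = gas_O2, initial_O2 = initial_O2,
                 donor_volume = donor_volume,
                 receiver_volume = receiver_volume,
                 mcl_thickness = mcl_thickness, mcl_area = mcl_area),
            class = "hap_geometry")
}
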