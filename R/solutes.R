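#' Solute specification
#'
#' Describes one diffusible (or deliberately non-diffusing) chemical
#' species: a prodrug, one of its metabolites, or oxygen. Rate constants
#' are first order. A metabolic chain is expressed through `child`: the
#' species into which this one is converted (stoichiometrically, 1:1).
#' Conversion of a prodrug is cell-line and oxygen dependent (see
#' [metabolism_spec()]); conversion of a downstream metabolite is
#' ordinary chemistry and uses the line-independent `k_convert`.
#'
#' @param name identifier, e.g. `"SN30000"`.
#' @param D_medium diffusivity in bulk medium (um^2/s).
#' @param D_tissue diffusivity inside spheroid/MCL tissue (um^2/s);
#'   must not exceed `D_medium`.
#' @param K_in,K_out membrane uptake/efflux rate constants (1/s, per
#'   intracellular volume). `K_in/K_out > 1` encodes lipophilic
#'   partitioning into cells.
#' @param k_decay_medium first-order loss in cell-free medium (1/s).
#' @param k_loss_cell first-order intracellular loss other than tracked
#'   conversion to `child` (1/s).
#' @param k_convert first-order intracellular conversion to `child`
#'   (1/s) for non-enzymatic steps; ignored for species with a
#'   [metabolism_spec()] attached to a cell line.
#' @param child name of the next solute in the chain, or `NULL`.
#' @param diffusible logical; `FALSE` for species confined to the cell
#'   of origin (e.g. a short-lived free radical), which then must have
#'   `K_in = K_out = 0`.
#' @return object of class `hap_solute`.
#' @export
solute_spec <- function(name, D_medium, D_tissue, K_in = 0, K_out = 0,
                        k_decay_medium = 0, k_loss_cell = 0, k_convert = 0,
                        child = NULL, diffusible = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  rates <- c(K_in = K_in, K_out = K_out, k_decay_medium = k_decay_medium,
             k_loss_cell = k_loss_cell, k_convert = k_convert)
  if (any(rates < 0)) {
    stop("all rate constants must be >= 0 for solute '", name, "'",
         call. = FALSE)
  }
  if (D_medium < 0 || D_tissue < 0) {
    stop("diffusivities must be >= 0 for solute '", name, "'", call. = FALSE)
  }
  if (D_tissue > D_medium) {
    stop("D_tissue must not exceed D_medium for solute '", name, "'",
         call. = FALSE)
  }
  if (!diffusible && (K_in > 0 || K_out > 0)) {
    stop("a non-diffusing solute must have K_in = K_out = 0 ('", name, "')",
         call. = FALSE)
  }
  structure(
    list(name = name, D_medium = D_medium, D_tissue = D_tissue,
         K_in = K_in, K_out = K_out, k_decay_medium = k_decay_medium,
         k_loss_cell = k_loss_cell, k_convert = k_convert,
         child = child, diffusible = diffusible),
    class = "hap_solute"
  )
}

#' Oxygen-dependent metabolism specification
#'
#' First-order metabolic consumption of a prodrug by one cell line:
#' anoxic rate constant `K_met0` inhibited by oxygen with
#' half-maximal-inhibition concentration `K_O2`,
#' `K_met(O2) = K_met0 * K_O2 / (K_O2 + O2)`.
#'
#' @param K_met0 anoxic rate constant (1/s internally; use
#'   [convert_units()] for printed 1/min values).
#' @param K_O2 oxygen concentration of half-maximal inhibition (uM).
#' @param cell_line identifier of the metabolizing line.
#' @return object of class `hap_metabolism`.
#' @export
metabolism_spec <- function(K_met0, K_O2, cell_line) {
  stopifnot(K_met0 >= 0, K_O2 > 0)
  structure(list(K_met0 = K_met0, K_O2 = K_O2, cell_line = cell_line),
            class = "hap_metabolism")
}

#' Kill model
#'
#' Pharmacodynamic rule converting drug exposure into a clonogenic kill
#' hazard. Two laws are supported:
#' \describe{
#'   \item{`metabolism_rate`}{hazard rate = `K_c * M'` where `M'` is the
#'     cell's instantaneous rate of prodrug metabolism (uM/s); used when
#'     the proximal cytotoxin is too short-lived to leave the cell, so
#'     killing tracks activation itself (no bystander effect).}
#'   \item{`concentration`}{hazard rate = `K_c * C_i` where `C_i` is the
#'     intracellular concentration of the cytotoxic metabolite named in
#'     `acts_on`; diffusible cytotoxins acting this way mediate
#'     bystander killing.}
#' }
#' `K_c` is stored in internal units (1/uM for `metabolism_rate`,
#' 1/uM/s for `concentration`); printed values are usually 1/mM or
#' 1/mM/s, see [convert_units()].
#'
#' @param mode `"metabolism_rate"` or `"concentration"`.
#' @param K_c potency constant (internal units as above).
#' @param acts_on solute whose formation rate (metabolism mode: the
#'   parent prodrug is metabolized into it) or concentration drives
#'   killing.
#' @param label optional display label.
#' @return object of class `hap_kill_model`.
#' @export
kill_model <- function(mode = c("metabolism_rate", "concentration"),
                       K_c, acts_on, label = acts_on) {
  mode <- match.arg(mode)
  stopifnot(K_c >= 0)
  structure(list(mode = mode, K_c = K_c, acts_on = acts_on, label = label),
            class = "hap_kill_model")
}

#' Cell line specification
#'
#' @param name identifier (e.g. `"POR-R"`, `"PORko-G"`, `"HCT116"`).
#' @param role `"activator"` or `"target"`.
#' @param doubling_time population doubling time (h).
#' @param metabolism named list mapping solute name to
#'   [metabolism_spec()] for prodrugs this line consumes.
#' @param marker selection label used to split clonogenic readouts.
#' @return object of class `hap_cell_line`.
#' @export
cell_line_spec <- function(name, role = c("activator", "target"),
                           doubling_time, metabolism = list(),
                           marker = name) {
  role <- match.arg(role)
  stopifnot(doubling_time > 0)
  structure(list(name = name, role = role, doubling_time = doubling_time,
                 metabolism = metabolism, marker = marker),
            class = "hap_cell_line")
}

# K_met (1/s) for a line/solute at local oxygen; 0 if line lacks the enzyme
.line_kmet <- function(line, solute_name, O2) {
  ms <- line$metabolism[[solute_name]]
  if (is.null(ms)) return(rep_len(0, length(O2)))
  oxygen_dependent_kmet(ms, O2)
}

#' Validate a metabolic chain of solutes
#'
#' Checks the chain formed by `child` links is acyclic with length <= 3
#' tracked conversions (Prodrug -> Metabolite 1 -> Metabolite 2 ->
#' untracked products) and that every child names a solute in the set.
#'
#' @param solutes named list of [solute_spec()] objects.
#' @return invisibly, the solute names in parent-before-child order.
#' @export
validate_chain <- function(solutes) {
  nm <- vapply(solutes, `[[`, "", "name")
  names(solutes) <- nm
  for (s in solutes) {
    if (!is.null(s$child) && !s$child %in% nm) {
      stop("child solute '", s$child, "' of '", s$name, "' not defined",
           call. = FALSE)
    }
  }
  parents <- vapply(solutes, function(s) is.null(.parent_of(solutes, s$name)),
                    TRUE)
  order <- character(0)
  for (root in nm[parents]) {
    node <- root; depth <- 0L
    while (!is.null(node)) {
      if (node %in% order) stop("metabolic chain is cyclic", call. = FALSE)
      order <- c(order, node)
      node <- solutes[[node]]$child
      depth <- depth + 1L
      if (depth > 4L) stop("metabolic chain longer than 3 conversions",
                           call. = FALSE)
    }
  }
  if (!setequal(order, nm)) stop("metabolic chain is cyclic", call. = FALSE)
  invisible(order)
}

.parent_of <- function(solutes, name) {
  for (s in solutes) if (identical(s$child, name)) return(s$name)
  NULL
}
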