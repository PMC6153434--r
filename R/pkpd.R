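#' Oxygen dependence of prodrug metabolism
#'
#' `K_met(O2) = K_met0 * K_O2 / (K_O2 + O2)`: metabolic activation is
#' maximal under anoxia and half-maximally inhibited at `O2 = K_O2`.
#'
#' @param spec a [metabolism_spec()].
#' @param O2 oxygen concentration(s), uM; must be >= 0.
#' @return first-order rate constant(s), 1/s.
#' @examples
#' ms <- metabolism_spec(convert_units(14, "1/min", "1/s"), 0.126, "POR-R")
#' convert_units(oxygen_dependent_kmet(ms, 2.5), "1/s", "1/min")
#' @export
oxygen_dependent_kmet <- function(spec, O2) {
  if (any(O2 < 0)) stop("O2 must be >= 0", call. = FALSE)
  spec$K_met0 * spec$K_O2 / (spec$K_O2 + O2)
}

#' Michaelis-Menten oxygen consumption rate
#'
#' Molar rate of cellular oxygen metabolism,
#' `rate = V_max * C / (K_m + C)`.
#'
#' @param C_O2 oxygen concentration (uM), >= 0.
#' @param V_max maximal consumption (mol cell^-1 s^-1).
#' @param K_m half-saturation oxygen concentration (uM).
#' @return consumption rate (mol cell^-1 s^-1).
#' @export
michaelis_menten_O2_rate <- function(C_O2, V_max, K_m) {
  if (any(C_O2 < 0)) stop("C_O2 must be >= 0", call. = FALSE)
  V_max * C_O2 / (K_m + C_O2)
}

#' Prodrug metabolism rate
#'
#' `M' = K_met(O2) * C_i`: the instantaneous rate at which a cell
#' converts intracellular prodrug into its proximal metabolite.
#'
#' @param C_i intracellular prodrug concentration (uM).
#' @param spec [metabolism_spec()] of the cell line for this prodrug.
#' @param O2 local oxygen (uM).
#' @return metabolism rate M' (uM/s).
#' @export
metabolism_rate <- function(C_i, spec, O2) {
  oxygen_dependent_kmet(spec, O2) * C_i
}

#' Kill hazard rate for a cell state
#'
#' Instantaneous clonogenic kill hazard (1/s) under a [kill_model()]:
#' `K_c * M'` (metabolism-rate mode) or `K_c * C` (concentration mode).
#' Survival over an exposure is `exp(-integral of hazard dt)`; the
#' discrete small-interval kill probability `P_kill = hazard * dt` is
#' the first-order expansion of `1 - exp(-hazard * dt)`.
#'
#' @param model a [kill_model()].
#' @param M_prime metabolism rate (uM/s), used in `metabolism_rate` mode.
#' @param C intracellular cytotoxin concentration (uM), used in
#'   `concentration` mode.
#' @return hazard rate(s), 1/s.
#' @export
kill_hazard_rate <- function(model, M_prime = NULL, C = NULL) {
  if (model$mode == "metabolism_rate") {
    if (is.null(M_prime)) stop("M_prime required in metabolism_rate mode",
                               call. = FALSE)
    model$K_c * M_prime
  } else {
    if (is.null(C)) stop("C required in concentration mode", call. = FALSE)
    model$K_c * C
  }
}

#' Kill probability over a finite interval
#'
#' `1 - exp(-hazard * dt)`, the exact interval-decomposable form whose
#' small-`dt` limit is the discrete rule `P_kill = K_c * (M' or C) * dt`.
#'
#' @inheritParams kill_hazard_rate
#' @param dt interval (s).
#' @return kill probability in `[0, 1]`.
#' @export
kill_probability <- function(model, dt, M_prime = NULL, C = NULL) {
  h <- kill_hazard_rate(model, M_prime = M_prime, C = C)
  1 - exp(-h * dt)
}

#' Combine kill probabilities from independent cytotoxins
#'
#' `P = 1 - (1 - P1)(1 - P2)`: survival probabilities multiply when a
#' cell is simultaneously exposed to two cytotoxic metabolites.
#'
#' @param P1,P2 kill probabilities in `[0, 1]` (vectorized).
#' @return combined kill probability.
#' @export
combine_kills <- function(P1, P2) {
  if (any(P1 < 0 | P1 > 1 | P2 < 0 | P2 > 1)) {
    stop("kill probabilities must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - P1) * (1 - P2)
}

#' Surviving fraction of a cell population
#'
#' Clonogenic surviving fraction over the viable cells of one lineage:
#' in `"expectation"` mode the mean of `exp(log_survival)`; in
#' `"bernoulli"` mode each cell survives with probability
#' `exp(log_survival)` and the realized clonogen fraction is returned.
#'
#' @param cells a cell population (as carried by a spheroid state), with
#'   fields `line`, `state` and `log_survival`.
#' @param lineage line index or name to filter on (`NULL` = all).
#' @param mode `"expectation"` or `"bernoulli"`.
#' @param seed RNG seed for `"bernoulli"` mode.
#' @param lines optional list of [cell_line_spec()] used to resolve a
#'   lineage given by name.
#' @return surviving fraction (scalar).
#' @export
surviving_fraction <- function(cells, lineage = NULL,
                               mode = c("expectation", "bernoulli"),
                               seed = NULL, lines = NULL) {
  mode <- match.arg(mode)
  keep <- cells$state == 0L
  if (!is.null(lineage)) {
    if (is.character(lineage)) {
      stopifnot(!is.null(lines))
      lineage <- which(vapply(lines, `[[`, "", "name") == lineage)
    }
    keep <- keep & cells$line == lineage
  }
  if (!any(keep)) stop("no viable cells match the lineage filter",
                       call. = FALSE)
  p <- exp(cells$log_survival[keep])
  if (mode == "expectation") return(mean(p))
  with_seed(seed, mean(stats::rbinom(length(p), 1L, p)))
}

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
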