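#' Unit handling
#'
#' All internal computation uses a single canonical unit system:
#' concentrations in uM, lengths in um, time in s, volumes in um^3 for
#' lattice bookkeeping and mL for culture compartments, amounts in
#' uM.um^3 on the lattice and umol in compartments. Configuration files
#' and constructors accept the units the experimental literature prints
#' (min^-1, mM^-1 s^-1, mm, mL, ...) and convert on entry.
#'
#' @name units
NULL

# multiplicative factor from a printed unit to the internal unit
.unit_table <- c(
  # time
  "s" = 1, "min" = 60, "h" = 3600,
  # rates
  "1/s" = 1, "1/min" = 1 / 60, "1/h" = 1 / 3600,
  # length
  "um" = 1, "mm" = 1e3, "cm" = 1e4, "m" = 1e6,
  # area
  "um2" = 1, "mm2" = 1e6, "cm2" = 1e8,
  # volume
  "um3" = 1, "mL" = 1, "uL" = 1e-3, "L" = 1e3,
  # diffusivity
  "um2/s" = 1, "cm2/s" = 1e8,
  # concentration
  "uM" = 1, "mM" = 1e3, "M" = 1e6, "nM" = 1e-3,
  # inverse concentration (kill potency, metabolism mode)
  "1/mM" = 1e-3, "1/uM" = 1,
  # inverse concentration per time (kill potency, concentration mode)
  "1/mM/s" = 1e-3, "1/uM/s" = 1, "1/mM/min" = 1e-3 / 60,
  # molar per-cell rates (oxygen consumption)
  "mol/cell/s" = 1,
  # dimensionless
  "1" = 1, "fraction" = 1, "cells" = 1
)

#' Convert a value between declared units
#'
#' Converts `value` from `from` units to `to` units. Both units must be
#' drawn from the same dimension family (the function only checks that a
#' conversion factor exists for each; dimensional consistency is the
#' caller's responsibility, as in the parameter registry where each named
#' parameter fixes its dimension).
#'
#' @param value numeric vector.
#' @param from,to unit strings, e.g. `"1/min"`, `"uM"`, `"mm"`.
#' @return numeric vector in `to` units.
#' @examples
#' convert_units(1.88, "1/min", "1/s")
#' convert_units(0.092, "1/mM/s", "1/uM/s")
#' @export
convert_units <- function(value, from, to) {
  f <- .unit_factor(from)
  t <- .unit_factor(to)
  value * (f / t)
}

.unit_factor <- function(u) {
  stopifnot(is.character(u), length(u) == 1L)
  if (!nzchar(u)) return(1)          # dimensionless
  if (!u %in% names(.unit_table)) {
    stop("unknown units: '", u, "'", call. = FALSE)
  }
  .unit_table[[u]]
}

# value in internal canonical units given its declared unit string
.to_internal <- function(value, units) value * .unit_factor(units)
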