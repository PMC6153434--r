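#' Provenance-tagged parameter registry
#'
#' Every number a simulation consumes resolves to exactly one registry
#' entry carrying its units, provenance class and citation. Provenance
#' classes: `PAPER` (printed in the source literature), `FITTED`
#' (estimated from data, here or upstream), `ASSUMED` (plausible default
#' not printed anywhere; always overridable).
#'
#' @param name,value,units,provenance,cite parallel vectors describing
#'   the entries.
#' @return object of class `hap_registry` (a data.frame).
#' @seealso [load_parameter_registry()], [registry_get()]
#' @export
parameter_registry <- function(name, value, units, provenance, cite = "") {
  stopifnot(length(name) == length(value), length(units) == length(value))
  provenance <- as.character(provenance)
  bad <- setdiff(unique(provenance), c("PAPER", "ASSUMED", "FITTED"))
  if (length(bad)) stop("unknown provenance class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (anyDuplicated(name)) {
    stop("duplicate parameter names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  }
  for (u in unique(units)) .unit_factor(u)  # reject unknown units early
  if (any(provenance == "PAPER" & !nzchar(cite))) {
    stop("PAPER entries must carry a citation", call. = FALSE)
  }
  structure(
    data.frame(name = name, value = value, units = units,
               provenance = provenance,
               cite = rep_len(cite, length(name)),
               stringsAsFactors = FALSE),
    class = c("hap_registry", "data.frame")
  )
}

#' Look up a registry entry in internal units
#'
#' @param registry a `hap_registry`.
#' @param name entry name.
#' @param internal convert to internal canonical units (default) or
#'   return the stored value as-is.
#' @return numeric scalar.
#' @export
registry_get <- function(registry, name, internal = TRUE) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("parameter '", name, "' missing from registry",
                     call. = FALSE)
  v <- registry$value[i]
  if (internal) .to_internal(v, registry$units[i]) else v
}

#' Override registry entries
#'
#' Replaces values (and optionally units/provenance) of existing entries
#' or appends new ones. Overridden entries keep their name; provenance
#' defaults to `"ASSUMED"` for overrides without an explicit class.
#'
#' @param registry a `hap_registry`.
#' @param ... named scalar values, interpreted in the entry's declared
#'   units.
#' @param provenance provenance class for the overrides.
#' @param cite citation string for the overrides.
#' @return the modified registry.
#' @export
registry_set <- function(registry, ..., provenance = "ASSUMED", cite = "") {
  vals <- list(...)
  for (nm in names(vals)) {
    i <- match(nm, registry$name)
    if (is.na(i)) stop("cannot override unknown parameter '", nm,
                       "'; add it with parameter_registry()", call. = FALSE)
    registry$value[i] <- vals[[nm]]
    registry$provenance[i] <- provenance
    registry$cite[i] <- cite
  }
  registry
}

#' Check that required entries exist
#'
#' @param registry a `hap_registry`.
#' @param names required entry names.
#' @return invisibly `TRUE`; errors listing every missing name.
#' @export
registry_require <- function(registry, names) {
  missing <- setdiff(names, registry$name)
  if (length(missing)) {
    stop("registry missing required entries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Summarize provenance of a registry
#'
#' Lists the `ASSUMED` entries (the ones a fully constrained experiment
#' must not depend on) and flags whether the registry is fully
#' constrained (only `PAPER` + `FITTED` entries).
#'
#' @param registry a `hap_registry`.
#' @return list with `assumed` (character vector) and
#'   `fully_constrained` (logical).
#' @export
registry_provenance <- function(registry) {
  assumed <- registry$name[registry$provenance == "ASSUMED"]
  list(assumed = assumed, fully_constrained = length(assumed) == 0L)
}

#' Load a parameter registry from a YAML file
#'
#' The file holds a `parameters:` map whose leaves are
#' `{value, units, provenance, cite}`; units are mandatory strings (bare
#' numbers are rejected), matching the schema written by
#' [write_parameter_registry()].
#'
#' @param path YAML file path.
#' @return a `hap_registry`.
#' @export
load_parameter_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$parameters)) stop("no 'parameters' map in ", path,
                                    call. = FALSE)
  entries <- doc$parameters
  nm <- names(entries)
  get_field <- function(e, f, nm) {
    if (is.null(e[[f]])) stop("parameter '", nm, "' lacks field '", f,
                              "' (units must be explicit)", call. = FALSE)
    e[[f]]
  }
  parameter_registry(
    name = nm,
    value = vapply(seq_along(entries),
                   function(i) as.numeric(get_field(entries[[i]], "value", nm[i])), 0),
    units = vapply(seq_along(entries),
                   function(i) as.character(get_field(entries[[i]], "units", nm[i])), ""),
    provenance = vapply(seq_along(entries), function(i)
      as.character(entries[[i]]$provenance %||% "ASSUMED"), ""),
    cite = vapply(seq_along(entries), function(i)
      as.character(entries[[i]]$cite %||% ""), "")
  )
}

#' Write a parameter registry to YAML
#'
#' @param registry a `hap_registry`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_parameter_registry <- function(registry, path) {
  entries <- lapply(seq_len(nrow(registry)), function(i) {
    list(value = registry$value[i], units = registry$units[i],
         provenance = registry$provenance[i], cite = registry$cite[i])
  })
  names(entries) <- registry$name
  yaml::write_yaml(list(parameters = entries), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
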