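#' Log-linear slope of a survival curve
#'
#' Ordinary least squares of `log10(SF)` against prodrug concentration,
#' through the origin (`SF = 1` at zero dose is exact in the forward
#' model) or with a free intercept. In the well-mixed, no-depletion
#' limit of a constant 1-h exposure the slope equals
#' `-K_c * K_met * t * log10(e)` (metabolism-rate law on intracellular
#' prodrug at equilibrium) and is the summary the linear-regression
#' fits of measured survival curves report.
#'
#' @param dose_response `DoseResponse` data.frame with `prodrug_uM`,
#'   `lineage`, and `SF` or `log10_SF` columns.
#' @param lineage lineage to fit.
#' @param intercept `"origin"` (default) or `"free"`.
#' @return list: `slope` (per uM), `se`, `intercept`, `n`.
#' @export
loglinear_slope <- function(dose_response, lineage,
                            intercept = c("origin", "free")) {
  intercept <- match.arg(intercept)
  d <- dose_response[dose_response$lineage == lineage, ]
  if (nrow(d) < 3) stop("need at least 3 points to fit a slope",
                        call. = FALSE)
  if (is.null(d$log10_SF)) d$log10_SF <- log10(d$SF)
  fit <- if (intercept == "origin") {
    stats::lm(log10_SF ~ prodrug_uM - 1, data = d)
  } else {
    stats::lm(log10_SF ~ prodrug_uM, data = d)
  }
  cf <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  i <- match("prodrug_uM", rownames(cf))
  list(slope = cf[i, 1], se = cf[i, 2],
       intercept = if (intercept == "free") cf[1, 1] else 0,
       n = nrow(d))
}

#' Fit specification for monolayer calibration
#'
#' @param free named list: parameter names (registry names) to free,
#'   each with `c(lower, upper)` bounds (finite) in the registry's
#'   declared units.
#' @param data `DoseResponse` data.frame (may contain a `replicate`
#'   column).
#' @param lineages lineage names present in `data` to fit against; each
#'   must map to one of the model's lines.
#' @param sf_floor detection floor applied to observed SF (default
#'   10^-4.5, the colony-count limit).
#' @param seed RNG seed for the multi-start optimizer.
#' @param n_starts multi-start count.
#' @return object of class `hap_fitspec`.
#' @export
fit_spec <- function(free, data, lineages = unique(data$lineage),
                     sf_floor = 10^-4.5, seed = 1L, n_starts = 5L) {
  stopifnot(length(free) >= 1, all(vapply(free, length, 0L) == 2L),
            all(is.finite(unlist(free))))
  structure(list(free = free, data = data, lineages = lineages,
                 sf_floor = sf_floor, seed = seed, n_starts = n_starts),
            class = "hap_fitspec")
}

# identifiability guard: in the no-depletion limit only K_c * K_met0 is
# identified from a single lineage's monolayer curve
.check_identifiable <- function(free, lineages) {
  nm <- names(free)
  frees_kc <- any(grepl("^K_c", nm))
  frees_kmet <- any(grepl("^K_met0", nm))
  if (frees_kc && frees_kmet && length(lineages) < 2) {
    stop("K_c and K_met0 are jointly unidentifiable from a single ",
         "lineage's monolayer curve (only their product is); supply ",
         "multi-lineage data or fix one of them", call. = FALSE)
  }
}

#' Calibrate model parameters from monolayer dose-response data
#'
#' Minimizes the sum of squared residuals on `log10(SF)` between
#' observed monolayer survival and the forward monolayer simulation
#' ([run_monolayer_assay()] runs inside the objective), over the free
#' parameters of the [fit_spec()], with bounded Nelder-Mead
#' (logit-transformed box) and seeded multi-start. Deterministic given
#' the seed.
#'
#' @param model `hap_prodrug_model` providing the starting registry.
#' @param lines line pair (see [model_cell_lines()]).
#' @param spec a [fit_spec()].
#' @param duration_h exposure duration (h).
#' @param n_nodes monolayer column nodes for the forward model (small
#'   values make fitting cheap; the well is near-well-mixed).
#' @return object of class `hap_fit`: `estimates` (named, registry
#'   units), `se` (from the residual curvature), `loss`, `convergence`,
#'   `registry` (patched, provenance `FITTED`), `trace`.
#' @export
fit_monolayer <- function(model, lines, spec, duration_h = 1,
                          n_nodes = 6) {
  stopifnot(inherits(spec, "hap_fitspec"))
  d <- spec$data
  d <- d[d$lineage %in% spec$lineages & d$prodrug_uM > 0, ]
  concs <- sort(unique(d$prodrug_uM))
  if (length(concs) < 4 ||
      (max(-log10(pmax(d$SF, spec$sf_floor))) -
         min(-log10(pmax(d$SF, spec$sf_floor)))) < 2) {
    stop("data must cover >= 4 concentrations spanning >= 2 decades of SF",
         call. = FALSE)
  }
  if (diff(range(d$SF)) < 1e-6) stop("degenerate data: SF is flat",
                                     call. = FALSE)
  .check_identifiable(spec$free, spec$lineages)

  reg0 <- model$registry
  pnames <- names(spec$free)
  registry_require(reg0, pnames)
  lo <- vapply(spec$free, `[[`, 0, 1L)
  hi <- vapply(spec$free, `[[`, 0, 2L)
  obs <- d
  obs$obs_l10 <- log10(pmax(obs$SF, spec$sf_floor))

  forward <- function(theta) {
    reg <- reg0
    for (i in seq_along(pnames)) {
      j <- match(pnames[i], reg$name)
      reg$value[j] <- theta[i]
      reg$provenance[j] <- "FITTED"
    }
    m <- prodrug_model(model$name, registry = reg)
    ll <- model_cell_lines(m, registry = reg)
    used <- Filter(function(l) l$name %in% spec$lineages,
                   ll[c("activator", "target")])
    run_monolayer_assay(
      m, used, n_nodes = n_nodes,
      protocol = exposure_protocol(concs, duration_h = duration_h,
                                   mixing_ratios = 0))
  }
  objective <- function(theta) {
    pred <- try(forward(theta), silent = TRUE)
    if (inherits(pred, "try-error")) return(1e6)
    key <- paste(pred$lineage, pred$prodrug_uM)
    pl10 <- log10(pmax(pred$SF, spec$sf_floor))[
      match(paste(obs$lineage, obs$prodrug_uM), key)]
    sum((obs$obs_l10 - pl10)^2)
  }

  # box-constrained Nelder-Mead on a logit scale, seeded multi-start
  to_box <- function(z) lo + (hi - lo) / (1 + exp(-z))
  from_box <- function(x) stats::qlogis(pmin(pmax((x - lo) / (hi - lo),
                                                  1e-6), 1 - 1e-6))
  start0 <- vapply(pnames, function(nm) reg0$value[match(nm, reg0$name)], 0)
  start0 <- pmin(pmax(start0, lo + 1e-9), hi - 1e-9)
  starts <- with_seed(spec$seed, {
    s <- list(from_box(start0))
    for (i in seq_len(spec$n_starts - 1L)) {
      s[[i + 1L]] <- from_box(lo + stats::runif(length(lo)) * (hi - lo))
    }
    s
  })
  best <- NULL
  trace <- list()
  for (st in starts) {
    fit <- if (length(pnames) == 1L) {
      o <- stats::optimize(function(z) objective(to_box(z)),
                           interval = from_box(c(lo + 1e-9, hi - 1e-9)),
                           tol = 1e-4)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(st, function(z) objective(to_box(z)),
                   method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-9))
    }
    trace[[length(trace) + 1L]] <- c(fit$par, loss = fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("calibration failed to converge; trace attached", call. = FALSE)
  }
  est <- to_box(best$par)
  names(est) <- pnames

  # approximate SEs from the curvature of the residual surface
  se <- rep(NA_real_, length(est))
  n_obs <- nrow(obs)
  sigma2 <- best$value / max(n_obs - length(est), 1)
  for (i in seq_along(est)) {
    h <- pmax(abs(est[i]) * 1e-3, 1e-9)
    th_p <- est; th_p[i] <- min(est[i] + h, hi[i])
    th_m <- est; th_m[i] <- max(est[i] - h, lo[i])
    d2 <- (objective(th_p) - 2 * best$value + objective(th_m)) /
      ((th_p[i] - est[i]) * (est[i] - th_m[i]))
    if (is.finite(d2) && d2 > 0) se[i] <- sqrt(2 * sigma2 / d2)
  }
  names(se) <- pnames

  reg_out <- reg0
  for (i in seq_along(pnames)) {
    j <- match(pnames[i], reg_out$name)
    reg_out$value[j] <- est[i]
    reg_out$provenance[j] <- "FITTED"
    reg_out$cite[j] <- "fit_monolayer()"
  }
  structure(list(estimates = est, se = se, loss = best$value,
                 convergence = best$convergence %||% 0L,
                 registry = reg_out, trace = trace),
            class = "hap_fit")
}
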