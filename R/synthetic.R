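#' Replicate-noise model for synthetic datasets
#'
#' Clonogenic surviving fractions scatter multiplicatively between
#' replicate experiments, so synthetic SF replicates draw lognormal
#' noise with coefficient of variation `sf_cv` (mean-corrected, so the
#' expectation equals the forward-model SF); values below the
#' colony-count detection floor are censored. Diffusion-assay time
#' courses receive additive Gaussian noise scaled to the donor bolus.
#'
#' @param sf_cv lognormal CV on SF (default 0.15).
#' @param counting_floor minimum detectable SF (default 10^-4.5).
#' @param timecourse_noise additive SD as a fraction of the initial
#'   donor concentration (default 0.02).
#' @param seed RNG seed.
#' @return object of class `hap_noise`.
#' @export
noise_model <- function(sf_cv = 0.15, counting_floor = 10^-4.5,
                        timecourse_noise = 0.02, seed = 1L) {
  stopifnot(sf_cv >= 0, counting_floor > 0, counting_floor < 1,
            timecourse_noise >= 0)
  structure(list(sf_cv = sf_cv, counting_floor = counting_floor,
                 timecourse_noise = timecourse_noise, seed = seed),
            class = "hap_noise")
}

#' Generate a synthetic monolayer dose-response dataset
#'
#' Runs the forward monolayer model at the true parameters, then applies
#' mean-corrected lognormal replicate noise and the detection floor. The
#' true parameter values are embedded in the result (and written as
#' header comments by [write_dose_response()]) so recovery studies are
#' self-scoring.
#'
#' @param model `hap_prodrug_model` holding the true parameters.
#' @param lines line pair (or single line in a list).
#' @param protocol an [exposure_protocol()].
#' @param noise a [noise_model()].
#' @param n_replicates replicates per concentration.
#' @param ... passed to [run_monolayer_assay()].
#' @return `DoseResponse` data.frame with `prodrug_uM`, `lineage`,
#'   `SF`, `log10_SF`, `replicate`, `censored`; attribute
#'   `true_parameters` (named vector, registry units) and `seed`.
#' @export
synth_dose_response <- function(model, lines, protocol,
                                noise = noise_model(), n_replicates = 3,
                                ...) {
  base <- run_monolayer_assay(model, lines, protocol, ...)
  sigma <- sqrt(log(1 + noise$sf_cv^2))
  out <- with_seed(noise$seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      d <- base
      z <- stats::rnorm(nrow(d))
      d$SF <- d$SF * exp(sigma * z - sigma^2 / 2)
      d$replicate <- r
      d
    })
    do.call(rbind, reps)
  })
  out$censored <- out$SF < noise$counting_floor
  out$SF <- pmax(out$SF, noise$counting_floor)
  out$log10_SF <- log10(out$SF)
  attr(out, "true_parameters") <- stats::setNames(
    model$registry$value, model$registry$name)
  attr(out, "seed") <- noise$seed
  class(out) <- c("hap_dose_response", "data.frame")
  out
}

#' Generate a synthetic MCL diffusion time course
#'
#' Forward-simulates the MCL assay, applies additive measurement noise
#' and the 100-uL sampling-volume depletion of each draw: every sampled
#' time point removes `sample_volume_mL` from donor and receiver, which
#' reduces the compartment amounts for later draws.
#'
#' @param model `hap_prodrug_model`.
#' @param lines line pair.
#' @param activator_fraction slab activator fraction.
#' @param sample_times_s sampling times (s).
#' @param noise a [noise_model()].
#' @param sample_volume_mL medium removed per draw per compartment.
#' @param donor_bolus donor prodrug bolus (uM).
#' @param ... passed to [simulate_mcl()].
#' @return data.frame: `t_s`, `compartment`, `solute`,
#'   `concentration_uM`, `amount_umol`, `volume_mL`, `clipped`;
#'   attributes `true_parameters`, `seed`.
#' @export
synth_mcl_timecourse <- function(model, lines, activator_fraction,
                                 sample_times_s = seq(1800, 5 * 3600, 1800),
                                 noise = noise_model(),
                                 sample_volume_mL = 0.1,
                                 donor_bolus = NULL, ...) {
  donor_bolus <- donor_bolus %||%
    registry_get(model$registry, "mcl_donor_bolus")
  sim <- simulate_mcl(model, lines, activator_fraction,
                      donor_bolus = donor_bolus,
                      duration = max(sample_times_s),
                      times = c(0, sample_times_s), ...)
  tc <- sim$timecourse
  tc <- tc[tc$t_s > 0, ]
  v0 <- registry_get(model$registry, "mcl_compartment_volume")
  draws <- match(tc$t_s, sort(unique(tc$t_s)))   # draw number per row
  tc$volume_mL <- v0 - (draws - 1) * sample_volume_mL
  if (any(tc$volume_mL <= 0)) {
    stop("sampling schedule exhausts the compartment volume", call. = FALSE)
  }
  sd_abs <- noise$timecourse_noise * donor_bolus
  tc <- with_seed(noise$seed, {
    tc$concentration_uM <- tc$concentration_uM +
      stats::rnorm(nrow(tc), sd = sd_abs)
    tc
  })
  tc$clipped <- tc$concentration_uM < 0
  tc$concentration_uM[tc$clipped] <- 0
  # amounts reflect both noise and the depleted volumes
  tc$amount_umol <- tc$concentration_uM * tc$volume_mL * 1e-3
  attr(tc, "true_parameters") <- stats::setNames(
    model$registry$value, model$registry$name)
  attr(tc, "seed") <- noise$seed
  tc
}

#' Write a dose-response table with its true-parameter manifest
#'
#' CSV with `# name = value` header comments carrying the generating
#' parameters, readable back with [read_dose_response()].
#'
#' @param dr a `DoseResponse` (e.g. from [synth_dose_response()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dose_response <- function(dr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tp <- attr(dr, "true_parameters")
  if (!is.null(tp)) {
    writeLines(sprintf("# true %s = %.10g", names(tp), tp), con)
  }
  utils::write.csv(as.data.frame(dr), con, row.names = FALSE)
  invisible(path)
}

#' Read a dose-response table written by [write_dose_response()]
#'
#' @param path CSV file.
#' @return `DoseResponse` data.frame with a `true_parameters` attribute
#'   when the manifest header is present.
#' @export
read_dose_response <- function(path) {
  lines_all <- readLines(path)
  hdr <- grep("^# true ", lines_all, value = TRUE)
  body <- lines_all[!startsWith(lines_all, "#")]
  d <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (length(hdr)) {
    nm <- sub("^# true ([^=]+) = .*$", "\\1", hdr)
    val <- as.numeric(sub("^.*= ", "", hdr))
    attr(d, "true_parameters") <- stats::setNames(val, trimws(nm))
  }
  class(d) <- c("hap_dose_response", "data.frame")
  d
}
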