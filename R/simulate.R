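#' Generative profile for one genotype/cell/temperature condition
#'
#' Describes the stochastic world the analysis assumes: each cell pair
#' carries a latent polarity state drawn from `(p_normal, p_reversed,
#' p_symmetric)`; its true log intensity ratio is the depth-attenuation
#' trend (`attenuation_intercept + attenuation_slope * z`) plus a state
#' offset (`+effect_size`, `-effect_size`, or 0) plus Gaussian noise of SD
#' `noise_sd` on the log scale.  Defaults mirror the published wild-type
#' calibration: slope -0.034 per micrometre, intercept 0.0148, residual SD
#' 0.0613 (log10 scale).  Focal-plane distances default to uniform(-3, 3)
#' micrometres, spanning the regression's working range.  Distal
#' intensities are log-normal around 100 arbitrary units; only ratios
#' matter downstream, so the scale is arbitrary.
#'
#' @param genotype genotype label.
#' @param cell `"Z1"` or `"Z4"`.
#' @param temperature_c rearing temperature, a grouping key.
#' @param p_normal,p_reversed,p_symmetric latent-state mixture; must sum
#'   to 1.  Default is fully symmetric (a control-like condition).
#' @param effect_size mean |true log ratio| of polarized states.
#' @param effect_jitter_sd optional SD of a normal jitter on the effect
#'   size, modelling biological variability; default 0 (fixed offset).
#' @param noise_sd residual SD on the log-ratio scale (> 0).
#' @param attenuation_slope,attenuation_intercept depth trend parameters.
#' @param z_distribution `list(kind = "uniform", lo, hi)` or
#'   `list(kind = "normal", mu, sd)` for the focal-plane distances.
#' @param intensity_meanlog,intensity_sdlog log-normal parameters for the
#'   distal intensity draw (natural-log scale).
#' @param dtc_outcome_probs optional named probabilities over
#'   `both_present`, `anterior_missing`, `posterior_missing`,
#'   `both_missing`, `dpd`, summing to 1; required by
#'   [simulate_phenotype_table()].
#' @param log_base log base tying the simulation to the analysis scale.
#' @return an object of class `genotype_profile`.
#' @export
genotype_profile <- function(genotype, cell = "Z1", temperature_c = 22.5,
                             p_normal = 0, p_reversed = 0, p_symmetric = 1,
                             effect_size = 0.4, effect_jitter_sd = 0,
                             noise_sd = 0.0613,
                             attenuation_slope = -0.034,
                             attenuation_intercept = 0.0148,
                             z_distribution = list(kind = "uniform",
                                                   lo = -3, hi = 3),
                             intensity_meanlog = log(100),
                             intensity_sdlog = 0.25,
                             dtc_outcome_probs = NULL,
                             log_base = 10) {
  p <- c(p_normal, p_reversed, p_symmetric)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("state probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (!cell %in% .pola_cells) stop("unknown cell label", call. = FALSE)
  if (!z_distribution$kind %in% c("uniform", "normal")) {
    stop("z_distribution kind must be 'uniform' or 'normal'", call. = FALSE)
  }
  if (!is.null(dtc_outcome_probs)) {
    if (!all(.pola_outcomes %in% names(dtc_outcome_probs)) ||
        any(dtc_outcome_probs < 0) ||
        abs(sum(dtc_outcome_probs) - 1) > 1e-8) {
      stop("dtc_outcome_probs must name ",
           paste(.pola_outcomes, collapse = ", "), " and sum to 1",
           call. = FALSE)
    }
    dtc_outcome_probs <- dtc_outcome_probs[.pola_outcomes]
  }
  structure(list(genotype = genotype, cell = cell,
                 temperature_c = temperature_c,
                 p_normal = p_normal, p_reversed = p_reversed,
                 p_symmetric = p_symmetric,
                 effect_size = effect_size,
                 effect_jitter_sd = effect_jitter_sd,
                 noise_sd = noise_sd,
                 attenuation_slope = attenuation_slope,
                 attenuation_intercept = attenuation_intercept,
                 z_distribution = z_distribution,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 dtc_outcome_probs = dtc_outcome_probs,
                 log_base = log_base),
            class = "genotype_profile")
}

.draw_z <- function(n, zd) {
  switch(zd$kind,
         uniform = runif(n, zd$lo, zd$hi),
         normal = rnorm(n, zd$mu, zd$sd))
}

# turn true log ratios into an intensity pair: draw the distal intensity,
# set the proximal one to match the ratio exactly
.emit_measurements <- function(profile, z, y, reporter) {
  n <- length(z)
  distal <- rlnorm(n, profile$intensity_meanlog, profile$intensity_sdlog)
  proximal <- distal * profile$log_base^y
  data.frame(
    animal_id = sprintf("sim%05d", seq_len(n)),
    genotype = profile$genotype,
    temperature_c = profile$temperature_c,
    cell = profile$cell,
    reporter = reporter,
    intensity_proximal = proximal,
    intensity_distal = distal,
    z_distance_um = z,
    stringsAsFactors = FALSE)
}

#' Simulate symmetric-control cell pairs
#'
#' Draws `n` control-reporter pairs whose true log ratio is the depth
#' trend plus Gaussian noise — the world in which the calibration's
#' assumptions hold exactly.  Deterministic given `seed`; the caller's RNG
#' state is untouched.
#'
#' @param n number of cell pairs (>= 1).
#' @param profile a [genotype_profile()] (its mixture is ignored; controls
#'   are symmetric by construction).
#' @param seed integer seed.
#' @return a measurement `data.frame` with `reporter = "control_nls"`.
#' @export
simulate_control <- function(n, profile, seed = NULL) {
  stopifnot(inherits(profile, "genotype_profile"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  with_seed(seed, {
    z <- .draw_z(n, profile$z_distribution)
    y <- profile$attenuation_intercept + profile$attenuation_slope * z +
      rnorm(n, 0, profile$noise_sd)
    .emit_measurements(profile, z, y, "control_nls")
  })
}

#' Simulate polarity-reporter cell pairs with latent truth
#'
#' Each pair draws a latent state from the profile's mixture; its true
#' residual component is `+effect_size` (normal), `-effect_size`
#' (reversed), or 0 (symmetric), optionally jittered, on top of the same
#' depth trend and noise as the controls.  The latent truth travels in a
#' sidecar `data.frame` attached as `attr(x, "truth")` (and writable via
#' [write_truth()]) so the pipeline under test cannot accidentally read
#' the labels from the measurement table itself.
#'
#' @inheritParams simulate_control
#' @param reporter reporter label to emit; default `"pop1"`.
#' @return a measurement `data.frame`; `attr(, "truth")` holds
#'   `animal_id`, `true_class`, `true_effect`.
#' @export
simulate_reporter <- function(n, profile, seed = NULL, reporter = "pop1") {
  stopifnot(inherits(profile, "genotype_profile"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!reporter %in% setdiff(.pola_reporters, "control_nls")) {
    stop("reporter must be one of: ",
         paste(setdiff(.pola_reporters, "control_nls"), collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    states <- sample(c("normal", "reversed", "symmetric"), n, replace = TRUE,
                     prob = c(profile$p_normal, profile$p_reversed,
                              profile$p_symmetric))
    eff <- profile$effect_size
    if (profile$effect_jitter_sd > 0) {
      eff <- pmax(0, rnorm(n, eff, profile$effect_jitter_sd))
    }
    offset <- ifelse(states == "normal", eff,
                     ifelse(states == "reversed", -eff, 0))
    z <- .draw_z(n, profile$z_distribution)
    y <- profile$attenuation_intercept + profile$attenuation_slope * z +
      offset + rnorm(n, 0, profile$noise_sd)
    out <- .emit_measurements(profile, z, y, reporter)
    attr(out, "truth") <- data.frame(animal_id = out$animal_id,
                                     true_class = states,
                                     true_effect = offset,
                                     stringsAsFactors = FALSE)
    out
  })
}

#' @rdname simulate_reporter
#' @param x a simulated measurement table carrying a `"truth"` attribute.
#' @param path output CSV path for the truth sidecar.
#' @export
write_truth <- function(x, path) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stop("no truth sidecar attached", call. = FALSE)
  write.table(truth, path, sep = ",", row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Simulate a phenotype penetrance table
#'
#' Draws per-genotype outcome counts from each profile's
#' `dtc_outcome_probs` (a multinomial over both-present /
#' anterior-missing / posterior-missing / both-missing / double-posterior)
#' and tallies missing-phenotype penetrance per region.  Animals with the
#' double-posterior phenotype are counted as having both cells present,
#' matching the published scoring convention.
#'
#' @param profiles list of [genotype_profile()]s, each with
#'   `dtc_outcome_probs`.
#' @param n_per_genotype animals scored per genotype.
#' @param seed integer seed.
#' @return a phenotype `data.frame` with columns `genotype`, `region`,
#'   `pct_missing` (rounded to one decimal, as printed tables are), `n`,
#'   and the true `count_missing`.
#' @export
simulate_phenotype_table <- function(profiles, n_per_genotype, seed = NULL) {
  if (inherits(profiles, "genotype_profile")) profiles <- list(profiles)
  n_per_genotype <- as.integer(n_per_genotype)
  if (n_per_genotype < 1L) stop("n_per_genotype must be >= 1", call. = FALSE)
  for (p in profiles) {
    stopifnot(inherits(p, "genotype_profile"))
    if (is.null(p$dtc_outcome_probs)) {
      stop("profile '", p$genotype, "' has no dtc_outcome_probs",
           call. = FALSE)
    }
  }
  with_seed(seed, {
    rows <- lapply(profiles, function(p) {
      cts <- drop(rmultinom(1, n_per_genotype, p$dtc_outcome_probs))
      names(cts) <- .pola_outcomes
      # dpd counts as both DTCs present
      miss <- c(anterior = cts[["anterior_missing"]] + cts[["both_missing"]],
                posterior = cts[["posterior_missing"]] + cts[["both_missing"]])
      data.frame(genotype = p$genotype,
                 region = .pola_regions,
                 pct_missing = round(100 * miss / n_per_genotype, 1),
                 n = n_per_genotype,
                 count_missing = as.integer(miss),
                 stringsAsFactors = FALSE)
    })
    validate_phenotype_table(do.call(rbind, rows))
  })
}
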