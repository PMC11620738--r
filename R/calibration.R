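#' Two-sided Student-t critical value
#'
#' Returns the `1 - alpha/2` quantile of Student's t distribution, the
#' half-width multiplier of the symmetric `(1 - alpha)` confidence band.
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha two-sided tail mass, in (0, 1); default 0.05.
#' @return positive scalar.
#' @examples
#' t_critical(95)        # ~1.9853
#' @export
t_critical <- function(df, alpha = 0.05) {
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  qt(1 - alpha / 2, df = df)
}

#' Construct a depth-attenuation calibration model
#'
#' Bundles the fitted (or published) regression of control-reporter log
#' ratio on focal-plane distance with the constant confidence band used
#' for classification.  The band half-width is `v_upper = t_crit *
#' residual_se` with `t_crit` the two-sided `(1 - alpha)` Student-t
#' quantile at `df = n - 2`; `v_lower = -v_upper`.  Note the band uses one
#' SE for all distances (no leverage term): it is a constant band around
#' the line, which is exactly how the classification bounds are defined.
#'
#' @param slope,intercept regression coefficients (log-ratio units per
#'   distance unit; log-ratio units).
#' @param residual_se residual standard error, `sqrt(SSR / (n - 2))`.
#' @param n number of control pairs the calibration is based on (>= 3).
#' @param alpha band tail mass, default 0.05 (a 95% band).
#' @param log_base logarithm base the calibration was computed on.
#' @return an object of class `calibration_model`: a list with fields
#'   `slope`, `intercept`, `residual_se`, `n`, `df`, `t_crit`, `v_upper`,
#'   `v_lower`, `alpha`, `log_base`.
#' @examples
#' # the published wild-type control calibration (n = 97)
#' calibration_model(-0.034, 0.0148, 0.0613, n = 97)
#' @export
calibration_model <- function(slope, intercept, residual_se, n,
                              alpha = 0.05, log_base = 10) {
  n <- as.integer(n)
  if (n < 3L) stop("calibration needs n >= 3", call. = FALSE)
  if (residual_se < 0) stop("residual_se must be >= 0", call. = FALSE)
  df <- n - 2L
  t_crit <- t_critical(df, alpha)
  v_upper <- t_crit * residual_se
  structure(list(slope = slope, intercept = intercept,
                 residual_se = residual_se, n = n, df = df,
                 t_crit = t_crit, v_upper = v_upper, v_lower = -v_upper,
                 alpha = alpha, log_base = log_base),
            class = "calibration_model")
}

#' Fit the depth-attenuation regression on symmetric-control measurements
#'
#' Ordinary least squares of `y = log_ratio` on `x = z_distance_um` over
#' control-reporter cell pairs.  Because the control reporter is expressed
#' equally in both daughters, any systematic trend of its log ratio with
#' the focal-plane distance measures depth-dependent signal attenuation;
#' the residual scatter around the line sets the width of the
#' classification band.
#'
#' @param control a measurement `data.frame`; every row must have
#'   `reporter == "control_nls"`.
#' @param alpha band tail mass, default 0.05.
#' @param log_base logarithm base for the ratio, default 10.
#' @return a [calibration_model()] with `residual_se = sqrt(SSR / (n - 2))`.
#' @examples
#' ctl <- simulate_control(200, genotype_profile("N2"), seed = 7)
#' fit_depth_regression(ctl)
#' @export
fit_depth_regression <- function(control, alpha = 0.05, log_base = 10) {
  control <- validate_measurements(control, action = "error")
  if (nrow(control) < 3L) {
    stop("insufficient data: calibration needs at least 3 control pairs",
         call. = FALSE)
  }
  if (any(control$reporter != "control_nls")) {
    stop("input mix: calibration input must contain only control_nls ",
         "reporter measurements", call. = FALSE)
  }
  x <- control$z_distance_um
  if (length(unique(x)) < 2L) {
    stop("degenerate design: all z_distance_um values identical",
         call. = FALSE)
  }
  y <- log_ratio(control, base = log_base)
  fit <- lm(y ~ x)
  ssr <- sum(fit$residuals^2)
  n <- length(y)
  calibration_model(slope = unname(coef(fit)[2L]),
                    intercept = unname(coef(fit)[1L]),
                    residual_se = sqrt(ssr / (n - 2L)),
                    n = n, alpha = alpha, log_base = log_base)
}

#' Predicted log ratio at a focal-plane distance
#'
#' The theoretical log ratio of a symmetrically expressed reporter whose
#' daughters sit `z` distance units apart: `intercept + slope * z`.
#'
#' @param model a [calibration_model()].
#' @param z signed focal-plane distance(s), proximal minus distal.
#' @return numeric vector of predictions.
#' @export
predict_log_ratio <- function(model, z) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(!is.finite(z))) stop("z must be finite", call. = FALSE)
  model$intercept + model$slope * z
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Depth-attenuation calibration (log base", x$log_base, ")\n")
  cat(sprintf("  y-hat = %.6g + %.6g * z   (n = %d, df = %d)\n",
              x$intercept, x$slope, x$n, x$df))
  cat(sprintf("  residual SE = %.6g; t(%.3g%%, df) = %.6g\n",
              x$residual_se, 100 * (1 - x$alpha), x$t_crit))
  cat(sprintf("  band half-width v_upper = %.6g (v_lower = %.6g)\n",
              x$v_upper, x$v_lower))
  invisible(x)
}

.calibration_fields <- c("slope", "intercept", "residual_se", "n", "df",
                         "t_crit", "v_upper", "v_lower", "alpha", "log_base")

#' Store and reload a calibration model as key-value text
#'
#' So classification runs can reuse a stored calibration.  The file holds
#' one `key = value` pair per line, full double precision.
#'
#' @param model a [calibration_model()].
#' @param path text file path.
#' @return `write_calibration`: `path`, invisibly.  `read_calibration`:
#'   the reconstructed model (derived fields recomputed and checked).
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  vals <- vapply(model[.calibration_fields], function(v)
    format(v, digits = 17, scientific = FALSE), character(1))
  writeLines(paste(.calibration_fields, "=", vals), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2L)))
  need <- c("slope", "intercept", "residual_se", "n", "alpha", "log_base")
  if (!all(need %in% keys)) {
    stop("calibration file is missing field(s): ",
         paste(setdiff(need, keys), collapse = ", "), call. = FALSE)
  }
  v <- setNames(vals, keys)
  calibration_model(v[["slope"]], v[["intercept"]], v[["residual_se"]],
                    n = v[["n"]], alpha = v[["alpha"]],
                    log_base = v[["log_base"]])
}
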