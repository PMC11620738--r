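#' Score reporter measurements against a calibration
#'
#' Reduces each cell pair to its depth-corrected residual
#' `r = y - y_hat`, where `y` is the observed log intensity ratio and
#' `y_hat` the calibration prediction at the pair's focal-plane distance,
#' then classifies:
#' \describe{
#'   \item{signed_class}{`"normal"` if `r > v_upper`, `"reversed"` if
#'     `r < v_lower`, `"symmetric"` otherwise.  Ties on the boundary are
#'     symmetric (the rules are strict inequalities).}
#'   \item{absolute_class}{`"polarized"` if `|r| > v_upper`, else
#'     `"unpolarized"`.  The same band half-width serves both rules.}
#' }
#'
#' Scoring control-reporter rows is permitted for diagnostics but flagged
#' with a warning, since the calibration was built from them.
#'
#' @param model a fitted [calibration_model()].
#' @param measurements a measurement `data.frame`.
#' @return the input columns plus `y`, `y_hat`, `residual`,
#'   `signed_class`, `absolute_class` — one polarity call per row.
#' @examples
#' mod <- calibration_model(-0.034, 0.0148, 0.0613, n = 97)
#' rep <- simulate_reporter(5, genotype_profile("mut", p_normal = 1,
#'                          p_reversed = 0, p_symmetric = 0), seed = 3)
#' score_measurements(mod, rep)
#' @export
#' Classify a depth-corrected residual against the calibration band
#'
#' The elementary classification rules, exposed for direct use: signed
#' class is `"normal"` when `r > v_upper`, `"reversed"` when
#' `r < v_lower`, otherwise `"symmetric"`; absolute class is
#' `"polarized"` when `|r| > v_upper`.  Both rules use strict
#' inequalities, so a residual landing exactly on a bound is symmetric /
#' unpolarized.
#'
#' @param model a [calibration_model()].
#' @param r numeric vector of residuals.
#' @return a `data.frame` with columns `residual`, `signed_class`,
#'   `absolute_class`.
#' @export
classify_residual <- function(model, r) {
  stopifnot(inherits(model, "calibration_model"))
  data.frame(
    residual = r,
    signed_class = ifelse(r > model$v_upper, "normal",
                          ifelse(r < model$v_lower, "reversed",
                                 "symmetric")),
    absolute_class = ifelse(abs(r) > model$v_upper, "polarized",
                            "unpolarized"),
    stringsAsFactors = FALSE)
}

score_measurements <- function(model, measurements) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is.finite(model$v_upper)) {
    stop("model error: calibration band is not finite", call. = FALSE)
  }
  m <- validate_measurements(measurements, action = "error")
  if (nrow(m) == 0L) stop("no measurements to score", call. = FALSE)
  if (any(m$reporter == "control_nls")) {
    warning("scoring control_nls measurements against a calibration ",
            "derived from controls; calls are diagnostic only",
            call. = FALSE)
  }
  y <- log_ratio(m, base = model$log_base)
  y_hat <- predict_log_ratio(model, m$z_distance_um)
  r <- y - y_hat
  cls <- classify_residual(model, r)
  out <- cbind(m, data.frame(y = y, y_hat = y_hat, residual = r,
                             signed_class = cls$signed_class,
                             absolute_class = cls$absolute_class,
                             stringsAsFactors = FALSE))
  class(out) <- c("polarity_calls", "data.frame")
  out
}

# normalize temperatures to one decimal so 15 and 15.0 group together
.norm_temp <- function(t) sprintf("%.1f", as.numeric(t))

#' Summarize polarity calls by genotype, cell, and temperature
#'
#' @param calls output of [score_measurements()].
#' @param by grouping columns; default `c("genotype", "cell",
#'   "temperature_c")`.  Temperature is matched after normalization to one
#'   decimal place.
#' @return a `data.frame` with one row per group, in sorted group order:
#'   `n_calls`, class fractions (`fraction_normal`, `fraction_reversed`,
#'   `fraction_symmetric`, summing to 1), `fraction_polarized`, and the
#'   mean signed and absolute residuals.
#' @export
summarize_calls <- function(calls, by = c("genotype", "cell",
                                          "temperature_c")) {
  if (is.null(calls) || nrow(calls) == 0L) {
    warning("no calls to summarize", call. = FALSE)
    return(data.frame())
  }
  stopifnot(all(c(by, "residual", "signed_class") %in% names(calls)))
  keys <- calls[, by, drop = FALSE]
  if ("temperature_c" %in% by) {
    keys$temperature_c <- .norm_temp(keys$temperature_c)
  }
  key_str <- do.call(paste, c(unname(keys), sep = "\r"))
  groups <- sort(unique(key_str))
  rows <- lapply(groups, function(g) {
    idx <- key_str == g
    sub <- calls[idx, , drop = FALSE]
    k <- keys[which(idx)[1L], , drop = FALSE]
    n <- nrow(sub)
    data.frame(
      k,
      n_calls = n,
      fraction_normal = sum(sub$signed_class == "normal") / n,
      fraction_reversed = sum(sub$signed_class == "reversed") / n,
      fraction_symmetric = sum(sub$signed_class == "symmetric") / n,
      fraction_polarized = sum(sub$absolute_class == "polarized") / n,
      mean_signed_residual = mean(sub$residual),
      mean_absolute_residual = mean(abs(sub$residual)),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if ("temperature_c" %in% by) {
    out$temperature_c <- as.numeric(out$temperature_c)
  }
  out
}

#' Violin-plot summary of residual distributions
#'
#' Kernel-density violins of the depth-corrected residuals per group, with
#' horizontal reference lines at 0 and at the classification bounds.  The
#' density bandwidth is fixed (default 0.2 on the residual scale).  In
#' `"signed"` mode the density support extends 2 bandwidths past the data
#' range; in `"absolute"` mode (densities of `|residual|`) it is truncated
#' exactly at the observed extremes, so the violin never dips below zero.
#'
#' @param calls output of [score_measurements()].
#' @param model the [calibration_model()] supplying `v_upper`/`v_lower`.
#' @param mode `"signed"` or `"absolute"`.
#' @param by grouping columns for one violin each.
#' @param bw kernel bandwidth on the residual scale.
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @param summary_file optional CSV path for the accompanying group
#'   summary table (deterministic for identical input).
#' @return invisibly, a list with `summary` (the [summarize_calls()]
#'   table), `ref_lines` (the horizontal reference levels drawn),
#'   `densities` (per-group density objects), and `skipped` (groups with a
#'   single call, skipped with a warning).
#' @export
plot_violin <- function(calls, model, mode = c("signed", "absolute"),
                        by = c("genotype", "cell", "temperature_c"),
                        bw = 0.2, file = NULL, summary_file = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "calibration_model"),
            all(c(by, "residual") %in% names(calls)))
  keys <- calls[, by, drop = FALSE]
  if ("temperature_c" %in% by) {
    keys$temperature_c <- .norm_temp(keys$temperature_c)
  }
  key_str <- do.call(paste, c(unname(keys), sep = " / "))
  groups <- sort(unique(key_str))

  vals <- if (mode == "signed") calls$residual else abs(calls$residual)
  cut <- if (mode == "signed") 2 else 0
  dens <- list(); skipped <- character(0)
  for (g in groups) {
    v <- vals[key_str == g]
    if (length(v) < 2L) {
      warning("group '", g, "' has fewer than 2 calls; skipped",
              call. = FALSE)
      skipped <- c(skipped, g)
      next
    }
    dens[[g]] <- density(v, bw = bw, cut = cut)
  }
  ref_lines <- if (mode == "signed") {
    c(zero = 0, v_upper = model$v_upper, v_lower = model$v_lower)
  } else {
    c(zero = 0, v_upper = model$v_upper)
  }

  if (length(dens) > 0L) {
    if (!is.null(file)) {
      png(file, width = 200 + 160 * length(dens), height = 480)
      on.exit(dev.off(), add = TRUE)
    }
    ylim <- range(unlist(lapply(dens, `[[`, "x")), ref_lines)
    plot.new()
    plot.window(xlim = c(0.5, length(dens) + 0.5), ylim = ylim)
    axis(2)
    axis(1, at = seq_along(dens), labels = names(dens), las = 2,
         cex.axis = 0.7)
    for (i in seq_along(dens)) {
      d <- dens[[i]]
      half <- 0.4 * d$y / max(d$y)
      polygon(c(i - half, rev(i + half)), c(d$x, rev(d$x)),
              col = "grey85", border = "grey30")
    }
    abline(h = ref_lines["zero"], lty = 2, col = "black")
    abline(h = ref_lines[names(ref_lines) != "zero"], lty = 2, col = "red")
    title(ylab = if (mode == "signed") "residual log ratio"
          else "|residual log ratio|",
          main = sprintf("%s residuals (bw = %g)", mode, bw))
  }

  summary <- summarize_calls(calls, by = by)
  if (!is.null(summary_file)) {
    write.table(summary, summary_file, sep = ",", row.names = FALSE,
                quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(list(summary = summary, ref_lines = ref_lines,
                 densities = dens, skipped = skipped))
}
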