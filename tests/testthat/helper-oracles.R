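# Independent oracles, deliberately on different code paths from the
# implementation they check.

# Student-t quantile by root-finding on the CDF (never calls qt)
oracle_t_quantile <- function(df, p) {
  uniroot(function(q) pt(q, df = df) - p, interval = c(0, 1e4),
          tol = 1e-10, extendInt = "upX")$root
}

# closed-form simple OLS: slope/intercept/residual SE and the slope's
# standard error, from the textbook sums
oracle_ols <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2))
  list(slope = slope, intercept = intercept, residual_se = se,
       slope_se = se / sqrt(sxx),
       intercept_se = se * sqrt(1 / n + xb^2 / sxx))
}

# 2x2 Pearson chi-square via the hand formula n(ad-bc)^2 / product of margins
oracle_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# brute-force re-scoring: compose log, predict, subtract, compare with
# plain arithmetic (no package classification code)
oracle_score <- function(model, m) {
  y <- log(m$intensity_proximal / m$intensity_distal, base = model$log_base)
  yh <- model$intercept + model$slope * m$z_distance_um
  r <- y - yh
  v <- model$t_crit * model$residual_se
  signed <- rep("symmetric", length(r))
  signed[r > v] <- "normal"
  signed[r < -v] <- "reversed"
  data.frame(residual = r, signed_class = signed,
             absolute_class = ifelse(abs(r) > v, "polarized", "unpolarized"),
             stringsAsFactors = FALSE)
}

# a measurement table whose log ratios and depths are exactly as given
make_measurements <- function(y, z, reporter = "pop1", genotype = "g",
                              cell = "Z1", temperature_c = 22.5,
                              base = 10, distal = 100) {
  k <- max(length(y), length(z))
  y <- rep_len(y, k); z <- rep_len(z, k); distal <- rep_len(distal, k)
  data.frame(animal_id = sprintf("a%03d", seq_len(k)),
             genotype = genotype, temperature_c = temperature_c,
             cell = cell, reporter = reporter,
             intensity_proximal = distal * base^y,
             intensity_distal = distal,
             z_distance_um = z, stringsAsFactors = FALSE)
}

# the published wild-type calibration constants
paper_model <- function() calibration_model(-0.034, 0.0148, 0.0613, n = 97)
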