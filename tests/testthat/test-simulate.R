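test_that("generators are pure, seeded, and respect boundary sizes", {
  prof <- genotype_profile("N2")
  expect_error(simulate_control(0, prof), ">= 1")
  expect_error(simulate_reporter(0, prof), ">= 1")
  expect_equal(nrow(simulate_control(1, prof, seed = 4)), 1L)

  a <- simulate_control(50, prof, seed = 123)
  b <- simulate_control(50, prof, seed = 123)
  expect_identical(a, b)
  r1 <- simulate_reporter(50, prof, seed = 123)
  r2 <- simulate_reporter(50, prof, seed = 123)
  expect_identical(r1, r2)
  expect_identical(attr(r1, "truth"), attr(r2, "truth"))

  # the caller's RNG stream is untouched by a seeded generator
  set.seed(99); u1 <- runif(1)
  set.seed(99); invisible(simulate_control(10, prof, seed = 5)); u2 <- runif(1)
  expect_identical(u1, u2)
})

test_that("profile validation rejects inconsistent configurations", {
  expect_error(genotype_profile("g", p_normal = 0.5, p_reversed = 0.2,
                                p_symmetric = 0.2), "sum to 1")
  expect_error(genotype_profile("g", noise_sd = 0), "noise_sd")
  expect_error(genotype_profile("g", effect_size = -1), "effect_size")
  expect_error(genotype_profile("g", cell = "Z3"), "cell")
  expect_error(genotype_profile("g", z_distribution = list(kind = "cauchy")),
               "uniform")
  expect_error(genotype_profile("g", dtc_outcome_probs = c(both_present = 1)),
               "dtc_outcome_probs")
  expect_error(simulate_reporter(5, genotype_profile("g"),
                                 reporter = "control_nls"), "reporter")
})

test_that("simulated controls recover the generative regression", {
  m <- simulate_control(5000, genotype_profile("N2"), seed = 2718)
  fit <- fit_depth_regression(m)
  ref <- oracle_ols(m$z_distance_um, log_ratio(m))
  expect_lt(abs(fit$slope - (-0.034)), 3 * ref$slope_se)
  expect_lt(abs(fit$intercept - 0.0148), 3 * ref$intercept_se)
  expect_equal(fit$residual_se, 0.0613, tolerance = 0.05)
  expect_true(all(m$reporter == "control_nls"))
  expect_true(all(m$intensity_proximal > 0 & m$intensity_distal > 0))
})

test_that("reporter truth sidecar reflects the latent mixture", {
  sym <- simulate_reporter(200, genotype_profile("g", p_symmetric = 1),
                           seed = 31)
  expect_true(all(attr(sym, "truth")$true_class == "symmetric"))
  expect_true(all(attr(sym, "truth")$true_effect == 0))

  mix <- simulate_reporter(4000, genotype_profile(
    "g", p_normal = 0.5, p_reversed = 0.5, p_symmetric = 0), seed = 32)
  truth <- attr(mix, "truth")
  expect_equal(mean(truth$true_class == "normal"), 0.5, tolerance = 0.05)
  expect_false("true_class" %in% names(mix))  # labels stay in the sidecar

  f <- withr::local_tempfile(fileext = ".csv")
  write_truth(mix, f)
  expect_identical(read.csv(f, stringsAsFactors = FALSE)$true_class,
                   truth$true_class)
  expect_error(write_truth(data.frame(x = 1), f), "truth")
})

test_that("strong polarity is called correctly by the full pipeline", {
  cal <- fit_depth_regression(
    simulate_control(5000, genotype_profile("N2"), seed = 5050))
  rep1 <- simulate_reporter(2000, genotype_profile(
    "mut", p_normal = 1, p_reversed = 0, p_symmetric = 0,
    effect_size = 0.4), seed = 51)
  calls <- score_measurements(cal, rep1)
  expect_gte(mean(calls$signed_class == "normal"), 0.99)
})

test_that("a half-and-half mixture yields half-and-half signed calls", {
  cal <- fit_depth_regression(
    simulate_control(5000, genotype_profile("N2"), seed = 5050))
  mix <- simulate_reporter(2000, genotype_profile(
    "triple", p_normal = 0.5, p_reversed = 0.5, p_symmetric = 0,
    effect_size = 0.4), seed = 52)
  s <- summarize_calls(score_measurements(cal, mix))
  expect_equal(s$fraction_normal, 0.5, tolerance = 0.08)
  expect_equal(s$fraction_reversed, 0.5, tolerance = 0.08)
})

test_that("classifier power is monotone in effect size", {
  cal <- fit_depth_regression(
    simulate_control(10000, genotype_profile("N2"), seed = 6060))
  power <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(eff) {
    rep_i <- simulate_reporter(3000, genotype_profile(
      "g", p_normal = 1, p_reversed = 0, p_symmetric = 0,
      effect_size = eff), seed = 61)
    mean(score_measurements(cal, rep_i)$signed_class == "normal")
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
})

test_that("summary fractions converge to analytic mixture predictions", {
  # P(call normal | state) is exactly a normal tail once the calibration
  # is essentially noiseless; computed here independently of the package
  cal <- fit_depth_regression(
    simulate_control(20000, genotype_profile("N2"), seed = 7070))
  sd0 <- 0.0613
  for (cfg in list(c(0.3, 0.1, 0.6, 0.2), c(0.6, 0.3, 0.1, 0.4))) {
    prof <- genotype_profile("g", p_normal = cfg[1], p_reversed = cfg[2],
                             p_symmetric = cfg[3], effect_size = cfg[4])
    n <- 6000
    calls <- score_measurements(cal, simulate_reporter(n, prof, seed = 71))
    hit_up <- function(mu) pnorm((mu - cal$v_upper) / sd0)
    exp_normal <- cfg[1] * hit_up(cfg[4]) + cfg[2] * hit_up(-cfg[4]) +
      cfg[3] * hit_up(0)
    exp_reversed <- cfg[2] * hit_up(cfg[4]) + cfg[1] * hit_up(-cfg[4]) +
      cfg[3] * hit_up(0)
    got <- summarize_calls(calls)
    tol <- 4 * sqrt(0.25 / n) + 0.01
    expect_lt(abs(got$fraction_normal - exp_normal), tol)
    expect_lt(abs(got$fraction_reversed - exp_reversed), tol)
  }
})

test_that("phenotype tables honour outcome probabilities and round-trip", {
  clean <- genotype_profile("wt", dtc_outcome_probs = c(
    both_present = 1, anterior_missing = 0, posterior_missing = 0,
    both_missing = 0, dpd = 0))
  tab <- simulate_phenotype_table(clean, 50, seed = 81)
  expect_equal(tab$pct_missing, c(0, 0))
  expect_equal(tab$count_missing, c(0L, 0L))

  # dpd counts as both present; both_missing counts in both regions
  probs <- c(both_present = 0.3, anterior_missing = 0.25,
             posterior_missing = 0.15, both_missing = 0.2, dpd = 0.1)
  prof <- genotype_profile("mut", dtc_outcome_probs = probs)
  tab2 <- simulate_phenotype_table(list(prof, clean), 137, seed = 82)
  expect_equal(nrow(tab2), 4L)
  expect_true(all(tab2$count_missing <= tab2$n))

  # printed percentages reconstruct to the true counts
  for (i in seq_len(nrow(tab2))) {
    expect_identical(reconstruct_count(tab2$pct_missing[i], tab2$n[i]),
                     tab2$count_missing[i])
  }

  expect_error(simulate_phenotype_table(genotype_profile("g"), 10),
               "dtc_outcome_probs")
  expect_error(simulate_phenotype_table(clean, 0), ">= 1")
  expect_identical(simulate_phenotype_table(prof, 137, seed = 9),
                   simulate_phenotype_table(prof, 137, seed = 9))
})
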