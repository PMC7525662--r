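test_that("noiseless lines are recovered exactly", {
  tru <- c(a = 0.01, b = 0.02, c = 0.04, d = 0.08)
  fit <- fit_prediction_line(tru, tru)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r2, 1)
  expect_equal(mean_percent_bias(fit), 0)
  fit2 <- fit_prediction_line(2 * tru, tru)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$r2, 1)
})

test_that("fit errors on degenerate input", {
  expect_error(fit_prediction_line(c(a = 1, b = 2), c(a = 1, b = 2)),
               "at least 3")
  same <- c(a = 1, b = 1, c = 1)
  expect_error(fit_prediction_line(same, same), "zero variance")
})

test_that("pairs are matched by organ label, not position", {
  tru <- c(a = 0.01, b = 0.02, c = 0.04)
  pred <- 2 * tru[c("c", "a", "b")]
  expect_equal(fit_prediction_line(pred, tru)$slope, 2)
})

test_that("slope recovery lies within the fit's own 95% CI (seeded)", {
  p <- generate_dose_pairs(n_organs = 10, slope = 0.6, noise_cv = 0.15,
                           seed = 99)
  fit <- fit_prediction_line(p$predicted, p$true)
  expect_gte(0.6, fit$ci["low"])
  expect_lte(0.6, fit$ci["high"])
})

test_that("two-point through-origin fit equals the closed form", {
  # closed-form oracle: slope = sum(x y) / sum(x^2)
  x <- c(0.01, 0.03, 0.05)
  y <- c(0.02, 0.055, 0.11)
  fit <- fit_prediction_line(y, x, through_origin = TRUE)
  expect_equal(fit$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
})

test_that("mean percent bias is |1 - slope| x 100 and symmetric", {
  expect_equal(mean_percent_bias(1), 0)
  expect_equal(mean_percent_bias(2.111), 111.1)
  expect_equal(mean_percent_bias(0.4166), 58.34)
  for (x in c(0.1, 0.3, 0.7))
    expect_equal(mean_percent_bias(1 + x), mean_percent_bias(1 - x))
})

test_that("identity-line verdicts use inclusive CI bounds", {
  expect_equal(identity_line_test(2.111, c(1.898, 2.323)), "differs")
  expect_equal(identity_line_test(1.019, c(0.7037, 1.335)),
               "does not differ")
  expect_equal(identity_line_test(1, c(1, 1)), "does not differ")
})

test_that("Bland-Altman summary matches a hand recomputation", {
  # identical arrays: everything zero
  same <- c(a = 1, b = 2, c = 3)
  ba0 <- bland_altman(same, same)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  # constant +1 offset: mean diff 1, SD 0
  ba1 <- bland_altman(same + 1, same)
  expect_equal(ba1$mean_diff, 1)
  expect_equal(ba1$sd_diff, 0)
  # seeded noisy pairs vs spreadsheet-style recomputation
  withr::with_seed(5, {
    tru <- runif(8, 0.01, 0.1)
    prd <- tru + rnorm(8, 0.002, 0.005)
  })
  names(tru) <- names(prd) <- letters[1:8]
  ba <- bland_altman(prd, tru)
  d <- prd - tru
  expect_equal(ba$mean_diff, sum(d) / 8)
  expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / 7))
  expect_equal(unname(ba$loa),
               mean(d) + c(-1.96, 1.96) * sd(d))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("limits of agreement hold ~95% of large normal samples", {
  withr::with_seed(2024, {
    tru <- runif(10000, 0.01, 0.1)
    prd <- tru + rnorm(10000, 0, 0.01)
  })
  ba <- bland_altman(prd, tru)
  inside <- mean(ba$differences >= ba$loa[1] & ba$differences <= ba$loa[2])
  expect_gt(inside, 0.94)
  expect_lt(inside, 0.965)
})

test_that("LLI sensitivity detects a constructed outlier", {
  tru <- c(kidneys = 0.02, liver = 0.03, lungs = 0.04, brain = 0.05,
           "LLI wall" = 0.06)
  # all organs on slope 0.8; LLI pair far off the line inflates the slope
  pred <- 0.8 * tru
  pred["LLI wall"] <- 0.20
  out <- lli_sensitivity(pred, tru)
  expect_equal(out$bias_without, 20, tolerance = 1e-9)
  expect_gt(out$bias_with, out$bias_without)
  expect_gt(out$improvement_ratio, 1)
  # LLI pair exactly on the line: ratio 1
  on_line <- lli_sensitivity(0.8 * tru, tru)
  expect_equal(on_line$improvement_ratio, 1, tolerance = 1e-9)
  expect_error(lli_sensitivity(pred[-5], tru[-5]), "LLI absent")
  # removal leaving < 3 pairs
  small <- tru[c("kidneys", "liver", "LLI wall")]
  expect_error(lli_sensitivity(0.8 * small, small), "fewer than 3")
})

test_that("correction factor pools normalised-FBP biases", {
  biases <- mean_percent_bias(c(0.5956, 0.7793, 0.4166, 0.5404))
  cf <- correction_factor(biases)
  expect_equal(cf$mean_percent, mean(biases))
  expect_equal(cf$rounded_percent, 42)
  expect_equal(unname(cf$range), c(min(biases), max(biases)))
  expect_equal(correction_factor(40)$range, c(low = 40, high = 40))
  expect_error(correction_factor(numeric(0)), "empty")
  expect_error(correction_factor(list()), "empty")
})

test_that("correction factor warns on mixed model configurations", {
  tru <- c(a = 0.01, b = 0.02, c = 0.04, d = 0.05)
  mk <- function(recon, norm) {
    bias_report(0.6 * tru, tru,
                model = list(reconstruction = recon, normalised = norm,
                             phantom = "adult male"))
  }
  expect_silent(cf <- correction_factor(list(mk("FBP", TRUE))))
  expect_warning(correction_factor(list(mk("FBP", TRUE),
                                        mk("iterative", TRUE))),
                 "mixed model types")
})

test_that("applying the correction restores the line of identity", {
  tru <- c(a = 0.01, b = 0.02, c = 0.04, d = 0.07)
  pred <- 0.5956 * tru
  fit <- fit_prediction_line(pred, tru)
  corrected <- apply_correction(pred, slope = fit$slope)
  refit <- fit_prediction_line(corrected, tru)
  expect_equal(refit$slope, 1, tolerance = 1e-9)
  # worked values
  expect_equal(apply_correction(1, slope = 1), 1)
  expect_equal(apply_correction(0.5956, slope = 0.5956), 1)
  expect_equal(apply_correction(0.58, bias_percent = 42,
                                mode = "simplified"), 1)
  expect_error(apply_correction(1, slope = -1), "positive")
  expect_error(apply_correction(1, bias_percent = 100, mode = "simplified"),
               "bias < 100")
})

test_that("reconstruction comparison recovers exact and noiseless ratios", {
  tau_f <- c(kidneys = 0.5, liver = 0.2, lungs = 0.1, brain = 0.05)
  same <- compare_reconstructions(tau_f, tau_f)
  expect_equal(same$slope, 1)
  expect_equal(same$mean_ratio, 1)
  scaled <- compare_reconstructions(tau_f, 1.6 * tau_f)
  expect_equal(scaled$slope, 1.6)
  expect_equal(scaled$r2, 1)
  expect_equal(scaled$mean_ratio, 1.6)
})

test_that("reconstruction ratio is recovered from a seeded synthetic cohort", {
  tau_f <- tau_i <- numeric(0)
  for (i in 1:6) {
    pair <- generate_scan(kinetic_spec(rho = 1.6, noise_cv = 0.1,
                                       seed = 100 + i),
                          subject_id = paste0("S", i))
    rf <- residence_times(pair$fbp)
    ri <- residence_times(pair$iterative)
    tau_f <- c(tau_f, unname(rf$tau))
    tau_i <- c(tau_i, unname(ri$tau))
  }
  cmp <- compare_reconstructions(tau_f, tau_i)
  expect_gte(1.6, cmp$ci["low"])
  expect_lte(1.6, cmp$ci["high"])
  expect_gt(cmp$r2, 0.9)
})

test_that("bias reports serialise with the comparison-table columns", {
  tru <- c(a = 0.01, b = 0.02, c = 0.04, d = 0.05)
  rep1 <- bias_report(2 * tru, tru, model = "demo")
  path <- withr::local_tempfile(fileext = ".csv")
  write_bias_reports(rep1, path)
  df <- read.csv(path)
  expect_equal(names(df), c("model", "r2", "mean_pct_bias", "slope", "sem",
                            "ci_low", "ci_high", "n", "lli_included"))
  expect_equal(df$slope, 2)
  expect_equal(df$mean_pct_bias, 100)
})
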