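test_that("signal transduction is affine with two quadruplexes per product duplex", {
  expect_equal(signal_from_species(0, background = 100), 100)
  expect_equal(signal_from_species(10, gain = 1, background = 0), 20)  # both ends
  # doubling the duplex doubles the background-subtracted signal
  s1 <- signal_from_species(7, gain = 3, background = 50)
  s2 <- signal_from_species(14, gain = 3, background = 50)
  expect_equal(s2 - 50, 2 * (s1 - 50))
  # superposition (affinity) holds exactly
  f <- function(d, h) signal_from_species(d, h, gain = 2.5, background = 0,
                                          leak_weight = 0.1)
  expect_equal(f(3, 5) + f(4, 1), f(7, 6))
  expect_error(signal_from_species(1, gain = -1), "gain")
  expect_error(signal_from_species(-1), "concentrations")
})

test_that("delta-F and F/F0 follow their definitions", {
  expect_equal(delta_f(100, 100), 0)
  expect_equal(f_over_f0(100, 100), 1)
  expect_equal(f_over_f0(200, 100), 2)
  expect_equal(delta_f(7, 3), -delta_f(3, 7))
  expect_error(f_over_f0(10, 0), "F0")
})

test_that("noise-free readouts recover the generator line exactly", {
  tab <- generate_calibration_readouts(
    calibration_design(concentrations_nM = c(0, 0.01, 0.05, 0.1, 0.5, 1),
                       sigma = 0))
  fit <- fit_log_linear(tab, range = c(0.01, 1))
  expect_equal(fit$slope, assay_slope, tolerance = 1e-6)
  expect_equal(fit$intercept, assay_intercept, tolerance = 1e-6)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  # exact recovery holds for any generator line
  tab2 <- generate_calibration_readouts(
    calibration_design(slope = -55.5, intercept = 12.25, sigma = 0))
  fit2 <- fit_log_linear(tab2)
  expect_equal(fit2$slope, -55.5, tolerance = 1e-6)
  expect_equal(fit2$intercept, 12.25, tolerance = 1e-6)
})

test_that("two points interpolate exactly and degenerate fits error", {
  tab <- readout_table(c(0.1, 1), c(1, 1), c(10, 30))
  fit <- fit_log_linear(tab)
  expect_equal(predict_signal(fit, 0.1), 10)
  expect_equal(predict_signal(fit, 1), 30)
  expect_error(fit_log_linear(readout_table(c(1, 1), c(1, 2), c(5, 6))),
               "distinct")
  expect_error(fit_log_linear(readout_table(0, 1, 5)), "no positive")
})

test_that("prediction follows Y = a lg X + b and refitting predictions is idempotent", {
  fit <- list(slope = assay_slope, intercept = assay_intercept)
  expect_identical(predict_signal(fit, 1), assay_intercept)
  expect_equal(predict_signal(fit, 10), assay_intercept + assay_slope)
  expect_error(predict_signal(fit, 0), "X must be > 0")
  xs <- c(0.01, 0.05, 0.1, 0.5, 1)
  refit <- fit_log_linear(readout_table(xs, seq_along(xs),
                                        predict_signal(fit, xs)))
  expect_equal(refit$slope, fit$slope, tolerance = 1e-9)
  expect_equal(refit$intercept, fit$intercept, tolerance = 1e-9)
})

test_that("r equals the Pearson correlation of lg X with the mean signals", {
  tab <- generate_calibration_readouts(calibration_design(seed = 5))
  fit <- fit_log_linear(tab, range = c(0.01, 1))
  agg <- aggregate(signal ~ concentration_nM, data = tab[tab$concentration_nM > 0 &
    tab$concentration_nM <= 1, ], FUN = mean)
  expect_equal(fit$r, cor(log10(agg$concentration_nM), agg$signal))
  expect_equal(fit$r_squared, fit$r^2, tolerance = 1e-12)
})

test_that("3-sigma/S limit of detection arithmetic and scaling", {
  expect_equal(lod_3sigma(list(sd = 0, mean = 0), list(slope = 3))$lod, 0)
  expect_equal(lod_3sigma(list(sd = 1, mean = 0), list(slope = 3))$lod, 1)
  bs <- blank_stats(c(100, 102, 98))
  expect_equal(bs$sd, 2)
  l <- lod_3sigma(bs, list(slope = assay_slope, intercept = assay_intercept))
  expect_equal(l$lod, 3 * 2 / assay_slope, tolerance = 1e-12)
  # scales linearly in sigma, inversely in |S|
  l1 <- lod_3sigma(list(sd = 2, mean = 0), list(slope = 10))$lod
  l2 <- lod_3sigma(list(sd = 4, mean = 0), list(slope = 10))$lod
  l3 <- lod_3sigma(list(sd = 2, mean = 0), list(slope = -20))$lod
  expect_equal(l2, 2 * l1)
  expect_equal(l3, l1 / 2)
  expect_error(lod_3sigma(bs, list(slope = 0)), "degenerate")
  expect_error(blank_stats(5), "n >= 2")
  # the inverted concentration form maps F0 + 3 sigma through the calibration
  li <- lod_3sigma(list(sd = 50, mean = 1800),
                   list(slope = assay_slope, intercept = assay_intercept))
  expect_equal(li$lod_conc_nM,
               10^((1800 + 150 - assay_intercept) / assay_slope), tolerance = 1e-12)
})
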