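test_that("spectrum smoothing averages ten neighbours and keeps the grid", {
  wl <- seq(220, 320, by = 1)
  flat <- cd_spectrum(wl, rep(3.5, length(wl)))
  expect_equal(smooth_spectrum(flat)$signal, rep(3.5, length(wl)))
  # single spike spreads over the window by hand-computed averages
  sig <- rep(0, 101); sig[51] <- 10
  sm <- smooth_spectrum(cd_spectrum(wl, sig))
  # interior full windows contain the spike exactly once: mean = 10/10
  expect_equal(sm$signal[51], 1)
  expect_equal(sm$signal[47], 1)   # window 43..52 includes point 51
  expect_equal(sm$signal[57], 0)   # window 53..62 does not
  expect_equal(sum(sm$signal > 0), 10L)
  expect_equal(sm$wavelengths, wl)
  expect_error(smooth_spectrum(cd_spectrum(wl[1:5], sig[1:5])), "at least 10")
})

test_that("smoothing commutes with blank subtraction for matched blanks", {
  set.seed(81)
  wl <- seq(220, 320, by = 0.5)
  sample_sig <- rnorm(length(wl))
  blank_sig <- rnorm(length(wl), sd = 0.1)
  blank <- cd_spectrum(wl, blank_sig)
  spec <- cd_spectrum(wl, sample_sig, blank = blank)
  a <- smooth_spectrum(subtract_blank(spec))$signal
  b <- subtract_blank(smooth_spectrum(spec))$signal
  expect_equal(a, b)
})

test_that("molar ellipticity conversion follows the standard normalisation", {
  wl <- seq(220, 320, by = 1)
  sig <- sin(wl / 10)
  spec <- cd_spectrum(wl, sig, concentration = 5e-6, pathlength = 0.1)
  me <- to_molar_ellipticity(spec)
  expect_equal(me$signal, sig / (10 * 0.1 * 5e-6))
  expect_equal(me$units, "deg.cm2.dmol-1")
  # doubling the concentration halves the output
  spec2 <- cd_spectrum(wl, sig, concentration = 1e-5, pathlength = 0.1)
  expect_equal(to_molar_ellipticity(spec2)$signal, me$signal / 2)
  # zero signal maps to zero; inverse transform is the identity
  expect_equal(to_molar_ellipticity(cd_spectrum(wl, rep(0, length(wl)),
                                                concentration = 5e-6))$signal,
               rep(0, length(wl)))
  back <- me$signal * (10 * 0.1 * 5e-6)
  expect_equal(back, sig)
  expect_error(to_molar_ellipticity(cd_spectrum(wl, sig, concentration = 0)),
               "concentration")
})

test_that("melt fitting recovers noiseless parameters to high precision", {
  mc <- simulate_melt(tm = 78, hill_slope = 0.4, noise_sd = 0)
  fit <- fit_melt(mc)
  expect_lt(abs(fit$tm - 78), 0.01)
  expect_lt(abs(fit$hill_slope - 0.4), 0.01)
  expect_lt(fit$residual_norm, 1e-6)
})

test_that("melt fitting recovers Tm within half a degree at 2% noise", {
  errs <- vapply(1:50, function(i) {
    mc <- simulate_melt(tm = 78, hill_slope = 0.4, noise_sd = 0.02, seed = i)
    fit_melt(mc)$tm - 78
  }, 0)
  expect_lt(mean(abs(errs)), 0.5)
})

test_that("degenerate melt inputs are rejected with diagnostics", {
  expect_error(fit_melt(melt_curve(25:95, 0.01 * (25:95))), "plateau")
  # rising half-sigmoid with no upper plateau in range
  y <- 1 / (1 + exp(-0.1 * ((25:95) - 110)))
  expect_error(fit_melt(melt_curve(25:95, y)))
  expect_error(fit_melt(melt_curve(25:30, rep(c(0, 1), 3))), "at least 8")
})

test_that("melt fitting is invariant to affine rescaling of the signal", {
  mc <- simulate_melt(tm = 70, hill_slope = 0.5, noise_sd = 0.02, seed = 5)
  f1 <- fit_melt(mc)
  scaled <- melt_curve(mc$temperature, 2.4e5 * mc$signal - 3.1e4)
  f2 <- fit_melt(scaled)
  expect_equal(f2$tm, f1$tm, tolerance = 1e-6)
  expect_equal(f2$hill_slope, f1$hill_slope, tolerance = 1e-6)
  expect_equal(f2$upper, 2.4e5 * f1$upper - 3.1e4, tolerance = 1e-4)
})

test_that("melt fit methods expose coefficients, predictions and residuals", {
  mc <- simulate_melt(tm = 68, hill_slope = 0.5, noise_sd = 0.01, seed = 8)
  fit <- fit_melt(mc)
  expect_named(coef(fit), c("tm", "hill_slope", "lower", "upper"))
  expect_equal(length(predict(fit)), nrow(mc))
  expect_equal(predict(fit) + residuals(fit), mc$signal)
})

test_that("the Pfaffl ratio follows the efficiency-corrected model", {
  expect_equal(pfaffl_ratio(2, 2, 0, 0), 1)
  expect_equal(pfaffl_ratio(2, 2, 1, 0), 2)
  expect_error(pfaffl_ratio(1, 2, 1, 1), "exceed 1")
  expect_error(pfaffl_ratio(2, 2.5, 1, 1), "exceed 2")
  # log-space oracle agreement to 1e-12 relative on random measurements
  set.seed(91)
  for (i in 1:100) {
    et <- runif(1, 1.5, 2); er <- runif(1, 1.5, 2)
    dt <- runif(1, -5, 5); dr <- runif(1, -5, 5)
    oracle <- exp(dt * log(et)) / exp(dr * log(er))
    expect_equal(pfaffl_ratio(et, er, dt, dr), oracle, tolerance = 1e-12)
  }
  # inverse symmetry: negating both differences inverts the ratio
  expect_equal(pfaffl_ratio(1.9, 1.7, 2.3, 1.1) *
               pfaffl_ratio(1.9, 1.7, -2.3, -1.1), 1, tolerance = 1e-12)
})

test_that("relative translation efficiency normalises means with delta-method SEM", {
  set.seed(95)
  df <- data.frame(
    construct = rep(c("wildtype", "g4mut", "g4del"), each = 6),
    luminescence = c(rnorm(6, 100, 6), rnorm(6, 175, 10), rnorm(6, 230, 12)))
  out <- relative_efficiency(df, "wildtype")
  expect_equal(out$relative[out$construct == "wildtype"], 1)
  means <- tapply(df$luminescence, df$construct, mean)
  expect_equal(out$relative[out$construct == "g4mut"],
               unname(means["g4mut"] / means["wildtype"]))
  # doubling the reference gives exactly 2
  df2 <- data.frame(construct = rep(c("r", "x"), each = 3),
                    luminescence = c(10, 10, 10, 20, 20, 20))
  expect_equal(relative_efficiency(df2, "r")$relative,
               c(1, 2))
  expect_error(relative_efficiency(df, "missing"), "not present")
})

test_that("delta-method SEM agrees with a bootstrap of the ratio", {
  set.seed(97)
  df <- data.frame(
    construct = rep(c("refc", "test"), each = 12),
    luminescence = c(rnorm(12, 100, 7), rnorm(12, 180, 12)))
  out <- relative_efficiency(df, "refc")
  a <- df$luminescence[df$construct == "test"]
  r <- df$luminescence[df$construct == "refc"]
  boot <- vapply(1:10000, function(i)
    mean(sample(a, replace = TRUE)) / mean(sample(r, replace = TRUE)), 0)
  sem <- out$relative_sem[out$construct == "test"]
  expect_lt(abs(sem - sd(boot)) / sd(boot), 0.05)
})
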