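#' Circular-dichroism spectrum
#'
#' Container for a CD spectrum: signal in millidegrees on a strictly
#' increasing wavelength grid, with the sample concentration and cuvette
#' path length needed for molar ellipticity conversion, and an optional
#' buffer blank recorded on the same grid.
#'
#' @param wavelengths Wavelength grid in nm, strictly increasing.
#' @param signal Signal in millidegrees (or molar ellipticity after
#'   conversion; tracked in `units`).
#' @param concentration Total species concentration in mol/L.
#' @param pathlength Cuvette path length in cm.
#' @param blank Optional `cd_spectrum` buffer blank on the same grid.
#' @param units Signal units label.
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, signal, concentration = NA_real_,
                        pathlength = 0.1, blank = NULL,
                        units = "millidegrees") {
  stopifnot(length(wavelengths) == length(signal),
            all(diff(wavelengths) > 0))
  if (!is.null(blank)) {
    stopifnot(inherits(blank, "cd_spectrum"))
    if (!isTRUE(all.equal(blank$wavelengths, wavelengths)))
      stop("blank grid does not match sample grid")
  }
  structure(list(wavelengths = wavelengths, signal = signal,
                 concentration = concentration, pathlength = pathlength,
                 blank = blank, units = units),
            class = "cd_spectrum")
}

#' Subtract the buffer blank from a spectrum
#' @param spec A [cd_spectrum()] with a blank attached.
#' @return Blank-subtracted `cd_spectrum` (blank removed).
#' @export
subtract_blank <- function(spec) {
  if (is.null(spec$blank)) return(spec)
  out <- spec
  out$signal <- spec$signal - spec$blank$signal
  out$blank <- NULL
  out
}

#' Smooth a CD spectrum by neighbour averaging
#'
#' Moving average over a ten-point neighbourhood (the point and its
#' neighbours), truncating the window at the spectrum edges; the
#' wavelength grid is unchanged. Smoothing is linear, so it commutes with
#' blank subtraction for matched blanks.
#'
#' @param spec A [cd_spectrum()] with at least 10 points.
#' @param window Neighbourhood size (default 10 points).
#' @return Smoothed `cd_spectrum`.
#' @export
smooth_spectrum <- function(spec, window = 10L) {
  n <- length(spec$signal)
  if (n < window) stop(sprintf("need at least %d points, have %d", window, n))
  half_lo <- floor((window - 1L) / 2L)
  half_hi <- ceiling((window - 1L) / 2L)
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_lo)
    hi <- min(n, i + half_hi)
    mean(spec$signal[lo:hi])
  }, 0)
  out <- spec
  out$signal <- sm
  if (!is.null(out$blank)) out$blank <- smooth_spectrum(spec$blank, window)
  out
}

#' Convert millidegrees to molar ellipticity
#'
#' Standard normalisation to total species concentration:
#' theta_molar = millidegrees / (10 x pathlength_cm x concentration_M),
#' in deg cm^2 dmol^-1.
#'
#' @param spec A [cd_spectrum()] in millidegrees with positive
#'   concentration and path length.
#' @return `cd_spectrum` in molar ellipticity units.
#' @export
to_molar_ellipticity <- function(spec) {
  if (!is.finite(spec$concentration) || spec$concentration <= 0)
    stop("concentration must be positive")
  if (spec$pathlength <= 0) stop("pathlength must be positive")
  out <- spec
  out$signal <- spec$signal / (10 * spec$pathlength * spec$concentration)
  out$units <- "deg.cm2.dmol-1"
  out
}

#' Melt curve
#'
#' CD signal at 260 nm versus temperature for a thermal unfolding
#' experiment.
#'
#' @param temperatures Degrees C, strictly increasing.
#' @param signal Molar ellipticity at 260 nm.
#' @return An object of class `melt_curve` (also a data.frame).
#' @export
melt_curve <- function(temperatures, signal) {
  stopifnot(length(temperatures) == length(signal),
            all(diff(temperatures) > 0))
  structure(data.frame(temperature = temperatures, signal = signal),
            class = c("melt_curve", "data.frame"))
}

.melt_model <- function(temp, tm, h, lower, upper) {
  lower + (upper - lower) / (1 + exp(h * (temp - tm)))
}

#' Fit a variable-slope sigmoid to a melt curve
#'
#' Least-squares fit of the four-parameter logistic
#' `y = lower + (upper - lower) / (1 + exp(h * (T - tm)))`, the
#' variable-slope sigmoidal dose-response family in temperature. With this
#' parameterisation `h > 0` corresponds to an unfolding transition whose
#' signal decreases with temperature, and `lower < upper` always. Fitting
#' uses Levenberg-Marquardt least squares with a deterministic multi-start
#' grid over the slope (seeded, so results are reproducible); the midpoint
#' crossing of the data initialises `tm`. Non-convergence, a fitted `tm`
#' outside the data range, or inverted plateaus raise an explicit error
#' with diagnostics rather than returning a best-effort value.
#'
#' @param curve A [melt_curve()] (or data.frame with `temperature`,
#'   `signal`) with at least 8 points spanning both plateaus.
#' @param seed Integer seed for the multi-start jitter.
#' @return Object of class `melt_fit` with components `tm` (deg C),
#'   `hill_slope`, `lower`, `upper`, `residual_norm`, `fitted`, `curve`.
#'   Methods: `print`, `coef`, `predict`, `residuals`, `plot`.
#' @examples
#' mc <- simulate_melt(tm = 78, hill_slope = 0.4, noise_sd = 0)
#' fit_melt(mc)$tm
#' @export
fit_melt <- function(curve, seed = 1L) {
  stopifnot(all(c("temperature", "signal") %in% names(curve)))
  temp <- curve$temperature
  y <- curve$signal
  if (length(temp) < 8L)
    stop("need at least 8 points spanning both plateaus")
  rng <- range(temp)
  lo0 <- min(y); up0 <- max(y)
  mid <- (lo0 + up0) / 2
  tm0 <- temp[which.min(abs(y - mid))]
  decreasing <- stats::coef(stats::lm(y ~ temp))[2L] < 0
  set.seed(seed)
  h_grid <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.5) * (if (decreasing) 1 else -1)
  tm_grid <- unique(c(tm0, tm0 + stats::runif(2, -5, 5)))
  best <- NULL
  for (h0 in h_grid) for (t0 in tm_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        signal ~ lower + (upper - lower) / (1 + exp(h * (temperature - tm))),
        data = data.frame(temperature = temp, signal = y),
        start = list(tm = t0, h = h0, lower = lo0, upper = up0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop(sprintf(paste0("melt fit did not converge (n = %d, T range %.1f-%.1f, ",
                        "signal range %.3g-%.3g); check that both plateaus ",
                        "are represented"),
                 length(temp), rng[1L], rng[2L], lo0, up0))
  p <- stats::coef(best$fit)
  if (p[["lower"]] > p[["upper"]]) {
    # reparameterise the mirror solution (h and plateaus both flipped)
    p <- c(tm = p[["tm"]], h = -p[["h"]],
           lower = p[["upper"]], upper = p[["lower"]])
  }
  if (p[["tm"]] < rng[1L] || p[["tm"]] > rng[2L])
    stop(sprintf(paste0("melt fit rejected: fitted tm %.1f outside data range ",
                        "%.1f-%.1f; the transition midpoint is not covered"),
                 p[["tm"]], rng[1L], rng[2L]))
  coverage <- abs(.melt_model(rng[1L], p[["tm"]], p[["h"]], p[["lower"]], p[["upper"]]) -
                  .melt_model(rng[2L], p[["tm"]], p[["h"]], p[["lower"]], p[["upper"]])) /
    abs(p[["upper"]] - p[["lower"]])
  if (!is.finite(coverage) || coverage < 0.8)
    stop(sprintf(paste0("melt fit rejected: only %.0f%% of the transition lies ",
                        "inside the data range; a plateau is missing"),
                 100 * coverage))
  fitted <- .melt_model(temp, p[["tm"]], p[["h"]], p[["lower"]], p[["upper"]])
  structure(list(tm = unname(p[["tm"]]), hill_slope = unname(p[["h"]]),
                 lower = unname(p[["lower"]]), upper = unname(p[["upper"]]),
                 residual_norm = sqrt(sum((y - fitted)^2)),
                 fitted = fitted,
                 curve = data.frame(temperature = temp, signal = y)),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("melt_fit: Tm = %.2f degC, slope = %.3f, plateaus [%.3g, %.3g], ||r|| = %.3g\n",
              x$tm, x$hill_slope, x$lower, x$upper, x$residual_norm))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm = object$tm, hill_slope = object$hill_slope,
    lower = object$lower, upper = object$upper)
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  temp <- if (is.null(newdata)) object$curve$temperature else newdata$temperature
  .melt_model(temp, object$tm, object$hill_slope, object$lower, object$upper)
}

#' @export
residuals.melt_fit <- function(object, ...) {
  object$curve$signal - object$fitted
}

#' @export
plot.melt_fit <- function(x, ...) {
  graphics::plot(x$curve$temperature, x$curve$signal,
                 xlab = "Temperature (degC)", ylab = "Signal",
                 main = sprintf("Melt fit: Tm = %.1f degC", x$tm), ...)
  grid_t <- seq(min(x$curve$temperature), max(x$curve$temperature), length.out = 200)
  graphics::lines(grid_t, .melt_model(grid_t, x$tm, x$hill_slope, x$lower, x$upper))
  graphics::abline(v = x$tm, lty = 2)
  invisible(x)
}

#' Efficiency-corrected relative expression ratio
#'
#' The Pfaffl model for relative quantification:
#' `ratio = E_target ^ dCP_target / E_reference ^ dCP_reference`, where the
#' E are per-cycle amplification efficiencies (2 = perfect doubling) and
#' the dCP are crossing-point differences (control minus sample) in cycles.
#'
#' @param e_target,e_reference Amplification efficiencies in (1, 2].
#' @param dcp_target,dcp_reference Crossing-point differences
#'   (control - sample), cycles. Vectors are recycled elementwise.
#' @return Numeric ratio(s).
#' @examples
#' pfaffl_ratio(2, 2, 1, 0)   # 2
#' pfaffl_ratio(1.8, 1.9, 0, 0) # 1
#' @export
pfaffl_ratio <- function(e_target, e_reference, dcp_target, dcp_reference) {
  if (any(e_target <= 1) || any(e_reference <= 1))
    stop("amplification efficiencies must exceed 1 (per-cycle fold change)")
  if (any(e_target > 2) || any(e_reference > 2))
    stop("amplification efficiencies cannot exceed 2 (perfect doubling)")
  e_target^dcp_target / e_reference^dcp_reference
}

#' Relative translation efficiency from luminescence replicates
#'
#' Normalises per-construct luminescence means to a designated reference
#' construct. The standard error of each normalised mean is propagated by
#' the delta method for a ratio of independent means:
#' `sem(a/r) = (a/r) * sqrt((sem_a/a)^2 + (sem_r/r)^2)`; the reference row
#' is exactly 1 with its own relative SEM.
#'
#' @param data data.frame with columns `construct` and `luminescence` (one
#'   row per replicate).
#' @param reference Name of the reference construct.
#' @return data.frame with `construct`, `n`, `mean`, `sem` (raw),
#'   `relative`, `relative_sem`; the raw replicate table is attached as
#'   attribute `replicates`.
#' @export
relative_efficiency <- function(data, reference) {
  stopifnot(all(c("construct", "luminescence") %in% names(data)))
  if (!reference %in% data$construct)
    stop("reference construct not present: ", reference)
  gs <- split(data$luminescence, data$construct)
  if (any(lengths(gs) < 2L))
    stop("need at least 2 replicates per construct")
  means <- vapply(gs, mean, 0)
  sems <- vapply(gs, function(v) stats::sd(v) / sqrt(length(v)), 0)
  rm_ <- means[[reference]]; rs <- sems[[reference]]
  rel <- means / rm_
  rel_sem <- rel * sqrt((sems / means)^2 + (rs / rm_)^2)
  rel[reference] <- 1
  rel_sem[reference] <- rs / rm_
  out <- data.frame(construct = names(means), n = lengths(gs),
                    mean = unname(means), sem = unname(sems),
                    relative = unname(rel), relative_sem = unname(rel_sem),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "replicates") <- data
  out
}
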