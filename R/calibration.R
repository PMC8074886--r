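# Linear calibration: signal extraction, ordinary least-squares fitting,
# S/N-based detection limits, inverse prediction, and LC peak integration.

#' Signal extraction rule for CD spectra
#'
#' How a single scalar "CD signal" is read off a spectrum: either the grid
#' point of maximum absolute ellipticity inside a wavelength window
#' (`"peak"`, the default, over 190--220 nm where amino-acid Cotton effects
#' sit), or the ellipticity at a fixed wavelength (`"fixed"`). The extracted
#' value keeps its sign.
#'
#' @param mode `"peak"` or `"fixed"`.
#' @param window Length-2 numeric, nm, for peak mode; `window[1] < window[2]`.
#' @param wavelength Single wavelength, nm, for fixed mode.
#' @return A `signal_rule` object.
#' @export
signal_rule <- function(mode = c("peak", "fixed"), window = c(190, 220),
                        wavelength = NULL) {
  mode <- match.arg(mode)
  if (mode == "peak") {
    if (length(window) != 2L || !is.numeric(window) || window[1] >= window[2])
      cdq_stop("invalid_parameter", "`window` must be numeric c(lo, hi) with lo < hi")
  } else {
    assert_scalar_num(wavelength, "wavelength", positive = TRUE)
  }
  structure(list(mode = mode, window = window, wavelength = wavelength),
            class = "signal_rule")
}

#' Extract the scalar CD signal from a spectrum
#'
#' Peak mode returns the signed ellipticity at the grid point of maximum
#' `|theta|` inside the rule's window; on an exact tie the lowest wavelength
#' wins. Fixed mode returns the value at the grid point nearest the rule's
#' wavelength.
#'
#' @param spectrum A [cd_spectrum()].
#' @param rule A [signal_rule()]; defaults to peak over 190--220 nm.
#' @return List with `wavelength` (nm) and `theta` (mdeg, signed).
#' @export
extract_signal <- function(spectrum, rule = signal_rule()) {
  wl <- spectrum$wavelengths
  if (rule$mode == "peak") {
    if (rule$window[1] < min(wl) || rule$window[2] > max(wl))
      cdq_stop("range_error",
               sprintf("extraction window [%g, %g] nm outside spectrum grid [%g, %g]",
                       rule$window[1], rule$window[2], min(wl), max(wl)))
    idx <- which(wl >= rule$window[1] & wl <= rule$window[2])
    k <- idx[which.max(abs(spectrum$theta[idx]))]  # which.max: first (lowest-nm) on ties
  } else {
    if (rule$wavelength < min(wl) || rule$wavelength > max(wl))
      cdq_stop("range_error",
               sprintf("wavelength %g nm outside spectrum grid", rule$wavelength))
    k <- which.min(abs(wl - rule$wavelength))
  }
  list(wavelength = wl[k], theta = spectrum$theta[k])
}

#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of `signal = slope * conc + intercept` to a
#' standard series, with the coefficient of determination
#' `R^2 = 1 - SSE/SST`, the concentration validity range set to the extremes
#' of the input series, and S/N-based limits of detection and quantification
#' (see [lod_loq()]). The noise level used for LOD/LOQ is `noise_sd` when
#' given, else the residual standard error of the fit.
#'
#' @param conc Concentrations, mM; at least 3 points with at least 2
#'   distinct values.
#' @param signal Measured signals, same length as `conc` (mdeg for CD peak
#'   signals, mAU min for LC areas).
#' @param modality `"CD"` or `"LC"`.
#' @param noise_sd Optional known noise standard deviation, signal units.
#' @param extraction Optional [signal_rule()] recorded with the curve.
#' @param slope_eps Smallest acceptable `|slope|`; below it the response is
#'   considered flat and an error is raised.
#' @return A `calibration_curve` object with fields `slope`, `intercept`,
#'   `r_squared`, `conc_lo`, `conc_hi`, `lod`, `loq`, `sigma` (residual SE),
#'   `n`, `modality`, `extraction`.
#' @examples
#' x <- c(5, 10, 15, 20, 25)
#' fit_calibration(x, 0.1927 * x - 0.53033)
#' @export
fit_calibration <- function(conc, signal, modality = c("CD", "LC"),
                            noise_sd = NULL, extraction = NULL,
                            slope_eps = 1e-12) {
  modality <- match.arg(modality)
  if (length(conc) != length(signal))
    cdq_stop("invalid_parameter", "`conc` and `signal` must have equal length")
  if (length(conc) < 3L)
    cdq_stop("insufficient_data",
             sprintf("calibration needs >= 3 points, got %d", length(conc)))
  if (length(unique(conc)) < 2L)
    cdq_stop("degenerate_design", "all concentrations identical: zero design variance")
  fit <- stats::lm(signal ~ conc, data = data.frame(conc = conc, signal = signal))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (abs(slope) < slope_eps)
    cdq_stop("flat_response", sprintf("|slope| = %g below tolerance %g", abs(slope), slope_eps))
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((signal - mean(signal))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  df_res <- length(conc) - 2L
  sigma <- if (!is.null(noise_sd)) noise_sd
           else if (df_res > 0) sqrt(sse / df_res) else 0
  if (!is.finite(sigma)) sigma <- 0
  ll <- lod_loq(sigma, slope)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 conc_lo = min(conc), conc_hi = max(conc),
                 lod = ll[["lod"]], loq = ll[["loq"]],
                 sigma = sigma, n = length(conc),
                 modality = modality, extraction = extraction),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: y = %.6g x %s %.6g (n = %d)\n",
              x$modality, x$slope, if (x$intercept < 0) "-" else "+",
              abs(x$intercept), x$n))
  cat(sprintf("  R^2 = %.6g, range [%g, %g] mM, LOD %.4g, LOQ %.4g mM\n",
              x$r_squared, x$conc_lo, x$conc_hi, x$lod, x$loq))
  invisible(x)
}

#' Signal-to-noise detection and quantification limits
#'
#' LOD is the concentration whose expected signal is 3 times the noise
#' standard deviation (S/N = 3); LOQ uses S/N = 10. Converted to
#' concentration units through the calibration slope: `lod = 3 sd/|slope|`,
#' `loq = 10 sd/|slope|`.
#'
#' @param noise_sd Noise standard deviation, signal units; >= 0.
#' @param slope Calibration slope, signal units per mM; non-zero.
#' @return Named numeric `c(lod = , loq = )`, mM.
#' @export
lod_loq <- function(noise_sd, slope) {
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_num(slope, "slope")
  if (slope == 0)
    cdq_stop("flat_response", "zero slope: detection limits undefined")
  c(lod = 3 * noise_sd / abs(slope), loq = 10 * noise_sd / abs(slope))
}

#' Predict the expected signal at a concentration
#'
#' @param object A `calibration_curve`.
#' @param conc Concentration(s), mM.
#' @param ... Ignored.
#' @return Predicted signal(s), `slope * conc + intercept`.
#' @export
predict.calibration_curve <- function(object, conc, ...) {
  object$slope * conc + object$intercept
}

#' Inverse prediction: concentration from a measured signal
#'
#' Returns `(signal - intercept) / slope` with the sign preserved: for a CD
#' curve fitted on L standards, a negative result indicates a D excess. The
#' `in_range` flag is `FALSE` when the absolute concentration falls outside
#' the curve's fitted range or below its LOQ; out-of-range is flagged, never
#' fatal.
#'
#' @param curve A `calibration_curve`.
#' @param signal Measured signal, curve units; vectorised.
#' @return List with `conc` (mM, signed) and `in_range` (logical).
#' @export
invert_calibration <- function(curve, signal) {
  conc <- (signal - curve$intercept) / curve$slope
  in_range <- abs(conc) >= curve$conc_lo & abs(conc) <= curve$conc_hi &
    abs(conc) >= curve$loq
  list(conc = conc, in_range = in_range)
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integral of the absorbance over `[t_lo, t_hi]`, after
#' subtracting a constant baseline estimated as the mean absorbance over the
#' supplied baseline windows (no subtraction when `baseline_windows` is
#' `NULL`).
#'
#' @param chrom A [chromatogram()].
#' @param t_lo,t_hi Integration window, min; `t_lo < t_hi`, inside the grid.
#' @param baseline_windows Optional list of length-2 numeric windows (min)
#'   whose pooled mean absorbance is subtracted before integrating.
#' @return Peak area, mAU min.
#' @export
integrate_peak <- function(chrom, t_lo, t_hi, baseline_windows = NULL) {
  tt <- chrom$times
  if (t_lo >= t_hi)
    cdq_stop("invalid_parameter", "`t_lo` must be < `t_hi`")
  if (t_lo < min(tt) || t_hi > max(tt))
    cdq_stop("range_error",
             sprintf("integration window [%g, %g] min outside grid [%g, %g]",
                     t_lo, t_hi, min(tt), max(tt)))
  if (length(tt) < 2L)
    cdq_stop("validation_error", "need >= 2 points to integrate")
  base <- 0
  if (!is.null(baseline_windows)) {
    sel <- rep(FALSE, length(tt))
    for (w in baseline_windows) sel <- sel | (tt >= w[1] & tt <= w[2])
    if (!any(sel))
      cdq_stop("range_error", "baseline windows contain no grid points")
    base <- mean(chrom$absorbance[sel])
  }
  idx <- which(tt >= t_lo & tt <= t_hi)
  if (length(idx) < 2L)
    cdq_stop("range_error", "integration window contains fewer than 2 grid points")
  pracma::trapz(tt[idx], chrom$absorbance[idx] - base)
}
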