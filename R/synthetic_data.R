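# Forward simulator of CD spectra and achiral LC chromatograms.
#
# The spectral model is a sum of Gaussian Cotton bands: the L-enantiomer of
# an analyte carries the stored band set; the D-enantiomer is its exact
# mirror (every band amplitude negated). A mixture therefore produces a
# noise-free ellipticity proportional to c_L - c_D at each wavelength, and a
# racemic mixture a null spectrum. On an achiral LC column the two
# enantiomers co-elute, so the chromatographic peak area reports c_L + c_D
# regardless of the ratio.

.default_wavelengths <- function() seq(185, 260, by = 0.5)
.default_times <- function() seq(0, 6, by = 0.01)
.default_path_len <- 0.1   # cm; standard far-UV cuvette

#' A Gaussian Cotton band
#'
#' One signed CD band of an analyte's L-enantiomer: a Gaussian in wavelength
#' with peak molar circular dichroism `amplitude` at `center`.
#'
#' @param center Band centre, nm.
#' @param width Gaussian standard deviation, nm; > 0.
#' @param amplitude Peak molar CD at the centre, L mol^-1 cm^-1, signed.
#' @return A `cotton_band` object.
#' @export
cotton_band <- function(center, width, amplitude) {
  assert_scalar_num(center, "center", positive = TRUE)
  assert_scalar_num(width, "width", positive = TRUE)
  assert_scalar_num(amplitude, "amplitude")
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "cotton_band")
}

#' Ground-truth description of one chiral analyte
#'
#' Chiroptical and chromatographic properties used by the simulator: the
#' Cotton bands of the L-enantiomer (the D-enantiomer is the mirror image),
#' the achiral-LC retention behaviour shared by both enantiomers, and the
#' LC response factor (peak area per mM of total analyte). The net band
#' amplitude inside the 190--220 nm window must be positive, the sign
#' convention for L-amino acids.
#'
#' @param name Analyte label.
#' @param bands A single [cotton_band()] or a list of them.
#' @param retention_time LC retention time, min.
#' @param retention_width Gaussian peak standard deviation, min; > 0.
#' @param response_factor LC area per mM total concentration,
#'   mAU min / mM; > 0.
#' @return An `analyte_spec` object.
#' @export
analyte_spec <- function(name, bands, retention_time, retention_width,
                         response_factor) {
  if (inherits(bands, "cotton_band")) bands <- list(bands)
  if (!is.list(bands) || length(bands) < 1L ||
      !all(vapply(bands, inherits, logical(1), "cotton_band")))
    cdq_stop("invalid_parameter", "`bands` must be one or more cotton_band objects")
  assert_scalar_num(retention_time, "retention_time", positive = TRUE)
  assert_scalar_num(retention_width, "retention_width", positive = TRUE)
  assert_scalar_num(response_factor, "response_factor", positive = TRUE)
  spec <- structure(list(name = as.character(name)[1], bands = bands,
                         retention_time = retention_time,
                         retention_width = retention_width,
                         response_factor = response_factor),
                    class = "analyte_spec")
  win <- seq(190, 220, by = 0.1)
  if (sum(delta_eps_profile(spec, win)) <= 0)
    cdq_stop("invalid_parameter",
             "net band amplitude in 190-220 nm must be positive (L-enantiomer convention)")
  spec
}

#' Molar CD of the L-enantiomer across a wavelength grid
#'
#' @param analyte An [analyte_spec()].
#' @param wavelengths Numeric vector of wavelengths, nm.
#' @return Vector of molar CD values, L mol^-1 cm^-1.
#' @export
delta_eps_profile <- function(analyte, wavelengths) {
  out <- numeric(length(wavelengths))
  for (b in analyte$bands)
    out <- out + b$amplitude * exp(-((wavelengths - b$center)^2) / (2 * b$width^2))
  out
}

#' CD spectrum container
#'
#' A measured or simulated spectrum: strictly increasing wavelength grid and
#' matching ellipticity values in millidegrees, plus the path length the
#' spectrum was acquired at.
#'
#' @param wavelengths Strictly increasing wavelength grid, nm.
#' @param theta Ellipticity per grid point, mdeg.
#' @param path_len Path length, cm.
#' @param label Free-text label.
#' @return A `cd_spectrum` object.
#' @export
cd_spectrum <- function(wavelengths, theta, path_len = .default_path_len,
                        label = "") {
  if (length(wavelengths) != length(theta))
    cdq_stop("validation_error", "wavelengths and theta must have equal length")
  if (length(wavelengths) < 1L || any(!is.finite(wavelengths)) || any(!is.finite(theta)))
    cdq_stop("validation_error", "spectrum values must be finite and non-empty")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    cdq_stop("validation_error", "wavelength grid must be strictly increasing")
  assert_scalar_num(path_len, "path_len", positive = TRUE)
  structure(list(wavelengths = as.numeric(wavelengths),
                 theta = as.numeric(theta),
                 path_len = path_len, label = as.character(label)[1]),
            class = "cd_spectrum")
}

#' Achiral LC chromatogram container
#'
#' @param times Strictly increasing time grid, min; non-negative.
#' @param absorbance Detector absorbance per grid point, mAU.
#' @param label Free-text label.
#' @return A `chromatogram` object.
#' @export
chromatogram <- function(times, absorbance, label = "") {
  if (length(times) != length(absorbance))
    cdq_stop("validation_error", "times and absorbance must have equal length")
  if (length(times) < 1L || any(!is.finite(times)) || any(!is.finite(absorbance)))
    cdq_stop("validation_error", "chromatogram values must be finite and non-empty")
  if (length(times) > 1L && any(diff(times) <= 0))
    cdq_stop("validation_error", "time grid must be strictly increasing")
  if (any(times < 0))
    cdq_stop("validation_error", "time grid must be non-negative")
  structure(list(times = as.numeric(times),
                 absorbance = as.numeric(absorbance),
                 label = as.character(label)[1]),
            class = "chromatogram")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %s: %d points, %.1f-%.1f nm, path %.3g cm\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$path_len))
  invisible(x)
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s: %d points, %.2f-%.2f min\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

# mdeg per mM at the given path length: theta_mdeg = 3298 * de * c_mM * l
# (the 1/1000 mM->M and 1000 deg->mdeg conversions cancel).
.theta_mdeg_per_mM <- function(delta_eps, path_len)
  .theta_factor * delta_eps * path_len

#' Simulate a CD spectrum of an enantiomer mixture
#'
#' The noise-free ellipticity at each wavelength is the band-sum molar CD of
#' the L-enantiomer times `(c_L - c_D)`, scaled by path length and the
#' degree/millidegree conversions; the mirror rule for the D-enantiomer is
#' built in. Independent homoscedastic Gaussian noise of standard deviation
#' `noise_sd` mdeg is added per grid point; the same `seed` with the same
#' inputs reproduces the spectrum bitwise.
#'
#' @param analyte An [analyte_spec()].
#' @param c_L,c_D L- and D-enantiomer concentrations, mM; non-negative.
#' @param path_len Path length, cm.
#' @param noise_sd Instrument noise standard deviation, mdeg; >= 0.
#' @param seed Optional integer seed for the noise realisation.
#' @param wavelengths Wavelength grid, nm.
#' @param pH Optional solution pH; if supplied, the whole spectrum is scaled
#'   by [ph_factor()] (flat at 1 between pH 3 and 8).
#' @return A [cd_spectrum()].
#' @examples
#' leu <- default_analytes()$leu
#' s <- simulate_cd(leu, c_L = 8, c_D = 0, noise_sd = 0, seed = 1)
#' max(s$theta)
#' @export
simulate_cd <- function(analyte, c_L, c_D = 0, path_len = .default_path_len,
                        noise_sd = 0.02, seed = NULL,
                        wavelengths = .default_wavelengths(), pH = NULL) {
  assert_scalar_num(c_L, "c_L", nonneg = TRUE)
  assert_scalar_num(c_D, "c_D", nonneg = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  de <- delta_eps_profile(analyte, wavelengths)
  theta <- .theta_mdeg_per_mM(de, path_len) * (c_L - c_D)
  if (!is.null(pH)) theta <- theta * ph_factor(pH)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    theta <- theta + stats::rnorm(length(theta), sd = noise_sd)
  }
  cd_spectrum(wavelengths, theta, path_len,
              label = sprintf("%s L=%g D=%g mM", analyte$name, c_L, c_D))
}

#' Simulate an achiral LC chromatogram
#'
#' Enantiomers co-elute on an achiral column, so the trace carries a single
#' Gaussian peak at the analyte's retention time whose area equals
#' `response_factor * c_total`, independent of the L:D ratio. Per-point
#' Gaussian noise of sd `noise_sd` mAU is added.
#'
#' @param analyte An [analyte_spec()].
#' @param c_total Total (L + D) concentration, mM; non-negative.
#' @param noise_sd Detector noise standard deviation, mAU; >= 0.
#' @param seed Optional integer seed.
#' @param times Time grid, min.
#' @return A [chromatogram()].
#' @export
simulate_lc <- function(analyte, c_total, noise_sd = 0.5, seed = NULL,
                        times = .default_times()) {
  assert_scalar_num(c_total, "c_total", nonneg = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  area <- analyte$response_factor * c_total
  height <- area / (analyte$retention_width * sqrt(2 * pi))
  ab <- height * exp(-((times - analyte$retention_time)^2) /
                       (2 * analyte$retention_width^2))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    ab <- ab + stats::rnorm(length(ab), sd = noise_sd)
  }
  chromatogram(times, ab,
               label = sprintf("%s total=%g mM", analyte$name, c_total))
}

#' pH attenuation of the CD signal
#'
#' Amino-acid CD intensity is stable across the mid-pH plateau (pH 3--8)
#' and falls off toward strongly acidic or basic conditions as protonation
#' states shift. The attenuation is modelled as 1 on the plateau with
#' piecewise-linear ramps reaching `floor_acid` at pH 1 and `floor_base` at
#' pH 12, clamped at those floors beyond.
#'
#' @param pH Solution pH in `[0, 14]`; vectorised.
#' @param floor_acid,floor_base Attenuation floors at the acidic and basic
#'   ends, in `[0, 1]`.
#' @return Multiplicative attenuation factor(s) in `[0, 1]`.
#' @examples
#' ph_factor(7)   # 1
#' ph_factor(1)   # acid floor
#' @export
ph_factor <- function(pH, floor_acid = 0.6, floor_base = 0.5) {
  if (!is.numeric(pH) || any(!is.finite(pH)))
    cdq_stop("invalid_parameter", "`pH` must be finite numeric")
  if (any(pH < 0 | pH > 14))
    cdq_stop("invalid_parameter", "`pH` must lie in [0, 14]")
  f <- rep(1, length(pH))
  lo <- pH < 3
  f[lo] <- pmax(floor_acid, floor_acid + (1 - floor_acid) * (pH[lo] - 1) / 2)
  hi <- pH > 8
  f[hi] <- pmax(floor_base, 1 - (1 - floor_base) * (pH[hi] - 8) / 4)
  f
}

# Deterministic per-element seed derivation from one master seed.
derive_seed <- function(seed, i) (as.integer(seed) + 7919L * as.integer(i)) %% 2147483629L

#' Simulate a calibration standard series
#'
#' One spectrum per listed concentration for a pure L or pure D standard,
#' with per-spectrum seeds derived deterministically from the master seed so
#' the whole series is reproducible element-wise.
#'
#' @param analyte An [analyte_spec()].
#' @param concs Non-empty vector of concentrations, mM; all >= 0.
#' @param handedness `"L"` or `"D"`.
#' @param noise_sd Noise sd, mdeg.
#' @param seed Optional master seed.
#' @param path_len Path length, cm.
#' @param wavelengths Wavelength grid, nm.
#' @return A list with one element per concentration, each a list with
#'   fields `conc` (mM) and `spectrum` (a [cd_spectrum()]).
#' @export
make_calibration_series <- function(analyte, concs, handedness = c("L", "D"),
                                    noise_sd = 0.02, seed = NULL,
                                    path_len = .default_path_len,
                                    wavelengths = .default_wavelengths()) {
  handedness <- match.arg(handedness)
  if (length(concs) < 1L)
    cdq_stop("invalid_parameter", "`concs` must be non-empty")
  lapply(seq_along(concs), function(i) {
    ci <- concs[i]
    si <- if (is.null(seed)) NULL else derive_seed(seed, i)
    sp <- if (handedness == "L")
      simulate_cd(analyte, c_L = ci, c_D = 0, path_len = path_len,
                  noise_sd = noise_sd, seed = si, wavelengths = wavelengths)
    else
      simulate_cd(analyte, c_L = 0, c_D = ci, path_len = path_len,
                  noise_sd = noise_sd, seed = si, wavelengths = wavelengths)
    list(conc = ci, spectrum = sp)
  })
}

#' Bundled example analytes
#'
#' Three ready-made [analyte_spec()] fixtures loosely modelled on leucine,
#' proline and methionine. Each carries a single positive Cotton band in the
#' far-UV; band amplitudes are chosen so the peak-ellipticity calibration
#' slope at the default 0.1 cm path equals the corresponding published
#' single-analyte calibration slope (0.1927, 1.0363 and 0.1899 mdeg/mM) — a
#' convenience anchor for simulations, not a claim about true molar CD
#' values.
#'
#' @param path_len Path length (cm) at which the slope anchor applies.
#' @return Named list of `analyte_spec` objects: `leu`, `pro`, `met`.
#' @export
default_analytes <- function(path_len = .default_path_len) {
  amp <- function(slope) slope / (.theta_factor * path_len)
  list(
    leu = analyte_spec("Leu", cotton_band(202, 8, amp(0.1927)),
                       retention_time = 3.6, retention_width = 0.08,
                       response_factor = 20),
    pro = analyte_spec("Pro", cotton_band(199, 7, amp(1.0363)),
                       retention_time = 2.2, retention_width = 0.07,
                       response_factor = 45),
    met = analyte_spec("Met", cotton_band(204, 9, amp(0.1899)),
                       retention_time = 2.9, retention_width = 0.09,
                       response_factor = 70)
  )
}
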