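# Core CD signal law.
#
# Circular dichroism measures the differential absorbance of left- vs
# right-circularly polarised light, dA = A_L - A_R = de * c * l, where de is
# the molar circular dichroism (L mol^-1 cm^-1), c the molar concentration
# (mol/L) and l the path length (cm). Spectra are historically reported as
# ellipticity theta = 3298 * dA (degrees); instruments print millidegrees.
# The conversion factor 3298 is treated as an exact defined constant.

.theta_factor <- 3298

#' Parameters of the CD signal law
#'
#' Bundles the three quantities entering the differential-absorbance law
#' \eqn{\Delta A = \Delta\varepsilon \, c \, l}: the molar circular dichroism
#' \eqn{\Delta\varepsilon} (signed, L mol\eqn{^{-1}} cm\eqn{^{-1}}), the molar
#' concentration \eqn{c} (mol/L) and the cuvette path length \eqn{l} (cm).
#'
#' @param delta_eps Molar circular dichroism, signed. Opposite in sign for
#'   the two enantiomers of a chiral compound.
#' @param conc Molar concentration, mol/L; must be non-negative.
#' @param path_len Path length in cm; must be strictly positive.
#' @return An object of class `cd_signal_params`.
#' @examples
#' p <- cd_signal_params(delta_eps = -2, conc = 0.5, path_len = 1)
#' delta_absorbance(p)
#' @export
cd_signal_params <- function(delta_eps, conc, path_len) {
  assert_scalar_num(delta_eps, "delta_eps")
  assert_scalar_num(conc, "conc", nonneg = TRUE)
  assert_scalar_num(path_len, "path_len", positive = TRUE)
  structure(list(delta_eps = delta_eps, conc = conc, path_len = path_len),
            class = "cd_signal_params")
}

#' Differential absorbance of a chiral sample
#'
#' Evaluates \eqn{\Delta A = \Delta\varepsilon \, c \, l}. The sign follows
#' the sign of `delta_eps`; the result is dimensionless.
#'
#' @param params A [cd_signal_params()] object.
#' @return Differential absorbance \eqn{\Delta A}.
#' @export
delta_absorbance <- function(params) {
  if (!inherits(params, "cd_signal_params"))
    params <- do.call(cd_signal_params, as.list(params))
  params$delta_eps * params$conc * params$path_len
}

#' Convert differential absorbance to ellipticity (degrees)
#'
#' \eqn{\theta = 3298 \, \Delta A}. The factor 3298 converts differential
#' absorbance to the historical degree scale of ellipticity and is exact
#' here. [deltaA_from_ellipticity()] is its exact inverse.
#'
#' @param delta_a Differential absorbance (dimensionless); vectorised.
#' @return Ellipticity in degrees.
#' @examples
#' ellipticity_from_deltaA(1)  # 3298
#' @export
ellipticity_from_deltaA <- function(delta_a) .theta_factor * delta_a

#' @rdname ellipticity_from_deltaA
#' @param theta_deg Ellipticity in degrees.
#' @export
deltaA_from_ellipticity <- function(theta_deg) theta_deg / .theta_factor

#' Invert the signal law: concentration from ellipticity
#'
#' \eqn{c = \theta / (3298 \, \Delta\varepsilon \, l)}, the inverse of the
#' forward chain [delta_absorbance()] then [ellipticity_from_deltaA()].
#' An achiral analyte (`delta_eps == 0`) has no CD response and cannot be
#' quantified this way.
#'
#' @param theta_deg Ellipticity in degrees; vectorised.
#' @param delta_eps Molar circular dichroism; must be non-zero.
#' @param path_len Path length in cm; must be positive.
#' @return Molar concentration, mol/L (signed: a negative value means the
#'   signal has the sign opposite to `delta_eps`).
#' @export
conc_from_theta <- function(theta_deg, delta_eps, path_len) {
  assert_scalar_num(delta_eps, "delta_eps")
  assert_scalar_num(path_len, "path_len", positive = TRUE)
  if (delta_eps == 0)
    cdq_stop("degenerate_analyte",
             "delta_eps is 0: achiral response, no CD-based quantification possible")
  theta_deg / (.theta_factor * delta_eps * path_len)
}

#' Millidegree/degree conversion
#'
#' CD instruments report ellipticity in millidegrees; the signal-law factor
#' 3298 is stated for degrees. `deg_to_mdeg()` and `mdeg_to_deg()` convert
#' between the two scales.
#'
#' @param theta_deg,theta_mdeg Ellipticity values; vectorised.
#' @return The converted ellipticity.
#' @export
deg_to_mdeg <- function(theta_deg) 1000 * theta_deg

#' @rdname deg_to_mdeg
#' @export
mdeg_to_deg <- function(theta_mdeg) theta_mdeg / 1000
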