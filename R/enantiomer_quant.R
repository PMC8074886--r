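# Mixture deconvolution.
#
# CD sees only the enantiomer imbalance: inverting the mixture ellipticity
# against an L-standard calibration gives a signed quantity whose magnitude
# is c_a = |c1 - c2| and whose sign marks which enantiomer is in excess.
# An achiral LC column cannot tell the enantiomers apart, so its peak area
# calibrates to the sum c_b = c1 + c2. The two linear relations solve to
# c1 = (c_b + s * c_a)/2 and c2 = (c_b - s * c_a)/2 with s the excess sign.

#' Paired CD/LC measurement of an enantiomer mixture
#'
#' @param c_a Absolute concentration difference `|c1 - c2|` from the CD
#'   channel, mM; >= 0.
#' @param excess_sign `+1` (L excess), `-1` (D excess) or `0` (racemic).
#' @param c_b Concentration sum `c1 + c2` from the LC channel, mM; >= 0.
#' @return A `mixture_measurement` object.
#' @export
mixture_measurement <- function(c_a, excess_sign, c_b) {
  assert_scalar_num(c_a, "c_a", nonneg = TRUE)
  assert_scalar_num(c_b, "c_b", nonneg = TRUE)
  if (!excess_sign %in% c(-1, 0, 1))
    cdq_stop("invalid_parameter", "`excess_sign` must be -1, 0 or +1")
  structure(list(c_a = c_a, excess_sign = excess_sign, c_b = c_b),
            class = "mixture_measurement")
}

#' Design of a volumetric enantiomer mixture
#'
#' Two stocks of the same concentration `c_stock`, one L and one D, mixed at
#' volume fractions `ratio_L : ratio_D` (summing to 1).
#'
#' @param c_stock Common stock concentration, mM; >= 0.
#' @param ratio_L,ratio_D Volume fractions in `[0, 1]` summing to 1.
#' @return A `mixture_design` object.
#' @export
mixture_design <- function(c_stock, ratio_L, ratio_D = 1 - ratio_L) {
  assert_scalar_num(c_stock, "c_stock", nonneg = TRUE)
  assert_scalar_num(ratio_L, "ratio_L", nonneg = TRUE)
  assert_scalar_num(ratio_D, "ratio_D", nonneg = TRUE)
  if (abs(ratio_L + ratio_D - 1) > 1e-9)
    cdq_stop("invalid_design",
             sprintf("ratio_L + ratio_D must equal 1 (got %g)", ratio_L + ratio_D))
  structure(list(c_stock = c_stock, ratio_L = ratio_L, ratio_D = ratio_D),
            class = "mixture_design")
}

#' Nominal enantiomer concentrations of a mixture design
#'
#' @param design A [mixture_design()].
#' @return Named numeric `c(c1 = , c2 = )`: L and D concentrations, mM
#'   (`c_stock * ratio_L`, `c_stock * ratio_D`).
#' @examples
#' expected_mixture(mixture_design(8, 0.60))   # 4.80, 3.20
#' expected_mixture(mixture_design(25, 0.55))  # 13.75, 11.25
#' @export
expected_mixture <- function(design) {
  c(c1 = design$c_stock * design$ratio_L, c2 = design$c_stock * design$ratio_D)
}

#' Solve for absolute L and D concentrations
#'
#' Combines the CD-derived difference and LC-derived sum:
#' `c1 = (c_b + s c_a)/2`, `c2 = (c_b - s c_a)/2` with `s` the excess sign.
#' A zero sign demands `c_a <= tol` and yields the racemic split. A
#' difference exceeding the sum (`c_a > c_b`) would imply a negative
#' concentration; by default this raises an infeasible-measurement error
#' (silent clipping hides calibration inconsistency), or with
#' `clip = TRUE` the smaller component is set to 0 and the result flagged.
#'
#' @param m A [mixture_measurement()].
#' @param tol Racemic tolerance on `c_a` when `excess_sign` is 0, mM.
#' @param clip Clip an infeasible `c_a > c_b` to the pure-enantiomer
#'   boundary instead of erroring.
#' @return A `mixture_result`: fields `c1`, `c2` (mM), `ee` (% enantiomeric
#'   excess, `100 (c1 - c2)/(c1 + c2)`, 0 for an empty mixture),
#'   `measurement`, and `flags` (character vector of warnings).
#' @examples
#' solve_enantiomers(mixture_measurement(2.60, +1, 13.00))  # 7.80 / 5.20
#' @export
solve_enantiomers <- function(m, tol = 1e-9, clip = FALSE) {
  flags <- character(0)
  c_a <- m$c_a
  s <- m$excess_sign
  if (s == 0) {
    if (c_a > tol)
      cdq_stop("infeasible_measurement",
               sprintf("excess_sign 0 but c_a = %g exceeds racemic tolerance %g", c_a, tol),
               c_a = c_a, c_b = m$c_b)
    c_a <- 0
  }
  if (c_a > m$c_b) {
    if (!clip)
      cdq_stop("infeasible_measurement",
               sprintf("c_a = %g exceeds c_b = %g: would imply a negative concentration",
                       c_a, m$c_b),
               c_a = c_a, c_b = m$c_b)
    flags <- c(flags, sprintf("clipped: c_a %.6g > c_b %.6g, smaller component set to 0",
                              c_a, m$c_b))
    c_a <- m$c_b
  }
  # larger component first; the smaller by subtraction is then exact
  # (Sterbenz) and c1 + c2 reproduces c_b bit-for-bit
  hi <- (m$c_b + c_a) / 2
  lo <- m$c_b - hi
  if (s >= 0) { c1 <- hi; c2 <- lo } else { c1 <- lo; c2 <- hi }
  ee <- if (m$c_b > 0) 100 * (c1 - c2) / (c1 + c2) else 0
  structure(list(c1 = c1, c2 = c2, ee = ee, measurement = m, flags = flags),
            class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf("<mixture_result> c1 (L) = %.4f mM, c2 (D) = %.4f mM, ee = %.2f%%\n",
              x$c1, x$c2, x$ee))
  cat(sprintf("  from c_a = %.4f, sign = %+d, c_b = %.4f\n",
              x$measurement$c_a, as.integer(x$measurement$excess_sign),
              x$measurement$c_b))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  if (!is.null(x$reference))
    cat(sprintf("  vs reference (%.2f, %.2f): diff %.1f%% / %.1f%%\n",
                x$reference[1], x$reference[2], x$diff_pct[1], x$diff_pct[2]))
  invisible(x)
}

#' Relative difference between an experimental and a reference value
#'
#' The accuracy statistic `100 |exp - cal| / cal`, in percent; reporting
#' layers round it to one decimal (ties away from zero).
#'
#' @param exp_val Experimental value.
#' @param cal_val Reference ("calculated") value; must be > 0.
#' @return Percent relative difference; vectorised.
#' @examples
#' diff_percent(3.50, 3.20)  # 9.375 -> printed as 9.4
#' @export
diff_percent <- function(exp_val, cal_val) {
  if (any(!is.finite(cal_val)) || any(cal_val <= 0))
    cdq_stop("invalid_reference", "reference value must be finite and > 0")
  100 * abs(exp_val - cal_val) / cal_val
}

#' Quantify an enantiomer mixture from a CD spectrum and an LC trace
#'
#' Full pipeline: extract the signed peak ellipticity from the mixture CD
#' spectrum and invert it against the L-standard CD curve, giving the
#' signed imbalance `d`; its magnitude is `c_a` and its sign the excess
#' sign, with `|d|` below `max(LOD, 1e-9)` treated as racemic (sub-LOD
#' signed values are noise). Integrate the LC peak and invert against the
#' LC curve for `c_b`. Then [solve_enantiomers()]. All intermediates are
#' kept in the result.
#'
#' @param cd_spec Mixture [cd_spectrum()].
#' @param chrom Mixture [chromatogram()].
#' @param cd_curve L-standard CD `calibration_curve` (signal: peak mdeg).
#' @param lc_curve LC `calibration_curve` (signal: area, mAU min).
#' @param cd_rule [signal_rule()] for the CD extraction; defaults to the
#'   curve's stored rule, else peak over 190--220 nm.
#' @param lc_window Length-2 integration window, min.
#' @param baseline_windows Passed to [integrate_peak()].
#' @param clip_infeasible Passed to [solve_enantiomers()] as `clip`.
#' @param reference Optional length-2 numeric `c(c1, c2)` of nominal
#'   concentrations; when supplied, per-component [diff_percent()] accuracy
#'   is attached to the result.
#' @return A `mixture_result` with extra fields `intermediates` (list:
#'   `theta`, `wavelength`, `d`, `c_a`, `excess_sign`, `area`, `c_b`) and,
#'   given a reference, `reference` and `diff_pct`.
#' @export
quantify_mixture <- function(cd_spec, chrom, cd_curve, lc_curve,
                             cd_rule = NULL, lc_window,
                             baseline_windows = NULL,
                             clip_infeasible = FALSE, reference = NULL) {
  if (is.null(cd_rule))
    cd_rule <- if (!is.null(cd_curve$extraction)) cd_curve$extraction else signal_rule()
  ext <- extract_signal(cd_spec, cd_rule)
  inv_cd <- invert_calibration(cd_curve, ext$theta)
  d <- inv_cd$conc
  racemic_tol <- max(cd_curve$lod, 1e-9)
  if (abs(d) < racemic_tol) {
    c_a <- 0; s <- 0
  } else {
    c_a <- abs(d); s <- sign(d)
  }
  area <- integrate_peak(chrom, lc_window[1], lc_window[2],
                         baseline_windows = baseline_windows)
  inv_lc <- invert_calibration(lc_curve, area)
  c_b <- inv_lc$conc
  flags <- character(0)
  if (c_b < 0) {
    flags <- c(flags, sprintf("LC sum inverted negative (%.4g mM), clamped to 0", c_b))
    c_b <- 0
  }
  if (!inv_cd$in_range) flags <- c(flags, "CD difference outside calibrated range/LOQ")
  if (!inv_lc$in_range) flags <- c(flags, "LC sum outside calibrated range/LOQ")
  res <- solve_enantiomers(mixture_measurement(c_a, s, c_b),
                           tol = racemic_tol, clip = clip_infeasible)
  res$flags <- c(res$flags, flags)
  res$intermediates <- list(theta = ext$theta, wavelength = ext$wavelength,
                            d = d, c_a = c_a, excess_sign = s,
                            area = area, c_b = c_b)
  if (!is.null(reference)) {
    res$reference <- reference
    res$diff_pct <- c(diff_percent(res$c1, reference[1]),
                      diff_percent(res$c2, reference[2]))
  }
  res
}

#' Format a mixture result as a one-row report
#'
#' Column order follows the published mixture tables: nominal (Cal.),
#' experimental (Exp.) and percent difference per enantiomer; Cal./diff
#' columns are `NA` when no reference was supplied. Concentrations are
#' rounded to `digits` decimals, differences to one decimal, ties away from
#' zero.
#'
#' @param result A `mixture_result`.
#' @param digits Reporting precision for concentrations.
#' @return A one-row `data.frame`.
#' @export
report_row <- function(result, digits = 2) {
  ref <- result$reference
  data.frame(
    cal_L = if (is.null(ref)) NA_real_ else round_half_up(ref[1], digits),
    cal_D = if (is.null(ref)) NA_real_ else round_half_up(ref[2], digits),
    exp_L = round_half_up(result$c1, digits),
    exp_D = round_half_up(result$c2, digits),
    diff_L = if (is.null(ref)) NA_real_ else round_half_up(result$diff_pct[1], 1),
    diff_D = if (is.null(ref)) NA_real_ else round_half_up(result$diff_pct[2], 1)
  )
}
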