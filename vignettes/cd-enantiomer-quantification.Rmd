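---
title: "Quantifying enantiomer mixtures with CD and achiral LC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enantiomer mixtures with CD and achiral LC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdquant)
```

## The measurement model

Circular dichroism (CD) reports the differential absorbance of left- and
right-circularly polarised light by a chiral sample,
$\Delta A = \Delta\varepsilon\,c\,l$, with $\Delta\varepsilon$ the molar
circular dichroism (L mol$^{-1}$ cm$^{-1}$), $c$ the molar concentration
and $l$ the path length in cm. Spectra are conventionally expressed as
ellipticity $\theta = 3298\,\Delta A$ in degrees; we treat 3298 as an exact
defined constant and work internally in millidegrees, the unit instruments
actually print (`deg_to_mdeg()`/`mdeg_to_deg()` convert). Everything above
the signal law speaks mM, the scale laboratory standard series are prepared
at; the mM/M and deg/mdeg conversions cancel so that the simulator's
millidegree signal per mM is simply $3298\,\Delta\varepsilon\,l$.

Three facts make the mixture problem solvable with two *achiral-selectivity*
measurements:

1. enantiomers have exactly opposite $\Delta\varepsilon$, so the CD signal
   of a mixture is proportional to $c_1 - c_2$ (L minus D) and a racemic
   mixture is CD-silent;
2. within the linear range, ellipticity at any wavelength is proportional
   to concentration, so an L-standard calibration curve inverted on a
   mixture signal yields a signed imbalance $d$ with $|d| = c_a = |c_1-c_2|$
   and $\mathrm{sign}(d)$ the excess enantiomer (positive Cotton effects at
   190–220 nm for the L series);
3. enantiomers co-elute on an achiral LC column, so the peak area
   calibrates to the sum $c_b = c_1 + c_2$.

`solve_enantiomers()` combines these as $c_1 = (c_b + s\,c_a)/2$,
$c_2 = (c_b - s\,c_a)/2$. Numerically we compute the larger component first
and obtain the smaller by subtraction: by Sterbenz's lemma that subtraction
is exact in floating point, so the returned pair always satisfies
$c_1 + c_2 = c_b$ bit-for-bit. A measured $c_a > c_b$ would imply a
negative concentration; it is a hard error by default because it signals an
inconsistency between the two calibrations — clipping to the
pure-enantiomer boundary is available (`clip = TRUE`) but always flagged.

## What the simulator emulates — and what it does not

No instrument data ship with the package; a forward simulator stands in
for the CD spectrometer and the LC system so that every stage is testable.

* **Band shape.** Cotton effects are modelled as Gaussians in wavelength —
  the standard chiroptical band approximation. Real amino-acid far-UV
  bands are asymmetric and overlap with buffer absorbance; none of that is
  modelled, so passing tests demonstrate correctness of the *analysis*, not
  robustness to real band shapes.
* **Mirror rule.** The D-enantiomer spectrum is the exact pointwise
  negation of the L spectrum, and mixtures are strictly additive. This is
  the idealisation the method itself assumes (no enantiomer aggregation or
  chiral solvent effects).
* **Noise.** Additive, homoscedastic, independent Gaussian noise per grid
  point (default 0.02 mdeg for CD, 0.5 mAU for LC). Real CD noise grows
  steeply below 195 nm as the photomultiplier voltage rises; baseline
  drift, stray light and saturation are out of scope. The defaults were
  chosen so that a five-point calibration lands in the R² ≥ 0.999 regime
  reported for the bench method.
* **LC peak.** A single Gaussian at the analyte's retention time with area
  `response_factor × c_total`, independent of the L:D ratio (perfect
  co-elution). Tailing, column overload and gradient artefacts are not
  modelled.
* **pH.** Only a scalar attenuation: `ph_factor()` is 1 on the pH 3–8
  plateau where amino-acid CD intensity is stable, with invented
  piecewise-linear ramps to configurable floors (0.6 at pH 1, 0.5 at
  pH 12). Band *shifts* with protonation state are not modelled.
* **Grids.** 185–260 nm at 0.5 nm for CD (covering the 190–220 nm window
  with margin) and 0–6 min at 0.01 min for LC; path length defaults to
  0.1 cm, the usual far-UV cuvette.
* **Anchoring.** The bundled `default_analytes()` ("Leu", "Pro", "Met")
  carry single positive far-UV bands whose amplitudes are tuned so each
  peak-ellipticity calibration slope at the default path length equals a
  published single-analyte slope (0.1927, 1.0363, 0.1899 mdeg/mM). This is
  a convenience anchor that puts simulations on a realistic signal scale —
  not a claim about the true $\Delta\varepsilon$ of those amino acids.
* **Seeding.** One master seed; series members derive per-element seeds by
  fixed modular arithmetic, so any simulated object is bitwise reproducible.

## Calibration choices

* **Unweighted OLS** (`fit_calibration()`), five points being the typical
  series length. Heteroscedastic weighting and nonlinear models are out of
  scope. The fit is rejected below 3 points, with zero concentration
  variance, or with |slope| under `slope_eps` (default 1e-12).
* **Signal extraction** (`extract_signal()`): the default rule takes the
  grid point of maximum |θ| inside 190–220 nm, keeping the sign; exact ties
  resolve to the lowest wavelength. A fixed-wavelength mode is available.
  Because the same rule (with the same small max-of-noise bias) is applied
  to standards and unknowns, the bias is largely absorbed by the fitted
  intercept.
* **LOD/LOQ**: converted to concentration as $3\sigma/|m|$ and
  $10\sigma/|m|$ from the S/N = 3 and S/N = 10 definitions, with $\sigma$
  the known noise sd if supplied, else the residual standard error.
  Published LOD/LOQ values for the bench instruments follow no single
  σ-rule and are deliberately not reproduced.
* **Validity range** is the extreme of the input series; inverse
  predictions outside it, or below the LOQ, are flagged (`in_range`),
  never fatal — a mixture *difference* can legitimately sit below the
  range the standards were prepared at.
* **Racemic tolerance**: in `quantify_mixture()` a signed CD inversion
  with $|d| < \max(\mathrm{LOD}, 10^{-9}\,\mathrm{mM})$ is treated as sign
  0 (racemic), since a sub-LOD sign is noise.
* **Peak integration** (`integrate_peak()`): trapezoidal, with an optional
  constant baseline estimated as the mean absorbance over user-given
  baseline windows (none by default).
* **Reporting**: concentrations at 2 decimals and percent differences at
  1 decimal, rounding ties away from zero — plain `round()` would turn a
  recomputed 6.25 % into 6.2 % where the reference tables print 6.3 %.
  Internal values keep full precision.

## Reference-table replay

Two transcribed accuracy tables ship under `inst/extdata/`: single-analyte
checks (L/D Leu, Pro, Met, Trp) and 36 mixture deconvolutions (three
stocks × four L:D ratios per analyte). `validate_reference_tables()`
recomputes every nominal concentration from stock × mixing ratio and every
percent difference from its own Cal./Exp. pair, and names any cell that
disagrees. Two printed cells are internally inconsistent in the source
(one single-analyte Pro cell prints 4.2 % where its own pair gives 4.0 %,
consistent instead with dividing by the experimental value; one mixture
Pro cell prints 1.6 % where its pair gives 0.5 %); the validator reports
exactly these, and the test suite pins that behaviour rather than
reproducing the typos. The headline figures hold as recomputed: all
single-analyte differences ≤ 7.7 % and all mixture differences ≤ 9.4 %,
i.e. under the claimed 10 %.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` use five-point calibrations,
200-replicate Monte-Carlo recovery runs (per-component error < 10 % in at
least 95 % of replicates at default noise), 200-replicate R²-regime checks,
a 10⁴-pair exact round-trip grid for the solver, and 100-replicate minimum
R² for the headline figure — sizes at which every result is stable to the
seed while the whole suite runs in seconds.

## Known limitations

* Exactly two co-eluting chiral species; diastereomers or a third chiral
  component violate the two-equation model silently.
* Both channels must be in their linear ranges; the package flags but does
  not correct saturation or nonlinearity.
* The CD and LC measurements are independent (no hyphenated LC-CD); volume
  cancellation assumes both aliquots come from the same mixture.
* Uncertainty propagation from calibration residuals is not reported by
  default; the `sigma` field of each curve carries what first-order
  propagation would need.
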