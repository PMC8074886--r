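# Shared fixtures: everything is generated in code at test time.

LEU <- default_analytes()$leu
LC_WINDOW <- c(3.0, 4.2)   # brackets the Leu retention peak (3.6 +- 0.6 min)

# Build matched CD (L-standard) and LC calibration curves from the simulator.
build_curves <- function(analyte = LEU, concs = c(5, 10, 15, 20, 25),
                         noise_sd_cd = 0, noise_sd_lc = 0, seed = NULL,
                         lc_window = LC_WINDOW) {
  ser <- make_calibration_series(analyte, concs, "L",
                                 noise_sd = noise_sd_cd, seed = seed)
  cd_sig <- vapply(ser, function(e) extract_signal(e$spectrum)$theta, numeric(1))
  cd <- fit_calibration(concs, cd_sig, "CD",
                        noise_sd = if (noise_sd_cd > 0) noise_sd_cd else NULL,
                        extraction = signal_rule())
  lc_area <- vapply(seq_along(concs), function(i) {
    si <- if (is.null(seed)) NULL else seed + 10000L + i
    integrate_peak(simulate_lc(analyte, concs[i], noise_sd = noise_sd_lc,
                               seed = si),
                   lc_window[1], lc_window[2])
  }, numeric(1))
  lc <- fit_calibration(concs, lc_area, "LC",
                        noise_sd = if (noise_sd_lc > 0) noise_sd_lc else NULL)
  list(cd = cd, lc = lc)
}

# Closed-form simple-regression oracle, independent of stats::lm.
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- slope * x + intercept
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
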