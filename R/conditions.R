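# Classed conditions so callers can distinguish failure modes with
# expect_error(class = ...) / tryCatch(cdq_<class> = ...).
cdq_stop <- function(class, msg, ..., call = sys.call(-1)) {
  stop(errorCondition(msg, ...,
                      class = c(paste0("cdq_", class), "cdq_error"),
                      call = call))
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                              finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)))
    cdq_stop("invalid_parameter", sprintf("`%s` must be a finite numeric scalar", name))
  if (positive && x <= 0)
    cdq_stop("invalid_parameter", sprintf("`%s` must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    cdq_stop("invalid_parameter", sprintf("`%s` must be >= 0 (got %g)", name, x))
  invisible(x)
}

# One-decimal rounding with ties away from zero, the convention used by the
# published accuracy tables (plain round() would turn 6.25 into 6.2).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
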