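test_that("nominal mixture concentrations follow stock times volume ratio", {
  expect_equal(expected_mixture(mixture_design(8, 0.60)),
               c(c1 = 4.80, c2 = 3.20))
  expect_equal(expected_mixture(mixture_design(25, 0.55)),
               c(c1 = 13.75, c2 = 11.25))
  expect_equal(expected_mixture(mixture_design(7, 0.5)), c(c1 = 3.5, c2 = 3.5))
  expect_error(mixture_design(8, 0.6, 0.5), class = "cdq_invalid_design")
})

test_that("the difference/sum solver returns the published worked example", {
  r <- solve_enantiomers(mixture_measurement(2.60, +1, 13.00))
  expect_equal(c(r$c1, r$c2), c(7.80, 5.20))
  expect_equal(r$ee, 100 * 2.60 / 13.00)
  rac <- solve_enantiomers(mixture_measurement(0, 0, 10))
  expect_equal(c(rac$c1, rac$c2), c(5, 5))
  pureD <- solve_enantiomers(mixture_measurement(5, -1, 5))
  expect_equal(c(pureD$c1, pureD$c2), c(0, 5))
  expect_equal(pureD$ee, -100)
  empty <- solve_enantiomers(mixture_measurement(0, 0, 0))
  expect_identical(empty$ee, 0)
})

test_that("solver algebra round-trips exactly over a randomized grid", {
  set.seed(2024)
  n <- 10000L
  # dyadic concentrations (multiples of 2^-10 mM, 0-50 mM): sums and
  # differences are exactly representable, so recovery must be bit-exact
  c1 <- sample.int(51201L, n, replace = TRUE) / 1024
  c2 <- sample.int(51201L, n, replace = TRUE) / 1024
  bad <- 0L
  for (i in seq_len(n)) {
    m <- mixture_measurement(abs(c1[i] - c2[i]), sign(c1[i] - c2[i]), c1[i] + c2[i])
    r <- solve_enantiomers(m, tol = 1e-12)
    if (!identical(c(r$c1, r$c2), c(c1[i], c2[i]))) bad <- bad + 1L
    if (!identical(r$c1 + r$c2, m$c_b)) bad <- bad + 1L
    if (r$ee < -100 || r$ee > 100) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("swapping the excess sign swaps the two enantiomers", {
  set.seed(31)
  for (i in 1:50) {
    cb <- stats::runif(1, 1, 40)
    ca <- stats::runif(1, 0, cb)
    rp <- solve_enantiomers(mixture_measurement(ca, +1, cb))
    rm <- solve_enantiomers(mixture_measurement(ca, -1, cb))
    expect_identical(c(rp$c1, rp$c2), c(rm$c2, rm$c1))
    expect_identical(rp$ee, -rm$ee)
  }
})

test_that("infeasible difference > sum errors by default and clips on request", {
  m <- mixture_measurement(6, +1, 5)
  err <- tryCatch(solve_enantiomers(m), condition = identity)
  expect_s3_class(err, "cdq_infeasible_measurement")
  expect_equal(err$c_a, 6)
  expect_equal(err$c_b, 5)
  clipped <- solve_enantiomers(m, clip = TRUE)
  expect_equal(c(clipped$c1, clipped$c2), c(5, 0))
  expect_true(any(grepl("clipped", clipped$flags)))
  # a nonzero difference with a claimed-racemic sign is inconsistent
  expect_error(solve_enantiomers(mixture_measurement(0.5, 0, 10), tol = 1e-9),
               class = "cdq_infeasible_measurement")
})

test_that("the accuracy statistic is percent deviation from the reference", {
  expect_equal(round_half_up(diff_percent(3.50, 3.20), 1), 9.4)
  expect_equal(round_half_up(diff_percent(14.00, 13.00), 1), 7.7)
  expect_identical(diff_percent(4, 4), 0)
  expect_error(diff_percent(1, 0), class = "cdq_invalid_reference")
})

test_that("noise-free end-to-end quantification recovers the design exactly", {
  curves <- build_curves(noise_sd_cd = 0, noise_sd_lc = 0)
  ref <- expected_mixture(mixture_design(8, 0.60))
  res <- quantify_mixture(simulate_cd(LEU, ref[1], ref[2], noise_sd = 0),
                          simulate_lc(LEU, sum(ref), noise_sd = 0),
                          curves$cd, curves$lc, lc_window = LC_WINDOW,
                          reference = ref)
  expect_equal(c(res$c1, res$c2), unname(ref), tolerance = 1e-6)
  expect_equal(unname(res$diff_pct), c(0, 0), tolerance = 1e-4)
  # D-excess mixture: sign comes out negative and the components swap
  res2 <- quantify_mixture(simulate_cd(LEU, ref[2], ref[1], noise_sd = 0),
                           simulate_lc(LEU, sum(ref), noise_sd = 0),
                           curves$cd, curves$lc, lc_window = LC_WINDOW)
  expect_equal(res2$intermediates$excess_sign, -1)
  expect_equal(c(res2$c1, res2$c2), unname(ref[c(2, 1)]), tolerance = 1e-6)
  # racemic mixture: difference below tolerance, even split
  res3 <- quantify_mixture(simulate_cd(LEU, 4, 4, noise_sd = 0),
                           simulate_lc(LEU, 8, noise_sd = 0),
                           curves$cd, curves$lc, lc_window = LC_WINDOW)
  expect_equal(res3$intermediates$excess_sign, 0)
  expect_equal(c(res3$c1, res3$c2), c(4, 4), tolerance = 1e-6)
})

test_that("recovery error vanishes as instrument noise is dialled to zero", {
  ref <- expected_mixture(mixture_design(8, 0.60))
  mean_err <- function(noise) {
    mean(vapply(1:20, function(r) {
      curves <- build_curves(noise_sd_cd = noise, noise_sd_lc = noise * 25,
                             seed = 7000L + r)
      res <- quantify_mixture(
        simulate_cd(LEU, ref[1], ref[2], noise_sd = noise, seed = 8000L + r),
        simulate_lc(LEU, sum(ref), noise_sd = noise * 25, seed = 9000L + r),
        curves$cd, curves$lc, lc_window = LC_WINDOW)
      max(abs(c(res$c1, res$c2) - ref))
    }, numeric(1)))
  }
  errs <- vapply(c(0.02, 0.002, 0), mean_err, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-6)
})

test_that("Monte-Carlo recovery at default noise stays under 10% per component", {
  ref <- expected_mixture(mixture_design(8, 0.60))
  ok <- vapply(1:200, function(r) {
    curves <- build_curves(noise_sd_cd = 0.02, noise_sd_lc = 0.5, seed = 20000L + r)
    res <- quantify_mixture(
      simulate_cd(LEU, ref[1], ref[2], noise_sd = 0.02, seed = 30000L + r),
      simulate_lc(LEU, sum(ref), noise_sd = 0.5, seed = 40000L + r),
      curves$cd, curves$lc, lc_window = LC_WINDOW, reference = ref)
    all(res$diff_pct < 10)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
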