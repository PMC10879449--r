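test_that("taper banks are orthonormal and correctly shaped", {
  for (fam in c("dpss", "sine")) {
    bank <- build_taper_bank(128L, 3L, fam)
    gram <- bank$tapers %*% t(bank$tapers)
    expect_lt(max(abs(gram - diag(3L))), 1e-8)
    expect_equal(dim(bank$tapers), c(3L, 128L))
  }
  bank4 <- build_taper_bank(128L, 4L, "sine")
  expect_equal(dim(bank4$tapers), c(4L, 128L))
  expect_error(build_taper_bank(128L, 3L, "hamming"))
})

test_that("single-taper spectrum of white noise is flat in expectation", {
  bank <- build_taper_bank(128L, 1L, "dpss")
  set.seed(4)
  # average many periodograms; band estimates over equal-width sub-bands of
  # (0, 2) should agree with each other and with sigma^2 * width / nyquist
  bands <- list(band_spec(0.3, 0.7), band_spec(0.8, 1.2), band_spec(1.3, 1.7))
  est <- matrix(NA_real_, 40L, 3L)
  for (r in seq_len(40L)) {
    x <- uniform_ibi(rnorm(1200L, 0, 5))
    for (j in seq_along(bands))
      est[r, j] <- mean(sliding_band_power(x, bands[[j]], bank)$power)
  }
  expected <- 25 * 0.4 / 2
  expect_equal(unname(colMeans(est)), rep(expected, 3L), tolerance = 0.1)
})

test_that("a 0.25 Hz sinusoid of amplitude 40 yields ~800 ms^2 band power", {
  x <- uniform_sine(amp = 40, freq = 0.25)
  bp <- sliding_band_power(x, band_spec(0.12, 0.40))
  expect_equal(range(bp$second), c(16L, 284L))
  expect_true(all(abs(bp$power - 800) / 800 < 0.10))
  # constant input: nothing left after detrending
  x0 <- uniform_sine(amp = 0)
  bp0 <- sliding_band_power(x0, band_spec(0.12, 0.40))
  expect_true(all(bp0$power < 1e-12))
  # window longer than series: empty result
  short <- uniform_ibi(rep(800, 60L))
  expect_equal(nrow(sliding_band_power(short, band_spec(0.12, 0.40))), 0L)
})

test_that("a masked segment invalidates exactly +/-16 s of output", {
  x <- uniform_sine()
  tg <- seq(0, 299.75, by = 0.25)
  x$valid_mask[tg >= 100 & tg < 110] <- FALSE
  bp <- sliding_band_power(x, band_spec(0.12, 0.40))
  invalid <- bp$second[!bp$valid]
  expect_equal(invalid, 84:125)
  expect_true(all(is.na(bp$power[!bp$valid])))
})

test_that("Parseval: integrated one-sided PSD matches window variance", {
  set.seed(9)
  x <- uniform_ibi(rnorm(1200L, 800, 12))
  full <- band_spec(1e-3, 1.999)
  bp <- sliding_band_power(x, full)
  # compare each window's integral with its variance
  vals <- x$values
  ratio <- vapply(seq_len(nrow(bp)), function(j) {
    i0 <- (bp$second[j] - 16L) * 4L + 1L
    w <- vals[i0:(i0 + 127L)]
    bp$power[j] / var(w)
  }, numeric(1L))
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("log transform applies the floor and preserves order", {
  expect_equal(band_power_to_rsa(800), log(800))
  expect_equal(band_power_to_rsa(0, floor = 1e-6), log(1e-6))
  p <- c(0.5, 1, 10, 100)
  expect_true(all(diff(band_power_to_rsa(p)) > 0))
})

test_that("estimate_rsa recovers a known target and rejects misconfiguration", {
  beats <- simulate_beats_from_rsa(log(800), 300, 0.25, 800, seed = 1L)
  u <- interpolate_4hz(beats_to_ibi(beats), 300)
  rsa <- estimate_rsa(u, "parent")
  expect_s3_class(rsa, "rsa_series")
  expect_lt(max(abs(rsa$rsa - log(800))), 0.1)   # round-trip, ln ms^2

  # out-of-band modulation (0.05 Hz) leaks only marginal power into the band
  beats_lo <- simulate_beats_from_rsa(log(800), 300, 0.05, 800, seed = 1L)
  u_lo <- interpolate_4hz(beats_to_ibi(beats_lo), 300)
  rsa_lo <- estimate_rsa(u_lo, "parent")
  expect_lt(mean(exp(rsa_lo$rsa)), 0.02 * 800)

  # child band: selected by age, error when unconfigured
  rsa_child <- estimate_rsa(u, "child", child_age = 8)
  expect_equal(attr(rsa_child, "band")$low, 0.15)
  expect_error(estimate_rsa(u, "child", child_age = 3), "no configured")
  expect_error(estimate_rsa(u, "child"), "child_age")
})

test_that("valid-second bookkeeping is computable from the mask in closed form", {
  x <- uniform_sine()
  tg <- seq(0, 299.75, by = 0.25)
  x$valid_mask[tg >= 40 & tg < 52] <- FALSE
  x$valid_mask[tg >= 200 & tg < 210.25] <- FALSE
  bp <- sliding_band_power(x, band_spec(0.12, 0.40))
  # total output seconds: duration - 32 (+1 for the inclusive endpoint grid)
  expect_equal(nrow(bp), 300L - 32L + 1L)
  # a masked sample interval [a, b) invalidates integer seconds
  # ceiling(a - 16) .. floor(b - dt + 16): its own span plus 16 s both ways
  lost_for <- function(a, b) floor(b - 0.25 + 16) - ceiling(a - 16) + 1
  expect_equal(sum(!bp$valid), lost_for(40, 52) + lost_for(200, 210.25))
})
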