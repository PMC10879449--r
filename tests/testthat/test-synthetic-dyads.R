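test_that("noise-free dynamics-free process is constant at its means", {
  p <- var_params(6.5, 6.0, 0, 0, 0, 0, innovation_cov = matrix(0, 2L, 2L))
  sim <- simulate_var_series(p, 50L, seed = 1L)
  expect_equal(sim$parent, rep(6.5, 50L))
  expect_equal(sim$child, rep(6.0, 50L))
})

test_that("simulated moments match the discrete Lyapunov solution", {
  p <- test_params(beta_cp = 0.3)
  B <- matrix(c(p$phi_parent, p$beta_child_to_parent,
                p$beta_parent_to_child, p$phi_child), 2L, 2L, byrow = TRUE)
  G_oracle <- series_sum_cov(B, p$innovation_cov)
  lag1_oracle <- B %*% G_oracle
  sim <- simulate_var_series(p, 1e5, seed = 42L)
  y <- sweep(cbind(sim$parent, sim$child), 2L, c(p$mu_parent, p$mu_child))
  n <- nrow(y)
  lag1_emp <- crossprod(y[-1L, ], y[-n, ]) / (n - 1L)   # E[z_t z_{t-1}']
  scale <- max(abs(lag1_oracle))
  expect_lt(max(abs(lag1_emp - lag1_oracle)) / scale, 0.01)
  G_emp <- crossprod(y) / n
  expect_lt(max(abs(G_emp - G_oracle)) / max(abs(G_oracle)), 0.01)
})

test_that("generators are reproducible under a fixed seed", {
  p <- test_params(beta_pc = 0.2, beta_cp = -0.1)
  expect_identical(simulate_var_series(p, 100L, seed = 7L),
                   simulate_var_series(p, 100L, seed = 7L))
  b1 <- simulate_beats_from_rsa(log(800), 60, 0.25, 800, seed = 3L)
  b2 <- simulate_beats_from_rsa(log(800), 60, 0.25, 800, seed = 3L)
  expect_identical(b1$times, b2$times)
  spec <- cohort_spec(3L, seed = 11L)
  expect_identical(make_cohort(spec), make_cohort(spec))
})

test_that("non-stationary or invalid parameter sets are rejected", {
  expect_error(var_params(6, 6, 1.1, 0.4), "spectral radius")
  expect_error(var_params(6, 6, 0.8, 0.8, 0.5, 0.5), "spectral radius")
  expect_error(var_params(6, 6, 0.4, 0.4,
                          innovation_cov = matrix(c(1, 0.5, 0.2, 1), 2L)),
               "symmetric")
  expect_error(var_params(6, 6, 0.4, 0.4,
                          innovation_cov = matrix(c(1, 2, 2, 1), 2L)),
               "semi-definite")
})

test_that("beat synthesis encodes the target band power as IBI modulation", {
  # A = sqrt(2 * 800) = 40 ms around an 800 ms base
  b <- simulate_beats_from_rsa(log(800), 300, 0.25, 800, seed = 1L)
  ibi <- diff(b$times) * 1000
  expect_equal(mean(ibi), 800, tolerance = 0.01)
  expect_gt(max(abs(ibi - 800)), 36)
  expect_lt(max(abs(ibi - 800)), 40.5)
  # zero modulation: perfectly regular beats
  b0 <- simulate_beats_from_rsa(-Inf, 60, 0.25, 800, seed = 1L)
  expect_equal(diff(b0$times), rep(0.8, length(b0$times) - 1L))
  # non-physical amplitude (A >= base_ibi) is rejected
  expect_error(simulate_beats_from_rsa(13, 60, 0.25, 800, seed = 1L),
               "negative IBI")
})

test_that("corruption is identity at zero rates and records its truth map", {
  b <- simulate_beats_from_rsa(log(800), 300, 0.25, 800, seed = 2L)
  out <- corrupt_beats(b, artifact_spec(), seed = 1L)
  expect_identical(out$beats$times, b$times)
  expect_length(out$truth$corrupted_idx, 0L)

  spec <- artifact_spec(dropout_segments = list(c(100, 12)))
  out2 <- corrupt_beats(b, spec, seed = 1L)
  expect_equal(out2$truth$dropout_segments[[1L]], c(100, 112))
  expect_false(any(out2$beats$times >= 100 & out2$beats$times < 112))
})

test_that("ectopic corruption count falls in the Poisson 99% interval", {
  # 2/min over ~300 s -> Poisson(10); 99% interval from qpois
  b <- simulate_beats_from_rsa(log(800), 300, 0.25, 800, seed = 2L)
  lo <- qpois(0.005, 10); hi <- qpois(0.995, 10)
  out <- corrupt_beats(b, artifact_spec(ectopic_rate = 2), seed = 5L)
  n_cor <- length(out$truth$corrupted_idx)
  expect_gte(n_cor, lo)
  expect_lte(n_cor, hi)
})

test_that("cohort assembly records regimes and usability flags", {
  spec <- cohort_spec(4L, regime_mix = c(positive = 1, negative = 0, null = 0),
                      seed = 2L,
                      unusable = list(list(dyad = 2L, task = "conflict")))
  recs <- make_cohort(spec)
  expect_length(recs, 8L)
  expect_true(all(vapply(recs, function(r)
    all(r$regimes == "positive"), logical(1L))))
  expect_true(all(vapply(recs, function(r)
    r$params$beta_parent_to_child == 0.3, logical(1L))))
  un <- vapply(recs, function(r) !r$usable, logical(1L))
  expect_equal(sum(un), 1L)
  expect_equal(recs[[which(un)]]$task, "conflict")
  # null regime gives zero cross-lags
  recs0 <- make_cohort(cohort_spec(1L, regime_mix = c(positive = 0,
                                                      negative = 0, null = 1),
                                   seed = 3L))
  expect_equal(recs0[[1L]]$params$beta_parent_to_child, 0)
  expect_equal(recs0[[1L]]$params$beta_child_to_parent, 0)
})
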