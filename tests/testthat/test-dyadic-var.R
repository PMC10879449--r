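test_that("PSR is 1 on identical chains and large on separated chains", {
  set.seed(1)
  x <- matrix(rnorm(200), ncol = 2L)
  expect_equal(unname(psr(list(x, x))), c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)

  # brute-force variance-ratio oracle on two shifted chains
  a <- matrix(rnorm(5000), ncol = 1L)
  b <- a + 10
  R <- psr(list(a, b))
  n <- 2500; m <- 2
  halves <- list(a[2501:5000, 1L], b[2501:5000, 1L])
  W <- mean(sapply(halves, var))
  B <- n * var(sapply(halves, mean))
  expect_equal(unname(R), sqrt(((n - 1) / n * W + B / n) / W), ignore_attr = TRUE)
  expect_gt(R, 5)

  # well-mixed chains from one stationary distribution converge
  set.seed(2)
  c1 <- matrix(rnorm(5000), ncol = 1L)
  c2 <- matrix(rnorm(5000), ncol = 1L)
  expect_lt(psr(list(c1, c2)), 1.05)

  # degenerate zero-variance chains
  z <- matrix(1, 100L, 1L)
  Rz <- psr(list(z, z))
  expect_equal(unname(Rz), 1, ignore_attr = TRUE)
  expect_true(attr(Rz, "degenerate"))
})

test_that("the sampler recovers a known cross-lag and is deterministic", {
  rec <- sim_record(test_params(beta_cp = 0.3), seed = 7L)
  cfg <- mcmc_config(seed = 11L)
  post <- fit_dyad_var(rec, cfg)
  b_cp <- post[post$parameter == "beta_child_to_parent", ]
  expect_lt(abs(b_cp$median - 0.3), 0.15)
  expect_true(attr(post, "converged"))
  expect_true(all(post$psr < 1.05))
  expect_true(all(post$cri_low <= post$median & post$median <= post$cri_high))
  expect_identical(post, fit_dyad_var(rec, cfg))
})

test_that("credible intervals classify synchrony by the zero-exclusion rule", {
  fake_post <- function(lo_pc, hi_pc, lo_cp, hi_cp) {
    out <- data.frame(
      parameter = c("beta_parent_to_child", "beta_child_to_parent"),
      median = c((lo_pc + hi_pc) / 2, (lo_cp + hi_cp) / 2),
      cri_low = c(lo_pc, lo_cp), cri_high = c(hi_pc, hi_cp), psr = 1)
    attr(out, "dyad_id") <- "d"; attr(out, "task") <- "t"
    class(out) <- c("var_posterior", "data.frame")
    out
  }
  call <- classify_synchrony(fake_post(0.1, 0.4, -0.2, 0.1))
  expect_equal(call$parent_driven, "positive")
  expect_equal(call$child_driven, "null")
  expect_equal(classify_synchrony(fake_post(-0.4, -0.1, 0, 0.2))$parent_driven,
               "negative")
  # an endpoint exactly at zero counts as containing zero
  expect_equal(classify_synchrony(fake_post(-0.4, -0.1, 0, 0.2))$child_driven,
               "null")
})

test_that("conjugate reduction matches the closed-form posterior", {
  # with dynamics fixed at zero the model is a bivariate normal
  # mean/covariance problem with conjugate updates; under the flat-limit
  # normal prior on the mean, E[mu | y] = ybar and the covariance posterior
  # is IW(nu0 + n - 1, S0 + S_centred) with mean (S0 + S_centred)/(n - 1)
  rec <- sim_record(test_params(), seed = 13L)
  post <- fit_dyad_var(rec, mcmc_config(seed = 5L), fix_dynamics = TRUE)
  y <- rec$y[-1L, ]
  n <- nrow(y)
  ybar <- colMeans(y)
  Sc <- crossprod(sweep(y, 2L, ybar))
  Sig_mean <- (diag(2) + Sc) / (n - 1)
  expect_equal(post$median[1:2], unname(ybar), tolerance = 0.01)
  expect_equal(post$median[7:8], unname(diag(Sig_mean)), tolerance = 0.05)
  expect_equal(post$median[9], Sig_mean[1L, 2L], tolerance = 0.02)
  # dynamics stayed fixed
  expect_true(all(post$median[3:6] == 0))
})

test_that("interior missing seconds are augmented, not dropped", {
  params <- test_params(beta_cp = 0.3)
  sim <- simulate_var_series(params, 300L, seed = 23L)
  pr <- data.frame(second = sim$second, rsa = sim$parent, valid = TRUE)
  cr <- data.frame(second = sim$second, rsa = sim$child, valid = TRUE)
  full <- fit_dyad_var(dyad_task_record("d", "t", pr, cr),
                       mcmc_config(seed = 3L))
  set.seed(41)
  pr2 <- pr; pr2$valid[sample(5:295, 30L)] <- FALSE
  cr2 <- cr; cr2$valid[sample(5:295, 30L)] <- FALSE
  miss <- fit_dyad_var(dyad_task_record("d", "t", pr2, cr2),
                       mcmc_config(seed = 3L))
  expect_lt(mean(abs(full$median[1:6] - miss$median[1:6])), 0.05)
})

test_that("records without enough overlapping valid seconds are rejected", {
  pr <- const_rsa_df(60L, 6.5)
  cr <- const_rsa_df(60L, 6.0)
  cr$valid[1:30] <- FALSE
  expect_error(dyad_task_record("d", "t", pr, cr), "unusable")
  expect_error(dyad_task_record("d", "t", pr, const_rsa_df(59L, 6)),
               "same second grid")
})
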