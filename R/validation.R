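#' Parameter-recovery and calibration study for the dyadic dynamic model
#'
#' Simulates dyads from the lag-1 model across the cross-lag regime grid
#' (both cross-lags set to -effect, 0, +effect), fits each with the Gibbs
#' sampler and measures: per-regime mean bias of the posterior medians of
#' the dynamic coefficients, empirical 95% credible-interval coverage of the
#' true cross-lags, and — on additional null-coupling replicates — the rate
#' at which a truly null cross-lag is classified non-null by the
#' zero-exclusion rule.
#'
#' @param n_per_regime Replicates per cross-lag regime.
#' @param n_null Additional null-coupling replicates for the false-non-null
#'   rate.
#' @param n_seconds Series length per dyad.
#' @param effect Cross-lag magnitude of the non-null regimes.
#' @param seed Master seed.
#' @param config An [mcmc_config()]; its seed is overridden per replicate.
#' @return A list: `bias` (regime x coefficient matrix of mean
#'   median-minus-truth), `coverage` (cross-lag CrI coverage proportion),
#'   `coverage_n` (number of coverage events), `false_nonnull_rate`,
#'   `false_nonnull_n`, `mean_discarded_fraction`, `n_fits`.
#' @export
recovery_study <- function(n_per_regime = 67L, n_null = 300L,
                           n_seconds = 300L, effect = 0.3, seed = 1L,
                           config = mcmc_config(min_iterations = 1000L)) {
  set.seed(as.integer(seed))
  sim_seeds <- sample.int(2^30, 3L * n_per_regime + n_null)
  fit_seeds <- sample.int(2^30, 3L * n_per_regime + n_null)
  regimes <- c(-effect, 0, effect)
  coef_names <- c("phi_parent", "phi_child",
                  "beta_parent_to_child", "beta_child_to_parent")
  bias <- matrix(0, 3L, 4L,
                 dimnames = list(paste0("beta=", regimes), coef_names))
  covered <- 0L; cover_n <- 0L
  discarded <- numeric(0)
  k <- 0L
  fit_one <- function(beta, s_sim, s_fit) {
    p <- var_params(6.5, 6.0, 0.4, 0.4,
                    beta_parent_to_child = beta, beta_child_to_parent = beta,
                    innovation_cov = matrix(c(0.09, 0.018, 0.018, 0.09), 2L))
    sim <- simulate_var_series(p, n_seconds, seed = s_sim)
    rec <- dyad_task_record(
      "sim", "sim",
      data.frame(second = sim$second, rsa = sim$parent, valid = TRUE),
      data.frame(second = sim$second, rsa = sim$child, valid = TRUE))
    cfg <- config
    cfg$seed <- s_fit
    fit_dyad_var(rec, cfg)
  }
  for (r in seq_along(regimes)) {
    beta <- regimes[r]
    meds <- matrix(0, n_per_regime, 4L)
    for (i in seq_len(n_per_regime)) {
      k <- k + 1L
      post <- fit_one(beta, sim_seeds[k], fit_seeds[k])
      rows <- match(coef_names, post$parameter)
      meds[i, ] <- post$median[rows]
      cl_rows <- match(c("beta_parent_to_child", "beta_child_to_parent"),
                       post$parameter)
      covered <- covered + sum(post$cri_low[cl_rows] <= beta &
                                 post$cri_high[cl_rows] >= beta)
      cover_n <- cover_n + 2L
      discarded <- c(discarded, attr(post, "discarded_fraction"))
    }
    truth <- c(0.4, 0.4, beta, beta)
    bias[r, ] <- colMeans(meds) - truth
  }
  false_nonnull <- 0L
  for (i in seq_len(n_null)) {
    k <- k + 1L
    post <- fit_one(0, sim_seeds[k], fit_seeds[k])
    cl_rows <- match(c("beta_parent_to_child", "beta_child_to_parent"),
                     post$parameter)
    false_nonnull <- false_nonnull + sum(post$cri_low[cl_rows] > 0 |
                                           post$cri_high[cl_rows] < 0)
    discarded <- c(discarded, attr(post, "discarded_fraction"))
  }
  list(bias = bias,
       coverage = covered / cover_n, coverage_n = cover_n,
       false_nonnull_rate = false_nonnull / (2L * n_null),
       false_nonnull_n = 2L * n_null,
       mean_discarded_fraction = mean(discarded),
       n_fits = k)
}

#' Empirical size of the ADF screen on unit-root data
#'
#' Simulates pure random walks and measures how often the unit root is
#' (wrongly) rejected at the configured level — the empirical size of the
#' test, which should sit near its nominal alpha.
#'
#' @param n_reps Number of replicate walks.
#' @param n_seconds Length of each walk.
#' @param model ADF deterministic specification.
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @return A list with `size` (rejection proportion) and `n_reps`.
#' @export
adf_size_study <- function(n_reps = 2000L, n_seconds = 300L,
                           model = "single-mean", alpha = 0.05, seed = 1L) {
  set.seed(as.integer(seed))
  rej <- logical(n_reps)
  for (i in seq_len(n_reps))
    rej[i] <- adf_test(cumsum(stats::rnorm(n_seconds)), model,
                       alpha = alpha)$reject_unit_root
  list(size = mean(rej), n_reps = n_reps)
}
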