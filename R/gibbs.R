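#' One dyad-task record ready for dynamic modelling
#'
#' Aligns the parent and child RSA series on one per-second grid. The series
#' are trimmed to start at the first second where both are valid (the initial
#' condition of the lag-1 model is treated as fixed) and to end at the last
#' second where either is valid. Missing interior seconds are retained and
#' handled by data augmentation during fitting.
#'
#' @param dyad_id Identifier.
#' @param task Task label.
#' @param parent_rsa,child_rsa `rsa_series` objects (or data.frames with
#'   `second`, `rsa`, `valid`) on identical second grids.
#' @param min_valid Minimum number of seconds where both series are valid.
#' @return An object of class `dyad_task_record` with matrix `y` (T x 2,
#'   parent then child, NA where invalid).
#' @export
dyad_task_record <- function(dyad_id, task, parent_rsa, child_rsa,
                             min_valid = 50L) {
  if (!identical(parent_rsa$second, child_rsa$second))
    stop("parent and child series must share the same second grid")
  yp <- ifelse(parent_rsa$valid, parent_rsa$rsa, NA_real_)
  yc <- ifelse(child_rsa$valid, child_rsa$rsa, NA_real_)
  both <- is.finite(yp) & is.finite(yc)
  if (sum(both) < min_valid)
    stop(sprintf("unusable record: only %d seconds with both series valid (need %d)",
                 sum(both), min_valid))
  first <- which(both)[1L]
  last <- max(which(is.finite(yp) | is.finite(yc)))
  y <- cbind(parent = yp, child = yc)[first:last, , drop = FALSE]
  structure(list(dyad_id = dyad_id, task = task, y = y,
                 seconds = parent_rsa$second[first:last]),
            class = "dyad_task_record")
}

#' MCMC configuration for the dyadic dynamic model
#'
#' Defaults follow the estimation conventions of the analysis: two unthinned
#' chains, at most 100,000 iterations each, early termination once the
#' potential scale reduction factor of every parameter drops below 1.05,
#' posterior summarised by the median of the post-burn-in pooled draws.
#'
#' @param n_chains Number of chains (>= 2).
#' @param max_iterations Per-chain iteration cap.
#' @param psr_threshold Early-termination PSR threshold (> 1).
#' @param check_interval Iterations between convergence checks.
#' @param min_iterations Iterations before the first check; also sets the
#'   smallest usable posterior sample.
#' @param burn_in_fraction Fraction of each chain discarded as burn-in.
#' @param seed Integer seed.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, max_iterations = 100000L,
                        psr_threshold = 1.05, check_interval = 500L,
                        min_iterations = 1000L, burn_in_fraction = 0.5,
                        seed = 1L) {
  stopifnot(n_chains >= 2L, psr_threshold > 1,
            burn_in_fraction > 0, burn_in_fraction < 1,
            min_iterations >= 20L, max_iterations >= min_iterations)
  structure(list(n_chains = as.integer(n_chains),
                 max_iterations = as.integer(max_iterations),
                 psr_threshold = psr_threshold,
                 check_interval = as.integer(check_interval),
                 min_iterations = as.integer(min_iterations),
                 burn_in_fraction = burn_in_fraction,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

.param_names <- c("mu_parent", "mu_child", "phi_parent", "phi_child",
                  "beta_parent_to_child", "beta_child_to_parent",
                  "sigma2_parent", "sigma2_child", "sigma_pc")

# sample from N(mean, Precision^-1) given upper Cholesky of the precision
rmvnorm_prec <- function(mean, prec) {
  R <- chol(prec)
  mean + backsolve(R, stats::rnorm(length(mean)))
}

riwish <- function(df, scale) {
  W <- stats::rWishart(1L, df, solve(scale))[, , 1L]
  solve(W)
}

inv2 <- function(A) {
  d <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
  matrix(c(A[2L, 2L], -A[2L, 1L], -A[1L, 2L], A[1L, 1L]), 2L, 2L) / d
}

# sufficient cross-products of the lag-aligned data; recomputed only when
# data augmentation changes Y
lag_crossprods <- function(Y) {
  Tn <- nrow(Y)
  Y0 <- Y[-Tn, , drop = FALSE]
  Y1 <- Y[-1L, , drop = FALSE]
  list(Tn = Tn, cs0 = colSums(Y0), cs1 = colSums(Y1),
       S00 = crossprod(Y0), S01 = crossprod(Y0, Y1), S11 = crossprod(Y1))
}

# one Gibbs sweep updating the chain state in place; returns the state
gibbs_sweep <- function(state, prior, fix_dynamics) {
  xp <- state$xp
  Tn <- xp$Tn
  n1 <- Tn - 1
  mu <- state$mu; B <- state$B; Sigma <- state$Sigma
  W <- inv2(Sigma)

  # --- means | dynamics, covariance (latent mean centering: the means are
  #     parameters inside the likelihood, not pre-subtracted averages)
  M <- diag(2) - B
  P <- diag(2) / prior$mu_var + n1 * t(M) %*% W %*% M
  h <- t(M) %*% W %*% (xp$cs1 - B %*% xp$cs0)
  mu <- drop(rmvnorm_prec(solve(P, h), P))

  # centered cross-products for the current means
  S <- xp$S00 - outer(xp$cs0, mu) - outer(mu, xp$cs0) + n1 * outer(mu, mu)
  C <- xp$S01 - outer(xp$cs0, mu) - outer(mu, xp$cs1) + n1 * outer(mu, mu)
  SZ11 <- xp$S11 - outer(xp$cs1, mu) - outer(mu, xp$cs1) + n1 * outer(mu, mu)

  # --- dynamic coefficients | means, covariance
  if (!fix_dynamics) {
    P4 <- rbind(cbind(W[1L, 1L] * S, W[1L, 2L] * S),
                cbind(W[2L, 1L] * S, W[2L, 2L] * S))
    diag(P4) <- diag(P4) + 1 / prior$b_var
    h4 <- c(W[1L, 1L] * C[, 1L] + W[1L, 2L] * C[, 2L],
            W[2L, 1L] * C[, 1L] + W[2L, 2L] * C[, 2L])
    b <- rmvnorm_prec(solve(P4, h4), P4)
    B <- matrix(b, 2L, 2L, byrow = TRUE)
  }

  # --- innovation covariance | means, dynamics
  EtE <- SZ11 - t(C) %*% t(B) - B %*% C + B %*% S %*% t(B)
  EtE <- (EtE + t(EtE)) / 2
  Sigma <- riwish(prior$iw_df + n1, prior$iw_scale + EtE)
  W <- inv2(Sigma)

  # --- missing values | everything (data augmentation)
  if (length(state$miss_rows)) {
    Y <- state$Y
    BtWB <- t(B) %*% W %*% B
    for (t in state$miss_rows) {
      zt_prev <- Y[t - 1L, ] - mu
      if (t < Tn) {
        P2 <- W + BtWB
        h2 <- W %*% (B %*% zt_prev) + t(B) %*% W %*% (Y[t + 1L, ] - mu)
      } else {
        P2 <- W
        h2 <- W %*% (B %*% zt_prev)
      }
      m2 <- solve(P2, h2)
      mis <- state$miss_pattern[[as.character(t)]]
      if (length(mis) == 2L) {
        Y[t, ] <- mu + drop(rmvnorm_prec(drop(m2), P2))
      } else {
        i <- mis; j <- 3L - i
        zobs <- Y[t, j] - mu[j]
        cond_mean <- m2[i] - P2[i, j] / P2[i, i] * (zobs - m2[j])
        Y[t, i] <- mu[i] + cond_mean + stats::rnorm(1L, 0, sqrt(1 / P2[i, i]))
      }
    }
    state$Y <- Y
    state$xp <- lag_crossprods(Y)
  }

  state$mu <- mu; state$B <- B; state$Sigma <- Sigma
  state
}

state_to_draw <- function(state) {
  c(state$mu, state$B[1L, 1L], state$B[2L, 2L],
    state$B[2L, 1L], state$B[1L, 2L],
    state$Sigma[1L, 1L], state$Sigma[2L, 2L], state$Sigma[1L, 2L])
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Computed per parameter from the between- and within-chain variances of
#' the second half of each chain, floored at 1 (the raw ratio can dip just
#' below 1 for well-mixed chains). Chains with (numerically) zero variance
#' yield PSR 1 with a degeneracy flag.
#'
#' @param chains List of draw matrices (iterations x parameters), one per
#'   chain, with >= 10 draws each.
#' @return Named numeric vector of PSR values; attribute `"degenerate"`
#'   flags zero-variance parameters.
#' @export
psr <- function(chains) {
  stopifnot(length(chains) >= 2L)
  halves <- lapply(chains, function(ch) {
    ch <- as.matrix(ch)
    stopifnot(nrow(ch) >= 10L)
    ch[(floor(nrow(ch) / 2) + 1L):nrow(ch), , drop = FALSE]
  })
  n <- min(vapply(halves, nrow, integer(1L)))
  halves <- lapply(halves, function(h) h[seq_len(n), , drop = FALSE])
  m <- length(halves)
  p <- ncol(halves[[1L]])
  out <- numeric(p)
  degen <- logical(p)
  for (j in seq_len(p)) {
    xs <- vapply(halves, function(h) h[, j], numeric(n))
    Wv <- mean(apply(xs, 2L, stats::var))
    Bv <- n * stats::var(colMeans(xs))
    if (Wv < 1e-300) { out[j] <- 1; degen[j] <- TRUE; next }
    # floored at 1: the (n-1)/n deflation term can push the raw ratio just
    # below 1 when the chains agree
    out[j] <- max(1, sqrt(((n - 1) / n * Wv + Bv / n) / Wv))
  }
  names(out) <- colnames(chains[[1L]])
  attr(out, "degenerate") <- degen
  out
}

#' Fit the Bayesian bivariate lag-1 dynamic model to one dyad-task record
#'
#' Gibbs sampler for the latent-mean-centered model
#' \deqn{y_t - \mu = B (y_{t-1} - \mu) + \epsilon_t, \quad
#'       \epsilon_t \sim N(0, \Sigma)}
#' with conditionally conjugate blocks: diffuse normal priors (variance 1e6)
#' on the means and dynamic coefficients, inverse-Wishart (identity scale,
#' 3 degrees of freedom) on the innovation covariance, and normal full
#' conditionals for interior missing seconds (data augmentation). Two or
#' more chains start from dispersed values; sampling terminates early when
#' every parameter's potential scale reduction factor falls below the
#' configured threshold, otherwise at the iteration cap (then flagged
#' non-converged). Draws whose standardized autoregressive or cross-lagged
#' coefficients exceed 1 in magnitude (coefficients scaled by the implied
#' stationary standard-deviation ratio), or whose transition matrix is
#' explosive, are removed from the summarized posterior as inadmissible and
#' counted in `discarded_fraction`.
#'
#' @param record A [dyad_task_record()].
#' @param config An [mcmc_config()].
#' @param fix_dynamics If `TRUE`, the dynamic coefficients are fixed at 0 and
#'   only means and covariance are sampled (the model reduces to a bivariate
#'   normal mean/covariance problem; used for sampler validation).
#' @return An object of class `var_posterior`: data.frame with one row per
#'   parameter (`median`, `cri_low`, `cri_high`, `psr`) and attributes
#'   `converged`, `n_iterations_used`, `discarded_fraction`, `dyad_id`,
#'   `task`.
#' @export
fit_dyad_var <- function(record, config = mcmc_config(),
                         fix_dynamics = FALSE) {
  stopifnot(inherits(record, "dyad_task_record"),
            inherits(config, "mcmc_config"))
  Y0 <- record$y
  Tn <- nrow(Y0)
  prior <- list(mu_var = 1e6, b_var = 1e6, iw_df = 3, iw_scale = diag(2))

  miss_pattern <- list()
  for (t in seq_len(Tn)) {
    mis <- which(!is.finite(Y0[t, ]))
    if (length(mis)) miss_pattern[[as.character(t)]] <- mis
  }
  miss_rows <- as.integer(names(miss_pattern))

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)

  ybar <- colMeans(Y0, na.rm = TRUE)
  ysd <- apply(Y0, 2L, stats::sd, na.rm = TRUE)
  ysd[!is.finite(ysd) | ysd < 1e-6] <- 1e-6

  states <- vector("list", config$n_chains)
  draws <- vector("list", config$n_chains)
  for (cc in seq_len(config$n_chains)) {
    set.seed(chain_seeds[cc])
    disp <- (-1)^cc * (cc + 1) / 2
    Yc <- Y0
    if (length(miss_rows)) {
      for (t in miss_rows) {
        mis <- miss_pattern[[as.character(t)]]
        Yc[t, mis] <- ybar[mis] + stats::rnorm(length(mis), 0, ysd[mis])
      }
    }
    states[[cc]] <- list(
      Y = Yc, xp = lag_crossprods(Yc),
      mu = ybar + disp * ysd,
      B = matrix(0, 2L, 2L),
      Sigma = diag(ysd^2) * (if (cc %% 2L) 1 else 4),
      miss_rows = miss_rows, miss_pattern = miss_pattern,
      rng = get(".Random.seed", envir = globalenv()))
    draws[[cc]] <- matrix(NA_real_, config$max_iterations, 9L,
                          dimnames = list(NULL, .param_names))
  }

  n_done <- 0L
  converged <- FALSE
  while (n_done < config$max_iterations) {
    n_next <- min(n_done + config$check_interval, config$max_iterations)
    for (cc in seq_len(config$n_chains)) {
      assign(".Random.seed", states[[cc]]$rng, envir = globalenv())
      st <- states[[cc]]
      for (it in (n_done + 1L):n_next) {
        st <- gibbs_sweep(st, prior, fix_dynamics)
        draws[[cc]][it, ] <- state_to_draw(st)
      }
      st$rng <- get(".Random.seed", envir = globalenv())
      states[[cc]] <- st
    }
    n_done <- n_next
    if (n_done >= config$min_iterations) {
      active <- if (fix_dynamics) c(1:2, 7:9) else 1:9
      R <- psr(lapply(draws, function(d) d[seq_len(n_done), active,
                                           drop = FALSE]))
      if (all(R < config$psr_threshold)) { converged <- TRUE; break }
    }
  }

  burn <- floor(n_done * config$burn_in_fraction)
  pooled <- do.call(rbind, lapply(draws, function(d)
    d[(burn + 1L):n_done, , drop = FALSE]))
  active <- if (fix_dynamics) c(1:2, 7:9) else 1:9
  R_final <- psr(lapply(draws, function(d)
    d[seq_len(n_done), , drop = FALSE]))

  admissible <- admissible_draws(pooled)
  discarded_fraction <- 1 - mean(admissible)
  kept <- pooled[admissible, , drop = FALSE]
  if (!nrow(kept)) kept <- pooled     # pathological: keep all, flag stands out

  qs <- apply(kept, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  out <- data.frame(parameter = .param_names,
                    median = qs[1L, ], cri_low = qs[2L, ], cri_high = qs[3L, ],
                    psr = unname(R_final))
  rownames(out) <- NULL
  attr(out, "converged") <- converged
  attr(out, "n_iterations_used") <- n_done
  attr(out, "discarded_fraction") <- discarded_fraction
  attr(out, "dyad_id") <- record$dyad_id
  attr(out, "task") <- record$task
  class(out) <- c("var_posterior", "data.frame")
  out
}

# admissibility safeguard: a draw is kept when its transition matrix is
# stationary and every standardized coefficient (scaled by the implied
# stationary sd ratio) is at most 1 in magnitude
admissible_draws <- function(pooled) {
  n <- nrow(pooled)
  ok <- logical(n)
  for (i in seq_len(n)) {
    B <- matrix(c(pooled[i, "phi_parent"], pooled[i, "beta_child_to_parent"],
                  pooled[i, "beta_parent_to_child"], pooled[i, "phi_child"]),
                2L, 2L, byrow = TRUE)
    if (spectral_radius(B) >= 1) next
    Sigma <- matrix(c(pooled[i, "sigma2_parent"], pooled[i, "sigma_pc"],
                      pooled[i, "sigma_pc"], pooled[i, "sigma2_child"]), 2L)
    G <- tryCatch(stationary_covariance(B, Sigma), error = function(e) NULL)
    if (is.null(G) || any(diag(G) <= 0)) next
    sdv <- sqrt(diag(G))
    Bstd <- B * outer(1 / sdv, sdv)
    ok[i] <- all(abs(Bstd) <= 1)
  }
  ok
}

#' Classify parent- and child-driven synchrony from a fitted posterior
#'
#' Applies the credible-interval rule: an interpersonal effect is non-null
#' when its 95% credible interval excludes zero — entirely positive gives
#' positive synchrony (same-direction prediction), entirely negative gives
#' negative synchrony (opposite-direction prediction); an interval containing
#' zero (including an endpoint exactly at zero) is null. Parent-driven
#' synchrony is read from the parent-to-child cross-lag, child-driven from
#' the child-to-parent cross-lag.
#'
#' @param posterior A `var_posterior` from [fit_dyad_var()].
#' @return A data.frame (class `synchrony_call`) with `dyad_id`, `task`,
#'   `parent_driven`, `child_driven` in `{"positive","negative","null"}`.
#' @export
classify_synchrony <- function(posterior) {
  stopifnot(inherits(posterior, "var_posterior"))
  call_one <- function(param) {
    row <- posterior[posterior$parameter == param, ]
    if (row$cri_low > 0) "positive"
    else if (row$cri_high < 0) "negative"
    else "null"
  }
  out <- data.frame(dyad_id = attr(posterior, "dyad_id"),
                    task = attr(posterior, "task"),
                    parent_driven = call_one("beta_parent_to_child"),
                    child_driven = call_one("beta_child_to_parent"))
  class(out) <- c("synchrony_call", "data.frame")
  out
}
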