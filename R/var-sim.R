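#' Parameters of the bivariate lag-1 dyadic RSA process
#'
#' Bundles the level, autoregressive, cross-lagged and innovation-covariance
#' parameters of the within-dyad bivariate lag-1 model
#' \deqn{y_t - \mu = B (y_{t-1} - \mu) + \epsilon_t, \quad
#'       \epsilon_t \sim N(0, \Sigma),}
#' where `y_t = (parent_t, child_t)` is the pair of per-second RSA values in
#' ln ms^2 and the transition matrix is
#' \deqn{B = \begin{pmatrix} \phi_{parent} & \beta_{c \to p} \\
#'                           \beta_{p \to c} & \phi_{child} \end{pmatrix}.}
#' `beta_parent_to_child` is the parent-driven cross-lag (parent's RSA
#' fluctuation at one second predicting the child's the next second);
#' `beta_child_to_parent` is the child-driven cross-lag.
#'
#' @param mu_parent,mu_child Trait-like levels of the two series (ln ms^2).
#' @param phi_parent,phi_child Within-person autoregression (dimensionless).
#' @param beta_parent_to_child Parent-driven cross-lag (dimensionless).
#' @param beta_child_to_parent Child-driven cross-lag (dimensionless).
#' @param innovation_cov 2x2 symmetric positive semi-definite covariance of
#'   the contemporaneous innovations ((ln ms^2)^2).
#'
#' @return An object of class `var_params`.
#' @export
var_params <- function(mu_parent, mu_child,
                       phi_parent, phi_child,
                       beta_parent_to_child = 0, beta_child_to_parent = 0,
                       innovation_cov = diag(2) * 0.25) {
  innovation_cov <- as.matrix(innovation_cov)
  stopifnot(is.numeric(mu_parent), is.numeric(mu_child),
            length(mu_parent) == 1L, length(mu_child) == 1L,
            all(dim(innovation_cov) == c(2L, 2L)))
  if (max(abs(innovation_cov - t(innovation_cov))) > 1e-10)
    stop("innovation_cov must be symmetric")
  ev <- eigen(innovation_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("innovation_cov must be positive semi-definite")
  B <- transition_matrix(phi_parent, phi_child,
                         beta_parent_to_child, beta_child_to_parent)
  if (spectral_radius(B) >= 1)
    stop("transition matrix has spectral radius >= 1: process is not stationary")
  structure(
    list(mu_parent = mu_parent, mu_child = mu_child,
         phi_parent = phi_parent, phi_child = phi_child,
         beta_parent_to_child = beta_parent_to_child,
         beta_child_to_parent = beta_child_to_parent,
         innovation_cov = innovation_cov),
    class = "var_params")
}

# row 1 = parent equation, row 2 = child equation
transition_matrix <- function(phi_parent, phi_child,
                              beta_parent_to_child, beta_child_to_parent) {
  matrix(c(phi_parent, beta_parent_to_child,
           beta_child_to_parent, phi_child), 2L, 2L)
}

spectral_radius <- function(B) max(Mod(eigen(B, only.values = TRUE)$values))

#' Stationary covariance of a bivariate lag-1 process
#'
#' Solves the discrete Lyapunov equation `Gamma = B Gamma B' + Sigma` for the
#' stationary (lag-0) covariance by the vectorisation identity
#' `vec(Gamma) = (I - B (x) B)^{-1} vec(Sigma)`. The stationary lag-1
#' cross-covariance matrix is `B Gamma`.
#'
#' @param B 2x2 transition matrix with spectral radius < 1.
#' @param Sigma 2x2 innovation covariance.
#' @return 2x2 stationary covariance matrix.
#' @export
stationary_covariance <- function(B, Sigma) {
  if (spectral_radius(B) >= 1)
    stop("spectral radius >= 1: no stationary covariance")
  v <- solve(diag(4) - kronecker(B, B), as.vector(Sigma))
  G <- matrix(v, 2L, 2L)
  (G + t(G)) / 2
}

#' Simulate paired per-second RSA series from the dyadic lag-1 model
#'
#' Generates `n_seconds` of the parent and child RSA series under the lag-1
#' recursion with Gaussian innovations. The initial state is drawn from the
#' stationary distribution, so the simulated process is stationary from the
#' first sample — matching the assumption that the fitted dynamic model and
#' the Dickey-Fuller screen both rely on.
#'
#' @param params A [var_params()] object.
#' @param n_seconds Length of the series (>= 10).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A data.frame with columns `second` (0-based), `parent`, `child`
#'   (ln ms^2), and the generating `params` attached as attribute `"params"`.
#' @export
simulate_var_series <- function(params, n_seconds, seed) {
  stopifnot(inherits(params, "var_params"), n_seconds >= 10)
  B <- transition_matrix(params$phi_parent, params$phi_child,
                         params$beta_parent_to_child,
                         params$beta_child_to_parent)
  Sigma <- params$innovation_cov
  mu <- c(params$mu_parent, params$mu_child)
  set.seed(as.integer(seed))
  y <- matrix(0, n_seconds, 2L)
  if (max(abs(Sigma)) == 0 && max(abs(B)) == 0) {
    # degenerate noise-free, dynamics-free case: constant at the means
    y[, 1L] <- mu[1L]; y[, 2L] <- mu[2L]
  } else {
    G0 <- stationary_covariance(B, Sigma)
    y[1L, ] <- mu + drop(MASS::mvrnorm(1L, c(0, 0), G0))
    eps <- MASS::mvrnorm(n_seconds - 1L, c(0, 0), Sigma)
    eps <- matrix(eps, ncol = 2L)
    for (t in 2:n_seconds)
      y[t, ] <- mu + B %*% (y[t - 1L, ] - mu) + eps[t - 1L, ]
  }
  out <- data.frame(second = seq_len(n_seconds) - 1L,
                    parent = y[, 1L], child = y[, 2L])
  attr(out, "params") <- params
  out
}
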