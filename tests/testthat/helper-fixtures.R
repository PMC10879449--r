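# shared fixture builders; everything is generated in code at test time

const_rsa_df <- function(n, value, valid = TRUE) {
  data.frame(second = seq_len(n) - 1L, rsa = value,
             valid = rep(valid, length.out = n))
}

# standard moderate dyad parameters used across the dynamic-model tests
test_params <- function(beta_pc = 0, beta_cp = 0, phi = 0.4) {
  var_params(6.5, 6.0, phi, phi,
             beta_parent_to_child = beta_pc,
             beta_child_to_parent = beta_cp,
             innovation_cov = matrix(c(0.09, 0.018, 0.018, 0.09), 2L))
}

sim_record <- function(params, n = 300L, seed = 1L) {
  sim <- simulate_var_series(params, n, seed = seed)
  dyad_task_record(
    "d1", "t1",
    data.frame(second = sim$second, rsa = sim$parent, valid = TRUE),
    data.frame(second = sim$second, rsa = sim$child, valid = TRUE))
}

# independent oracle for the stationary covariance: truncated series sum
# Gamma = sum_k B^k Sigma (B^k)', avoiding the package's Lyapunov solver
series_sum_cov <- function(B, Sigma, k_max = 400L) {
  G <- Sigma
  Bk <- B
  for (k in seq_len(k_max)) {
    G <- G + Bk %*% Sigma %*% t(Bk)
    Bk <- Bk %*% B
  }
  G
}

# a regular 4 Hz IBI signal as uniform_ibi
uniform_sine <- function(duration = 300, base = 800, amp = 40, freq = 0.25,
                         rate = 4) {
  tg <- seq(0, duration - 1 / rate, by = 1 / rate)
  uniform_ibi(base + amp * sin(2 * pi * freq * tg), rate = rate)
}
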