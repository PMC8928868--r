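# Log-uniform random parameter draws around the reference values, used by
# the oracle-equivalence and non-negativity property tests.
draw_params <- function(n, seed = 42) {
  set.seed(seed)
  base <- model_params()
  lapply(seq_len(n), function(i) {
    lu <- function(x, f = 2) x * exp(stats::runif(1, -log(f), log(f)))
    T <- lu(base$T, 1.5)
    model_params(
      alpha = lu(base$alpha, 3), beta = lu(base$beta, 2),
      delta = lu(base$delta, 2), mu = lu(base$mu, 2),
      tau = stats::runif(1, 0.3 * T, 1.1 * T),
      sigma = lu(base$sigma, 2), rho = lu(base$rho, 2),
      T = T, t_l = stats::runif(1, 0.1, 0.9) * T
    )
  })
}

draw_states <- function(n, seed = 43) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    season_state(s_hat = 10^stats::runif(1, 2, 5),
                 v_hat = 10^stats::runif(1, 2, 5))
  })
}
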