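# shared fixtures for the kinetic-model tests

# reference parameter set used throughout: p_ss = 1, b_ss = 0.005, P_i = 200
example_params <- function() rate_params(k_init = 1, k_pre = 0.5,
                                         k_rel = 0.5, k_term = 1)

# random strictly positive parameter sets (log-uniform over two decades)
random_params <- function(n) {
  lapply(seq_len(n), function(i) {
    k <- 10^stats::runif(4, -1, 1)
    l_p <- stats::runif(1, 20, 200)
    rate_params(k[1], k[2], k[3], k[4],
                l_p = l_p, l_b = l_p * 10^stats::runif(1, 1, 2.5))
  })
}

# independent finite-difference oracle: change in steady state when one
# parameter moves k_lo -> k_hi, computed purely from the closed-form
# steady_state at the two parameter settings
fd_delta <- function(params, parameter, k_hi, k_lo, which = c("p", "b")) {
  which <- match.arg(which)
  at <- function(val) {
    v <- unclass(params)
    v[[parameter]] <- val
    steady_state(rate_params(v$k_init, v$k_pre, v$k_rel, v$k_term,
                             l_p = v$l_p, l_b = v$l_b))
  }
  hi <- at(k_hi); lo <- at(k_lo)
  if (which == "p") hi$p_ss - lo$p_ss else hi$b_ss - lo$b_ss
}
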