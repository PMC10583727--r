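# small parameter draws for property tests: valid nested exchangeable ICC
# pairs with 0 <= a1 <= a0 and positive eigenvalues for the given dims
draw_icc <- function(ns, m, rmax = 0.5) {
  repeat {
    a0 <- runif(1, 0, rmax)
    a1 <- runif(1, 0, a0)
    ev <- c(1 - a0, 1 + (m - 1) * a0 - m * a1,
            1 + (m - 1) * a0 + (ns - 1) * m * a1)
    if (all(ev > 1e-6)) return(c(a0 = a0, a1 = a1))
  }
}

make_small_trial <- function(n_c = 2, n_s = 2, m = 3, seed = 1,
                             alpha0 = 0.2, alpha1 = 0.1,
                             rho0 = 0.3, rho1 = 0.1, beta = c(1, .2, .3, .1)) {
  simulate_trial(
    design_spec(n_c, n_s, m, "cluster"),
    outcome_model(alpha0 = alpha0, alpha1 = alpha1),
    modifier_model(mu_x = 1, rho0 = rho0, rho1 = rho1),
    beta = beta, seed = seed
  )
}
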