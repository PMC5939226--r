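# shared fixtures, built in code

# a small completed Ap/Av dataset from a known agent
sim_small_apav <- function(beta = 2, f = -10, w = 2, n_reps = 2, seed = 42,
                           subject_id = "s01") {
  pars <- subject_params("APAV", beta = beta, f = f, w = w)
  sess <- generate_session(n_reps = n_reps, n_blocks = 2, seed = seed,
                           subject_id = subject_id)
  sess <- sess[sess$condition == "APAV", ]
  list(trials = simulate_subject(sess, pars, seed = seed + 1), params = pars)
}

# log of integral exp(logf(theta)) dtheta over [lo, hi] by offset quadrature
log_quadrature_1d <- function(logf, lo, hi) {
  grid <- seq(lo, hi, length.out = 2001)
  lv <- vapply(grid, logf, numeric(1))
  m <- max(lv)
  m + log(sum(exp(lv - m)) * (grid[2] - grid[1])) # midpoint-ish Riemann
}

# log of a 2-D integral by pracma::integral2 with an offset
log_quadrature_2d <- function(logf, lo1, hi1, lo2, hi2, offset) {
  f <- function(x, y) {
    z <- matrix(0, nrow = NROW(x), ncol = NCOL(x))
    for (ii in seq_along(x)) z[ii] <- exp(logf(c(x[ii], y[ii])) - offset)
    z
  }
  q <- pracma::integral2(f, lo1, hi1, lo2, hi2, reltol = 1e-8)
  offset + log(q$Q)
}

# data log likelihood of a beta-only (or any) spec at unconstrained theta
loglik_at <- function(trials, spec, theta) {
  names(theta) <- spec$free_all
  -negative_log_likelihood(trials, aactask:::params_from_theta(spec, theta))
}

log_prior_at <- function(theta, mu, sd) {
  sum(dnorm(theta, mu, sd, log = TRUE))
}
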