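# Independent oracles, kept deliberately separate from the package's
# code paths: recursive NB pmf, per-cell ZINB evaluation, and grid
# searches for the optimizers.

# NB pmf via the term-by-term recursion
#   f(0) = (1 + mu*phi)^(-1/phi),
#   f(k) = f(k-1) * (k - 1 + 1/phi) / k * (mu*phi / (1 + mu*phi)),
# written without lgamma and without dnbinom.
nb_pmf_recursive <- function(y, mu, phi) {
  a <- 1 / phi
  q <- mu * phi / (1 + mu * phi)
  f <- (1 + mu * phi)^(-a)
  if (y == 0) return(f)
  for (k in seq_len(y)) f <- f * (k - 1 + a) / k * q
  f
}

zinb_pmf_oracle <- function(y, mu, phi, p) {
  p * (y == 0) + (1 - p) * nb_pmf_recursive(y, mu, phi)
}

# per-cell ZINB log-likelihood (no factorization)
zinb_loglik_oracle <- function(y, mu, phi, p) {
  sum(vapply(y, function(yi) log(zinb_pmf_oracle(yi, mu, phi, p)),
             numeric(1)))
}

# dense grid search for the posterior mode of the dispersion; with
# refine = TRUE a second 2001-point pass zooms into the bracketing
# interval (still brute force, resolution ~1e-5 in log phi)
post_mode_grid <- function(y, mu, p, prior, n_grid = 2001,
                           refine = FALSE) {
  eta <- seq(prior$theta - 6 * prior$sigma, prior$theta + 6 * prior$sigma,
             length.out = n_grid)
  lp <- log_posterior_phi(exp(eta), y, mu, p, prior)
  i <- which.max(lp)
  if (refine) {
    lo <- eta[max(i - 1L, 1L)]
    hi <- eta[min(i + 1L, n_grid)]
    eta <- seq(lo, hi, length.out = n_grid)
    lp <- log_posterior_phi(exp(eta), y, mu, p, prior)
    i <- which.max(lp)
  }
  exp(eta[i])
}

# 2-D lattice search for the refinement optimum at fixed dispersion
refine_grid <- function(y, phi, mu_max, p_max, n_grid = 201) {
  mus <- seq(0.01, mu_max, length.out = n_grid)
  ps <- seq(0.01, min(p_max, 0.99), length.out = n_grid)
  best <- -Inf
  for (m in mus) {
    ll <- vapply(ps, function(q) zinb_loglik(y, m, phi, q), numeric(1))
    i <- which.max(ll)
    if (ll[i] > best) best <- ll[i]
  }
  best
}

# draw one random ZINB parameter triple for property-style loops
rand_params <- function() {
  list(mu = exp(stats::runif(1, log(0.2), log(20))),
       phi = exp(stats::runif(1, log(0.05), log(5))),
       p = stats::runif(1, 0.02, 0.9))
}
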