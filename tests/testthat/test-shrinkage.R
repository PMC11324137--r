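test_that("prior estimation follows the median/adjusted-variance recipe", {
  # identical estimates with no estimation noise: location log(c),
  # scale at its floor
  pr <- estimate_phi_prior(rep(0.8, 60), est_var = 0)
  expect_equal(pr$theta, log(0.8))
  expect_equal(pr$sigma, 0.1)

  # arithmetic of the variance adjustment: sample variance minus mean
  # estimation variance
  lp <- rnorm(200)
  lp <- (lp - mean(lp)) / sd(lp) * sqrt(0.40)  # sample var exactly 0.40
  pr <- estimate_phi_prior(exp(lp + 2), est_var = 0.15)
  expect_equal(pr$sigma^2, 0.25, tolerance = 1e-12)
  expect_equal(pr$theta, median(lp) + 2)

  # hyperparameter recovery from a log-normal ensemble
  set.seed(5)
  phis <- exp(rnorm(5000, 0.03, 0.57))
  pr <- estimate_phi_prior(phis, est_var = 0)
  expect_lt(abs(pr$theta - 0.03), 0.04)
  expect_lt(abs(pr$sigma - 0.57), 0.03)

  expect_error(estimate_phi_prior(rep(1, 10)), "at least 50")
  expect_error(phi_prior(0, -1), "positive")
})

test_that("log posterior equals likelihood plus log-normal prior", {
  set.seed(13)
  pr <- phi_prior(0.1, 0.6)
  for (i in 1:100) {
    th <- rand_params()
    y <- rzinb(50, th$mu, th$phi, th$p)
    ph1 <- exp(runif(1, -2, 2)); ph2 <- exp(runif(1, -2, 2))
    d_pkg <- log_posterior_phi(ph1, y, th$mu, th$p, pr) -
      log_posterior_phi(ph2, y, th$mu, th$p, pr)
    d_ora <- (zinb_loglik_oracle(y, th$mu, ph1, th$p) +
                stats::dlnorm(ph1, 0.1, 0.6, log = TRUE)) -
      (zinb_loglik_oracle(y, th$mu, ph2, th$p) +
         stats::dlnorm(ph2, 0.1, 0.6, log = TRUE))
    expect_equal(d_pkg, d_ora, tolerance = 1e-8)
  }
  expect_error(log_posterior_phi(-1, c(0L, 1L), 1, 0.5, pr), "positive")
})

test_that("all-zero peaks reduce the posterior to its analytic form", {
  pr <- phi_prior(-0.2, 0.5)
  y <- rep(0L, 40)
  phis <- c(0.2, 1, 3)
  expected <- 40 * log(0.3 + 0.7 * (1 + 2 * phis)^(-1 / phis)) -
    (log(phis) + 0.2)^2 / (2 * 0.25) - log(phis) - log(0.5)
  expect_equal(log_posterior_phi(phis, y, mu = 2, p = 0.3, pr), expected,
               tolerance = 1e-10)

  # with p = 1 the likelihood is flat in phi: the mode is the analytic
  # prior mode exp(theta - sigma^2), also found by grid search
  m <- posterior_mode_phi(y, mu = 2, p = 1, pr)
  expect_equal(m$phi_tilde, exp(-0.2 - 0.25), tolerance = 1e-4)
  expect_equal(m$phi_tilde, post_mode_grid(y, 2, 1, pr), tolerance = 1e-2)
})

test_that("posterior mode agrees with dense grid search", {
  set.seed(29)
  worst <- 0
  for (i in 1:100) {
    th <- rand_params()
    pr <- phi_prior(rnorm(1, 0, 0.5), runif(1, 0.2, 1))
    y <- rzinb(80, th$mu, th$phi, th$p)
    em <- zinb_em(y)
    if (em$degenerate) next
    m <- posterior_mode_phi(y, em$mu, em$p, pr, phi_init = em$phi)
    g <- post_mode_grid(y, em$mu, em$p, pr, refine = TRUE)
    rel <- abs(log(m$phi_tilde) - log(g)) / max(abs(log(g)), 1)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-3)
})

test_that("prior-dominated and likelihood-dominated limits hold", {
  set.seed(31)
  y <- rzinb(200, mu = 4, phi = 1.5, p = 0.2)
  em <- zinb_em(y)
  # sigma -> 0: the mode collapses to exp(theta)
  m <- posterior_mode_phi(y, em$mu, em$p, phi_prior(-0.7, 1e-4), em$phi)
  expect_equal(m$phi_tilde, exp(-0.7), tolerance = 1e-3)
  # many cells, true phi far from exp(theta): likelihood wins
  y_big <- rzinb(10000, mu = 4, phi = 2.5, p = 0.2)
  em_big <- zinb_em(y_big)
  m_big <- posterior_mode_phi(y_big, em_big$mu, em_big$p,
                              phi_prior(-1, 0.5), em_big$phi)
  expect_lt(abs(log(m_big$phi_tilde) - log(em_big$phi)), 0.05)
})

test_that("the mode moves continuously along a sigma grid", {
  set.seed(37)
  y <- rzinb(300, mu = 3, phi = 2, p = 0.3)
  em <- zinb_em(y)
  sigmas <- seq(0.05, 1.5, length.out = 60)
  modes <- vapply(sigmas, function(s)
    posterior_mode_phi(y, em$mu, em$p, phi_prior(-0.5, s), em$phi)$phi_tilde,
    numeric(1))
  # no branch jumps: successive modes differ by a bounded factor
  expect_true(all(abs(diff(log(modes))) < 0.3))
  # the path runs from the prior anchor toward the EM estimate
  gap <- abs(log(modes) - log(em$phi))
  expect_lt(gap[length(gap)], gap[1])
  expect_lt(abs(log(modes[1]) - (-0.5)), abs(log(em$phi) - (-0.5)) / 2)
})

test_that("shrinkage reduces the error of the dispersion estimate", {
  set.seed(43)
  n_peaks <- 300
  prior_true <- phi_prior(0.03, 0.57)
  base <- draw_baseline(n_peaks, prior = prior_true)
  err_em <- err_shr <- rep(NA_real_, n_peaks)
  for (g in seq_len(n_peaks)) {
    y <- rzinb(100, base$mu[g], base$phi[g], base$p[g])
    em <- zinb_em(y)
    if (em$degenerate || !em$converged) next
    m <- posterior_mode_phi(y, em$mu, em$p, prior_true, em$phi)
    err_em[g] <- (log(em$phi) - log(base$phi[g]))^2
    err_shr[g] <- (log(m$phi_tilde) - log(base$phi[g]))^2
  }
  ok <- !is.na(err_em)
  expect_gt(sum(ok), 200)
  # paired comparison: the shrinkage gain exceeds its standard error
  d <- err_em[ok] - err_shr[ok]
  expect_gt(mean(d), 2 * sd(d) / sqrt(length(d)))
})
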