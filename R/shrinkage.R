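# Empirical-Bayes dispersion shrinkage: log-normal prior on phi estimated
# genome-wide, posterior mode per peak by Newton-Raphson in log(phi).

#' Log-normal prior on the dispersion
#'
#' Container for the hyperparameters of the log-normal prior on the
#' per-peak NB dispersion: `theta` is the location and `sigma` the scale
#' of `log(phi)`.
#'
#' @param theta prior location of `log(phi)`.
#' @param sigma prior scale of `log(phi)` (> 0).
#' @return an object of class `"phi_prior"`.
#' @export
phi_prior <- function(theta, sigma) {
  stopifnot(is.finite(theta), is.finite(sigma))
  if (sigma <= 0) stop("'sigma' must be positive")
  structure(list(theta = theta, sigma = sigma), class = "phi_prior")
}

#' @export
print.phi_prior <- function(x, ...) {
  cat(sprintf("log-normal dispersion prior: theta = %.4f, sigma = %.4f\n",
              x$theta, x$sigma))
  invisible(x)
}

#' Estimate the dispersion prior from genome-wide EM estimates
#'
#' The prior location is the median of `log(phi_hat)` across peaks. The
#' prior scale is the sample variance of `log(phi_hat)` minus the mean
#' estimation variance of the individual `log(phi_hat)` (delta-method
#' variances from the EM observed information), floored so the prior never
#' collapses: the raw spread of the estimates overstates the biological
#' spread by the estimation noise.
#'
#' @param phi_hat vector of valid per-peak EM dispersion estimates.
#' @param est_var per-peak estimation variances of `log(phi_hat)`;
#'   recycled. Missing entries are dropped from the mean.
#' @param min_peaks minimum number of valid estimates required.
#' @param sigma_floor lower bound for `sigma`.
#' @return a [phi_prior()].
#' @export
estimate_phi_prior <- function(phi_hat, est_var = 0, min_peaks = 50,
                               sigma_floor = 0.1) {
  ok <- is.finite(phi_hat) & phi_hat > 0
  phi_hat <- phi_hat[ok]
  if (length(phi_hat) < min_peaks)
    stop("need at least ", min_peaks, " valid dispersion estimates to ",
         "estimate the prior (got ", length(phi_hat), "); supply a larger ",
         "input or an explicit 'phi_prior'")
  lp <- log(phi_hat)
  est_var <- rep_len(est_var, length(ok))[ok]
  mv <- mean(est_var[is.finite(est_var)])
  if (!is.finite(mv)) mv <- 0
  s2 <- max(stats::var(lp) - mv, sigma_floor^2)
  phi_prior(theta = stats::median(lp), sigma = sqrt(s2))
}

# Internal: log conditional posterior of phi from collapsed stats,
# term-by-term expansion (up to terms constant in phi).
.log_post_phi <- function(st, phi, mu, p, theta, sigma) {
  a <- 1 / phi
  lmp <- log1p(mu * phi)
  lp <- 0
  if (st$n1 > 0) lp <- st$n1 * log(p + (1 - p) * exp(-a * lmp))
  if (st$n2 > 0) {
    lp <- lp + sum(st$cnts * lgamma(st$vals + a)) - st$n2 * lgamma(a) -
      st$n2 * a * lmp + st$sum_y * (log(mu * phi) - lmp)
  }
  lp - (log(phi) - theta)^2 / (2 * sigma^2) - log(phi) - log(sigma)
}

#' Log conditional posterior density of the dispersion
#'
#' Logarithm (up to an additive constant free of `phi`) of the conditional
#' posterior of one peak's dispersion given its counts, the peak's
#' prevalence and mean, and the genome-wide log-normal prior: the ZINB
#' likelihood factorized over zero and non-zero cells plus the log-normal
#' log-density of `phi`. Implemented term-by-term; equals
#' `zinb_loglik(y, mu, phi, p) + dlnorm(phi, theta, sigma, log = TRUE)`
#' up to a constant independent of `phi`.
#'
#' @param phi dispersion value(s) at which to evaluate (> 0); vectorized.
#' @param y non-empty count vector for the peak.
#' @param mu,p plug-in mean and prevalence (from the EM fit).
#' @param prior a [phi_prior()].
#' @return numeric vector of log-densities up to a constant.
#' @export
log_posterior_phi <- function(phi, y, mu, p, prior) {
  stopifnot(inherits(prior, "phi_prior"))
  if (any(!is.finite(phi)) || any(phi <= 0)) stop("'phi' must be positive")
  .check_params(mu, 1, p)
  st <- .peak_stats(y)
  vapply(phi, function(f) .log_post_phi(st, f, mu, p, prior$theta, prior$sigma),
         numeric(1))
}

# Newton-Raphson in eta = log(phi) with step-halving; golden-section
# fallback on the prior-centred interval when Newton fails. C++ kernel.
.posterior_mode <- function(st, mu, p, prior, phi_init = NULL) {
  if (is.null(phi_init)) phi_init <- NA_real_
  .cpp_post_mode(st$vals, st$cnts, st$n, mu, p,
                 prior$theta, prior$sigma, phi_init)
}

#' Posterior-mode (shrunken) dispersion for one peak
#'
#' Maximizes the log conditional posterior of the dispersion (see
#' [log_posterior_phi()]) by Newton-Raphson in `log(phi)` with
#' step-halving, starting from the EM estimate. If Newton fails (loss of
#' curvature, non-finite derivatives, or no ascent direction), a bounded
#' golden-section search on `log(phi)` in `theta +/- 6 sigma` guarantees a
#' result; `status` records which route produced the mode.
#'
#' @inheritParams log_posterior_phi
#' @param phi_init starting dispersion (typically the EM estimate);
#'   `NULL` starts at the prior mode.
#' @return a list with `phi_tilde` (posterior-mode dispersion) and
#'   `status` (`"newton"` or `"fallback"`).
#' @export
posterior_mode_phi <- function(y, mu, p, prior, phi_init = NULL) {
  stopifnot(inherits(prior, "phi_prior"))
  .check_params(mu, 1, p)
  .posterior_mode(.peak_stats(y), mu, p, prior, phi_init)
}
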