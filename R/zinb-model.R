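# ZINB probability model, per-peak sufficient statistics, and the EM
# algorithm used for initial parameter estimation.

# Numerical box for the dispersion; below the floor the NB is effectively
# Poisson, above the cap the Gamma terms of the pmf lose precision.
.PHI_MIN <- 1e-6
.PHI_MAX <- 1e3

.check_counts <- function(y, arg = "y") {
  if (length(y) == 0L) stop("'", arg, "' must be a non-empty count vector")
  if (anyNA(y)) stop("'", arg, "' contains missing values")
  if (any(y < 0) || any(y != round(y)))
    stop("'", arg, "' must contain non-negative integer counts")
  as.numeric(y)
}

.check_params <- function(mu, phi, p) {
  stopifnot(is.finite(mu), is.finite(phi), is.finite(p))
  if (mu <= 0) stop("'mu' must be positive")
  if (phi <= 0) stop("'phi' must be positive")
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  invisible(NULL)
}

# Collapse a count vector to the sufficient statistics of the ZINB
# likelihood: the zero cells enter only through n1, the non-zero cells
# only through their value histogram. Every likelihood evaluation is then
# O(#unique values) instead of O(#cells).
.stats_from_nz <- function(nz, n) {
  if (length(nz)) {
    vals <- sort(unique(nz))
    cnts <- tabulate(match(nz, vals))
  } else {
    vals <- numeric(0)
    cnts <- numeric(0)
  }
  sum_y <- sum(nz)
  sum_y2 <- sum(nz^2)
  ybar <- sum_y / n
  list(
    n = n, n1 = n - length(nz), n2 = length(nz),
    vals = vals, cnts = cnts,
    sum_y = sum_y,
    lgy1 = sum(cnts * lgamma(vals + 1)),
    ybar = ybar,
    s2 = if (n > 1) (sum_y2 - n * ybar^2) / (n - 1) else NA_real_
  )
}

.peak_stats <- function(y) {
  y <- .check_counts(y)
  .stats_from_nz(y[y > 0], length(y))
}

# Merge the statistics of two disjoint cell sets for the same peak
# (pooled fits reuse the per-group histograms).
.merge_stats <- function(s1, s2) {
  .stats_from_nz(c(rep(s1$vals, s1$cnts), rep(s2$vals, s2$cnts)),
                 s1$n + s2$n)
}

# ZINB log-likelihood from collapsed statistics (the two-product
# factorization: zero cells and non-zero cells separately). C++ kernel.
.zinb_ll <- function(st, mu, phi, p) {
  .cpp_zinb_ll(st$vals, st$cnts, st$n, mu, phi, p)
}

#' Zero-inflated negative binomial density
#'
#' Density (probability mass) function of the zero-inflated negative
#' binomial distribution. A count is an excess (structural) zero with
#' probability `p`, and otherwise drawn from a negative binomial with mean
#' `mu` and dispersion `phi` under the Gamma-Poisson parameterization, so
#' that the NB variance is `mu + mu^2 * phi` (NB size `1/phi`).
#'
#' @param x vector of non-negative integer counts.
#' @param mu NB mean (> 0); recycled against `x`.
#' @param phi NB dispersion (> 0); recycled.
#' @param p prevalence of excess zeros in `[0, 1]`; recycled.
#' @param log logical; return log-probabilities?
#' @return numeric vector of (log-)probabilities.
#' @examples
#' dzinb(0, mu = 1, phi = 1, p = 0.5)   # 0.75
#' sum(dzinb(0:500, mu = 3, phi = 0.6, p = 0.2))  # ~1
#' @export
dzinb <- function(x, mu, phi, p, log = FALSE) {
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("'x' must contain non-negative integers")
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (any(phi <= 0)) stop("'phi' must be positive")
  if (any(p < 0) || any(p > 1)) stop("'p' must lie in [0, 1]")
  k <- max(length(x), length(mu), length(phi), length(p))
  x <- rep_len(x, k); mu <- rep_len(mu, k)
  phi <- rep_len(phi, k); p <- rep_len(p, k)
  nb <- stats::dnbinom(x, size = 1 / phi, mu = mu)
  d <- (1 - p) * nb + p * (x == 0)
  if (log) base::log(d) else d
}

#' Simulate zero-inflated negative binomial counts
#'
#' @param n number of draws.
#' @param mu,phi,p ZINB parameters, recycled to length `n` (see [dzinb()]).
#' @return integer vector of counts.
#' @export
rzinb <- function(n, mu, phi, p) {
  mu <- rep_len(mu, n); phi <- rep_len(phi, n); p <- rep_len(p, n)
  zero <- stats::rbinom(n, 1L, p) == 1L
  out <- stats::rnbinom(n, size = 1 / phi, mu = mu)
  out[zero] <- 0L
  out
}

#' ZINB log-likelihood of one peak
#'
#' Log-likelihood of a count vector under a single ZINB distribution,
#' computed via the factorized form in which all zero cells contribute
#' `log(p + (1-p) (1+mu*phi)^(-1/phi))` and non-zero cells contribute the
#' NB terms. Equals the per-cell sum of [dzinb()] log-probabilities.
#'
#' @param y non-empty vector of non-negative integer counts.
#' @param mu,phi,p scalar ZINB parameters.
#' @return scalar log-likelihood.
#' @export
zinb_loglik <- function(y, mu, phi, p) {
  .check_params(mu, phi, p)
  .zinb_ll(.peak_stats(y), mu, phi, p)
}

#' Fit a ZINB distribution to one peak by EM
#'
#' Maximum-likelihood estimation of the per-peak ZINB parameters
#' `(p, mu, phi)` via an EM algorithm. The latent indicator for each zero
#' cell (excess zero vs. NB sampling zero) is integrated in the E-step;
#' the M-step updates `p` in closed form (mean responsibility), the mean
#' as a responsibility-weighted average, and the dispersion by bounded
#' maximization of the responsibility-weighted NB likelihood in
#' `log(phi)` (guarded so the M-step objective never decreases). The
#' log-likelihood is non-decreasing over iterations.
#'
#' Peaks that cannot support a fit (fewer than `min_nonzero` non-zero
#' cells) are flagged degenerate instead of raising an error.
#'
#' @param y non-empty vector of non-negative integer counts (one peak
#'   across cells).
#' @param tol relative log-likelihood change for convergence.
#' @param max_iter maximum EM iterations.
#' @param min_nonzero minimum number of non-zero cells for a fit.
#' @return an object of class `"zinb_em"`: a list with elements `p`, `mu`,
#'   `phi`, `loglik`, `loglik_trace`, `n_iter`, `converged`, `degenerate`,
#'   `se2_logphi` (delta-method variance of `log(phi)` from the observed
#'   information; `NA` when the curvature is unusable), `phi_interior`
#'   (whether `phi` is away from its numerical box), and the cell counts
#'   `n`, `n1` (zeros), `n2` (non-zeros).
#' @examples
#' set.seed(1)
#' y <- rzinb(500, mu = 5, phi = 0.5, p = 0.3)
#' fit <- zinb_em(y)
#' unlist(fit[c("p", "mu", "phi")])
#' @export
zinb_em <- function(y, tol = 1e-8, max_iter = 500, min_nonzero = 3) {
  .zinb_em_st(.peak_stats(y), tol = tol, max_iter = max_iter,
              min_nonzero = min_nonzero)
}

.zinb_em_st <- function(st, tol = 1e-8, max_iter = 500, min_nonzero = 3) {
  fit <- .cpp_em(st$vals, st$cnts, st$n, tol, as.integer(max_iter),
                 as.integer(min_nonzero))
  out <- list(
    p = NA_real_, mu = NA_real_, phi = NA_real_,
    loglik = NA_real_, loglik_trace = numeric(0),
    n_iter = 0L, converged = FALSE, degenerate = TRUE,
    se2_logphi = NA_real_, phi_interior = FALSE,
    n = st$n, n1 = st$n1, n2 = st$n2
  )
  class(out) <- "zinb_em"
  if (isTRUE(fit$degenerate)) return(out)
  out[c("p", "mu", "phi", "loglik", "loglik_trace", "n_iter", "converged",
        "se2_logphi", "phi_interior")] <-
    fit[c("p", "mu", "phi", "loglik", "loglik_trace", "n_iter", "converged",
          "se2_logphi", "phi_interior")]
  out$degenerate <- FALSE
  out
}

#' @export
print.zinb_em <- function(x, ...) {
  if (x$degenerate) {
    cat("ZINB EM fit: degenerate peak (", x$n2, "non-zero cells )\n")
  } else {
    cat(sprintf(
      "ZINB EM fit: p = %.4f, mu = %.4f, phi = %.4f (loglik %.3f, %d iter%s)\n",
      x$p, x$mu, x$phi, x$loglik, x$n_iter,
      if (x$converged) "" else ", not converged"
    ))
  }
  invisible(x)
}
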