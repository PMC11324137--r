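# Bounded coordinate-wise re-optimization of mean and prevalence at the
# shrunken dispersion.

#' Refine mean and prevalence at a fixed (shrunken) dispersion
#'
#' After the dispersion has moved from its EM estimate to the
#' empirical-Bayes posterior mode, the mean and prevalence are re-fit by
#' iterative bounded one-dimensional likelihood maximization: per outer
#' iteration, `mu` is maximized over `[0.01, mu_max]` holding the previous
#' `p`, then `p` over `[0.01, p_max]` holding the previous `mu` (both
#' one-dimensional searches condition on the previous iterate). Iteration
#' stops when the relative change of both parameters falls below `tol` or
#' after `max_iter` outer iterations. Each 1-D search uses Brent-type
#' derivative-free optimization. The returned pair is the
#' likelihood-best iterate visited (including the starting values), so
#' refinement never worsens the objective at the fixed dispersion.
#'
#' @param y non-empty count vector for the peak.
#' @param mu0,p0 starting values (typically EM estimates).
#' @param phi dispersion held fixed (typically the posterior mode).
#' @param mu_max,p_max upper bounds; conventionally the maxima of the EM
#'   estimates across all peaks. `p_max` is capped at 0.99 to keep the
#'   mixture identifiable.
#' @param tol relative-change convergence tolerance.
#' @param max_iter maximum outer iterations.
#' @return a list with refined `mu`, `p`, the fixed `phi`, `loglik` at the
#'   returned pair, `n_iter`, and `converged`.
#' @export
refine_zinb <- function(y, mu0, p0, phi, mu_max, p_max = 0.99,
                        tol = 1e-6, max_iter = 100) {
  if (!is.finite(phi) || phi <= 0) stop("'phi' must be positive")
  st <- .peak_stats(y)
  .refine(st, mu0, p0, phi, mu_max, p_max, tol, max_iter)
}

.refine <- function(st, mu0, p0, phi, mu_max, p_max = 0.99,
                    tol = 1e-6, max_iter = 100) {
  out <- .cpp_refine(st$vals, st$cnts, st$n, mu0, p0, phi,
                     mu_max, p_max, tol, as.integer(max_iter))
  out$phi <- phi
  out
}
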