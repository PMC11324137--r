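# Per-peak differential accessibility testing: the composite shrunken
# LRT (3 d.f.) and the plain ZINB LRT variants, plus BH correction and
# differential calling.

# Coerce a peak-by-cell count input (dense matrix, sparse Matrix, or
# peak_matrix) to a list of per-peak sufficient statistics. Sparse input
# is traversed through its slots; no densification.
.stats_list <- function(x) {
  if (inherits(x, "peak_matrix")) x <- x$counts
  if (inherits(x, "sparseMatrix")) {
    tC <- methods::as(Matrix::t(x), "CsparseMatrix")
    n <- nrow(tC)
    px <- tC@p
    vx <- tC@x
    if (any(vx < 0) || any(vx != round(vx)))
      stop("count matrix must contain non-negative integers")
    lapply(seq_len(ncol(tC)), function(g) {
      k <- px[g + 1L] - px[g]
      v <- if (k > 0L) vx[px[g] + seq_len(k)] else numeric(0)
      .stats_from_nz(v[v > 0], n)
    })
  } else {
    x <- as.matrix(x)
    if (anyNA(x) || any(x < 0) || any(x != round(x)))
      stop("count matrix must contain non-negative integers")
    lapply(seq_len(nrow(x)), function(g) {
      y <- x[g, ]
      .stats_from_nz(y[y > 0], length(y))
    })
  }
}

.peak_ids <- function(x, n_peaks) {
  ids <- if (inherits(x, "peak_matrix")) x$peaks$peak_id else rownames(x)
  if (is.null(ids)) ids <- sprintf("peak_%05d", seq_len(n_peaks))
  ids
}

.resolve_group <- function(x, group) {
  if (is.null(group) && inherits(x, "peak_matrix")) group <- x$group
  if (is.null(group)) stop("'group' labels are required")
  group <- as.factor(group)
  if (nlevels(group) != 2L)
    stop("'group' must have exactly two levels (got ", nlevels(group), ")")
  ncol_x <- if (inherits(x, "peak_matrix")) ncol(x$counts) else ncol(x)
  if (length(group) != ncol_x)
    stop("length of 'group' (", length(group), ") does not match the ",
         "number of cells (", ncol_x, ")")
  group
}

# Estimate the genome-wide dispersion prior from a list of EM fits.
# Only informative dispersions enter: converged fits away from the
# numerical box whose delta-method SE(log phi) is below 1 (in the
# ultra-sparse regime phi is near-unidentifiable and its estimate
# diverges; such peaks carry no information about the prior).
.prior_from_em <- function(em, se2_cap = 1) {
  se2 <- vapply(em, `[[`, numeric(1), "se2_logphi")
  usable <- !vapply(em, `[[`, logical(1), "degenerate") &
    vapply(em, `[[`, logical(1), "converged") &
    vapply(em, `[[`, logical(1), "phi_interior") &
    is.finite(se2) & se2 < se2_cap
  estimate_phi_prior(vapply(em[usable], `[[`, numeric(1), "phi"),
                     se2[usable])
}

# Run the full estimation pipeline (EM -> shrinkage -> refinement) over a
# list of per-peak statistics for one fitting context, under a given
# genome-wide dispersion prior.
.fit_context <- function(stats, prior = NULL, min_nonzero = 3,
                         shrink = TRUE, refine = TRUE, em = NULL) {
  if (is.null(em)) em <- lapply(stats, .zinb_em_st, min_nonzero = min_nonzero)
  p_em <- vapply(em, `[[`, numeric(1), "p")
  mu_em <- vapply(em, `[[`, numeric(1), "mu")
  phi_em <- vapply(em, `[[`, numeric(1), "phi")
  ll_em <- vapply(em, `[[`, numeric(1), "loglik")
  deg <- vapply(em, `[[`, logical(1), "degenerate")
  if (all(deg)) stop("all peaks are degenerate in one fitting context")

  out <- data.frame(
    p_em = p_em, mu_em = mu_em, phi_em = phi_em, loglik_em = ll_em,
    em_converged = vapply(em, `[[`, logical(1), "converged"),
    n_nonzero = vapply(em, `[[`, integer(1), "n2"),
    degenerate = deg,
    phi_shrunk = NA_real_, shrink_status = NA_character_,
    mu_ref = NA_real_, p_ref = NA_real_, loglik_ref = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!shrink) {
    out$phi_shrunk <- phi_em
    out$mu_ref <- mu_em
    out$p_ref <- p_em
    out$loglik_ref <- ll_em
    return(list(fits = out, prior = NULL))
  }

  if (is.null(prior)) prior <- .prior_from_em(em)
  stopifnot(inherits(prior, "phi_prior"))
  mu_max <- max(mu_em[!deg])
  p_max <- min(max(c(p_em[!deg], 0.01)), 0.99)

  for (g in which(!deg)) {
    sm <- .posterior_mode(stats[[g]], mu_em[g], p_em[g], prior,
                          phi_init = phi_em[g])
    out$phi_shrunk[g] <- sm$phi_tilde
    out$shrink_status[g] <- sm$status
    if (refine) {
      rf <- .refine(stats[[g]], mu_em[g], p_em[g], sm$phi_tilde,
                    mu_max = mu_max, p_max = p_max)
      out$mu_ref[g] <- rf$mu
      out$p_ref[g] <- rf$p
      out$loglik_ref[g] <- rf$loglik
    } else {
      out$mu_ref[g] <- mu_em[g]
      out$p_ref[g] <- p_em[g]
      out$loglik_ref[g] <- .zinb_ll(stats[[g]], mu_em[g], sm$phi_tilde,
                                    p_em[g])
    }
  }
  list(fits = out, prior = prior)
}

#' Fit the shrunken ZINB model to every peak of one cell group
#'
#' Runs the full estimation pipeline for a single set of cells: per-peak
#' EM fits, empirical-Bayes dispersion shrinkage under a log-normal prior
#' estimated from this matrix's own EM dispersions, and bounded
#' refinement of mean and prevalence at the shrunken dispersion.
#'
#' @param x peak-by-cell count matrix (dense, sparse [Matrix::Matrix], or
#'   a `peak_matrix` from [read_peak_counts()]).
#' @param prior optional [phi_prior()]; by default estimated from the EM
#'   dispersion estimates of this matrix (requires >= 50 usable peaks).
#' @param min_nonzero minimum non-zero cells for a peak to be fit.
#' @return a data.frame with one row per peak: EM estimates (`p_em`,
#'   `mu_em`, `phi_em`, `loglik_em`), the shrunken dispersion
#'   (`phi_shrunk`), refined estimates (`mu_ref`, `p_ref`,
#'   `loglik_ref`), and flags. The estimated prior is attached as
#'   attribute `"prior"`.
#' @export
fit_zinb_peaks <- function(x, prior = NULL, min_nonzero = 3) {
  stats <- .stats_list(x)
  ctx <- .fit_context(stats, prior = prior, min_nonzero = min_nonzero)
  fits <- cbind(peak_id = .peak_ids(x, length(stats)), ctx$fits,
                stringsAsFactors = FALSE)
  attr(fits, "prior") <- ctx$prior
  fits
}

.finalize_results <- function(res, df, method, n_clipped, fdr_cut = NULL) {
  res$fdr <- bh_adjust(res$pvalue)
  res <- res[, c("peak_id", "lambda_lr", "df", "pvalue", "fdr",
                 "log2fc_mu", "log2fc_p", "log2fc_phi", "status")]
  class(res) <- c("da_results", "data.frame")
  attr(res, "method") <- method
  attr(res, "test_df") <- df
  attr(res, "n_clipped") <- n_clipped
  res
}

#' Composite shrunken ZINB differential accessibility test
#'
#' For every peak, tests the joint null that the two cell groups share
#' all three ZINB parameters (prevalence, mean, dispersion) against the
#' alternative that any differ, using a likelihood-ratio statistic with 3
#' degrees of freedom. The parameters entering both likelihoods are the
#' refined/shrunken estimates: the pooled cells (null) and each group
#' (alternative) are run through the full pipeline (EM, empirical-Bayes
#' dispersion shrinkage, then bounded refinement of mean and prevalence).
#' One genome-wide log-normal dispersion prior, estimated from the
#' pooled-cell EM dispersions across all peaks, is shared by all three
#' fitting contexts: shrinking the null and alternative fits toward
#' different targets would bias the likelihood-ratio statistic.
#'
#' Peaks with fewer than `min_nonzero` non-zero cells in either group are
#' reported with `status = "degenerate"` and missing p-value; they are
#' excluded from the BH ranking denominator.
#'
#' @param x peak-by-cell count matrix (dense, sparse, or `peak_matrix`).
#' @param group two-level factor of cell group labels; taken from `x`
#'   when `x` is a `peak_matrix` carrying labels.
#' @param prior optional [phi_prior()] used for all three fitting
#'   contexts; by default estimated from the pooled-cell EM fits
#'   (requires >= 50 informative peaks).
#' @param min_nonzero degeneracy rule threshold.
#' @return a `da_results` data.frame with one row per peak: `peak_id`,
#'   `lambda_lr`, `df`, `pvalue`, `fdr` (BH), `log2fc_mu`, `log2fc_p`,
#'   `log2fc_phi` (log2 ratios of group-1 to group-2 refined estimates),
#'   and `status`. The number of negative statistics clipped to zero is
#'   attached as attribute `"n_clipped"`.
#' @examples
#' sim <- simulate_accessibility(n_peaks = 60, n_cells_per_group = 50,
#'                               scenario = "mean", log2fc = 2, seed = 1)
#' res <- zinbda(sim$counts, sim$group, prior = phi_prior(0.03, 0.57))
#' head(res)
#' @export
zinbda <- function(x, group = NULL, prior = NULL, min_nonzero = 3) {
  group <- .resolve_group(x, group)
  idx1 <- which(group == levels(group)[1])
  idx2 <- which(group == levels(group)[2])

  counts <- if (inherits(x, "peak_matrix")) x$counts else x
  n_peaks <- nrow(counts)
  s1 <- .stats_list(counts[, idx1, drop = FALSE])
  s2 <- .stats_list(counts[, idx2, drop = FALSE])
  s0 <- mapply(.merge_stats, s1, s2, SIMPLIFY = FALSE)

  # one genome-wide dispersion prior, estimated from the pooled-cell EM
  # fits and shared by all three fitting contexts (asymmetric priors
  # would bias the likelihood-ratio statistic)
  em0 <- lapply(s0, .zinb_em_st, min_nonzero = min_nonzero)
  if (is.null(prior)) prior <- .prior_from_em(em0)
  c1 <- .fit_context(s1, prior = prior, min_nonzero = min_nonzero)
  c2 <- .fit_context(s2, prior = prior, min_nonzero = min_nonzero)
  c0 <- .fit_context(s0, prior = prior, min_nonzero = min_nonzero, em = em0)

  tested <- !c1$fits$degenerate & !c2$fits$degenerate
  ll0 <- c0$fits$loglik_ref
  llA <- c1$fits$loglik_ref + c2$fits$loglik_ref
  raw <- 2 * (llA - ll0)
  n_clipped <- sum(tested & is.finite(raw) & raw < 0)
  lambda <- ifelse(tested, pmax(raw, 0), NA_real_)

  res <- data.frame(
    peak_id = .peak_ids(x, n_peaks),
    lambda_lr = lambda,
    df = ifelse(tested, 3L, NA_integer_),
    pvalue = ifelse(tested,
                    stats::pchisq(lambda, df = 3, lower.tail = FALSE),
                    NA_real_),
    log2fc_mu = log2(c1$fits$mu_ref / c2$fits$mu_ref),
    log2fc_p = log2(c1$fits$p_ref / c2$fits$p_ref),
    log2fc_phi = log2(c1$fits$phi_shrunk / c2$fits$phi_shrunk),
    status = ifelse(tested, "tested", "degenerate"),
    stringsAsFactors = FALSE
  )
  out <- .finalize_results(res, 3L, "zinbda", n_clipped)
  attr(out, "prior") <- prior
  out
}

# Joint ML fit of the reduced model for a plain ZINB LRT: the tested
# parameters are shared between groups, the remaining ones stay free per
# group. Box-constrained quasi-Newton on (log mu, logit p, log phi).
.reduced_fit <- function(s1, s2, test, em1, em2, em0) {
  free <- setdiff(c("mu", "p", "phi"), test)
  par <- c()
  lower <- c(); upper <- c()
  tr <- list(mu = log, p = stats::qlogis, phi = log)
  box <- list(mu = c(log(1e-6), log(1e6)),
              p = c(-15, 15),
              phi = c(log(.PHI_MIN), log(.PHI_MAX)))
  clamp <- function(v, b) min(max(v, b[1] + 1e-9), b[2] - 1e-9)
  pe <- function(em, w) switch(w, mu = em$mu, p = min(max(em$p, 1e-6), 1 - 1e-6),
                               phi = em$phi)
  for (w in test) {
    par <- c(par, clamp(tr[[w]](pe(em0, w)), box[[w]]))
    lower <- c(lower, box[[w]][1]); upper <- c(upper, box[[w]][2])
  }
  for (w in free) for (em in list(em1, em2)) {
    par <- c(par, clamp(tr[[w]](pe(em, w)), box[[w]]))
    lower <- c(lower, box[[w]][1]); upper <- c(upper, box[[w]][2])
  }
  decode <- function(par) {
    th <- list(g1 = list(), g2 = list())
    i <- 0L
    inv <- list(mu = exp, p = stats::plogis, phi = exp)
    for (w in test) {
      i <- i + 1L
      th$g1[[w]] <- th$g2[[w]] <- inv[[w]](par[i])
    }
    for (w in free) {
      th$g1[[w]] <- inv[[w]](par[i + 1L])
      th$g2[[w]] <- inv[[w]](par[i + 2L])
      i <- i + 2L
    }
    th
  }
  negll <- function(par) {
    th <- decode(par)
    v <- -(.zinb_ll(s1, th$g1$mu, th$g1$phi, th$g1$p) +
             .zinb_ll(s2, th$g2$mu, th$g2$phi, th$g2$p))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- try(stats::optim(par, negll, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 200)), silent = TRUE)
  if (inherits(opt, "try-error")) return(-negll(par))
  -min(opt$value, negll(par))
}

# Box-constrained polish of one group's unconstrained ZINB fit, started
# from the EM estimate; returns the better of the two log-likelihoods.
.polish_full <- function(s, em) {
  par <- c(log(em$mu), stats::qlogis(min(max(em$p, 1e-6), 1 - 1e-6)),
           log(em$phi))
  negll <- function(v) {
    out <- -.zinb_ll(s, exp(v[1]), exp(v[3]), stats::plogis(v[2]))
    if (!is.finite(out)) 1e10 else out
  }
  opt <- try(stats::optim(par, negll, method = "L-BFGS-B",
                          lower = c(log(1e-6), -15, log(.PHI_MIN)),
                          upper = c(log(1e6), 15, log(.PHI_MAX)),
                          control = list(maxit = 200)), silent = TRUE)
  if (inherits(opt, "try-error")) return(em$loglik)
  max(em$loglik, -opt$value)
}

#' Plain ZINB likelihood-ratio test variants
#'
#' Per-peak ZINB likelihood-ratio tests on a chosen subset of parameters,
#' without dispersion shrinkage or refinement. The full model fits each
#' group by plain EM; the reduced model shares the tested parameters
#' between groups (remaining parameters stay group-specific, fitted by
#' joint box-constrained maximization). Degrees of freedom equal the
#' number of tested parameters. With `test = c("mu", "p", "phi")` the
#' reduced model is the pooled plain EM fit.
#'
#' @inheritParams zinbda
#' @param test character subset of `c("mu", "p", "phi")` to test.
#' @return a `da_results` data.frame (see [zinbda()]); fold changes are
#'   log2 ratios of the plain group EM estimates.
#' @export
zinb_lrt <- function(x, group = NULL, test = c("mu", "p", "phi"),
                     min_nonzero = 3) {
  test <- match.arg(test, c("mu", "p", "phi"), several.ok = TRUE)
  test <- intersect(c("mu", "p", "phi"), unique(test))
  group <- .resolve_group(x, group)
  counts <- if (inherits(x, "peak_matrix")) x$counts else x
  idx1 <- which(group == levels(group)[1])
  idx2 <- which(group == levels(group)[2])
  s1 <- .stats_list(counts[, idx1, drop = FALSE])
  s2 <- .stats_list(counts[, idx2, drop = FALSE])
  s0 <- mapply(.merge_stats, s1, s2, SIMPLIFY = FALSE)
  n_peaks <- length(s1)
  df <- length(test)

  lambda <- rep(NA_real_, n_peaks)
  l2mu <- l2p <- l2phi <- rep(NA_real_, n_peaks)
  tested <- rep(FALSE, n_peaks)
  n_clipped <- 0L
  for (g in seq_len(n_peaks)) {
    em1 <- .zinb_em_st(s1[[g]], min_nonzero = min_nonzero)
    em2 <- .zinb_em_st(s2[[g]], min_nonzero = min_nonzero)
    if (em1$degenerate || em2$degenerate) next
    em0 <- .zinb_em_st(s0[[g]], min_nonzero = min_nonzero)
    ll_full <- em1$loglik + em2$loglik
    ll_red <- if (df == 3L) em0$loglik else
      .reduced_fit(s1[[g]], s2[[g]], test, em1, em2, em0)
    if (ll_red > ll_full) {
      # the joint reduced search out-optimized an under-converged EM:
      # polish each group's full fit from its EM estimate
      ll_full <- .polish_full(s1[[g]], em1) + .polish_full(s2[[g]], em2)
    }
    raw <- 2 * (ll_full - ll_red)
    if (is.finite(raw) && raw < 0) n_clipped <- n_clipped + 1L
    lambda[g] <- max(raw, 0)
    tested[g] <- TRUE
    l2mu[g] <- log2(em1$mu / em2$mu)
    l2p[g] <- log2(em1$p / em2$p)
    l2phi[g] <- log2(em1$phi / em2$phi)
  }
  res <- data.frame(
    peak_id = .peak_ids(x, n_peaks),
    lambda_lr = lambda,
    df = ifelse(tested, df, NA_integer_),
    pvalue = ifelse(tested,
                    stats::pchisq(lambda, df = df, lower.tail = FALSE),
                    NA_real_),
    log2fc_mu = l2mu, log2fc_p = l2p, log2fc_phi = l2phi,
    status = ifelse(tested, "tested", "degenerate"),
    stringsAsFactors = FALSE
  )
  .finalize_results(res, df, paste0("zinb_lrt(", paste(test, collapse = ","), ")"),
                    n_clipped)
}

#' Benjamini-Hochberg adjustment with missing values
#'
#' Step-up BH adjusted values via [stats::p.adjust()]. Missing entries
#' propagate as missing and are excluded from the ranking denominator
#' (the effective number of tests is the number of non-missing
#' p-values).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`, possibly with
#'   `NA` entries.
#' @return numeric vector of BH-adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Call differential peaks
#'
#' A peak is called differential when its BH-adjusted FDR is below
#' `fdr_cut` and the absolute log2 fold change of the mean exceeds
#' `lfc_cut`. Peaks with missing FDR (degenerate) are never called.
#'
#' @param results a `da_results` data.frame (from [zinbda()] or
#'   [zinb_lrt()]).
#' @param fdr_cut FDR threshold (default 0.05).
#' @param lfc_cut absolute log2 fold-change threshold on the mean
#'   (default 0.5).
#' @return logical vector, one entry per peak.
#' @export
call_differential <- function(results, fdr_cut = 0.05, lfc_cut = 0.5) {
  out <- results$fdr < fdr_cut & abs(results$log2fc_mu) > lfc_cut
  out[is.na(out)] <- FALSE
  out
}
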