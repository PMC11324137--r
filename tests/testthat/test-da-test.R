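make_two_group <- function(n_peaks, n_cells, mu1, p1, phi1,
                           mu2 = mu1, p2 = p1, phi2 = phi1) {
  g1 <- matrix(rzinb(n_peaks * n_cells, rep(mu1, n_cells),
                     rep(phi1, n_cells), rep(p1, n_cells)), n_peaks)
  g2 <- matrix(rzinb(n_peaks * n_cells, rep(mu2, n_cells),
                     rep(phi2, n_cells), rep(p2, n_cells)), n_peaks)
  list(counts = cbind(g1, g2),
       group = factor(rep(c("a", "b"), each = n_cells)))
}

test_that("identical groups give null statistics and unit p-values", {
  set.seed(51)
  m <- matrix(rzinb(30 * 60, 3, 1, 0.3), 30, 60)
  x <- cbind(m, m)  # group b is a copy of group a
  res <- zinbda(x, factor(rep(c("a", "b"), each = 60)),
               prior = phi_prior(0, 0.57))
  expect_s3_class(res, "da_results")
  expect_true(all(res$lambda_lr < 1, na.rm = TRUE))
  expect_true(all(res$pvalue > 0.8, na.rm = TRUE))
  expect_true(all(abs(res$log2fc_mu) < 0.2, na.rm = TRUE))
})

test_that("reported p-values are the chi-square tail of the statistic", {
  set.seed(53)
  tg <- make_two_group(40, 50, mu1 = 3, p1 = 0.3, phi1 = 1, mu2 = 6)
  res <- zinbda(tg$counts, tg$group, prior = phi_prior(0, 0.57))
  ok <- !is.na(res$pvalue)
  expect_equal(res$pvalue[ok],
               pchisq(res$lambda_lr[ok], df = 3, lower.tail = FALSE))
  expect_true(all(res$df[ok] == 3))
  expect_true(all(res$lambda_lr[ok] >= 0))

  resv <- zinb_lrt(tg$counts, tg$group, test = "mu")
  okv <- !is.na(resv$pvalue)
  expect_equal(resv$pvalue[okv],
               pchisq(resv$lambda_lr[okv], df = 1, lower.tail = FALSE))
})

test_that("the composite test detects a strong mean shift", {
  set.seed(55)
  sim <- simulate_accessibility(n_peaks = 200, n_cells_per_group = 80,
                                scenario = "mean", log2fc = 2.5, seed = 56)
  res <- zinbda(sim$counts, sim$group)
  calls <- !is.na(res$fdr) & res$fdr < 0.05
  cm <- confusion_metrics(calls, sim$truth$is_differential)
  expect_gt(cm$tpr, 0.5)
  expect_lt(cm$fdp, 0.2)
})

test_that("degenerate peaks are flagged and excluded from the BH ranking", {
  set.seed(57)
  tg <- make_two_group(20, 40, mu1 = 4, p1 = 0.3, phi1 = 1)
  tg$counts[3, 1:40] <- 0L   # all-zero in group a
  tg$counts[7, ] <- 0L       # all-zero everywhere
  res <- zinbda(tg$counts, tg$group, prior = phi_prior(0, 0.57))
  expect_equal(res$status[c(3, 7)], c("degenerate", "degenerate"))
  expect_true(all(is.na(res$pvalue[c(3, 7)])))
  expect_true(all(is.na(res$fdr[c(3, 7)])))
  # BH denominator = number of tested peaks
  ok <- !is.na(res$pvalue)
  expect_equal(res$fdr[ok], p.adjust(res$pvalue[ok], "BH"))
})

test_that("LRT variants are nested and ordered by the driving parameter", {
  set.seed(59)
  # prevalence-only difference: ZINB(p) must reject more than ZINB(mu)
  tg <- make_two_group(60, 70, mu1 = 4, p1 = 0.15, phi1 = 0.8, p2 = 0.65)
  res_p <- zinb_lrt(tg$counts, tg$group, test = "p")
  res_mu <- zinb_lrt(tg$counts, tg$group, test = "mu")
  rej_p <- sum(res_p$pvalue < 0.05, na.rm = TRUE)
  rej_mu <- sum(res_mu$pvalue < 0.05, na.rm = TRUE)
  expect_gt(rej_p, rej_mu)
  # nesting keeps the statistic non-negative (up to clipping, which is
  # logged)
  expect_true(all(res_p$lambda_lr >= 0, na.rm = TRUE))
  expect_lte(attr(res_p, "n_clipped"), 1)
  # identical groups under the 3-parameter variant: reduced = pooled fit
  m <- matrix(rzinb(25 * 50, 3, 1, 0.3), 25, 50)
  res0 <- zinb_lrt(cbind(m, m), factor(rep(c("a", "b"), each = 50)))
  expect_true(all(res0$lambda_lr < 1, na.rm = TRUE))
})

test_that("BH adjustment handles ties, singletons, and missing values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.07), 0.07)
  out <- bh_adjust(c(0.01, NA, 0.02, 0.03, NA, 0.04))
  expect_true(all(is.na(out[c(2, 5)])))
  expect_equal(out[!is.na(out)], rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("differential calling applies both thresholds", {
  res <- data.frame(fdr = c(0.04, 0.04, NA, 0.10, 0.001),
                    log2fc_mu = c(0.6, 0.3, 2.0, 0.9, -0.8))
  expect_equal(call_differential(res),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(call_differential(res, fdr_cut = 0.2, lfc_cut = 0.25),
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
})
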