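test_that("simulation is deterministic under a seed", {
  s1 <- simulate_accessibility(n_peaks = 50, n_cells_per_group = 30,
                               scenario = "all", log2fc = 1, seed = 99)
  s2 <- simulate_accessibility(n_peaks = 50, n_cells_per_group = 30,
                               scenario = "all", log2fc = 1, seed = 99)
  s3 <- simulate_accessibility(n_peaks = 50, n_cells_per_group = 30,
                               scenario = "all", log2fc = 1, seed = 100)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(as.matrix(s1$counts), as.matrix(s3$counts)))
})

test_that("baseline draws follow the dispersion prior and the table", {
  base <- draw_baseline(10000, prior = phi_prior(0.03, 0.57), seed = 61)
  lph <- log(base$phi)
  expect_lt(abs(mean(lph) - 0.03), 3 * 0.57 / sqrt(10000))
  expect_lt(abs(sd(lph) - 0.57), 0.02)
  expect_true(all(base$p >= 0.01 & base$p <= 0.9))
  expect_true(all(base$mu > 0))

  tab <- data.frame(mu = 2.5, p = 0.4)
  b1 <- draw_baseline(20, baseline = tab, seed = 62)
  expect_true(all(b1$mu == 2.5) && all(b1$p == 0.4))
  expect_error(draw_baseline(5, baseline = data.frame(mu = numeric(0),
                                                      p = numeric(0))),
               "empty")
})

test_that("effect injection splits, scales, and clips as configured", {
  base <- data.frame(mu = rep(2, 4000), p = rep(0.3, 4000),
                     phi = rep(1, 4000))
  tr <- apply_effect(base, scenario = "mean", log2fc = 1,
                     prop_differential = 0.2, seed = 63)
  expect_equal(sum(tr$is_differential), 800)
  expect_equal(sum(tr$direction == "multiplied", na.rm = TRUE), 400)
  expect_equal(sum(tr$direction == "divided", na.rm = TRUE), 400)
  expect_setequal(unique(tr$mu2[tr$is_differential]), c(4, 1))
  expect_true(all(tr$mu2[!tr$is_differential] == 2))

  # a null effect changes nothing
  tr0 <- apply_effect(base, scenario = "all", log2fc = 0, seed = 64)
  expect_equal(tr0[, c("mu2", "p2", "phi2")],
               setNames(tr0[, c("mu1", "p1", "phi1")],
                        c("mu2", "p2", "phi2")))

  # prevalence scaling clips at 0.99 and records it
  basep <- data.frame(mu = rep(2, 100), p = rep(0.6, 100),
                      phi = rep(1, 100))
  trp <- apply_effect(basep, scenario = "prevalence", log2fc = 1,
                      prop_differential = 1, seed = 65)
  expect_true(all(trp$p2 <= 0.99))
  expect_true(all(trp$p_clipped[trp$direction == "multiplied"]))
})

test_that("simulated counts match the ZINB moment identities", {
  truth <- data.frame(
    peak_id = sprintf("peak_%05d", 1:4),
    is_differential = FALSE, direction = NA_character_,
    mu1 = c(0.5, 2, 5, 10), p1 = c(0.1, 0.3, 0.6, 0.8),
    phi1 = c(0.2, 1, 0.5, 2),
    mu2 = c(0.5, 2, 5, 10), p2 = c(0.1, 0.3, 0.6, 0.8),
    phi2 = c(0.2, 1, 0.5, 2),
    p_clipped = FALSE, stringsAsFactors = FALSE
  )
  sim <- generate_counts(truth, n_cells_per_group = 10000, seed = 67)
  cnt <- as.matrix(sim$counts)
  n <- ncol(cnt)
  for (g in 1:4) {
    mu <- truth$mu1[g]; p <- truth$p1[g]; phi <- truth$phi1[g]
    m_the <- (1 - p) * mu
    v_the <- (1 - p) * (mu + mu^2 * phi) + p * (1 - p) * mu^2
    z_the <- p + (1 - p) * (1 + mu * phi)^(-1 / phi)
    expect_lt(abs(mean(cnt[g, ]) - m_the), 3 * sqrt(v_the / n))
    expect_lt(abs(mean(cnt[g, ] == 0) - z_the),
              3 * sqrt(z_the * (1 - z_the) / n))
    expect_lt(abs(stats::var(cnt[g, ]) / v_the - 1), 0.1)
  }
})

test_that("pure zero-inflation produces all-zero rows", {
  truth <- data.frame(
    peak_id = "peak_00001", is_differential = FALSE,
    direction = NA_character_,
    mu1 = 5, p1 = 1, phi1 = 1, mu2 = 5, p2 = 1, phi2 = 1,
    p_clipped = FALSE, stringsAsFactors = FALSE
  )
  sim <- generate_counts(truth, n_cells_per_group = 200, seed = 68)
  expect_equal(Matrix::nnzero(sim$counts), 0)
})
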