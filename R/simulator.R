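# Semi-parametric simulator of sparse peak-by-cell scATAC-seq counts
# with fold-change injection on mean, prevalence, and/or dispersion.

#' Draw baseline per-peak ZINB parameters
#'
#' Baseline `(mu, p)` pairs are sampled jointly with replacement from a
#' table of per-peak estimates, preserving their empirical correlation;
#' dispersions are drawn independently from the log-normal prior. With
#' `baseline = "synthetic"`, `(mu, p)` come from a built-in emulator of
#' accessible peaks within one profiled cell type: `log(mu) ~
#' Normal(log 3, 0.7)`, and the prevalence of excess zeros decreases
#' logistically with `log(mu)` (`p = plogis(-0.3 - 0.7 (log mu - log 3)
#' + eps)`, `eps ~ Normal(0, 0.5)`, clipped to `[0.01, 0.9]`), so that
#' rarely accessible peaks carry more structural zeros. The regime is
#' chosen so that genome-wide EM log-dispersion estimates at 100 cells
#' come out approximately Gaussian with spread below one — the empirical
#' behaviour that motivates the log-normal shrinkage prior. Peaks closed
#' in the profiled cell type (the bulk of a whole-matrix scATAC-seq
#' count table, which is far sparser overall) sit upstream of
#' differential testing and are not emulated.
#'
#' @param n_peaks number of peaks.
#' @param baseline `"synthetic"` or a data.frame with columns `mu` and
#'   `p` (one row per observed peak).
#' @param prior [phi_prior()] for the dispersion draws; default
#'   `phi_prior(0.03, 0.57)`.
#' @param seed optional integer seed for reproducible draws.
#' @return data.frame with columns `mu`, `p`, `phi`.
#' @export
draw_baseline <- function(n_peaks, baseline = "synthetic",
                          prior = phi_prior(0.03, 0.57), seed = NULL) {
  stopifnot(inherits(prior, "phi_prior"), n_peaks >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(baseline) && identical(baseline, "synthetic")) {
    lmu <- stats::rnorm(n_peaks, log(3), 0.7)
    mu <- exp(lmu)
    p <- stats::plogis(-0.3 - 0.7 * (lmu - log(3)) +
                         stats::rnorm(n_peaks, 0, 0.5))
    p <- pmin(pmax(p, 0.01), 0.9)
  } else {
    baseline <- as.data.frame(baseline)
    if (nrow(baseline) == 0L) stop("'baseline' table is empty")
    if (!all(c("mu", "p") %in% names(baseline)))
      stop("'baseline' must have columns 'mu' and 'p'")
    rows <- sample.int(nrow(baseline), n_peaks, replace = TRUE)
    mu <- baseline$mu[rows]
    p <- baseline$p[rows]
  }
  phi <- exp(stats::rnorm(n_peaks, prior$theta, prior$sigma))
  data.frame(mu = mu, p = p, phi = phi)
}

#' Inject group-2 effects into baseline parameters
#'
#' Group 1 keeps the baseline parameters. For a random subset of
#' `prop_differential` of the peaks, the scenario's parameter set (mean,
#' prevalence, dispersion, or all three) is multiplied by `2^log2fc` for
#' half of the differential peaks and divided for the other half (split
#' sizes differ by at most one). The prevalence is clipped to
#' `[0.01, 0.99]` after scaling; `p_clipped` records where the clip was
#' binding. Non-differential peaks are identical across groups.
#'
#' @param base data.frame from [draw_baseline()] (columns `mu`, `p`,
#'   `phi`).
#' @param scenario one of `"mean"`, `"prevalence"`, `"dispersion"`,
#'   `"all"`.
#' @param log2fc non-negative effect size on the log2 scale.
#' @param prop_differential fraction of differential peaks in `[0, 1]`.
#' @param seed optional integer seed.
#' @return a data.frame ("simulation truth") with one row per peak:
#'   `peak_id`, `is_differential`, `direction` (`"multiplied"`,
#'   `"divided"`, or `NA`), group-wise parameters `mu1, p1, phi1, mu2,
#'   p2, phi2`, and `p_clipped`.
#' @export
apply_effect <- function(base, scenario = c("mean", "prevalence",
                                            "dispersion", "all"),
                         log2fc, prop_differential = 0.2, seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(log2fc >= 0, prop_differential >= 0, prop_differential <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(base)
  k <- round(prop_differential * n)
  diff_idx <- sample.int(n, k)
  n_mult <- ceiling(k / 2)
  mult_idx <- diff_idx[seq_len(n_mult)]
  div_idx <- diff_idx[-seq_len(n_mult)]

  fac <- rep(1, n)
  fac[mult_idx] <- 2^log2fc
  fac[div_idx] <- 2^(-log2fc)

  mu2 <- base$mu; p2 <- base$p; phi2 <- base$phi
  if (scenario %in% c("mean", "all")) mu2 <- mu2 * fac
  if (scenario %in% c("prevalence", "all")) p2 <- p2 * fac
  if (scenario %in% c("dispersion", "all")) phi2 <- phi2 * fac
  p2c <- pmin(pmax(p2, 0.01), 0.99)

  direction <- rep(NA_character_, n)
  direction[mult_idx] <- "multiplied"
  direction[div_idx] <- "divided"
  data.frame(
    peak_id = sprintf("peak_%05d", seq_len(n)),
    is_differential = seq_len(n) %in% diff_idx,
    direction = direction,
    mu1 = base$mu, p1 = base$p, phi1 = base$phi,
    mu2 = mu2, p2 = p2c, phi2 = phi2,
    p_clipped = p2c != p2,
    stringsAsFactors = FALSE
  )
}

.sim_group <- function(mu, p, phi, n_cells) {
  n <- length(mu)
  m <- matrix(rzinb(n * n_cells,
                    mu = rep(mu, n_cells),
                    phi = rep(phi, n_cells),
                    p = rep(p, n_cells)),
              nrow = n, ncol = n_cells)
  m
}

#' Generate a labeled two-group count matrix from simulation truth
#'
#' Draws per-peak, per-cell ZINB counts under the group-wise parameters
#' of a truth table: an excess-zero indicator `Bernoulli(p)`, otherwise
#' `NB(mu, phi)`.
#'
#' @param truth data.frame from [apply_effect()].
#' @param n_cells_per_group cells per group.
#' @param seed optional integer seed.
#' @return list with `counts` (sparse peak-by-cell [Matrix::Matrix]),
#'   `group` (two-level factor, `"group1"`/`"group2"`), `peaks`
#'   (data.frame with synthetic 0-based half-open BED coordinates), and
#'   `truth`.
#' @export
generate_counts <- function(truth, n_cells_per_group = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g1 <- .sim_group(truth$mu1, truth$p1, truth$phi1, n_cells_per_group)
  g2 <- .sim_group(truth$mu2, truth$p2, truth$phi2, n_cells_per_group)
  counts <- methods::as(Matrix::Matrix(cbind(g1, g2), sparse = TRUE),
                        "CsparseMatrix")
  n <- nrow(counts)
  width <- 500L
  peaks <- data.frame(
    chrom = "chr1",
    start = (seq_len(n) - 1L) * 2L * width,
    end = (seq_len(n) - 1L) * 2L * width + width,
    peak_id = truth$peak_id,
    stringsAsFactors = FALSE
  )
  group <- factor(rep(c("group1", "group2"), each = n_cells_per_group))
  barcodes <- sprintf("cell_%04d", seq_len(2L * n_cells_per_group))
  dimnames(counts) <- list(truth$peak_id, barcodes)
  structure(list(counts = counts, group = group, peaks = peaks,
                 barcodes = barcodes, truth = truth),
            class = "peak_matrix")
}

#' Simulate a two-group differential accessibility benchmark data set
#'
#' One-call wrapper around [draw_baseline()], [apply_effect()] and
#' [generate_counts()]. The defaults reproduce the benchmark design: 4000
#' peaks, 100 cells per group, 20% differential peaks, effect sizes on a
#' log2 grid, baseline `(mu, p)` pairs from the synthetic sparse-peak
#' emulator, and dispersions from `phi_prior(0.03, 0.57)`.
#'
#' @inheritParams draw_baseline
#' @inheritParams apply_effect
#' @inheritParams generate_counts
#' @param n_cells_per_group cells per group (default 100).
#' @return a `peak_matrix` list (see [generate_counts()]).
#' @examples
#' sim <- simulate_accessibility(n_peaks = 100, n_cells_per_group = 40,
#'                               scenario = "all", log2fc = 1.5, seed = 7)
#' Matrix::nnzero(sim$counts) / length(sim$counts)  # sparsity
#' @export
simulate_accessibility <- function(n_peaks = 4000, n_cells_per_group = 100,
                                   prop_differential = 0.2,
                                   scenario = c("mean", "prevalence",
                                                "dispersion", "all"),
                                   log2fc = 1, baseline = "synthetic",
                                   prior = phi_prior(0.03, 0.57),
                                   seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  base <- draw_baseline(n_peaks, baseline = baseline, prior = prior)
  truth <- apply_effect(base, scenario = scenario, log2fc = log2fc,
                        prop_differential = prop_differential)
  generate_counts(truth, n_cells_per_group = n_cells_per_group)
}
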