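# zinbDA

Differential chromatin accessibility (DA) analysis for single-cell
ATAC-seq, testing *distribution* differences rather than mean shifts
alone.

scATAC-seq peak-by-cell matrices are small counts with abundant zeros,
and two groups of cells can differ in any of three distributional
properties of a peak: the prevalence of excess zeros *p*, the negative
binomial mean *μ*, and the dispersion *φ* (Gamma–Poisson
parameterization, Var = μ + μ²φ). zinbDA models each peak as
zero-inflated negative binomial,

    f(y) = p·I(y = 0) + (1 − p)·NB(y | μ, φ),

and tests, per peak, the composite null H₀: (p, μ, φ) equal across
groups with a likelihood-ratio statistic λ_LR = −2 log L(H₀)/L(Hₐ)
referred to χ²₃. The parameters entering both likelihoods come from a
three-stage estimation pipeline:

1. **EM** — per-peak maximum likelihood with a latent excess-zero
   indicator;
2. **empirical-Bayes dispersion shrinkage** — a log-normal prior on φ
   estimated genome-wide (location = median of log φ̂, scale = variance
   of log φ̂ adjusted for estimation noise), with the posterior mode
   found by Newton–Raphson in log φ;
3. **refinement** — bounded coordinate-wise re-maximization of μ and p
   at the shrunken dispersion.

Plain ZINB LRT variants on any parameter subset (`zinb_lrt()`), a
semi-parametric two-group benchmark simulator with fold-change
injection (`simulate_accessibility()`), benchmark metrics (TPR, FDP,
observed FDR curves, true discovery rate at top-ranked calls), 10x-style
MatrixMarket/BED/TSV I/O, and a CLI are included. Intended users:
computational biologists running cell-type or condition contrasts on
peak-by-cell matrices, and methodologists benchmarking DA tests.

## Worked example

```r
library(zinbDA)

# a benchmark data set: 300 peaks, 100 cells per group, 20% differential
# peaks with a 4-fold (log2FC = 2) mean difference
sim <- simulate_accessibility(n_peaks = 300, n_cells_per_group = 100,
                              scenario = "mean", log2fc = 2, seed = 1)
res <- zinbda(sim$counts, sim$group)
head(res[order(res$pvalue), ], 3)
#>       peak_id lambda_lr df       pvalue          fdr log2fc_mu    log2fc_p  log2fc_phi status
#> 18 peak_00018  98.19400  3 3.799993e-21 1.132398e-18 -2.130546 -0.02270533 -0.22965710 tested
#> 22 peak_00022  68.07425  3 1.102911e-14 1.277384e-12 -2.100774  0.06875475 -0.01543282 tested
#> 41 peak_00041  67.76269  3 1.285957e-14 1.277384e-12 -2.159764  0.18396591 -0.52164898 tested

calls <- call_differential(res)          # FDR < 0.05 and |log2FC(mu)| > 0.5
cm <- confusion_metrics(calls, sim$truth$is_differential)
unlist(cm[c("tpr", "fdp")])
#>        tpr        fdp
#> 0.90000000 0.01818182
```

`peak_00018` sits in the "divided" half of the differential peaks (its
group-2 mean is 4-fold lower, log2fc_mu ≈ −2.1); at FDR < 0.05 with the
fold-change filter the test recovers 90% of the planted differential
peaks with under 2% false discoveries. On real data, read a 10x-style triplet
with `read_peak_counts("counts.mtx", "peaks.bed", "barcodes.tsv")`
(group labels in the barcodes file's second column) and pass the result
straight to `zinbda()`.

The same workflow is scriptable:

```sh
Rscript inst/cli/zinbda.R simulate --scenario mean --log2fc 2 --n-peaks 300 --seed 1 --out simdir
Rscript inst/cli/zinbda.R test --mtx simdir/counts.mtx --peaks simdir/peaks.bed \
        --barcodes simdir/barcodes.tsv --out results.tsv
Rscript inst/cli/zinbda.R evaluate --results results.tsv --truth simdir/truth.tsv --out report.tsv
```

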