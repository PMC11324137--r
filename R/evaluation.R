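# Benchmark metrics over simulated truth: TPR, FDP, observed FDR curves,
# and true discovery rate among top-ranked calls.

#' Confusion metrics against simulation truth
#'
#' True positive rate `TPR = TP / (TP + FN)` and false discovery
#' proportion `FDP = FP / max(1, FP + TP)` (the guard makes the FDP zero
#' when nothing is called).
#'
#' @param calls logical vector of differential calls, one per peak.
#' @param truth logical vector of true differential status, same length
#'   and peak order (or a truth data.frame with column
#'   `is_differential`).
#' @return list with `tpr`, `fdp`, and the counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_metrics <- function(calls, truth) {
  if (is.data.frame(truth)) truth <- truth$is_differential
  if (length(calls) != length(truth))
    stop("'calls' and 'truth' must align on the same peaks")
  calls <- as.logical(calls); truth <- as.logical(truth)
  tp <- sum(calls & truth)
  fp <- sum(calls & !truth)
  fn <- sum(!calls & truth)
  tn <- sum(!calls & !truth)
  list(
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fdp = fp / max(1, fp + tp),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' Observed FDR across nominal BH levels
#'
#' For each nominal FDR level, peaks are called by BH at that level in
#' every replicate and the false discovery proportion is averaged over
#' replicates (the observed FDR is the expectation of the FDP).
#'
#' @param pvalues list of per-replicate p-value vectors (missing entries
#'   allowed; they are never called).
#' @param truths list of matching per-replicate truth vectors (logical,
#'   or data.frames with `is_differential`).
#' @param nominal numeric grid of nominal FDR levels.
#' @return data.frame with columns `nominal`, `observed_fdr`,
#'   `n_replicates`.
#' @export
fdr_curve <- function(pvalues, truths,
                      nominal = c(0.01, 0.02, 0.05, 0.1, 0.15, 0.2)) {
  if (!is.list(pvalues)) pvalues <- list(pvalues)
  if (!is.list(truths) || is.data.frame(truths)) truths <- list(truths)
  if (length(pvalues) != length(truths) || length(pvalues) < 1)
    stop("need matching, non-empty lists of p-values and truths")
  fdrs <- lapply(pvalues, bh_adjust)
  obs <- vapply(nominal, function(a) {
    mean(mapply(function(f, tr) {
      if (is.data.frame(tr)) tr <- tr$is_differential
      calls <- !is.na(f) & f < a
      confusion_metrics(calls, tr)$fdp
    }, fdrs, truths))
  }, numeric(1))
  data.frame(nominal = nominal, observed_fdr = obs,
             n_replicates = length(pvalues))
}

#' True discovery rate among top-ranked differential calls
#'
#' Peaks are first called differential (BH FDR below `fdr_cut` and
#' absolute log2 mean fold change above `lfc_cut`), then ranked by
#' ascending p-value with ties broken by descending likelihood-ratio
#' statistic. `TDR(q)` is the proportion of truly differential peaks
#' among the top `q%` of the called peaks; at `q = 100` it is the
#' proportion of true peaks in the whole call set.
#'
#' @param results a `da_results` data.frame (see [zinbda()]).
#' @param truth logical truth vector or truth data.frame aligned with
#'   `results`.
#' @param top percentages of top-ranked calls to evaluate.
#' @param fdr_cut,lfc_cut calling thresholds (see [call_differential()]).
#' @return data.frame with columns `top_pct`, `tdr`, `n_top`. All `tdr`
#'   are `NA` when no peak is called.
#' @export
tdr_top <- function(results, truth, top = c(20, 40, 60, 80, 100),
                    fdr_cut = 0.05, lfc_cut = 0.5) {
  if (is.data.frame(truth)) truth <- truth$is_differential
  if (nrow(results) != length(truth))
    stop("'results' and 'truth' must align on the same peaks")
  calls <- call_differential(results, fdr_cut = fdr_cut, lfc_cut = lfc_cut)
  idx <- which(calls)
  if (length(idx) == 0L)
    return(data.frame(top_pct = top, tdr = NA_real_, n_top = 0L))
  ord <- idx[order(results$pvalue[idx], -results$lambda_lr[idx])]
  truth <- as.logical(truth)
  out <- vapply(top, function(q) {
    k <- max(1L, ceiling(q / 100 * length(ord)))
    mean(truth[ord[seq_len(k)]])
  }, numeric(1))
  n_top <- vapply(top, function(q)
    as.integer(max(1, ceiling(q / 100 * length(ord)))), integer(1))
  data.frame(top_pct = top, tdr = out, n_top = n_top)
}
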