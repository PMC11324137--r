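# Reading and writing count matrices (MatrixMarket + BED + barcodes TSV,
# dense CSV fallback) and results tables.

#' Read a 10x-style peak-by-cell count matrix
#'
#' Reads a MatrixMarket coordinate integer matrix together with a BED
#' file of peak coordinates (0-based half-open; rows of the matrix) and a
#' barcodes TSV (one barcode per line, optional second column with the
#' cell group label; columns of the matrix).
#'
#' @param path_mtx MatrixMarket (.mtx) file.
#' @param path_peaks_bed BED3+ file; a 4th column, when present, is used
#'   as the peak identifier.
#' @param path_barcodes_tsv barcodes TSV.
#' @return an object of class `"peak_matrix"`: a list with `counts`
#'   (sparse integer [Matrix::Matrix], peaks in rows), `peaks`
#'   (data.frame `chrom`, `start`, `end`, `peak_id`), `barcodes`, and
#'   `group` (two-level factor, or `NULL` when the barcodes file has no
#'   group column).
#' @export
read_peak_counts <- function(path_mtx, path_peaks_bed, path_barcodes_tsv) {
  for (f in c(path_mtx, path_peaks_bed, path_barcodes_tsv))
    if (!file.exists(f)) stop("file not found: ", f)
  counts <- methods::as(Matrix::readMM(path_mtx), "CsparseMatrix")
  bad <- which(counts@x < 0 | counts@x != round(counts@x))
  if (length(bad)) {
    i <- counts@i[bad[1]] + 1L
    j <- findInterval(bad[1] - 1L, counts@p, left.open = TRUE)
    stop("non-integer or negative count at matrix entry (row ", i,
         ", column ", j, "): ", counts@x[bad[1]])
  }
  peaks <- utils::read.table(path_peaks_bed, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  if (ncol(peaks) < 3) stop("malformed BED: need at least 3 columns")
  if (!is.numeric(peaks[[2]]) || !is.numeric(peaks[[3]]) ||
      any(peaks[[2]] < 0) || any(peaks[[3]] <= peaks[[2]]))
    stop("malformed BED: start/end must be 0-based half-open integers ",
         "with end > start")
  peak_id <- if (ncol(peaks) >= 4) as.character(peaks[[4]]) else
    sprintf("%s:%d-%d", peaks[[1]], peaks[[2]], peaks[[3]])
  peaks <- data.frame(chrom = as.character(peaks[[1]]),
                      start = as.integer(peaks[[2]]),
                      end = as.integer(peaks[[3]]),
                      peak_id = peak_id, stringsAsFactors = FALSE)
  bc <- utils::read.table(path_barcodes_tsv, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(peaks) != nrow(counts))
    stop("dimension mismatch: ", nrow(peaks), " peaks in BED vs ",
         nrow(counts), " matrix rows")
  if (nrow(bc) != ncol(counts))
    stop("dimension mismatch: ", nrow(bc), " barcodes vs ",
         ncol(counts), " matrix columns")
  group <- if (ncol(bc) >= 2) factor(bc[[2]]) else NULL
  dimnames(counts) <- list(peaks$peak_id, bc[[1]])
  structure(list(counts = counts, peaks = peaks, barcodes = bc[[1]],
                 group = group),
            class = "peak_matrix")
}

#' Read a dense CSV count matrix
#'
#' Dense fallback for small examples: rows are peaks (row names = peak
#' identifiers), columns are cells.
#'
#' @param path CSV file with a header of cell barcodes and row names in
#'   the first column.
#' @return a `peak_matrix` (with placeholder coordinates and no group
#'   labels).
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    stop("count matrix must contain non-negative integers")
  counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  n <- nrow(counts)
  peaks <- data.frame(chrom = NA_character_, start = NA_integer_,
                      end = NA_integer_,
                      peak_id = rownames(m), stringsAsFactors = FALSE)
  structure(list(counts = counts, peaks = peaks, barcodes = colnames(m),
                 group = NULL),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat("peak_matrix:", nrow(x$counts), "peaks x", ncol(x$counts), "cells;",
      sprintf("%.2f%% non-zero", 100 * Matrix::nnzero(x$counts) /
                length(x$counts)), "\n")
  if (!is.null(x$group))
    cat("groups:", paste(levels(x$group), table(x$group), collapse = ", "),
        "\n")
  invisible(x)
}

#' Write a peak matrix (and simulation truth) to disk
#'
#' Writes `counts.mtx` (MatrixMarket), `peaks.bed`, `barcodes.tsv`
#' (barcode + group label when present), and `truth.tsv` when the object
#' carries simulation truth.
#'
#' @param x a `peak_matrix` (e.g. from [simulate_accessibility()]).
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_peak_counts <- function(x, dir) {
  stopifnot(inherits(x, "peak_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f_mtx <- file.path(dir, "counts.mtx")
  f_bed <- file.path(dir, "peaks.bed")
  f_bc <- file.path(dir, "barcodes.tsv")
  Matrix::writeMM(x$counts, f_mtx)
  utils::write.table(x$peaks[, c("chrom", "start", "end", "peak_id")],
                     f_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bc <- if (is.null(x$group)) data.frame(x$barcodes) else
    data.frame(x$barcodes, as.character(x$group))
  utils::write.table(bc, f_bc, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files <- c(f_mtx, f_bed, f_bc)
  if (!is.null(x$truth)) {
    f_truth <- file.path(dir, "truth.tsv")
    utils::write.table(x$truth, f_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f_truth)
  }
  invisible(files)
}

#' Write a differential accessibility results table
#'
#' Tab-separated table with one row per peak and a stable column order:
#' `peak_id, chrom, start, end, lambda_lr, df, pvalue, fdr, log2fc_mu,
#' log2fc_p, log2fc_phi, status`. Coordinates (0-based half-open) are
#' filled from `peaks` when given, `NA` otherwise. Missing values are
#' written as `NA`.
#'
#' @param results a `da_results` data.frame.
#' @param path output file.
#' @param peaks optional peak coordinate data.frame (`chrom`, `start`,
#'   `end`, `peak_id`) aligned with the results.
#' @return invisibly, `path`.
#' @export
write_da_results <- function(results, path, peaks = NULL) {
  n <- nrow(results)
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = rep(NA_character_, n),
                        start = rep(NA_integer_, n),
                        end = rep(NA_integer_, n))
  } else {
    if (nrow(peaks) != n) stop("'peaks' must align with 'results'")
  }
  tab <- data.frame(
    peak_id = results$peak_id,
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    results[, c("lambda_lr", "df", "pvalue", "fdr",
                "log2fc_mu", "log2fc_p", "log2fc_phi", "status")],
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results table written by [write_da_results()]
#'
#' @param path TSV file.
#' @return data.frame with the full column set.
#' @export
read_da_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
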