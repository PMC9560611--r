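## Inferred-CNV summary scoring.
##
## The windowed scorer is a deliberately simplified, expression-only CNV
## score: centered log2 ratios against a normal-cell reference, smoothed by
## a genomic moving average per chromosome. It is format-compatible with
## externally produced CNV expression-score matrices (e.g. CopyKAT output
## read through readExpressionMatrix), which can be substituted directly;
## it performs no segmentation and no ploidy calling.

#' Convert raw counts to TPM
#'
#' Per cell: `TPM(g) = 1e6 * (count(g)/length(g)) / sum_g'(count(g')/
#' length(g'))`. Cells whose counts are all zero yield an all-zero column
#' with a warning.
#'
#' @param counts a `SummarizedExperiment` of raw counts
#'   (see [ExpressionMatrix()]).
#' @param gene_lengths named numeric vector, gene symbol -> length in bases
#'   (all genes of `counts` must be present, with positive length).
#' @return a `SummarizedExperiment` of TPM with the same dimensions.
#' @export
countsToTpm <- function(counts, gene_lengths) {
  rd <- SummarizedExperiment::rowData(counts)
  m <- SummarizedExperiment::assay(counts)
  len <- gene_lengths[rd$gene_symbol]
  missing <- rd$gene_symbol[is.na(len)]
  if (length(missing))
    stop("missing gene length for: ", paste(utils::head(missing, 5),
                                            collapse = ", "))
  if (any(len <= 0)) stop("gene lengths must be positive")
  rate <- m / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with all-zero counts get all-zero TPM",
            call. = FALSE)
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  ExpressionMatrix(tpm,
    genes = data.frame(gene_symbol = rd$gene_symbol, chrom = rd$chrom,
                       start = rd$start),
    cells = colnames(m), assay_name = "tpm")
}

## centered moving average with truncation at block ends: row i averages
## rows max(1, i-hb) .. min(n, i+ha), hb = floor((w-1)/2), ha = w-1-hb
.window_mean <- function(m, window) {
  n <- nrow(m)
  if (window <= 1 || n == 1) return(m)
  hb <- (window - 1L) %/% 2L
  ha <- window - 1L - hb
  cs <- rbind(0, apply(m, 2, cumsum))
  lo <- pmax(seq_len(n) - hb, 1L)
  hi <- pmin(seq_len(n) + ha, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' Simplified windowed CNV expression scores
#'
#' For each gene and cell, computes `log2(TPM + 1)` centered by subtracting
#' the per-gene mean over the reference normal cells, then smooths with a
#' centered moving average over a genomic window of `window` genes within
#' each chromosome (truncated, not wrapped, at chromosome ends). With
#' `window = 1` the centered log ratios are returned unchanged. A
#' chromosome with fewer than 2 genes is left unsmoothed with a warning.
#'
#' @param tpm a `SummarizedExperiment` of TPM, rows in genomic order.
#' @param normal_cells character vector of reference cell ids (non-empty,
#'   subset of the matrix cells).
#' @param window window size in genes (default 100).
#' @return a `SummarizedExperiment` of CNV expression scores, same
#'   dimensions and order as the input.
#' @export
windowedCnvScores <- function(tpm, normal_cells, window = 100) {
  if (!length(normal_cells)) stop("normal_cells must be non-empty")
  m <- SummarizedExperiment::assay(tpm)
  if (!all(normal_cells %in% colnames(m)))
    stop("normal_cells must be a subset of the matrix cells")
  rd <- SummarizedExperiment::rowData(tpm)
  ord <- order(rd$chrom, rd$start)
  if (!identical(ord, seq_len(nrow(m))))
    stop("rows must be in genomic order (chrom, start); ",
         "use readExpressionMatrix/ExpressionMatrix")
  l <- log2(m + 1)
  r <- l - rowMeans(l[, normal_cells, drop = FALSE])
  out <- r
  for (ch in unique(rd$chrom)) {
    idx <- which(rd$chrom == ch)
    if (length(idx) < 2) {
      if (window > 1)
        warning("chromosome ", ch, " has < 2 genes; scores unsmoothed",
                call. = FALSE)
      next
    }
    out[idx, ] <- .window_mean(r[idx, , drop = FALSE], window)
  }
  ExpressionMatrix(out,
    genes = data.frame(gene_symbol = rd$gene_symbol, chrom = rd$chrom,
                       start = rd$start),
    cells = colnames(m), assay_name = "cnv_score")
}

#' Per-cell mean absolute CNV expression score
#'
#' The per-cell mean over all scored genes of the absolute CNV expression
#' score — the summary used to compare cells against the normal baseline.
#' Higher values indicate predicted structural alterations.
#'
#' @param scores a `SummarizedExperiment` of CNV expression scores.
#' @return data.frame with columns `cell_id`, `mean_abs_score`.
#' @export
meanAbsCnv <- function(scores) {
  m <- SummarizedExperiment::assay(scores)
  data.frame(cell_id = colnames(m),
             mean_abs_score = unname(colMeans(abs(m))),
             stringsAsFactors = FALSE)
}
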