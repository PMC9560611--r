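#' Read a gene-by-cell expression matrix
#'
#' Reads a TSV whose first three columns are gene metadata (`gene_symbol`,
#' `chrom`, `start`) followed by one numeric column per cell, into a
#' `SummarizedExperiment`. Rows are re-sorted into genomic order (chromosome,
#' then start) — the order required by the windowed CNV scorer. The matrix
#' may hold raw counts, TPM, or CNV expression scores depending on pipeline
#' stage.
#'
#' @param path path to the TSV (header required).
#' @param assay_name name for the single assay (default "values").
#' @return a `SummarizedExperiment` with rowData columns `gene_symbol`,
#'   `chrom`, `start`.
#' @export
readExpressionMatrix <- function(path, assay_name = "values") {
  d <- data.table::fread(path, header = TRUE, sep = "\t",
                         showProgress = FALSE)
  meta_cols <- c("gene_symbol", "chrom", "start")
  if (!all(meta_cols %in% names(d)[1:3]))
    stop("expression matrix must start with columns gene_symbol, chrom, start")
  cells <- setdiff(names(d), meta_cols)
  for (cc in cells) {
    col <- d[[cc]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("non-numeric value at gene '%s', cell column '%s'",
                   d$gene_symbol[bad], cc))
    }
  }
  key <- paste(d$gene_symbol, d$chrom, d$start)
  if (anyDuplicated(key))
    stop("duplicate gene entries (same symbol, chrom, start): ",
         key[duplicated(key)][1])
  ExpressionMatrix(
    values = as.matrix(d[, cells, with = FALSE]),
    genes = data.frame(gene_symbol = d$gene_symbol, chrom = d$chrom,
                       start = as.integer(d$start)),
    cells = cells, assay_name = assay_name)
}

#' Assemble an expression SummarizedExperiment in genomic order
#'
#' The standard container for count / TPM / CNV-score matrices throughout
#' the package. Rows are sorted by (chrom, start).
#'
#' @param values numeric genes-by-cells matrix.
#' @param genes data.frame with columns `gene_symbol`, `chrom`, `start`
#'   (one row per matrix row).
#' @param cells cell identifiers (one per matrix column).
#' @param assay_name assay name.
#' @return a `SummarizedExperiment`.
#' @export
ExpressionMatrix <- function(values, genes, cells = colnames(values),
                             assay_name = "values") {
  stopifnot(nrow(values) == nrow(genes), ncol(values) == length(cells))
  ord <- order(genes$chrom, genes$start)
  values <- values[ord, , drop = FALSE]
  genes <- genes[ord, , drop = FALSE]
  dimnames(values) <- list(genes$gene_symbol, cells)
  assays <- list(values)
  names(assays) <- assay_name
  SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(gene_symbol = genes$gene_symbol,
                                   chrom = genes$chrom,
                                   start = as.integer(genes$start)))
}

#' Write an expression SummarizedExperiment as a TSV
#'
#' Inverse of [readExpressionMatrix()]; numeric values are written with full
#' double precision so a write/read round trip is exact for integers and
#' accurate to at least 12 significant digits for reals.
#'
#' @param se a `SummarizedExperiment` with rowData `gene_symbol`, `chrom`,
#'   `start`.
#' @param path output path.
#' @param assay which assay to write (default first).
#' @export
writeExpressionMatrix <- function(se, path, assay = 1L) {
  rd <- SummarizedExperiment::rowData(se)
  m <- SummarizedExperiment::assay(se, assay)
  out <- data.table::data.table(
    gene_symbol = rd$gene_symbol, chrom = rd$chrom, start = rd$start)
  out <- cbind(out, data.table::as.data.table(m))
  data.table::fwrite(out, path, sep = "\t")
}

## genomic-order check used by the CNV scorer
.is_genomic_order <- function(se) {
  rd <- SummarizedExperiment::rowData(se)
  !is.unsorted(order(rd$chrom, rd$start)) &&
    identical(order(rd$chrom, rd$start), seq_len(nrow(se)))
}
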