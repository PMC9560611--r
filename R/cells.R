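## Cell-level QC, profile assembly, baseline thresholds and 2-D
## classification against the normal-cell baseline.

.REGION_LABELS <- c("HIGH_CNV_HIGH_DRIVER", "HIGH_CNV_ONLY",
                    "HIGH_DRIVER_ONLY", "NEITHER")

#' Median/MAD quality-control filter for cells
#'
#' Excludes low-quality cells: for each of library size, number of expressed
#' genes and total mRNA, values are log-transformed (`log1p`) and a cell is
#' excluded when any metric falls below `median - n_mads * MAD` (lower tail
#' only; MAD uses the normal-consistency constant 1.4826 by default).
#' Additionally, cells with fewer than `min_genes` expressed genes are
#' excluded. Every failed criterion is reported.
#'
#' @param metrics data.frame with columns `cell_id`, `library_size`,
#'   `n_genes`, `total_mrna`.
#' @param n_mads number of MADs below the median tolerated (default 4).
#' @param min_genes constant floor on expressed genes (default 1000).
#' @param mad_constant scale constant passed to [stats::mad()] (default
#'   1.4826; set 1 for the raw MAD).
#' @return list with `kept` (cell ids, input order) and `excluded`
#'   (data.frame with columns `cell_id`, `reason`; one row per failed
#'   criterion).
#' @export
qcFilter <- function(metrics, n_mads = 4, min_genes = 1000,
                     mad_constant = 1.4826) {
  stopifnot(nrow(metrics) >= 1)
  fails <- list()
  for (metric in c("library_size", "n_genes", "total_mrna")) {
    l <- log1p(metrics[[metric]])
    cut <- stats::median(l) - n_mads * stats::mad(l, constant = mad_constant)
    bad <- l < cut
    if (any(bad))
      fails[[metric]] <- data.frame(cell_id = metrics$cell_id[bad],
                                    reason = paste0(metric, "_mad"))
  }
  low <- metrics$n_genes < min_genes
  if (any(low))
    fails$min_genes <- data.frame(cell_id = metrics$cell_id[low],
                                  reason = "min_genes")
  excluded <- if (length(fails)) do.call(rbind, c(fails,
    make.row.names = FALSE)) else
    data.frame(cell_id = character(), reason = character())
  list(kept = setdiff(metrics$cell_id, excluded$cell_id),
       excluded = excluded)
}

#' Assemble per-cell profiles
#'
#' Joins driver calls, effect-class counts and CNV summaries into one
#' profile per cell. Cells must all carry variant data (effect counts);
#' a missing CNV summary is allowed (the cell is excluded from 2-D
#' classification downstream).
#'
#' @param cell_metadata data.frame with columns `cell_id`, `patient_id`,
#'   `group` ("tumor" or "normal"), `tissue_or_dataset`.
#' @param driver_calls data.frame from [matchDrivers()].
#' @param effect_counts data.frame from [countEffectClasses()] covering
#'   every metadata cell.
#' @param cnv_profiles optional data.frame from [meanAbsCnv()].
#' @return data.frame with columns `cell_id`, `patient_id`, `group`,
#'   `tissue_or_dataset`, `n_variants`, `n_drivers`, `n_splice`,
#'   `mean_abs_cnv` (NA where missing).
#' @export
buildCellProfiles <- function(cell_metadata, driver_calls, effect_counts,
                              cnv_profiles = NULL) {
  stopifnot(all(c("cell_id", "patient_id", "group", "tissue_or_dataset")
                %in% names(cell_metadata)))
  missing <- setdiff(cell_metadata$cell_id, effect_counts$cell_id)
  if (length(missing))
    stop("cells without variant data: ",
         paste(utils::head(missing, 10), collapse = ", "))
  if (!is.null(cnv_profiles)) {
    orphan <- setdiff(cnv_profiles$cell_id, cell_metadata$cell_id)
    if (length(orphan))
      stop("cells present in CNV but absent from variant inputs: ",
           paste(utils::head(orphan, 10), collapse = ", "))
  }
  idx <- match(cell_metadata$cell_id, effect_counts$cell_id)
  n_drivers <- table(factor(driver_calls$cell_id,
                            levels = cell_metadata$cell_id))
  cnv <- rep(NA_real_, nrow(cell_metadata))
  if (!is.null(cnv_profiles)) {
    ci <- match(cell_metadata$cell_id, cnv_profiles$cell_id)
    cnv <- cnv_profiles$mean_abs_score[ci]
  }
  data.frame(
    cell_id = cell_metadata$cell_id,
    patient_id = cell_metadata$patient_id,
    group = cell_metadata$group,
    tissue_or_dataset = cell_metadata$tissue_or_dataset,
    n_variants = effect_counts$n_total[idx],
    n_drivers = as.integer(n_drivers),
    n_splice = effect_counts$n_splice[idx],
    mean_abs_cnv = cnv,
    stringsAsFactors = FALSE)
}

#' Nearest-rank percentile
#'
#' The `ceiling(q/100 * n)`-th smallest value — deterministic and
#' integer-friendly for count data. (The product is rounded to 9 decimals
#' before the ceiling to keep exact rank boundaries stable under floating
#' point.)
#'
#' @param values non-empty numeric vector.
#' @param q percentile in (0, 100].
#' @return the nearest-rank percentile value.
#' @export
percentileNearestRank <- function(values, q) {
  if (!length(values)) stop("values must be non-empty")
  stopifnot(q > 0, q <= 100)
  n <- length(values)
  k <- ceiling(round(q / 100 * n, 9))
  k <- min(max(k, 1L), n)
  sort(values)[k]
}

#' Baseline thresholds from normal cells
#'
#' Nearest-rank percentile cutoffs computed over normal-group profiles:
#' the driver-count cutoff over all normals, the CNV cutoff over normals
#' with a CNV measurement present. The contributing n is recorded per
#' threshold.
#'
#' @param profiles data.frame from [buildCellProfiles()].
#' @param q percentile (default 99).
#' @return a [BaselineThresholds].
#' @export
thresholdsFromNormals <- function(profiles, q = 99) {
  normals <- profiles[profiles$group == "normal", , drop = FALSE]
  if (!nrow(normals)) stop("no normal cells to derive thresholds from")
  cnv <- normals$mean_abs_cnv[!is.na(normals$mean_abs_cnv)]
  new("BaselineThresholds",
      driver_p = percentileNearestRank(normals$n_drivers, q),
      cnv_p = if (length(cnv)) percentileNearestRank(cnv, q) else NA_real_,
      n_driver = nrow(normals), n_cnv = length(cnv), percentile = q)
}

#' Classify cells against baseline thresholds
#'
#' Two-dimensional classification of cells into the four baseline-exceedance
#' regions. Membership is strict: a cell is driver-high when
#' `n_drivers > driver cutoff` and CNV-high when `mean_abs_cnv > CNV
#' cutoff`; a cell exactly at a cutoff is not high. Cells without a CNV
#' measurement are omitted with a warning.
#'
#' @param profiles data.frame from [buildCellProfiles()].
#' @param thresholds a [BaselineThresholds].
#' @return data.frame with columns `cell_id`, `label` (one of
#'   HIGH_CNV_HIGH_DRIVER, HIGH_CNV_ONLY, HIGH_DRIVER_ONLY, NEITHER).
#' @export
classifyCells <- function(profiles, thresholds) {
  has_cnv <- !is.na(profiles$mean_abs_cnv)
  if (any(!has_cnv))
    warning(sum(!has_cnv), " cell(s) without CNV omitted from classification",
            call. = FALSE)
  p <- profiles[has_cnv, , drop = FALSE]
  driver_high <- p$n_drivers > driverThreshold(thresholds)
  cnv_high <- p$mean_abs_cnv > cnvThreshold(thresholds)
  label <- ifelse(cnv_high & driver_high, "HIGH_CNV_HIGH_DRIVER",
           ifelse(cnv_high, "HIGH_CNV_ONLY",
           ifelse(driver_high, "HIGH_DRIVER_ONLY", "NEITHER")))
  data.frame(cell_id = p$cell_id, label = label, stringsAsFactors = FALSE)
}
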