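## Nonparametric group comparisons used for tumor-vs-normal contrasts.

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) comparison of two samples,
#' with midrank tie handling. The p-value is exact (full enumeration) when
#' both samples have at most 8 observations and there are no ties;
#' otherwise it uses the normal approximation with tie-corrected variance
#' and continuity correction. Computation is delegated to
#' [stats::wilcox.test()], whose W statistic is the U statistic for `x`.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with elements `U` and `p`.
#' @export
mannWhitneyU <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Cliff's delta effect size
#'
#' `delta = (#(x_i > y_j) - #(x_i < y_j)) / (n_x * n_y)`, in `[-1, 1]`.
#' Computed through midranks (O((n+m) log(n+m)), exact for the pair-count
#' definition), so large samples are fine.
#'
#' @param x,y non-empty numeric vectors.
#' @return Cliff's delta.
#' @export
cliffsDelta <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # #(x>y) + #(x=y)/2
  (2 * u1 - nx * ny) / (nx * ny)  # numerator is the exact pair-count margin
}

#' Per-patient correlation between driver load and inferred CNV
#'
#' For each patient, Pearson correlation between per-cell driver counts and
#' mean absolute CNV scores on raw values, and Spearman correlation
#' computed as Pearson on midranks; two-sided p-values via the t-transform
#' with n-2 degrees of freedom ([stats::cor.test()]). Patients with fewer
#' than `min_n` cells carrying both measurements, or with zero variance in
#' either variable, are reported with missing statistics (the latter with a
#' warning).
#'
#' @param profiles data.frame from [buildCellProfiles()].
#' @param min_n minimum cells per patient (default 3).
#' @return data.frame with columns `patient_id`, `n`, `pearson_r`,
#'   `pearson_p`, `spearman_r`, `spearman_p`.
#' @export
correlationTable <- function(profiles, min_n = 3) {
  p <- profiles[!is.na(profiles$mean_abs_cnv), , drop = FALSE]
  patients <- unique(profiles$patient_id)
  rows <- lapply(patients, function(pt) {
    d <- p[p$patient_id == pt, , drop = FALSE]
    out <- data.frame(patient_id = pt, n = nrow(d), pearson_r = NA_real_,
                      pearson_p = NA_real_, spearman_r = NA_real_,
                      spearman_p = NA_real_)
    if (nrow(d) < min_n) return(out)
    x <- d$n_drivers; y <- d$mean_abs_cnv
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance for patient ", pt,
              "; correlations unavailable", call. = FALSE)
      return(out)
    }
    pe <- stats::cor.test(x, y, method = "pearson")
    sp <- stats::cor.test(rank(x), rank(y), method = "pearson")
    out$pearson_r <- unname(pe$estimate); out$pearson_p <- pe$p.value
    out$spearman_r <- unname(sp$estimate); out$spearman_p <- sp$p.value
    out
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
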