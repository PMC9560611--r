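## End-to-end workflow: qc -> annotate -> coverage -> cnv -> profiles ->
## thresholds -> classification -> statistics, over a cohort directory as
## produced by generateCohort() (or assembled by hand in the same layout).

#' Combine per-cell VariantSets
#'
#' Concatenates VariantSets, re-keying variant ids to stay unique.
#'
#' @param sets list of [VariantSet] objects.
#' @return a single [VariantSet].
#' @export
combineVariantSets <- function(sets) {
  offset <- 0L
  vs <- list(); as_ <- list()
  for (s in sets) {
    v <- variantTable(s); a <- annotationTable(s)
    v$variant_id <- v$variant_id + offset
    if (nrow(a)) a$variant_id <- a$variant_id + offset
    offset <- offset + (if (nrow(v)) max(variantTable(s)$variant_id) else 0L)
    vs[[length(vs) + 1L]] <- v
    if (nrow(a)) as_[[length(as_) + 1L]] <- a
  }
  VariantSet(do.call(rbind, vs),
             if (length(as_)) do.call(rbind, as_) else NULL)
}

.stage_msg <- function(stage, ..., quiet = FALSE) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full cancer-cell-identification pipeline
#'
#' Executes QC, variant filtering and driver annotation, coverage-based
#' status calling, CNV scoring, profile assembly, normal-baseline
#' thresholding, 2-D classification and tumor-vs-normal statistics over a
#' cohort directory, writing TSV/JSON outputs and a run manifest.
#'
#' Expected cohort layout (as written by [generateCohort()]):
#' `counts.tsv`, `metadata.tsv` (cell_id, patient_id, group,
#' tissue_or_dataset, optional total_mrna), `catalog.tsv`,
#' `common_sites.vcf`, `gene_model.gtf`, `gene_lengths.tsv`,
#' `vcf/<cell>.vcf`, `depth/<cell>.tsv`.
#'
#' @param cohort_dir input cohort directory.
#' @param out_dir output directory (created).
#' @param min_qual variant quality floor (default 30).
#' @param min_depth depth floor for absence calling (default 5).
#' @param top_k status-matrix alteration count (default 25).
#' @param window CNV smoothing window in genes (default 100).
#' @param percentile baseline percentile (default 99).
#' @param n_mads QC MAD multiplier (default 4).
#' @param min_genes QC expressed-genes floor (default 1000; lower it for
#'   reduced synthetic gene panels).
#' @param skip_cnv if TRUE, CNV scoring and 2-D classification are skipped;
#'   driver profiles are still produced.
#' @param quiet suppress stage log messages.
#' @return invisibly, a list with elements `profiles`, `thresholds`,
#'   `classification`, `status`, `stats`, `correlations`, `qc`.
#' @export
runPipeline <- function(cohort_dir, out_dir,
                        min_qual = 30, min_depth = 5, top_k = 25,
                        window = 100, percentile = 99, n_mads = 4,
                        min_genes = 1000, skip_cnv = FALSE, quiet = FALSE) {
  need <- c("counts.tsv", "metadata.tsv", "catalog.tsv", "common_sites.vcf",
            "gene_model.gtf", "gene_lengths.tsv")
  for (f in need)
    if (!file.exists(file.path(cohort_dir, f)))
      stop("input stage: missing input file ", file.path(cohort_dir, f))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  meta <- as.data.frame(data.table::fread(
    file.path(cohort_dir, "metadata.tsv"), showProgress = FALSE))
  counts <- readExpressionMatrix(file.path(cohort_dir, "counts.tsv"),
                                 assay_name = "counts")
  cm <- SummarizedExperiment::assay(counts)

  ## ---- qc ----
  metrics <- data.frame(
    cell_id = colnames(cm),
    library_size = colSums(cm),
    n_genes = colSums(cm > 0),
    total_mrna = if ("total_mrna" %in% names(meta))
      meta$total_mrna[match(colnames(cm), meta$cell_id)] else colSums(cm))
  qc <- qcFilter(metrics, n_mads = n_mads, min_genes = min_genes)
  kept <- qc$kept
  .stage_msg("qc", length(kept), " of ", nrow(metrics), " cells kept",
             quiet = quiet)
  data.table::fwrite(qc$excluded, file.path(out_dir, "qc_excluded.tsv"),
                     sep = "\t")
  meta <- meta[meta$cell_id %in% kept, , drop = FALSE]

  ## ---- annotate ----
  catalog <- tryCatch(
    readDriverCatalog(file.path(cohort_dir, "catalog.tsv")),
    error = function(e) stop("annotate stage: ", conditionMessage(e)))
  common <- readCommonSites(file.path(cohort_dir, "common_sites.vcf"))
  sets <- lapply(kept, function(cell) {
    f <- file.path(cohort_dir, "vcf", paste0(cell, ".vcf"))
    if (!file.exists(f)) stop("annotate stage: missing VCF for cell ", cell)
    readAnnotatedVcf(f, cell)
  })
  all_variants <- combineVariantSets(sets)
  filtered <- removeCommonSites(filterQuality(all_variants, min_qual),
                                common)
  effect_counts <- countEffectClasses(filtered, cells = kept)
  driver_calls <- matchDrivers(filtered, catalog)
  .stage_msg("annotate", nVariants(filtered), " variants after filters; ",
             nrow(driver_calls), " driver calls", quiet = quiet)
  data.table::fwrite(driver_calls, file.path(out_dir, "driver_calls.tsv"),
                     sep = "\t")

  ## ---- coverage ----
  cds <- readCdsModel(file.path(cohort_dir, "gene_model.gtf"))
  depths <- lapply(kept, function(cell) {
    f <- file.path(cohort_dir, "depth", paste0(cell, ".tsv"))
    if (file.exists(f)) readDepthTrack(f, cell) else DepthTrack(cell)
  })
  names(depths) <- kept
  status <- buildStatusMatrix(kept, driver_calls, cds, depths,
                              top_k = top_k, min_depth = min_depth)
  .stage_msg("coverage", nrow(statusGrid(status)),
             " alterations in status matrix", quiet = quiet)
  writeStatusMatrix(status, file.path(out_dir, "status_matrix.tsv"))

  ## ---- cnv ----
  cnv_profiles <- NULL
  if (!skip_cnv) {
    gl <- data.table::fread(file.path(cohort_dir, "gene_lengths.tsv"),
                            showProgress = FALSE)
    lengths <- stats::setNames(gl$length, gl$gene_symbol)
    tpm <- countsToTpm(counts[, kept], lengths)
    normals <- meta$cell_id[meta$group == "normal"]
    scores <- windowedCnvScores(tpm, normal_cells = normals,
                                window = window)
    writeExpressionMatrix(scores, file.path(out_dir, "cnv_scores.tsv"))
    cnv_profiles <- meanAbsCnv(scores)
    data.table::fwrite(cnv_profiles,
                       file.path(out_dir, "cnv_profiles.tsv"), sep = "\t")
    .stage_msg("cnv", "scored ", nrow(cnv_profiles), " cells",
               quiet = quiet)
  }

  ## ---- profiles, thresholds, classification ----
  profiles <- buildCellProfiles(meta, driver_calls, effect_counts,
                                cnv_profiles)
  data.table::fwrite(profiles, file.path(out_dir, "profiles.tsv"),
                     sep = "\t")
  thresholds <- thresholdsFromNormals(profiles, q = percentile)
  jsonlite::write_json(list(
    percentile = thresholds@percentile,
    driver_threshold = thresholds@driver_p,
    cnv_threshold = thresholds@cnv_p,
    n_normal_driver = thresholds@n_driver,
    n_normal_cnv = thresholds@n_cnv),
    file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  classification <- NULL
  if (!skip_cnv) {
    classification <- classifyCells(profiles, thresholds)
    data.table::fwrite(classification,
                       file.path(out_dir, "classification.tsv"), sep = "\t")
  }
  .stage_msg("classify",
             if (is.null(classification)) "skipped (no CNV)" else
               paste(sum(classification$label != "NEITHER"),
                     "cells exceed baseline"), quiet = quiet)

  ## ---- statistics ----
  tum <- profiles$n_drivers[profiles$group == "tumor"]
  nor <- profiles$n_drivers[profiles$group == "normal"]
  stats_out <- list()
  if (length(tum) && length(nor)) {
    mw <- mannWhitneyU(tum, nor)
    mw_splice <- mannWhitneyU(profiles$n_splice[profiles$group == "tumor"],
                              profiles$n_splice[profiles$group == "normal"])
    stats_out <- list(
      driver_mw_U = mw$U, driver_mw_p = mw$p,
      driver_cliffs_delta = cliffsDelta(tum, nor),
      splice_mw_p = mw_splice$p,
      splice_cliffs_delta = cliffsDelta(
        profiles$n_splice[profiles$group == "tumor"],
        profiles$n_splice[profiles$group == "normal"]))
    if (!is.null(cnv_profiles)) {
      cnv_t <- profiles$mean_abs_cnv[profiles$group == "tumor"]
      cnv_n <- profiles$mean_abs_cnv[profiles$group == "normal"]
      mw_cnv <- mannWhitneyU(cnv_t[!is.na(cnv_t)], cnv_n[!is.na(cnv_n)])
      stats_out$cnv_mw_p <- mw_cnv$p
      stats_out$cnv_cliffs_delta <- cliffsDelta(cnv_t[!is.na(cnv_t)],
                                                cnv_n[!is.na(cnv_n)])
    }
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  correlations <- correlationTable(profiles)
  data.table::fwrite(correlations, file.path(out_dir, "correlations.tsv"),
                     sep = "\t")

  ## ---- manifest ----
  inputs <- file.path(cohort_dir, need)
  manifest <- list(
    tool = "scDriverLoad",
    version = as.character(utils::packageVersion("scDriverLoad")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(min_qual = min_qual, min_depth = min_depth,
                      top_k = top_k, window = window,
                      percentile = percentile, n_mads = n_mads,
                      min_genes = min_genes, skip_cnv = skip_cnv),
    input_md5 = as.list(tools::md5sum(inputs)),
    counts = list(cells_input = nrow(metrics), cells_kept = length(kept),
                  variants_filtered = nVariants(filtered),
                  driver_calls = nrow(driver_calls),
                  status_alterations = nrow(statusGrid(status))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(profiles = profiles, thresholds = thresholds,
                 classification = classification, status = status,
                 stats = stats_out, correlations = correlations, qc = qc))
}

#' Generate a cohort, run the pipeline, and score recovery against truth
#'
#' Convenience wrapper used for validation: generates a synthetic cohort
#' from `config`, runs the full pipeline, and compares recovered per-cell
#' driver counts, baseline classification and CNV ranking against the
#' generator's ground truth.
#'
#' @param config a [cohortConfig()].
#' @param dir working directory (cohort under `cohort/`, outputs under
#'   `out/`).
#' @param min_genes QC floor passed to [runPipeline()] (default 100, half
#'   the default synthetic gene panel).
#' @param quiet suppress stage messages (default TRUE).
#' @param ... further arguments to [runPipeline()].
#' @return list with elements `truth`, `result`, and a `report` list:
#'   `driver_recovery` (fraction of cells whose recovered driver count
#'   equals the planted count), `high_driver_sensitivity` (fraction of
#'   planted high-driver tumor cells labeled HIGH_DRIVER_ONLY or
#'   HIGH_CNV_HIGH_DRIVER), `normal_exceedance` (fraction of normal cells
#'   above the driver threshold), `aneuploid_separated` (TRUE when every
#'   planted-aneuploid cell outranks every diploid cell on mean absolute
#'   CNV), `mw_p` (tumor-vs-normal driver-count Mann-Whitney p).
#' @export
endToEndCheck <- function(config = cohortConfig(),
                          dir = tempfile("cohort_run_"),
                          min_genes = 100, quiet = TRUE, ...) {
  cohort_dir <- file.path(dir, "cohort")
  out_dir <- file.path(dir, "out")
  truth <- generateCohort(config, out_dir = cohort_dir)
  res <- runPipeline(cohort_dir, out_dir, min_genes = min_genes,
                     quiet = quiet, ...)
  p <- res$profiles
  idx <- match(p$cell_id, truth$cell_id)
  recovery <- mean(p$n_drivers == truth$n_planted_drivers[idx])

  thr <- driverThreshold(res$thresholds)
  tumor_high <- p$cell_id[p$group == "tumor" &
                          truth$n_planted_drivers[idx] > thr]
  lab <- res$classification$label[
    match(tumor_high, res$classification$cell_id)]
  sens <- if (length(tumor_high))
    mean(lab %in% c("HIGH_DRIVER_ONLY", "HIGH_CNV_HIGH_DRIVER")) else NA

  normal_exceed <- mean(p$n_drivers[p$group == "normal"] > thr)

  an <- truth$aneuploid[idx]
  cnv <- p$mean_abs_cnv
  sep <- if (any(an) && any(!an))
    min(cnv[an], na.rm = TRUE) > max(cnv[!an], na.rm = TRUE) else NA
  mw <- res$stats$driver_mw_p

  list(truth = truth, result = res,
       report = list(driver_recovery = recovery,
                     high_driver_sensitivity = sens,
                     normal_exceedance = normal_exceed,
                     aneuploid_separated = sep,
                     mw_p = mw))
}
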