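#' @import methods
NULL

## status levels used throughout the coverage module
.STATUS_LEVELS <- c("present", "absent", "insufficient")

#' VariantSet: annotated variant calls for one or more cells
#'
#' Holds quality-scored variant calls (one row per ALT allele; multiallelic
#' records are decomposed upstream) together with their functional
#' annotations, one annotation row per parsed ANN entry. `annotations` is
#' linked to `variants` through `variant_id`; a variant with no annotation
#' rows is a non-genic call.
#'
#' @slot variants data.frame with columns `variant_id` (integer key),
#'   `cell_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `qual`.
#' @slot annotations data.frame with columns `variant_id`, `gene_symbol`,
#'   `effect_terms` (list column of sequence-ontology terms), `hgvs_p`
#'   (HGVS protein change or ""), `transcript_id`.
#' @export
setClass("VariantSet",
  representation(variants = "data.frame", annotations = "data.frame"))

setValidity("VariantSet", function(object) {
  v <- object@variants
  a <- object@annotations
  need_v <- c("variant_id", "cell_id", "chrom", "pos", "ref", "alt", "qual")
  need_a <- c("variant_id", "gene_symbol", "effect_terms", "hgvs_p",
              "transcript_id")
  if (!all(need_v %in% names(v)))
    return(paste("variants must have columns:", paste(need_v, collapse = ", ")))
  if (!all(need_a %in% names(a)))
    return(paste("annotations must have columns:", paste(need_a, collapse = ", ")))
  if (nrow(v)) {
    if (any(v$pos < 1)) return("all pos must be >= 1")
    if (any(v$qual < 0)) return("all qual must be >= 0")
    if (any(v$ref == v$alt)) return("ref must differ from alt")
    if (anyDuplicated(v$variant_id)) return("variant_id must be unique")
  }
  if (nrow(a) && !all(a$variant_id %in% v$variant_id))
    return("annotation variant_id not present in variants")
  TRUE
})

#' @describeIn VariantSet construct from component tables
#' @param variants,annotations component data.frames (see slots).
#' @export
VariantSet <- function(variants, annotations = NULL) {
  if (is.null(annotations))
    annotations <- data.frame(variant_id = integer(), gene_symbol = character(),
      effect_terms = I(list()), hgvs_p = character(),
      transcript_id = character())
  new("VariantSet", variants = as.data.frame(variants),
      annotations = as.data.frame(annotations))
}

#' @describeIn VariantSet variant table accessor
#' @param x a VariantSet.
#' @export
variantTable <- function(x) x@variants

#' @describeIn VariantSet annotation table accessor
#' @export
annotationTable <- function(x) x@annotations

#' @describeIn VariantSet number of variants
#' @export
nVariants <- function(x) nrow(x@variants)

setMethod("show", "VariantSet", function(object) {
  cat("VariantSet with", nrow(object@variants), "variants (",
      length(unique(object@variants$cell_id)), "cells ),",
      nrow(object@annotations), "annotations\n")
})

#' DriverCatalog: local oncogenicity annotations
#'
#' Maps (gene symbol, compact protein change) pairs to oncogenicity labels.
#' An alteration is a putative driver when its label is one of
#' `driverLabels(x)` (default: Oncogenic, Likely Oncogenic, Predicted
#' Oncogenic).
#'
#' @slot entries data.frame with columns `gene_symbol`,
#'   `protein_change_short` (e.g. "L755S", "V322fs", "Q3478*"),
#'   `oncogenicity`.
#' @slot driver_labels character vector of labels conferring putative-driver
#'   status.
#' @export
setClass("DriverCatalog",
  representation(entries = "data.frame", driver_labels = "character"))

setValidity("DriverCatalog", function(object) {
  e <- object@entries
  need <- c("gene_symbol", "protein_change_short", "oncogenicity")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  key <- paste(toupper(e$gene_symbol), e$protein_change_short)
  if (anyDuplicated(key)) return("duplicate (gene, protein change) entries")
  if (!length(object@driver_labels)) return("driver_labels must be non-empty")
  TRUE
})

#' @describeIn DriverCatalog construct from an entry table
#' @param entries data.frame (see slots).
#' @param driver_labels labels that confer putative-driver status.
#' @export
DriverCatalog <- function(entries,
    driver_labels = c("Oncogenic", "Likely Oncogenic", "Predicted Oncogenic")) {
  new("DriverCatalog", entries = as.data.frame(entries),
      driver_labels = driver_labels)
}

#' @describeIn DriverCatalog entry table accessor
#' @param x a DriverCatalog.
#' @export
catalogEntries <- function(x) x@entries

#' @describeIn DriverCatalog driver label set accessor
#' @export
driverLabels <- function(x) x@driver_labels

setMethod("show", "DriverCatalog", function(object) {
  cat("DriverCatalog with", nrow(object@entries), "entries;",
      sum(object@entries$oncogenicity %in% object@driver_labels),
      "driver-labeled\n")
})

#' DepthTrack: sparse per-base read depth for one cell
#'
#' Positions absent from the track have depth 0; only positive depths are
#' stored. Query with [depthAt()].
#'
#' @slot cell_id originating cell identifier.
#' @slot depths data.frame with columns `chrom`, `pos`, `depth` (all stored
#'   depths >= 1).
#' @export
setClass("DepthTrack",
  representation(cell_id = "character", depths = "data.frame"))

setValidity("DepthTrack", function(object) {
  d <- object@depths
  if (!all(c("chrom", "pos", "depth") %in% names(d)))
    return("depths must have columns chrom, pos, depth")
  if (nrow(d) && any(d$depth < 1)) return("stored depths must be >= 1")
  if (nrow(d) && anyDuplicated(paste(d$chrom, d$pos)))
    return("duplicate positions in depth track")
  TRUE
})

#' @describeIn DepthTrack construct from a position/depth table
#' @param cell_id cell identifier.
#' @param depths data.frame with columns chrom, pos, depth; rows with depth 0
#'   are dropped (zeros are implicit).
#' @export
DepthTrack <- function(cell_id, depths = NULL) {
  if (is.null(depths))
    depths <- data.frame(chrom = character(), pos = integer(),
                         depth = integer())
  depths <- as.data.frame(depths)
  depths <- depths[depths$depth > 0, , drop = FALSE]
  rownames(depths) <- NULL
  new("DepthTrack", cell_id = cell_id, depths = depths)
}

#' @describeIn DepthTrack vectorized depth lookup; unlisted positions are 0
#' @param track a DepthTrack.
#' @param chrom,pos equal-length chromosome and 1-based position vectors.
#' @export
depthAt <- function(track, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  d <- track@depths
  if (!nrow(d)) return(rep(0L, length(chrom)))
  idx <- match(paste0(chrom, ":", pos), paste0(d$chrom, ":", d$pos))
  out <- d$depth[idx]
  out[is.na(out)] <- 0L
  as.integer(out)
}

setMethod("show", "DepthTrack", function(object) {
  cat("DepthTrack for cell", object@cell_id, "with",
      nrow(object@depths), "covered positions\n")
})

#' CdsModel: coding-sequence gene model
#'
#' CDS segments grouped by transcript and sorted in transcript coding order:
#' ascending genomic coordinates on the + strand, descending on -. The
#' `frame` of a segment is the number of bases to skip at its (coding-order)
#' start to reach the next codon boundary, GTF convention.
#'
#' @slot segments data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `frame`, `transcript_id`, `gene_symbol`.
#' @export
setClass("CdsModel", representation(segments = "data.frame"))

setValidity("CdsModel", function(object) {
  s <- object@segments
  need <- c("chrom", "start", "end", "strand", "frame", "transcript_id",
            "gene_symbol")
  if (!all(need %in% names(s)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  if (nrow(s)) {
    if (any(s$start > s$end)) return("start must be <= end")
    if (!all(s$strand %in% c("+", "-"))) return("strand must be + or -")
    if (!all(s$frame %in% 0:2)) return("frame must be 0, 1 or 2")
  }
  TRUE
})

#' @describeIn CdsModel construct from a segment table (re-sorted into coding
#'   order per transcript)
#' @param segments data.frame (see slots).
#' @export
CdsModel <- function(segments) {
  s <- as.data.frame(segments)
  if (nrow(s)) {
    key <- ifelse(s$strand == "-", -s$start, s$start)
    s <- s[order(s$transcript_id, key), , drop = FALSE]
    rownames(s) <- NULL
  }
  new("CdsModel", segments = s)
}

#' @describeIn CdsModel segment table accessor
#' @param x a CdsModel.
#' @export
cdsSegments <- function(x) x@segments

setMethod("show", "CdsModel", function(object) {
  s <- object@segments
  cat("CdsModel:", length(unique(s$transcript_id)), "transcripts,",
      length(unique(s$gene_symbol)), "genes,", nrow(s), "CDS segments\n")
})

#' ResidueLocus: the genomic bases encoding one protein residue
#'
#' The three positions are listed in coding (codon) order: ascending genomic
#' coordinates on the + strand, descending on -. They need not be contiguous
#' when the codon spans an exon junction.
#'
#' @slot gene_symbol,transcript_id gene and mapping transcript.
#' @slot residue_index 1-based codon number.
#' @slot positions data.frame with columns `chrom`, `pos`, exactly 3 rows.
#' @slot strand "+" or "-".
#' @export
setClass("ResidueLocus",
  representation(gene_symbol = "character", transcript_id = "character",
                 residue_index = "integer", positions = "data.frame",
                 strand = "character"))

setValidity("ResidueLocus", function(object) {
  if (nrow(object@positions) != 3) return("a residue locus has exactly 3 bases")
  if (!object@strand %in% c("+", "-")) return("strand must be + or -")
  if (object@residue_index < 1) return("residue_index must be >= 1")
  TRUE
})

setMethod("show", "ResidueLocus", function(object) {
  cat(sprintf("ResidueLocus %s residue %d (%s, %s): %s\n",
      object@gene_symbol, object@residue_index, object@transcript_id,
      object@strand,
      paste0(object@positions$chrom, ":", object@positions$pos,
             collapse = ", ")))
})

#' @describeIn ResidueLocus locus position accessor
#' @param x a ResidueLocus.
#' @export
locusPositions <- function(x) x@positions

#' StatusMatrix: present/absent/insufficient calls per alteration and cell
#'
#' Rows are alterations ("GENE p.change" compact form), columns are cells;
#' each entry is one of "present", "absent", "insufficient". "present" is
#' decided by the filtered variant call alone; depth only separates "absent"
#' (all three codon bases covered at the minimum depth) from "insufficient".
#'
#' @slot status character matrix with alteration rownames and cell colnames.
#' @slot alterations data.frame with columns `gene_symbol`,
#'   `protein_change_short`, `n_present` (row order matches `status`).
#' @export
setClass("StatusMatrix",
  representation(status = "matrix", alterations = "data.frame"))

setValidity("StatusMatrix", function(object) {
  if (nrow(object@status) != nrow(object@alterations))
    return("status rows must match alteration table")
  if (length(object@status) &&
      !all(object@status %in% .STATUS_LEVELS))
    return("status values must be present/absent/insufficient")
  TRUE
})

#' @describeIn StatusMatrix the status grid
#' @param x a StatusMatrix.
#' @export
statusGrid <- function(x) x@status

#' @describeIn StatusMatrix the ranked alteration table
#' @export
statusAlterations <- function(x) x@alterations

setMethod("show", "StatusMatrix", function(object) {
  tab <- table(factor(object@status, levels = .STATUS_LEVELS))
  cat("StatusMatrix:", nrow(object@status), "alterations x",
      ncol(object@status), "cells (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
})

#' BaselineThresholds: normal-cell percentile cutoffs
#'
#' Nearest-rank percentile cutoffs for driver count and mean absolute CNV
#' score, computed from cells of known non-cancer origin. Each threshold
#' records the number of normal cells with the relevant measurement present.
#'
#' @slot driver_p numeric driver-count cutoff.
#' @slot cnv_p numeric mean-absolute-CNV cutoff.
#' @slot n_driver,n_cnv number of normal cells contributing to each cutoff.
#' @slot percentile the percentile used (default 99).
#' @export
setClass("BaselineThresholds",
  representation(driver_p = "numeric", cnv_p = "numeric",
                 n_driver = "integer", n_cnv = "integer",
                 percentile = "numeric"))

setValidity("BaselineThresholds", function(object) {
  if (object@n_driver < 1) return("needs >= 1 normal cell for driver cutoff")
  if (object@percentile <= 0 || object@percentile > 100)
    return("percentile must be in (0, 100]")
  TRUE
})

setMethod("show", "BaselineThresholds", function(object) {
  cat(sprintf(
    "BaselineThresholds (p%g): driver > %g (n=%d), CNV > %g (n=%d)\n",
    object@percentile, object@driver_p, object@n_driver, object@cnv_p,
    object@n_cnv))
})

#' @describeIn BaselineThresholds driver-count cutoff
#' @param x a BaselineThresholds.
#' @export
driverThreshold <- function(x) x@driver_p

#' @describeIn BaselineThresholds CNV-score cutoff
#' @export
cnvThreshold <- function(x) x@cnv_p
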