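## VCF reading (via vcfR) and writing.
##
## ANN INFO subfields follow the pipe-delimited SnpEff >= 4.1 layout:
##   Allele | Annotation | Impact | Gene_Name | Gene_ID | Feature_Type |
##   Feature_ID | Biotype | Rank | HGVS.c | HGVS.p | ...
## Fields are taken positionally (1 = allele, 2 = effects, 4 = gene,
## 7 = transcript, 11 = HGVS.p); extra trailing fields are ignored.

.ANN_MIN_FIELDS <- 11L

.validate_vcf_fix <- function(fix, path) {
  if (!nrow(fix)) return(invisible(NULL))
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  bad <- which(is.na(pos) | pos < 1 |
               !grepl("^[ACGTN]+$", fix[, "REF"]) |
               !grepl("^[ACGTN*,]+$", fix[, "ALT"]))
  if (length(bad))
    stop(sprintf("malformed VCF record %d in %s (POS/REF/ALT)", bad[1], path))
  invisible(NULL)
}

## parse one record's ANN string into annotation rows for a given set of ALTs;
## returns a data.frame keyed by alt allele
.parse_ann <- function(ann_string, alts) {
  if (is.na(ann_string) || !nzchar(ann_string)) return(NULL)
  entries <- strsplit(ann_string, ",", fixed = TRUE)[[1]]
  fields <- strsplit(entries, "|", fixed = TRUE)
  short <- vapply(fields, length, 0L) < .ANN_MIN_FIELDS
  if (any(short)) {
    warning("ANN entry with unrecognized layout (",
            sum(short), " entries skipped)", call. = FALSE)
    fields <- fields[!short]
    if (!length(fields)) return(NULL)
  }
  allele <- vapply(fields, `[[`, "", 1L)
  ## annotations whose allele matches no ALT of this record are attached to
  ## every decomposed ALT (complex SnpEff allele notation)
  allele[!allele %in% alts] <- NA_character_
  data.frame(
    allele = allele,
    gene_symbol = vapply(fields, `[[`, "", 4L),
    effects = vapply(fields, `[[`, "", 2L),
    hgvs_p = vapply(fields, `[[`, "", 11L),
    transcript_id = vapply(fields, `[[`, "", 7L),
    stringsAsFactors = FALSE)
}

#' Read an annotated per-cell VCF
#'
#' Reads a VCF 4.x file into a [VariantSet]. One variant is produced per ALT
#' allele per record (multiallelic records are decomposed); SnpEff-style
#' `ANN` INFO subfields are parsed into annotation rows, with `effect_terms`
#' split on `&`. Records without an `ANN` field yield variants with no
#' annotations. Missing QUAL (`.`) is treated as 0.
#'
#' @param path path to a VCF file.
#' @param cell_id identifier of the originating cell, stored on every
#'   variant.
#' @return a [VariantSet].
#' @export
readAnnotatedVcf <- function(path, cell_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  n <- nrow(fix)
  empty <- VariantSet(data.frame(
    variant_id = integer(), cell_id = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(), qual = numeric()))
  if (!n) return(empty)
  .validate_vcf_fix(fix, path)

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep.int(seq_len(n), n_alt)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- 0
  variants <- data.frame(
    variant_id = seq_along(rec),
    cell_id = cell_id,
    chrom = fix[rec, "CHROM"],
    pos = as.integer(fix[rec, "POS"]),
    ref = fix[rec, "REF"],
    alt = unlist(alts, use.names = FALSE),
    qual = qual[rec],
    stringsAsFactors = FALSE)

  info <- fix[, "INFO"]
  ann_raw <- rep(NA_character_, n)
  has_info <- which(!is.na(info))
  rx <- regexpr("(?:^|;)ANN=[^;]*", info[has_info], perl = TRUE)
  hit <- rx > 0
  m <- regmatches(info[has_info], rx)
  ann_raw[has_info[hit]] <- sub("^;?ANN=", "", m)

  ann_list <- vector("list", nrow(variants))
  for (r in which(!is.na(ann_raw))) {
    parsed <- .parse_ann(ann_raw[r], alts[[r]])
    if (is.null(parsed)) next
    vids <- which(rec == r)
    for (k in seq_along(vids)) {
      take <- is.na(parsed$allele) | parsed$allele == alts[[r]][k]
      if (any(take)) {
        p <- parsed[take, , drop = FALSE]
        p$variant_id <- vids[k]
        ann_list[[vids[k]]] <- p
      }
    }
  }
  ann_rows <- do.call(rbind, ann_list)
  if (is.null(ann_rows) || !nrow(ann_rows)) return(VariantSet(variants))
  annotations <- data.frame(
    variant_id = ann_rows$variant_id,
    gene_symbol = ann_rows$gene_symbol,
    effect_terms = I(strsplit(ann_rows$effects, "&", fixed = TRUE)),
    hgvs_p = ann_rows$hgvs_p,
    transcript_id = ann_rows$transcript_id,
    stringsAsFactors = FALSE)
  VariantSet(variants, annotations)
}

#' Read a common-variant site list
#'
#' Reads a sites VCF (dbSNP-common stand-in) into an allele-level exclusion
#' table, one row per (site, ALT allele); multiallelic lines are decomposed.
#'
#' @param path path to a VCF of sites.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt` (unique
#'   rows).
#' @export
readCommonSites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  fix <- v@fix
  if (!nrow(fix))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  .validate_vcf_fix(fix, path)
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  rec <- rep.int(seq_len(nrow(fix)), lengths(alts))
  out <- data.frame(
    chrom = fix[rec, "CHROM"],
    pos = as.integer(fix[rec, "POS"]),
    ref = fix[rec, "REF"],
    alt = unlist(alts, use.names = FALSE),
    stringsAsFactors = FALSE)
  unique(out)
}

.VCF_HEADER <- c(
  "##fileformat=VCFv4.2",
  paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
         "annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name ",
         "| Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank ",
         "| HGVS.c | HGVS.p | cDNA.pos / cDNA.length | CDS.pos / CDS.length ",
         "| AA.pos / AA.length | Distance | ERRORS / WARNINGS / INFO'\">"),
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")

#' Write a VariantSet as a VCF file
#'
#' Emits one biallelic record per variant, with annotations re-encoded as a
#' SnpEff-layout `ANN` INFO subfield. Round-trips through
#' [readAnnotatedVcf()] (positions, alleles, qualities, gene symbols, effect
#' terms, HGVS.p, transcript ids).
#'
#' @param x a [VariantSet].
#' @param path output path.
#' @export
writeVariantVcf <- function(x, path) {
  v <- variantTable(x)
  a <- annotationTable(x)
  info <- rep(".", nrow(v))
  if (nrow(a)) {
    ann <- vapply(seq_len(nrow(a)), function(i) {
      vi <- match(a$variant_id[i], v$variant_id)
      hp <- a$hgvs_p[i]
      entry <- paste(v$alt[vi], paste(a$effect_terms[[i]], collapse = "&"),
        ".", a$gene_symbol[i], ".", "transcript", a$transcript_id[i],
        "protein_coding", ".", ".", hp, "", "", "", "", "", sep = "|")
      entry
    }, "")
    grp <- split(ann, a$variant_id)
    idx <- match(names(grp), as.character(v$variant_id))
    info[idx] <- paste0("ANN=", vapply(grp, paste, "", collapse = ","))
  }
  lines <- c(.VCF_HEADER, if (nrow(v)) paste(
    v$chrom, v$pos, ".", v$ref, v$alt,
    formatC(v$qual, format = "g", digits = 15), ".", info, sep = "\t"))
  writeLines(lines, path)
}

#' Write a common-sites table as a sites VCF
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param path output path.
#' @export
writeCommonSitesVcf <- function(sites, path) {
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             if (nrow(sites)) paste(sites$chrom, sites$pos, ".", sites$ref,
                                    sites$alt, ".", ".", ".", sep = "\t"))
  writeLines(lines, path)
}
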