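## Driver annotation: quality filtering, common-SNP removal, effect-class
## tallies and putative-driver matching against a local oncogenicity catalog.

.SPLICE_TERMS <- c("splice_donor_variant", "splice_acceptor_variant",
                   "splice_region_variant")

.AA3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Sec = "U", Ter = "*")

#' Read a local oncogenicity catalog
#'
#' The catalog is a TSV with header columns `gene`, `alteration`,
#' `oncogenicity`, emulating locally cached oncogenicity annotations.
#' Alterations are compact protein changes (e.g. "L755S", "V322fs",
#' "Q3478*").
#'
#' @param path path to the catalog TSV.
#' @param driver_labels oncogenicity labels that confer putative-driver
#'   status.
#' @return a [DriverCatalog].
#' @export
readDriverCatalog <- function(path,
    driver_labels = c("Oncogenic", "Likely Oncogenic",
                      "Predicted Oncogenic")) {
  d <- data.table::fread(path, header = TRUE, sep = "\t",
                         showProgress = FALSE)
  need <- c("gene", "alteration", "oncogenicity")
  if (!all(need %in% names(d)))
    stop("catalog must have header columns gene, alteration, oncogenicity: ",
         path)
  DriverCatalog(data.frame(gene_symbol = d$gene,
                           protein_change_short = d$alteration,
                           oncogenicity = d$oncogenicity),
                driver_labels = driver_labels)
}

#' Write a driver catalog TSV
#'
#' @param catalog a [DriverCatalog].
#' @param path output path.
#' @export
writeDriverCatalog <- function(catalog, path) {
  e <- catalogEntries(catalog)
  data.table::fwrite(
    data.table::data.table(gene = e$gene_symbol,
                           alteration = e$protein_change_short,
                           oncogenicity = e$oncogenicity),
    path, sep = "\t")
}

.subset_variants <- function(x, keep) {
  v <- variantTable(x)[keep, , drop = FALSE]
  a <- annotationTable(x)
  a <- a[a$variant_id %in% v$variant_id, , drop = FALSE]
  rownames(v) <- rownames(a) <- NULL
  VariantSet(v, a)
}

#' Filter variants on call quality
#'
#' Keeps variants whose phred-scaled quality is at least `min_qual`
#' (inclusive threshold; the conventional cutoff is 30). Order is preserved
#' and the operation is idempotent.
#'
#' @param x a [VariantSet].
#' @param min_qual minimum quality score (default 30).
#' @return a filtered [VariantSet].
#' @export
filterQuality <- function(x, min_qual = 30) {
  .subset_variants(x, variantTable(x)$qual >= min_qual)
}

#' Remove population-common variant sites
#'
#' Drops variants whose (chrom, pos, ref, alt) exactly matches an entry of
#' the common-site table, preventing common germline polymorphism from
#' counting as evidence of cancer status. Matching is allele-exact by
#' default; positional matching (drop anything at a listed chrom/pos) is
#' available for fidelity experiments.
#'
#' @param x a [VariantSet].
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (see [readCommonSites()]).
#' @param positional if TRUE, match on (chrom, pos) only.
#' @return a filtered [VariantSet].
#' @export
removeCommonSites <- function(x, sites, positional = FALSE) {
  v <- variantTable(x)
  if (!nrow(v) || !nrow(sites)) return(x)
  if (positional) {
    hit <- paste0(v$chrom, ":", v$pos) %in% paste0(sites$chrom, ":", sites$pos)
  } else {
    hit <- paste(v$chrom, v$pos, v$ref, v$alt) %in%
      paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  }
  .subset_variants(x, !hit)
}

#' Normalize an HGVS protein change to compact form
#'
#' Converts HGVS.p strings with 3-letter residue codes (with or without the
#' "p." prefix, optionally parenthesized) to the compact 1-letter form used
#' by oncogenicity catalogs: `L755S` for missense, `Q3478*` for stop gains
#' (`Ter` or `*`), and `V322fs` for frameshifts (reference residue +
#' position + "fs"; any trailing `Ter` extension is dropped, the usual
#' catalog convention). Unparseable strings (duplications, extensions,
#' delins, synonymous) return "" with a warning.
#'
#' @param hgvs_p character vector of HGVS protein changes.
#' @return character vector of compact changes ("" where unparseable).
#' @export
normalizeProteinChange <- function(hgvs_p) {
  s <- as.character(hgvs_p)
  s <- sub("^p\\.", "", s)
  s <- sub("^\\((.*)\\)$", "\\1", s)
  out <- character(length(s))

  aa <- function(code) unname(.AA3TO1[code])

  ## frameshift: ref residue + position + fs (alt residue / Ter ext ignored)
  m <- regmatches(s, regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})?fs",
                             s))
  is_fs <- lengths(m) > 0
  out[is_fs] <- vapply(m[is_fs], function(g) {
    r <- aa(g[2])
    if (is.na(r)) "" else paste0(r, g[3], "fs")
  }, "")

  ## substitution (missense or stop gain)
  m <- regmatches(s, regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}|\\*)$",
                             s))
  is_sub <- lengths(m) > 0 & !is_fs
  out[is_sub] <- vapply(m[is_sub], function(g) {
    r <- aa(g[2])
    a <- if (g[4] == "*") "*" else aa(g[4])
    if (is.na(r) || is.na(a)) "" else paste0(r, g[3], a)
  }, "")

  bad <- nzchar(s) & !is.na(s) & !nzchar(out)
  if (any(bad))
    warning("unparseable HGVS.p (left unmatched): ",
            paste(utils::head(unique(s[bad]), 5), collapse = ", "),
            call. = FALSE)
  out[is.na(s)] <- ""
  out
}

#' Match variants against the driver catalog
#'
#' Identifies putative driver alterations: annotations whose normalized
#' protein change matches a catalog entry carrying a driver label. Gene
#' matching is case-insensitive; protein-change matching is exact. Multiple
#' records or annotations supporting the same alteration in the same cell
#' collapse to a single call, so per-cell driver load counts unique
#' alterations.
#'
#' @param x a [VariantSet] (already quality- and common-filtered).
#' @param catalog a [DriverCatalog].
#' @return data.frame of driver calls with columns `cell_id`, `gene_symbol`,
#'   `protein_change_short`, `oncogenicity`, and supporting-variant columns
#'   `chrom`, `pos`, `ref`, `alt`, `qual`.
#' @export
matchDrivers <- function(x, catalog) {
  v <- variantTable(x)
  a <- annotationTable(x)
  empty <- data.frame(cell_id = character(), gene_symbol = character(),
    protein_change_short = character(), oncogenicity = character(),
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), qual = numeric())
  if (!nrow(a)) return(empty)
  e <- catalogEntries(catalog)
  e <- e[e$oncogenicity %in% driverLabels(catalog), , drop = FALSE]
  if (!nrow(e)) return(empty)

  has_p <- nzchar(a$hgvs_p) & !is.na(a$hgvs_p)
  a <- a[has_p, , drop = FALSE]
  if (!nrow(a)) return(empty)
  pcs <- suppressWarnings(normalizeProteinChange(a$hgvs_p))
  key <- paste(toupper(a$gene_symbol), pcs)
  idx <- match(key, paste(toupper(e$gene_symbol), e$protein_change_short))
  hit <- which(!is.na(idx) & nzchar(pcs))
  if (!length(hit)) return(empty)

  vi <- match(a$variant_id[hit], v$variant_id)
  calls <- data.frame(
    cell_id = v$cell_id[vi],
    gene_symbol = e$gene_symbol[idx[hit]],
    protein_change_short = e$protein_change_short[idx[hit]],
    oncogenicity = e$oncogenicity[idx[hit]],
    chrom = v$chrom[vi], pos = v$pos[vi], ref = v$ref[vi], alt = v$alt[vi],
    qual = v$qual[vi],
    stringsAsFactors = FALSE)
  ## one call per (cell, gene, protein change); first supporting record wins
  dup <- duplicated(paste(calls$cell_id, toupper(calls$gene_symbol),
                          calls$protein_change_short))
  calls <- calls[!dup, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Tally effect classes per cell
#'
#' Counts, for each cell, total variants, coding variants (any annotation
#' with a protein-level consequence) and splice-site variants (any
#' annotation whose effect terms intersect splice donor / acceptor / region).
#' Each variant counts at most once per class.
#'
#' @param x a [VariantSet].
#' @param cells optional cell ids to report (cells absent from `x` report
#'   zeros); defaults to the cells present.
#' @return data.frame with columns `cell_id`, `n_total`, `n_coding`,
#'   `n_splice`.
#' @export
countEffectClasses <- function(x, cells = NULL) {
  v <- variantTable(x)
  a <- annotationTable(x)
  if (is.null(cells)) cells <- unique(v$cell_id)
  coding_ids <- unique(a$variant_id[nzchar(a$hgvs_p) & !is.na(a$hgvs_p)])
  splice_ids <- unique(a$variant_id[vapply(a$effect_terms, function(tt)
    any(tt %in% .SPLICE_TERMS), NA)])
  n_total <- table(factor(v$cell_id, levels = cells))
  n_coding <- table(factor(v$cell_id[v$variant_id %in% coding_ids],
                           levels = cells))
  n_splice <- table(factor(v$cell_id[v$variant_id %in% splice_ids],
                           levels = cells))
  data.frame(cell_id = cells,
             n_total = as.integer(n_total),
             n_coding = as.integer(n_coding),
             n_splice = as.integer(n_splice),
             stringsAsFactors = FALSE)
}
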