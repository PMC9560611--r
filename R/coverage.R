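## Residue-to-genome mapping and coverage-based absence calling.
##
## A variant call decides PRESENT on its own; read depth is used only to
## distinguish ABSENT (all three codon bases covered at the minimum depth)
## from INSUFFICIENT coverage. The minimum depth never influences presence.

## coding-order base coordinates of one segment, as a function of offsets
## within the segment walk (1-based)
.segment_bases <- function(seg, offsets) {
  if (seg$strand == "+") seg$start + offsets - 1L else seg$end - offsets + 1L
}

## pick the mapping transcript for a gene: longest total CDS, ties broken by
## lexicographically smallest transcript id (a common canonical-transcript
## proxy)
.canonical_transcript <- function(segments, gene) {
  s <- segments[toupper(segments$gene_symbol) == toupper(gene), ,
                drop = FALSE]
  if (!nrow(s)) return(NULL)
  len <- tapply(s$end - s$start + 1L, s$transcript_id, sum)
  tx <- names(len)[order(-len, names(len))][1]
  s[s$transcript_id == tx, , drop = FALSE]
}

#' Map a protein residue to its genomic base positions
#'
#' Walks the frame-adjusted, strand-ordered CDS of the gene's mapping
#' transcript (the longest CDS; ties broken by smallest transcript id) and
#' returns the three genomic bases at coding offsets
#' `3*(residue_index-1)+1 .. 3*residue_index`. The frame of the first CDS
#' segment shifts the walk start; codons may span exon junctions. A
#' transcript whose frame-adjusted CDS length is not a multiple of 3 is
#' accepted with a warning (its trailing partial codon is unmappable).
#'
#' @param gene gene symbol (case-insensitive).
#' @param residue_index 1-based codon number.
#' @param cds a [CdsModel].
#' @param transcript_id optional explicit transcript to map on.
#' @return a [ResidueLocus].
#' @export
residueToLocus <- function(gene, residue_index, cds, transcript_id = NULL) {
  segments <- cdsSegments(cds)
  if (!is.null(transcript_id)) {
    s <- segments[segments$transcript_id == transcript_id, , drop = FALSE]
  } else {
    s <- .canonical_transcript(segments, gene)
  }
  if (is.null(s) || !nrow(s))
    stop("no CDS segments for gene ", gene)
  residue_index <- as.integer(residue_index)
  if (is.na(residue_index) || residue_index < 1)
    stop("residue_index must be a positive integer")

  lens <- s$end - s$start + 1L
  skip <- s$frame[1]                      # frame-adjust the walk start
  adj_total <- sum(lens) - skip
  if (adj_total %% 3 != 0)
    warning(sprintf(
      "CDS of %s (%s) has frame-adjusted length %d, not a multiple of 3",
      gene, s$transcript_id[1], adj_total), call. = FALSE)
  offs <- 3L * (residue_index - 1L) + 1:3  # offsets along adjusted walk
  if (offs[3] > adj_total)
    stop(sprintf("residue %d beyond CDS of %s (%s): %d coding bases",
                 residue_index, gene, s$transcript_id[1], adj_total))

  cum <- cumsum(lens) - skip               # adjusted cumulative lengths
  seg_idx <- findInterval(offs - 1L, cum) + 1L
  within <- offs - c(0L, cum)[seg_idx]     # offset within segment walk
  within <- within + ifelse(seg_idx == 1L, skip, 0L)
  pos <- vapply(seq_len(3), function(k)
    as.numeric(.segment_bases(s[seg_idx[k], ], within[k])), 0)
  new("ResidueLocus", gene_symbol = s$gene_symbol[1],
      transcript_id = s$transcript_id[1], residue_index = residue_index,
      positions = data.frame(chrom = s$chrom[seg_idx], pos = as.integer(pos),
                             stringsAsFactors = FALSE),
      strand = s$strand[1])
}

## residue index parsed from a compact protein change ("L755S" -> 755)
.residue_index_of <- function(protein_change_short) {
  m <- regmatches(protein_change_short,
                  regexec("^[A-Za-z*](\\d+)", protein_change_short))
  vapply(m, function(g) if (length(g)) as.integer(g[2]) else NA_integer_,
         0L)
}

#' Call alteration status for one cell
#'
#' Three-way call for a (cell, alteration) pair: `present` when the cell
#' carries a filtered driver call for the alteration (presence is decided by
#' the variant call, not depth); otherwise `absent` when the cell's read
#' depth is at least `min_depth` at all three bases of the residue locus;
#' otherwise `insufficient`.
#'
#' @param locus a [ResidueLocus] for the alteration's residue.
#' @param gene,protein_change_short the alteration.
#' @param cell_drivers data.frame of the cell's driver calls
#'   (see [matchDrivers()]); may be empty.
#' @param depth the cell's [DepthTrack].
#' @param min_depth minimum depth required to infer absence (default 5).
#' @return one of "present", "absent", "insufficient".
#' @export
callStatus <- function(locus, gene, protein_change_short, cell_drivers,
                       depth, min_depth = 5) {
  if (nrow(cell_drivers) &&
      any(toupper(cell_drivers$gene_symbol) == toupper(gene) &
          cell_drivers$protein_change_short == protein_change_short))
    return("present")
  p <- locusPositions(locus)
  d <- depthAt(depth, p$chrom, p$pos)
  if (all(d >= min_depth)) "absent" else "insufficient"
}

#' Build the alteration-status matrix
#'
#' Ranks driver alterations by the number of cells in which they are
#' present (descending; ties broken by gene then protein change,
#' ascending), keeps the `top_k` most frequent, and calls
#' present/absent/insufficient for every retained alteration in every cell.
#' Alterations whose residue cannot be mapped on the gene model are
#' excluded with a warning.
#'
#' @param cells cell identifiers (matrix columns, in order).
#' @param driver_calls data.frame of driver calls (see [matchDrivers()]).
#' @param cds a [CdsModel] used for residue mapping.
#' @param depths named list of [DepthTrack] objects, one per cell.
#' @param top_k number of most frequent alterations to retain (default 25).
#' @param min_depth minimum depth to infer absence (default 5).
#' @return a [StatusMatrix].
#' @export
buildStatusMatrix <- function(cells, driver_calls, cds, depths,
                              top_k = 25, min_depth = 5) {
  alts <- unique(driver_calls[, c("gene_symbol", "protein_change_short")])
  loci <- list()
  keep <- logical(nrow(alts))
  for (i in seq_len(nrow(alts))) {
    ri <- .residue_index_of(alts$protein_change_short[i])
    loc <- if (is.na(ri)) NULL else tryCatch(
      residueToLocus(alts$gene_symbol[i], ri, cds),
      error = function(e) NULL)
    if (is.null(loc)) {
      warning(sprintf("excluding %s %s: residue locus unresolvable",
                      alts$gene_symbol[i], alts$protein_change_short[i]),
              call. = FALSE)
    } else {
      keep[i] <- TRUE
      loci[[paste(alts$gene_symbol[i], alts$protein_change_short[i])]] <- loc
    }
  }
  alts <- alts[keep, , drop = FALSE]

  call_key <- paste(driver_calls$gene_symbol,
                    driver_calls$protein_change_short)
  alt_key <- paste(alts$gene_symbol, alts$protein_change_short)
  n_present <- vapply(alt_key, function(k)
    length(unique(driver_calls$cell_id[call_key == k & driver_calls$cell_id
                                       %in% cells])), 0L)
  ord <- order(-n_present, alts$gene_symbol, alts$protein_change_short)
  ord <- utils::head(ord, top_k)
  alts <- alts[ord, , drop = FALSE]
  alt_key <- alt_key[ord]
  n_present <- n_present[ord]

  status <- matrix("insufficient", nrow = nrow(alts), ncol = length(cells),
                   dimnames = list(alt_key, cells))
  if (nrow(alts)) {
    pos_tab <- do.call(rbind, lapply(alt_key, function(k)
      locusPositions(loci[[k]])))
    for (ci in seq_along(cells)) {
      cell <- cells[ci]
      tr <- depths[[cell]]
      if (is.null(tr)) tr <- DepthTrack(cell)
      d <- depthAt(tr, pos_tab$chrom, pos_tab$pos)
      covered <- colSums(matrix(d >= min_depth, nrow = 3)) == 3
      status[covered, ci] <- "absent"
      mine <- call_key[driver_calls$cell_id == cell]
      status[alt_key %in% mine, ci] <- "present"
    }
  }
  rownames(alts) <- NULL
  new("StatusMatrix", status = status,
      alterations = data.frame(alts, n_present = as.integer(n_present),
                               row.names = NULL))
}

#' Write a status matrix TSV
#'
#' Rows are alterations ("GENE change"), columns cells, values in
#' present/absent/insufficient.
#'
#' @param x a [StatusMatrix].
#' @param path output path.
#' @export
writeStatusMatrix <- function(x, path) {
  out <- data.table::data.table(alteration = rownames(statusGrid(x)))
  out <- cbind(out, data.table::as.data.table(statusGrid(x)))
  data.table::fwrite(out, path, sep = "\t")
}
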