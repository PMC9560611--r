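#' Read CDS features from a GTF gene model
#'
#' Imports a GTF (Ensembl/UCSC dialect) via `rtracklayer` and returns the
#' CDS geometry as a [CdsModel], with segments of each transcript sorted in
#' transcript coding order (ascending coordinates on the + strand,
#' descending on -). Transcripts containing any CDS feature without a frame
#' are rejected with a warning. Gene symbols come from the `gene_name`
#' attribute when present, falling back to `gene_id`.
#'
#' @param path path to a GTF file.
#' @return a [CdsModel]; empty (with a warning) if the file holds no CDS
#'   features.
#' @export
readCdsModel <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(g)
  empty <- CdsModel(data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), frame = integer(), transcript_id = character(),
    gene_symbol = character()))
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) {
    warning("no CDS features in ", path, call. = FALSE)
    return(empty)
  }
  gene_symbol <- if ("gene_name" %in% names(cds) &&
                     !all(is.na(cds$gene_name))) {
    ifelse(is.na(cds$gene_name), cds$gene_id, cds$gene_name)
  } else cds$gene_id
  seg <- data.frame(
    chrom = as.character(cds$seqnames),
    start = cds$start,
    end = cds$end,
    strand = as.character(cds$strand),
    frame = suppressWarnings(as.integer(as.character(cds$phase))),
    transcript_id = cds$transcript_id,
    gene_symbol = gene_symbol,
    stringsAsFactors = FALSE)
  bad_tx <- unique(seg$transcript_id[is.na(seg$frame)])
  if (length(bad_tx)) {
    warning("rejecting ", length(bad_tx),
            " transcript(s) with frameless CDS: ",
            paste(utils::head(bad_tx, 5), collapse = ", "), call. = FALSE)
    seg <- seg[!seg$transcript_id %in% bad_tx, , drop = FALSE]
  }
  if (!nrow(seg)) return(empty)
  CdsModel(seg)
}
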