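#' Read a per-cell depth track
#'
#' Reads a 3-column `samtools depth`-style TSV (chrom, 1-based position,
#' depth) into a sparse [DepthTrack]; positions not listed report depth 0.
#' Duplicate positions are resolved last-record-wins with a warning.
#'
#' @param path path to the depth TSV (no header).
#' @param cell_id identifier of the originating cell.
#' @return a [DepthTrack].
#' @export
readDepthTrack <- function(path, cell_id) {
  if (file.size(path) == 0) return(DepthTrack(cell_id))
  d <- data.table::fread(path, header = FALSE, sep = "\t",
                         colClasses = list(character = 1),
                         showProgress = FALSE)
  if (!nrow(d)) return(DepthTrack(cell_id))
  if (ncol(d) != 3)
    stop("depth file must have 3 columns (chrom, pos, depth): ", path)
  data.table::setnames(d, c("chrom", "pos", "depth"))
  if (!is.numeric(d$pos) || !is.numeric(d$depth) ||
      any(d$pos != floor(d$pos)) || any(d$depth != floor(d$depth)))
    stop("non-integer position or depth in ", path)
  key <- paste0(d$chrom, ":", d$pos)
  if (anyDuplicated(key)) {
    warning("duplicate positions in ", path, " (last record wins)",
            call. = FALSE)
    d <- d[!duplicated(key, fromLast = TRUE), ]
  }
  DepthTrack(cell_id, data.frame(chrom = d$chrom, pos = as.integer(d$pos),
                                 depth = as.integer(d$depth)))
}

#' Write a depth track as a 3-column TSV
#'
#' Only positive depths are written (zeros are implicit in the dialect).
#'
#' @param track a [DepthTrack].
#' @param path output path.
#' @export
writeDepthTrack <- function(track, path) {
  d <- track@depths
  data.table::fwrite(d, path, sep = "\t", col.names = FALSE)
}
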