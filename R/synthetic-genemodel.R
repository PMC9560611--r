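## Synthetic gene-model generation.
##
## Produces a compact multi-chromosome coding gene model with multi-exon
## transcripts on both strands, valid GTF frames, and codons spanning exon
## junctions, plus the generator's own base-by-base codon bookkeeping used
## to plant variants and to cross-check residue mapping.

.AA1TO3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val")

## run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

## gene symbols and realistic residue counts for the driver genes the
## default catalog annotates; remaining genes are generic
.NAMED_GENES <- data.frame(
  gene_symbol = c("ERBB2", "PIK3CA", "TP53", "KRAS", "NCOR1", "KMT2C",
                  "APC", "BRAF", "SMAD4", "PTEN"),
  n_residues = c(1255L, 1068L, 393L, 189L, 2440L, 4911L, 2843L, 766L,
                 552L, 403L),
  stringsAsFactors = FALSE)

#' Generate a synthetic coding gene model
#'
#' Lays `n_genes` single-transcript genes across `n_chroms` chromosomes in
#' genomic order, with 1-4 CDS segments per transcript, both strands,
#' GTF-convention frames, and frame-adjusted CDS lengths that are exact
#' multiples of 3. The first ten genes carry well-known driver-gene symbols
#' with realistic protein lengths so catalog alterations such as ERBB2
#' L755S map onto them; at least one transcript is guaranteed to contain
#' codons spanning an exon junction. The generator keeps its own
#' base-by-base codon coordinate map (see [codonPositions()]), which
#' downstream residue mapping can be checked against.
#'
#' @param n_genes number of genes (>= `n_chroms`; default 200).
#' @param n_chroms number of chromosomes (default 4).
#' @param seed RNG seed; a fixed seed yields byte-identical output.
#' @return an object of class `SyntheticGeneModel`: a list with elements
#'   `genes` (data.frame: gene_id, gene_symbol, transcript_id, chrom,
#'   strand, n_residues, cds_length, start), `segments` (CDS segment table
#'   as in [CdsModel]), `gtf_lines` (GTF text), and `coords`
#'   (per-gene coding-order base coordinates).
#' @export
generateGeneModel <- function(n_genes = 200, n_chroms = 4, seed = 1) {
  stopifnot(n_genes >= n_chroms, n_genes >= nrow(.NAMED_GENES))
  .with_seed(seed, {
    per_chrom <- ceiling(n_genes / n_chroms)
    chrom <- paste0("chr", rep(seq_len(n_chroms), each = per_chrom))[
      seq_len(n_genes)]
    symbols <- c(.NAMED_GENES$gene_symbol,
                 sprintf("G%04d", seq_len(n_genes - nrow(.NAMED_GENES))))
    nres <- c(.NAMED_GENES$n_residues,
              sample(60:400, n_genes - nrow(.NAMED_GENES), replace = TRUE))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    strand[1] <- "+"  # ERBB2 fixed; its forced junction codon (below)

    cursor <- stats::setNames(rep(1000L, n_chroms),
                              paste0("chr", seq_len(n_chroms)))
    genes <- vector("list", n_genes)
    segs <- vector("list", n_genes)
    coords <- vector("list", n_genes)
    gtf <- vector("list", n_genes)

    for (i in seq_len(n_genes)) {
      len <- 3L * nres[i]
      n_ex <- sample(1:4, 1)
      if (i == 1) {
        ## guarantee a junction-spanning codon: first exon length = 1 mod 3
        n_ex <- 3L
        lens <- c(100L, 350L, len - 450L)
      } else if (n_ex == 1) {
        lens <- len
      } else {
        cuts <- sort(sample(len - 1L, n_ex - 1L))
        lens <- diff(c(0L, cuts, len))
      }
      ## coding-order frames, GTF convention
      before <- cumsum(c(0L, lens[-length(lens)]))
      frame <- (3L - before %% 3L) %% 3L

      ## genomic layout: ascending blocks; coding order follows strand
      glens <- if (strand[i] == "+") lens else rev(lens)
      gaps <- if (n_ex > 1) sample(80:800, n_ex - 1, replace = TRUE)
              else integer()
      starts <- cursor[chrom[i]] + cumsum(c(0L, glens[-n_ex] + gaps))
      ends <- starts + glens - 1L
      cursor[chrom[i]] <- ends[n_ex] + sample(2000:5000, 1)

      ## coding-order view of the genomic blocks
      ord <- if (strand[i] == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      co_start <- starts[ord]; co_end <- ends[ord]
      coords[[i]] <- unlist(lapply(seq_len(n_ex), function(k)
        if (strand[i] == "+") seq.int(co_start[k], co_end[k])
        else seq.int(co_end[k], co_start[k])), use.names = FALSE)

      gid <- sprintf("GENE%04d", i)
      tid <- sprintf("TX%04d", i)
      segs[[i]] <- data.frame(
        chrom = chrom[i], start = co_start, end = co_end,
        strand = strand[i], frame = frame, transcript_id = tid,
        gene_symbol = symbols[i], stringsAsFactors = FALSE)
      genes[[i]] <- data.frame(
        gene_id = gid, gene_symbol = symbols[i], transcript_id = tid,
        chrom = chrom[i], strand = strand[i], n_residues = nres[i],
        cds_length = len, start = starts[1], stringsAsFactors = FALSE)
      ## GTF CDS lines in genomic order
      gord <- order(starts)
      fr_genomic <- frame[match(gord, ord)]
      gtf[[i]] <- sprintf(
        "%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
        chrom[i], starts[gord], ends[gord], strand[i], fr_genomic,
        gid, tid, symbols[i])
    }
    genes <- do.call(rbind, genes)
    names(coords) <- genes$gene_symbol
    model <- list(genes = genes, segments = do.call(rbind, segs),
                  gtf_lines = unlist(gtf), coords = coords)
    class(model) <- "SyntheticGeneModel"
    model
  })
}

#' Generator-side codon coordinates
#'
#' The synthetic generator's own bookkeeping: the three genomic base
#' positions (coding order) of a residue, read straight off the generator's
#' base-by-base CDS coordinate walk. Used to plant variants and as an
#' independent reference for [residueToLocus()].
#'
#' @param model a `SyntheticGeneModel`.
#' @param gene gene symbol.
#' @param residue 1-based residue index.
#' @return data.frame with columns `chrom`, `pos` (3 rows, coding order).
#' @export
codonPositions <- function(model, gene, residue) {
  co <- model$coords[[gene]]
  if (is.null(co)) stop("gene not in model: ", gene)
  if (3 * residue > length(co))
    stop("residue ", residue, " beyond CDS of ", gene)
  g <- model$genes[model$genes$gene_symbol == gene, ]
  data.frame(chrom = g$chrom,
             pos = co[(3L * (residue - 1L) + 1L):(3L * residue)],
             stringsAsFactors = FALSE)
}

#' Write a synthetic gene model as GTF
#'
#' @param model a `SyntheticGeneModel`.
#' @param path output path.
#' @export
writeGeneModelGtf <- function(model, path) {
  writeLines(model$gtf_lines, path)
}

#' @export
print.SyntheticGeneModel <- function(x, ...) {
  cat("SyntheticGeneModel:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosomes\n")
  invisible(x)
}
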