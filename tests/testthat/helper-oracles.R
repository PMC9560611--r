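# Independent oracles: brute-force or definitional re-computations kept
# deliberately separate from the implementations they check.

## spliced-CDS walk: concatenate every base coordinate of the transcript in
## coding order, drop the leading `frame` bases, and read codon positions
## directly off the vector
oracle_residue_positions <- function(segments, residue) {
  segs <- segments[order(ifelse(segments$strand == "-", -segments$start,
                                segments$start)), , drop = FALSE]
  walk <- unlist(lapply(seq_len(nrow(segs)), function(k) {
    s <- segs[k, ]
    if (s$strand == "+") seq.int(s$start, s$end) else seq.int(s$end, s$start)
  }))
  chroms <- rep(segs$chrom, segs$end - segs$start + 1)
  skip <- segs$frame[1]
  if (skip > 0) {
    walk <- walk[-seq_len(skip)]
    chroms <- chroms[-seq_len(skip)]
  }
  idx <- (3 * (residue - 1) + 1):(3 * residue)
  data.frame(chrom = chroms[idx], pos = walk[idx])
}

## random multi-exon transcript covering both strands and all frames; the
## frame-adjusted CDS length is a multiple of 3
oracle_random_transcript <- function(tx_id = "TXR") {
  n_ex <- sample(1:5, 1)
  frame0 <- sample(0:2, 1)
  n_codons <- sample(4:60, 1)
  total <- 3L * n_codons + frame0
  lens <- if (n_ex == 1) total else
    diff(c(0L, sort(sample(total - 1L, n_ex - 1L)), total))
  strand <- sample(c("+", "-"), 1)
  glens <- if (strand == "+") lens else rev(lens)
  gaps <- if (n_ex > 1) sample(5:200, n_ex - 1, replace = TRUE) else integer()
  starts <- 1000L + cumsum(c(0L, glens[-n_ex] + gaps))
  ends <- starts + glens - 1L
  ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  ## GTF frame: bases to skip at each segment's coding-order start (R's %%
  ## is modular, so this also covers a frame0 skip spilling past exon 1)
  before <- c(0L, cumsum(lens)[-n_ex])
  frame <- ifelse(seq_len(n_ex) == 1L, frame0,
                  (3L - ((before - frame0) %% 3L)) %% 3L)
  data.frame(chrom = "chrR", start = starts[ord], end = ends[ord],
             strand = strand, frame = frame, transcript_id = tx_id,
             gene_symbol = "GENER", stringsAsFactors = FALSE)
}

## O(n*m) pair-count Cliff's delta
oracle_cliffs_delta <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

## exhaustive-permutation Mann-Whitney for untied samples: U for x plus the
## two-sided exact p mirroring the standard doubling rule
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  obs <- sum(rank(pool)[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(ii) {
    r <- rank(pool)
    sum(r[ii]) - nx * (nx + 1) / 2
  })
  p_le <- mean(us <= obs)
  p_ge <- mean(us >= obs)
  p <- min(1, 2 * min(p_le, p_ge))
  list(U = obs, p = p)
}

## integer-arithmetic nearest-rank percentile (q integer)
oracle_percentile <- function(values, q) {
  n <- length(values)
  k <- (q * n + 99L) %/% 100L  # smallest k with 100k >= qn
  sort(values)[max(1L, min(k, n))]
}

## direct O(G*W) truncated window mean
oracle_window_mean <- function(m, window) {
  n <- nrow(m)
  hb <- (window - 1) %/% 2
  ha <- window - 1 - hb
  out <- m
  for (i in seq_len(n)) {
    lo <- max(1, i - hb); hi <- min(n, i + ha)
    out[i, ] <- colMeans(m[lo:hi, , drop = FALSE])
  }
  out
}
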