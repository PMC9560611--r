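test_that("residue offsets map correctly on plain single-exon CDS", {
  plus <- CdsModel(data.frame(chrom = "chr1", start = 1001, end = 1099,
                              strand = "+", frame = 0,
                              transcript_id = "T1", gene_symbol = "GA"))
  loc <- residueToLocus("GA", 2, plus)
  expect_equal(locusPositions(loc)$pos, c(1004, 1005, 1006))

  minus <- CdsModel(data.frame(chrom = "chr1", start = 2001, end = 2099,
                               strand = "-", frame = 0,
                               transcript_id = "T2", gene_symbol = "GB"))
  loc2 <- residueToLocus("GB", 1, minus)
  expect_equal(locusPositions(loc2)$pos, c(2099, 2098, 2097))

  ## beyond the CDS
  expect_error(residueToLocus("GA", 34, plus), "beyond CDS")
})

test_that("junction-spanning codons match the spliced-walk oracle", {
  ## + strand, exon1 contributes 1 base of codon 2
  segs <- data.frame(chrom = "chr1", start = c(101, 201), end = c(104, 298),
                     strand = "+", frame = c(0, 2),
                     transcript_id = "TJ", gene_symbol = "GJ")
  loc <- residueToLocus("GJ", 2, CdsModel(segs))
  expect_equal(locusPositions(loc)$pos, c(104, 201, 202))
  expect_equal(locusPositions(loc)$pos,
               oracle_residue_positions(segs, 2)$pos)
})

test_that("residue mapping agrees with the spliced-CDS walk oracle on
           randomized multi-exon transcripts", {
  set.seed(101)
  for (i in 1:60) {
    segs <- oracle_random_transcript()   # rows already in coding order
    cds <- CdsModel(segs)
    n_codons <- (sum(segs$end - segs$start + 1) - segs$frame[1]) %/% 3
    for (r in unique(c(1, sample(n_codons, 2), n_codons))) {
      got <- locusPositions(suppressWarnings(
        residueToLocus("GENER", r, cds)))
      want <- oracle_residue_positions(segs, r)
      expect_equal(got$pos, want$pos)
      expect_equal(got$chrom, want$chrom)
    }
  }
})

test_that("canonical transcript selection prefers longest CDS then id", {
  segs <- data.frame(
    chrom = "chr1", start = c(100, 100, 500), end = c(198, 198, 550),
    strand = "+", frame = 0,
    transcript_id = c("TXB", "TXA", "TXA"),
    gene_symbol = "GM")
  ## TXA total 150 > TXB 100
  loc <- residueToLocus("GM", 1, CdsModel(segs))
  expect_equal(loc@transcript_id, "TXA")

  tie <- data.frame(chrom = "chr1", start = c(100, 100), end = c(198, 198),
                    strand = "+", frame = 0,
                    transcript_id = c("TXB", "TXA"), gene_symbol = "GT")
  expect_equal(residueToLocus("GT", 1, CdsModel(tie))@transcript_id, "TXA")
})

test_that("status calls follow the presence-then-coverage rule", {
  locus <- residueToLocus("GA", 2, CdsModel(data.frame(
    chrom = "chr1", start = 1001, end = 1099, strand = "+", frame = 0,
    transcript_id = "T1", gene_symbol = "GA")))
  no_calls <- data.frame(cell_id = character(), gene_symbol = character(),
                         protein_change_short = character())
  call <- data.frame(cell_id = "c1", gene_symbol = "GA",
                     protein_change_short = "L2S")
  track <- function(depths) DepthTrack("c1", data.frame(
    chrom = "chr1", pos = c(1004, 1005, 1006), depth = depths))

  expect_equal(callStatus(locus, "GA", "L2S", no_calls, track(c(5, 5, 5))),
               "absent")
  expect_equal(callStatus(locus, "GA", "L2S", no_calls, track(c(5, 4, 7))),
               "insufficient")
  ## presence overrides depth entirely
  expect_equal(callStatus(locus, "GA", "L2S", call, track(c(1, 1, 2))),
               "present")
})

test_that("status call truth table is exact on the full depth grid", {
  locus <- residueToLocus("GA", 1, CdsModel(data.frame(
    chrom = "chr1", start = 1001, end = 1099, strand = "+", frame = 0,
    transcript_id = "T1", gene_symbol = "GA")))
  call <- data.frame(cell_id = "c1", gene_symbol = "GA",
                     protein_change_short = "M1V")
  no_call <- call[0, ]
  grid <- expand.grid(d1 = 0:6, d2 = 0:6, d3 = 0:6, has_call = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tr <- DepthTrack("c1", data.frame(chrom = "chr1", pos = 1001:1003,
                                      depth = as.integer(c(g$d1, g$d2, g$d3))))
    got <- callStatus(locus, "GA", "M1V",
                      if (g$has_call) call else no_call, tr, min_depth = 5)
    want <- if (g$has_call) "present"
            else if (min(g$d1, g$d2, g$d3) >= 5) "absent"
            else "insufficient"
    expect_identical(got, want)
  }
})

test_that("raising min_depth only converts absent to insufficient", {
  set.seed(21)
  locus <- residueToLocus("GA", 3, CdsModel(data.frame(
    chrom = "chr1", start = 1001, end = 1099, strand = "+", frame = 0,
    transcript_id = "T1", gene_symbol = "GA")))
  no_call <- data.frame(cell_id = character(), gene_symbol = character(),
                        protein_change_short = character())
  call <- data.frame(cell_id = "c1", gene_symbol = "GA",
                     protein_change_short = "K3R")
  for (i in 1:40) {
    dd <- sample(0:12, 3, replace = TRUE)
    tr <- DepthTrack("c1", data.frame(chrom = "chr1", pos = 1007:1009,
                                      depth = dd))
    has <- i %% 2 == 0
    cd <- if (has) call else no_call
    s_lo <- callStatus(locus, "GA", "K3R", cd, tr, min_depth = 3)
    s_hi <- callStatus(locus, "GA", "K3R", cd, tr, min_depth = 8)
    if (has) {
      expect_identical(s_lo, "present"); expect_identical(s_hi, "present")
    } else {
      expect_false(s_lo == "insufficient" && s_hi == "absent")
    }
  }
})

test_that("status matrix ranks by presence with lexicographic tie-break", {
  cds <- CdsModel(data.frame(chrom = "chr1",
    start = c(1000, 3000, 5000), end = c(1998, 3998, 5998),
    strand = "+", frame = 0,
    transcript_id = c("T1", "T2", "T3"),
    gene_symbol = c("AAA", "BBB", "CCC")))
  cells <- sprintf("c%02d", 1:12)
  mk <- function(gene, pcs, cls) data.frame(cell_id = cls,
    gene_symbol = gene, protein_change_short = pcs,
    oncogenicity = "Oncogenic", chrom = "chr1", pos = 1L, ref = "A",
    alt = "G", qual = 40)
  calls <- rbind(mk("CCC", "L5S", cells[1:10]),
                 mk("AAA", "K9R", cells[1:7]),
                 mk("BBB", "A2G", cells[4:10]))
  depths <- setNames(lapply(cells, DepthTrack), cells)

  sm <- buildStatusMatrix(cells, calls, cds, depths, top_k = 2)
  a <- statusAlterations(sm)
  expect_equal(nrow(a), 2)
  expect_equal(a$gene_symbol, c("CCC", "AAA"))  # 10 first; tie 7/7 -> AAA
  expect_equal(a$n_present, c(10L, 7L))

  ## per-row present count equals the alteration cell frequency
  expect_equal(unname(rowSums(statusGrid(sm) == "present")),
               a$n_present)

  ## top_k beyond the number of alterations returns everything
  sm_all <- buildStatusMatrix(cells, calls, cds, depths, top_k = 25)
  expect_equal(nrow(statusAlterations(sm_all)), 3)

  ## a cell with empty depth and no calls is entirely insufficient
  expect_true(all(statusGrid(sm_all)[, "c12"] == "insufficient"))
})

test_that("unmappable alterations are excluded with a warning", {
  cds <- CdsModel(data.frame(chrom = "chr1", start = 1000, end = 1029,
                             strand = "+", frame = 0,
                             transcript_id = "T1", gene_symbol = "AAA"))
  calls <- data.frame(cell_id = "c1",
                      gene_symbol = c("AAA", "ZZZ"),
                      protein_change_short = c("L2S", "L5S"),
                      oncogenicity = "Oncogenic", chrom = "chr1", pos = 1L,
                      ref = "A", alt = "G", qual = 40)
  expect_warning(
    sm <- buildStatusMatrix("c1", calls, cds,
                            list(c1 = DepthTrack("c1"))),
    "unresolvable")
  expect_equal(statusAlterations(sm)$gene_symbol, "AAA")
})
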