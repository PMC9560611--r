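test_that("readAnnotatedVcf transcribes ANN fields and decomposes records", {
  p <- write_vcf_body(c(
    vcf_line("chr17", 39724001, "T", "C", 52.1,
             paste0("ANN=", ann_entry("C", "missense_variant", "ERBB2",
                                      "p.Leu755Ser", tx = "ENST001"))),
    vcf_line("chr1", 100, "A", "G,T", 45,
             paste0("ANN=", ann_entry("G", "missense_variant", "GENEB",
                                      "p.Ala2Gly"), ",",
                    ann_entry("T", "intron_variant", "GENEB"))),
    vcf_line("chr2", 200, "C", "A", 31)))
  vs <- readAnnotatedVcf(p, "cellA")
  v <- variantTable(vs)
  a <- annotationTable(vs)

  expect_equal(nrow(v), 4)  # 1 + 2 (multiallelic split) + 1
  expect_true(all(v$cell_id == "cellA"))

  first <- a[a$variant_id == v$variant_id[v$pos == 39724001], ]
  expect_equal(first$gene_symbol, "ERBB2")
  expect_equal(first$hgvs_p, "p.Leu755Ser")
  expect_equal(first$transcript_id, "ENST001")

  multi <- v[v$pos == 100, ]
  expect_equal(nrow(multi), 2)
  expect_setequal(multi$alt, c("G", "T"))
  expect_equal(multi$chrom, c("chr1", "chr1"))
  ## each decomposed allele received its own matching annotation
  ann_g <- a[a$variant_id == multi$variant_id[multi$alt == "G"], ]
  expect_equal(ann_g$hgvs_p, "p.Ala2Gly")
  ann_t <- a[a$variant_id == multi$variant_id[multi$alt == "T"], ]
  expect_equal(ann_t$effect_terms[[1]], "intron_variant")

  ## record with no ANN: empty annotations
  expect_false(v$variant_id[v$pos == 200] %in% a$variant_id)
})

test_that("effect terms are split on & and biallelic files map 1:1", {
  p <- write_vcf_body(c(
    vcf_line("chr1", 10, "A", "G", 40,
             paste0("ANN=", ann_entry("G",
               "splice_region_variant&intron_variant", "GENEC"))),
    vcf_line("chr1", 20, "C", "T", 40),
    vcf_line("chr1", 30, "G", "A", 40)))
  vs <- readAnnotatedVcf(p, "c1")
  expect_equal(nVariants(vs), 3)  # N biallelic lines -> N variants
  terms <- annotationTable(vs)$effect_terms[[1]]
  expect_equal(terms, c("splice_region_variant", "intron_variant"))
})

test_that("malformed records and unknown ANN layouts are handled", {
  bad <- write_vcf_body(vcf_line("chr1", 10, "XX", "G", 40))
  expect_error(readAnnotatedVcf(bad, "c"), "malformed VCF record 1")
  odd <- write_vcf_body(vcf_line("chr1", 10, "A", "G", 40,
                                 "ANN=G|missense_variant|MODERATE"))
  expect_warning(vs <- readAnnotatedVcf(odd, "c"), "unrecognized layout")
  expect_equal(nrow(annotationTable(vs)), 0)
})

test_that("readCommonSites decomposes multiallelic lines", {
  p <- write_vcf_body(c(vcf_line("chr1", 100, "A", "G", "."),
                        vcf_line("chr2", 50, "C", "G,T", ".")))
  s <- readCommonSites(p)
  expect_equal(nrow(s), 3)
  expect_setequal(s$alt[s$chrom == "chr2"], c("G", "T"))

  empty <- write_vcf_body(character())
  expect_equal(nrow(readCommonSites(empty)), 0)
})

test_that("readCdsModel orders segments in coding order per strand", {
  p <- write_gtf(c(gtf_cds("chr1", 1001, 1099, "+", 0),
                   gtf_cds("chr2", 2001, 2050, "-", 0, gene = "GENEB",
                           tx = "TX2"),
                   gtf_cds("chr2", 2101, 2150, "-", 2, gene = "GENEB",
                           tx = "TX2")))
  cds <- readCdsModel(p)
  s <- cdsSegments(cds)
  minus <- s[s$transcript_id == "TX2", ]
  expect_equal(minus$start, c(2101, 2001))  # higher coordinates first on -
  expect_equal(minus$frame, c(2, 0))

  exon_only <- write_gtf(paste("chr1\tsim\texon\t1\t10\t.\t+\t.",
                               "\tgene_id \"G\"; transcript_id \"T\";"))
  expect_warning(empty <- readCdsModel(exon_only), "no CDS")
  expect_equal(nrow(cdsSegments(empty)), 0)
})

test_that("depth tracks default to zero and resolve duplicates last-wins", {
  p <- tempfile()
  writeLines(c("chr1\t10\t7", "chr1\t11\t4"), p)
  d <- readDepthTrack(p, "c1")
  expect_equal(depthAt(d, c("chr1", "chr1", "chr2"), c(10, 12, 10)),
               c(7L, 0L, 0L))

  writeLines(character(), p)
  expect_equal(depthAt(readDepthTrack(p, "c1"), "chr1", 10), 0L)

  writeLines(c("chr1\t10\t7", "chr1\t10\t3"), p)
  expect_warning(d2 <- readDepthTrack(p, "c1"), "duplicate")
  expect_equal(depthAt(d2, "chr1", 10), 3L)

  writeLines("chr1\t10\tx", p)
  expect_error(readDepthTrack(p, "c1"), "non-integer")
})

test_that("expression matrices sort into genomic order and round-trip", {
  m <- matrix(c(1.5, 2, 3, 4.25, 5, 6), nrow = 3,
              dimnames = list(NULL, c("c1", "c2")))
  se <- make_expr(m, chrom = c("chr2", "chr1", "chr1"),
                  start = c(100, 500, 50), genes = c("B", "C", "A"))
  rd <- SummarizedExperiment::rowData(se)
  expect_equal(rd$gene_symbol, c("A", "C", "B"))  # (chrom, start) order

  p <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(se, p)
  back <- readExpressionMatrix(p)
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(se), tolerance = 1e-12)
  expect_equal(colnames(back), colnames(se))

  ## 1x1 exact round trip
  one <- make_expr(matrix(42L), genes = "Z")
  writeExpressionMatrix(one, p)
  expect_identical(as.vector(SummarizedExperiment::assay(
    readExpressionMatrix(p))), 42L)

  ## non-numeric cell is reported with gene and column
  writeLines(c("gene_symbol\tchrom\tstart\tc1", "A\tchr1\t1\toops"), p)
  expect_error(readExpressionMatrix(p), "gene 'A', cell column 'c1'")

  ## duplicate gene on same chrom/start is rejected
  writeLines(c("gene_symbol\tchrom\tstart\tc1", "A\tchr1\t1\t5",
               "A\tchr1\t1\t6"), p)
  expect_error(readExpressionMatrix(p), "duplicate")
})

test_that("variant sets round-trip through VCF write/read", {
  v <- data.frame(variant_id = 1:2, cell_id = "cellZ",
                  chrom = c("chr1", "chr2"), pos = c(123L, 456L),
                  ref = c("A", "C"), alt = c("G", "T"),
                  qual = c(31.25, 58.904))
  a <- data.frame(variant_id = 2L, gene_symbol = "TP53",
                  effect_terms = I(list(c("missense_variant"))),
                  hgvs_p = "p.Tyr205Cys", transcript_id = "TXZ")
  p <- tempfile(fileext = ".vcf")
  writeVariantVcf(VariantSet(v, a), p)
  back <- readAnnotatedVcf(p, "cellZ")
  bv <- variantTable(back)
  expect_equal(bv[, c("chrom", "pos", "ref", "alt", "qual")],
               v[, c("chrom", "pos", "ref", "alt", "qual")],
               tolerance = 1e-12)
  ba <- annotationTable(back)
  expect_equal(ba$gene_symbol, "TP53")
  expect_equal(ba$hgvs_p, "p.Tyr205Cys")
  expect_equal(bv$pos[match(ba$variant_id, bv$variant_id)], 456L)
})
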