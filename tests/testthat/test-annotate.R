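test_that("quality filter is inclusive at the threshold", {
  vs <- make_variants("c1", "chr1", c(10, 20, 30), "A", "G",
                      qual = c(30.0, 29.99, 45))
  kept <- variantTable(filterQuality(vs, 30))
  expect_equal(kept$pos, c(10, 30))  # 30.0 kept, 29.99 removed

  empty <- make_variants(character(), character(), integer(), character(),
                         character(), numeric())
  expect_equal(nVariants(filterQuality(empty, 30)), 0)
})

test_that("common-site removal is allele-exact", {
  vs <- make_variants("c1", "chr1", c(100, 100), "A", c("G", "T"),
                      qual = 40)
  sites <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G")
  out <- variantTable(removeCommonSites(vs, sites))
  expect_equal(out$alt, "T")  # same position, different allele: kept

  expect_equal(nVariants(removeCommonSites(vs,
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character()))), 2)

  pos_out <- variantTable(removeCommonSites(vs, sites, positional = TRUE))
  expect_equal(nrow(pos_out), 0)
})

test_that("HGVS protein changes normalize to catalog compact form", {
  expect_equal(normalizeProteinChange("p.Leu755Ser"), "L755S")
  expect_equal(normalizeProteinChange("p.His1047Arg"), "H1047R")
  expect_equal(normalizeProteinChange("p.Val322fs"), "V322fs")
  expect_equal(normalizeProteinChange("p.Gln3478*"), "Q3478*")
  expect_equal(normalizeProteinChange("p.Gln3478Ter"), "Q3478*")
  expect_equal(normalizeProteinChange("Tyr205Cys"), "Y205C")  # bare form
  ## frameshift with alt residue and Ter extension keeps ref+pos+fs only
  expect_equal(suppressWarnings(
    normalizeProteinChange("p.Val322LeufsTer12")), "V322fs")
  expect_warning(out <- normalizeProteinChange("p.Leu75dup"), "unparseable")
  expect_equal(out, "")
  expect_equal(suppressWarnings(normalizeProteinChange(
    c("p.Leu755Ser", "garbage"))), c("L755S", ""))
})

test_that("driver matching honors labels and collapses duplicates", {
  v <- data.frame(variant_id = 1:4, cell_id = c("c1", "c1", "c1", "c2"),
                  chrom = "chr1", pos = c(10L, 11L, 12L, 10L), ref = "A",
                  alt = "G", qual = 40)
  a <- data.frame(
    variant_id = 1:4,
    gene_symbol = c("erbb2", "TP53", "TP53", "BRCA2"),
    effect_terms = I(replicate(4, "missense_variant", simplify = FALSE)),
    hgvs_p = c("p.Leu755Ser", "p.Tyr205Cys", "p.Tyr205Cys", "p.Thr100Met"),
    transcript_id = "TX")
  calls <- matchDrivers(VariantSet(v, a), toy_catalog())

  ## gene matching case-insensitive; duplicate TP53 Y205C collapses;
  ## Likely Neutral BRCA2 entry yields no call
  expect_equal(nrow(calls), 2)
  expect_setequal(paste(calls$gene_symbol, calls$protein_change_short),
                  c("ERBB2 L755S", "TP53 Y205C"))
  expect_true(all(calls$cell_id == "c1"))
  expect_true(all(calls$oncogenicity %in%
                  driverLabels(toy_catalog())))
})

test_that("effect classes count each variant once per class", {
  v <- data.frame(variant_id = 1:4, cell_id = "c1", chrom = "chr1",
                  pos = 1:4 * 10L, ref = "A", alt = "G", qual = 40)
  a <- data.frame(
    variant_id = c(1L, 2L, 2L, 3L),
    gene_symbol = "GENEA",
    effect_terms = I(list("splice_donor_variant",
                          c("splice_region_variant", "intron_variant"),
                          "splice_acceptor_variant",
                          "missense_variant")),
    hgvs_p = c("", "", "", "p.Ala2Gly"),
    transcript_id = "TX")
  cc <- countEffectClasses(VariantSet(v, a))
  expect_equal(cc$n_total, 4)    # variant 4 has no annotation, still total
  expect_equal(cc$n_coding, 1)
  expect_equal(cc$n_splice, 2)   # variant 2 counted once despite two hits
})

test_that("packaged toy VCF matches its hand-enumerated composition", {
  vcf <- system.file("extdata", "toy_cell.vcf", package = "scDriverLoad")
  sites <- readCommonSites(system.file("extdata", "toy_common_sites.vcf",
                                       package = "scDriverLoad"))
  vs <- readAnnotatedVcf(vcf, "TOY")
  expect_equal(nVariants(vs), 50)

  q <- filterQuality(vs, 30)
  expect_equal(nVariants(q), 40)          # 10 records at qual 25 removed
  both <- removeCommonSites(q, sites)
  expect_equal(nVariants(both), 34)       # 6 further allele-exact matches
  ## the allele-mismatched common entry at pos 1040 does not remove
  expect_true(1040 %in% variantTable(both)$pos)
  cc <- countEffectClasses(both)
  expect_equal(cc$n_coding, 3)
  expect_equal(cc$n_splice, 1)
})

test_that("filters are monotone, idempotent, and conserve count ordering", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 60
    vs <- make_variants(sample(c("c1", "c2"), n, TRUE), "chr1",
                        sample(500, n), "A",
                        sample(c("G", "T"), n, TRUE),
                        qual = round(runif(n, 0, 60), 1))
    sites_sm <- data.frame(chrom = "chr1", pos = sample(500, 30),
                           ref = "A", alt = "G")
    sites_lg <- rbind(sites_sm, data.frame(chrom = "chr1",
                      pos = sample(500, 100), ref = "A", alt = "T"))

    ## raising min_qual never increases counts
    q1 <- nVariants(filterQuality(vs, 20))
    q2 <- nVariants(filterQuality(vs, 30))
    q3 <- nVariants(filterQuality(vs, 50))
    expect_true(q1 >= q2 && q2 >= q3)

    ## enlarging the site set never increases counts
    expect_gte(nVariants(removeCommonSites(vs, sites_sm)),
               nVariants(removeCommonSites(vs, sites_lg)))

    ## idempotence
    f1 <- filterQuality(vs, 30)
    expect_equal(variantTable(filterQuality(f1, 30)), variantTable(f1))
    r1 <- removeCommonSites(vs, sites_sm)
    expect_equal(variantTable(removeCommonSites(r1, sites_sm)),
                 variantTable(r1))
  }
})

test_that("per-cell driver load never exceeds coding or total counts", {
  d <- tempfile()
  cfg <- cohortConfig(seed = 3, n_normal = 15, n_tumor = 10,
                      n_common_sites = 50)
  generateCohort(cfg, out_dir = d)
  catalog <- readDriverCatalog(file.path(d, "catalog.tsv"))
  sites <- readCommonSites(file.path(d, "common_sites.vcf"))
  cells <- sub("\\.vcf$", "", list.files(file.path(d, "vcf")))
  vs <- combineVariantSets(lapply(cells, function(cl)
    readAnnotatedVcf(file.path(d, "vcf", paste0(cl, ".vcf")), cl)))
  f <- removeCommonSites(filterQuality(vs, 30), sites)
  cc <- countEffectClasses(f, cells = cells)
  calls <- matchDrivers(f, catalog)
  nd <- table(factor(calls$cell_id, levels = cells))
  expect_true(all(as.integer(nd) <= cc$n_coding))
  expect_true(all(cc$n_coding <= cc$n_total))
})
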