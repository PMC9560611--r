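# Fixture builders: small VCF/GTF/TSV inputs assembled in code.

vcf_header <- c(
  "##fileformat=VCFv4.2",
  paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
         "annotations: Allele | Annotation | Annotation_Impact | Gene_Name",
         " | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | ",
         "Rank | HGVS.c | HGVS.p | etc\">"),
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")

write_vcf_body <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c(vcf_header, body), path)
  path
}

ann_entry <- function(allele, effects, gene, hgvs_p = "", tx = "TX1") {
  paste(allele, effects, "MOD", gene, "GID", "transcript", tx,
        "protein_coding", ".", ".", hgvs_p, "", "", "", "", "", sep = "|")
}

vcf_line <- function(chrom, pos, ref, alt, qual, info = ".") {
  paste(chrom, pos, ".", ref, alt, qual, ".", info, sep = "\t")
}

write_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_cds <- function(chrom, start, end, strand, frame, gene = "GENEA",
                    tx = "TX1") {
  sprintf(paste0("%s\tsim\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id \"%s\"; ",
                 "transcript_id \"%s\"; gene_name \"%s\";"),
          chrom, start, end, strand, frame, gene, tx, gene)
}

## a minimal catalog with one entry per call type
toy_catalog <- function() {
  DriverCatalog(data.frame(
    gene_symbol = c("ERBB2", "PIK3CA", "TP53", "NCOR1", "KMT2C", "BRCA2"),
    protein_change_short = c("L755S", "H1047R", "Y205C", "V322fs",
                             "Q3478*", "T100M"),
    oncogenicity = c("Oncogenic", "Oncogenic", "Likely Oncogenic",
                     "Likely Oncogenic", "Likely Oncogenic",
                     "Likely Neutral"),
    stringsAsFactors = FALSE))
}

## VariantSet built directly from vectors (annotation-free)
make_variants <- function(cell_id, chrom, pos, ref, alt, qual) {
  VariantSet(data.frame(variant_id = seq_along(pos), cell_id = cell_id,
                        chrom = chrom, pos = pos, ref = ref, alt = alt,
                        qual = qual, stringsAsFactors = FALSE))
}

## expression SummarizedExperiment from a plain matrix, genes on one or more
## chromosomes in the given order
make_expr <- function(m, chrom = rep("chr1", nrow(m)),
                      start = seq_len(nrow(m)) * 100,
                      genes = sprintf("G%03d", seq_len(nrow(m))),
                      cells = sprintf("C%02d", seq_len(ncol(m)))) {
  ExpressionMatrix(m, genes = data.frame(gene_symbol = genes, chrom = chrom,
                                         start = start), cells = cells)
}
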