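---
title: "Driver-alteration load and inferred CNV: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver-alteration load and inferred CNV: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

scDriverLoad treats cancer-cell identification in full-length-transcript
scRNA-seq as a two-axis outlier problem against a normal-cell baseline.

**Axis 1 — driver load.** For each cell, variant calls are filtered at a
minimum phred-scaled quality of 30 (inclusive), stripped of
population-common alleles, and matched against a local oncogenicity
catalog. The catalog maps (gene symbol, compact protein change) pairs to
labels; an alteration counts as a putative driver when its label is
Oncogenic, Likely Oncogenic, or Predicted Oncogenic. The driver load
`n_drivers` is the number of *unique* (gene, protein change) pairs called
in the cell, so several reads or transcripts supporting the same
alteration count once.

**Axis 2 — CNV burden.** Per cell, the mean over genes of the absolute
inferred-CNV expression score. Score matrices from external CNV-inference
tools are consumed as-is through `readExpressionMatrix()`; alternatively
`windowedCnvScores()` provides a deliberately simplified internal scorer
(below).

**Baseline and classification.** Both axes are summarized over cells of
known non-cancer origin by the nearest-rank 99th percentile. A cell is
high on an axis when it strictly exceeds the cutoff ("high" means `> 5
putative drivers` when the cutoff is 5, never `>=`). The 2x2 combination
gives four regions; `HIGH_DRIVER_ONLY` cells are the ones CNV-based
filtering alone would discard despite a driver profile incompatible with
normal tissue.

### Assumptions

- Variant quality is the site-level QUAL of the caller. The quality filter
  is applied to that field; genotype-level metrics are not consulted.
- A call decides presence on its own. Read depth is used *only* to decide
  whether a non-call means absent: a cell is `absent` for an alteration
  when all three bases of the encoding codon have depth >= `min_depth`
  (default 5), and `insufficient` otherwise. Raising `min_depth` can only
  convert `absent` to `insufficient`.
- Annotation (`ANN`) strings follow the SnpEff >= 4.1 positional layout;
  they are parsed, not recomputed.

## Residue-to-genome mapping

The codon of residue *r* occupies coding offsets `3(r-1)+1 .. 3r` along
the transcript CDS walked in coding order: ascending genomic coordinates
on the + strand, descending on -. The GTF `frame` of the first CDS segment
shifts the walk start (the implementation also tolerates a frame skip that
spills past a short first exon, using modular arithmetic). Codons may span
exon junctions, in which case the three bases are non-contiguous.

Design choices where the convention was open:

- **Transcript selection.** When a gene has several transcripts, the one
  with the longest total CDS is used; ties break to the lexicographically
  smallest transcript id. This is the common "canonical transcript" proxy
  and is overridable via `transcript_id=`.
- **Partial codons.** Transcripts whose frame-adjusted CDS length is not a
  multiple of 3 are accepted with a warning; only the trailing partial
  codon is unmappable.
- **Frameshift/stop alterations** map to the residue index parsed from the
  compact change string (`V322fs` maps residue 322), the same rule as
  missense.
- **Catalog matching** is case-insensitive on gene symbol and exact on the
  compact change; frameshifts compare reference residue + position + `fs`
  only (catalog convention), so `p.Val322LeufsTer12` matches `V322fs`.
  Duplication/extension/delins HGVS forms are left unmatched with a
  warning rather than guessed.
- **Common-site removal** is allele-exact on (chrom, pos, ref, alt);
  positional removal would silently delete somatic alleles co-located with
  common SNPs. A `positional = TRUE` switch exists for fidelity
  experiments.

## The simplified CNV scorer

`windowedCnvScores()` is an explicitly simplified, expression-only
stand-in for full CNV-inference tools, provided so the pipeline is
self-contained; its output is format-compatible with externally produced
score matrices, which should be preferred for real data. Per gene and
cell it computes `log2(TPM + 1)` (pseudocount 1), subtracts the per-gene
mean over the reference normal cells, and smooths with a centered moving
average over a genomic window of `window` genes (default 100) within each
chromosome. Numerical conventions, chosen once for determinism:

- window rows `i - floor((w-1)/2) .. i + ceil((w-1)/2)`, truncated (not
  wrapped) at chromosome ends, so `window = 1` returns the centered log
  ratios unchanged;
- a chromosome with fewer than 2 genes is left unsmoothed with a warning;
- no segmentation and no aneuploid/diploid calling — ploidy labels from
  external tools are accepted as optional metadata, not recomputed;
- the per-cell summary averages |score| over *all* scored genes, with no
  gene subsetting.

## Quality control

`qcFilter()` log-transforms (`log1p`) library size, expressed-gene count
and total mRNA, and excludes a cell when any metric falls below
`median - 4 * MAD` (lower tail only — bright cells are not removed). The
MAD uses the normal-consistency constant 1.4826, the prevailing scRNA-seq
QC convention (`mad_constant = 1` gives the raw MAD). An absolute floor of
1000 expressed genes is applied on top. With a small synthetic gene panel
the floor must be scaled to the panel (the end-to-end runs here use 100,
half the default 200-gene panel). Note that with strongly discrete
metrics (nearly all cells expressing every panel gene) the MAD can
degenerate to 0, in which case any cell below the median is excluded;
cells exactly at the median are kept.

## Statistics

- **Mann-Whitney U** delegates to `stats::wilcox.test`: exact enumeration
  when both samples have <= 8 observations and no ties, otherwise the
  normal approximation with tie-corrected variance and continuity
  correction. Extremely small p-values on large cohorts are therefore
  approximation-regime values by construction.
- **Cliff's delta** is computed through midranks; the numerator
  `2*U1 - n*m` is the exact integer pair-count margin, so the result is
  bit-identical to the O(nm) double loop.
- **Correlations** per patient: Pearson on raw values; Spearman computed
  as Pearson on midranks; two-sided p-values via the t-transform with
  n - 2 degrees of freedom. Patients with < 3 usable cells or zero
  variance are reported with missing statistics.
- **Percentiles** are nearest-rank: the `ceil(q/100 * n)`-th smallest
  value — deterministic and integer-friendly for count data (the product
  is rounded to 9 decimals before the ceiling so exact rank boundaries are
  stable under floating point). Each baseline threshold is computed over
  the normal cells carrying the relevant measurement, and the
  contributing n is recorded per threshold, because QC, variant analysis
  and CNV scoring can each drop different cells.

## What the synthetic generator emulates

`generateCohort()` produces a complete, seeded input set. Its defaults are
the study conditions the package validates against:

- **Normal driver counts** follow a point mass at zero with probability
  0.513 plus a zero-truncated Poisson whose rate (~1.443) is solved so
  the overall mean is 0.92, truncated above at 9. This is the simplest
  family that reproduces all three published baseline moments (zero
  fraction, mean, maximum) simultaneously; a plain zero-inflated Poisson
  cannot hit a 51.3% zero fraction and mean 0.92 with that zero-inflation
  mass.
- **Tumor cells** (300 by default, vs 1000 normals) draw Poisson(6)
  random catalog drivers plus recurrent shared drivers — ERBB2 L755S at
  penetrance 0.6, PIK3CA H1047R at 0.25, TP53 Y205C at 0.15 — mimicking
  clonal driver structure.
- **Planted variant qualities** are uniform in [30, 60], so the quality
  filter is exercised but never removes planted truth; a separate decoy
  knob plants sub-threshold records (qualities in [5, 29.5]).
- **Depth tracks** cover every catalog driver locus. A (cell, locus) pair
  drops out with probability 0.3; covered loci draw per-base depth as
  `5 + NB(mean 15, size 3)`, so the non-dropout fraction of non-carrier
  cells is guaranteed callable `absent`. This floor is the generator's
  coverage guarantee, not a property of real data.
- **Expression** is log-normal per gene (baseline log2 mean 5 — deep
  per-gene coverage typical of full-length protocols — SD 1) with
  cell-level size factors (SD 0.15 in log2), per-entry noise (SD 0.15)
  and Poisson sampling. One planted copy-number block (chr1, 40 genes,
  log2 shift 0.8) affects 35% of tumor cells; at these settings planted
  aneuploid cells separate from all diploid cells on mean |CNV|, which is
  a design requirement of the generator, not a claim about effect sizes
  in real tumors.
- Background variants (mean 30/cell, 40% drawn from the emitted
  common-sites pool, 10% with splice annotations) exercise the common-SNP
  filter and the effect-class tallies without ever colliding with catalog
  entries, so driver-count recovery against ground truth is exact by
  construction.

What it does **not** emulate: read-level noise (no FASTQ/BAM), allelic
dropout correlated with expression, doublets, ambient RNA, transcript
sequence content, annotation errors, or germline variation beyond the
common-site pool. Passing the end-to-end checks therefore demonstrates
the correctness of the plumbing and the discriminative behavior of the
statistics under the stated model — not calling performance on real data.

## Validation problem sizes

The test suite checks the absence rule on the exhaustive depth grid
{0..6}^3 x {call, no-call}; residue mapping against a base-by-base
spliced-CDS walk on 200 randomized multi-exon transcripts (both strands,
all leading frames, 1-5 exons); the statistics against brute-force
pair-count, exhaustive-permutation and definitional oracles; percentiles
against a sort-and-index oracle on 1000 random vectors including ties and
constant vectors; baseline calibration on 5000 generator draws; and
end-to-end recovery on a 1000 + 300-cell cohort, where recovered driver
counts equal planted counts for every cell and two identical runs produce
byte-identical outputs apart from the manifest timestamp.

## Known limitations

- Upstream read processing (trimming, alignment, pileup, raw calling) and
  effect prediction are out of scope; the package starts from annotated
  VCFs and depth tracks.
- The oncogenicity catalog is a local table; it does not query any
  annotation service, and transcript-specific annotation is not attempted
  (matching is on gene + protein change only).
- The internal CNV scorer has no segmentation model; on small gene panels
  its window can span a whole chromosome, making the score a per-chromosome
  mean.
- The nearest-rank percentile on counts is coarse: with a driver cutoff of
  5, cells with exactly 5 drivers are classed low, and the realized
  normal exceedance can differ from 1% when the count distribution has
  heavy ties at the cutoff.
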