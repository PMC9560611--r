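## Seeded synthetic cohort generation.
##
## Emits a complete pipeline input set -- per-cell annotated VCFs, per-cell
## depth tracks, a counts matrix, an oncogenicity catalog, a common-sites
## VCF, a GTF gene model and a ground-truth table -- whose normal-cell
## driver-count distribution is calibrated to the published normal-tissue
## baseline (51.3% zeros, mean 0.92, maximum 9).

## zero-truncated-Poisson rate whose mean equals target_mean
.ztp_lambda <- function(target_mean) {
  stopifnot(target_mean > 1)
  stats::uniroot(function(l) l / (1 - exp(-l)) - target_mean,
                 c(1e-8, 100))$root
}

#' Sample normal-cell driver counts
#'
#' The normal-baseline count model: a point mass at zero with probability
#' `zero_inflation`, otherwise a zero-truncated Poisson whose rate is
#' solved so the overall mean equals `mean_count`; counts are truncated
#' above at `max_count` by redrawing. With the defaults, the zero
#' fraction is exactly the zero-inflation mass and the distribution
#' matches the published normal-tissue baseline (51.3% zeros, mean 0.92,
#' maximum 9).
#'
#' @param n number of cells.
#' @param zero_inflation point mass at zero (default 0.513).
#' @param mean_count overall mean (default 0.92); must exceed
#'   `1 - zero_inflation`.
#' @param max_count upper truncation (default 9).
#' @return integer vector of driver counts.
#' @export
rNormalDriverCounts <- function(n, zero_inflation = 0.513,
                                mean_count = 0.92, max_count = 9) {
  lam <- .ztp_lambda(mean_count / (1 - zero_inflation))
  out <- integer(n)
  nonzero <- stats::runif(n) >= zero_inflation
  out[nonzero] <- .rztp(sum(nonzero), lam, max_count)
  out
}

## draw zero-truncated Poisson, truncated above at max_k
.rztp <- function(n, lambda, max_k) {
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rpois(length(todo), lambda)
    ok <- draw >= 1 & draw <= max_k
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Cohort configuration
#'
#' Bundles all parameters of the synthetic-cohort generator. The defaults
#' are the study conditions the package is calibrated to: a normal
#' population with zero-inflation 0.513 and overall mean driver count 0.92
#' truncated at 9; tumor cells drawing Poisson(6) drivers plus recurrent
#' shared drivers; one planted copy-number block producing a high-CNV
#' tumor subpopulation.
#'
#' @param seed RNG seed (fixed seed implies byte-identical outputs).
#' @param n_normal,n_tumor cohort sizes (default 1000 normal, 300 tumor).
#' @param normal_zero_inflation probability mass placed directly at zero
#'   for normal driver counts (default 0.513).
#' @param normal_mean overall mean normal driver count (default 0.92); the
#'   non-zero component is zero-truncated Poisson with rate solved from
#'   this mean.
#' @param normal_max hard upper truncation of normal driver counts
#'   (default 9).
#' @param tumor_driver_rate Poisson rate of tumor driver counts (default 6).
#' @param recurrent_drivers data.frame with columns `gene`,
#'   `protein_change_short`, `penetrance`: shared drivers added to tumor
#'   cells with the given penetrance.
#' @param cnv_blocks data.frame with columns `chrom`, `gene_from`,
#'   `gene_to` (gene indices within the chromosome, genomic order),
#'   `log2_shift`, `fraction` (fraction of tumor cells affected).
#' @param depth_mean,depth_size negative-binomial mean and dispersion of
#'   per-base depth at driver loci for covered cells.
#' @param depth_dropout probability that a (cell, locus) pair has no
#'   coverage at all; covered non-carrier loci are guaranteed callable
#'   (depth floor at `min_callable_depth`).
#' @param min_callable_depth depth floor applied to covered loci
#'   (default 5, the absence-calling minimum).
#' @param background_variant_rate mean non-driver variants per cell.
#' @param common_snp_fraction fraction of background variants drawn from
#'   the common-sites list.
#' @param decoy_rate mean sub-quality-threshold decoy variants per cell
#'   (qualities below 30, exercising the quality filter).
#' @param splice_fraction fraction of non-common background variants
#'   annotated with splice effects.
#' @param n_common_sites size of the common-sites pool.
#' @param expr_base_log2_mean,expr_base_log2_sd per-gene baseline log2
#'   expression distribution.
#' @param expr_cell_sd cell-level library-size factor SD (log2).
#' @param expr_noise_sd per-entry log2 noise SD.
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(seed = 1, n_normal = 1000, n_tumor = 300,
    normal_zero_inflation = 0.513, normal_mean = 0.92, normal_max = 9,
    tumor_driver_rate = 6,
    recurrent_drivers = data.frame(
      gene = c("ERBB2", "PIK3CA", "TP53"),
      protein_change_short = c("L755S", "H1047R", "Y205C"),
      penetrance = c(0.6, 0.25, 0.15), stringsAsFactors = FALSE),
    cnv_blocks = data.frame(chrom = "chr1", gene_from = 1, gene_to = 40,
                            log2_shift = 0.8, fraction = 0.35),
    depth_mean = 20, depth_size = 3, depth_dropout = 0.3,
    min_callable_depth = 5,
    background_variant_rate = 30, common_snp_fraction = 0.4,
    decoy_rate = 5, splice_fraction = 0.1, n_common_sites = 500,
    expr_base_log2_mean = 5, expr_base_log2_sd = 1,
    expr_cell_sd = 0.15, expr_noise_sd = 0.15) {
  cfg <- as.list(environment())
  probs <- c(cfg$normal_zero_inflation, cfg$depth_dropout,
             cfg$common_snp_fraction, cfg$splice_fraction,
             cfg$recurrent_drivers$penetrance, cfg$cnv_blocks$fraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$tumor_driver_rate >= 0, cfg$background_variant_rate >= 0,
            cfg$decoy_rate >= 0, cfg$n_normal >= 0, cfg$n_tumor >= 0,
            cfg$normal_mean / (1 - cfg$normal_zero_inflation) > 1)
  class(cfg) <- "CohortConfig"
  cfg
}

## default catalog over the model's named genes plus randomized entries;
## call inside the cohort RNG stream
.build_catalog <- function(model, n_random = 30, n_neutral = 10) {
  fixed <- data.frame(
    gene_symbol = c("ERBB2", "PIK3CA", "PIK3CA", "TP53", "TP53", "TP53",
                    "KRAS", "NCOR1", "KMT2C", "APC", "BRAF", "SMAD4",
                    "PTEN"),
    protein_change_short = c("L755S", "H1047R", "E545K", "Y205C", "P72R",
                             "R175H", "G12D", "V322fs", "Q3478*", "R1450*",
                             "V600E", "R361H", "R130Q"),
    oncogenicity = c("Oncogenic", "Oncogenic", "Oncogenic",
                     "Likely Oncogenic", "Likely Oncogenic", "Oncogenic",
                     "Oncogenic", "Likely Oncogenic", "Likely Oncogenic",
                     "Oncogenic", "Oncogenic", "Likely Oncogenic",
                     "Predicted Oncogenic"),
    stringsAsFactors = FALSE)
  aa <- names(.AA1TO3)
  rand_entry <- function(n, labels) {
    genes <- sample(model$genes$gene_symbol, n, replace = TRUE)
    nres <- model$genes$n_residues[match(genes, model$genes$gene_symbol)]
    pos <- vapply(nres, function(m) sample(2:(m - 1), 1), 0L)
    data.frame(gene_symbol = genes,
               protein_change_short = paste0(sample(aa, n, replace = TRUE),
                                             pos,
                                             sample(aa, n, replace = TRUE)),
               oncogenicity = sample(labels, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  entries <- rbind(fixed,
    rand_entry(n_random, c("Oncogenic", "Likely Oncogenic",
                           "Predicted Oncogenic")),
    rand_entry(n_neutral, c("Likely Neutral", "Inconclusive")))
  entries <- entries[!duplicated(paste(entries$gene_symbol,
                                       entries$protein_change_short)), ]
  rownames(entries) <- NULL
  DriverCatalog(entries)
}

## compact change -> (hgvs_p, effect) for planted driver records
.plant_annotation <- function(pcs) {
  m <- regmatches(pcs, regexec("^([A-Z])(\\d+)(fs|\\*|[A-Z])$", pcs))[[1]]
  ref3 <- unname(.AA1TO3[m[2]])
  if (m[4] == "fs") {
    list(hgvs = paste0("p.", ref3, m[3], "fs"), effect = "frameshift_variant")
  } else if (m[4] == "*") {
    list(hgvs = paste0("p.", ref3, m[3], "*"), effect = "stop_gained")
  } else {
    list(hgvs = paste0("p.", ref3, m[3], unname(.AA1TO3[m[4]])),
         effect = "missense_variant")
  }
}

#' Generate a complete synthetic cohort on disk
#'
#' Draws per-cell driver sets (normal: zero-inflated truncated Poisson
#' calibrated to the normal baseline; tumor: Poisson plus recurrent shared
#' drivers), emits planted drivers as annotated VCF records with qualities
#' in \[30, 60\] (so the quality filter never removes planted truth, while
#' separate sub-threshold decoys exercise it), plants copy-number blocks as
#' multiplicative expression shifts in a fraction of tumor cells, and
#' writes depth tracks at every catalog driver locus with per-cell
#' dropout. Background variants (some drawn from the emitted common-sites
#' list, some with splice or non-catalog missense annotations) are layered
#' on every cell. All randomness derives from `config$seed`; a fixed seed
#' yields a byte-identical file set.
#'
#' @param config a [cohortConfig()].
#' @param model a `SyntheticGeneModel` (default: `generateGeneModel()`
#'   seeded from the config).
#' @param out_dir output directory (created; VCFs under `vcf/`, depth
#'   under `depth/`).
#' @return invisibly, the ground-truth table (also written to
#'   `truth.tsv`): per cell `cell_id`, `group`, `patient_id`,
#'   `tissue_or_dataset`, `n_planted_drivers`, `planted_drivers`
#'   (";"-separated "GENE:change"), `aneuploid`, `expected_qc`.
#' @export
generateCohort <- function(config, model = NULL, out_dir) {
  stopifnot(inherits(config, "CohortConfig"))
  if (is.null(model))
    model <- generateGeneModel(seed = config$seed + 1000L)
  for (g in config$recurrent_drivers$gene)
    if (!g %in% model$genes$gene_symbol)
      stop("recurrent driver gene absent from model: ", g)
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "depth"), showWarnings = FALSE)

  .with_seed(config$seed, {
    catalog <- .build_catalog(model)
    ce <- catalogEntries(catalog)
    drivers <- ce[ce$oncogenicity %in% driverLabels(catalog), ]
    driver_key <- paste(drivers$gene_symbol, drivers$protein_change_short)

    ## residue loci of every catalog driver, from generator bookkeeping
    loci <- lapply(seq_len(nrow(drivers)), function(i) {
      ri <- .residue_index_of(drivers$protein_change_short[i])
      codonPositions(model, drivers$gene_symbol[i], ri)
    })
    names(loci) <- driver_key
    driver_bases <- unique(unlist(lapply(loci, function(p)
      paste0(p$chrom, ":", p$pos))))

    ## ---- cells and planted driver sets ----
    n_n <- config$n_normal; n_t <- config$n_tumor
    cells <- c(sprintf("N%04d", seq_len(n_n)), sprintf("T%04d", seq_len(n_t)))
    group <- rep(c("normal", "tumor"), c(n_n, n_t))
    tissue <- character(n_n + n_t)
    tissue[group == "normal"] <- sample(
      c("pancreas", "liver", "fibroblast", "neutrophil"), n_n,
      replace = TRUE)
    tissue[group == "tumor"] <- "tumor"
    patient <- character(n_n + n_t)
    patient[group == "normal"] <- paste0("NORM_",
                                         tissue[group == "normal"])
    patient[group == "tumor"] <- sample(paste0("PT0", 1:3), n_t,
                                        replace = TRUE)

    n_counts <- rNormalDriverCounts(n_n, config$normal_zero_inflation,
                                    config$normal_mean, config$normal_max)

    planted <- vector("list", n_n + n_t)
    for (i in seq_len(n_n))
      planted[[i]] <- if (n_counts[i])
        sample(driver_key, min(n_counts[i], length(driver_key))) else
        character()
    rec <- config$recurrent_drivers
    rec_key <- paste(rec$gene, rec$protein_change_short)
    for (i in seq_len(n_t)) {
      k <- stats::rpois(1, config$tumor_driver_rate)
      base <- sample(driver_key, min(k, length(driver_key)))
      extra <- rec_key[stats::runif(nrow(rec)) < rec$penetrance]
      planted[[n_n + i]] <- union(base, extra)
    }

    ## ---- common-site pool (never collides with driver codon bases) ----
    chroms <- unique(model$genes$chrom)
    pool_chrom <- sample(chroms, config$n_common_sites, replace = TRUE)
    span <- max(model$segments$end) + 100000L
    repeat {
      pool_pos <- sample.int(span, config$n_common_sites, replace = TRUE)
      if (!any(paste0(pool_chrom, ":", pool_pos) %in% driver_bases)) break
    }
    bases <- c("A", "C", "G", "T")
    pool_ref <- sample(bases, config$n_common_sites, replace = TRUE)
    pool_alt <- vapply(pool_ref, function(r) sample(setdiff(bases, r), 1),
                       "")
    common <- unique(data.frame(chrom = pool_chrom, pos = pool_pos,
                                ref = pool_ref, alt = pool_alt,
                                stringsAsFactors = FALSE))
    common <- common[order(common$chrom, common$pos), ]
    writeCommonSitesVcf(common, file.path(out_dir, "common_sites.vcf"))

    ## ---- per-cell VCFs ----
    splice_effects <- c("splice_donor_variant&intron_variant",
                        "splice_acceptor_variant&intron_variant",
                        "splice_region_variant&intron_variant")
    catalog_key <- paste(ce$gene_symbol, ce$protein_change_short)
    n_bg <- stats::rpois(n_n + n_t, config$background_variant_rate)
    n_decoy <- stats::rpois(n_n + n_t, config$decoy_rate)
    for (i in seq_along(cells)) {
      vrows <- list(); arows <- list(); vid <- 0L
      add <- function(chrom, pos, ref, alt, qual, ann = NULL) {
        vid <<- vid + 1L
        vrows[[vid]] <<- data.frame(variant_id = vid, cell_id = cells[i],
          chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
          qual = qual, stringsAsFactors = FALSE)
        if (!is.null(ann)) {
          ann$variant_id <- vid
          arows[[length(arows) + 1L]] <<- ann
        }
      }
      ## planted drivers
      for (key in planted[[i]]) {
        di <- match(key, driver_key)
        p <- loci[[key]]
        ref <- sample(bases, 1)
        alt <- sample(setdiff(bases, ref), 1)
        pa <- .plant_annotation(drivers$protein_change_short[di])
        tx <- model$genes$transcript_id[
          match(drivers$gene_symbol[di], model$genes$gene_symbol)]
        add(p$chrom[1], p$pos[1], ref, alt,
            round(stats::runif(1, 30, 60), 1),
            data.frame(gene_symbol = drivers$gene_symbol[di],
                       effect_terms = I(list(strsplit(pa$effect, "&")[[1]])),
                       hgvs_p = pa$hgvs, transcript_id = tx,
                       stringsAsFactors = FALSE))
      }
      ## background variants
      if (n_bg[i] > 0) for (j in seq_len(n_bg[i])) {
        if (stats::runif(1) < config$common_snp_fraction) {
          s <- common[sample.int(nrow(common), 1), ]
          add(s$chrom, s$pos, s$ref, s$alt, round(stats::runif(1, 30, 60), 1))
        } else {
          gi <- sample.int(nrow(model$genes), 1)
          pos <- model$genes$start[gi] + sample.int(1000, 1)
          ref <- sample(bases, 1); alt <- sample(setdiff(bases, ref), 1)
          u <- stats::runif(1)
          ann <- if (u < config$splice_fraction) {
            data.frame(gene_symbol = model$genes$gene_symbol[gi],
              effect_terms = I(list(strsplit(sample(splice_effects, 1),
                                             "&")[[1]])),
              hgvs_p = "", transcript_id = model$genes$transcript_id[gi],
              stringsAsFactors = FALSE)
          } else if (u < config$splice_fraction + 0.4) {
            ## non-catalog missense
            repeat {
              r1 <- sample(names(.AA1TO3), 1)
              a1 <- sample(setdiff(names(.AA1TO3), r1), 1)
              ri <- sample.int(model$genes$n_residues[gi], 1)
              pcs <- paste0(r1, ri, a1)
              if (!paste(model$genes$gene_symbol[gi], pcs) %in% catalog_key)
                break
            }
            data.frame(gene_symbol = model$genes$gene_symbol[gi],
              effect_terms = I(list("missense_variant")),
              hgvs_p = paste0("p.", .AA1TO3[r1], ri, .AA1TO3[a1]),
              transcript_id = model$genes$transcript_id[gi],
              stringsAsFactors = FALSE)
          } else NULL
          add(model$genes$chrom[gi], pos, ref, alt,
              round(stats::runif(1, 30, 60), 1), ann)
        }
      }
      ## sub-threshold decoys
      if (n_decoy[i] > 0) for (j in seq_len(n_decoy[i])) {
        gi <- sample.int(nrow(model$genes), 1)
        ref <- sample(bases, 1); alt <- sample(setdiff(bases, ref), 1)
        add(model$genes$chrom[gi],
            model$genes$start[gi] + sample.int(1000, 1), ref, alt,
            round(stats::runif(1, 5, 29.5), 1))
      }
      v <- if (vid) do.call(rbind, vrows) else
        data.frame(variant_id = integer(), cell_id = character(),
                   chrom = character(), pos = integer(), ref = character(),
                   alt = character(), qual = numeric())
      a <- if (length(arows)) do.call(rbind, arows) else NULL
      ord <- order(v$chrom, v$pos)
      v <- v[ord, , drop = FALSE]
      writeVariantVcf(VariantSet(v, a),
                      file.path(out_dir, "vcf", paste0(cells[i], ".vcf")))
    }

    ## ---- depth tracks at every catalog driver locus ----
    all_pos <- do.call(rbind, loci)
    n_loci <- length(loci)
    for (i in seq_along(cells)) {
      carrier <- driver_key %in% planted[[i]]
      covered <- carrier | stats::runif(n_loci) >= config$depth_dropout
      if (any(covered)) {
        idx <- which(covered)
        draw <- config$min_callable_depth + stats::rnbinom(
          3L * length(idx),
          mu = max(config$depth_mean - config$min_callable_depth, 1),
          size = config$depth_size)
        rows <- all_pos[unlist(lapply(idx, function(k)
          (k - 1L) * 3L + 1:3)), ]
        d <- data.frame(chrom = rows$chrom, pos = rows$pos,
                        depth = draw, stringsAsFactors = FALSE)
        d <- d[!duplicated(paste0(d$chrom, ":", d$pos)), ]
        d <- d[order(d$chrom, d$pos), ]
      } else {
        d <- data.frame(chrom = character(), pos = integer(),
                        depth = integer())
      }
      writeDepthTrack(DepthTrack(cells[i], d),
                      file.path(out_dir, "depth", paste0(cells[i], ".tsv")))
    }

    ## ---- expression counts with planted CNV blocks ----
    G <- nrow(model$genes)
    aneuploid <- rep(FALSE, n_n + n_t)
    shift <- matrix(0, G, n_n + n_t)
    blocks <- config$cnv_blocks
    if (!is.null(blocks) && nrow(blocks)) for (b in seq_len(nrow(blocks))) {
      on_chrom <- which(model$genes$chrom == blocks$chrom[b])
      gidx <- on_chrom[blocks$gene_from[b]:min(blocks$gene_to[b],
                                               length(on_chrom))]
      t_idx <- n_n + seq_len(n_t)
      hit <- t_idx[stats::runif(n_t) < blocks$fraction[b]]
      shift[gidx, hit] <- shift[gidx, hit] + blocks$log2_shift[b]
      aneuploid[hit] <- TRUE
    }
    b_g <- stats::rnorm(G, config$expr_base_log2_mean,
                        config$expr_base_log2_sd)
    s_c <- stats::rnorm(n_n + n_t, 0, config$expr_cell_sd)
    mu <- 2 ^ (outer(b_g, s_c, "+") + shift +
               matrix(stats::rnorm(G * (n_n + n_t), 0,
                                   config$expr_noise_sd), G))
    counts <- matrix(stats::rpois(G * (n_n + n_t), mu), G,
                     dimnames = list(model$genes$gene_symbol, cells))
    se <- ExpressionMatrix(counts,
      genes = data.frame(gene_symbol = model$genes$gene_symbol,
                         chrom = model$genes$chrom,
                         start = model$genes$start),
      cells = cells, assay_name = "counts")
    writeExpressionMatrix(se, file.path(out_dir, "counts.tsv"))

    ## ---- supporting files ----
    writeGeneModelGtf(model, file.path(out_dir, "gene_model.gtf"))
    data.table::fwrite(data.table::data.table(
      gene_symbol = model$genes$gene_symbol,
      length = model$genes$cds_length),
      file.path(out_dir, "gene_lengths.tsv"), sep = "\t")
    writeDriverCatalog(catalog, file.path(out_dir, "catalog.tsv"))
    total_mrna <- colSums(counts) * 2 ^ stats::rnorm(n_n + n_t, 0, 0.05)
    data.table::fwrite(data.table::data.table(
      cell_id = cells, patient_id = patient, group = group,
      tissue_or_dataset = tissue, total_mrna = total_mrna),
      file.path(out_dir, "metadata.tsv"), sep = "\t")
    writeLines(cells[group == "normal"], file.path(out_dir, "normals.txt"))

    truth <- data.frame(
      cell_id = cells, group = group, patient_id = patient,
      tissue_or_dataset = tissue,
      n_planted_drivers = lengths(planted),
      planted_drivers = vapply(planted, function(k)
        paste(sub(" ", ":", k), collapse = ";"), ""),
      aneuploid = aneuploid,
      expected_qc = "keep",
      stringsAsFactors = FALSE)
    data.table::fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")
    invisible(truth)
  })
}
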