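#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a livestock
#' genomic-selection cohort at desk scale: a training population of 1,700
#' individuals, sparse causal SNPs sitting inside cis-regulatory elements,
#' an annotation cascade (element -> gene -> functional term -> metaterm)
#' that mediates the causal effects, and a moderately heritable quantitative
#' trait.
#'
#' @param n_samples number of individuals.
#' @param n_noncoding_snps,n_coding_snps SNP counts by category.
#' @param n_elements,n_genes,n_terms,n_metaterms annotation graph sizes.
#' @param maf_range minor-allele-frequency range, in `(0, 0.5]`.
#' @param n_causal_elements number of elements harbouring a causal
#'   noncoding SNP.
#' @param n_causal_coding number of causal coding SNPs.
#' @param heritability_target narrow-sense heritability of the simulated
#'   trait, in `[0, 1)`; 0 is allowed as a pure-noise boundary case.
#' @param interaction_fraction fraction of causal SNP pairs (within the
#'   causal metaterm) given a pairwise epistatic effect.
#' @param ld_block_size,ld_rho optional block-LD mode: adjacent SNPs within
#'   blocks of this size are generated from an AR(1) Gaussian copula with
#'   correlation `ld_rho`. `ld_block_size = 1` (default) gives linkage
#'   equilibrium.
#' @param seed RNG seed; identical config + seed gives bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1700, n_noncoding_snps = 900,
                       n_coding_snps = 100, n_elements = 120, n_genes = 60,
                       n_terms = 40, n_metaterms = 8,
                       maf_range = c(0.05, 0.5), n_causal_elements = 10,
                       n_causal_coding = 5, heritability_target = 0.4,
                       interaction_fraction = 0, ld_block_size = 1,
                       ld_rho = 0.6, seed = 1) {
  cfg <- list(n_samples = n_samples, n_noncoding_snps = n_noncoding_snps,
              n_coding_snps = n_coding_snps, n_elements = n_elements,
              n_genes = n_genes, n_terms = n_terms,
              n_metaterms = n_metaterms, maf_range = maf_range,
              n_causal_elements = n_causal_elements,
              n_causal_coding = n_causal_coding,
              heritability_target = heritability_target,
              interaction_fraction = interaction_fraction,
              ld_block_size = ld_block_size, ld_rho = ld_rho, seed = seed)
  counts <- cfg[c("n_samples", "n_noncoding_snps", "n_coding_snps",
                  "n_elements", "n_genes", "n_terms", "n_metaterms")]
  if (any(unlist(counts) < 1)) stop("sim_config: counts must be positive")
  if (heritability_target < 0 || heritability_target >= 1)
    stop("sim_config: heritability_target must lie in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("sim_config: maf_range must lie in (0, 0.5]")
  if (interaction_fraction < 0 || interaction_fraction > 1)
    stop("sim_config: interaction_fraction must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a cohort with a known annotation-mediated causal cascade
#'
#' Generates genotypes, the annotation graph, allele-level impact scores and
#' a phenotype whose genetic signal flows through the graph: causal
#' noncoding SNPs sit inside cis-regulatory elements linked (within a
#' +/-1 Mb window) to the signature genes of a designated causal metaterm,
#' causal coding SNPs sit inside those genes, and per-SNP additive effects
#' are proportional to the simulated allele-impact difference. Effect-size
#' multipliers follow the null/small/medium/large mixture-scale convention
#' of mixture-prior Bayesian genomic models. Environmental noise is scaled
#' so the realized Var(genetic)/Var(total) matches `heritability_target`.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_cohort` with elements `genotypes`
#'   ([geno_matrix()]), `bundle` ([annotation_bundle()]), `impacts`
#'   ([impact_scores()]), `phenotype` ([phenotype()]) and `truth` (causal
#'   ids, per-SNP additive effects, genetic values, realized heritability).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_causal_elements > config$n_elements)
    stop("simulate_cohort: more causal elements requested than elements exist")
  if (config$n_causal_coding > config$n_coding_snps)
    stop("simulate_cohort: more causal coding SNPs requested than coding SNPs")
  set.seed(config$seed)
  n <- config$n_samples

  ## ---- genome layout -------------------------------------------------
  n_chrom <- max(1L, round(config$n_genes / 25))
  chrom_len <- 6e7
  chroms <- paste0("chr", seq_len(n_chrom))
  gene_chrom <- sample(chroms, config$n_genes, replace = TRUE)
  gene_start <- as.integer(floor(runif(config$n_genes, 2e6, chrom_len - 2e6)))
  gene_width <- as.integer(floor(runif(config$n_genes, 5e3, 3e4)))
  genes <- data.frame(chrom = gene_chrom, start = gene_start,
                      end = gene_start + gene_width,
                      label = sprintf("gene%03d", seq_len(config$n_genes)),
                      stringsAsFactors = FALSE)

  ## ---- metaterm / term / gene function structure ---------------------
  terms <- sprintf("term%03d", seq_len(config$n_terms))
  metaterms <- sprintf("metaterm%02d", seq_len(config$n_metaterms))
  # each metaterm has a disjoint-ish signature set of terms
  term_meta <- matrix(0, config$n_terms, config$n_metaterms,
                      dimnames = list(terms, metaterms))
  sig_terms <- split(seq_len(config$n_terms),
                     rep_len(seq_len(config$n_metaterms), config$n_terms))
  for (m in seq_len(config$n_metaterms))
    term_meta[sig_terms[[m]], m] <- abs(stats::rnorm(length(sig_terms[[m]]),
                                                     1, 0.3))
  # gene x term scores: low-rank factor product plus noise, then a boost of
  # the causal-module block so the cascade is annotation-consistent
  r <- 4
  gts <- tcrossprod(matrix(stats::rnorm(config$n_genes * r, 0, 0.5),
                           ncol = r),
                    matrix(stats::rnorm(config$n_terms * r, 0, 0.5),
                           ncol = r)) +
    matrix(stats::rnorm(config$n_genes * config$n_terms, 0, 0.1),
           config$n_genes)
  dimnames(gts) <- list(genes$label, terms)

  causal_metaterm <- metaterms[1]
  causal_terms <- terms[sig_terms[[1]]]
  n_causal_genes <- max(2L, ceiling(config$n_genes / 6))
  causal_genes <- sample(genes$label, n_causal_genes)
  gts[causal_genes, causal_terms] <-
    gts[causal_genes, causal_terms] + abs(stats::rnorm(
      length(causal_genes) * length(causal_terms), 1.5, 0.3))

  signature_flags <- stats::setNames(rep(FALSE, config$n_genes), genes$label)
  signature_flags[causal_genes] <- TRUE
  extra_sig <- sample(setdiff(genes$label, causal_genes),
                      min(5, config$n_genes - n_causal_genes))
  signature_flags[extra_sig] <- TRUE
  conserved_flags <- stats::setNames(
    runif(config$n_genes) < 0.3, genes$label)
  conserved_flags[sample(causal_genes, ceiling(n_causal_genes / 2))] <- TRUE

  ## ---- cis-regulatory elements near genes ----------------------------
  host_gene <- integer(config$n_elements)
  # causal elements are placed near causal genes so the cascade is real
  host_gene[seq_len(config$n_causal_elements)] <-
    sample(match(causal_genes, genes$label), config$n_causal_elements,
           replace = TRUE)
  if (config$n_elements > config$n_causal_elements)
    host_gene[(config$n_causal_elements + 1):config$n_elements] <-
      sample(config$n_genes, config$n_elements - config$n_causal_elements,
             replace = TRUE)
  elem_width <- as.integer(floor(runif(config$n_elements, 300, 2000)))
  elem_start <- as.integer(pmax(0, genes$start[host_gene] +
    floor(runif(config$n_elements, -8e5, 8e5))))
  elements <- data.frame(chrom = genes$chrom[host_gene], start = elem_start,
                         end = elem_start + elem_width,
                         label = sprintf("elem%04d",
                                         seq_len(config$n_elements)),
                         stringsAsFactors = FALSE)
  causal_elements <- elements$label[seq_len(config$n_causal_elements)]

  # element -> gene: all genes whose interval lies within 1 Mb
  e2g <- do.call(rbind, lapply(seq_len(config$n_elements), function(i) {
    same <- genes$chrom == elements$chrom[i]
    gap <- pmax(0, pmax(genes$start - elements$end[i],
                        elements$start[i] - genes$end))
    hit <- same & gap <= 1e6
    if (!any(hit)) return(NULL)
    data.frame(element = elements$label[i], gene = genes$label[hit],
               stringsAsFactors = FALSE)
  }))

  ## ---- SNPs -----------------------------------------------------------
  # noncoding SNPs inside elements; at least one per causal element
  nc_elem <- c(seq_len(config$n_causal_elements),
               sample(config$n_elements,
                      config$n_noncoding_snps - config$n_causal_elements,
                      replace = TRUE))
  nc_pos <- elements$start[nc_elem] +
    floor(runif(config$n_noncoding_snps) * (elem_width[nc_elem] - 1))
  # coding SNPs inside genes; causal ones inside causal genes
  cd_gene <- c(sample(match(causal_genes, genes$label),
                      config$n_causal_coding, replace = TRUE),
               sample(config$n_genes,
                      config$n_coding_snps - config$n_causal_coding,
                      replace = TRUE))
  cd_pos <- genes$start[cd_gene] +
    floor(runif(config$n_coding_snps) * (gene_width[cd_gene] - 1))

  snp_id <- c(sprintf("ncsnp%05d", seq_len(config$n_noncoding_snps)),
              sprintf("cdsnp%05d", seq_len(config$n_coding_snps)))
  alle <- function(k) sample(c("A", "C", "G", "T"), k, replace = TRUE)
  p_tot <- config$n_noncoding_snps + config$n_coding_snps
  snps <- snp_table(
    snp_id,
    chrom = c(elements$chrom[nc_elem], genes$chrom[cd_gene]),
    pos = as.integer(c(nc_pos, cd_pos)),
    ref_allele = alle(p_tot), alt_allele = alle(p_tot),
    category = rep(c("noncoding", "coding"),
                   c(config$n_noncoding_snps, config$n_coding_snps)),
    nonsynonymous = c(rep(FALSE, config$n_noncoding_snps),
                      runif(config$n_coding_snps) < 0.4)
  )
  snp_to_element <- stats::setNames(elements$label[nc_elem],
                                    snp_id[seq_len(config$n_noncoding_snps)])
  snp_to_gene <- stats::setNames(
    genes$label[cd_gene],
    snp_id[config$n_noncoding_snps + seq_len(config$n_coding_snps)])

  causal_nc <- names(snp_to_element)[match(causal_elements, snp_to_element)]
  causal_cd <- snp_id[config$n_noncoding_snps + seq_len(config$n_causal_coding)]
  causal_ids <- c(causal_nc, causal_cd)

  ## ---- genotypes ------------------------------------------------------
  maf <- runif(p_tot, config$maf_range[1], config$maf_range[2])
  # draw along genomic order so the optional block-LD copula correlates
  # physically adjacent SNPs
  ord <- order(snps$chrom, snps$pos)
  codes <- matrix(0L, n, p_tot)
  codes[, ord] <- draw_genotypes(n, maf[ord], config$ld_block_size,
                                 config$ld_rho)
  dimnames(codes) <- list(paste0("ind", sprintf("%05d", seq_len(n))), snp_id)

  ## ---- impact scores --------------------------------------------------
  is_causal <- snp_id %in% causal_ids
  ref_sc <- alt_sc <- numeric(p_tot)
  nc_idx <- seq_len(config$n_noncoding_snps)
  # non-causal: near-zero Gaussian deltas, scores mostly modest
  ref_sc <- runif(p_tot, 0.02, 0.55)
  alt_sc <- pmin(1, pmax(0, ref_sc + stats::rnorm(p_tot, 0, 0.02)))
  # causal: one allele firmly in a peak, large |delta|
  ci <- which(is_causal)
  ref_sc[ci] <- runif(length(ci), 0.5, 0.9)
  alt_sc[ci] <- pmin(1, pmax(0, ref_sc[ci] -
    sample(c(-1, 1), length(ci), replace = TRUE) * runif(length(ci), 0.3, 0.5)))
  impacts <- impact_scores(
    noncoding_access = data.frame(snp_id = snp_id[nc_idx],
                                  ref_score = ref_sc[nc_idx],
                                  alt_score = alt_sc[nc_idx],
                                  stringsAsFactors = FALSE),
    coding_mfe = data.frame(snp_id = snp_id[-nc_idx],
                            ref_score = ref_sc[-nc_idx],
                            alt_score = alt_sc[-nc_idx],
                            stringsAsFactors = FALSE),
    peak_threshold = 0.147
  )

  ## ---- additive effects and phenotype --------------------------------
  delta <- alt_sc - ref_sc
  beta <- stats::setNames(numeric(p_tot), snp_id)
  h2 <- config$heritability_target
  if (h2 > 0) {
    # magnitude proportional to impact delta, scaled by the small/medium/
    # large mixture-scale sds (1e-4, 1e-3, 1e-2 relative variance)
    comp <- sample(2:4, length(ci), replace = TRUE, prob = c(0.5, 0.3, 0.2))
    scale_sd <- sqrt(c(1e-4, 1e-3, 1e-2))[comp - 1]
    beta[ci] <- delta[ci] * scale_sd / sqrt(1e-3)
  }
  centered <- sweep(codes, 2, colMeans(codes))
  g <- as.numeric(centered %*% beta)

  interactions <- NULL
  if (h2 > 0 && config$interaction_fraction > 0 && length(causal_ids) >= 2) {
    npair <- floor(config$interaction_fraction * length(causal_ids) / 2)
    if (npair >= 1) {
      pairs <- matrix(sample(causal_ids, 2 * npair), ncol = 2)
      wsd <- stats::sd(beta[ci])
      w <- stats::rnorm(npair, 0, if (wsd > 0) wsd else 0.01)
      for (q in seq_len(npair))
        g <- g + w[q] * centered[, pairs[q, 1]] * centered[, pairs[q, 2]]
      interactions <- data.frame(snp_a = pairs[, 1], snp_b = pairs[, 2],
                                 weight = w, stringsAsFactors = FALSE)
    }
  }

  var_g <- stats::var(g)
  sigma_e2 <- if (h2 > 0 && var_g > 0) var_g * (1 - h2) / h2 else 1
  e <- stats::rnorm(n, 0, sqrt(sigma_e2))
  y <- g + e
  realized_h2 <- if (stats::var(y) > 0) var_g / stats::var(y) else 0

  bundle <- annotation_bundle(
    element_intervals = elements, snp_to_element = snp_to_element,
    gene_intervals = genes, element_to_gene = e2g,
    snp_to_gene = snp_to_gene, gene_term_scores = gts,
    term_metaterm_weights = term_meta,
    conserved_gene_flags = conserved_flags,
    signature_gene_flags = signature_flags, snps = snps)

  structure(list(
    genotypes = geno_matrix(codes, snps = snps),
    bundle = bundle,
    impacts = impacts,
    phenotype = phenotype(y, samples = rownames(codes), trait = "sim_trait"),
    truth = list(causal_snp_ids = causal_ids, effects = beta,
                 causal_elements = causal_elements,
                 causal_genes = causal_genes, causal_terms = causal_terms,
                 causal_metaterms = causal_metaterm,
                 interactions = interactions, genetic_values = g,
                 sigma_e2 = sigma_e2, maf = stats::setNames(maf, snp_id),
                 realized_heritability = realized_h2),
    config = config
  ), class = "sim_cohort")
}

# Binomial(2, maf) genotypes; optional AR(1) Gaussian-copula block LD.
draw_genotypes <- function(n, maf, block = 1, rho = 0.6) {
  p <- length(maf)
  if (block <= 1) {
    return(matrix(stats::rbinom(n * p, 2, rep(maf, each = n)), nrow = n))
  }
  codes <- matrix(0L, n, p)
  thr <- stats::qnorm(maf)
  for (hap in 1:2) {
    z <- matrix(stats::rnorm(n * p), n, p)
    for (j in seq(2, p)) {
      if ((j - 1) %% block != 0)
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
    codes <- codes + (sweep(z, 2, thr, "<") * 1L)
  }
  codes
}

#' @export
print.sim_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "Synthetic cohort: %d samples, %d SNPs (%d noncoding + %d coding)\n",
    "  causal SNPs: %d | target h2 = %.2f, realized h2 = %.3f\n"),
    cfg$n_samples, cfg$n_noncoding_snps + cfg$n_coding_snps,
    cfg$n_noncoding_snps, cfg$n_coding_snps,
    length(x$truth$causal_snp_ids), cfg$heritability_target,
    x$truth$realized_heritability))
  invisible(x)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Writes genotypes, SNP metadata, phenotype, impact scores and the
#' annotation bundle in the package's standard formats, plus a
#' `truth.tsv` of simulated per-SNP effects.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_snp_table(sim$genotypes$snps, file.path(dir, "snps.tsv"))
  write_phenotypes(sim$phenotype, file.path(dir, "phenotype.tsv"))
  write_impact_scores(sim$impacts, file.path(dir, "impacts.tsv"))
  write_annotation_bundle(sim$bundle, file.path(dir, "bundle"))
  truth <- data.frame(snp_id = names(sim$truth$effects),
                      effect = unname(sim$truth$effects),
                      causal = names(sim$truth$effects) %in%
                        sim$truth$causal_snp_ids)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
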