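# Small in-code fixtures shared across tests.

tiny_snps <- function() {
  snp_table(
    snp_id = c("nc1", "nc2", "nc3", "cd1", "cd2"),
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr2"),
    pos = c(150L, 420L, 150L, 1050L, 2100L),
    ref_allele = c("A", "C", "G", "T", "A"),
    alt_allele = c("G", "T", "A", "C", "C"),
    category = c("noncoding", "noncoding", "noncoding", "coding", "coding"),
    nonsynonymous = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

tiny_bundle <- function(snps = tiny_snps()) {
  elements <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                         start = c(100L, 400L, 100L),
                         end = c(200L, 500L, 200L),
                         label = c("e1", "e2", "e3"),
                         stringsAsFactors = FALSE)
  genes <- data.frame(chrom = c("chr1", "chr2"),
                      start = c(1000L, 2000L), end = c(1200L, 2300L),
                      label = c("gA", "gB"), stringsAsFactors = FALSE)
  gts <- matrix(c(1.2, 0, 0.4, 0.9), 2, 2,
                dimnames = list(c("gA", "gB"), c("t1", "t2")))
  tmw <- matrix(c(1, 0.5, 0, 1), 2, 2,
                dimnames = list(c("t1", "t2"), c("m1", "m2")))
  annotation_bundle(
    element_intervals = elements,
    snp_to_element = c(nc1 = "e1", nc2 = "e2", nc3 = "e3"),
    gene_intervals = genes,
    element_to_gene = data.frame(element = c("e1", "e2", "e3"),
                                 gene = c("gA", "gA", "gB"),
                                 stringsAsFactors = FALSE),
    snp_to_gene = c(cd1 = "gA", cd2 = "gB"),
    gene_term_scores = gts,
    term_metaterm_weights = tmw,
    conserved_gene_flags = c(gA = TRUE, gB = FALSE),
    signature_gene_flags = c(gA = FALSE, gB = TRUE),
    snps = snps
  )
}

tiny_impacts <- function() {
  impact_scores(
    noncoding_access = data.frame(
      snp_id = c("nc1", "nc2", "nc3"),
      ref_score = c(0.6, 0.3, 0.1), alt_score = c(0.2, 0.32, 0.12),
      stringsAsFactors = FALSE),
    coding_mfe = data.frame(
      snp_id = c("cd1", "cd2"),
      ref_score = c(0.5, 0.4), alt_score = c(0.8, 0.41),
      stringsAsFactors = FALSE),
    peak_threshold = 0.147
  )
}

tiny_geno <- function(n = 20, seed = 1, snps = tiny_snps()) {
  set.seed(seed)
  codes <- matrix(rbinom(n * nrow(snps), 2, 0.4), n, nrow(snps),
                  dimnames = list(paste0("i", seq_len(n)), snps$snp_id))
  geno_matrix(codes, snps = snps)
}

# moderate-size simulated cohort for model tests
small_sim <- function(seed = 1, n = 300, h2 = 0.5, ...) {
  simulate_cohort(sim_config(
    n_samples = n, n_noncoding_snps = 120, n_coding_snps = 30,
    n_elements = 40, n_genes = 20, n_terms = 12, n_metaterms = 4,
    n_causal_elements = 6, n_causal_coding = 3,
    heritability_target = h2, seed = seed, ...))
}

random_codes <- function(n, p, seed = 1, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(p, 0.1, 0.5)
  matrix(rbinom(n * p, 2, rep(maf, each = n)), n, p,
         dimnames = list(paste0("i", seq_len(n)), paste0("s", seq_len(p))))
}

# compact cohort whose entity counts fit small network widths
tune_sim <- function(seed = 1, n = 80, h2 = 0.6) {
  simulate_cohort(sim_config(
    n_samples = n, n_noncoding_snps = 60, n_coding_snps = 8,
    n_elements = 12, n_genes = 8, n_terms = 6, n_metaterms = 3,
    n_causal_elements = 4, n_causal_coding = 2,
    heritability_target = h2, seed = seed))
}
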