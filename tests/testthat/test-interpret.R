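test_that("rho scores match closed-form order statistics", {
  r1 <- rho_score(0.5)
  expect_equal(r1$rho, 0.5)          # Beta(1,1) is uniform
  expect_equal(r1$p, 0.5)
  r2 <- rho_score(c(0.1, 0.9))
  expect_equal(r2$beta_scores, c(1 - 0.9^2, 0.9^2))
  expect_equal(r2$rho, 0.19)
  expect_equal(r2$p, 0.38)
  expect_lt(rho_score(rep(1e-8, 3))$rho, 1e-15)
  expect_error(rho_score(c(0.2, 0)), "\\(0, 1\\]")
  expect_error(rho_score(c(0.2, 1.2)), "\\(0, 1\\]")
})

test_that("beta order-statistic probabilities agree with binomial sums", {
  # independent oracle: P(U_(k) <= r) = sum_{j>=k} C(m,j) r^j (1-r)^(m-j)
  for (m in c(3, 5)) {
    for (r in c(0.1, 0.35, 0.8)) {
      ranks <- rep(r, m)
      bs <- rho_score(ranks)$beta_scores
      oracle <- vapply(seq_len(m), function(k)
        sum(stats::dbinom(k:m, m, r)), numeric(1))
      expect_equal(bs, oracle, tolerance = 1e-12)
    }
  }
  # and with Monte-Carlo order statistics on a random rank vector
  set.seed(3)
  r <- sort(runif(4))
  bs <- rho_score(r)$beta_scores
  U <- matrix(runif(4 * 20000), ncol = 4)
  U <- t(apply(U, 1, sort))
  mc <- vapply(1:4, function(k) mean(U[, k] <= r[k]), numeric(1))
  expect_lt(max(abs(bs - mc)), 3 * sqrt(0.25 / 20000) * 3 + 0.01)
})

test_that("rank extraction is traceable and ranks degenerate cases", {
  sim <- small_sim(seed = 101, n = 60)
  spec <- network_spec(annotation_level = 4, base_unit = 4,
                       unit_ratio = c(1, 1, 1), learning_rate = 0.02,
                       dropout_rate = 0)
  nets <- lapply(1:3, function(f) {
    net <- build_network(sim$genotypes$snps, sim$bundle, sim$impacts,
                         spec, init_seed = f)
    train_network(net, sim$genotypes, sim$phenotype, steps = 5, seed = f)
  })
  rl <- extract_node_weights(nets, "metaterm")
  expect_equal(dim(rl$ranks), c(length(rl$ids), 3L))
  expect_true(all(rl$ranks > 0 & rl$ranks <= 1))
  # within a replicate, ranks are a permutation of (1..N)/N
  expect_equal(sort(unname(rl$ranks[, 1])),
               seq_along(rl$ids) / length(rl$ids))
  # every node resolves to exactly one entity
  expect_false(anyNA(rl$entities))
  # a node with all-zero outgoing weights lands at the last rank
  net0 <- nets[[1]]
  net0$layers[[3]]$W[, 1] <- 0   # kill gene-node 1's fan-out... column 1
  rg <- extract_node_weights(list(net0), "gene")
  expect_equal(unname(rg$ranks[1, 1]), 1)  # normalized last rank = N/N = 1
  # a single-node layer always ranks 1/1
  one <- extract_node_weights(nets, "gene")
  expect_true(all(one$ranks <= 1))
  # mismatched specs error
  spec2 <- network_spec(annotation_level = 1, base_unit = 4,
                        unit_ratio = c(1, 1, 1))
  net_other <- build_network(sim$genotypes$snps, sim$bundle, sim$impacts,
                             spec2)
  expect_error(extract_node_weights(c(nets[1], list(net_other)), "gene"),
               "share one network_spec")
})

test_that("aggregation is calibrated under the uniform null", {
  set.seed(11)
  m <- 5; N <- 60
  false_hits <- 0; total_reps <- 400
  for (rep in seq_len(total_reps)) {
    ranks <- vapply(seq_len(m), function(j)
      sample(N) / N, numeric(N))
    rl <- structure(list(layer = "gene", ids = paste0("n", 1:N),
                         entities = paste0("n", 1:N), ranks = ranks),
                    class = "node_ranks")
    tab <- aggregate_layer(rl, alpha = 0.05)
    false_hits <- false_hits + sum(tab$significant)
  }
  # under the global null the expected FDR bound caps the per-rep
  # rejection fraction near alpha
  expect_lt(false_hits / (total_reps * N), 0.05)
})

test_that("a consistently top-ranked node dominates its layer", {
  m <- 5; N <- 100
  set.seed(12)
  ranks <- vapply(seq_len(m), function(j) {
    r <- sample(2:N) / N
    c(1 / N, r)
  }, numeric(N))
  rl <- structure(list(layer = "gene", ids = paste0("n", 1:N),
                       entities = paste0("n", 1:N), ranks = ranks),
                  class = "node_ranks")
  tab <- aggregate_layer(rl, alpha = 0.01)
  expect_equal(tab$node[1], "n1")
  expect_equal(min(tab$adjusted_p), tab$adjusted_p[tab$node == "n1"])
  # adjusted p is monotone non-decreasing in rho
  expect_true(all(diff(tab$adjusted_p[order(tab$rho)]) >= -1e-12))
})

test_that("backward tracing reports only the layers the level supports", {
  sim <- small_sim(seed = 103, n = 60)
  make_nets <- function(level) {
    spec <- network_spec(annotation_level = level, base_unit = 75,
                         unit_ratio = c(1, 1, 1), learning_rate = 0.02,
                         dropout_rate = 0)
    lapply(1:3, function(f)
      train_network(build_network(sim$genotypes$snps, sim$bundle,
                                  sim$impacts, spec, init_seed = f),
                    sim$genotypes, sim$phenotype, steps = 5, seed = f))
  }
  tr1 <- backward_trace(make_nets(1), sim$bundle)
  expect_setequal(names(tr1$layers), c("noncoding_snp", "coding_snp"))
  tr4 <- backward_trace(make_nets(4), sim$bundle)
  expect_setequal(names(tr4$layers),
                  c("noncoding_snp", "coding_snp", "element",
                    "rna_structure", "gene", "term", "metaterm"))
})

test_that("cis-SNP prioritization applies window, p and peak filters", {
  snps <- snp_table(
    snp_id = c("close", "at_boundary", "too_far", "no_peak", "weak_p"),
    chrom = "chr1",
    pos = c(5000L, 2009999L, 2510000L,
            6000L, 7000L),
    ref_allele = "A", alt_allele = "G", category = "noncoding")
  genes <- data.frame(chrom = "chr1", start = 10000L, end = 1010000L,
                      label = "gT", stringsAsFactors = FALSE)
  bundle <- annotation_bundle(gene_intervals = genes)
  impacts <- impact_scores(
    noncoding_access = data.frame(
      snp_id = snps$snp_id,
      ref_score = c(0.6, 0.5, 0.6, 0.117, 0.6),
      alt_score = c(0.2, 0.2, 0.2, 0.106, 0.2)),
    peak_threshold = 0.147)
  snp_layer <- data.frame(
    node = snps$snp_id, entity = snps$snp_id,
    rho = 0.001, p = 0.005,
    adjusted_p = c(0.001, 0.002, 0.001, 0.0005, 0.5),
    significant = TRUE, stringsAsFactors = FALSE)
  trace <- structure(list(layers = list(noncoding_snp = snp_layer),
                          significant = list(gene = "gT"), level = 4,
                          alpha_node = 0.01),
                     class = "backward_trace")
  res <- prioritize_cis_snps(trace, bundle, snps, impacts)
  # boundary distance exactly 1 Mb is included; 2.5 Mb away excluded;
  # both alleles under the peak threshold excluded despite smallest p;
  # weak adjusted p excluded
  expect_setequal(res$snp_id, c("close", "at_boundary"))
  expect_equal(res$snp_id[1], "close")   # ranked by adjusted p
  expect_equal(res$distance[res$snp_id == "at_boundary"], 1e6)
})

test_that("the simulated causal metaterm is flagged in most runs", {
  hits <- 0
  for (seed in 1:5) {
    sim <- simulate_cohort(sim_config(
      n_samples = 300, n_noncoding_snps = 130, n_coding_snps = 20,
      n_elements = 30, n_genes = 15, n_terms = 12, n_metaterms = 4,
      n_causal_elements = 8, n_causal_coding = 4,
      heritability_target = 0.6, seed = 110 + seed))
    spec <- network_spec(annotation_level = 4, base_unit = 50,
                         unit_ratio = c(1, 1, 1), learning_rate = 0.05,
                         dropout_rate = 0.05)
    plan <- make_folds(300, 5, seed = seed)
    nets <- lapply(1:5, function(f) {
      tr <- plan$fold_id != f
      net <- build_network(sim$genotypes$snps, sim$bundle, sim$impacts,
                           spec, init_seed = seed * 10 + f)
      train_network(net, sim$genotypes$codes[tr, ],
                    as.numeric(sim$phenotype)[tr], steps = 40,
                    seed = seed * 10 + f)
    })
    tr <- backward_trace(nets, sim$bundle, alpha_node = 0.05)
    mt <- tr$layers$metaterm
    best <- mt$entity[which.min(mt$adjusted_p)]
    if (identical(best, sim$truth$causal_metaterms)) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("permuted phenotypes yield few significant entities", {
  sim <- small_sim(seed = 130, n = 200, h2 = 0.6)
  spec <- network_spec(annotation_level = 4, base_unit = 30,
                       unit_ratio = c(1, 1, 1), learning_rate = 0.05,
                       dropout_rate = 0.05)
  set.seed(9)
  yperm <- sample(as.numeric(sim$phenotype))
  nets <- lapply(1:5, function(f) {
    train_network(build_network(sim$genotypes$snps, sim$bundle,
                                sim$impacts, spec, init_seed = f),
                  sim$genotypes$codes, yperm, steps = 25, seed = f)
  })
  tr <- backward_trace(nets, sim$bundle, alpha_node = 0.01)
  n_sig <- sum(vapply(tr$layers, function(t) sum(t$significant),
                      numeric(1)))
  n_nodes <- sum(vapply(tr$layers, nrow, numeric(1)))
  expect_lt(n_sig / n_nodes, 0.05)
})
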