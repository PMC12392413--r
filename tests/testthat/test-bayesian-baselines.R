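test_that("disjoint class rules match their stated worked cases", {
  snps <- snp_table(
    snp_id = c("in_c", "near_d", "far", "in_d_nonsyn"),
    chrom = "chr1",
    pos = c(1100L,                    # inside the conserved gene
            2300L + 49999L,           # 49,999 bp beyond the signature gene
            5000000L,               # nowhere near anything
            2100L),                   # inside the signature gene
    ref_allele = "A", alt_allele = "G",
    category = c("coding", "noncoding", "noncoding", "coding"),
    nonsynonymous = c(TRUE, FALSE, FALSE, TRUE))
  genes <- data.frame(chrom = "chr1", start = c(1000L, 2000L),
                      end = c(1200L, 2300L), label = c("gA", "gB"),
                      stringsAsFactors = FALSE)
  b <- annotation_bundle(gene_intervals = genes,
                         conserved_gene_flags = c(gA = TRUE, gB = FALSE),
                         signature_gene_flags = c(gA = FALSE, gB = TRUE))
  cl <- build_disjoint_classes(snps, b)
  got <- setNames(as.character(cl$class_label), cl$snp_id)
  expect_equal(got[["in_c"]], "I")
  expect_equal(got[["near_d"]], "IV")
  expect_equal(got[["far"]], "V")
  expect_equal(got[["in_d_nonsyn"]], "II")
})

test_that("class labels agree with a brute-force rule evaluator", {
  for (seed in 1:3) {
    sim <- small_sim(seed = seed + 40, n = 30)
    snps <- sim$genotypes$snps
    b <- sim$bundle
    cl <- build_disjoint_classes(snps, b)
    genes <- b$gene_intervals
    cg <- genes[genes$label %in% names(which(b$conserved_gene_flags)), ]
    dg <- genes[genes$label %in% names(which(b$signature_gene_flags)), ]
    hits <- function(i, tab, flank = 0) {
      any(tab$chrom == snps$chrom[i] &
            snps$pos[i] >= tab$start - flank &
            snps$pos[i] < tab$end + flank)
    }
    expected <- vapply(seq_len(nrow(snps)), function(i) {
      a <- snps$nonsynonymous[i]
      if (a && hits(i, cg)) "I"
      else if (a && hits(i, dg)) "II"
      else if (!a && hits(i, cg, 50000)) "III"
      else if (!a && hits(i, dg, 50000)) "IV"
      else "V"
    }, character(1))
    expect_equal(as.character(cl$class_label), expected)
    # disjoint and exhaustive by construction
    expect_false(anyNA(cl$class_label))
  }
})

test_that("chains are reproducible and argument contracts enforced", {
  codes <- random_codes(60, 40, seed = 50)
  y <- rnorm(60)
  f1 <- bayesr(codes, y, burnin = 100, numit = 300, seed = 4)
  f2 <- bayesr(codes, y, burnin = 100, numit = 300, seed = 4)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$pi, f2$pi)
  f3 <- bayesr(codes, y, burnin = 100, numit = 300, seed = 5)
  expect_false(identical(f1$beta, f3$beta))
  expect_error(bayesr(codes, y, burnin = 300, numit = 300), "exceed")
})

test_that("mixture proportions are simplex rows and null effects are zero", {
  codes <- random_codes(80, 60, seed = 51)
  set.seed(52)
  y <- rnorm(80) + 0.4 * scale(codes[, 1])
  fit <- bayesr(codes, y, burnin = 200, numit = 600, seed = 1)
  expect_equal(unname(rowSums(fit$pi)), 1, tolerance = 1e-12)
  # a SNP never leaving the null component has an exactly zero posterior
  # mean effect
  never <- fit$pip == 0
  if (any(never)) expect_true(all(fit$beta[never] == 0))
})

test_that("a pure-noise trait is recognized as effectively null", {
  set.seed(42)
  codes <- random_codes(400, 500, seed = 42)
  y <- rnorm(400)
  fit <- bayesr(codes, y, burnin = 1000, numit = 3000, seed = 1)
  # the large-effect component is suppressed and the null component is
  # modal; the posterior genetic signal is negligible
  expect_lt(fit$pi["all", "large"], 0.15)
  expect_gt(sum(fit$pi["all", c("null", "small")]), 0.5)
  expect_lt(stats::var(fit$fitted) / stats::var(y), 0.15)
})

test_that("large-effect causal SNPs get elevated posterior inclusion", {
  wins <- 0
  for (seed in 1:5) {
    set.seed(seed + 60)
    codes <- random_codes(300, 300, seed = seed + 60)
    causal <- sample(300, 10)
    # generative model matched to the mixture prior's large component
    sigma_g2 <- 4
    beta <- rnorm(10, 0, sqrt(1e-2 * sigma_g2))
    g <- as.numeric(scale(codes[, causal], scale = FALSE) %*% beta)
    y <- g + rnorm(300, 0, max(sd(g), 0.1))
    fit <- bayesr(codes, y, burnin = 500, numit = 1500, seed = seed)
    if (median(fit$pip[causal]) > median(fit$pip[-causal]))
      wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("single-class BayesRC reproduces the BayesR chain exactly", {
  codes <- random_codes(50, 30, seed = 70)
  set.seed(71)
  y <- rnorm(50)
  cls <- setNames(rep("only", 30), colnames(codes))
  fr <- bayesr(codes, y, burnin = 100, numit = 300, seed = 2)
  fc <- bayesrc(codes, y, cls, burnin = 100, numit = 300, seed = 2)
  expect_identical(unname(fr$beta), unname(fc$beta))
  expect_identical(unname(fr$pi), unname(fc$pi))
  expect_identical(fr$sigma_e2, fc$sigma_e2)
})

test_that("an empty class's mixing proportions stay at the prior mean", {
  codes <- random_codes(60, 40, seed = 72)
  set.seed(73)
  y <- rnorm(60)
  cls <- setNames(factor(rep("a", 40), levels = c("a", "b")),
                  colnames(codes))
  # class b is declared but holds no SNPs: its posterior is the prior
  fit <- bayesrc(codes, y, cls, burnin = 500, numit = 3000, seed = 7)
  expect_equal(unname(fit$pi["b", ]), rep(0.25, 4), tolerance = 0.05)
})

test_that("causal-class enrichment is recovered by BayesRC", {
  wins <- 0
  for (seed in 1:5) {
    set.seed(seed + 80)
    codes <- random_codes(300, 300, seed = seed + 80)
    causal <- 1:30                     # concentrated in class I
    sigma_g2 <- 4
    beta <- rnorm(30, 0, sqrt(1e-2 * sigma_g2))
    g <- as.numeric(scale(codes[, causal], scale = FALSE) %*% beta)
    y <- g + rnorm(300, 0, max(sd(g), 0.1))
    cls <- setNames(c(rep("I", 30), rep("V", 270)), colnames(codes))
    fit <- bayesrc(codes, y, cls, burnin = 500, numit = 1500, seed = seed)
    nonnull <- 1 - fit$pi[, "null"]
    if (nonnull["I"] > nonnull["V"]) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("posterior mean of a single-SNP effect matches quadrature", {
  set.seed(90)
  n <- 40
  x <- rbinom(n, 2, 0.4)
  y <- 0.5 + 0.45 * (x - mean(x)) + rnorm(n, 0, 0.5)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "s1"))
  fit <- bayesr(X, y, burnin = 4000, numit = 20000, seed = 3)

  # independent oracle: dense numerical integration of the full posterior
  # (flat mu; scaled-inv-chi2(nu=4, vy/2) on both variances; component
  # marginally uniform over the 4 mixture classes under Dirichlet(1,1,1,1))
  xc <- x - mean(x)
  n <- length(y)
  Sy <- sum(y); Syy <- sum(y^2); Sx <- sum(xc); Sxy <- sum(xc * y)
  Sxx <- sum(xc^2)
  vy <- var(y); nu <- 4; s_g <- vy / 2; s_e <- vy / 2
  mu_grid <- seq(mean(y) - 6 * sd(y) / sqrt(n),
                 mean(y) + 6 * sd(y) / sqrt(n), length.out = 61)
  se_grid <- exp(seq(log(vy / 40), log(vy * 6), length.out = 61))
  sg_grid <- exp(seq(log(vy / 400), log(vy * 60), length.out = 41))
  b_grid <- seq(-1.2, 1.2, length.out = 121)
  log_sichi2 <- function(s2, scale) -(nu / 2 + 1) * log(s2) -
    nu * scale / (2 * s2)
  gammas <- c(0, 1e-4, 1e-3, 1e-2)
  num <- 0; den <- 0
  for (sg in sg_grid) {
    for (k in 1:4) {
      if (k == 1) {
        # beta fixed at zero: 2-D integral over (mu, sigma_e2)
        RSS <- outer(mu_grid, rep(1, length(se_grid)),
                     function(m, d) Syy - 2 * m * Sy + n * m^2)
        ll <- -outer(rep(1, length(mu_grid)), n / 2 * log(2 * pi * se_grid)) -
          RSS / (2 * outer(rep(1, length(mu_grid)), se_grid))
        lp <- ll + outer(rep(1, length(mu_grid)),
                         log_sichi2(se_grid, s_e) + log(se_grid)) +
          log_sichi2(sg, s_g) + log(sg)
        w <- sum(exp(lp - 40))
        den <- den + w           # beta contribution zero
      } else {
        v <- gammas[k] * sg
        for (m in mu_grid) {
          RSS <- Syy - 2 * m * Sy + n * m^2 -
            2 * b_grid * (Sxy - m * Sx) + b_grid^2 * Sxx
          ll <- outer(RSS, 2 * se_grid, "/") * (-1) -
            outer(rep(1, length(b_grid)), n / 2 * log(2 * pi * se_grid))
          lpb <- -b_grid^2 / (2 * v) - 0.5 * log(2 * pi * v)
          lp <- ll + lpb +
            outer(rep(1, length(b_grid)),
                  log_sichi2(se_grid, s_e) + log(se_grid)) +
            log_sichi2(sg, s_g) + log(sg)
          w <- exp(lp - 40)
          den <- den + sum(w)
          num <- num + sum(b_grid * rowSums(w))
        }
      }
    }
  }
  oracle_mean <- num / den
  expect_equal(unname(fit$beta), oracle_mean, tolerance = 0.05)
})
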