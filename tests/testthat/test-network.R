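test_that("layer widths follow base_unit x unit_ratio", {
  spec <- network_spec(base_unit = 110, unit_ratio = c(1, 2, 4, 5, 6, 7))
  expect_equal(layer_widths(spec), c(110L, 220L, 440L, 550L, 660L, 770L))
})

test_that("the penalized loss matches its closed form", {
  expect_equal(compute_loss(c(1, 2), c(1, 2), list(matrix(0, 2, 2))), 0)
  expect_equal(compute_loss(c(1, 2), c(0, 0)), 2.5)
  expect_equal(compute_loss(c(1), c(1), list(10), "L2", 0.01), 1e-5)
  expect_equal(compute_loss(c(1), c(1), list(10), "L1", 0.01), 1e-6)
  expect_error(compute_loss(numeric(0), numeric(0)), "empty")
  # zero penalty equals the MSE to machine precision
  set.seed(1)
  y <- rnorm(10); yh <- rnorm(10)
  expect_equal(compute_loss(y, yh, list(matrix(rnorm(4), 2)), "L2", 0),
               mean((y - yh)^2))
})

test_that("optimal_step returns the first attainment of the minimum", {
  expect_equal(optimal_step(c(5, 4, 3, 2, 1)), 5)
  expect_equal(optimal_step(c(5, 4, 4, 4)), 2)
  trace <- c(seq(20, 9, length.out = 602), rep(8.799624, 104))
  expect_equal(optimal_step(trace), 603)
  expect_error(optimal_step(numeric(0)), "empty")
})

test_that("a zero learning rate freezes the loss trace", {
  geno <- tiny_geno(n = 16)
  y <- rnorm(16)
  spec <- network_spec(annotation_level = 2, base_unit = 5,
                       unit_ratio = c(1, 1), learning_rate = 0,
                       dropout_rate = 0.2)
  net <- build_network(geno$snps, tiny_bundle(), tiny_impacts(), spec)
  net <- train_network(net, geno, y, steps = 8, seed = 1)
  expect_equal(length(unique(round(net$loss_trace, 12))), 1)
})

test_that("training is reproducible under a fixed seed", {
  geno <- tiny_geno(n = 24)
  set.seed(9); y <- rnorm(24)
  spec <- network_spec(annotation_level = 4, base_unit = 5,
                       unit_ratio = c(1, 1, 1), learning_rate = 0.02,
                       dropout_rate = 0.1)
  t1 <- train_network(build_network(geno$snps, tiny_bundle(),
                                    tiny_impacts(), spec, init_seed = 3),
                      geno, y, steps = 12, seed = 5)$loss_trace
  t2 <- train_network(build_network(geno$snps, tiny_bundle(),
                                    tiny_impacts(), spec, init_seed = 3),
                      geno, y, steps = 12, seed = 5)$loss_trace
  expect_identical(t1, t2)
})

test_that("an unannotated SNP has exactly zero influence on the output", {
  snps <- tiny_snps()
  b <- tiny_bundle()
  # orphan: strip nc3's element assignment (and e3's gene link) so its
  # input node has zero fan-out
  b2 <- annotation_bundle(
    element_intervals = b$element_intervals,
    snp_to_element = b$snp_to_element[c("nc1", "nc2")],
    gene_intervals = b$gene_intervals,
    element_to_gene = b$element_to_gene,
    snp_to_gene = b$snp_to_gene,
    gene_term_scores = b$gene_term_scores,
    term_metaterm_weights = b$term_metaterm_weights,
    conserved_gene_flags = b$conserved_gene_flags,
    signature_gene_flags = b$signature_gene_flags, snps = snps)
  geno <- tiny_geno(n = 20)
  set.seed(2); y <- rnorm(20)
  for (lv in c(1, 4)) {
    spec <- network_spec(annotation_level = lv, base_unit = 6,
                         unit_ratio = c(1, 1, 1), learning_rate = 0.02)
    net <- build_network(geno$snps, b2, tiny_impacts(), spec)
    net <- train_network(net, geno, y, steps = 10, seed = 1)
    X <- geno$codes
    base <- predict(net, X)
    # finite difference in the orphan SNP's direction
    for (h in c(1, 2)) {
      Xp <- X
      Xp[, "nc3"] <- (X[, "nc3"] + h) %% 3
      expect_identical(predict(net, Xp), base)
    }
    # an annotated SNP does influence the output
    Xq <- X
    Xq[, "nc1"] <- 2 - X[, "nc1"]
    expect_false(identical(predict(net, Xq), base))
  }
})

test_that("backpropagation matches finite-difference gradients", {
  geno <- tiny_geno(n = 12)
  set.seed(4); y <- rnorm(12)
  spec <- network_spec(annotation_level = 4, base_unit = 4,
                       unit_ratio = c(1, 1, 1), learning_rate = 0.01,
                       dropout_rate = 0, reg_rate = 0.01, reg_norm = "L2")
  net <- build_network(geno$snps, tiny_bundle(), tiny_impacts(), spec)
  X <- geno$codes[, net$snp_ids]
  fw <- annogs:::forward_pass(net, X, mode = "eval_batch",
                              keep_cache = TRUE)
  gr <- annogs:::backward_pass(net, X, y, fw)
  loss_at <- function(net) {
    p <- annogs:::forward_pass(net, X, mode = "eval_batch")$yhat
    compute_loss(y, p, annogs:::all_weights(net), spec$reg_norm,
                 spec$reg_rate, spec$penalty_coefficient)
  }
  eps <- 1e-6
  check <- function(get, set, g) {
    set.seed(11)
    idx <- sample(length(g), min(5, length(g)))
    for (i in idx) {
      if (g[i] == 0 && get(net)[i] == 0) next  # masked entry
      n2 <- net
      v <- get(n2); v[i] <- v[i] + eps
      n2 <- set(n2, v)
      fd <- (loss_at(n2) - loss_at(net)) / eps
      expect_equal(fd, g[i], tolerance = 1e-3)
    }
  }
  check(function(n) n$layers[[2]]$W,
        function(n, v) { n$layers[[2]]$W <- v; n },
        gr$layers[[2]]$W)
  check(function(n) n$layers[[1]]$W,
        function(n, v) { n$layers[[1]]$W <- v; n },
        gr$layers[[1]]$W)
  check(function(n) n$out$W,
        function(n, v) { n$out$W <- v; n }, gr$out$W)
  check(function(n) n$layers[[3]]$gamma,
        function(n, v) { n$layers[[3]]$gamma <- v; n },
        gr$layers[[3]]$gamma)
  check(function(n) n$layers[[1]]$b,
        function(n, v) { n$layers[[1]]$b <- v; n },
        gr$layers[[1]]$b)
})

test_that("a depth-zero linear network converges to least squares", {
  set.seed(21)
  geno <- tiny_geno(n = 60)
  X <- geno$codes
  y <- as.numeric(0.4 * X[, 1] - 0.3 * X[, 4] + rnorm(60, 0, 0.3))
  spec <- network_spec(annotation_level = 1, base_unit = 1,
                       unit_ratio = integer(0), activation = "linear",
                       learning_rate = 0.005, momentum = 0,
                       dropout_rate = 0, reg_rate = 0,
                       use_batch_norm = FALSE)
  net <- build_network(geno$snps, tiny_bundle(), tiny_impacts(), spec)
  net <- train_network(net, geno, y, steps = 2000, seed = 1)
  expect_true(all(diff(net$loss_trace) <= 1e-10))
  lsq <- stats::lm(y ~ X)
  expect_equal(utils::tail(net$loss_trace, 1),
               mean(stats::residuals(lsq)^2), tolerance = 1e-3)
})

test_that("prediction is deterministic and equivariant to row order", {
  geno <- tiny_geno(n = 18)
  set.seed(6); y <- rnorm(18)
  spec <- network_spec(annotation_level = 4, base_unit = 6,
                       unit_ratio = c(1, 1, 1), learning_rate = 0.02,
                       dropout_rate = 0.3)
  net <- train_network(build_network(geno$snps, tiny_bundle(),
                                     tiny_impacts(), spec),
                       geno, y, steps = 10, seed = 2)
  X <- geno$codes
  p1 <- predict(net, X)
  expect_identical(p1, predict(net, X))      # dropout off at inference
  perm <- sample(18)
  expect_equal(predict(net, X[perm, ]), p1[perm])
  # identical rows give identical predictions
  Xdup <- X[c(1, 1, 2), ]
  pd <- predict(net, Xdup)
  expect_identical(pd[1], pd[2])
  # all-zero weights give a constant (bias) output
  net0 <- net
  for (l in seq_along(net0$layers)) net0$layers[[l]]$W[] <- 0
  net0$out$W[] <- 0
  expect_equal(length(unique(predict(net0, X))), 1)
})

test_that("training aborts with a diagnostic on divergence", {
  geno <- tiny_geno(n = 16)
  set.seed(8); y <- rnorm(16) * 10
  spec <- network_spec(annotation_level = 1, base_unit = 5,
                       unit_ratio = c(1, 1), learning_rate = 1e7,
                       dropout_rate = 0)
  net <- build_network(geno$snps, tiny_bundle(), tiny_impacts(), spec)
  expect_error(train_network(net, geno, y, steps = 50, seed = 1),
               "non-finite loss at step")
})

test_that("deep_annotation wraps build/train/predict coherently", {
  sim <- small_sim(seed = 31, n = 120)
  spec <- network_spec(base_unit = 10, unit_ratio = c(1, 1, 1),
                       learning_rate = 0.05, dropout_rate = 0.1)
  fit <- deep_annotation(sim$genotypes, sim$phenotype, sim$bundle,
                         sim$impacts, spec = spec, level = 3, steps = 15,
                         seed = 4)
  expect_s3_class(fit, "deep_annotation")
  expect_equal(fit$network$level, 3)
  expect_length(fit$fitted, 120)
  expect_equal(predict(fit), fit$fitted)
  expect_equal(fit$residuals, as.numeric(sim$phenotype) - fit$fitted)
  s <- summary(fit)
  expect_equal(s$steps, 15)
  expect_true(s$optimal_step >= 1 && s$optimal_step <= 15)
})
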