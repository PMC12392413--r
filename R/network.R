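#' Network hyperparameter specification
#'
#' Describes the annotation-structured network: six internal layers whose
#' widths are `base_unit * unit_ratio`, plus a scalar output node. The
#' first three internal layers carry biological identities (cis-regulatory
#' elements / RNA structures, genes, metaterms) and are sparsified by
#' connectivity masks derived from the annotation graph; the remaining
#' layers are unconstrained hidden layers. `annotation_level` selects how
#' much annotation enters the network:
#' \itemize{
#'   \item 1 (genotype) — genotype only, masked MLP;
#'   \item 2 (snp_annotation) — + per-SNP allele-impact channel at the
#'     element layer;
#'   \item 3 (function) — + gene-function term features at the gene layer;
#'   \item 4 (network) — + metaterm module features at the metaterm layer.
#' }
#' Defaults are the voted-optimal settings for this model family:
#' learning rate 0.1, base unit 110, ratio 1:2:4:5:6:7, L2 regularizer at
#' rate 0.01, momentum 0.9, dropout 0.1.
#'
#' @param annotation_level integer 1-4.
#' @param base_unit base width multiplier.
#' @param unit_ratio integer vector of per-layer multipliers; its length is
#'   the number of internal layers (0 gives a direct linear map, useful for
#'   convex sanity checks).
#' @param activation `"relu"`, `"tanh"` or `"linear"`.
#' @param learning_rate,momentum SGD-with-momentum settings.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @param dropout_rate dropout probability in `[0, 1)` (training only).
#' @param reg_norm `"L1"` or `"L2"` weight penalty.
#' @param reg_rate regularizer rate (alpha).
#' @param penalty_coefficient fixed binding penalty coefficient multiplying
#'   the weight norm in the loss (default 1e-5).
#' @param use_batch_norm logical; batch normalization on internal layers.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(annotation_level = 4, base_unit = 110,
                         unit_ratio = c(1, 2, 4, 5, 6, 7),
                         activation = c("relu", "tanh", "linear"),
                         learning_rate = 0.1, momentum = 0.9,
                         bn_momentum = 0.9, dropout_rate = 0.1,
                         reg_norm = c("L2", "L1"), reg_rate = 0.01,
                         penalty_coefficient = 1e-5,
                         use_batch_norm = TRUE) {
  activation <- match.arg(activation)
  reg_norm <- match.arg(reg_norm)
  if (!annotation_level %in% 1:4)
    stop("network_spec: annotation_level must be 1, 2, 3 or 4")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("network_spec: dropout_rate must lie in [0, 1)")
  if (reg_rate < 0) stop("network_spec: reg_rate must be >= 0")
  if (length(unit_ratio) && any(unit_ratio < 1))
    stop("network_spec: unit_ratio entries must be positive integers")
  structure(list(annotation_level = annotation_level, base_unit = base_unit,
                 unit_ratio = unit_ratio, activation = activation,
                 learning_rate = learning_rate, momentum = momentum,
                 bn_momentum = bn_momentum, dropout_rate = dropout_rate,
                 reg_norm = reg_norm, reg_rate = reg_rate,
                 penalty_coefficient = penalty_coefficient,
                 use_batch_norm = use_batch_norm),
            class = "network_spec")
}

#' Layer widths of a network specification
#' @param spec a [network_spec()].
#' @return Integer vector of internal layer widths.
#' @export
layer_widths <- function(spec) as.integer(spec$base_unit * spec$unit_ratio)

#' Penalized training loss
#'
#' Mean squared error plus the binding weight penalty:
#' `loss = (1/n) sum (y - yhat)^2 + penalty_coefficient * alpha *
#' sum |w_i|^k`, with `k = 1` (L1) or `2` (L2) over every weight tensor.
#'
#' @param y_real observed phenotypes.
#' @param y_pred predicted phenotypes (same length, `n >= 1`).
#' @param weights list of weight matrices/vectors (biases excluded).
#' @param reg_norm `"L1"` or `"L2"`.
#' @param reg_rate regularizer rate alpha.
#' @param penalty_coefficient binding penalty coefficient (default 1e-5).
#' @return The scalar loss.
#' @export
compute_loss <- function(y_real, y_pred, weights = list(),
                         reg_norm = "L2", reg_rate = 0,
                         penalty_coefficient = 1e-5) {
  if (length(y_real) == 0) stop("compute_loss: empty phenotype vector")
  if (length(y_real) != length(y_pred))
    stop("compute_loss: length mismatch")
  k <- if (reg_norm == "L1") 1 else 2
  pen <- sum(vapply(weights, function(w) sum(abs(w)^k), numeric(1)))
  mean((y_real - y_pred)^2) + penalty_coefficient * reg_rate * pen
}

## ---------------------------------------------------------------------
## Structure: entity allocation, masks and annotation feature maps
## ---------------------------------------------------------------------

#' Build an annotation-structured network
#'
#' Constructs the masked network for a SNP set and annotation bundle.
#' Internal layer 1 nodes are cis-regulatory elements (noncoding side) and
#' per-coding-SNP RNA-structure units; layer 2 nodes are genes; layer 3
#' nodes are metaterms; deeper layers are unconstrained. Connectivity masks
#' restrict SNP -> element/structure and element/structure -> gene edges to
#' the annotation graph, so every node is traceable to one biological
#' entity and a SNP without an element/gene assignment has exactly zero
#' fan-out (its gradient on the output is identically zero). Annotation
#' enters as fixed, non-trainable feature maps concatenated at the target
#' layer: per-SNP impact-weighted dosages (level >= 2), gene-burden term
#' scores (level >= 3) and metaterm module scores (level 4).
#'
#' @param snps a [snp_table()] for the genotype columns.
#' @param bundle an [annotation_bundle()].
#' @param impacts an [impact_scores()].
#' @param spec a [network_spec()].
#' @param init_seed RNG seed for weight initialization (scaled-uniform).
#' @return An object of class `annot_network`.
#' @export
build_network <- function(snps, bundle, impacts, spec,
                          init_seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  validate_annotation_bundle(bundle, snps = snps)
  level <- spec$annotation_level
  widths <- layer_widths(spec)
  L <- length(widths)
  p <- nrow(snps)
  snp_ids <- snps$snp_id
  coding <- snps$snp_id[snps$category == "coding"]

  ## entity layer 1: elements + one structure unit per coding SNP
  ent1 <- c(bundle$element_intervals$label,
            if (length(coding)) paste0("struct:", coding))
  ent1_type <- c(rep("element", nrow(bundle$element_intervals)),
                 rep("rna_structure", length(coding)))
  snp_ent <- rep(NA_character_, p)
  names(snp_ent) <- snp_ids
  nc <- names(bundle$snp_to_element)
  snp_ent[nc] <- unname(bundle$snp_to_element)
  snp_ent[coding] <- paste0("struct:", coding)

  genes <- bundle$gene_intervals$label
  mts <- colnames(bundle$term_metaterm_weights)
  terms <- colnames(bundle$gene_term_scores)

  delta <- impact_deltas(impacts, snps)

  ## SNP -> gene incidence (delta-weighted), for the term/metaterm features
  P <- matrix(0, p, length(genes), dimnames = list(snp_ids, genes))
  if (length(genes)) {
    e2g <- bundle$element_to_gene
    for (j in seq_len(p)) {
      id <- snp_ids[j]
      gs <- if (!is.na(snp_ent[id]) && startsWith(snp_ent[id], "struct:")) {
        unname(bundle$snp_to_gene[id])
      } else if (!is.na(snp_ent[id])) {
        e2g$gene[e2g$element == snp_ent[id]]
      } else character(0)
      gs <- gs[!is.na(gs)]
      if (length(gs)) P[j, gs] <- delta[id]
    }
    cnt <- colSums(P != 0)
    ok <- cnt > 0
    P[, ok] <- sweep(P[, ok, drop = FALSE], 2, cnt[ok], "/")
  }

  S <- bundle$gene_term_scores     # genes x terms
  Wtm <- bundle$term_metaterm_weights  # terms x metaterms

  node_of <- function(width, ents) {
    if (length(ents) == 0) return(rep(NA_character_, width))
    ents[(seq_len(width) - 1L) %% length(ents) + 1L]
  }
  ent_nodes <- list()
  masks <- vector("list", L)
  in_dims <- integer(L)

  # mask from node entity labels x input entity labels and a pair relation
  pair_mask <- function(row_ents, col_ents, relation) {
    M <- matrix(0, length(row_ents), length(col_ents))
    valid <- which(!is.na(col_ents))
    if (length(valid) == 0) return(M)
    for (i in seq_along(row_ents)) {
      if (is.na(row_ents[i])) next
      hit <- relation(row_ents[i], col_ents[valid])
      M[i, valid[hit]] <- 1
    }
    M
  }
  nodes1 <- nodes2 <- nodes3 <- character(0)
  if (L >= 1) {
    nodes1 <- node_of(widths[1], ent1)
    ent_nodes[[1]] <- nodes1
    gmask <- pair_mask(nodes1, unname(snp_ent[snp_ids]),
                       function(a, b) a == b)
    m1 <- gmask
    if (level >= 2) m1 <- cbind(m1, gmask)
    masks[[1]] <- m1
    in_dims[1] <- ncol(m1)
  }
  if (L >= 2) {
    nodes2 <- node_of(widths[2], genes)
    ent_nodes[[2]] <- nodes2
    link <- matrix(FALSE, length(ent1), length(genes),
                   dimnames = list(ent1, genes))
    if (nrow(bundle$element_to_gene))
      link[cbind(bundle$element_to_gene$element,
                 bundle$element_to_gene$gene)] <- TRUE
    if (length(bundle$snp_to_gene))
      link[cbind(paste0("struct:", names(bundle$snp_to_gene)),
                 unname(bundle$snp_to_gene))] <- TRUE
    m2 <- pair_mask(nodes2, nodes1, function(g, es) link[es, g])
    if (level >= 3 && length(terms)) {
      tm <- pair_mask(nodes2, terms, function(g, ts) S[g, ts] != 0)
      m2 <- cbind(m2, tm)
    }
    masks[[2]] <- m2
    in_dims[2] <- ncol(m2)
  }
  if (L >= 3) {
    nodes3 <- node_of(widths[3], mts)
    ent_nodes[[3]] <- nodes3
    if (length(genes) && length(mts)) {
      reach <- ((abs(S) > 0) %*% (abs(Wtm) > 0)) > 0   # genes x metaterms
      m3 <- pair_mask(nodes3, nodes2, function(m, gs) reach[gs, m])
    } else {
      m3 <- matrix(1, widths[3], widths[2])
    }
    if (level >= 4 && length(mts)) {
      fm <- pair_mask(nodes3, mts, function(a, b) a == b)
      m3 <- cbind(m3, fm)
    }
    masks[[3]] <- m3
    in_dims[3] <- ncol(m3)
  }
  if (L >= 4) {
    for (l in 4:L) {
      ent_nodes[[l]] <- rep(NA_character_, widths[l])
      masks[[l]] <- matrix(1, widths[l], widths[l - 1])
      in_dims[l] <- widths[l - 1]
    }
  }

  ## scaled-uniform initialization on the masked connectivity
  set.seed(init_seed)
  init_mat <- function(nout, nin, mask = NULL) {
    lim <- sqrt(6 / (nin + nout))
    W <- matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
    if (!is.null(mask)) W <- W * mask
    W
  }
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    layers[[l]] <- list(
      W = init_mat(widths[l], in_dims[l], masks[[l]]),
      b = numeric(widths[l]),
      gamma = rep(1, widths[l]), beta = numeric(widths[l]),
      r_mean = numeric(widths[l]), r_var = rep(1, widths[l]))
  }
  out_in <- if (L >= 1) widths[L] else p * (1 + (level >= 2))
  out <- list(W = init_mat(1, out_in), b = 0)

  structure(list(spec = spec, layers = layers, out = out, masks = masks,
                 ent_nodes = ent_nodes, snp_ids = snp_ids,
                 snp_category = stats::setNames(snps$category, snp_ids),
                 snp_ent = snp_ent, ent1 = ent1, ent1_type = ent1_type,
                 genes = genes, terms = terms, metaterms = mts,
                 delta = delta, P = P, S = S, Wtm = Wtm,
                 level = level, trained = FALSE),
            class = "annot_network")
}

# Fixed annotation feature maps for a code matrix (samples x SNPs).
annotation_features <- function(net, X) {
  feats <- list(impact = NULL, term = NULL, metaterm = NULL)
  if (net$level >= 2)
    feats$impact <- sweep(X, 2, net$delta[colnames(X)], "*")
  if (net$level >= 3 && length(net$terms)) {
    B <- X %*% net$P              # impact-weighted gene burden
    feats$term <- (B %*% net$S) / max(1, nrow(net$S))
  }
  if (net$level >= 4 && length(net$metaterms) && !is.null(feats$term))
    feats$metaterm <- (feats$term %*% net$Wtm) / max(1, nrow(net$Wtm))
  feats
}

activate <- function(Y, act) {
  switch(act, relu = pmax(Y, 0), tanh = tanh(Y), linear = Y)
}
activate_grad <- function(Y, act) {
  switch(act, relu = (Y > 0) * 1, tanh = 1 - tanh(Y)^2,
         linear = array(1, dim(Y)))
}

# Forward pass. mode: "train" (batch stats, dropout, update running stats),
# "eval_batch" (batch stats, no dropout, no update -- the deterministic
# training-loss view) or "infer" (running stats, no dropout).
forward_pass <- function(net, X, mode = "infer", keep_cache = FALSE) {
  spec <- net$spec
  L <- length(net$layers)
  eps <- 1e-5
  feats <- annotation_features(net, X)
  cache <- list(inputs = list(), Z = list(), Zhat = list(), mu = list(),
                v = list(), Ypre = list(), drop = list(), H = list())
  A <- X
  for (l in seq_len(L)) {
    In <- A
    if (l == 1 && !is.null(feats$impact)) In <- cbind(A, feats$impact)
    if (l == 2 && !is.null(feats$term)) In <- cbind(A, feats$term)
    if (l == 3 && !is.null(feats$metaterm)) In <- cbind(A, feats$metaterm)
    ly <- net$layers[[l]]
    Z <- In %*% t(ly$W)
    Z <- sweep(Z, 2, ly$b, "+")
    if (spec$use_batch_norm) {
      if (mode == "infer") {
        mu <- ly$r_mean; v <- ly$r_var
      } else {
        mu <- colMeans(Z)
        v <- colMeans(Z^2) - mu^2
        if (mode == "train") {
          net$layers[[l]]$r_mean <- spec$bn_momentum * ly$r_mean +
            (1 - spec$bn_momentum) * mu
          net$layers[[l]]$r_var <- spec$bn_momentum * ly$r_var +
            (1 - spec$bn_momentum) * v
        }
      }
      Zhat <- sweep(sweep(Z, 2, mu), 2, sqrt(v + eps), "/")
      Y <- sweep(sweep(Zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    } else {
      mu <- NULL; v <- NULL; Zhat <- NULL; Y <- Z
    }
    H <- activate(Y, spec$activation)
    if (mode == "train" && spec$dropout_rate > 0) {
      keep <- matrix(stats::runif(length(H)) >= spec$dropout_rate,
                     nrow(H), ncol(H))
      H <- H * keep / (1 - spec$dropout_rate)
    } else keep <- NULL
    if (keep_cache) {
      cache$inputs[l] <- list(In); cache$Z[l] <- list(Z)
      cache$Zhat[l] <- list(Zhat); cache$mu[l] <- list(mu)
      cache$v[l] <- list(v); cache$Ypre[l] <- list(Y)
      cache$drop[l] <- list(keep); cache$H[l] <- list(H)
    }
    A <- H
  }
  if (L == 0 && !is.null(feats$impact)) A <- cbind(A, feats$impact)
  yhat <- as.numeric(A %*% t(net$out$W) + net$out$b)
  if (keep_cache) cache$A_last <- A
  list(yhat = yhat, cache = cache, net = net)
}

penalty_grad <- function(W, spec) {
  if (spec$reg_rate == 0) return(0 * W)
  co <- spec$penalty_coefficient * spec$reg_rate
  if (spec$reg_norm == "L1") co * sign(W) else co * 2 * W
}

# Backward pass for one full-batch step; returns gradients matching the
# parameter layout of the network.
backward_pass <- function(net, X, y, fw) {
  spec <- net$spec
  L <- length(net$layers)
  n <- length(y)
  eps <- 1e-5
  cache <- fw$cache
  grads <- list(layers = vector("list", L), out = NULL)
  dyhat <- matrix(2 * (fw$yhat - y) / n, ncol = 1)
  A_last <- cache$A_last
  grads$out <- list(W = t(dyhat) %*% A_last + penalty_grad(net$out$W, spec),
                    b = sum(dyhat))
  dA <- dyhat %*% net$out$W
  if (L == 0) return(grads)
  for (l in L:1) {
    ly <- net$layers[[l]]
    dH <- dA[, seq_len(ncol(cache$H[[l]])), drop = FALSE]
    if (!is.null(cache$drop[[l]]))
      dH <- dH * cache$drop[[l]] / (1 - spec$dropout_rate)
    dY <- dH * activate_grad(cache$Ypre[[l]], spec$activation)
    if (spec$use_batch_norm) {
      Zhat <- cache$Zhat[[l]]
      vv <- cache$v[[l]] + eps
      dgamma <- colSums(dY * Zhat)
      dbeta <- colSums(dY)
      dZhat <- sweep(dY, 2, ly$gamma, "*")
      # batch-norm backprop with batch statistics
      dZ <- sweep(dZhat -
                    outer(rep(1, n), colMeans(dZhat)) -
                    Zhat * outer(rep(1, n), colMeans(dZhat * Zhat)),
                  2, sqrt(vv), "/")
      db <- colSums(dZ)
    } else {
      dZ <- dY
      dgamma <- 0 * ly$gamma; dbeta <- 0 * ly$beta
      db <- colSums(dZ)
    }
    In <- cache$inputs[[l]]
    dW <- (t(dZ) %*% In + penalty_grad(ly$W, spec)) * net$masks[[l]]
    grads$layers[[l]] <- list(W = dW, b = db, gamma = dgamma, beta = dbeta)
    dIn <- dZ %*% ly$W
    dA <- dIn   # injected blocks are fixed inputs; surplus columns dropped
  }
  grads
}

all_weights <- function(net) {
  c(lapply(net$layers, `[[`, "W"), list(net$out$W))
}

#' Train an annotation-structured network
#'
#' Full-batch gradient descent with momentum on the penalized loss (mean
#' squared error plus the binding weight penalty). Batch normalization uses
#' batch statistics during training and accumulates running statistics with
#' `bn_momentum`; dropout is applied during training only. The recorded
#' `loss_trace` is the deterministic training loss (batch statistics,
#' dropout off) after each update, so a zero learning rate yields a
#' constant trace. An optional validation set records a parallel
#' `validation_trace`.
#'
#' @param net an [build_network()] result.
#' @param genotypes a [geno_matrix()] (or code matrix) over the network's
#'   SNPs.
#' @param phenotypes a [phenotype()] or numeric vector.
#' @param steps number of optimizer updates (`>= 1`).
#' @param seed RNG seed controlling dropout masks.
#' @param validation optional list(genotypes, phenotypes) for a validation
#'   loss trace.
#' @return The trained `annot_network`, with `loss_trace`, `optimal_step`
#'   and (if requested) `validation_trace`.
#' @export
train_network <- function(net, genotypes, phenotypes, steps = 200,
                          seed = 1, validation = NULL) {
  stopifnot(steps >= 1)
  X <- net_codes(net, genotypes)
  y <- as.numeric(phenotypes)
  spec <- net$spec
  set.seed(seed)
  vel <- list(layers = lapply(net$layers, function(ly)
    list(W = 0 * ly$W, b = 0 * ly$b, gamma = 0 * ly$gamma,
         beta = 0 * ly$beta)),
    out = list(W = 0 * net$out$W, b = 0))
  loss_trace <- numeric(steps)
  val_trace <- if (!is.null(validation)) numeric(steps) else NULL
  Xv <- if (!is.null(validation)) net_codes(net, validation$genotypes)
  yv <- if (!is.null(validation)) as.numeric(validation$phenotypes)
  lr <- spec$learning_rate; mom <- spec$momentum
  for (s in seq_len(steps)) {
    fw <- forward_pass(net, X, mode = "train", keep_cache = TRUE)
    net <- fw$net                       # running BN stats updated
    gr <- backward_pass(net, X, y, fw)
    for (l in seq_along(net$layers)) {
      for (par in c("W", "b", "gamma", "beta")) {
        vel$layers[[l]][[par]] <- mom * vel$layers[[l]][[par]] -
          lr * gr$layers[[l]][[par]]
        net$layers[[l]][[par]] <- net$layers[[l]][[par]] +
          vel$layers[[l]][[par]]
      }
    }
    vel$out$W <- mom * vel$out$W - lr * gr$out$W
    vel$out$b <- mom * vel$out$b - lr * gr$out$b
    net$out$W <- net$out$W + vel$out$W
    net$out$b <- net$out$b + vel$out$b
    pred <- forward_pass(net, X, mode = "eval_batch")$yhat
    loss_trace[s] <- compute_loss(y, pred, all_weights(net), spec$reg_norm,
                                  spec$reg_rate, spec$penalty_coefficient)
    if (!is.finite(loss_trace[s]))
      stop("train_network: non-finite loss at step ", s,
           "; lower the learning rate")
    if (!is.null(val_trace)) {
      pv <- forward_pass(net, Xv, mode = "eval_batch")$yhat
      val_trace[s] <- compute_loss(yv, pv, all_weights(net), spec$reg_norm,
                                   spec$reg_rate, spec$penalty_coefficient)
    }
  }
  net$loss_trace <- loss_trace
  net$validation_trace <- val_trace
  net$optimal_step <- optimal_step(loss_trace)
  net$trained <- TRUE
  net
}

net_codes <- function(net, genotypes) {
  X <- if (inherits(genotypes, "geno_matrix")) genotypes$codes else
    as.matrix(genotypes)
  missing_snps <- setdiff(net$snp_ids, colnames(X))
  if (length(missing_snps))
    stop("genotypes lack SNPs the network was built on: ",
         paste(utils::head(missing_snps, 5), collapse = ", "))
  X[, net$snp_ids, drop = FALSE]
}

#' First step attaining the minimum training loss
#'
#' The optimal number of training steps is the first step after which the
#' loss never decreases again, i.e. the first attainment of the global
#' minimum of the loss trace.
#'
#' @param loss_trace numeric vector of per-step losses.
#' @return Integer step index in `[1, length(loss_trace)]`.
#' @export
optimal_step <- function(loss_trace) {
  if (length(loss_trace) == 0) stop("optimal_step: empty loss trace")
  which.min(loss_trace)
}

#' Predict phenotypes from a trained network
#'
#' Deterministic inference: dropout off, batch normalization in inference
#' mode (running statistics).
#'
#' @param object a trained `annot_network`.
#' @param newdata a [geno_matrix()] or code matrix over the network's SNPs.
#' @param ... unused.
#' @return Numeric vector of predictions, one per sample.
#' @export
predict.annot_network <- function(object, newdata, ...) {
  X <- net_codes(object, newdata)
  forward_pass(object, X, mode = "infer")$yhat
}

#' @export
print.annot_network <- function(x, ...) {
  lv <- c("genotype", "snp_annotation", "function", "network")
  cat(sprintf(paste0(
    "Annotation-structured network (level %d: %s)\n",
    "  %d SNPs -> internal widths [%s] -> 1\n"),
    x$level, lv[x$level], length(x$snp_ids),
    paste(vapply(x$layers, function(l) nrow(l$W), integer(1)),
          collapse = ", ")))
  if (x$trained)
    cat(sprintf("  trained %d steps; optimal step %d (loss %.6f)\n",
                length(x$loss_trace), x$optimal_step,
                min(x$loss_trace)))
  invisible(x)
}

#' Fit the annotation-structured genomic selection model
#'
#' One-call interface: builds the masked network for the cohort's SNP set
#' and annotation bundle, trains it, and returns a fitted model object
#' with the usual methods (`print`, `summary`, `predict`, `plot` of the
#' loss trace, `fitted`, `residuals`).
#'
#' @param genotypes a [geno_matrix()] with SNP metadata.
#' @param phenotypes a [phenotype()] or numeric vector.
#' @param bundle an [annotation_bundle()].
#' @param impacts an [impact_scores()].
#' @param spec a [network_spec()]; `level` overrides its annotation level.
#' @param level optional annotation level 1-4.
#' @param steps training steps.
#' @param seed RNG seed (weight init and dropout).
#' @param validation optional list(genotypes, phenotypes).
#' @return An object of class `deep_annotation`.
#' @export
deep_annotation <- function(genotypes, phenotypes, bundle, impacts,
                            spec = network_spec(), level = NULL,
                            steps = 200, seed = 1, validation = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"), !is.null(genotypes$snps))
  if (!is.null(level)) spec$annotation_level <- level
  net <- build_network(genotypes$snps, bundle, impacts, spec,
                       init_seed = seed)
  net <- train_network(net, genotypes, phenotypes, steps = steps,
                       seed = seed + 1L, validation = validation)
  fitted_vals <- predict(net, genotypes)
  structure(list(network = net, fitted = fitted_vals,
                 y = as.numeric(phenotypes),
                 residuals = as.numeric(phenotypes) - fitted_vals),
            class = "deep_annotation")
}

#' @export
print.deep_annotation <- function(x, ...) {
  print(x$network)
  cat(sprintf("  in-sample PCC = %.3f\n",
              suppressWarnings(stats::cor(x$fitted, x$y))))
  invisible(x)
}

#' @export
summary.deep_annotation <- function(object, ...) {
  net <- object$network
  out <- list(level = net$level, steps = length(net$loss_trace),
              optimal_step = net$optimal_step,
              final_loss = utils::tail(net$loss_trace, 1),
              min_loss = min(net$loss_trace),
              pcc = suppressWarnings(stats::cor(object$fitted, object$y)))
  class(out) <- "summary.deep_annotation"
  out
}

#' @export
print.summary.deep_annotation <- function(x, ...) {
  cat(sprintf(paste0("Annotation network (level %d): %d steps, optimal ",
                     "step %d\n  min loss %.6f, final loss %.6f, ",
                     "in-sample PCC %.3f\n"),
              x$level, x$steps, x$optimal_step, x$min_loss, x$final_loss,
              x$pcc))
  invisible(x)
}

#' @export
predict.deep_annotation <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  predict(object$network, newdata)
}

#' @export
fitted.deep_annotation <- function(object, ...) object$fitted

#' @export
residuals.deep_annotation <- function(object, ...) object$residuals

#' @export
plot.deep_annotation <- function(x, ...) {
  plot(x$network$loss_trace, type = "l", xlab = "training step",
       ylab = "penalized loss", main = "Training loss", ...)
  graphics::abline(v = x$network$optimal_step, lty = 2)
  invisible(x)
}
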