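#' Genomic relationship matrix
#'
#' Computes `K = ZZ'/p` on column-standardized genotype codes: each SNP
#' column is centered by twice its allele frequency and scaled by
#' `sqrt(2 f (1 - f))`, so the mean diagonal of `K` is close to 1 and the
#' genetic variance component of a fit against `K` lives on the phenotypic
#' scale. Monomorphic SNPs contribute a zero column.
#'
#' @param genotypes a [geno_matrix()] (or bare code matrix).
#' @param snp_subset optional character vector of SNP ids to restrict to.
#' @return A list of class `grm`: `matrix` (n x n), `p` (SNP count),
#'   `snp_ids`, and the `centers`/`scales` used (kept for prediction on new
#'   genotypes).
#' @export
compute_grm <- function(genotypes, snp_subset = NULL) {
  codes <- if (inherits(genotypes, "geno_matrix")) genotypes$codes else
    as.matrix(genotypes)
  if (!is.null(snp_subset)) {
    if (length(snp_subset) == 0) stop("compute_grm: empty SNP subset")
    missing <- setdiff(snp_subset, colnames(codes))
    if (length(missing))
      stop("compute_grm: unknown SNPs in subset: ",
           paste(utils::head(missing, 5), collapse = ", "))
    codes <- codes[, snp_subset, drop = FALSE]
  }
  Z <- standardize_codes(codes)
  p <- ncol(codes)
  K <- tcrossprod(Z$Z) / p
  structure(list(matrix = K, p = p, snp_ids = colnames(codes),
                 centers = Z$centers, scales = Z$scales),
            class = "grm")
}

standardize_codes <- function(codes, centers = NULL, scales = NULL) {
  if (is.null(centers)) {
    f <- colMeans(codes) / 2
    centers <- 2 * f
    scales <- sqrt(2 * f * (1 - f))
  }
  Z <- sweep(codes, 2, centers)
  ok <- scales > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, scales[ok], "/")
  Z[, !ok] <- 0
  list(Z = Z, centers = centers, scales = scales)
}

# Restricted log-likelihood of y = 1*mu + sum_m g_m + e with
# V = sum_m sigma2[m] * K[[m]] + sigma2_e * I. Includes all constants so
# values are comparable across nested fits.
reml_loglik <- function(sigma2, sigma2_e, Ks, y) {
  n <- length(y)
  V <- diag(sigma2_e, n)
  for (m in seq_along(Ks)) V <- V + sigma2[m] * Ks[[m]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  xvx <- sum(Vi1)
  if (xvx <= 0) return(-Inf)
  mu <- sum(Viy) / xvx
  r <- y - mu
  Vir <- Viy - mu * Vi1
  -0.5 * (logdetV + log(xvx) + sum(r * Vir) + (n - 1) * log(2 * pi))
}

# Single-kernel REML via eigendecomposition; returns variance components,
# fixed effect and the rotated pieces needed for BLUP.
reml_single <- function(K, y, tol = 1e-8) {
  n <- length(y)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  xt <- crossprod(U, rep(1, n))
  prof <- function(log_lambda) {
    lambda <- exp(log_lambda)            # sigma_g2 / sigma_e2
    w <- 1 / (lambda * d + 1)
    xwx <- sum(xt^2 * w)
    mu <- sum(xt * yt * w) / xwx
    r <- yt - xt * mu
    ss <- sum(r^2 * w)
    s2e <- ss / (n - 1)
    -0.5 * (sum(log(lambda * d + 1)) + (n - 1) * log(s2e) + log(xwx) +
              (n - 1) + (n - 1) * log(2 * pi))
  }
  opt <- stats::optimize(prof, c(-20, 20), maximum = TRUE, tol = tol)
  lambda <- exp(opt$maximum)
  w <- 1 / (lambda * d + 1)
  xwx <- sum(xt^2 * w)
  mu <- sum(xt * yt * w) / xwx
  r <- yt - xt * mu
  s2e <- sum(r^2 * w) / (n - 1)
  s2g <- lambda * s2e
  if (!is.finite(s2e) || !is.finite(s2g))
    stop("REML did not converge; optimizer trace: ",
         paste(utils::capture.output(utils::str(opt)), collapse = " "))
  # boundary handling: tiny ratios are clipped to an exact zero component
  if (lambda < 1e-8) s2g <- 0
  list(sigma_g2 = s2g, sigma_e2 = s2e, mu = mu,
       loglik = reml_loglik(s2g, s2e, list(K), y),
       Vinv_r = U %*% ((yt - xt * mu) * (1 / (s2g * d + s2e))))
}

finish_blup_fit <- function(method, y, mu, Vinv_r, Ks, sigma_g2, sigma_e2,
                            loglik, Zs, ps, snp_ids_by_class, centers, scales) {
  g_by_class <- lapply(seq_along(Ks), function(m)
    as.numeric(sigma_g2[m] * (Ks[[m]] %*% Vinv_r)))
  g <- Reduce(`+`, g_by_class)
  u <- stats::setNames(numeric(length(unlist(snp_ids_by_class))),
                       unlist(snp_ids_by_class))
  for (m in seq_along(Ks)) {
    u[snp_ids_by_class[[m]]] <-
      as.numeric((sigma_g2[m] / ps[m]) * crossprod(Zs[[m]], Vinv_r))
  }
  h2 <- sum(sigma_g2) / (sum(sigma_g2) + sigma_e2)
  structure(list(method = method, mu_hat = mu, genetic_values = g,
                 genetic_values_by_class = g_by_class,
                 snp_effects = u,
                 variance = list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                                 log_likelihood = loglik),
                 h2 = h2, fitted = mu + g, residuals = y - mu - g, y = y,
                 centers = centers, scales = scales,
                 snp_ids = names(u)),
            class = "blup_fit")
}

#' GBLUP mixed-model genomic prediction
#'
#' Fits `y = mu + g + e` with `g ~ N(0, K sigma_g^2)` and
#' `e ~ N(0, I sigma_e^2)`, where `K` is the genomic relationship matrix.
#' Variance components are estimated by REML (eigendecomposition of `K`,
#' profiled residual variance). Genetic values are the BLUPs
#' `sigma_g^2 K V^-1 (y - mu)`; per-SNP effects are back-solved from them.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes a [phenotype()] (or numeric vector, sample order
#'   matching the genotypes).
#' @param grm optional precomputed [compute_grm()] result.
#' @return An object of class `blup_fit` with components `mu_hat`,
#'   `genetic_values`, `snp_effects`, `variance` (`sigma_g2`, `sigma_e2`,
#'   `log_likelihood`), `h2`, `fitted`, `residuals`.
#' @seealso [rrblup()], [multiblup()], [predict.blup_fit()]
#' @export
gblup <- function(genotypes, phenotypes, grm = NULL) {
  y <- as.numeric(phenotypes)
  if (length(y) < 3) stop("gblup: need at least 3 samples")
  if (is.null(grm)) grm <- compute_grm(genotypes)
  codes <- if (inherits(genotypes, "geno_matrix")) genotypes$codes else
    as.matrix(genotypes)
  codes <- codes[, grm$snp_ids, drop = FALSE]
  Z <- standardize_codes(codes, grm$centers, grm$scales)$Z
  fit <- reml_single(grm$matrix, y)
  finish_blup_fit("gblup", y, fit$mu, fit$Vinv_r, list(grm$matrix),
                  fit$sigma_g2, fit$sigma_e2, fit$loglik, list(Z),
                  grm$p, list(grm$snp_ids), grm$centers, grm$scales)
}

#' Ridge-regression BLUP (marker-effect model)
#'
#' Fits `y = mu + G u + e` with `u ~ N(0, I sigma_u^2)`. The ridge
#' parameter `lambda = sigma_e^2 / sigma_u^2` is estimated by REML; marker
#' effects are the normal-equation solve
#' `u = (G'G + lambda I)^-1 G'(y - mu)`. Predictions are identical to
#' [gblup()] under the matched variance scaling `K = GG'/p`.
#'
#' @inheritParams gblup
#' @return A `blup_fit` (method `"rrblup"`).
#' @export
rrblup <- function(genotypes, phenotypes) {
  y <- as.numeric(phenotypes)
  if (length(y) < 3) stop("rrblup: need at least 3 samples")
  codes <- if (inherits(genotypes, "geno_matrix")) genotypes$codes else
    as.matrix(genotypes)
  sz <- standardize_codes(codes)
  G <- sz$Z
  p <- ncol(G)
  K <- tcrossprod(G) / p
  fit <- reml_single(K, y)
  sigma_u2 <- fit$sigma_g2 / p
  if (sigma_u2 <= 0) {
    u <- stats::setNames(numeric(p), colnames(codes))
  } else {
    lambda <- fit$sigma_e2 / sigma_u2
    r <- y - fit$mu
    A <- crossprod(G)
    diag(A) <- diag(A) + lambda
    u <- stats::setNames(as.numeric(solve(A, crossprod(G, r))),
                         colnames(codes))
  }
  g <- as.numeric(G %*% u)
  structure(list(method = "rrblup", mu_hat = fit$mu, genetic_values = g,
                 genetic_values_by_class = list(g),
                 snp_effects = u,
                 variance = list(sigma_g2 = fit$sigma_g2,
                                 sigma_e2 = fit$sigma_e2,
                                 sigma_u2 = sigma_u2,
                                 lambda = if (sigma_u2 > 0)
                                   fit$sigma_e2 / sigma_u2 else Inf,
                                 log_likelihood = fit$loglik),
                 h2 = fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2),
                 fitted = fit$mu + g, residuals = y - fit$mu - g, y = y,
                 centers = sz$centers, scales = sz$scales,
                 snp_ids = colnames(codes)),
            class = "blup_fit")
}

#' Multi-kernel BLUP with class-specific variance components
#'
#' Extends [gblup()] to several random effects: the SNP set is partitioned
#' into classes, each with its own relationship matrix
#' `K_m = Z_m Z_m' / p_m` and variance `sigma_m^2`. Components are
#' estimated by REML through bounded quasi-Newton optimization of the
#' restricted log-likelihood of `V = sum_m sigma_m^2 K_m + sigma_e^2 I`.
#'
#' @inheritParams gblup
#' @param snp_classes named character/factor: class label per SNP id; must
#'   cover all SNPs. Empty classes are dropped with a warning.
#' @return A `blup_fit` (method `"multiblup"`) whose `variance$sigma_g2` is
#'   a named per-class vector.
#' @export
multiblup <- function(genotypes, phenotypes, snp_classes) {
  y <- as.numeric(phenotypes)
  codes <- if (inherits(genotypes, "geno_matrix")) genotypes$codes else
    as.matrix(genotypes)
  cls <- snp_classes[colnames(codes)]
  if (anyNA(cls))
    stop("multiblup: snp_classes must cover every SNP in the genotypes")
  labels <- unique(as.character(cls))
  declared <- if (is.factor(snp_classes)) levels(snp_classes) else
    unique(as.character(snp_classes))
  empty <- setdiff(declared, labels)
  if (length(empty))
    warning("multiblup: dropping empty class(es): ",
            paste(empty, collapse = ", "))
  sz <- standardize_codes(codes)
  Zs <- lapply(labels, function(l) sz$Z[, cls == l, drop = FALSE])
  ps <- vapply(Zs, ncol, integer(1))
  Ks <- lapply(seq_along(Zs), function(m) tcrossprod(Zs[[m]]) / ps[m])
  ids <- lapply(labels, function(l) colnames(codes)[cls == l])
  m <- length(Ks)
  vy <- stats::var(y)
  par0 <- log(c(rep(vy / (2 * m), m), vy / 2))
  nll <- function(par) {
    s <- exp(par)
    -reml_loglik(s[seq_len(m)], s[m + 1], Ks, y)
  }
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = log(vy) - 25, upper = log(vy) + 10,
                      control = list(factr = 1e7, maxit = 300))
  if (opt$convergence != 0)
    stop("multiblup: REML did not converge (code ", opt$convergence, "): ",
         opt$message)
  s <- exp(opt$par)
  sigma_g2 <- s[seq_len(m)]
  # boundary report: components at the lower box edge are effectively zero
  sigma_g2[opt$par[seq_len(m)] <= log(vy) - 24] <- 0
  names(sigma_g2) <- labels
  sigma_e2 <- s[m + 1]
  n <- length(y)
  V <- diag(sigma_e2, n)
  for (k in seq_len(m)) V <- V + sigma_g2[k] * Ks[[k]]
  ch <- chol(V)
  Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  mu <- sum(Viy) / sum(Vi1)
  Vinv_r <- Viy - mu * Vi1
  finish_blup_fit("multiblup", y, mu, Vinv_r, Ks, sigma_g2, sigma_e2,
                  -opt$value, Zs, ps, ids, sz$centers, sz$scales)
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, p = %d SNPs\n", toupper(x$method),
              length(x$y), length(x$snp_effects)))
  sg <- x$variance$sigma_g2
  if (length(sg) > 1) {
    cat("  variance components:\n")
    for (l in names(sg)) cat(sprintf("    sigma2[%s] = %.5g\n", l, sg[l]))
  } else {
    cat(sprintf("  sigma_g2 = %.5g\n", sg))
  }
  cat(sprintf("  sigma_e2 = %.5g | h2 = %.3f | REML logLik = %.3f\n",
              x$variance$sigma_e2, x$h2, x$variance$log_likelihood))
  invisible(x)
}

#' @export
summary.blup_fit <- function(object, ...) {
  out <- list(method = object$method, n = length(object$y),
              p = length(object$snp_effects), variance = object$variance,
              h2 = object$h2,
              fit_pcc = stats::cor(object$fitted, object$y))
  class(out) <- "summary.blup_fit"
  out
}

#' @export
print.summary.blup_fit <- function(x, ...) {
  cat(sprintf("%s: n = %d, p = %d, h2 = %.3f, in-sample PCC = %.3f\n",
              toupper(x$method), x$n, x$p, x$h2, x$fit_pcc))
  invisible(x)
}

#' @export
coef.blup_fit <- function(object, ...) object$snp_effects

#' @export
fitted.blup_fit <- function(object, ...) object$fitted

#' @export
residuals.blup_fit <- function(object, ...) object$residuals

#' Predict phenotypes for new genotypes from a BLUP fit
#'
#' New genotype columns are standardized with the training centers/scales
#' and multiplied by the back-solved SNP effects.
#'
#' @param object a `blup_fit`.
#' @param newdata a [geno_matrix()] (or code matrix) with the training SNPs.
#' @param ... unused.
#' @return Numeric vector of predicted phenotypes.
#' @export
predict.blup_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  codes <- if (inherits(newdata, "geno_matrix")) newdata$codes else
    as.matrix(newdata)
  missing_snps <- setdiff(object$snp_ids, colnames(codes))
  if (length(missing_snps))
    stop("predict.blup_fit: newdata lacks SNPs: ",
         paste(utils::head(missing_snps, 5), collapse = ", "))
  codes <- codes[, object$snp_ids, drop = FALSE]
  Z <- standardize_codes(codes, object$centers, object$scales)$Z
  as.numeric(object$mu_hat + Z %*% object$snp_effects)
}
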