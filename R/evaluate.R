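#' Seeded balanced cross-validation folds
#'
#' Random partition of `n` samples into `k` folds whose sizes differ by at
#' most one.
#'
#' @param n number of samples.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed RNG seed.
#' @return A list of class `cv_plan`: `n`, `k`, `fold_id` (integer per
#'   sample), `seed`.
#' @export
make_folds <- function(n, k, seed = 1) {
  if (k < 2 || k > n) stop("make_folds: need 2 <= k <= n")
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(k), n))
  structure(list(n = n, k = k, fold_id = fold_id, seed = seed),
            class = "cv_plan")
}

#' Pearson correlation of predictions, pooled or per fold
#'
#' `mode = "together"` consolidates every testing fold before computing
#' one pooled correlation; `mode = "separate"` computes the correlation
#' within each testing fold. A zero-variance vector makes the correlation
#' undefined; `NA` is returned rather than 0.
#'
#' @param observed,predicted aligned numeric vectors.
#' @param mode `"together"` or `"separate"`.
#' @param plan a [make_folds()] plan (required for `"separate"`).
#' @return A single correlation (`together`) or a per-fold vector
#'   (`separate`).
#' @export
pcc <- function(observed, predicted, mode = c("together", "separate"),
                plan = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(observed) == length(predicted))
  safe_cor <- function(a, b) {
    if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    stats::cor(a, b)
  }
  if (mode == "together") return(safe_cor(observed, predicted))
  if (is.null(plan)) stop("pcc: separate mode needs a cv_plan")
  vapply(seq_len(plan$k), function(f) {
    idx <- plan$fold_id == f
    safe_cor(observed[idx], predicted[idx])
  }, numeric(1))
}

#' Relative efficiency of top-k selection
#'
#' Realized genetic gain when the top `k` individuals are selected by
#' predicted value, relative to selecting them by observed value:
#' `RE(k) = (mean(y[top-k by predicted]) - mean(y)) /
#'          (mean(y[top-k by observed]) - mean(y))`,
#' with both numerator and denominator centered on the full test-set mean.
#' Ties in the rankings are broken by stable sample order. By default
#' "top" means highest phenotype; set `minimize = TRUE` for traits improved
#' by lower values.
#'
#' @param observed,predicted aligned numeric vectors.
#' @param k number of selected individuals (`1 <= k < n`).
#' @param minimize select the lowest instead of the highest values.
#' @return The RE value, or `NA` when the denominator is zero.
#' @export
relative_efficiency <- function(observed, predicted, k, minimize = FALSE) {
  n <- length(observed)
  if (k < 1 || k >= n) stop("relative_efficiency: need 1 <= k < n")
  dir <- if (minimize) 1 else -1
  top_pred <- order(dir * predicted)[seq_len(k)]
  top_obs <- order(dir * observed)[seq_len(k)]
  test_mean <- mean(observed)
  den <- mean(observed[top_obs]) - test_mean
  if (den == 0) return(NA_real_)
  (mean(observed[top_pred]) - test_mean) / den
}

#' Relative-efficiency curve over top fractions or counts
#'
#' @param observed,predicted aligned numeric vectors.
#' @param k_values selected top counts; fractional values in (0, 1) are
#'   interpreted as percentages of the test size (floored, minimum 1).
#' @param minimize see [relative_efficiency()].
#' @return A `data.frame` (`k`, `re`).
#' @export
re_curve <- function(observed, predicted, k_values = (1:10) / 100,
                     minimize = FALSE) {
  n <- length(observed)
  ks <- vapply(k_values, function(k) {
    if (k < 1) max(1L, floor(k * n)) else as.integer(k)
  }, numeric(1))
  data.frame(k = ks,
             re = vapply(ks, function(k)
               relative_efficiency(observed, predicted, k, minimize),
               numeric(1)))
}

#' Paired t test on fold-wise metrics
#'
#' Standard paired t statistic on the per-fold differences of two models'
#' metrics. Zero-variance differences make the test undefined; `NA` is
#' returned.
#'
#' @param metric_a,metric_b per-fold metric vectors of equal length >= 2.
#' @return A list `t`, `p` (two-sided), `df`.
#' @export
paired_t <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2)
  d <- metric_a - metric_b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t <- if (mean(d) == 0) 0 else NA_real_
    return(list(t = t, p = NA_real_, df = length(d) - 1))
  }
  t <- mean(d) / (sd_d / sqrt(length(d)))
  df <- length(d) - 1
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Heritability explained by a SNP subset
#'
#' Restricts the genomic relationship matrix to the given SNPs, fits
#' [gblup()] by REML, and returns `sigma_g2 / (sigma_g2 + sigma_e2)`.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes a [phenotype()] or numeric vector.
#' @param snp_ids non-empty character vector of SNP ids.
#' @return Estimated heritability in `[0, 1]`.
#' @export
heritability_of_subset <- function(genotypes, phenotypes, snp_ids) {
  if (length(snp_ids) == 0) stop("heritability_of_subset: empty subset")
  grm <- compute_grm(genotypes, snp_subset = snp_ids)
  fit <- gblup(genotypes, phenotypes, grm = grm)
  fit$h2
}

#' Cross-validate a genomic prediction model
#'
#' Generic harness: `fit_fun(train_geno, train_phen)` must return an
#' object whose `predict(fit, test_geno)` yields numeric predictions.
#' Every sample is predicted exactly once, by the model that did not see
#' it.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes a [phenotype()] or numeric vector.
#' @param fit_fun function(genotypes, phenotypes) returning a fitted model.
#' @param k number of folds.
#' @param seed fold seed.
#' @param model_label label stored in the result.
#' @return A list of class `cv_result`: `plan`, `predictions` (aligned to
#'   samples), `observed`, `pcc_together`, `pcc_separate`, `re`
#'   (top 1-10 percent curve), `model`.
#' @export
cross_validate <- function(genotypes, phenotypes, fit_fun, k = 5, seed = 1,
                           model_label = "model") {
  y <- as.numeric(phenotypes)
  n <- length(y)
  plan <- make_folds(n, k, seed)
  preds <- rep(NA_real_, n)
  codes <- if (inherits(genotypes, "geno_matrix")) genotypes$codes else
    as.matrix(genotypes)
  for (f in seq_len(k)) {
    test <- plan$fold_id == f
    tr_geno <- codes[!test, , drop = FALSE]
    fit <- fit_fun(tr_geno, y[!test])
    preds[test] <- as.numeric(predict(fit, codes[test, , drop = FALSE]))
  }
  structure(list(plan = plan, predictions = preds, observed = y,
                 pcc_together = pcc(y, preds, "together"),
                 pcc_separate = pcc(y, preds, "separate", plan),
                 re = re_curve(y, preds), model = model_label),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV of %s: pooled PCC = %.3f, per-fold mean = %.3f\n",
              x$plan$k, x$model, x$pcc_together,
              mean(x$pcc_separate, na.rm = TRUE)))
  invisible(x)
}
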