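#' Hyperparameter candidate grid
#'
#' Candidate values per tunable dimension of the annotation network. The
#' default grid covers the values named for this model family: learning
#' rates 0.1 to 1e-5, L1/L2 regularizer norms, momentum 0.9/0.95, and a
#' small set of widths, ratios, regularizer and dropout rates. Every
#' dimension is user-extensible.
#'
#' @param learning_rate,reg_norm,reg_rate,momentum,bn_momentum,
#'   dropout_rate,base_unit per-dimension candidate vectors.
#' @param unit_ratio list of ratio vectors.
#' @return A list of class `hyper_grid`.
#' @export
hyper_grid <- function(learning_rate = c(0.1, 0.01, 0.001, 1e-4, 1e-5),
                       reg_norm = c("L1", "L2"),
                       reg_rate = c(0.1, 0.01, 0.001),
                       momentum = c(0.9, 0.95),
                       bn_momentum = c(0.9, 0.99),
                       dropout_rate = c(0.1, 0.3, 0.5),
                       base_unit = c(55, 110),
                       unit_ratio = list(c(1, 2, 4, 5, 6, 7),
                                         c(1, 2, 3, 4, 5, 6))) {
  g <- list(learning_rate = learning_rate, reg_norm = reg_norm,
            reg_rate = reg_rate, momentum = momentum,
            bn_momentum = bn_momentum, dropout_rate = dropout_rate,
            base_unit = base_unit, unit_ratio = unit_ratio)
  if (any(vapply(g, length, integer(1)) == 0))
    stop("hyper_grid: every dimension needs at least one candidate value")
  class(g) <- "hyper_grid"
  g
}

ratio_key <- function(r) paste(r, collapse = ":")

#' Randomly sample hyperparameter combinations
#'
#' Uniform sampling from the grid product, without replacement when the
#' product holds at least `count` combinations (so the candidates are
#' distinct), with replacement otherwise. Seed-reproducible.
#'
#' @param grid a [hyper_grid()].
#' @param count number of candidates (default 500).
#' @param seed RNG seed.
#' @return A list of candidate settings (named lists, one value per
#'   dimension).
#' @export
sample_candidates <- function(grid, count = 500, seed = 1) {
  stopifnot(count >= 1)
  sizes <- vapply(grid, length, integer(1))
  total <- prod(sizes)
  set.seed(seed)
  idx <- if (total >= count) sample(total, count) else
    sample(total, count, replace = TRUE)
  lapply(idx, function(i) {
    i <- i - 1
    val <- list()
    for (d in names(grid)) {
      k <- i %% sizes[d]
      i <- i %/% sizes[d]
      val[[d]] <- grid[[d]][[k + 1]]
    }
    val
  })
}

candidate_spec <- function(cand, level) {
  network_spec(annotation_level = level,
               base_unit = cand$base_unit, unit_ratio = cand$unit_ratio,
               learning_rate = cand$learning_rate,
               momentum = cand$momentum, bn_momentum = cand$bn_momentum,
               dropout_rate = cand$dropout_rate, reg_norm = cand$reg_norm,
               reg_rate = cand$reg_rate)
}

#' Evaluate hyperparameter candidates by k-fold cross-validation
#'
#' Trains the annotation network per candidate, annotation level and fold,
#' and records the Pearson correlation between predicted and observed
#' test-fold phenotypes, averaged over folds. A training failure or an
#' undefined correlation (e.g. a constant predictor) is recorded as `NA`
#' and excluded from later aggregation.
#'
#' @param candidates list from [sample_candidates()].
#' @param genotypes,phenotypes,bundle,impacts the cohort.
#' @param levels annotation levels to evaluate (default 1:4).
#' @param folds number of CV folds (default 2).
#' @param steps training steps per fold.
#' @param seed seed for folds and training.
#' @return Numeric matrix, candidates x levels, of fold-averaged PCCs.
#' @export
evaluate_candidates <- function(candidates, genotypes, phenotypes, bundle,
                                impacts, levels = 1:4, folds = 2,
                                steps = 60, seed = 1) {
  y <- as.numeric(phenotypes)
  plan <- make_folds(length(y), folds, seed)
  out <- matrix(NA_real_, length(candidates), length(levels),
                dimnames = list(NULL, paste0("level", levels)))
  snps <- genotypes$snps
  for (ci in seq_along(candidates)) {
    for (li in seq_along(levels)) {
      pccs <- vapply(seq_len(folds), function(f) {
        test <- plan$fold_id == f
        res <- tryCatch({
          spec <- candidate_spec(candidates[[ci]], levels[li])
          net <- build_network(snps, bundle, impacts, spec,
                               init_seed = seed + f)
          net <- train_network(net,
                               genotypes$codes[!test, , drop = FALSE],
                               y[!test], steps = steps, seed = seed + f)
          pred <- predict(net, genotypes$codes[test, , drop = FALSE])
          pcc(y[test], pred, "together")
        }, error = function(e) {
          message("candidate ", ci, " level ", levels[li], " fold ", f,
                  " failed: ", conditionMessage(e))
          NA_real_
        })
        if (is.null(res)) NA_real_ else res
      }, numeric(1))
      out[ci, li] <- mean(pccs)   # any failed fold propagates NA
    }
  }
  out
}

#' Tally per-level best values into a hyperparameter vote
#'
#' The voting unit: for one dimension, the best value per (annotation
#' level, statistic) pair — 4 levels x mean/median = 8 selections — is
#' counted as one vote each. The winner is the modal value; ties are
#' broken toward the value with the higher overall average PCC, and a
#' remaining tie falls back to the first-listed value.
#'
#' @param selections character vector of the 8 selected values.
#' @param values the dimension's candidate values (as characters; defines
#'   tally order).
#' @param avg_pcc optional named numeric: overall average PCC per value,
#'   used for tie-breaks.
#' @return A list `votes` (named integer tally over `values`), `winner`,
#'   `tie_break_used`, `tied_avg_pcc`.
#' @export
tally_votes <- function(selections, values, avg_pcc = NULL) {
  values <- as.character(values)
  votes <- vapply(values, function(v) sum(selections == v), integer(1))
  top <- values[votes == max(votes)]
  tie_break_used <- FALSE
  tied_avg_pcc <- NULL
  winner <- top[1]
  if (length(top) > 1 && !is.null(avg_pcc)) {
    tie_break_used <- TRUE
    tied_avg_pcc <- avg_pcc[top]
    winner <- top[which.max(tied_avg_pcc)]
  }
  list(votes = votes, winner = winner, tie_break_used = tie_break_used,
       tied_avg_pcc = tied_avg_pcc)
}

#' Voting selection of the best hyperparameters
#'
#' For every hyperparameter dimension, the PCC of a candidate value is
#' aggregated marginally over all sampled candidates carrying that value;
#' the best value is selected per (level, statistic in mean/median),
#' giving 8 selections, and [tally_votes()] picks the winner (ties broken
#' by the values' overall average PCC).
#'
#' @param pcc_table candidates x levels PCC matrix from
#'   [evaluate_candidates()].
#' @param candidates the matching candidate list.
#' @return A list of class `vote_result`: per dimension, the per-(level,
#'   statistic) selections, vote tally, winner and tie-break details; plus
#'   `optimal`, the winning setting per dimension.
#' @export
select_by_vote <- function(pcc_table, candidates) {
  if (is.null(dim(pcc_table)) || nrow(pcc_table) == 0)
    stop("select_by_vote: empty PCC table")
  if (ncol(pcc_table) < 4)
    stop("select_by_vote: PCC table must cover the 4 annotation levels")
  dims <- setdiff(names(candidates[[1]]), character(0))
  cand_val <- function(d) vapply(candidates, function(cc) {
    v <- cc[[d]]
    if (d == "unit_ratio") ratio_key(v) else as.character(v)
  }, character(1))
  out <- list()
  for (d in dims) {
    vals <- cand_val(d)
    uvals <- sort(unique(vals), method = "radix")
    agg <- function(stat, lvl) {
      per_val <- vapply(uvals, function(v) {
        x <- pcc_table[vals == v, lvl]
        x <- x[!is.na(x)]
        if (length(x) == 0) return(NA_real_)
        if (stat == "mean") mean(x) else stats::median(x)
      }, numeric(1))
      per_val
    }
    selections <- character(0)
    sel_detail <- list()
    for (stat in c("mean", "median")) {
      for (lvl in seq_len(ncol(pcc_table))) {
        per_val <- agg(stat, lvl)
        best <- uvals[which.max(per_val)]
        selections <- c(selections, best)
        sel_detail[[paste0(stat, "_level", lvl)]] <- best
      }
    }
    overall <- vapply(uvals, function(v) {
      x <- pcc_table[vals == v, , drop = FALSE]
      mean(x[!is.na(x)])
    }, numeric(1))
    tally <- tally_votes(selections, uvals, avg_pcc = overall)
    out[[d]] <- c(list(selections = sel_detail), tally)
  }
  optimal <- lapply(out, `[[`, "winner")
  structure(list(dimensions = out, optimal = optimal),
            class = "vote_result")
}

#' @export
print.vote_result <- function(x, ...) {
  cat("Hyperparameter vote:\n")
  for (d in names(x$dimensions)) {
    e <- x$dimensions[[d]]
    tb <- if (e$tie_break_used) " (tie broken by average PCC)" else ""
    cat(sprintf("  %-13s -> %s%s  [votes: %s]\n", d, e$winner, tb,
                paste(sprintf("%s=%d", names(e$votes), e$votes),
                      collapse = ", ")))
  }
  invisible(x)
}
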