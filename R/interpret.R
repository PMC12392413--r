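#' Node importance ranks across cross-validation replicates
#'
#' For each replicate model (one per CV fold), nodes of the requested
#' biological layer are scored by the sum of absolute outgoing weights,
#' ranked descending and normalized by the node count, yielding one rank
#' in `(0, 1]` per node per replicate.
#'
#' Layers: `"metaterm"`, `"gene"`, `"element"`, `"rna_structure"` address
#' internal nodes; `"term"` addresses the injected gene-function features
#' (annotation level >= 3); `"noncoding_snp"` / `"coding_snp"` address the
#' input features.
#'
#' @param models list of trained [build_network()] networks sharing one
#'   specification.
#' @param layer one of the layer names above.
#' @param statistic `"sum_abs"` (default) or `"max_abs"` outgoing-weight
#'   statistic.
#' @return A list of class `node_ranks`: `layer`, `ids`, `entities`,
#'   `ranks` (nodes x replicates matrix).
#' @export
extract_node_weights <- function(models, layer, statistic = c("sum_abs",
                                                              "max_abs")) {
  statistic <- match.arg(statistic)
  stopifnot(length(models) >= 1)
  specs <- lapply(models, function(m) m$spec)
  ok <- vapply(specs, function(s) identical(s, specs[[1]]), logical(1))
  if (!all(ok))
    stop("extract_node_weights: models must share one network_spec")
  red <- if (statistic == "sum_abs") function(w) sum(abs(w)) else
    function(w) max(abs(w))
  per_model <- lapply(models, function(net) node_scores(net, layer, red))
  ids <- per_model[[1]]$ids
  if (length(ids) == 0)
    return(structure(list(layer = layer, ids = character(0),
                          entities = character(0),
                          ranks = matrix(numeric(0), 0, length(models))),
                     class = "node_ranks"))
  scores <- vapply(per_model, `[[`, numeric(length(ids)), "score")
  scores <- matrix(scores, nrow = length(ids))
  N <- length(ids)
  ranks <- apply(scores, 2, function(s) rank(-s, ties.method = "first") / N)
  ranks <- matrix(ranks, nrow = N, dimnames = list(ids, NULL))
  structure(list(layer = layer, ids = ids,
                 entities = per_model[[1]]$entities, ranks = ranks),
            class = "node_ranks")
}

# Outgoing-weight scores for one model and layer.
node_scores <- function(net, layer, red) {
  L <- length(net$layers)
  p <- length(net$snp_ids)
  out_w_of_internal <- function(l) {
    # weights leaving internal layer l: first block of layer l+1 (or the
    # output weights when l is the last internal layer)
    if (l < L) net$layers[[l + 1]]$W[, seq_len(nrow(net$layers[[l]]$W)),
                                     drop = FALSE]
    else matrix(net$out$W[seq_len(nrow(net$layers[[l]]$W))], nrow = 1)
  }
  if (layer %in% c("noncoding_snp", "coding_snp")) {
    want <- if (layer == "noncoding_snp") "noncoding" else "coding"
    idx <- which(net$snp_category == want)
    W1 <- if (L >= 1) net$layers[[1]]$W else net$out$W
    score <- vapply(idx, function(j) {
      w <- W1[, j]
      if (net$level >= 2) w <- c(w, W1[, p + j])
      red(w)
    }, numeric(1))
    return(list(ids = net$snp_ids[idx], entities = net$snp_ids[idx],
                score = score))
  }
  node_ids <- function(prefix, idx) {
    if (length(idx) == 0) return(character(0))
    paste0(prefix, idx)
  }
  if (layer %in% c("element", "rna_structure")) {
    if (L < 1) stop("no internal layers in this network")
    nodes <- net$ent_nodes[[1]]
    type <- net$ent1_type[match(nodes, net$ent1)]
    idx <- which(!is.na(nodes) & type == layer)
    W <- out_w_of_internal(1)
    return(list(ids = node_ids("L1.", idx), entities = nodes[idx],
                score = vapply(idx, function(k) red(W[, k]), numeric(1))))
  }
  if (layer == "gene") {
    if (L < 2) stop("network too shallow for a gene layer")
    nodes <- net$ent_nodes[[2]]
    idx <- which(!is.na(nodes))
    W <- out_w_of_internal(2)
    return(list(ids = node_ids("L2.", idx), entities = nodes[idx],
                score = vapply(idx, function(k) red(W[, k]), numeric(1))))
  }
  if (layer == "term") {
    if (net$level < 3 || L < 2)
      stop("term features require annotation level >= 3")
    W2 <- net$layers[[2]]$W
    off <- nrow(net$layers[[1]]$W)
    ids <- net$terms
    return(list(ids = ids, entities = ids,
                score = vapply(seq_along(ids), function(t)
                  red(W2[, off + t]), numeric(1))))
  }
  if (layer == "metaterm") {
    if (L < 3) stop("network too shallow for a metaterm layer")
    nodes <- net$ent_nodes[[3]]
    idx <- which(!is.na(nodes))
    W <- out_w_of_internal(3)
    return(list(ids = node_ids("L3.", idx), entities = nodes[idx],
                score = vapply(idx, function(k) red(W[, k]), numeric(1))))
  }
  stop("unknown layer: ", layer)
}

#' Beta order-statistic rank-aggregation score
#'
#' Given an item's normalized ranks `r_1..r_m` in `(0, 1]` across `m`
#' independent rank lists, sorts them ascending and evaluates
#' `betaScore_k = P(Beta(k, m - k + 1) <= r_(k))`; the rho score is the
#' minimum over `k`, and the Bonferroni-corrected p value is
#' `min(1, rho * m)`.
#'
#' @param normalized_ranks numeric vector in `(0, 1]`.
#' @return A list `rho`, `p` (corrected p value), `beta_scores`.
#' @export
rho_score <- function(normalized_ranks) {
  r <- normalized_ranks
  if (length(r) < 1) stop("rho_score: need at least one rank")
  if (any(r <= 0 | r > 1)) stop("rho_score: ranks must lie in (0, 1]")
  m <- length(r)
  r <- sort(r)
  bs <- stats::pbeta(r, seq_len(m), m - seq_len(m) + 1)
  rho <- min(bs)
  list(rho = rho, p = min(1, rho * m), beta_scores = bs)
}

#' Aggregate a layer's rank lists into node significance
#'
#' Applies [rho_score()] to every node's ranks across replicates and
#' corrects across the layer's nodes with Benjamini-Hochberg.
#'
#' @param rank_lists a [extract_node_weights()] result.
#' @param alpha significance threshold on the adjusted p value.
#' @return A `data.frame` (`node`, `entity`, `rho`, `p`, `adjusted_p`,
#'   `significant`), sorted by adjusted p then rho.
#' @export
aggregate_layer <- function(rank_lists, alpha = 0.01) {
  ranks <- rank_lists$ranks
  sc <- apply(ranks, 1, function(r) unlist(rho_score(r)[c("rho", "p")]))
  out <- data.frame(node = rank_lists$ids, entity = rank_lists$entities,
                    rho = sc["rho", ], p = sc["p", ],
                    stringsAsFactors = FALSE)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$adjusted_p < alpha
  out[order(out$adjusted_p, out$rho), ]
}

#' Backward tracing of a trained model ensemble
#'
#' Extracts node weights per CV-replicate model at every biological layer
#' the annotation level supports, aggregates ranks into significance
#' ([rho_score()] + Benjamini-Hochberg per layer), and maps significant
#' nodes to their biological entities, reporting the
#' metaterm -> term -> gene -> element/SNP chain.
#'
#' @param models list of trained networks (one per fold).
#' @param bundle the matching [annotation_bundle()].
#' @param alpha_node adjusted-p threshold per node (default 0.01).
#' @return A list of class `backward_trace`: per-layer significance tables
#'   (`layers`), significant entity sets (`significant`), and the
#'   annotation level.
#' @export
backward_trace <- function(models, bundle, alpha_node = 0.01) {
  level <- models[[1]]$level
  L <- length(models[[1]]$layers)
  layer_names <- c("noncoding_snp", "coding_snp")
  if (level >= 2 && L >= 1)
    layer_names <- c(layer_names, "element", "rna_structure")
  if (level >= 3 && L >= 2) layer_names <- c(layer_names, "gene", "term")
  if (level >= 4 && L >= 3) layer_names <- c(layer_names, "metaterm")
  tabs <- list()
  for (ln in layer_names) {
    rl <- extract_node_weights(models, ln)
    if (length(rl$ids) == 0) next
    tabs[[ln]] <- aggregate_layer(rl, alpha = alpha_node)
  }
  sig <- lapply(tabs, function(t) unique(t$entity[t$significant]))
  structure(list(layers = tabs, significant = sig, level = level,
                 alpha_node = alpha_node),
            class = "backward_trace")
}

#' @export
print.backward_trace <- function(x, ...) {
  cat(sprintf("Backward trace (annotation level %d, alpha = %g):\n",
              x$level, x$alpha_node))
  for (ln in names(x$layers))
    cat(sprintf("  %-14s %4d nodes, %3d significant entities\n", ln,
                nrow(x$layers[[ln]]), length(x$significant[[ln]])))
  invisible(x)
}

#' Prioritize candidate cis-regulatory SNPs near significant genes
#'
#' Nominates noncoding SNPs lying within `window` bp of a significant
#' gene (distance from the gene interval boundaries; the exact boundary
#' distance is included), with a significant SNP-layer adjusted p value
#' (`< alpha_snp`), and whose better allele accessibility reaches the
#' open-chromatin peak threshold — SNPs with both allele scores below
#' `impacts$peak_threshold` are excluded regardless of significance.
#' Candidates are ranked by adjusted p.
#'
#' @param trace a [backward_trace()] result (supplies the significant
#'   genes and the SNP-layer significance).
#' @param bundle the [annotation_bundle()] (gene intervals).
#' @param snps the [snp_table()].
#' @param impacts the [impact_scores()].
#' @param window cis window in bp (default 1e6).
#' @param alpha_snp SNP-level adjusted-p threshold (default 0.05).
#' @param significant_genes optional character vector overriding the
#'   trace's significant gene set.
#' @return A `data.frame` (`snp_id`, `chrom`, `pos`, `gene`, `distance`,
#'   `adjusted_p`, `ref_score`, `alt_score`) ranked by adjusted p.
#' @export
prioritize_cis_snps <- function(trace, bundle, snps, impacts,
                                window = 1e6, alpha_snp = 0.05,
                                significant_genes = NULL) {
  genes <- if (is.null(significant_genes)) trace$significant$gene else
    significant_genes
  empty <- data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), gene = character(0),
                      distance = numeric(0), adjusted_p = numeric(0),
                      ref_score = numeric(0), alt_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(genes) == 0 || is.null(trace$layers$noncoding_snp))
    return(empty)
  snp_tab <- trace$layers$noncoding_snp
  pmap <- stats::setNames(snp_tab$adjusted_p, snp_tab$node)
  acc <- impacts$noncoding_access
  gi <- bundle$gene_intervals
  gi <- gi[gi$label %in% genes, , drop = FALSE]
  nc <- snps[snps$category == "noncoding", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(gi))) {
    same <- nc$chrom == gi$chrom[i]
    dist <- pmax(0, pmax(gi$start[i] - nc$pos, nc$pos - (gi$end[i] - 1)))
    hit <- same & dist <= window
    if (!any(hit)) next
    rows[[length(rows) + 1]] <- data.frame(
      snp_id = nc$snp_id[hit], chrom = nc$chrom[hit], pos = nc$pos[hit],
      gene = gi$label[i], distance = dist[hit], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  cand <- do.call(rbind, rows)
  cand$adjusted_p <- unname(pmap[cand$snp_id])
  idx <- match(cand$snp_id, acc$snp_id)
  cand$ref_score <- acc$ref_score[idx]
  cand$alt_score <- acc$alt_score[idx]
  keep <- !is.na(cand$adjusted_p) & cand$adjusted_p < alpha_snp &
    !is.na(cand$ref_score) &
    pmax(cand$ref_score, cand$alt_score) >= impacts$peak_threshold
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$adjusted_p, cand$snp_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
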