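#' Functional annotation bundle
#'
#' The SNP -> element -> gene -> term -> metaterm annotation graph used to
#' structure the prediction network and to define SNP classes for the
#' Bayesian baselines. All intervals are 0-based half-open (BED convention);
#' matrices carry genes/terms in `dimnames`.
#'
#' @param element_intervals cis-regulatory element intervals
#'   (`chrom`, `start`, `end`, `label`).
#' @param snp_to_element named character: noncoding SNP id -> element label.
#' @param gene_intervals gene intervals (`chrom`, `start`, `end`, `label` =
#'   gene id).
#' @param element_to_gene two-column `data.frame` (`element`, `gene`) linking
#'   elements to genes within the cis window.
#' @param snp_to_gene named character: SNP id -> gene id (coding SNPs).
#' @param gene_term_scores numeric matrix, genes x functional terms.
#' @param term_metaterm_weights numeric matrix, terms x metaterms.
#' @param conserved_gene_flags named logical per gene: gene lies in a
#'   conserved regulatory region.
#' @param signature_gene_flags named logical per gene: gene is a signature
#'   gene of some metaterm.
#' @param snps optional [snp_table()]; when given, every mapped SNP must
#'   exist in it.
#' @return A validated object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(element_intervals = empty_intervals(),
                              snp_to_element = character(0),
                              gene_intervals = empty_intervals(),
                              element_to_gene = data.frame(element = character(0),
                                                           gene = character(0)),
                              snp_to_gene = character(0),
                              gene_term_scores = matrix(0, 0, 0),
                              term_metaterm_weights = matrix(0, 0, 0),
                              conserved_gene_flags = logical(0),
                              signature_gene_flags = logical(0),
                              snps = NULL) {
  b <- structure(list(
    element_intervals = element_intervals,
    snp_to_element = snp_to_element,
    gene_intervals = gene_intervals,
    element_to_gene = element_to_gene,
    snp_to_gene = snp_to_gene,
    gene_term_scores = as.matrix(gene_term_scores),
    term_metaterm_weights = as.matrix(term_metaterm_weights),
    conserved_gene_flags = conserved_gene_flags,
    signature_gene_flags = signature_gene_flags
  ), class = "annotation_bundle")
  validate_annotation_bundle(b, snps = snps)
}

empty_intervals <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             label = character(0), stringsAsFactors = FALSE)
}

validate_annotation_bundle <- function(b, snps = NULL) {
  offenders <- function(x) paste(utils::head(unique(x), 5), collapse = ", ")
  elems <- b$element_intervals$label
  genes <- b$gene_intervals$label
  bad <- setdiff(unname(b$snp_to_element), elems)
  if (length(bad))
    stop("annotation_bundle: snp_to_element references unknown elements: ",
         offenders(bad))
  bad <- setdiff(b$element_to_gene$element, elems)
  if (length(bad))
    stop("annotation_bundle: element_to_gene references unknown elements: ",
         offenders(bad))
  bad <- setdiff(c(b$element_to_gene$gene, unname(b$snp_to_gene)), genes)
  if (length(bad))
    stop("annotation_bundle: maps reference unknown genes: ", offenders(bad))
  if (!is.null(snps)) {
    bad <- setdiff(c(names(b$snp_to_element), names(b$snp_to_gene)),
                   snps$snp_id)
    if (length(bad))
      stop("annotation_bundle: mapped SNPs absent from snp_table: ",
           offenders(bad))
  }
  if (length(b$gene_term_scores) && any(!is.finite(b$gene_term_scores)))
    stop("annotation_bundle: gene_term_scores contains non-finite values")
  if (length(b$term_metaterm_weights) && any(!is.finite(b$term_metaterm_weights)))
    stop("annotation_bundle: term_metaterm_weights contains non-finite values")
  bad <- setdiff(names(b$conserved_gene_flags), genes)
  if (length(bad))
    stop("annotation_bundle: conserved_gene_flags name unknown genes: ",
         offenders(bad))
  bad <- setdiff(names(b$signature_gene_flags), genes)
  if (length(bad))
    stop("annotation_bundle: signature_gene_flags name unknown genes: ",
         offenders(bad))
  b
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "Annotation bundle: %d elements, %d genes, %d terms, %d metaterms\n",
    "  snp->element: %d, snp->gene: %d, element->gene links: %d\n"),
    nrow(x$element_intervals), nrow(x$gene_intervals),
    ncol(x$gene_term_scores), ncol(x$term_metaterm_weights),
    length(x$snp_to_element), length(x$snp_to_gene),
    nrow(x$element_to_gene)))
  invisible(x)
}

#' SNP impact scores
#'
#' Allele-level functional impact scores: predicted chromatin accessibility
#' for noncoding SNPs and normalized RNA minimum free energy for coding
#' SNPs, both per allele in `[0, 1]`. `peak_threshold` is the accessibility
#' level above which an allele is considered to sit in an open-chromatin
#' peak.
#'
#' @param noncoding_access `data.frame` (`snp_id`, `ref_score`, `alt_score`).
#' @param coding_mfe `data.frame` (`snp_id`, `ref_score`, `alt_score`).
#' @param peak_threshold accessibility peak threshold in `[0, 1]`.
#' @return An object of class `impact_scores`.
#' @export
impact_scores <- function(noncoding_access = empty_scores(),
                          coding_mfe = empty_scores(),
                          peak_threshold = 0.147) {
  chk <- function(df, what) {
    sc <- c(df$ref_score, df$alt_score)
    if (length(sc) && (any(!is.finite(sc)) || any(sc < 0) || any(sc > 1)))
      stop("impact_scores: ", what, " scores must lie in [0, 1]")
    df
  }
  structure(list(noncoding_access = chk(noncoding_access, "accessibility"),
                 coding_mfe = chk(coding_mfe, "MFE"),
                 peak_threshold = peak_threshold),
            class = "impact_scores")
}

empty_scores <- function() {
  data.frame(snp_id = character(0), ref_score = numeric(0),
             alt_score = numeric(0), stringsAsFactors = FALSE)
}

#' Per-SNP impact deltas
#'
#' Signed allele-impact difference (alt - ref) for every SNP in `snps`,
#' zero for SNPs without a score.
#'
#' @param impacts an [impact_scores()].
#' @param snps a [snp_table()].
#' @return Named numeric vector over `snps$snp_id`.
#' @export
impact_deltas <- function(impacts, snps) {
  d <- stats::setNames(numeric(nrow(snps)), snps$snp_id)
  for (df in list(impacts$noncoding_access, impacts$coding_mfe)) {
    keep <- df$snp_id %in% names(d)
    d[df$snp_id[keep]] <- df$alt_score[keep] - df$ref_score[keep]
  }
  d
}

bundle_files <- c(elements = "elements.bed", genes = "genes.bed",
                  s2e = "snp_to_element.tsv", e2g = "element_to_gene.tsv",
                  s2g = "snp_to_gene.tsv", gts = "gene_term_scores.tsv",
                  tmw = "term_metaterm_weights.tsv", flags = "gene_flags.tsv")

#' Read / write an annotation bundle directory
#'
#' The on-disk layout is a directory of BED/TSV files: `elements.bed`,
#' `genes.bed`, `snp_to_element.tsv`, `element_to_gene.tsv`,
#' `snp_to_gene.tsv`, `gene_term_scores.tsv`, `term_metaterm_weights.tsv`
#' and `gene_flags.tsv`. Read-write round trips are lossless.
#'
#' @param dir directory path.
#' @param snps optional [snp_table()] for cross-validation of the maps.
#' @return `read_annotation_bundle` returns an [annotation_bundle()].
#' @export
read_annotation_bundle <- function(dir, snps = NULL) {
  fp <- function(f) file.path(dir, f)
  read_map <- function(f) {
    df <- utils::read.table(fp(f), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, colClasses = "character")
    stats::setNames(df[[2]], df[[1]])
  }
  read_mat <- function(f) {
    df <- utils::read.table(fp(f), header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE)
    as.matrix(df)
  }
  read_bed_or_empty <- function(f) {
    if (file.size(fp(f)) == 0) empty_intervals() else read_bed(fp(f))
  }
  flags <- utils::read.table(fp(bundle_files["flags"]), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE,
                             colClasses = c("character", "logical", "logical"))
  e2g <- utils::read.table(fp(bundle_files["e2g"]), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  annotation_bundle(
    element_intervals = read_bed_or_empty(bundle_files["elements"]),
    snp_to_element = read_map(bundle_files["s2e"]),
    gene_intervals = read_bed_or_empty(bundle_files["genes"]),
    element_to_gene = e2g,
    snp_to_gene = read_map(bundle_files["s2g"]),
    gene_term_scores = read_mat(bundle_files["gts"]),
    term_metaterm_weights = read_mat(bundle_files["tmw"]),
    conserved_gene_flags = stats::setNames(flags$conserved, flags$gene),
    signature_gene_flags = stats::setNames(flags$signature, flags$gene),
    snps = snps
  )
}

#' @rdname read_annotation_bundle
#' @param bundle an [annotation_bundle()] (for writing).
#' @export
write_annotation_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_map <- function(m, f, cols) {
    utils::write.table(data.frame(a = names(m), b = unname(m)) |>
                         stats::setNames(cols),
                       fp(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat <- function(m, f) {
    utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                       fp(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_bed(bundle$element_intervals, fp(bundle_files["elements"]))
  write_bed(bundle$gene_intervals, fp(bundle_files["genes"]))
  write_map(bundle$snp_to_element, bundle_files["s2e"], c("snp_id", "element"))
  utils::write.table(bundle$element_to_gene, fp(bundle_files["e2g"]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_map(bundle$snp_to_gene, bundle_files["s2g"], c("snp_id", "gene"))
  write_mat(bundle$gene_term_scores, bundle_files["gts"])
  write_mat(bundle$term_metaterm_weights, bundle_files["tmw"])
  genes <- bundle$gene_intervals$label
  flags <- data.frame(
    gene = genes,
    conserved = unname(bundle$conserved_gene_flags[genes]),
    signature = unname(bundle$signature_gene_flags[genes])
  )
  flags$conserved[is.na(flags$conserved)] <- FALSE
  flags$signature[is.na(flags$signature)] <- FALSE
  utils::write.table(flags, fp(bundle_files["flags"]), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read / write impact scores
#'
#' Stored as a single TSV with columns `snp_id`, `category`, `ref_score`,
#' `alt_score`; the accessibility peak threshold is kept in a
#' `#peak_threshold=` header line.
#'
#' @param path file path.
#' @export
read_impact_scores <- function(path) {
  first <- readLines(path, n = 1)
  thr <- if (startsWith(first, "#peak_threshold=")) {
    as.numeric(sub("#peak_threshold=", "", first))
  } else 0.147
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  pick <- function(cat) {
    sub <- df[df$category == cat, c("snp_id", "ref_score", "alt_score")]
    rownames(sub) <- NULL
    sub
  }
  impact_scores(noncoding_access = pick("noncoding"),
                coding_mfe = pick("coding"), peak_threshold = thr)
}

#' @rdname read_impact_scores
#' @param impacts an [impact_scores()] (for writing).
#' @export
write_impact_scores <- function(impacts, path) {
  df <- rbind(
    cbind(impacts$noncoding_access, category = rep("noncoding",
          nrow(impacts$noncoding_access))),
    cbind(impacts$coding_mfe, category = rep("coding",
          nrow(impacts$coding_mfe)))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#peak_threshold=%.17g", impacts$peak_threshold), con)
  utils::write.table(df[, c("snp_id", "category", "ref_score", "alt_score")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
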