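#' Genotype matrix container
#'
#' An `n x p` matrix of allele-dosage codes in `{0, 1, 2}`, where 0 is the
#' homozygote of the cohort's major allele, together with optional SNP
#' metadata. Missing entries are a hard error: complete matrices are required
#' (imputation is assumed to have happened upstream).
#'
#' @param codes integer/numeric matrix, samples in rows, SNPs in columns.
#'   Row names are sample ids, column names SNP ids.
#' @param snps optional [snp_table()] whose `snp_id` matches `colnames(codes)`.
#' @return An object of class `geno_matrix` with elements `codes`, `samples`,
#'   `snps`.
#' @export
geno_matrix <- function(codes, snps = NULL) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("sample", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("snp", seq_len(ncol(codes)))
  if (anyNA(codes)) {
    bad <- colnames(codes)[colSums(is.na(codes)) > 0]
    stop("geno_matrix: missing genotypes are not allowed (impute upstream); ",
         "SNPs with missing entries: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(codes %in% c(0, 1, 2)))
    stop("geno_matrix: genotype codes must all be 0, 1 or 2")
  if (!is.null(snps)) {
    snps <- validate_snp_table(snps)
    if (!setequal(colnames(codes), snps$snp_id))
      stop("geno_matrix: column names do not match snp_table snp_ids")
    # deterministic ordering by (chrom, pos)
    ord <- order(snps$chrom, snps$pos)
    snps <- snps[ord, , drop = FALSE]
    rownames(snps) <- NULL
    codes <- codes[, snps$snp_id, drop = FALSE]
  }
  structure(list(codes = codes, samples = rownames(codes), snps = snps),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d SNPs%s\n",
              nrow(x$codes), ncol(x$codes),
              if (is.null(x$snps)) " (no SNP metadata)" else ""))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Read genotypes from TSV or VCF
#'
#' The TSV layout is samples by SNPs: a header row of SNP ids and a first
#' column of sample ids. VCF input is restricted to biallelic SNPs; genotype
#' codes are oriented so that 0 is the homozygote of the major allele in the
#' loaded cohort (ties between alleles are broken toward REF). Any missing
#' genotype (`./.` or NA) is a load error naming the SNP.
#'
#' @param path path to the genotype file.
#' @param format `"tsv_matrix"` or `"vcf"`.
#' @param snps optional [snp_table()] supplying metadata for TSV input.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv_matrix", "vcf"), snps = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_genotypes: file not found: ", path)
  if (format == "tsv_matrix") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    geno_matrix(as.matrix(df), snps = snps)
  } else {
    read_genotypes_vcf(path)
  }
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))   # single-record files come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
    nchar(fix[, "ALT"]) != 1
  if (any(multi))
    stop("read_genotypes: non-biallelic or non-SNP VCF records at ",
         paste(utils::head(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), 5),
               collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alt_counts <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || grepl("\\.", g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    sum(alleles == "1")
  })
  if (anyNA(alt_counts)) {
    bad <- rownames(alt_counts)[rowSums(is.na(alt_counts)) > 0]
    if (is.null(bad)) bad <- which(rowSums(is.na(alt_counts)) > 0)
    stop("read_genotypes: missing genotype(s) at SNP(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; imputation is out of scope, supply complete genotypes")
  }
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  # orient to the major allele; ties broken toward REF
  alt_freq <- rowMeans(alt_counts) / 2
  codes <- t(alt_counts)
  flip <- alt_freq > 0.5
  codes[, flip] <- 2L - codes[, flip]
  colnames(codes) <- ids
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  major <- ifelse(flip, alt, ref)
  minor <- ifelse(flip, ref, alt)
  snps <- snp_table(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                    major, minor, category = "noncoding")
  geno_matrix(codes, snps = snps)
}

#' Write a genotype matrix as TSV
#'
#' @param geno a [geno_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(sample = rownames(geno$codes), geno$codes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Phenotype vector
#'
#' A named numeric vector of trait values, one per sample, carrying the trait
#' name as an attribute.
#'
#' @param values numeric vector of finite trait values.
#' @param samples sample ids, same order as `values`.
#' @param trait trait name.
#' @return A named numeric vector of class `phenotype`.
#' @export
phenotype <- function(values, samples = names(values), trait = "trait") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("phenotype: values must be finite")
  if (is.null(samples)) samples <- paste0("sample", seq_along(values))
  names(values) <- samples
  attr(values, "trait") <- trait
  class(values) <- "phenotype"
  values
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("Phenotype '%s': n = %d, mean = %.4g, sd = %.4g\n",
              attr(x, "trait"), length(x), mean(x), stats::sd(x)))
  invisible(x)
}

#' Read / write phenotypes as a two-column TSV (sample, value)
#'
#' @param path file path; header names the trait in the second column.
#' @param phen a [phenotype()] vector (for writing).
#' @return `read_phenotypes` returns a [phenotype()].
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  phenotype(df[[2]], samples = as.character(df[[1]]),
            trait = colnames(df)[2])
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phen, path) {
  df <- data.frame(sample = names(phen), value = as.numeric(phen))
  colnames(df)[2] <- attr(phen, "trait")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
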