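#' SNP metadata table
#'
#' Construct and validate the SNP metadata table used throughout the package.
#' Positions are 1-based (matching SNP names such as `"chr10:23833431"`);
#' on-disk interval files use the 0-based half-open BED convention and are
#' converted on read/write.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions (`>= 1`).
#' @param ref_allele,alt_allele single-character nucleotides.
#' @param category `"coding"` or `"noncoding"` for every SNP.
#' @param nonsynonymous logical; `TRUE` for SNPs predicted to cause a
#'   nonsynonymous coding change. Defaults to `FALSE`.
#'
#' @return A `data.frame` of class `snp_table` with one row per SNP.
#' @export
#' @examples
#' snp_table(c("s1", "s2"), c("chr1", "chr1"), c(100L, 250L),
#'           c("A", "C"), c("G", "T"), c("noncoding", "coding"))
snp_table <- function(snp_id, chrom, pos, ref_allele, alt_allele,
                      category, nonsynonymous = FALSE) {
  snp_id <- as.character(snp_id)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  nonsynonymous <- rep_len(as.logical(nonsynonymous), length(snp_id))
  tab <- data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele),
    category = as.character(category),
    nonsynonymous = nonsynonymous,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("snp_table", "data.frame")
  validate_snp_table(tab)
}

validate_snp_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  if (anyDuplicated(tab$snp_id))
    stop("snp_table: duplicated snp_id values: ",
         paste(unique(tab$snp_id[duplicated(tab$snp_id)]), collapse = ", "))
  if (any(is.na(tab$pos)) || any(tab$pos < 1L))
    stop("snp_table: positions must be integers >= 1 (1-based)")
  bad <- !tab$category %in% c("coding", "noncoding")
  if (any(bad))
    stop("snp_table: category must be 'coding' or 'noncoding' for every SNP; ",
         "offenders: ", paste(utils::head(tab$snp_id[bad], 5), collapse = ", "))
  nuc <- c("A", "C", "G", "T")
  if (!all(tab$ref_allele %in% nuc) || !all(tab$alt_allele %in% nuc))
    stop("snp_table: alleles must be single nucleotides A/C/G/T")
  tab
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("SNP table: %d SNPs (%d coding, %d noncoding) on %d chromosome(s)\n",
              nrow(x), sum(x$category == "coding"),
              sum(x$category == "noncoding"), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write / read a SNP table as TSV
#'
#' @param tab a [snp_table()].
#' @param path file path.
#' @return `read_snp_table` returns a validated `snp_table`.
#' @export
write_snp_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_table
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(snp_id = "character",
                                         chrom = "character"))
  snp_table(df$snp_id, df$chrom, df$pos, df$ref_allele, df$alt_allele,
            df$category, df$nonsynonymous)
}
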