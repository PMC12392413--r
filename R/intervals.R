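#' Read / write BED interval files
#'
#' Intervals are kept in the BED convention throughout: 0-based half-open
#' `[start, end)`. SNP positions are 1-based; a SNP maps to an interval when
#' `start <= pos < end` (so a SNP at the exclusive `end` coordinate is
#' outside, see [assign_snp_to_elements()]).
#'
#' @param path file path.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4)
    df[[4]] <- paste0("iv", seq_len(nrow(df)))
  df <- df[, 1:4]
  colnames(df) <- c("chrom", "start", "end", "label")
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$label <- as.character(df$label)
  if (any(df$end <= df$start)) stop("read_bed: intervals must satisfy start < end")
  df
}

#' @rdname read_bed
#' @param intervals interval `data.frame` as returned by `read_bed`.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Merge overlapping or book-ended intervals
#'
#' Overlapping (and directly adjacent) intervals on the same chromosome are
#' merged; the merged interval carries the label of its first constituent in
#' (chrom, start) order.
#'
#' @param intervals interval `data.frame` (`chrom`, `start`, `end`, `label`).
#' @return A merged interval `data.frame`, sorted by (chrom, start).
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  ord <- order(intervals$chrom, intervals$start, intervals$end)
  iv <- intervals[ord, , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  k <- 1L
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$chrom[i] == out$chrom[k] && iv$start[i] <= out$end[k]) {
      out$end[k] <- max(out$end[k], iv$end[i])
    } else {
      k <- k + 1L
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Assign SNPs to cis-regulatory element intervals
#'
#' Maps each SNP to the unique merged interval containing its position
#' (`start <= pos < end`). SNPs contained in no interval are absent from the
#' returned map; that is a valid outcome, not an error.
#'
#' @param snps a [snp_table()].
#' @param intervals interval `data.frame` (merged internally).
#' @return Named character vector: `snp_id -> interval label`.
#' @export
assign_snp_to_elements <- function(snps, intervals) {
  iv <- merge_intervals(intervals)
  out <- character(0)
  for (ch in unique(snps$chrom)) {
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    sc <- snps[snps$chrom == ch, , drop = FALSE]
    if (nrow(ivc) == 0 || nrow(sc) == 0) next
    idx <- findInterval(sc$pos, ivc$start)   # last interval with start <= pos
    hit <- idx >= 1 & ifelse(idx >= 1, sc$pos < ivc$end[pmax(idx, 1)], FALSE)
    if (any(hit)) {
      m <- ivc$label[idx[hit]]
      names(m) <- sc$snp_id[hit]
      out <- c(out, m)
    }
  }
  out[intersect(snps$snp_id, names(out))]
}
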