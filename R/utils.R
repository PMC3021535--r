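# shared small helpers

# genome may be a named character vector or a Biostrings::DNAStringSet
chrom_seq <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
    return(as.character(genome[[chrom]]))
  }
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  genome[[chrom]]
}

chrom_lengths <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    stats::setNames(Biostrings::width(genome), names(genome))
  else vapply(genome, nchar, integer(1))
}

reverse_complement_chr <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""),
                character(1)))
}

# integer allocation of n into groups proportional to p (sums to n)
allocate_counts <- function(n, p) {
  k <- floor(n * p)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- n * p - k
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1L
  }
  as.integer(k)
}

# data.frame(chrom,start,end) -> GRanges
df_granges <- function(df, extra = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  if (!is.null(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}
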