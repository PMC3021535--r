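#' Scan a sequence for PWM matches at a p-value threshold
#'
#' Scores every offset of `sequence` on both strands with the PWM's log-odds
#' matrix and reports a match wherever the score's upper-tail probability
#' under the background model (the exact [score_distribution()]) is below
#' `p_threshold`. Windows containing `N` are skipped silently and counted in
#' the `n_skipped` attribute. Minus-strand matches are scored by the
#' reverse-complemented matrix on the forward sequence; a match's `position`
#' is always the leftmost base of its span in forward coordinates (1-based).
#'
#' @param sequence character string or `Biostrings::DNAString` over
#'   `A C G T N`.
#' @param x a `pwm` object
#' @param p_threshold match cut-off, in (0, 1]; a match requires
#'   `p_value < p_threshold` (strict).
#' @param dist optional precomputed `score_distribution` for `x` (reuse this
#'   across calls when scanning many sequences).
#' @param both_strands scan the minus strand too (default TRUE).
#' @return data.frame with columns `position`, `strand`, `score`, `p_value`,
#'   `pwm_id`, sorted by position with `+` before `-` at equal position.
#'   A sequence shorter than the motif yields zero rows. Attribute
#'   `n_skipped` counts N-containing windows (per strand).
#' @export
scan_pwm <- function(sequence, x, p_threshold = 1e-4, dist = NULL,
                     both_strands = TRUE) {
  stopifnot(inherits(x, "pwm"), p_threshold > 0, p_threshold <= 1)
  if (is.null(dist)) dist <- score_distribution(x)
  seq_chr <- toupper(as.character(sequence))
  codes <- match(strsplit(seq_chr, "")[[1L]], DNA_BASES)
  w <- nrow(x$counts)
  L <- length(codes)
  empty <- data.frame(position = integer(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      pwm_id = character(), stringsAsFactors = FALSE)
  if (L < w) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  strand_scan <- function(pw) {
    K <- score_bins(pw, dist$bin_width)
    lo <- log_odds(pw)
    n <- L - w + 1L
    bins <- rep(0L, n)
    score <- rep(0, n)
    for (j in seq_len(w)) {
      cj <- codes[j:(j + n - 1L)]
      bins <- bins + K[j, ][cj]   # NA codes (N) propagate
      score <- score + lo[j, ][cj]
    }
    list(bins = bins, score = score)
  }
  res <- list(strand_scan(x))
  strands <- "+"
  if (both_strands) {
    res <- c(res, list(strand_scan(pwm_reverse_complement(x))))
    strands <- c("+", "-")
  }
  out <- list()
  n_skipped <- 0L
  for (k in seq_along(res)) {
    bins <- res[[k]]$bins
    n_skipped <- n_skipped + sum(is.na(bins))
    p <- rep(NA_real_, length(bins))
    ok <- !is.na(bins)
    p[ok] <- tail_p_bins(dist, bins[ok])
    hit <- which(ok & p < p_threshold)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        position = hit, strand = strands[[k]], score = res[[k]]$score[hit],
        p_value = p[hit], pwm_id = x$id, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  m <- do.call(rbind, out)
  m <- m[order(m$position, match(m$strand, c("+", "-"))), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "n_skipped") <- n_skipped
  m
}

#' Write motif matches as BED6
#'
#' One line per match; `name` is the PWM id, `score` is `-log10(p)` capped at
#' 1000, coordinates follow the BED 0-based half-open convention.
#'
#' @param matches data.frame from [scan_pwm()], plus a `chrom` column
#' @param width motif width (to compute span ends)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_matches_bed <- function(matches, width, path) {
  stopifnot(is.data.frame(matches), "chrom" %in% names(matches))
  gr <- GenomicRanges::GRanges(
    matches$chrom,
    IRanges::IRanges(start = matches$position, width = width),
    strand = matches$strand,
    name = matches$pwm_id,
    score = pmin(1000, -log10(matches$p_value)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
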