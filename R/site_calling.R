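#' Call bound segments from probe-level measurements
#'
#' A thresholded run-joining caller: maximal runs of probes with
#' `pxbar < pxbar_threshold`, allowing up to `max_gap_probes` interior
#' non-significant probes, retained when the run has at least `min_probes`
#' significant members. The segment span runs from the first significant
#' probe's start to the last significant probe's end; interior gap probes are
#' kept as members. Each segment's peak is the probe with the lowest
#' P\[Xbar\] (see [assign_peak()]).
#'
#' @param probes data.frame with columns `chrom`, `start`, `end`, `fold`,
#'   `pxbar` (probes need not be sorted)
#' @param pxbar_threshold per-probe significance cut-off (default 1e-3)
#' @param max_gap_probes interior non-significant probes tolerated (default 1)
#' @param min_probes minimum significant probes per segment (default 2)
#' @return data.frame of class `"bound_segments"`: `chrom`, `start`, `end`,
#'   `n_probes`, `n_significant`, `peak_start`, `peak_end`, `peak_center`,
#'   `peak_fold`, `max_fold`, `min_pxbar`, sorted by (chrom, start), with the
#'   member probe rows attached as a list column `probe_rows` (row indices
#'   into the sorted input, stored in attribute `"probes"`).
#' @export
call_segments <- function(probes, pxbar_threshold = 1e-3,
                          max_gap_probes = 1L, min_probes = 2L) {
  stopifnot(is.data.frame(probes),
            all(c("chrom", "start", "end", "fold", "pxbar") %in%
                  names(probes)),
            pxbar_threshold > 0, pxbar_threshold <= 1,
            max_gap_probes >= 0, min_probes >= 1)
  if (nrow(probes) && (any(probes$end <= probes$start) ||
                       any(probes$fold <= 0) ||
                       any(probes$pxbar <= 0 | probes$pxbar > 1)))
    stop("invalid probe rows: need end > start, fold > 0, pxbar in (0, 1]")
  probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
  rownames(probes) <- NULL
  out <- list()
  for (ch in unique(probes$chrom)) {
    p <- probes[probes$chrom == ch, , drop = FALSE]
    sig <- which(p$pxbar < pxbar_threshold)
    if (!length(sig)) next
    run_start <- sig[1L]
    prev <- sig[1L]
    members <- list()
    flush <- function(a, b) members[[length(members) + 1L]] <<- c(a, b)
    for (s in sig[-1L]) {
      if (s - prev - 1L > max_gap_probes) {
        flush(run_start, prev)
        run_start <- s
      }
      prev <- s
    }
    flush(run_start, prev)
    for (m in members) {
      idx <- m[1L]:m[2L]
      seg <- p[idx, , drop = FALSE]
      n_sig <- sum(seg$pxbar < pxbar_threshold)
      if (n_sig < min_probes) next
      pk <- assign_peak(seg)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = seg$start[1L], end = seg$end[nrow(seg)],
        n_probes = nrow(seg), n_significant = n_sig,
        peak_start = pk$peak_start, peak_end = pk$peak_end,
        peak_center = pk$peak_center, peak_fold = pk$peak_fold,
        max_fold = max(seg$fold), min_pxbar = min(seg$pxbar),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_probes = integer(), n_significant = integer(),
               peak_start = integer(), peak_end = integer(),
               peak_center = integer(), peak_fold = numeric(),
               max_fold = numeric(), min_pxbar = numeric(),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("bound_segments", "data.frame")
  res
}

#' Assign the peak of a bound segment
#'
#' The peak is the member probe with the lowest P\[Xbar\]; ties are broken by
#' higher fold change, then by leftmost position. The peak center is the
#' floor midpoint of that probe's span. Invariant to probe input order.
#'
#' @param seg_probes data.frame of the segment's probes (`start`, `end`,
#'   `fold`, `pxbar`)
#' @return list with `peak_start`, `peak_end`, `peak_center`, `peak_fold`,
#'   `peak_pxbar`
#' @export
assign_peak <- function(seg_probes) {
  stopifnot(nrow(seg_probes) >= 1)
  o <- order(seg_probes$pxbar, -seg_probes$fold, seg_probes$start)
  i <- o[1L]
  list(peak_start = seg_probes$start[i], peak_end = seg_probes$end[i],
       peak_center = (seg_probes$start[i] + seg_probes$end[i]) %/% 2L,
       peak_fold = seg_probes$fold[i], peak_pxbar = seg_probes$pxbar[i])
}

#' Filter ChIP segments against mock-ChIP segments
#'
#' A segment is dropped only when it is completely contained in the union of
#' the mock segments it overlaps AND its min P\[Xbar\] is not at least
#' `pxbar_ratio_keep`-fold stronger (smaller) than the best overlapping mock
#' min P\[Xbar\]. Partial overlap, no overlap, or a much stronger P\[Xbar\]
#' keeps the segment. Every decision is annotated.
#'
#' @param segments,mock_segments `bound_segments` (or data.frames with
#'   `chrom`, `start`, `end`, `min_pxbar`)
#' @param pxbar_ratio_keep strength ratio regarded as "much stronger"
#'   (default 100)
#' @return list with `kept`, `dropped` (both subsets of `segments` with an
#'   added `reason` column)
#' @export
filter_against_mock <- function(segments, mock_segments,
                                pxbar_ratio_keep = 100) {
  seg_gr <- df_granges(segments)
  mock_gr <- df_granges(mock_segments)
  ov <- GenomicRanges::findOverlaps(seg_gr, mock_gr)
  reason <- rep("no mock overlap", nrow(segments))
  drop <- rep(FALSE, nrow(segments))
  for (i in unique(S4Vectors::queryHits(ov))) {
    mocks <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    mock_union <- IRanges::reduce(IRanges::ranges(mock_gr[mocks]))
    contained <- any(IRanges::start(mock_union) <= segments$start[i] &
                       IRanges::end(mock_union) >= segments$end[i])
    best_mock <- min(mock_segments$min_pxbar[mocks])
    stronger <- segments$min_pxbar[i] < best_mock / pxbar_ratio_keep
    if (contained && !stronger) {
      drop[i] <- TRUE
      reason[i] <- sprintf(
        "contained in mock with comparable min P[Xbar] (%.3g vs %.3g)",
        segments$min_pxbar[i], best_mock)
    } else if (!contained) {
      reason[i] <- "partial mock overlap"
    } else {
      reason[i] <- sprintf(
        "contained in mock but much stronger min P[Xbar] (%.3g vs %.3g)",
        segments$min_pxbar[i], best_mock)
    }
  }
  segments$reason <- reason
  list(kept = segments[!drop, , drop = FALSE],
       dropped = segments[drop, , drop = FALSE])
}

#' Compare bound segments between two conditions (HS vs RT)
#'
#' Overlap is any base-pair intersection. Overlapping pairs (each first-set
#' segment matched to the second-set segment with the largest intersection)
#' contribute a fold ratio computed on their representative peak probes.
#'
#' @param hs_segments,rt_segments `bound_segments` tables (need `chrom`,
#'   `start`, `end`, `peak_fold`)
#' @return list of class `"condition_comparison"`: `frac_rt_in_hs` (fraction
#'   of RT segments overlapping an HS segment), `frac_hs_with_rt`,
#'   `pairs` (data.frame hs/rt indices and `fold_ratio` = HS peak fold / RT
#'   peak fold), `mean_ratio`
#' @export
compare_conditions <- function(hs_segments, rt_segments) {
  hs_gr <- df_granges(hs_segments)
  rt_gr <- df_granges(rt_segments)
  ov <- GenomicRanges::findOverlaps(rt_gr, hs_gr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  pairs <- data.frame(rt = integer(), hs = integer(),
                      fold_ratio = numeric())
  if (length(qh)) {
    w <- IRanges::width(IRanges::pintersect(IRanges::ranges(rt_gr)[qh],
                                            IRanges::ranges(hs_gr)[sh]))
    best <- vapply(split(seq_along(qh), qh),
                   function(ii) ii[which.max(w[ii])], integer(1))
    pairs <- data.frame(
      rt = qh[best], hs = sh[best],
      fold_ratio = hs_segments$peak_fold[sh[best]] /
        rt_segments$peak_fold[qh[best]])
  }
  structure(list(
    frac_rt_in_hs = if (nrow(rt_segments))
      length(unique(qh)) / nrow(rt_segments) else NA_real_,
    frac_hs_with_rt = if (nrow(hs_segments))
      length(unique(sh)) / nrow(hs_segments) else NA_real_,
    pairs = pairs,
    mean_ratio = if (nrow(pairs)) mean(pairs$fold_ratio) else NA_real_),
    class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<condition_comparison> %.1f%% of RT segments overlap HS; ",
           "%.1f%% of HS segments have RT signal; mean HS/RT peak fold ",
           "ratio %.2f (%d pairs)\n"),
    100 * x$frac_rt_in_hs, 100 * x$frac_hs_with_rt, x$mean_ratio,
    nrow(x$pairs)))
  invisible(x)
}

#' Write bound segments as an extended BED file
#'
#' BED3 coordinates plus columns `max_fold`, `min_pxbar`, `peak_start`,
#' `peak_end`, `peak_center` (peak coordinates 1-based, as in the rest of
#' the package).
#'
#' @param segments a `bound_segments` table
#' @param path output file
#' @return `path`, invisibly
#' @export
write_segments_bed <- function(segments, path) {
  df <- data.frame(chrom = segments$chrom, start = segments$start - 1L,
                   end = segments$end, max_fold = segments$max_fold,
                   min_pxbar = segments$min_pxbar,
                   peak_start = segments$peak_start,
                   peak_end = segments$peak_end,
                   peak_center = segments$peak_center)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
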