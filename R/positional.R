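#' Windowed motif-match histogram around segment peaks
#'
#' Scans the sequence flanking each peak (`+/- range` bp, truncated at
#' chromosome ends with length bookkeeping) for PWM matches below
#' `p_threshold` and bins each match by the offset of its start from the
#' peak center, in `width`-bp windows aggregated over all peaks.
#'
#' @param peaks data.frame with columns `chrom` and `peak_center` (or
#'   `peak`/`center`)
#' @param genome named character vector or `DNAStringSet`
#' @param x a `pwm`
#' @param p_threshold match cut-off (default 1e-4)
#' @param range scan half-width around each peak (default 2500)
#' @param width window width (default 50)
#' @param dist optional precomputed [score_distribution()]
#' @return object of class `"window_histogram"`: `pwm_id`, `window_width`,
#'   `range`, `breaks`, `counts`, `offsets` (all match offsets), `n_peaks`,
#'   `p_threshold`, `n_matches`, `covered` (bp of scanned sequence available
#'   per offset position, for truncation-adjusted expectations)
#' @export
match_histogram <- function(peaks, genome, x, p_threshold = 1e-4,
                            range = 2500, width = 50, dist = NULL) {
  stopifnot(inherits(x, "pwm"), range > 0, width > 0)
  centers <- peak_centers(peaks)
  if (is.null(dist)) dist <- score_distribution(x)
  lens <- chrom_lengths(genome)
  offsets <- integer(0)
  covered <- integer(2L * range + 1L)  # offsets -range..range
  for (i in seq_len(nrow(centers))) {
    ch <- centers$chrom[i]
    if (!ch %in% names(lens)) stop("peak on unknown chromosome: ", ch)
    ctr <- centers$center[i]
    s <- max(1L, ctr - as.integer(range))
    e <- min(lens[[ch]], ctr + as.integer(range))
    if (e < s) next
    covered[(s - ctr + range + 1L):(e - ctr + range + 1L)] <-
      covered[(s - ctr + range + 1L):(e - ctr + range + 1L)] + 1L
    seq_i <- substr(chrom_seq(genome, ch), s, e)
    m <- scan_pwm(seq_i, x, p_threshold, dist = dist)
    if (nrow(m)) {
      off <- s + m$position - 1L - ctr
      offsets <- c(offsets, off[off >= -range & off < range])
    }
  }
  breaks <- seq.int(-range, range, by = width)
  counts <- if (length(offsets))
    tabulate(pmin(floor((offsets + range) / width) + 1L,
                  length(breaks) - 1L), nbins = length(breaks) - 1L)
  else integer(length(breaks) - 1L)
  structure(list(pwm_id = x$id, window_width = width, range = range,
                 breaks = breaks, counts = counts, offsets = offsets,
                 n_peaks = nrow(centers), p_threshold = p_threshold,
                 n_matches = length(offsets), covered = covered),
            class = "window_histogram")
}

# tolerate the different peak-table spellings used across modules
peak_centers <- function(peaks) {
  stopifnot(is.data.frame(peaks), "chrom" %in% names(peaks))
  col <- intersect(c("peak_center", "peak", "center"), names(peaks))[1L]
  if (is.na(col)) stop("peaks need a peak_center / peak / center column")
  data.frame(chrom = as.character(peaks$chrom),
             center = as.integer(peaks[[col]]), stringsAsFactors = FALSE)
}

#' @export
print.window_histogram <- function(x, ...) {
  cat(sprintf(
    "<window_histogram> %s: %d matches (p<%g) over %d peaks, %d x %d bp windows\n",
    x$pwm_id, x$n_matches, x$p_threshold, x$n_peaks, length(x$counts),
    x$window_width))
  invisible(x)
}

#' @export
plot.window_histogram <- function(x, ...) {
  mids <- utils::head(x$breaks, -1) + x$window_width / 2
  graphics::barplot(x$counts, names.arg = mids, space = 0, border = NA,
                    xlab = "offset from peak (bp)", ylab = "matches",
                    main = x$pwm_id, ...)
  invisible(x)
}

#' Center-versus-flank chi-square test of positional enrichment
#'
#' Compares the number of matches immediately around the peak (offsets
#' -500..+500) with the local background (-1000..-550 and +550..+1000)
#' in a 1-df goodness-of-fit chi-square without continuity correction. The
#' expected split is proportional to the available interval lengths
#' (1001 : 902 bp per fully covered peak; truncated peaks contribute their
#' covered lengths).
#'
#' @param hist a `window_histogram` covering at least +/-1000 bp
#' @param center_range,flank_inner,flank_outer interval bounds (bp)
#' @return object of class `"center_flank_test"`: `center_count`,
#'   `flank_count`, `expected` (center, flank), `chi2`, `p`, `degenerate`
#'   (TRUE when no matches fall in either interval; then `p` = 1)
#' @export
center_flank_test <- function(hist, center_range = 500, flank_inner = 550,
                              flank_outer = 1000) {
  stopifnot(inherits(hist, "window_histogram"),
            hist$range >= flank_outer)
  off <- hist$offsets
  cc <- sum(abs(off) <= center_range)
  fc <- sum(abs(off) >= flank_inner & abs(off) <= flank_outer)
  idx <- seq_along(hist$covered) - hist$range - 1L   # offset per position
  center_len <- sum(hist$covered[abs(idx) <= center_range])
  flank_len <- sum(hist$covered[abs(idx) >= flank_inner &
                                  abs(idx) <= flank_outer])
  if (cc + fc == 0 || center_len == 0 || flank_len == 0) {
    return(structure(list(center_count = cc, flank_count = fc,
                          expected = c(center = NA_real_, flank = NA_real_),
                          chi2 = NA_real_, p = 1, degenerate = TRUE),
                     class = "center_flank_test"))
  }
  pr <- c(center_len, flank_len) / (center_len + flank_len)
  ts <- suppressWarnings(stats::chisq.test(c(cc, fc), p = pr))
  structure(list(center_count = cc, flank_count = fc,
                 expected = stats::setNames((cc + fc) * pr,
                                            c("center", "flank")),
                 chi2 = unname(ts$statistic), p = unname(ts$p.value),
                 degenerate = FALSE),
            class = "center_flank_test")
}

#' @export
print.center_flank_test <- function(x, ...) {
  if (x$degenerate)
    cat("<center_flank_test> no matches in test intervals; p = 1\n")
  else
    cat(sprintf(
      "<center_flank_test> center %d vs flank %d (expected %.1f : %.1f), chi2 = %.2f, p = %.3g\n",
      x$center_count, x$flank_count, x$expected[1], x$expected[2], x$chi2,
      x$p))
  invisible(x)
}

#' Compare all nGAAn-unit orientations of the heat shock element
#'
#' Builds the 8 triplet arrangements over {GAA, TTC} with
#' [make_triplet_pwm()], computes a [match_histogram()] and
#' [center_flank_test()] for each arrangement at each match threshold, and
#' ranks arrangements by center enrichment (observed / expected center
#' count) at the strictest threshold.
#'
#' @param peaks,genome as in [match_histogram()]
#' @param thresholds match p-value cut-offs (default `c(1e-4, 1e-5)`)
#' @param range,width histogram geometry
#' @return object of class `"orientation_scan"`: `results` (data.frame
#'   `arrangement`, `p_threshold`, `center`, `flank`, `chi2`, `p`,
#'   `enrichment`), `histograms` (nested list), `ranking` (arrangements
#'   ordered by decreasing center enrichment at the strictest threshold)
#' @export
orientation_scan <- function(peaks, genome, thresholds = c(1e-4, 1e-5),
                             range = 2500, width = 50) {
  units <- expand.grid(u1 = c("GAA", "TTC"), u2 = c("GAA", "TTC"),
                       u3 = c("GAA", "TTC"), stringsAsFactors = FALSE)
  rows <- list(); hists <- list()
  for (i in seq_len(nrow(units))) {
    arr <- unlist(units[i, ], use.names = FALSE)
    pw <- make_triplet_pwm(arr)
    dist <- score_distribution(pw)
    for (thr in thresholds) {
      h <- match_histogram(peaks, genome, pw, p_threshold = thr,
                           range = range, width = width, dist = dist)
      ts <- center_flank_test(h)
      enr <- if (ts$degenerate || ts$expected[["center"]] == 0) 0
             else ts$center_count / ts$expected[["center"]]
      rows[[length(rows) + 1L]] <- data.frame(
        arrangement = pw$id, p_threshold = thr, center = ts$center_count,
        flank = ts$flank_count, chi2 = ts$chi2, p = ts$p,
        enrichment = enr, stringsAsFactors = FALSE)
      hists[[pw$id]][[sprintf("%g", thr)]] <- h
    }
  }
  res <- do.call(rbind, rows)
  strict <- res[res$p_threshold == min(thresholds), ]
  ranking <- strict$arrangement[order(-strict$enrichment)]
  structure(list(results = res, histograms = hists, ranking = ranking),
            class = "orientation_scan")
}

#' @export
print.orientation_scan <- function(x, ...) {
  cat("<orientation_scan> arrangements by center enrichment:\n")
  print(x$results[order(x$results$p_threshold, -x$results$enrichment),
                  c("arrangement", "p_threshold", "center", "flank", "p",
                    "enrichment")],
        row.names = FALSE)
  invisible(x)
}

#' Screen a PWM library for group-specific positional enrichment
#'
#' For every PWM in the library and each peak group (HSF-bound promoters and
#' HSF-bound introns): a center-versus-flank chi-square with Bonferroni
#' correction over the library size; every PWM passing in a group is
#' re-tested with a scrambled version of its matrix (seeded column
#' permutation) and excluded if the scrambled matrix also passes -- the
#' control for base-composition bias. A promoter-versus-intron two-sample
#' chi-square on (center, flank) counts tests whether near-peak enrichment
#' differs between the groups.
#'
#' @param promoter_peaks,intron_peaks peak data.frames (may have zero rows;
#'   an empty group is skipped and flagged)
#' @param genome named character vector or `DNAStringSet`
#' @param pwm_library list of `pwm` objects
#' @param p_match per-match scan cut-off (default 1e-4)
#' @param alpha Bonferroni-corrected test-level cut-off (default 5.6e-2)
#' @param range,width histogram geometry (range must cover the +/-1000 test
#'   window)
#' @param scramble_seed seed for the scrambled-matrix controls
#' @return object of class `"group_screen"` with `table` (one row per PWM:
#'   per-group counts, Bonferroni-adjusted p-values, scrambled-control
#'   p-values, `flag` in promoter/intron/both/none, and the
#'   promoter-vs-intron chi-square), `n_pwms`, `skipped_groups`
#' @export
group_screen <- function(promoter_peaks, intron_peaks, genome, pwm_library,
                         p_match = 1e-4, alpha = 5.6e-2, range = 2500,
                         width = 50, scramble_seed = 1L) {
  if (inherits(pwm_library, "pwm")) pwm_library <- list(pwm_library)
  K <- length(pwm_library)
  stopifnot(K >= 1)
  groups <- list(promoter = promoter_peaks, intron = intron_peaks)
  skipped <- names(groups)[vapply(groups, function(g)
    is.null(g) || nrow(g) == 0, logical(1))]
  rows <- list()
  for (pw in pwm_library) {
    dist <- score_distribution(pw)
    rec <- list(pwm_id = pw$id)
    enriched <- c(promoter = FALSE, intron = FALSE)
    for (gname in names(groups)) {
      if (gname %in% skipped) {
        rec[[paste0(gname, "_center")]] <- NA_integer_
        rec[[paste0(gname, "_flank")]] <- NA_integer_
        rec[[paste0(gname, "_p_bonf")]] <- NA_real_
        next
      }
      h <- match_histogram(groups[[gname]], genome, pw, p_match,
                           range = range, width = width, dist = dist)
      ts <- center_flank_test(h)
      p_bonf <- min(1, ts$p * K)
      over <- !ts$degenerate && ts$center_count > ts$expected[["center"]]
      enriched[[gname]] <- over && p_bonf < alpha
      rec[[paste0(gname, "_center")]] <- ts$center_count
      rec[[paste0(gname, "_flank")]] <- ts$flank_count
      rec[[paste0(gname, "_p_bonf")]] <- p_bonf
    }
    rec$scrambled_p_bonf <- NA_real_
    rec$control_passed <- FALSE
    if (any(enriched)) {
      spw <- scramble_columns(pw, seed = scramble_seed)
      sdist <- score_distribution(spw)
      worst <- 1
      ctrl <- FALSE
      for (gname in names(groups)[enriched]) {
        h <- match_histogram(groups[[gname]], genome, spw, p_match,
                             range = range, width = width, dist = sdist)
        ts <- center_flank_test(h)
        pb <- min(1, ts$p * K)
        worst <- min(worst, pb)
        if (!ts$degenerate && ts$center_count > ts$expected[["center"]] &&
            pb < alpha) ctrl <- TRUE
      }
      rec$scrambled_p_bonf <- worst
      rec$control_passed <- ctrl
      if (ctrl) enriched[] <- FALSE   # composition artifact: exclude
    }
    rec$flag <- if (enriched[["promoter"]] && enriched[["intron"]]) "both"
      else if (enriched[["promoter"]]) "promoter"
      else if (enriched[["intron"]]) "intron" else "none"
    # promoter-vs-intron two-sample test on (center, flank) counts
    if (!length(skipped)) {
      tab <- matrix(c(rec$promoter_center, rec$promoter_flank,
                      rec$intron_center, rec$intron_flank), 2, byrow = TRUE)
      pv <- tryCatch(chi2_2x2(tab)$p, error = function(e) NA_real_)
      rec$promoter_vs_intron_p <- pv
    } else rec$promoter_vs_intron_p <- NA_real_
    rows[[length(rows) + 1L]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), n_pwms = K,
                 skipped_groups = skipped, alpha = alpha,
                 p_match = p_match),
            class = "group_screen")
}

#' @export
print.group_screen <- function(x, ...) {
  cat(sprintf("<group_screen> %d PWMs at match p<%g, Bonferroni alpha %g\n",
              x$n_pwms, x$p_match, x$alpha))
  if (length(x$skipped_groups))
    cat("  skipped empty group(s):",
        paste(x$skipped_groups, collapse = ", "), "\n")
  print(x$table[, c("pwm_id", "promoter_p_bonf", "intron_p_bonf", "flag")],
        row.names = FALSE)
  invisible(x)
}

#' Type-I error simulation for the center-versus-flank test
#'
#' Places `n_matches` match offsets uniformly over the +/-1000-bp test
#' region for each replicate and records whether the chi-square rejects at
#' `alpha` -- the null calibration check for [center_flank_test()].
#'
#' @param n_reps replicates (default 1000)
#' @param n_matches matches per replicate (default 50)
#' @param alpha nominal level (default 0.05)
#' @param seed RNG seed
#' @return list: `rejection_rate`, `n_reps`, `alpha`
#' @export
center_flank_null_sim <- function(n_reps = 1000, n_matches = 50,
                                  alpha = 0.05, seed = 1L) {
  set.seed(seed)
  rej <- logical(n_reps)
  template <- structure(list(range = 1000, covered = rep(1L, 2001L)),
                        class = "window_histogram")
  for (r in seq_len(n_reps)) {
    template$offsets <- sample(-1000:1000, n_matches, TRUE)
    ts <- center_flank_test(template)
    rej[r] <- !ts$degenerate && ts$p < alpha
  }
  list(rejection_rate = mean(rej), n_reps = n_reps, alpha = alpha)
}
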