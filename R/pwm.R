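#' Position weight matrix
#'
#' Constructs a position weight matrix (PWM) from per-position base counts.
#' The object stores raw counts together with a background base-frequency
#' model and a pseudocount rule; log-odds scores and exact score-distribution
#' p-values are derived from it by [log_odds()] and [score_distribution()].
#'
#' @param counts numeric matrix with one row per motif position and columns
#'   `A`, `C`, `G`, `T` (in that order if unnamed). All entries must be
#'   non-negative.
#' @param id character identifier for the matrix.
#' @param background base frequencies for `A`, `C`, `G`, `T`; must be strictly
#'   positive and sum to 1. Defaults to uniform 0.25.
#' @param pseudocount either `NULL` (default: 1% of each position's total
#'   count, added as `pseudocount * background` per base) or a single
#'   non-negative number applied to every position.
#' @return an object of class `"pwm"`.
#' @export
pwm <- function(counts, id = "pwm", background = rep(0.25, 4),
                pseudocount = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("`counts` must have 4 columns (A, C, G, T)")
  if (is.null(colnames(counts))) colnames(counts) <- DNA_BASES
  counts <- counts[, DNA_BASES, drop = FALSE]
  if (nrow(counts) < 1L) stop("PWM width must be >= 1")
  if (any(counts < 0)) stop("PWM counts must be non-negative")
  if (length(background) != 4L || any(background <= 0))
    stop("`background` must be 4 strictly positive frequencies")
  if (abs(sum(background) - 1) > 1e-9)
    stop("`background` must sum to 1")
  if (!is.null(pseudocount)) {
    stopifnot(length(pseudocount) == 1L, pseudocount >= 0)
  }
  background <- stats::setNames(as.numeric(background), DNA_BASES)
  structure(
    list(id = as.character(id), counts = counts, background = background,
         pseudocount = pseudocount),
    class = "pwm"
  )
}

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: %d positions, consensus %s\n",
              x$id, nrow(x$counts), pwm_consensus(x)))
  invisible(x)
}

#' PWM width (number of positions)
#' @param x a `pwm` object
#' @return integer width
#' @export
pwm_width <- function(x) nrow(x$counts)

#' Majority-base consensus string of a PWM
#' @param x a `pwm` object
#' @return character consensus; positions with no dominant base (less than
#'   half the position total) are written `n`.
#' @export
pwm_consensus <- function(x) {
  paste(apply(x$counts, 1L, function(r) {
    tot <- sum(r)
    b <- which.max(r)
    if (tot == 0 || r[b] <= tot / 2) "n" else DNA_BASES[b]
  }), collapse = "")
}

# per-position pseudocount vector under the object's rule
pwm_pseudocounts <- function(x) {
  tot <- rowSums(x$counts)
  if (is.null(x$pseudocount)) 0.01 * tot else rep(x$pseudocount, nrow(x$counts))
}

#' Log-odds score matrix of a PWM
#'
#' Converts counts to natural-log odds against the background model:
#' `entry(i, b) = log((counts(i, b) + pc_i * background(b)) /
#' (sum_b' counts(i, b') + pc_i)) - log(background(b))`, where `pc_i` is the
#' position's pseudocount.
#'
#' @param x a `pwm` object
#' @return numeric matrix (positions x 4) of log-odds scores.
#' @export
log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  pc <- pwm_pseudocounts(x)
  tot <- rowSums(x$counts)
  if (any(tot + pc == 0))
    stop("position with zero total counts and zero pseudocount")
  bg <- matrix(x$background, nrow(x$counts), 4L, byrow = TRUE)
  num <- x$counts + pc * bg
  # a zero cell with pseudocount 0 scores -Inf (the base never matches)
  lo <- log(num / (tot + pc)) - log(bg)
  dimnames(lo) <- dimnames(x$counts)
  lo
}

#' Reverse complement of a PWM
#' @param x a `pwm` object
#' @return a `pwm` with reversed positions and complemented bases; the
#'   background is complement-swapped accordingly.
#' @export
pwm_reverse_complement <- function(x) {
  stopifnot(inherits(x, "pwm"))
  cts <- x$counts[rev(seq_len(nrow(x$counts))), c("T", "G", "C", "A"),
                  drop = FALSE]
  colnames(cts) <- DNA_BASES
  pwm(cts, id = paste0(x$id, "_rc"),
      background = unname(x$background[c("T", "G", "C", "A")]),
      pseudocount = x$pseudocount)
}

#' Permute PWM columns (scrambled-matrix control)
#'
#' Applies a seeded uniform permutation to the motif positions. The multiset
#' of position columns is preserved, destroying positional structure while
#' keeping overall base composition -- the standard control for composition
#' bias in positional-enrichment screens.
#'
#' @param x a `pwm` object
#' @param seed integer seed for the permutation
#' @return a `pwm` with permuted positions, id suffixed `_scrambled`.
#' @export
scramble_columns <- function(x, seed = 1L) {
  stopifnot(inherits(x, "pwm"))
  perm <- with_local_seed(seed, sample.int(nrow(x$counts)))
  pwm(x$counts[perm, , drop = FALSE], id = paste0(x$id, "_scrambled"),
      background = unname(x$background), pseudocount = x$pseudocount)
}

# run code under a temporary RNG state, restoring the caller's afterwards
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Build an HSE-style triplet PWM from 5-bp nGAAn/nTTCn units
#'
#' The heat shock element is three adjacent 5-bp units, each `n` + a 3-bp
#' informative core (`GAA` or its reverse complement `TTC`) + `n`. The
#' canonical inverted-repeat element is `nGAAnnTTCnnGAAn`
#' (arrangement `c("GAA", "TTC", "GAA")`); the 8 possible arrangements of the
#' two unit types give the orientation variants compared by
#' [orientation_scan()].
#'
#' @param arrangement character vector of length 3 over `"GAA"` / `"TTC"`.
#' @param core_count count given to the consensus base at informative
#'   positions (spacer `n` positions get a flat 25/25/25/25 column).
#' @param background,pseudocount passed to [pwm()].
#' @return a 15-position `pwm`.
#' @export
make_triplet_pwm <- function(arrangement = c("GAA", "TTC", "GAA"),
                             core_count = 100, background = rep(0.25, 4),
                             pseudocount = NULL) {
  if (length(arrangement) != 3L || !all(arrangement %in% c("GAA", "TTC")))
    stop("`arrangement` must be 3 tokens over {\"GAA\", \"TTC\"}")
  unit <- function(core) {
    m <- matrix(0, 5L, 4L, dimnames = list(NULL, DNA_BASES))
    m[1L, ] <- m[5L, ] <- 25
    for (i in 1:3) m[i + 1L, strsplit(core, "")[[1L]][i]] <- core_count
    m
  }
  cts <- do.call(rbind, lapply(arrangement, unit))
  pwm(cts, id = paste0("HSE_", paste(arrangement, collapse = "-")),
      background = background, pseudocount = pseudocount)
}

#' Exact score distribution of a PWM under its background model
#'
#' Computes the exact probability distribution of the log-odds score of a
#' background-generated sequence of the motif's width, by position-wise
#' convolution over scores discretized to `bin_width`. The resulting tail
#' probability P(score >= s) is the match p-value used by [scan_pwm()]
#' (the Patser convention: single position, single strand, no
#' multiple-testing adjustment).
#'
#' @param x a `pwm` object
#' @param bin_width score discretization (natural-log units), default 1e-3.
#' @return an object of class `"score_distribution"` with elements
#'   `bin_width`, `min_bin` (integer index of the lowest score bin), `mass`
#'   (probability per bin) and `tail` (upper-tail probability per bin).
#' @export
score_distribution <- function(x, bin_width = 1e-3) {
  stopifnot(inherits(x, "pwm"), bin_width > 0, bin_width <= 1e-3)
  K <- score_bins(x, bin_width)
  bg <- x$background
  mass <- 1
  lo <- 0L
  for (i in seq_len(nrow(K))) {
    kmin <- min(K[i, ]); kmax <- max(K[i, ])
    new_lo <- lo + kmin
    new <- numeric(length(mass) + (kmax - kmin))
    for (b in 1:4) {
      sh <- K[i, b] - kmin
      idx <- seq_along(mass) + sh
      new[idx] <- new[idx] + mass * bg[b]
    }
    mass <- new
    lo <- new_lo
  }
  structure(
    list(pwm_id = x$id, bin_width = bin_width, min_bin = lo, mass = mass,
         tail = rev(cumsum(rev(mass)))),
    class = "score_distribution"
  )
}

# integer score bins, the shared discretization for distribution and
# scanning; -Inf entries (zero cells, zero pseudocount) are floored 50 score
# units below the lowest finite entry, far past any usable threshold
score_bins <- function(x, bin_width) {
  lo <- log_odds(x)
  if (any(!is.finite(lo))) {
    floor_score <- min(lo[is.finite(lo)]) - 50
    lo[!is.finite(lo)] <- floor_score
  }
  K <- round(lo / bin_width)
  storage.mode(K) <- "integer"
  K
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "<score_distribution> %s: %d bins of %g, score range [%.3f, %.3f]\n",
    x$pwm_id, length(x$mass), x$bin_width, x$min_bin * x$bin_width,
    (x$min_bin + length(x$mass) - 1) * x$bin_width))
  invisible(x)
}

# tail probability for integer bin-sum scores
tail_p_bins <- function(dist, bins) {
  idx <- bins - dist$min_bin + 1L
  idx[idx < 1L] <- 1L
  idx[idx > length(dist$tail)] <- length(dist$tail)
  dist$tail[idx]
}

#' Match p-value of a log-odds score
#'
#' @param dist a `score_distribution`
#' @param score numeric log-odds score(s)
#' @return upper-tail probability P(score' >= score) under the background
#'   model, resolved at the distribution's bin width.
#' @export
match_pvalue <- function(dist, score) {
  stopifnot(inherits(dist, "score_distribution"))
  tail_p_bins(dist, as.integer(round(score / dist$bin_width)))
}
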