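# Independent oracles and tiny fixtures shared across test files.
# These deliberately avoid the package's own code paths.

# exhaustive tail probability of the binned log-odds score: enumerates all
# 4^w background sequences and sums their probabilities
oracle_tail_by_enumeration <- function(pw, bin_width = 1e-3) {
  lo <- log_odds(pw)
  K <- round(lo / bin_width)
  w <- nrow(lo)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  binsum <- integer(nrow(grid))
  prob <- numeric(nrow(grid)) + 0
  bg <- pw$background
  pr <- rep(1, nrow(grid))
  for (j in seq_len(w)) {
    binsum <- binsum + K[j, grid[, j]]
    pr <- pr * bg[grid[, j]]
  }
  agg <- rowsum(pr, binsum)
  s <- as.integer(rownames(agg))
  o <- order(s)
  s <- s[o]; m <- agg[o]
  list(bins = s, tail = rev(cumsum(rev(m))))
}

# textbook Pearson chi-square for a 2x2 table, from the marginals
oracle_chi2_2x2 <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  chi2 <- sum((m - e)^2 / e)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# hand-coded Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# per-base brute-force genome composition fractions
oracle_composition <- function(models, chrom_lengths, promoter_radius) {
  tx <- models$transcripts
  ex <- models$exons
  tot <- sum(chrom_lengths)
  intragenic <- 0; promoter <- 0; intronic <- 0
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    in_tx <- logical(L); in_prom <- logical(L); in_ex <- logical(L)
    sel <- which(tx$chrom == ch)
    for (i in sel) {
      in_tx[tx$start[i]:tx$end[i]] <- TRUE
      a <- max(1, tx$tss[i] - promoter_radius)
      b <- min(L, tx$tss[i] + promoter_radius)
      in_prom[a:b] <- TRUE
    }
    for (j in which(ex$tx_id %in% tx$tx_id[sel]))
      in_ex[ex$start[j]:ex$end[j]] <- TRUE
    intragenic <- intragenic + sum(in_tx)
    promoter <- promoter + sum(in_prom)
    intronic <- intronic + sum(in_tx & !in_ex)
  }
  c(intragenic = intragenic / tot, promoter = promoter / tot,
    intronic = intronic / tot)
}

rc_chr <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""),
                character(1)))
}

random_seq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

random_pwm <- function(w, seed = 1, id = "rand") {
  set.seed(seed)
  m <- matrix(stats::rpois(4 * w, 20) + 1, w, 4)
  pwm(m, id = id)
}

# a two-gene annotation used by several annotation tests:
# geneA (+): exon1 5000..5199, intron1 5200..7999, exon2 8000..8399
# geneB (-): exon 20000..20999 (single exon, TSS at 20999)
tiny_models <- function() {
  gene_models(
    transcripts = data.frame(
      tx_id = c("geneA.t1", "geneB.t1"),
      gene_id = c("geneA", "geneB"),
      chrom = "chr1", strand = c("+", "-"),
      start = c(5000L, 20000L), end = c(8399L, 20999L),
      stringsAsFactors = FALSE),
    exons = data.frame(
      tx_id = c("geneA.t1", "geneA.t1", "geneB.t1"),
      start = c(5000L, 8000L, 20000L),
      end = c(5199L, 8399L, 20999L),
      stringsAsFactors = FALSE))
}

# small, fast simulated study reused by several files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sim_study(sim_config(
        genome_length = 4e5, n_chromosomes = 2, n_genes = 90,
        n_segments = 40, seed = 11))
    cache
  }
})

# study-scale simulation (~400 segments, Table-4-scale promoter counts),
# cached per session
study_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sim_study(sim_config(
        genome_length = 1e6, n_chromosomes = 4, n_genes = 520,
        n_segments = 400, seed = 101))
    cache
  }
})

extdata <- function(name) {
  system.file("extdata", name, package = "hsfchip", mustWork = TRUE)
}
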