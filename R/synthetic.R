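#' Configuration for a synthetic HSF ChIP-chip study
#'
#' Collects every generative knob of the simulator. The defaults encode the
#' study conditions the pipeline is built for: ~233-bp tiling with 60-mer
#' probes and repeat-masked gaps, bound segments averaging ~1.4 kb with
#' peaked fold-change profiles, HSEs planted within -400..+300 bp of peaks,
#' a room-temperature (RT) ChIP retaining 81% of heat-shock (HS) segments at
#' ~5-fold attenuation, two expression systems whose responsive gene sets
#' overlap by ~8%, and BEAF-motif planting probabilities of 0.27 / 0.66 for
#' induced / non-induced bound promoters.
#'
#' @param genome_length bp per chromosome
#' @param n_chromosomes number of chromosomes
#' @param n_genes total genes to place
#' @param isoforms_per_gene integer range `c(min, max)` of isoforms per gene;
#'   isoforms differ by transcription start site
#' @param probe_spacing,probe_length tiling grid (bp)
#' @param masked_gap_fraction fraction of the genome covered by probe-free
#'   (repeat-masked) gaps; one contiguous super-gap of at least
#'   `10 * probe_spacing` is always planted regardless
#' @param n_segments number of bound segments to plant
#' @param category_mix named fractions (summing to 1) of planted peaks in
#'   `promoter` (intergenic promoter), `intron`, `exon`, `intergenic`
#'   placements
#' @param hse_window offset interval (bp relative to peak) for planted HSEs
#' @param fold_model `c(meanlog, sdlog)` of the log-normal segment max fold
#'   change (shifted by 1, clamped to `[5, 100]`)
#' @param rt_retained_fraction fraction of HS segments also enriched at RT
#' @param rt_attenuation mean HS/RT peak fold ratio
#' @param noise_sd log-normal sd of multiplicative probe fold noise
#' @param pxbar_noise_sd sd of the noise on log10 P\[Xbar\]
#' @param fp_rate per-probe false-positive rate in background/mock signal
#' @param de_fraction_per_system named fractions of genes responsive per
#'   system (`cells`, `larvae`)
#' @param de_overlap_fraction target `|A & B| / |A | B|` overlap between the
#'   two systems' responsive sets
#' @param promoter_induced_fraction fraction of bound-promoter genes induced
#'   in the `cells` system (Table-4-style contingency structure)
#' @param mutant_retained_fraction fraction of larval responses retained in
#'   the HSF-mutant system
#' @param beaf_plant_prob_induced,beaf_plant_prob_noninduced BEAF-motif
#'   planting probability for induced / non-induced bound promoters
#' @param expr_noise_sd sd (log2) of expression fold noise
#' @param band_width cytological band width (bp)
#' @param polytene_overlap_rate probability that a bound band enters the
#'   polytene locus list
#' @param polytene_jitter 0 or 1: optional one-band jitter on locus indices
#' @param polytene_extra number of unrelated loci appended to the list
#' @param base_freq genome base composition (A, C, G, T)
#' @param seed integer seed; every generator derives its stream from it
#' @return validated list of class `"sim_config"`
#' @export
sim_config <- function(genome_length = 1e6,
                       n_chromosomes = 2,
                       n_genes = 260,
                       isoforms_per_gene = c(1, 3),
                       probe_spacing = 233,
                       probe_length = 60,
                       masked_gap_fraction = 0.02,
                       n_segments = 120,
                       category_mix = c(promoter = 0.27, intron = 0.35,
                                        exon = 0.22, intergenic = 0.16),
                       hse_window = c(-400, 300),
                       fold_model = c(meanlog = log(15), sdlog = 0.8),
                       rt_retained_fraction = 0.81,
                       rt_attenuation = 5,
                       noise_sd = 0.15,
                       pxbar_noise_sd = 0.3,
                       fp_rate = 0.002,
                       de_fraction_per_system = c(cells = 0.08,
                                                  larvae = 0.09),
                       de_overlap_fraction = 0.08,
                       promoter_induced_fraction = 11 / 115,
                       mutant_retained_fraction = 0.03,
                       beaf_plant_prob_induced = 0.27,
                       beaf_plant_prob_noninduced = 0.66,
                       expr_noise_sd = 0.1,
                       band_width = 10000,
                       polytene_overlap_rate = 0.9,
                       polytene_jitter = 0,
                       polytene_extra = 0,
                       base_freq = rep(0.25, 4),
                       seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(masked_gap_fraction, rt_retained_fraction,
             de_fraction_per_system, de_overlap_fraction,
             promoter_induced_fraction, mutant_retained_fraction,
             beaf_plant_prob_induced, beaf_plant_prob_noninduced,
             polytene_overlap_rate, fp_rate, category_mix)
  if (any(fracs < 0 | fracs > 1))
    stop("all fractions in sim_config must lie in [0, 1]")
  if (abs(sum(category_mix) - 1) > 1e-9)
    stop("category_mix must sum to 1 (tolerance 1e-9)")
  if (!all(c("promoter", "intron", "exon", "intergenic") %in%
           names(category_mix)))
    stop("category_mix must name promoter, intron, exon, intergenic")
  if (probe_spacing <= 0) stop("probe_spacing must be > 0")
  if (probe_length > probe_spacing)
    warning("probe_length exceeds probe_spacing: probes will overlap")
  if (!polytene_jitter %in% c(0, 1))
    stop("polytene_jitter must be 0 or 1")
  if (hse_window[1] > hse_window[2]) stop("hse_window must be increasing")
  if (length(base_freq) != 4 || any(base_freq <= 0) ||
      abs(sum(base_freq) - 1) > 1e-9)
    stop("base_freq must be 4 positive frequencies summing to 1")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d chrom x %g bp, %d genes, %d segments, seed %d\n",
    x$n_chromosomes, x$genome_length, x$n_genes, x$n_segments, x$seed))
  invisible(x)
}

probe_center_offset <- function(probe_length) (probe_length - 1L) %/% 2L

# nearest tiling-probe center to x (probe grid: starts 1, 1+spacing, ...)
snap_to_probe_center <- function(x, config, chrom_len) {
  off <- probe_center_offset(config$probe_length)
  k <- round((x - 1 - off) / config$probe_spacing)
  kmax <- (chrom_len - config$probe_length) %/% config$probe_spacing
  k <- pmax(0, pmin(k, kmax))
  as.integer(1 + k * config$probe_spacing + off)
}

#' Generate a synthetic genome and gene annotation
#'
#' Draws per-chromosome random sequence with the configured base composition
#' and places non-overlapping multi-isoform gene models (first introns are
#' long so that intron-exclusive binding sites > 1250 bp from every TSS
#' exist), plus repeat-masked probe-free gaps including one super-gap of at
#' least `10 * probe_spacing`.
#'
#' @param config a [sim_config()]
#' @return list of class `"sim_genome"`: `genome` (named character vector),
#'   `models` ([gene_models()]), `masks` (data.frame chrom/start/end),
#'   `chrom_lengths`.
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$genome_length
  genome <- stats::setNames(vapply(chroms, function(ch)
    paste(sample(DNA_BASES, L, TRUE, prob = config$base_freq),
          collapse = ""), character(1)), chroms)

  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chromosomes + 1)))
  tx_rows <- list(); ex_rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[[ci]]
    pos <- 2000L
    placed <- 0L
    while (placed < per_chrom[[ci]]) {
      gap <- round(stats::runif(1, 1500, 4000))
      start <- pos + gap
      n_ex <- sample(2:4, 1L)
      ex_len <- round(stats::runif(n_ex, 120, 400))
      int_len <- if (n_ex > 1)
        c(round(stats::runif(1, 1600, 2600)),
          if (n_ex > 2) round(stats::runif(n_ex - 2, 300, 900)))
      else integer(0)
      span <- sum(ex_len) + sum(int_len)
      end <- start + span - 1L
      if (end > L - 15000L)
        stop(sprintf(
          paste0("genome too small to place n_genes=%d: chromosome %s ",
                 "exhausted after %d genes (genome_length=%g)"),
          config$n_genes, ch, placed, L))
      gi <- gi + 1L
      placed <- placed + 1L
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("gene%04d", gi)
      # exon starts in genomic order; transcription order follows strand
      ex_start <- start + cumsum(c(0L, head(ex_len, -1) + int_len))
      ex_end <- ex_start + ex_len - 1L
      n_iso <- sample(config$isoforms_per_gene[1]:config$isoforms_per_gene[2],
                      1L)
      first_len <- if (strand == "+") ex_len[1L] else ex_len[n_ex]
      shifts <- c(0L, if (n_iso > 1)
        sort(sample(10:max(11L, min(100L, first_len - 20L)), n_iso - 1L)))
      for (iso in seq_len(n_iso)) {
        tx_id <- sprintf("%s.t%d", gene_id, iso)
        s <- shifts[[iso]]
        es <- ex_start; ee <- ex_end
        if (strand == "+") es[1L] <- es[1L] + s else ee[n_ex] <- ee[n_ex] - s
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          tx_id = tx_id, gene_id = gene_id, chrom = ch, strand = strand,
          start = es[1L], end = ee[n_ex], stringsAsFactors = FALSE)
        ex_rows[[length(ex_rows) + 1L]] <- data.frame(
          tx_id = tx_id, start = es, end = ee, stringsAsFactors = FALSE)
      }
      pos <- end
    }
  }
  tx <- if (length(tx_rows)) do.call(rbind, tx_rows) else
    data.frame(tx_id = character(), gene_id = character(),
               chrom = character(), strand = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  ex <- if (length(ex_rows)) do.call(rbind, ex_rows) else
    data.frame(tx_id = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  models <- gene_models(tx, ex)

  # repeat-masked gaps: one super-gap plus random gaps to reach the fraction
  super_len <- as.integer(ceiling(10 * config$probe_spacing) + 500)
  masks <- data.frame(chrom = chroms[[1L]],
                      start = as.integer(round(L * 0.45)),
                      end = as.integer(round(L * 0.45)) + super_len - 1L,
                      stringsAsFactors = FALSE)
  target <- config$masked_gap_fraction * L * config$n_chromosomes
  total <- super_len
  guard <- 0L
  while (total < target && guard < 10000L) {
    guard <- guard + 1L
    len <- round(stats::runif(1, 500, 3000))
    ch <- sample(chroms, 1L)
    s <- sample.int(L - len, 1L)
    cand <- c(s, s + len - 1L)
    hit <- masks$chrom == ch & masks$start <= cand[2L] & masks$end >= cand[1L]
    if (any(hit)) next
    masks <- rbind(masks, data.frame(chrom = ch, start = s, end = cand[2L],
                                     stringsAsFactors = FALSE))
    total <- total + len
  }
  masks <- masks[order(masks$chrom, masks$start), ]
  rownames(masks) <- NULL
  structure(list(genome = genome, models = models, masks = masks,
                 chrom_lengths = stats::setNames(rep(L, length(chroms)),
                                                 chroms)),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d chromosomes (%g bp), %d genes, %d masks\n",
              length(x$genome), sum(x$chrom_lengths),
              n_genes(x$models), nrow(x$masks)))
  invisible(x)
}

# ---- ground-truth planting -------------------------------------------------

#' Plant bound segments and HSE motifs into a synthetic genome
#'
#' Chooses peak locations per `category_mix` (intergenic promoter, intron
#' beyond 1250 bp of every isoform TSS, distal exon, or deep intergenic),
#' snaps each peak to the nearest tiling-probe center, draws the segment
#' span and max fold change, flags the RT-retained subset, and writes one
#' canonical HSE (`nGAAnnTTCnnGAAn`) into the sequence at a uniform offset
#' inside `hse_window` on a random strand.
#'
#' @param gi a `sim_genome`
#' @param config the [sim_config()]
#' @return list: `genome` (with motifs planted), `truth` (class
#'   `"sim_truth"`: `segments`, `motifs`).
#' @export
plant_ground_truth <- function(gi, config) {
  stopifnot(inherits(gi, "sim_genome"))
  set.seed(config$seed + 1L)
  models <- gi$models
  tx <- models$transcripts
  L <- gi$chrom_lengths
  n_seg <- config$n_segments
  counts <- allocate_counts(n_seg, config$category_mix[
    c("promoter", "intron", "exon", "intergenic")])
  names(counts) <- c("promoter", "intron", "exon", "intergenic")

  mask_guard <- df_granges(within(gi$masks, {
    start <- pmax(1L, start - 1500L); end <- end + 1500L
  }))
  tx_gr <- transcript_ranges(models)

  placed <- data.frame(chrom = character(), peak = integer(),
                       halfwidth = integer(), category = character(),
                       gene_id = character(), stringsAsFactors = FALSE)
  too_close <- function(ch, p, hw) {
    sel <- placed$chrom == ch
    any(abs(placed$peak[sel] - p) <
          placed$halfwidth[sel] + hw + 2L * config$probe_spacing)
  }
  free_of_mask <- function(ch, p, hw) {
    q <- GenomicRanges::GRanges(ch, IRanges::IRanges(p - hw, p + hw))
    !any(IRanges::overlapsAny(q, mask_guard))
  }
  in_any_tx <- function(ch, p) {
    q <- GenomicRanges::GRanges(ch, IRanges::IRanges(p, p))
    any(IRanges::overlapsAny(q, tx_gr))
  }
  tss_all <- tx[, c("chrom", "tss")]
  min_tss_dist <- function(ch, p) {
    d <- abs(tss_all$tss[tss_all$chrom == ch] - p)
    if (length(d)) min(d) else Inf
  }

  add_segment <- function(ch, peak_raw, category, gene_id, validate) {
    hw <- as.integer(round(stats::runif(1, 500, 900)))
    peak <- snap_to_probe_center(peak_raw, config, L[[ch]])
    if (peak - hw < 1L || peak + hw > L[[ch]]) return(FALSE)
    if (too_close(ch, peak, hw) || !free_of_mask(ch, peak, hw)) return(FALSE)
    if (!validate(peak)) return(FALSE)
    placed[nrow(placed) + 1L, ] <<- list(ch, peak, hw, category, gene_id)
    TRUE
  }

  # gene-targeted categories draw genes without replacement
  gene_pool <- unique(tx$gene_id)
  pick_gene <- function() {
    if (!length(gene_pool)) stop(
      "not enough genes to place the configured category_mix of segments")
    g <- sample(gene_pool, 1L)
    gene_pool <<- setdiff(gene_pool, g)
    g
  }
  primary_tx <- tx[!duplicated(tx$gene_id), ]  # isoform 1 per gene
  rownames(primary_tx) <- primary_tx$gene_id

  for (category in c("promoter", "intron", "exon", "intergenic")) {
    need <- counts[[category]]
    tries <- 0L
    while (need > 0L) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, counts[[category]]))
        stop(sprintf(
          "unable to place %d '%s' segments; genome too crowded", need,
          category))
      if (category == "intergenic") {
        ch <- sample(names(L), 1L)
        p <- sample.int(L[[ch]], 1L)
        ok <- add_segment(ch, p, category, NA_character_, function(pk)
          !in_any_tx(ch, pk) && min_tss_dist(ch, pk) > 1400 &&
            min_end_dist(models, ch, pk) > 1400)
        if (ok) need <- need - 1L
        next
      }
      g <- pick_gene()
      t1 <- primary_tx[g, ]
      ch <- t1$chrom
      exg <- models$exons[models$exons$tx_id == t1$tx_id, ]
      exg <- exg[order(exg$rank), ]
      ok <- FALSE
      if (category == "promoter") {
        u <- round(stats::runif(1, 200, 1000))
        p <- if (t1$strand == "+") t1$tss - u else t1$tss + u
        ok <- add_segment(ch, p, category, g, function(pk)
          !in_any_tx(ch, pk) && abs(pk - t1$tss) <= 1250 &&
            abs(pk - t1$tss) >= 50)
      } else if (category == "intron") {
        if (nrow(exg) >= 2L) {
          e1 <- exg[1L, ]; e2 <- exg[2L, ]
          intr <- if (t1$strand == "+") c(e1$end + 1L, e2$start - 1L)
                  else c(e2$end + 1L, e1$start - 1L)
          lo <- max(intr[1L] + 150L,
                    if (t1$strand == "+") t1$tss + 1400L else -Inf)
          hi <- min(intr[2L] - 150L,
                    if (t1$strand == "-") t1$tss - 1400L else Inf)
          if (hi > lo) {
            p <- round(stats::runif(1, lo, hi))
            ok <- add_segment(ch, p, category, g, function(pk)
              pk >= intr[1L] && pk <= intr[2L] &&
                min_tss_dist(ch, pk) > 1250)
          }
        }
      } else { # exon: a non-first exon beyond the promoter radius
        if (nrow(exg) >= 2L) {
          e2 <- exg[2L, ]
          p <- round(stats::runif(1, e2$start + 10L, e2$end - 10L))
          ok <- add_segment(ch, p, category, g, function(pk)
            pk >= e2$start && pk <= e2$end && min_tss_dist(ch, pk) > 1250)
        }
      }
      if (ok) need <- need - 1L
      else gene_pool <- c(gene_pool, g)   # return the gene for later tries
    }
  }

  placed <- placed[order(placed$chrom, placed$peak), ]
  rownames(placed) <- NULL
  n <- nrow(placed)
  segs <- data.frame(
    segment_id = sprintf("seg%03d", seq_len(n)),
    chrom = placed$chrom,
    start = placed$peak - placed$halfwidth,
    end = placed$peak + placed$halfwidth,
    peak = placed$peak,
    category = placed$category,
    gene_id = placed$gene_id,
    max_fold = pmin(100, pmax(5, 1 + stats::rlnorm(
      n, config$fold_model[["meanlog"]], config$fold_model[["sdlog"]]))),
    has_rt = stats::runif(n) < config$rt_retained_fraction,
    stringsAsFactors = FALSE)

  # plant one canonical HSE per segment
  genome <- gi$genome
  motifs <- data.frame(segment_id = character(), chrom = character(),
                       position = integer(), strand = character(),
                       motif_id = character(), offset = integer(),
                       stringsAsFactors = FALSE)
  canonical <- c("G", "A", "A", "T", "T", "C", "G", "A", "A")
  for (i in seq_len(n)) {
    off <- sample(config$hse_window[1L]:config$hse_window[2L], 1L)
    pos <- segs$peak[i] + off
    ch <- segs$chrom[i]
    if (pos < 1L || pos + 14L > L[[ch]]) next
    site <- sample(DNA_BASES, 15L, TRUE, prob = config$base_freq)
    site[c(2:4, 7:9, 12:14)] <- canonical
    strand <- sample(c("+", "-"), 1L)
    s <- paste(site, collapse = "")
    if (strand == "-") s <- reverse_complement_chr(s)
    substr(genome[[ch]], pos, pos + 14L) <- s
    motifs[nrow(motifs) + 1L, ] <-
      list(segs$segment_id[i], ch, pos, strand, "HSE_GAA-TTC-GAA", off)
  }
  truth <- structure(list(segments = segs, motifs = motifs,
                          responsive = NULL, beaf_promoters = NULL),
                     class = "sim_truth")
  list(genome = genome, truth = truth)
}

# distance from p to the nearest transcript 3' end on chrom
min_end_dist <- function(models, ch, p) {
  tx <- models$transcripts
  sel <- tx$chrom == ch
  ends <- ifelse(tx$strand[sel] == "+", tx$end[sel], tx$start[sel])
  if (!length(ends)) return(Inf)
  min(abs(ends - p))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d segments (%s), %d planted motifs\n",
              nrow(x$segments),
              paste(names(table(x$segments$category)),
                    table(x$segments$category), sep = ":", collapse = " "),
              nrow(x$motifs)))
  invisible(x)
}

# ---- probes & ChIP signal --------------------------------------------------

#' Generate tiling-probe coordinates
#'
#' 60-mer (configurable) probe spans every `probe_spacing` bp from position
#' 1, excluding any probe that intersects a masked gap.
#'
#' @param gi a `sim_genome` (its `masks` are honoured)
#' @param config the [sim_config()]
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive spans)
#' @export
sim_probes <- function(gi, config) {
  stopifnot(inherits(gi, "sim_genome"))
  out <- lapply(names(gi$chrom_lengths), function(ch) {
    L <- gi$chrom_lengths[[ch]]
    if (L < config$probe_length)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    starts <- seq.int(1L, L - config$probe_length + 1L,
                      by = config$probe_spacing)
    df <- data.frame(chrom = ch, start = starts,
                     end = starts + config$probe_length - 1L,
                     stringsAsFactors = FALSE)
    m <- gi$masks[gi$masks$chrom == ch, , drop = FALSE]
    if (nrow(m)) {
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(df$start, df$end), IRanges::IRanges(m$start, m$end))
      df <- df[!hit, , drop = FALSE]
    }
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate probe-level ChIP measurements for HS, RT and mock
#'
#' Probes under a planted segment receive fold changes following a Gaussian
#' profile peaked at the planted peak (multiplicative log-normal noise) and
#' a P\[Xbar\] that decreases monotonically with the underlying signal; the
#' RT table carries signal only at the retained subset, attenuated by
#' `rt_attenuation`; the mock table is pure background with the configured
#' false-positive rate.
#'
#' @param probes data.frame from [sim_probes()]
#' @param truth a `sim_truth`
#' @param config the [sim_config()]
#' @return list of three data.frames (`hs`, `rt`, `mock`) with columns
#'   `chrom`, `start`, `end`, `fold`, `pxbar`
#' @export
sim_chip <- function(probes, truth, config) {
  set.seed(config$seed + 2L)
  n <- nrow(probes)
  center <- probes$start + probe_center_offset(config$probe_length)
  background <- function() {
    fold <- exp(stats::rnorm(n, 0, config$noise_sd))
    # null probes stay clear of calling thresholds; significant background
    # arises only through the configured false-positive rate
    pxbar <- stats::runif(n, 0.01, 1)
    fp <- stats::runif(n) < config$fp_rate
    pxbar[fp] <- 10^-stats::runif(sum(fp), 3, 5)
    data.frame(chrom = probes$chrom, start = probes$start,
               end = probes$end, fold = fold, pxbar = pxbar,
               stringsAsFactors = FALSE)
  }
  overlay <- function(df, segs, atten = 1) {
    for (i in seq_len(nrow(segs))) {
      sel <- which(df$chrom == segs$chrom[i] & center >= segs$start[i] &
                     center <= segs$end[i])
      if (!length(sel)) next
      d <- center[sel] - segs$peak[i]
      sig <- (segs$end[i] - segs$start[i]) / 4   # halfwidth / 2
      s <- exp(-d^2 / (2 * sig^2))
      top <- 1 + (segs$max_fold[i] / atten - 1) * s
      df$fold[sel] <- pmax(top, 1e-3) *
        exp(stats::rnorm(length(sel), 0, config$noise_sd))
      u <- 3.2 + 9 * s + stats::rnorm(length(sel), 0, config$pxbar_noise_sd)
      df$pxbar[sel] <- pmin(1, 10^-pmax(u, 0.01))
    }
    df
  }
  hs <- overlay(background(), truth$segments)
  rt <- overlay(background(), truth$segments[truth$segments$has_rt, ,
                                             drop = FALSE],
                atten = config$rt_attenuation)
  list(hs = hs, rt = rt, mock = background())
}

# ---- expression ------------------------------------------------------------

#' Generate expression tables for two systems plus an HSF-mutant system
#'
#' Responsive genes are drawn per `de_fraction_per_system` with the
#' configured two-system overlap; genes owning a planted promoter segment
#' are induced in the `cells` system at `promoter_induced_fraction` (and
#' never responsive in `cells` otherwise), giving the simulated study the
#' induced / non-induced bound-promoter structure used by
#' [motif_induction_report()]. The `mutant` system retains only
#' `mutant_retained_fraction` of the larval responses. Fold changes use the
#' signed-ratio convention (|fold| >= 1; negative = repression); `fdr_p` is
#' a Benjamini-Hochberg adjusted p-value computed within each system.
#'
#' @param models a [gene_models()]
#' @param truth a `sim_truth` (with planted segments)
#' @param config the [sim_config()]
#' @return list: `expression` (data.frame `gene_id`, `system`,
#'   `fold_change`, `fdr_p`), `responsive` (named list of planted
#'   data.frames with `gene_id`, `fold`)
#' @export
sim_expression <- function(models, truth, config) {
  set.seed(config$seed + 3L)
  genes <- unique(models$transcripts$gene_id)
  segs <- truth$segments
  promoter_genes <- unique(stats::na.omit(
    segs$gene_id[segs$category == "promoter"]))
  n_cells <- round(config$de_fraction_per_system[["cells"]] * length(genes))
  n_larv <- round(config$de_fraction_per_system[["larvae"]] * length(genes))
  induced_bound <- sample(promoter_genes,
                          round(config$promoter_induced_fraction *
                                  length(promoter_genes)))
  other_pool <- setdiff(genes, promoter_genes)
  cells <- c(induced_bound,
             sample(other_pool, max(0, n_cells - length(induced_bound))))
  m <- round(config$de_overlap_fraction / (1 + config$de_overlap_fraction) *
               (n_cells + n_larv))
  m <- min(m, length(cells))
  larvae <- c(sample(cells, m),
              sample(setdiff(genes, cells), max(0, n_larv - m)))
  mutant <- if (length(larvae))
    sample(larvae, max(1, round(config$mutant_retained_fraction *
                                  length(larvae)))) else character(0)
  planted_fold <- function(set) {
    f <- 2 * 2^stats::rexp(length(set), rate = 1 / 1.5)
    f <- pmin(f, 250)
    sign <- ifelse(stats::runif(length(set)) < 0.95, 1, -1)
    data.frame(gene_id = set, fold = sign * f, stringsAsFactors = FALSE)
  }
  responsive <- list(cells = planted_fold(cells),
                     larvae = planted_fold(larvae))
  responsive$mutant <- responsive$larvae[
    responsive$larvae$gene_id %in% mutant, , drop = FALSE]
  tabs <- lapply(names(responsive), function(sys) {
    r <- responsive[[sys]]
    fold <- rep(1, length(genes))
    praw <- stats::runif(length(genes), 0.02, 1)
    i <- match(r$gene_id, genes)
    fold[i] <- r$fold
    praw[i] <- 10^-stats::runif(length(i), 5, 9)
    if (config$expr_noise_sd > 0) {
      lg <- log2(abs(fold)) * sign(fold) +
        stats::rnorm(length(genes), 0, config$expr_noise_sd)
      fold <- ifelse(lg >= 0, 2^lg, -2^(-lg))
    }
    data.frame(gene_id = genes, system = sys, fold_change = fold,
               fdr_p = bh_fdr(praw), stringsAsFactors = FALSE)
  })
  list(expression = do.call(rbind, tabs), responsive = responsive)
}

# ---- BEAF planting ---------------------------------------------------------

#' Synthetic BEAF-style insulator PWM
#'
#' A 7-bp informative core (`CGATACG`) flanked by one `n` on each side. The
#' core length is chosen so that at the 5e-4 scan threshold only the exact
#' core matches under a uniform background (the next score step, one
#' mismatch, has tail probability 1.3e-3): chance matches over a
#' promoter-sized region stay rare and presence/absence recovers the
#' planted Bernoulli structure.
#'
#' @param background,pseudocount passed to [pwm()]
#' @return a 9-position `pwm` with id `"BEAF_synth"`
#' @export
make_beaf_pwm <- function(background = rep(0.25, 4), pseudocount = NULL) {
  core <- c("C", "G", "A", "T", "A", "C", "G")
  m <- matrix(0, 9L, 4L, dimnames = list(NULL, DNA_BASES))
  m[1L, ] <- m[9L, ] <- 25
  for (i in seq_along(core)) m[i + 1L, core[[i]]] <- 100
  pwm(m, id = "BEAF_synth", background = background,
      pseudocount = pseudocount)
}

# plant BEAF cores near the peaks of bound promoters; returns genome + ids.
# offsets are small relative to the peak so that the insulator motif is
# concentrated in the center window of promoter-group histograms while
# staying inside the gene's promoter radius.
plant_beaf <- function(genome, models, truth, config) {
  set.seed(config$seed + 4L)
  segs <- truth$segments
  prom <- segs[segs$category == "promoter" & !is.na(segs$gene_id), ,
               drop = FALSE]
  prom <- prom[!duplicated(prom$gene_id), , drop = FALSE]
  induced <- truth$responsive$cells$gene_id
  core <- c("C", "G", "A", "T", "A", "C", "G")
  tx <- models$transcripts[!duplicated(models$transcripts$gene_id), ]
  rownames(tx) <- tx$gene_id
  occupied <- truth$motifs[, c("chrom", "position")]
  occupied$end <- occupied$position + 14L
  planted <- character(0)
  beaf_motifs <- list()
  for (i in seq_len(nrow(prom))) {
    g <- prom$gene_id[i]
    p_plant <- if (g %in% induced) config$beaf_plant_prob_induced
               else config$beaf_plant_prob_noninduced
    if (stats::runif(1) >= p_plant) next
    tss <- tx[g, "tss"]
    ch <- prom$chrom[i]
    ok <- FALSE
    for (try in 1:50) {
      pos <- prom$peak[i] + sample(-300:292, 1L)
      if (pos < 1L || pos + 8L > nchar(genome[[ch]])) next
      if (abs(pos + 4L - tss) > 1150) next
      clash <- occupied$chrom == ch & occupied$position <= pos + 8L &
        occupied$end >= pos
      if (any(clash)) next
      ok <- TRUE
      break
    }
    if (!ok) next
    site <- sample(DNA_BASES, 9L, TRUE, prob = config$base_freq)
    site[2:8] <- core
    s <- paste(site, collapse = "")
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") s <- reverse_complement_chr(s)
    substr(genome[[ch]], pos, pos + 8L) <- s
    occupied[nrow(occupied) + 1L, ] <- list(ch, pos, pos + 8L)
    planted <- c(planted, g)
    beaf_motifs[[length(beaf_motifs) + 1L]] <- data.frame(
      segment_id = prom$segment_id[i], chrom = ch, position = pos,
      strand = strand, motif_id = "BEAF_synth",
      offset = pos - prom$peak[i], stringsAsFactors = FALSE)
  }
  list(genome = genome, beaf_promoters = planted,
       motifs = if (length(beaf_motifs)) do.call(rbind, beaf_motifs)
                else NULL)
}

#' Motif presence per bound segment
#'
#' Scans each segment's span for PWM matches below `p_threshold` and
#' reports presence/absence -- the "promoter contains at least one BEAF
#' motif" predicate of the binding-by-induction contingency analysis.
#'
#' @param segments data.frame with `chrom`, `start`, `end`
#' @param genome named character vector or `DNAStringSet`
#' @param x a `pwm`
#' @param p_threshold match cut-off (default 5e-4, the BEAF-occurrence
#'   cut-off)
#' @return logical vector along `segments`
#' @export
segment_motif_presence <- function(segments, genome, x,
                                   p_threshold = 5e-4) {
  dist <- score_distribution(x)
  lens <- chrom_lengths(genome)
  vapply(seq_len(nrow(segments)), function(i) {
    ch <- segments$chrom[i]
    s <- max(1L, segments$start[i])
    e <- min(lens[[ch]], segments$end[i])
    nrow(scan_pwm(substr(chrom_seq(genome, ch), s, e), x, p_threshold,
                  dist = dist)) > 0
  }, logical(1))
}

# ---- cytology --------------------------------------------------------------

#' Generate a cytological band map and polytene locus list
#'
#' Bands of `band_width` bp partition each chromosome. The polytene locus
#' list contains the band of each planted segment with probability
#' `polytene_overlap_rate`, optionally jittered by one band index, plus
#' `polytene_extra` unrelated bands; each locus carries an ordinal staining
#' intensity.
#'
#' @param gi a `sim_genome`
#' @param truth a `sim_truth`
#' @param config the [sim_config()]
#' @return list: `bands` (data.frame `band`, `chrom`, `start`, `end`,
#'   `index`), `loci` (data.frame `locus`, `staining_intensity`)
#' @export
sim_cytology <- function(gi, truth, config) {
  set.seed(config$seed + 5L)
  bands <- do.call(rbind, lapply(names(gi$chrom_lengths), function(ch) {
    L <- gi$chrom_lengths[[ch]]
    starts <- seq.int(1L, L, by = config$band_width)
    data.frame(band = sprintf("%s.%03d", sub("^chr", "", ch),
                              seq_along(starts)),
               chrom = ch, start = starts,
               end = pmin(starts + config$band_width - 1L, L),
               index = seq_along(starts), stringsAsFactors = FALSE)
  }))
  rownames(bands) <- NULL
  segs <- truth$segments
  seg_bands <- unique(map_to_band(segs$chrom, segs$peak, bands))
  keep <- seg_bands[stats::runif(length(seg_bands)) <
                      config$polytene_overlap_rate]
  if (config$polytene_jitter == 1 && length(keep)) {
    i <- match(keep, bands$band)
    jit <- sample(c(-1L, 0L, 1L), length(keep), TRUE)
    j <- i + jit
    # clamp within the same chromosome
    bad <- j < 1L | j > nrow(bands) | bands$chrom[pmax(1L, pmin(j, nrow(bands)))] != bands$chrom[i]
    j[bad] <- i[bad]
    keep <- bands$band[j]
  }
  extra <- setdiff(bands$band, keep)
  if (config$polytene_extra > 0 && length(extra))
    keep <- c(keep, sample(extra, min(config$polytene_extra,
                                      length(extra))))
  keep <- unique(keep)
  loci <- data.frame(
    locus = keep,
    staining_intensity = sample(c(0.5, 1, 1.5, 2, 2.5, 3, 4),
                                length(keep), TRUE),
    stringsAsFactors = FALSE)
  list(bands = bands, loci = loci)
}

# ---- whole-study orchestration --------------------------------------------

#' Simulate a complete synthetic HSF ChIP-chip study
#'
#' Runs every generator in sequence -- genome and annotation, planted
#' segments and HSEs, expression systems, BEAF promoter planting, probe
#' tiling, HS/RT/mock ChIP signal, and cytology -- and returns everything
#' together with the ground truth needed for recovery tests.
#'
#' @param config a [sim_config()]
#' @return object of class `"hsf_sim"`: `config`, `genome` (named character
#'   vector), `models`, `masks`, `probes`, `chip` (list hs/rt/mock),
#'   `expression`, `cytology` (list bands/loci), `truth`.
#' @export
sim_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  gi <- sim_genome(config)
  pt <- plant_ground_truth(gi, config)
  gi$genome <- pt$genome
  truth <- pt$truth
  expr <- sim_expression(gi$models, truth, config)
  truth$responsive <- expr$responsive
  pb <- plant_beaf(gi$genome, gi$models, truth, config)
  gi$genome <- pb$genome
  truth$beaf_promoters <- pb$beaf_promoters
  if (!is.null(pb$motifs)) truth$motifs <- rbind(truth$motifs, pb$motifs)
  probes <- sim_probes(gi, config)
  chip <- sim_chip(probes, truth, config)
  cyt <- sim_cytology(gi, truth, config)
  structure(list(config = config, genome = gi$genome, models = gi$models,
                 masks = gi$masks, chrom_lengths = gi$chrom_lengths,
                 probes = probes, chip = chip,
                 expression = expr$expression, cytology = cyt,
                 truth = truth),
            class = "hsf_sim")
}

#' @export
print.hsf_sim <- function(x, ...) {
  cat(sprintf(
    paste0("<hsf_sim> seed %d: %d genes, %d probes, %d planted segments, ",
           "%d expression rows\n"),
    x$config$seed, n_genes(x$models), nrow(x$probes),
    nrow(x$truth$segments), nrow(x$expression)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits genome FASTA, annotation GFF3, probes BED (0-based half-open),
#' probe-level ChIP TSVs, expression TSV, band map and locus TSVs, truth
#' tables, and a JSON manifest echoing the seed and configuration.
#'
#' @param sim an `hsf_sim`
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_sim <- function(sim, outdir) {
  stopifnot(inherits(sim, "hsf_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(outdir, x)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome), fp("genome.fa"))
  rtracklayer::export(as_gff(sim$models), fp("annotation.gff3"),
                      format = "gff3")
  rtracklayer::export(df_granges(sim$probes), fp("probes.bed"),
                      format = "BED")
  tsv <- function(df, name) utils::write.table(
    df, fp(name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(sim$chip$hs, "chip_hs.tsv")
  tsv(sim$chip$rt, "chip_rt.tsv")
  tsv(sim$chip$mock, "chip_mock.tsv")
  tsv(sim$expression, "expression.tsv")
  tsv(sim$cytology$bands, "bands.tsv")
  tsv(sim$cytology$loci, "loci.tsv")
  tsv(sim$truth$segments, "truth_segments.tsv")
  tsv(sim$truth$motifs, "truth_motifs.tsv")
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(list(seed = cfg$seed, config = cfg),
                       fp("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read a probe-level ChIP table written by [write_sim()]
#' @param path TSV with columns chrom, start, end, fold, pxbar
#' @return data.frame
#' @export
read_probe_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "fold", "pxbar") %in% names(df)))
  df
}

#' Read an expression table written by [write_sim()]
#' @param path TSV with columns gene_id, system, fold_change, fdr_p
#' @return data.frame
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "system", "fold_change", "fdr_p") %in%
                  names(df)))
  df
}
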