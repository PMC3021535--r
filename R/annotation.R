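#' Nearest transcription start site to a position
#'
#' Minimizes `|peak_center - TSS|` over every isoform TSS on the peak's
#' chromosome. The signed distance is positive when the peak lies downstream
#' of the TSS in the gene's transcription direction and negative upstream.
#' Ties are broken toward a gene whose transcribed span contains the peak,
#' then by lexicographic gene id.
#'
#' @param chrom,peak_center position of the peak
#' @param models a [gene_models()]
#' @return list: `gene_id`, `tx_id`, `distance` (signed bp)
#' @export
nearest_tss <- function(chrom, peak_center, models) {
  tx <- models$transcripts
  if (!nrow(tx)) stop("annotation is empty")
  cand <- tx[tx$chrom == chrom, , drop = FALSE]
  if (!nrow(cand)) stop("no genes on chromosome ", chrom)
  d <- abs(cand$tss - peak_center)
  contains <- cand$start <= peak_center & cand$end >= peak_center
  o <- order(d, !contains, cand$gene_id)
  i <- o[1L]
  signed <- if (cand$strand[i] == "+") peak_center - cand$tss[i]
            else cand$tss[i] - peak_center
  list(gene_id = cand$gene_id[i], tx_id = cand$tx_id[i], distance = signed)
}

#' Genes within a window centered on a peak
#'
#' Returns every gene with an isoform TSS or transcribed span intersecting
#' `[peak_center - half_width, peak_center + half_width]`, ordered by
#' proximity of its closest TSS to the peak.
#'
#' @param chrom,peak_center peak position
#' @param models a [gene_models()]
#' @param half_width window half-width (default 1250, i.e. a 2500-bp window)
#' @return data.frame `gene_id`, `distance` (signed, closest isoform),
#'   ordered by `abs(distance)`
#' @export
genes_within_window <- function(chrom, peak_center, models,
                                half_width = 1250) {
  stopifnot(half_width > 0)
  tx <- models$transcripts
  empty <- data.frame(gene_id = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(tx)) return(empty)
  lo <- peak_center - half_width
  hi <- peak_center + half_width
  cand <- tx[tx$chrom == chrom &
               ((tx$tss >= lo & tx$tss <= hi) |
                  (tx$start <= hi & tx$end >= lo)), , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand$adist <- abs(cand$tss - peak_center)
  cand$signed <- ifelse(cand$strand == "+", peak_center - cand$tss,
                        cand$tss - peak_center)
  best <- do.call(rbind, lapply(split(cand, cand$gene_id), function(g)
    g[which.min(g$adist), c("gene_id", "signed", "adist")]))
  best <- best[order(best$adist, best$gene_id), ]
  data.frame(gene_id = best$gene_id, distance = best$signed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a binding site against the gene annotation
#'
#' Applies the partition rules over the union of isoforms: a site inside any
#' transcribed span is intragenic (sub-labelled exon/intron by the
#' containing isoform closest by TSS, or `promoter_intragenic` when it also
#' lies within `promoter_radius` of any TSS); otherwise a site within
#' `promoter_radius` of a TSS is `promoter_intergenic`; otherwise within
#' `downstream_radius` past a transcript 3' end is `downstream`; else
#' `intergenic`. The promoter is bidirectional
#' (`|peak - TSS| <= promoter_radius` on either side).
#'
#' @param chrom,peak_center peak position
#' @param models a [gene_models()]
#' @param promoter_radius bp around a TSS counted as promoter (default 1250)
#' @param downstream_radius bp past a 3' end counted as downstream
#'   (default 1250)
#' @return list: `category` (one of `promoter_intergenic`,
#'   `promoter_intragenic`, `exon`, `intron`, `downstream`, `intergenic`),
#'   `label` (e.g. `"Intron1"`, `"Exon2"`, or `NA`), `gene_id` (containing
#'   or promoter gene, or `NA`)
#' @export
classify_site <- function(chrom, peak_center, models,
                          promoter_radius = 1250,
                          downstream_radius = 1250) {
  tx <- models$transcripts
  cand <- tx[tx$chrom == chrom, , drop = FALSE]
  near_tss <- nrow(cand) > 0 &&
    any(abs(cand$tss - peak_center) <= promoter_radius)
  containing <- cand[cand$start <= peak_center & cand$end >= peak_center, ,
                     drop = FALSE]
  if (nrow(containing)) {
    # label by the containing isoform whose TSS is closest
    i <- which.min(abs(containing$tss - peak_center))
    t1 <- containing[i, ]
    ex <- models$exons[models$exons$tx_id == t1$tx_id, , drop = FALSE]
    in_ex <- ex[ex$start <= peak_center & ex$end >= peak_center, ,
                drop = FALSE]
    if (nrow(in_ex)) {
      label <- sprintf("Exon%d", in_ex$rank[1L])
      sub <- "exon"
    } else {
      # intron rank = rank of the exon preceding it in transcription order
      before <- if (t1$strand == "+") ex[ex$end < peak_center, , drop = FALSE]
                else ex[ex$start > peak_center, , drop = FALSE]
      r <- if (nrow(before)) max(before$rank) else 0L
      label <- sprintf("Intron%d", max(1L, r))
      sub <- "intron"
    }
    if (near_tss)
      return(list(category = "promoter_intragenic", label = label,
                  gene_id = t1$gene_id))
    return(list(category = sub, label = label, gene_id = t1$gene_id))
  }
  if (near_tss) {
    i <- which.min(abs(cand$tss - peak_center))
    return(list(category = "promoter_intergenic", label = NA_character_,
                gene_id = cand$gene_id[i]))
  }
  if (nrow(cand)) {
    end3 <- ifelse(cand$strand == "+", cand$end, cand$start)
    past <- ifelse(cand$strand == "+", peak_center - end3,
                   end3 - peak_center)
    ds <- past > 0 & past <= downstream_radius
    if (any(ds)) {
      i <- which(ds)[which.min(past[ds])]
      return(list(category = "downstream", label = NA_character_,
                  gene_id = cand$gene_id[i]))
    }
  }
  list(category = "intergenic", label = NA_character_,
       gene_id = NA_character_)
}

#' Annotate a set of peaks
#'
#' Vectorized convenience over [nearest_tss()], [genes_within_window()] and
#' [classify_site()], matching the per-site annotation reported for bound
#' segments (nearest gene, signed TSS distance, category, ordinal label).
#'
#' @param peaks data.frame with `chrom` and a peak-center column
#' @param models a [gene_models()]
#' @param promoter_radius,downstream_radius,half_width see the underlying
#'   functions
#' @return data.frame of class `"site_annotation"`: `chrom`, `peak_center`,
#'   `nearest_gene`, `distance_to_tss`, `category`, `label`,
#'   `genes_in_window` (comma-separated, in proximity order)
#' @export
annotate_sites <- function(peaks, models, promoter_radius = 1250,
                           downstream_radius = 1250, half_width = 1250) {
  centers <- peak_centers(peaks)
  rows <- lapply(seq_len(nrow(centers)), function(i) {
    ch <- centers$chrom[i]; p <- centers$center[i]
    nt <- nearest_tss(ch, p, models)
    cl <- classify_site(ch, p, models, promoter_radius, downstream_radius)
    gw <- genes_within_window(ch, p, models, half_width)
    data.frame(chrom = ch, peak_center = p, nearest_gene = nt$gene_id,
               distance_to_tss = nt$distance, category = cl$category,
               label = cl$label, site_gene = cl$gene_id,
               genes_in_window = paste(gw$gene_id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("site_annotation", "data.frame")
  res
}

#' Category breakdown of annotated sites
#'
#' Fractions of sites per exclusive category plus the derived aggregates:
#' `intragenic` (exon + intron + promoter_intragenic) and `promoter_any`
#' (promoter_intergenic + promoter_intragenic).
#'
#' @param sites a `site_annotation` (or any data.frame with a `category`
#'   column)
#' @return list: `fractions` (named, summing to 1 over exclusive
#'   categories), `counts`, `aggregates`
#' @export
category_breakdown <- function(sites) {
  stopifnot(nrow(sites) >= 1)
  cats <- c("promoter_intergenic", "promoter_intragenic", "exon", "intron",
            "downstream", "intergenic")
  counts <- table(factor(sites$category, levels = cats))
  fr <- as.numeric(counts) / nrow(sites)
  names(fr) <- cats
  list(fractions = fr, counts = stats::setNames(as.integer(counts), cats),
       aggregates = c(
         intragenic = unname(fr["exon"] + fr["intron"] +
                               fr["promoter_intragenic"]),
         promoter_any = unname(fr["promoter_intergenic"] +
                                 fr["promoter_intragenic"])))
}

#' Genome composition background fractions
#'
#' Base-pair fractions of the genome that are intragenic (union of all
#' isoform transcribed spans), promoter (union of +/- `promoter_radius`
#' around every isoform TSS, clipped to the chromosome), and intronic
#' (transcribed union minus the exon union) -- the background against which
#' site-category enrichment is judged.
#'
#' @param models a [gene_models()]
#' @param chrom_lengths named vector of chromosome lengths
#' @param promoter_radius default 1250
#' @return named numeric: `intragenic`, `promoter`, `intronic`
#' @export
genome_composition <- function(models, chrom_lengths,
                               promoter_radius = 1250) {
  total <- sum(chrom_lengths)
  tx <- models$transcripts
  if (!nrow(tx))
    return(c(intragenic = 0, promoter = 0, intronic = 0))
  bp <- function(gr) sum(IRanges::width(IRanges::reduce(gr)))
  per_chrom <- function(f) sum(vapply(names(chrom_lengths), f, numeric(1)))
  intragenic <- per_chrom(function(ch) {
    sel <- tx$chrom == ch
    if (!any(sel)) return(0)
    bp(IRanges::IRanges(tx$start[sel], tx$end[sel]))
  })
  promoter <- per_chrom(function(ch) {
    sel <- tx$chrom == ch
    if (!any(sel)) return(0)
    bp(IRanges::IRanges(pmax(1, tx$tss[sel] - promoter_radius),
                        pmin(chrom_lengths[[ch]],
                             tx$tss[sel] + promoter_radius)))
  })
  ex <- models$exons
  exch <- tx$chrom[match(ex$tx_id, tx$tx_id)]
  intronic <- per_chrom(function(ch) {
    sel <- tx$chrom == ch
    if (!any(sel)) return(0)
    tx_u <- IRanges::reduce(IRanges::IRanges(tx$start[sel], tx$end[sel]))
    esel <- exch == ch
    ex_u <- IRanges::reduce(IRanges::IRanges(ex$start[esel], ex$end[esel]))
    sum(IRanges::width(IRanges::setdiff(tx_u, ex_u)))
  })
  c(intragenic = intragenic / total, promoter = promoter / total,
    intronic = intronic / total)
}

#' Map genomic positions to cytological bands
#'
#' @param chrom,position vectors of positions
#' @param bands band map data.frame (`band`, `chrom`, `start`, `end`,
#'   `index`); bands must partition each chromosome (left-closed intervals)
#' @return character vector of band labels; a position outside all bands is
#'   an error naming it
#' @export
map_to_band <- function(chrom, position, bands) {
  stopifnot(length(chrom) == length(position))
  out <- character(length(position))
  for (ch in unique(chrom)) {
    b <- bands[bands$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    sel <- which(chrom == ch)
    if (!nrow(b))
      stop("position outside all bands: ", ch, ":", position[sel[1L]])
    i <- findInterval(position[sel], b$start)
    bad <- i < 1L | position[sel] > b$end[pmax(i, 1L)]
    if (any(bad))
      stop("position outside all bands: ", ch, ":",
           position[sel][which(bad)[1L]])
    out[sel] <- b$band[i]
  }
  out
}

#' Polytene-locus overlap test
#'
#' Builds, over all bands in the map, the 2x2 table (band hit by a ChIP
#' site within `offset_tolerance` band indices) x (band in the polytene
#' locus list) and tests independence with a 1-df chi-square without
#' continuity correction. Band-index tolerance never crosses a chromosome.
#'
#' @param site_bands character vector of bands containing ChIP sites
#' @param polytene_loci character vector of stained-locus band labels
#' @param bands the band map
#' @param offset_tolerance 0 (direct overlap) or 1 (within one band)
#' @return list of class `"polytene_overlap"`: `table` (2x2), `chi2`, `p`,
#'   `direct_overlap` (loci whose band holds a site), `within_tolerance`,
#'   `coverage` (fraction of loci within tolerance of a site band)
#' @export
polytene_overlap <- function(site_bands, polytene_loci, bands,
                             offset_tolerance = 0) {
  stopifnot(offset_tolerance %in% c(0, 1))
  bands <- bands[order(bands$chrom, bands$index), , drop = FALSE]
  hit_direct <- bands$band %in% site_bands
  hit <- hit_direct
  if (offset_tolerance == 1) {
    for (ch in unique(bands$chrom)) {
      sel <- which(bands$chrom == ch)
      h <- hit_direct[sel]
      hit[sel] <- h | c(h[-1L], FALSE) | c(FALSE, h[-length(h)])
    }
  }
  in_loci <- bands$band %in% polytene_loci
  tab <- table(factor(hit, c(TRUE, FALSE)), factor(in_loci, c(TRUE, FALSE)))
  dimnames(tab) <- list(site = c("hit", "no_site"),
                        polytene = c("locus", "no_locus"))
  ts <- tryCatch(chi2_2x2(unclass(tab)),
                 error = function(e) list(chi2 = NA_real_, p = NA_real_))
  loci_hit <- polytene_loci %in% bands$band[hit]
  structure(list(
    table = tab, chi2 = ts$chi2, p = ts$p,
    direct_overlap = sum(polytene_loci %in% bands$band[hit_direct]),
    within_tolerance = sum(loci_hit),
    coverage = if (length(polytene_loci)) mean(loci_hit) else NA_real_),
    class = "polytene_overlap")
}

#' @export
print.polytene_overlap <- function(x, ...) {
  cat(sprintf(
    "<polytene_overlap> %d/%d loci covered (%.0f%%), chi2 = %.2f, p = %.3g\n",
    x$within_tolerance, sum(x$table[, "locus"]), 100 * x$coverage, x$chi2,
    x$p))
  invisible(x)
}
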