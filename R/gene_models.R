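#' Multi-isoform gene models
#'
#' A light container for gene annotation as consumed by the site-annotation
#' and expression-integration stages: one row per transcript (isoform) with
#' its own transcription start site (TSS), plus an exon table. Coordinates
#' are 1-based inclusive throughout the package; GFF3/BED files written or
#' read by it follow each format's own convention via `rtracklayer`.
#'
#' @param transcripts data.frame with columns `tx_id`, `gene_id`, `chrom`,
#'   `strand` (`+`/`-`), `start`, `end`.
#' @param exons data.frame with columns `tx_id`, `start`, `end`. Exons of a
#'   transcript must be disjoint and lie within its span.
#' @return an object of class `"gene_models"`. The `tss` column is derived:
#'   `start` for `+` transcripts, `end` for `-`.
#' @export
gene_models <- function(transcripts, exons) {
  need <- c("tx_id", "gene_id", "chrom", "strand", "start", "end")
  stopifnot(all(need %in% names(transcripts)),
            all(c("tx_id", "start", "end") %in% names(exons)))
  transcripts <- as.data.frame(transcripts)[
    , union(need, names(transcripts)), drop = FALSE]
  exons <- as.data.frame(exons)
  if (nrow(transcripts)) {
    stopifnot(all(transcripts$strand %in% c("+", "-")),
              all(transcripts$end >= transcripts$start),
              !anyDuplicated(transcripts$tx_id))
    stopifnot(all(exons$tx_id %in% transcripts$tx_id))
    ord <- order(exons$tx_id, exons$start)
    exons <- exons[ord, , drop = FALSE]
    by_tx <- split(seq_len(nrow(exons)), exons$tx_id)
    for (ix in by_tx) {
      if (length(ix) > 1L &&
          any(exons$start[ix][-1L] <= exons$end[ix][-length(ix)]))
        stop("overlapping exons within transcript ",
             exons$tx_id[ix[1L]])
    }
    transcripts$tss <- ifelse(transcripts$strand == "+",
                              transcripts$start, transcripts$end)
    # exon rank in transcription order
    strand_of <- stats::setNames(transcripts$strand, transcripts$tx_id)
    exons$rank <- unlist(lapply(by_tx, function(ix) {
      if (strand_of[[exons$tx_id[ix[1L]]]] == "+") seq_along(ix)
      else rev(seq_along(ix))
    }), use.names = FALSE)[order(unlist(by_tx, use.names = FALSE))]
  } else {
    transcripts$tss <- integer(0)
    exons$rank <- integer(0)
  }
  rownames(transcripts) <- rownames(exons) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d transcripts, %d exons\n",
              length(unique(x$transcripts$gene_id)), nrow(x$transcripts),
              nrow(x$exons)))
  invisible(x)
}

n_genes <- function(models) length(unique(models$transcripts$gene_id))

# GRanges of transcript spans / exons (with tx metadata)
transcript_ranges <- function(models) {
  tx <- models$transcripts
  GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start, tx$end),
                         strand = tx$strand, tx_id = tx$tx_id,
                         gene_id = tx$gene_id)
}

exon_ranges <- function(models) {
  ex <- models$exons
  tx <- models$transcripts
  i <- match(ex$tx_id, tx$tx_id)
  GenomicRanges::GRanges(tx$chrom[i], IRanges::IRanges(ex$start, ex$end),
                         strand = tx$strand[i], tx_id = ex$tx_id,
                         rank = ex$rank)
}

#' Convert gene models to a GFF3-style GRanges
#'
#' Emits gene / mRNA / exon features with `ID` and `Parent` attributes,
#' suitable for `rtracklayer::export(..., format = "gff3")`.
#'
#' @param models a `gene_models` object
#' @return a `GRanges`
#' @export
as_gff <- function(models) {
  tx <- models$transcripts
  ex <- models$exons
  if (!nrow(tx)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$type <- character(0)
    return(gr)
  }
  gene_span <- do.call(rbind, lapply(split(tx, tx$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               strand = g$strand[1L], start = min(g$start),
               end = max(g$end), stringsAsFactors = FALSE)))
  gene_span <- gene_span[order(gene_span$chrom, gene_span$start), ]
  gg <- GenomicRanges::GRanges(
    gene_span$chrom, IRanges::IRanges(gene_span$start, gene_span$end),
    strand = gene_span$strand, type = "gene", ID = gene_span$gene_id,
    Parent = IRanges::CharacterList(vector("list", nrow(gene_span))))
  tg <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start, tx$end), strand = tx$strand,
    type = "mRNA", ID = tx$tx_id,
    Parent = IRanges::CharacterList(as.list(tx$gene_id)))
  i <- match(ex$tx_id, tx$tx_id)
  eg <- GenomicRanges::GRanges(
    tx$chrom[i], IRanges::IRanges(ex$start, ex$end), strand = tx$strand[i],
    type = "exon", ID = paste0(ex$tx_id, ".e", ex$rank),
    Parent = IRanges::CharacterList(as.list(ex$tx_id)))
  sort(c(gg, tg, eg), ignore.strand = TRUE)
}

#' Read gene models from a GFF3 file
#'
#' Accepts the subset of GFF3 written by [as_gff()] /
#' [write_sim()]: `mRNA` (or `transcript`) features parented to genes and
#' `exon` features parented to transcripts.
#'
#' @param path GFF3 file
#' @return a `gene_models` object
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  is_ex <- type == "exon"
  parent1 <- function(g) vapply(as.list(g$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  txg <- gr[is_tx]
  exg <- gr[is_ex]
  transcripts <- data.frame(
    tx_id = as.character(txg$ID), gene_id = parent1(txg),
    chrom = as.character(GenomicRanges::seqnames(txg)),
    strand = as.character(GenomicRanges::strand(txg)),
    start = GenomicRanges::start(txg), end = GenomicRanges::end(txg),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    tx_id = parent1(exg), start = GenomicRanges::start(exg),
    end = GenomicRanges::end(exg), stringsAsFactors = FALSE)
  gene_models(transcripts, exons)
}
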