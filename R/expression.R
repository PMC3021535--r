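#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via `stats::p.adjust(method = "BH")`, with
#' input validation; values are returned in input order.
#'
#' @param p raw p-values in \[0, 1\]
#' @return adjusted p-values
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression calls
#'
#' A gene is `up` when `fold_change >= fold_threshold` and
#' `fdr_p < alpha` (strict, per the "FDR corrected p-value less than 0.01"
#' rule; the fold cut-off is inclusive: "2-fold or greater"), `down` when
#' `fold_change <= -fold_threshold` with the same p rule, else `unchanged`.
#' Fold changes use the signed-ratio convention (|fold| >= 1; -1.5 means
#' 1.5-fold down).
#'
#' @param records data.frame with `gene_id`, `system`, `fold_change`,
#'   `fdr_p`
#' @param fold_threshold default 2
#' @param alpha default 0.01
#' @return the records with an added `status` factor (up/down/unchanged)
#' @export
differential_calls <- function(records, fold_threshold = 2, alpha = 0.01) {
  need <- c("gene_id", "system", "fold_change", "fdr_p")
  stopifnot(all(need %in% names(records)))
  if (anyDuplicated(records[, c("gene_id", "system")]))
    stop("duplicate (gene_id, system) rows in expression records")
  if (any(records$fdr_p < 0 | records$fdr_p > 1))
    stop("fdr_p outside [0, 1]")
  records$status <- ifelse(
    records$fold_change >= fold_threshold & records$fdr_p < alpha, "up",
    ifelse(records$fold_change <= -fold_threshold & records$fdr_p < alpha,
           "down", "unchanged"))
  records$status <- factor(records$status, c("up", "down", "unchanged"))
  records
}

regulated_genes <- function(calls, system = NULL) {
  if (!is.null(system)) calls <- calls[calls$system %in% system, ,
                                       drop = FALSE]
  unique(calls$gene_id[calls$status != "unchanged"])
}

#' Three-set Venn of bound and regulated genes
#'
#' The 7-region Venn over (bound genes, regulated in system A, regulated in
#' system B), plus the exactly-one-system count and percentage among
#' regulated genes (`exclusive = |A| + |B| - 2|A&B|` over
#' `union = |A| + |B| - |A&B|`).
#'
#' @param bound_genes character vector of HSF-associated genes
#' @param calls_a,calls_b differential-call tables (from
#'   [differential_calls()]) or plain character vectors of regulated genes
#' @return list of class `"binding_venn"`: `regions` (named counts),
#'   `membership` (named list of gene vectors), `one_system_count`,
#'   `one_system_pct`, `triple`
#' @export
intersect_lists <- function(bound_genes, calls_a, calls_b) {
  a <- if (is.character(calls_a)) unique(calls_a) else
    regulated_genes(calls_a)
  b <- if (is.character(calls_b)) unique(calls_b) else
    regulated_genes(calls_b)
  bound <- unique(bound_genes)
  inB <- function(g) g %in% bound
  regions <- list(
    bound_only = setdiff(bound, union(a, b)),
    a_only = setdiff(a, union(bound, b)),
    b_only = setdiff(b, union(bound, a)),
    bound_a = setdiff(intersect(bound, a), b),
    bound_b = setdiff(intersect(bound, b), a),
    a_b = setdiff(intersect(a, b), bound),
    bound_a_b = Reduce(intersect, list(bound, a, b)))
  ab <- length(intersect(a, b))
  un <- length(union(a, b))
  structure(list(
    regions = vapply(regions, length, integer(1)),
    membership = regions,
    one_system_count = length(a) + length(b) - 2L * ab,
    one_system_pct = if (un) 100 * (length(a) + length(b) - 2 * ab) / un
                     else NA_real_,
    triple = length(regions$bound_a_b)),
    class = "binding_venn")
}

#' @export
print.binding_venn <- function(x, ...) {
  cat("<binding_venn> regions:\n")
  print(x$regions)
  cat(sprintf("one-system: %d (%.1f%% of regulated); triple overlap: %d\n",
              x$one_system_count, x$one_system_pct, x$triple))
  invisible(x)
}

#' Genes associated with binding sites
#'
#' A gene is associated when (a) a segment peak lies within its transcribed
#' span (isoform union) or (b) one of its TSSs lies within `radius` of a
#' peak center.
#'
#' @param models a [gene_models()]
#' @param segments `bound_segments` (or data.frame with `chrom` and a peak
#'   column)
#' @param radius TSS association radius (default 1250)
#' @return character vector of associated gene ids
#' @export
gene_site_association <- function(models, segments, radius = 1250) {
  if (!nrow(segments)) return(character(0))
  centers <- peak_centers(segments)
  tx <- models$transcripts
  out <- character(0)
  for (ch in unique(centers$chrom)) {
    pk <- centers$center[centers$chrom == ch]
    sel <- tx$chrom == ch
    if (!any(sel)) next
    txc <- tx[sel, ]
    inside <- vapply(seq_len(nrow(txc)), function(i)
      any(pk >= txc$start[i] & pk <= txc$end[i]), logical(1))
    near <- vapply(seq_len(nrow(txc)), function(i)
      any(abs(pk - txc$tss[i]) <= radius), logical(1))
    out <- c(out, txc$gene_id[inside | near])
  }
  sort(unique(out))
}

#' Distance from gene TSSs to the nearest binding site
#'
#' Per gene, the signed distance (positive downstream of the TSS in the
#' gene's direction) to the closest peak center over all its isoform TSSs;
#' the summary reports mean and median of the absolute distances.
#'
#' @param models a [gene_models()]
#' @param segments peak table; must be non-empty
#' @param genes optional subset of gene ids (default: all)
#' @return list: `distances` (data.frame `gene_id`, `distance`), `summary`
#'   (`mean_abs`, `median_abs`)
#' @export
distance_to_nearest_site <- function(models, segments, genes = NULL) {
  centers <- peak_centers(segments)
  if (!nrow(centers)) stop("no binding sites supplied")
  tx <- models$transcripts
  if (!is.null(genes)) tx <- tx[tx$gene_id %in% genes, , drop = FALSE]
  rows <- lapply(split(tx, tx$gene_id), function(g) {
    best <- Inf; sgn <- NA_real_
    for (i in seq_len(nrow(g))) {
      pk <- centers$center[centers$chrom == g$chrom[i]]
      if (!length(pk)) next
      d <- pk - g$tss[i]
      j <- which.min(abs(d))
      if (abs(d[j]) < abs(best)) {
        best <- d[j]
        sgn <- if (g$strand[i] == "+") d[j] else -d[j]
      }
    }
    data.frame(gene_id = g$gene_id[1L], distance = sgn,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d <- d[!is.na(d$distance), , drop = FALSE]
  list(distances = d,
       summary = c(mean_abs = mean(abs(d$distance)),
                   median_abs = stats::median(abs(d$distance))))
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' No continuity correction, 1 df; a zero marginal makes the test undefined
#' and is reported as an error.
#'
#' @param table 2x2 matrix of non-negative counts
#' @return list: `chi2`, `p`, `table`
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal: chi-square test undefined")
  ts <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ts$statistic), p = unname(ts$p.value), table = table)
}

#' BEAF-motif-by-induction contingency report
#'
#' Summarizes, for HSF-bound promoters split by heat-shock induction of the
#' associated gene, the counts and percentages carrying (i) at least one
#' BEAF motif at the scan cut-off, (ii) an external BEAF ChIP binding
#' interval, and (iii) both, and applies [chi2_2x2()] to (i) and (ii).
#'
#' @param promoters data.frame with one row per bound promoter gene:
#'   `gene_id`, logical `induced`, logical `has_motif`, optional logical
#'   `beaf_bound`
#' @return list of class `"motif_induction_report"`: `counts` (data.frame),
#'   `motif_test`, `binding_test` (each a [chi2_2x2()] result or a
#'   zero-marginal flag)
#' @export
motif_induction_report <- function(promoters) {
  stopifnot(all(c("gene_id", "induced", "has_motif") %in% names(promoters)))
  grp <- factor(ifelse(promoters$induced, "induced", "non_induced"),
                c("induced", "non_induced"))
  n <- table(grp)
  summarize <- function(flag) {
    k <- table(grp[flag])
    data.frame(group = names(n), n = as.integer(n),
               k = as.integer(k[names(n)]),
               pct = 100 * as.integer(k[names(n)]) / as.integer(n),
               stringsAsFactors = FALSE)
  }
  test_of <- function(flag) {
    k <- table(grp[flag])
    tab <- rbind(with = as.integer(k[c("induced", "non_induced")]),
                 without = as.integer(n[c("induced", "non_induced")]) -
                   as.integer(k[c("induced", "non_induced")]))
    colnames(tab) <- c("induced", "non_induced")
    tryCatch(chi2_2x2(tab),
             error = function(e) list(chi2 = NA_real_, p = NA_real_,
                                      flag = conditionMessage(e)))
  }
  motif <- summarize(promoters$has_motif)
  out <- list(counts = motif, motif_test = test_of(promoters$has_motif),
              binding_counts = NULL, binding_test = NULL,
              both_counts = NULL)
  if ("beaf_bound" %in% names(promoters)) {
    out$binding_counts <- summarize(promoters$beaf_bound)
    out$binding_test <- test_of(promoters$beaf_bound)
    out$both_counts <- summarize(promoters$has_motif & promoters$beaf_bound)
  }
  structure(out, class = "motif_induction_report")
}

#' @export
print.motif_induction_report <- function(x, ...) {
  cat("<motif_induction_report> promoters with >=1 BEAF motif:\n")
  print(x$counts, row.names = FALSE)
  if (!is.na(x$motif_test$p))
    cat(sprintf("  motif-by-induction chi2 = %.2f, p = %.4f\n",
                x$motif_test$chi2, x$motif_test$p))
  if (!is.null(x$binding_counts)) {
    cat("promoters bound by BEAF:\n")
    print(x$binding_counts, row.names = FALSE)
    if (!is.na(x$binding_test$p))
      cat(sprintf("  binding-by-induction chi2 = %.2f, p = %.4f\n",
                  x$binding_test$chi2, x$binding_test$p))
  }
  invisible(x)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with the Manhattan (L1) distance and unweighted
#' average linkage (UPGMA), as used for heat-map ordering of log2
#' expression profiles.
#'
#' @param log2_matrix numeric matrix, rows = genes, columns = conditions;
#'   non-finite entries are an error listing the offending genes
#' @return list of class `"profile_clustering"`: `hclust`, `order` (leaf
#'   gene ids), `merge_heights`
#' @export
cluster_profiles <- function(log2_matrix) {
  m <- as.matrix(log2_matrix)
  bad <- !apply(is.finite(m), 1L, all)
  if (any(bad))
    stop("non-finite expression values for: ",
         paste(rownames(m)[bad], collapse = ", "))
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  hc <- stats::hclust(stats::dist(m, method = "manhattan"),
                      method = "average")
  structure(list(hclust = hc, order = rownames(m)[hc$order],
                 merge_heights = hc$height),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("<profile_clustering> %d leaves, max merge height %.3f\n",
              length(x$order), max(x$merge_heights)))
  invisible(x)
}

#' Export a profile clustering as a Newick tree
#' @param clustering a `profile_clustering`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Hypergeometric term enrichment
#'
#' One-sided hypergeometric tail probability of the observed overlap
#' between a gene list and each term's gene set, against a user-supplied
#' background (for intron-gene analyses, pass all genes with introns as the
#' background), with Benjamini-Hochberg adjustment.
#'
#' @param gene_list character vector; must be a subset of
#'   `background_genes`
#' @param background_genes character vector (the universe)
#' @param term_map named list: term -> character vector of genes (entries
#'   outside the background are ignored)
#' @return data.frame `term`, `overlap`, `term_size`, `p`, `p_adj`, sorted
#'   by `p`
#' @export
term_enrichment <- function(gene_list, background_genes, term_map) {
  background_genes <- unique(background_genes)
  gene_list <- unique(gene_list)
  missing <- setdiff(gene_list, background_genes)
  if (length(missing))
    stop("genes not in background: ", paste(missing, collapse = ", "))
  N <- length(background_genes)
  n <- length(gene_list)
  rows <- lapply(names(term_map), function(tm) {
    term_genes <- intersect(unique(term_map[[tm]]), background_genes)
    K <- length(term_genes)
    k <- length(intersect(term_genes, gene_list))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_fdr(res$p)
  res[order(res$p, res$term), ]
}
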