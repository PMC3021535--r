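test_that("differential calls apply the inclusive-fold strict-p rule", {
  rec <- data.frame(
    gene_id = c("Hsp70Bbb", "CG32850", "boundary", "down", "weak_p"),
    system = "cells",
    fold_change = c(41.9, 1.2, 2.0, -2.2, 3.0),
    fdr_p = c(2.0e-10, 0.7, 0.01, 4.66e-3, 0.02))
  calls <- differential_calls(rec)
  expect_equal(as.character(calls$status),
               c("up", "unchanged", "unchanged", "down", "unchanged"))
  # fold exactly at threshold with p just under alpha is called
  rec2 <- data.frame(gene_id = "g", system = "s", fold_change = 2,
                     fdr_p = 0.0099)
  expect_equal(as.character(differential_calls(rec2)$status), "up")
  # duplicate (gene, system) rows are an error
  expect_error(differential_calls(rbind(rec, rec[1, ])), "duplicate")
})

test_that("BH adjustment matches the hand-coded step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  # order invariance: values returned in input order
  p <- runif(15)
  o <- sample(15)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("venn regions partition the union and give the one-system stats", {
  v <- intersect_lists(c("a", "b", "c"), c("b", "c", "d"), c("c", "e"))
  expect_equal(sum(v$regions), length(unique(c("a", "b", "c", "d", "e"))))
  expect_equal(v$triple, 1L)
  expect_equal(unname(v$regions["a_only"]), 1L)  # d
  # disjoint inputs: no triple overlap
  v0 <- intersect_lists("x", "y", "z")
  expect_equal(v0$triple, 0L)
  # the published one-system arithmetic: |A|=211, |B|=237, |A&B|=33
  a <- paste0("g", 1:211)
  b <- c(paste0("g", 1:33), paste0("h", 1:204))
  v2 <- intersect_lists(character(0), a, b)
  expect_equal(v2$one_system_count, 211L + 237L - 66L)
  expect_equal(v2$one_system_pct, 100 * (211 + 237 - 66) / (211 + 237 - 33),
               tolerance = 1e-12)
  expect_equal(round(v2$one_system_pct), 92)
})

test_that("gene-site association covers gene bodies and promoter radius", {
  m <- tiny_models()
  # peak inside geneA's body, 4 kb from its TSS (rule a)
  segs <- data.frame(chrom = "chr1", peak_center = 8350L)
  expect_equal(gene_site_association(m, segs), "geneA")
  # peak 1.3 kb upstream of the TSS: not associated
  expect_length(gene_site_association(
    m, data.frame(chrom = "chr1", peak_center = 3700L)), 0L)
  # peak 1.2 kb from the TSS: associated via rule b
  expect_equal(gene_site_association(
    m, data.frame(chrom = "chr1", peak_center = 3800L)), "geneA")
  expect_length(gene_site_association(m, segs[0, ]), 0L)
})

test_that("distance to nearest site honours signs, gaps and medians", {
  m <- tiny_models()
  peaks <- data.frame(chrom = "chr1", peak_center = c(5000L, 150000L))
  d <- distance_to_nearest_site(m, peaks)
  expect_equal(d$distances$distance[d$distances$gene_id == "geneA"], 0)
  # geneB (- strand, TSS 20999): nearest peak at 5000, upstream side
  expect_equal(abs(d$distances$distance[d$distances$gene_id == "geneB"]),
               15999)
  expect_error(distance_to_nearest_site(m, peaks[0, ]), "no binding sites")
  expect_equal(unname(stats::median(c(10, 20, 30))), 20)

  # a responsive gene beyond a masked probe gap sits far from any called site
  cfg <- sim_config(genome_length = 3e5, n_chromosomes = 1, n_genes = 30,
                    n_segments = 6, seed = 19)
  sim <- sim_study(cfg)
  gap <- sim$masks[which.max(sim$masks$end - sim$masks$start), ]
  segs <- call_segments(sim$chip$hs)
  gap_mid <- (gap$start + gap$end) %/% 2L
  dist_gap <- min(abs(segs$peak_center - gap_mid))
  expect_gt(dist_gap, (gap$end - gap$start + 1) / 2)
})

test_that("the 2x2 chi-square reproduces published and textbook values", {
  # BEAF binding by induction: 3/8 induced vs 66/38 non-induced
  tab <- matrix(c(3, 8, 66, 38), 2, byrow = FALSE,
                dimnames = list(c("bound", "unbound"),
                                c("induced", "non_induced")))
  tab <- matrix(c(3, 66, 8, 38), 2, byrow = TRUE)
  ts <- chi2_2x2(tab)
  expect_equal(ts$chi2, 5.43, tolerance = 0.01)
  expect_equal(ts$p, 0.0198, tolerance = 0.01)
  expect_equal(chi2_2x2(matrix(10, 2, 2))$chi2, 0)
  expect_equal(chi2_2x2(matrix(10, 2, 2))$p, 1)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
  # oracle equivalence on random tables
  set.seed(77)
  for (i in 1:50) {
    m <- matrix(rpois(4, 30) + 1, 2)
    expect_equal(chi2_2x2(m)$chi2, oracle_chi2_2x2(m)$chi2,
                 tolerance = 1e-9)
  }
})

test_that("the motif-induction report reproduces the published percentages", {
  counts <- utils::read.table(extdata("beaf_promoter_counts.tsv"),
                              header = TRUE, sep = "\t")
  rownames(counts) <- counts$row
  n_ind <- counts["total_promoters", "induced"]
  n_non <- counts["total_promoters", "non_induced"]
  promoters <- data.frame(
    gene_id = sprintf("p%03d", seq_len(n_ind + n_non)),
    induced = rep(c(TRUE, FALSE), c(n_ind, n_non)))
  promoters$has_motif <- c(
    rep(c(TRUE, FALSE),
        c(counts["promoters_with_beaf_motif", "induced"],
          n_ind - counts["promoters_with_beaf_motif", "induced"])),
    rep(c(TRUE, FALSE),
        c(counts["promoters_with_beaf_motif", "non_induced"],
          n_non - counts["promoters_with_beaf_motif", "non_induced"])))
  promoters$beaf_bound <- c(
    rep(c(TRUE, FALSE),
        c(counts["promoters_bound_by_beaf", "induced"],
          n_ind - counts["promoters_bound_by_beaf", "induced"])),
    rep(c(TRUE, FALSE),
        c(counts["promoters_bound_by_beaf", "non_induced"],
          n_non - counts["promoters_bound_by_beaf", "non_induced"])))
  rep_ <- motif_induction_report(promoters)
  pct <- rep_$counts$pct
  names(pct) <- rep_$counts$group
  expect_equal(round(unname(pct["induced"])), 27)
  expect_equal(round(unname(pct["non_induced"])), 66)
  expect_equal(rep_$binding_test$p, 0.0198, tolerance = 0.01)
  # no motifs anywhere: percentages zero, test flagged undefined
  none <- promoters
  none$has_motif <- FALSE
  r0 <- motif_induction_report(none[, c("gene_id", "induced", "has_motif")])
  expect_true(all(r0$counts$pct == 0))
  expect_true(is.na(r0$motif_test$p))
})

test_that("profile clustering follows the average-linkage recurrence", {
  m <- matrix(c(0, 1, 5), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  cl <- cluster_profiles(m)
  expect_equal(cl$merge_heights, c(1, 4.5))
  # identical rows merge first at height zero
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  cl2 <- cluster_profiles(m2)
  expect_equal(cl2$merge_heights[1], 0)
  # permuting rows permutes leaves but preserves merge heights
  set.seed(3)
  m3 <- matrix(rnorm(40), 10, 4,
               dimnames = list(letters[1:10], NULL))
  perm <- sample(10)
  expect_equal(cluster_profiles(m3)$merge_heights,
               cluster_profiles(m3[perm, ])$merge_heights,
               tolerance = 1e-12)
  expect_setequal(cluster_profiles(m3)$order,
                  cluster_profiles(m3[perm, ])$order)
  expect_error(cluster_profiles(rbind(ok = c(1, 2), bad = c(NA, 1))),
               "bad")
  # Newick export round-trips through ape
  f <- tempfile(fileext = ".nwk")
  write_newick(cl, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, rownames(m))
})

test_that("term enrichment equals the hypergeometric tail", {
  bg <- paste0("g", 1:20)
  tm <- list(all = bg, rare = c("g1", "g2", "g3"))
  # a term covering the whole background is never enriched
  res <- term_enrichment(c("g1", "g2", "g3"), bg, tm)
  expect_equal(res$p[res$term == "all"], 1)
  # list = all genes of a rare term: exact tail sum
  expect_equal(res$p[res$term == "rare"],
               stats::phyper(2, 3, 17, 3, lower.tail = FALSE))
  expect_equal(res$p[res$term == "rare"], 1 / choose(20, 3))
  # empty list: all p 1
  res0 <- term_enrichment(character(0), bg, tm)
  expect_true(all(res0$p == 1))
  expect_error(term_enrichment("nope", bg, tm), "not in background")
})
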