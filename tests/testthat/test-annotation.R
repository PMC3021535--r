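models <- tiny_models()

test_that("nearest TSS uses the strand-aware sign convention", {
  # geneA (+) TSS at 5000; geneB (-) TSS at 20999
  expect_equal(nearest_tss("chr1", 5000, models)$distance, 0)
  # peak upstream of a + gene: negative
  at <- nearest_tss("chr1", 4800, models)
  expect_equal(at$gene_id, "geneA")
  expect_equal(at$distance, -200)
  # peak downstream of the + TSS: positive
  expect_equal(nearest_tss("chr1", 5200, models)$distance, 200)
  # minus-strand gene: upstream lies at higher coordinates
  expect_equal(nearest_tss("chr1", 20799, models)$distance, 200)
  expect_equal(nearest_tss("chr1", 21199, models)$distance, -200)
  expect_error(nearest_tss("chr1", 100,
                           gene_models(models$transcripts[0, ],
                                       models$exons[0, ])),
               "empty")
})

test_that("nearest TSS ties break toward the containing gene body", {
  m <- gene_models(
    transcripts = data.frame(
      tx_id = c("a.t1", "b.t1"), gene_id = c("a", "b"), chrom = "chr1",
      strand = "+", start = c(1000L, 3000L), end = c(2500L, 4000L)),
    exons = data.frame(tx_id = c("a.t1", "b.t1"),
                       start = c(1000L, 3000L), end = c(2500L, 4000L)))
  # position 2000: 1000 from both TSSs; only gene a contains it
  expect_equal(nearest_tss("chr1", 2000, m)$gene_id, "a")
})

test_that("gene windows are ordered by TSS proximity and truncate safely", {
  expect_equal(nrow(genes_within_window("chr1", 12000, models)), 0L)
  # both genes reachable with a huge window; order follows |distance|
  w <- genes_within_window("chr1", 5100, models, half_width = 20000)
  expect_equal(w$gene_id, c("geneA", "geneB"))
  expect_equal(w$distance, c(100, 15899))
  # a window over the chromosome start works
  expect_silent(genes_within_window("chr1", 10, models, half_width = 1250))
  # gene body intersection counts even when the TSS is outside the window
  w2 <- genes_within_window("chr1", 7000, models, half_width = 1100)
  expect_equal(w2$gene_id, "geneA")
})

test_that("site classification applies the partition rules", {
  # first intron, 2 kb from the TSS: intron-exclusive
  cl <- classify_site("chr1", 7000, models)
  expect_equal(cl$category, "intron")
  expect_equal(cl$label, "Intron1")
  # inside exon 1 right at the TSS: intragenic but promoter-near
  cl2 <- classify_site("chr1", 5005, models)
  expect_equal(cl2$category, "promoter_intragenic")
  expect_equal(cl2$label, "Exon1")
  # the same position with a tiny promoter radius is exonic
  cl3 <- classify_site("chr1", 5005, models, promoter_radius = 2)
  expect_equal(cl3$category, "exon")
  expect_equal(cl3$label, "Exon1")
  # second exon beyond the promoter radius
  cl4 <- classify_site("chr1", 8100, models)
  expect_equal(cl4$label, "Exon2")
  expect_equal(cl4$category, "exon")
  # 1200 bp upstream: promoter_intergenic; 1300 bp: intergenic
  expect_equal(classify_site("chr1", 3800, models)$category,
               "promoter_intergenic")
  expect_equal(classify_site("chr1", 3700, models)$category, "intergenic")
  # just past a + gene 3' end: downstream
  expect_equal(classify_site("chr1", 9000, models)$category, "downstream")
  # minus-strand promoter lies at coordinates above the TSS
  expect_equal(classify_site("chr1", 21500, models)$category,
               "promoter_intergenic")
})

test_that("category breakdown sums to one with the right aggregates", {
  sites <- data.frame(category = c("intron", "intron", "exon",
                                   "promoter_intergenic",
                                   "promoter_intragenic", "intergenic"))
  b <- category_breakdown(sites)
  expect_equal(sum(b$fractions), 1)
  expect_equal(unname(b$aggregates["intragenic"]), 4 / 6)
  expect_equal(unname(b$aggregates["promoter_any"]), 2 / 6)
  all_inter <- category_breakdown(data.frame(category = rep("intergenic", 5)))
  expect_equal(unname(all_inter$fractions["intergenic"]), 1)
})

test_that("genome composition equals union arithmetic and per-base oracle", {
  # one half-chromosome single-exon gene: intragenic 0.5, intronic 0
  m <- gene_models(
    transcripts = data.frame(tx_id = "g.t1", gene_id = "g", chrom = "chr1",
                             strand = "+", start = 1L, end = 5000L),
    exons = data.frame(tx_id = "g.t1", start = 1L, end = 5000L))
  comp <- genome_composition(m, c(chr1 = 10000L))
  expect_equal(unname(comp["intragenic"]), 0.5)
  expect_equal(unname(comp["intronic"]), 0)

  # nested isoforms do not double count
  m2 <- gene_models(
    transcripts = data.frame(tx_id = c("g.t1", "g.t2"), gene_id = "g",
                             chrom = "chr1", strand = "+",
                             start = c(1L, 1000L), end = c(5000L, 4000L)),
    exons = data.frame(tx_id = c("g.t1", "g.t2"), start = c(1L, 1000L),
                       end = c(5000L, 4000L)))
  comp2 <- genome_composition(m2, c(chr1 = 10000L))
  expect_equal(comp2[c("intragenic", "intronic")],
               comp[c("intragenic", "intronic")])

  # randomized annotation against the brute-force per-base oracle
  sim <- small_sim()
  lens <- sim$chrom_lengths
  expect_equal(genome_composition(sim$models, lens, 1250),
               oracle_composition(sim$models, lens, 1250),
               tolerance = 1e-12)
})

test_that("band mapping is left-closed and errors off the map", {
  bands <- data.frame(band = c("1.001", "1.002"), chrom = "chr1",
                      start = c(1L, 5001L), end = c(5000L, 10000L),
                      index = 1:2)
  expect_equal(map_to_band("chr1", 4999, bands), "1.001")
  expect_equal(map_to_band("chr1", 5001, bands), "1.002")
  expect_equal(map_to_band("chr1", 5000, bands), "1.001")
  expect_error(map_to_band("chr1", 10001, bands), "outside")
  expect_error(map_to_band("chr2", 10, bands), "outside")
  # all planted synthetic sites map to real bands
  sim <- small_sim()
  expect_silent(map_to_band(sim$truth$segments$chrom,
                            sim$truth$segments$peak, sim$cytology$bands))
})

test_that("polytene overlap handles shifts via the band-index tolerance", {
  bands <- data.frame(band = sprintf("1.%03d", 1:20), chrom = "chr1",
                      start = seq(1, by = 1000, length.out = 20),
                      end = seq(1000, by = 1000, length.out = 20),
                      index = 1:20)
  site_bands <- sprintf("1.%03d", c(3, 7, 11))
  # identical sets, tolerance 0: full coverage
  po <- polytene_overlap(site_bands, site_bands, bands, 0)
  expect_equal(po$coverage, 1)
  # all loci shifted one band: no direct overlap, full at tolerance 1
  shifted <- sprintf("1.%03d", c(4, 8, 12))
  p0 <- polytene_overlap(site_bands, shifted, bands, 0)
  expect_equal(p0$direct_overlap, 0L)
  expect_equal(p0$coverage, 0)
  p1 <- polytene_overlap(site_bands, shifted, bands, 1)
  expect_equal(p1$coverage, 1)
  expect_equal(p1$within_tolerance, 3L)
})

test_that("the polytene chi-square is calibrated under independence", {
  bands <- data.frame(band = sprintf("1.%03d", 1:200), chrom = "chr1",
                      start = seq(1, by = 1000, length.out = 200),
                      end = seq(1000, by = 1000, length.out = 200),
                      index = 1:200)
  set.seed(31)
  pvals <- replicate(400, {
    sites <- sample(bands$band, 40)
    loci <- sample(bands$band, 40)
    polytene_overlap(sites, loci, bands, 0)$p
  })
  # under the null the p-values should not pile up at small values
  expect_gt(mean(pvals > 0.05, na.rm = TRUE), 0.9)
  expect_gt(mean(pvals, na.rm = TRUE), 0.35)
})

test_that("annotated synthetic sites recover the planted categories", {
  sim <- small_sim()
  tr <- sim$truth$segments
  ann <- annotate_sites(tr, sim$models)
  # planted category -> expected exclusive classification
  expected <- c(promoter = "promoter_intergenic", intron = "intron",
                exon = "exon", intergenic = "intergenic")
  agree <- mean(ann$category == expected[tr$category])
  expect_gt(agree, 0.9)
  # promoter-planted segments annotate to their planted gene
  sel <- tr$category == "promoter"
  expect_true(all(ann$nearest_gene[sel] == tr$gene_id[sel]))
  expect_true(all(abs(ann$distance_to_tss[sel]) <= 1250))
})
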