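test_that("configuration invariants are enforced", {
  expect_error(sim_config(category_mix = c(promoter = 0.5, intron = 0.4,
                                           exon = 0.2, intergenic = 0.1)),
               "sum to 1")
  expect_error(sim_config(rt_retained_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(probe_spacing = 0), "probe_spacing")
  expect_warning(sim_config(probe_length = 300), "overlap")
  expect_error(sim_config(polytene_jitter = 2), "jitter")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(genome_length = 2e5, n_chromosomes = 1, n_genes = 20,
                    n_segments = 8, seed = 42)
  s1 <- sim_study(cfg)
  s2 <- sim_study(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim(s1, d1); write_sim(s2, d2)
  for (f in c("genome.fa", "annotation.gff3", "probes.bed",
              "chip_hs.tsv", "expression.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an annotation with zero genes is valid and empty", {
  cfg <- sim_config(genome_length = 1e5, n_chromosomes = 1, n_genes = 0,
                    n_segments = 0, seed = 1)
  gi <- sim_genome(cfg)
  expect_equal(n_genes(gi$models), 0L)
  f <- tempfile(fileext = ".gff3")
  rtracklayer::export(as_gff(gi$models), f, format = "gff3")
  expect_equal(n_genes(read_annotation(f)), 0L)
})

test_that("a genome too small for its genes fails with a sizing error", {
  expect_error(
    sim_genome(sim_config(genome_length = 5e4, n_chromosomes = 1,
                          n_genes = 50, seed = 1)),
    "too small")
})

test_that("probe tiling follows the grid and respects masks", {
  cfg <- sim_config(genome_length = 1e4, n_chromosomes = 1, n_genes = 0,
                    n_segments = 0, seed = 2)
  gi <- sim_genome(cfg)
  gi$masks <- gi$masks[0, ]                       # no mask
  probes <- sim_probes(gi, cfg)
  expect_equal(nrow(probes), floor(10000 / 233) + 1)  # offsets 0,233,...
  expect_equal(probes$start, 1L + 233L * (seq_len(nrow(probes)) - 1L))

  # fully masked chromosome: zero probes
  gi$masks <- data.frame(chrom = "chr1", start = 1L, end = 10000L)
  expect_equal(nrow(sim_probes(gi, cfg)), 0L)

  # window mask: no probe span intersects it
  gi$masks <- data.frame(chrom = "chr1", start = 2000L, end = 4999L)
  p <- sim_probes(gi, cfg)
  expect_false(any(p$start <= 4999 & p$end >= 2000))

  # the default masks always include one super-gap >= 10x spacing
  gi2 <- sim_genome(sim_config(genome_length = 2e5, n_chromosomes = 1,
                               n_genes = 10, seed = 3))
  expect_true(any(gi2$masks$end - gi2$masks$start + 1 >= 10 * 233))
})

test_that("transcript coverage of the emitted annotation matches itself", {
  # interval-union coverage recomputed from the written GFF3 agrees with
  # the in-memory models
  sim <- small_sim()
  f <- tempfile(fileext = ".gff3")
  rtracklayer::export(as_gff(sim$models), f, format = "gff3")
  back <- read_annotation(f)
  expect_equal(back$transcripts[order(back$transcripts$tx_id),
                                c("tx_id", "start", "end", "strand")],
               sim$models$transcripts[order(sim$models$transcripts$tx_id),
                                      c("tx_id", "start", "end", "strand")],
               ignore_attr = TRUE)
  cover <- function(m) {
    tx <- m$transcripts
    sum(vapply(unique(tx$chrom), function(ch)
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(tx$start[tx$chrom == ch],
                         tx$end[tx$chrom == ch])))), numeric(1)))
  }
  expect_equal(cover(back), cover(sim$models))
})

test_that("noise-free ChIP signal peaks at the planted peak probe", {
  cfg <- sim_config(genome_length = 3e5, n_chromosomes = 1, n_genes = 30,
                    n_segments = 10, noise_sd = 0, pxbar_noise_sd = 0,
                    fp_rate = 0, seed = 13)
  gi <- sim_genome(cfg)
  pt <- plant_ground_truth(gi, cfg)
  probes <- sim_probes(gi, cfg)
  chip <- sim_chip(probes, pt$truth, cfg)
  ctr <- probes$start + 29L
  for (i in seq_len(nrow(pt$truth$segments))) {
    seg <- pt$truth$segments[i, ]
    sel <- which(probes$chrom == seg$chrom & ctr >= seg$start &
                   ctr <= seg$end)
    top <- sel[which.max(chip$hs$fold[sel])]
    expect_true(probes$start[top] <= seg$peak & probes$end[top] >= seg$peak,
                label = sprintf("segment %d argmax probe contains peak", i))
  }
})

test_that("expression recovery is exact in the noise-free limit", {
  cfg <- sim_config(genome_length = 4e5, n_chromosomes = 1, n_genes = 60,
                    n_segments = 12, expr_noise_sd = 0, seed = 9)
  gi <- sim_genome(cfg)
  pt <- plant_ground_truth(gi, cfg)
  ex <- sim_expression(gi$models, pt$truth, cfg)
  calls <- differential_calls(ex$expression)
  for (sys in c("cells", "larvae")) {
    got <- sort(regulated_genes <- unique(
      calls$gene_id[calls$system == sys & calls$status != "unchanged"]))
    expect_equal(got, sort(ex$responsive[[sys]]$gene_id),
                 label = paste("system", sys))
  }
  # the mutant system retains almost nothing
  mut <- unique(calls$gene_id[calls$system == "mutant" &
                                calls$status != "unchanged"])
  expect_lte(length(mut), max(1, round(0.1 * nrow(ex$responsive$larvae))))
})

test_that("a zero DE fraction yields no differential calls", {
  cfg <- sim_config(genome_length = 4e5, n_chromosomes = 1, n_genes = 60,
                    n_segments = 12, expr_noise_sd = 0,
                    de_fraction_per_system = c(cells = 0, larvae = 0),
                    promoter_induced_fraction = 0, seed = 10)
  gi <- sim_genome(cfg)
  pt <- plant_ground_truth(gi, cfg)
  ex <- sim_expression(gi$models, pt$truth, cfg)
  calls <- differential_calls(ex$expression)
  expect_equal(sum(calls$status != "unchanged"), 0L)
})

test_that("the two-system overlap matches the configured fraction", {
  sim <- small_sim()
  a <- sim$truth$responsive$cells$gene_id
  b <- sim$truth$responsive$larvae$gene_id
  obs <- length(intersect(a, b)) / length(union(a, b))
  target <- sim$config$de_overlap_fraction
  n <- length(union(a, b))
  expect_lt(abs(obs - target), 1.96 * sqrt(target * (1 - target) / n) +
              1 / n)
})

test_that("cytological bands partition chromosomes; jitter stays local", {
  sim <- small_sim()
  bands <- sim$cytology$bands
  for (ch in names(sim$chrom_lengths)) {
    b <- bands[bands$chrom == ch, ]
    b <- b[order(b$start), ]
    expect_equal(b$start[1], 1L)
    expect_equal(b$end[nrow(b)], unname(sim$chrom_lengths[[ch]]))
    expect_true(all(b$start[-1] == b$end[-nrow(b)] + 1L))
  }
  # overlap 1, jitter 0: every planted band is a locus
  cfg <- sim_config(genome_length = 2e5, n_chromosomes = 1, n_genes = 20,
                    n_segments = 8, polytene_overlap_rate = 1,
                    polytene_jitter = 0, seed = 5)
  s <- sim_study(cfg)
  seg_bands <- map_to_band(s$truth$segments$chrom, s$truth$segments$peak,
                           s$cytology$bands)
  expect_true(all(seg_bands %in% s$cytology$loci$locus))
  # jitter 1: every locus within one band index of a planted band
  cfg2 <- sim_config(genome_length = 2e5, n_chromosomes = 1, n_genes = 20,
                     n_segments = 8, polytene_overlap_rate = 1,
                     polytene_jitter = 1, seed = 6)
  s2 <- sim_study(cfg2)
  bands2 <- s2$cytology$bands
  seg_idx <- bands2$index[match(
    unique(map_to_band(s2$truth$segments$chrom, s2$truth$segments$peak,
                       bands2)), bands2$band)]
  loci_idx <- bands2$index[match(s2$cytology$loci$locus, bands2$band)]
  expect_true(all(vapply(loci_idx, function(i) min(abs(i - seg_idx)) <= 1,
                         logical(1))))
})

test_that("planted segment invariants hold and files round-trip", {
  sim <- small_sim()
  tr <- sim$truth$segments
  expect_true(all(tr$peak >= tr$start & tr$peak <= tr$end))
  hse <- sim$truth$motifs[sim$truth$motifs$motif_id == "HSE_GAA-TTC-GAA", ]
  expect_true(all(hse$offset >= sim$config$hse_window[1] &
                    hse$offset <= sim$config$hse_window[2]))
  d <- tempfile()
  write_sim(sim, d)
  probes_back <- rtracklayer::import(file.path(d, "probes.bed"))
  expect_equal(length(probes_back), nrow(sim$probes))
  expect_equal(GenomicRanges::start(probes_back), sim$probes$start)
  hs_back <- read_probe_table(file.path(d, "chip_hs.tsv"))
  expect_equal(hs_back$fold, sim$chip$hs$fold, tolerance = 1e-9)
  ex_back <- read_expression_table(file.path(d, "expression.tsv"))
  expect_equal(nrow(ex_back), nrow(sim$expression))
  genome_back <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  expect_equal(as.character(genome_back[["chr1"]]),
               sim$genome[["chr1"]])
  unlink(d, recursive = TRUE)
})
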