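test_that("anchored matrices reproduce constant and impulse tracks", {
  anchors <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2400L,
                            name = "a", score = 1, strand = ".",
                            summit = 200L)
  am <- anchored_matrix(const_track(3, 5000), anchors, flank = 500,
                        bin_size = 10, normalize = "none")
  expect_true(all(am$values == 3))
  expect_equal(ncol(am$values), 100)

  sig <- rep(0, 5000)
  sig[2201] <- 1  # unit impulse at the anchor centre (0-based 2200)
  imp <- anchored_matrix(coverage_track(list(chr1 = sig)), anchors,
                         flank = 500, bin_size = 10, normalize = "none")
  expect_equal(sum(imp$values != 0), 1)
  central <- which(imp$bin_offsets == 0)
  expect_equal(imp$values[1, central], 1 / 10)
  expect_error(anchored_matrix(const_track(1), anchors, flank = 505,
                               bin_size = 10), "multiple")
})

test_that("anchored matrices equal per-base brute-force binning", {
  withr::local_seed(21)
  track <- random_track(6000)
  signal <- as.numeric(track$cov$chr1)
  anchors <- random_peaks(50, chrom_len = 6000, width_range = c(100, 300))
  am <- anchored_matrix(track, anchors, flank = 400, bin_size = 20,
                        normalize = "none")
  for (i in seq_len(nrow(anchors))) {
    cen <- anchors$start[i] + anchors$summit[i]
    want <- vapply(am$bin_offsets, function(o) {
      bf_window_sum(signal, cen + o, cen + o + 20) / 20
    }, 0)
    expect_equal(am$values[i, ], want, tolerance = 1e-9)
  }
})

test_that("bins beyond the chromosome end read as zero", {
  anchors <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                            name = "edge", score = 1, strand = ".",
                            summit = 50L)
  am <- anchored_matrix(const_track(2, 300), anchors, flank = 200,
                        bin_size = 10, normalize = "none")
  expect_true(all(am$values[1, am$bin_offsets < -60] == 0))
  expect_true(all(am$values[1, am$bin_offsets >= -50 &
                              am$bin_offsets < 240] == 2))
})

test_that("average profiles obey subsetting identities and symmetry", {
  withr::local_seed(3)
  track <- random_track(8000)
  anchors <- random_peaks(30, chrom_len = 8000)
  am <- anchored_matrix(track, anchors, flank = 200, bin_size = 10,
                        normalize = "none")
  one <- average_profile(am, rows = 5)
  expect_equal(one$value, am$values[5, ])
  expect_error(average_profile(am, rows = character(0)), "nonempty")

  # group profiles recombine to the whole-matrix profile
  g1 <- seq_len(10); g2 <- 11:30
  whole <- average_profile(am)$value
  recomb <- (10 * average_profile(am, g1)$value +
               20 * average_profile(am, g2)$value) / 30
  expect_equal(recomb, whole, tolerance = 1e-12)

  # symmetric coverage about every anchor gives a symmetric profile
  sym_sig <- rep(0, 4000)
  for (cen in c(1000, 3000)) {
    for (d in 0:99) {
      sym_sig[cen + 1 + d] <- 100 - d
      sym_sig[cen + 1 - d - 1] <- 100 - d
    }
  }
  sym_anchors <- tibble::tibble(chrom = "chr1", start = c(800L, 2800L),
                                end = c(1200L, 3200L),
                                name = c("s1", "s2"), score = 1,
                                strand = ".", summit = 200L)
  sam <- anchored_matrix(coverage_track(list(chr1 = sym_sig)), sym_anchors,
                         flank = 150, bin_size = 10, normalize = "none")
  prof <- average_profile(sam)$value
  expect_equal(prof, rev(prof), tolerance = 1e-9)
})

test_that("row order is identical across tracks built on the same anchors", {
  withr::local_seed(5)
  anchors <- random_peaks(40, chrom_len = 5000)
  m1 <- anchored_matrix(random_track(5000), anchors, flank = 100,
                        bin_size = 10)
  m2 <- anchored_matrix(random_track(5000), anchors, flank = 100,
                        bin_size = 10)
  expect_identical(m1$row_order, m2$row_order)
  expect_identical(m1$row_order, anchors$name)
})

test_that("metagene profiles are flat on uniform tracks and zero off-body", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(3000L, 12000L), end = c(5000L, 16000L),
                          strand = c("+", "-"),
                          tss = c(3000L, 15999L))
  mg <- metagene(const_track(4, 20000), genes, body_bins = 50,
                 flank = 1000, flank_bins = 10, normalize = "none")
  expect_true(all(abs(mg$profile$value - 4) < 1e-12))

  sig <- rep(0, 20000)
  sig[(3000 + 1):5000] <- 2
  sig[(12000 + 1):16000] <- 2
  mg2 <- metagene(coverage_track(list(chr1 = sig)), genes, body_bins = 50,
                  flank = 1000, flank_bins = 10, normalize = "none")
  expect_true(all(mg2$profile$value[mg2$profile$zone != "body"] == 0))
  expect_true(all(mg2$profile$value[mg2$profile$zone == "body"] == 2))
})

test_that("gene bodies of different lengths align after rescaling", {
  # both genes carry signal 1 over the first half of the body and 3 over
  # the second half (strand-aware), so their scaled profiles coincide
  sig <- rep(0, 10000)
  sig[(1000 + 1):(1000 + 100)] <- 1   # + strand gene, length 200
  sig[(1100 + 1):(1200)] <- 3
  sig[(5000 + 1):(5200)] <- 3         # - strand gene, length 400
  sig[(5200 + 1):(5400)] <- 1
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          start = c(1000L, 5000L), end = c(1200L, 5400L),
                          strand = c("+", "-"), tss = c(1000L, 5399L))
  mg <- metagene(coverage_track(list(chr1 = sig)), genes, body_bins = 100,
                 flank = 200, flank_bins = 4, normalize = "none")
  body <- mg$profile[mg$profile$zone == "body", ]
  expect_equal(body$value, rep(c(1, 3), each = 50))
  expect_equal(mg$gene_values[1, ], mg$gene_values[2, ], tolerance = 1e-12)
})

test_that("genes shorter than the body bin count are skipped with a warning", {
  genes <- tibble::tibble(gene_id = c("ok", "tiny"), chrom = "chr1",
                          start = c(1000L, 4000L), end = c(2000L, 4050L),
                          strand = "+", tss = c(1000L, 4000L))
  expect_warning(
    mg <- metagene(const_track(1, 6000), genes, body_bins = 100,
                   flank = 100, flank_bins = 2, normalize = "none"),
    "skipping 1")
  expect_equal(unique(mg$profile$n_genes), 1L)
})

test_that("genomic location splits promoter, intragenic and intergenic", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 10000L,
                          end = 20000L, strand = "+", tss = 10000L)
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(10300L, 15000L, 120000L) - 100L,
    end = c(10300L, 15000L, 120000L) + 100L,
    summit = 100L)
  loc <- genomic_location(peaks, genes)
  expect_equal(loc$location, c("promoter", "intragenic", "intergenic"))
  expect_equal(loc$proximal, c(TRUE, FALSE, FALSE))
  expect_equal(attr(loc, "fractions")[["distal"]], 2 / 3)
})

test_that("genomic location matches the all-pairs oracle on random peaks", {
  withr::local_seed(17)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
    start = sort(sample.int(9e5, 30)), strand = "+")
  genes$end <- genes$start + sample(2000:20000, 30, TRUE)
  genes$tss <- genes$start
  peaks <- random_peaks(1000, chrom_len = 1e6)
  loc <- genomic_location(peaks, genes)
  expect_equal(loc$location, bf_location(peaks, genes))
})

test_that("the co-factor profile rises at relocated-to sites upon induction", {
  cfg <- tiny_config(seed = 19)
  scn <- simulate_scenario(cfg)
  st <- scn$truth$site_table
  anchors <- scn$peaks$induced$Dox
  before <- anchored_matrix(scn$tracks$cofactor$noDox, anchors, flank = 500,
                            bin_size = 10)
  after <- anchored_matrix(scn$tracks$cofactor$Dox, anchors, flank = 500,
                           bin_size = 10)
  rows <- which(anchors$name %in% st$site_id[st$relocated_to])
  central <- which(before$bin_offsets == 0)
  expect_gt(average_profile(after, rows)$value[central],
            average_profile(before, rows)$value[central])
})
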