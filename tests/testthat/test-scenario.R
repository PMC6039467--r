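test_that("a fixed seed reproduces every artifact byte-identically", {
  cfg <- tiny_config(seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(simulate_scenario(cfg), d1)
  write_scenario(simulate_scenario(cfg), d2)
  for (rel in c("genome.fa", "genes.tsv", "counts.tsv",
                file.path("peaks", "pioneer_Dox.bed"),
                file.path("tracks", "induced_Dox.bedGraph"))) {
    expect_identical(unname(tools::md5sum(file.path(d1, rel))),
                     unname(tools::md5sum(file.path(d2, rel))),
                     label = rel)
  }
})

test_that("a pure ETS_GATA catalogue plants ETS and GATA at every site and no RUNX", {
  cfg <- tiny_config(
    site_class_fractions = c(ETS_GATA = 1, ETS_RUNX = 0, RUNX_only = 0,
                             TEAD = 0, promoter = 0),
    relocation_fraction = 0,  # no composite sites to relocate to
    seed = 3)
  bg <- build_genome(cfg)
  mt <- bg$truth$motif_table
  per_site <- split(mt$motif, mt$site_id)
  expect_length(per_site, nrow(bg$truth$site_table))
  expect_true(all(vapply(per_site, function(m)
    setequal(m, c("ETS", "GATA")), logical(1))))
  expect_false(any(mt$motif %in% c("RUNX", "ETS_RUNX")))
})

test_that("exactly round(fraction x occupied ETS_GATA sites) are flagged relocating", {
  for (rf in c(0.25, 0.6)) {
    cfg <- tiny_config(relocation_fraction = rf, seed = 5)
    truth <- build_genome(cfg)$truth
    n_eg <- sum(truth$site_table$class == "ETS_GATA")
    expect_equal(sum(truth$site_table$relocating), round(rf * n_eg))
    expect_equal(truth$true_relocation_fraction, round(rf * n_eg) / n_eg)
    # relocation is one-to-one: as many destination as origin sites
    expect_equal(sum(truth$site_table$relocated_to),
                 sum(truth$site_table$relocating))
  }
})

test_that("the induced factor has no peaks before induction", {
  scn <- simulate_scenario(tiny_config(seed = 2))
  expect_equal(nrow(scn$peaks$induced$noDox), 0)
  expect_equal(nrow(scn$peaks$induced$noDox_JQ1), 0)
  expect_gt(nrow(scn$peaks$induced$Dox), 0)
})

test_that("every occupied site appears in the corresponding peak set", {
  scn <- simulate_scenario(tiny_config(seed = 2))
  occ <- scn$truth$occupancy
  for (fac in c("pioneer", "induced", "cofactor")) {
    for (cond in scn$config$conditions) {
      want <- sort(occ$site_id[occ$factor == fac & occ$condition == cond &
                                 occ$occupancy > 0])
      expect_identical(sort(scn$peaks[[fac]][[cond]]$name), want,
                       label = paste(fac, cond))
    }
  }
})

test_that("without background all coverage stays within occupied sites +/- fragment length", {
  cfg <- tiny_config(background_rate = 0, seed = 4)
  scn <- simulate_scenario(cfg)
  track <- scn$tracks$pioneer$noDox
  occupied <- scn$peaks$pioneer$noDox
  fl <- cfg$fragment_length
  for (chr in names(track$cov)) {
    x <- track$cov[[chr]]
    ends <- cumsum(S4Vectors::runLength(x))
    starts <- ends - S4Vectors::runLength(x)
    nz <- S4Vectors::runValue(x) > 0
    if (!any(nz)) next
    p <- occupied[occupied$chrom == chr, ]
    ok <- vapply(which(nz), function(i) {
      any(p$start - fl <= starts[i] & ends[i] <= p$end + fl)
    }, logical(1))
    expect_true(all(ok), label = chr)
  }
})

test_that("total fragment counts match the Poisson expectation over 20 seeds", {
  # library size = sum over occupied sites of depth x occupancy, plus the
  # uniform background; each term is Poisson so the total is Poisson
  totals <- expected <- numeric(20)
  for (s in 1:20) {
    cfg <- tiny_config(seed = 100 + s)
    truth <- build_genome(cfg)$truth
    tk <- simulate_tracks(truth, cfg)
    occ <- truth$occupancy
    lam_sites <- cfg$depth_per_site *
      sum(occ$occupancy[occ$factor == "pioneer" & occ$condition == "Dox"])
    lam_bg <- cfg$background_rate * sum(truth$chrom_lengths) / 1000
    expected[s] <- lam_sites + lam_bg
    totals[s] <- tk$tracks$pioneer$Dox$library_size
  }
  z <- (totals - expected) / sqrt(expected)
  expect_true(all(abs(z) < 4))
})

test_that("coded fold structure is realised in the condition means", {
  # noise-free limit: dispersion 0 and a large baseline depth
  cfg <- tiny_config(seed = 6,
                     expression = list(dispersion = 0,
                                       baseline_meanlog = log(5e4),
                                       baseline_sdlog = 0.2))
  truth <- build_genome(cfg)$truth
  ex <- simulate_expression(truth, cfg)
  m <- ex$condition_fpkm
  up <- truth$gene_table$gene_id[substr(truth$gene_table$code, 1, 1) == "1"]
  i <- match(up, m$gene_id)
  expect_true(all(m$Dox[i] / m$noDox[i] >= 2))
  ten <- truth$gene_table$gene_id[truth$gene_table$code == "10"]
  j <- match(ten, m$gene_id)
  expect_true(all(m$Dox[j] / m$Dox_JQ1[j] >= 2))
})

test_that("in the noise-free limit classify-then-recover returns every code exactly", {
  cfg <- tiny_config(seed = 6,
                     expression = list(dispersion = 0,
                                       baseline_meanlog = log(5e4),
                                       baseline_sdlog = 0.2))
  truth <- build_genome(cfg)$truth
  ex <- simulate_expression(truth, cfg)
  codes <- code_genes(ex$condition_fpkm)
  expect_identical(
    codes$code[match(truth$gene_table$gene_id, codes$gene_id)],
    truth$gene_table$code)
  # the generator's differential list is exactly the non-"22" genes
  expect_setequal(ex$differential,
                  truth$gene_table$gene_id[truth$gene_table$code != "22"])
})

test_that("planted motif offsets are recovered perfectly at consensus threshold", {
  bg <- build_genome(tiny_config(seed = 9))
  motifs <- bundled_motifs()
  mt <- dplyr::left_join(bg$truth$motif_table,
                         bg$truth$site_table[c("site_id", "chrom", "start")],
                         by = "site_id")
  found <- vapply(seq_len(nrow(mt)), function(i) {
    site_seq <- Biostrings::subseq(bg$genome[[mt$chrom[i]]],
                                   mt$start[i] + 1L, mt$start[i] + 400L)
    hits <- scan_pwm(site_seq, motifs[[mt$motif[i]]],
                     threshold_fraction = 1)
    mt$offset[i] %in% hits$position[hits$strand == "+"]
  }, logical(1))
  expect_true(all(found))
})

test_that("infeasible configurations fail with sizing errors", {
  expect_error(scenario_config(genome_length = 1e5, n_sites = 2000),
               "infeasible")
  expect_error(
    build_genome(scenario_config(genome_length = 4.1e6, n_genes = 340,
                                 n_sites = 1000, seed = 1)),
    "infeasible")
})
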