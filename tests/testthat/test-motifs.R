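test_that("log-odds scores follow the definition", {
  uni <- pwm("uni", matrix(25, 4, 6), pseudocount = 0)
  expect_true(all(log_odds(uni) == 0))

  p <- pwm("det", matrix(c(4, 0, 0, 0), 4), pseudocount = 0.25)
  # (4 + .25) / (4 + 1) = 0.85 for the consensus base
  expect_equal(unname(log_odds(p)["A", 1]), log2(0.85 / 0.25),
               tolerance = 1e-12)
  expect_equal(log2(0.85 / 0.25), 1.765535, tolerance = 1e-6)

  m <- pwm("m", matrix(sample(0:50, 4 * 8, TRUE), 4, 8))
  lo <- log_odds(m)
  expect_equal(max(rowSums(matrix(apply(lo, 2, max), 1))),
               sum(apply(lo, 2, max)))

  zerop <- pwm("z", matrix(c(1, 0, 0, 0), 4), pseudocount = 0)
  expect_error(log_odds(zerop), "zero")
})

test_that("scanning finds the consensus on both strands at the right offsets", {
  motifs <- bundled_motifs()
  runx <- motifs$RUNX
  cons <- pwm_consensus(runx)
  seqn <- paste0("ATATATATAT", cons, "ATATATATAT")
  hits <- scan_pwm(seqn, runx, threshold_fraction = 1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 10L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, sum(apply(log_odds(runx), 2, max)),
               tolerance = 1e-9)

  rc <- paste0("ATATATATAT", revcomp_chr(cons), "ATATATATAT")
  rhits <- scan_pwm(rc, runx, threshold_fraction = 1)
  expect_equal(nrow(rhits), 1)
  expect_equal(rhits$position, 10L)
  expect_equal(rhits$strand, "-")

  expect_error(scan_pwm("ACG", runx), "shorter")
})

test_that("the scanner agrees with exhaustive scoring of every 6-mer", {
  withr::local_seed(33)
  p <- pwm("six", matrix(sample(0:20, 24, TRUE), 4, 6))
  lodds <- log_odds(p)
  rng <- sum(apply(lodds, 2, max)) - sum(apply(lodds, 2, min))
  thr <- sum(apply(lodds, 2, min)) + 0.8 * rng
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(expand.grid, rep(list(bases), 6))
  for (i in seq_len(nrow(kmers))) {
    b <- as.character(unlist(kmers[i, ]))
    fwd <- bf_score(b, lodds)
    rev <- bf_score(strsplit(revcomp_chr(paste(b, collapse = "")),
                             "")[[1]], lodds)
    hits <- scan_pwm(paste(b, collapse = ""), p, collapse = FALSE)
    expect_equal("+" %in% hits$strand, fwd >= thr - 1e-9)
    expect_equal("-" %in% hits$strand, rev >= thr - 1e-9)
    if (nrow(hits)) expect_true(all(hits$position == 0))
  }
})

test_that("scanning the reverse-complemented sequence mirrors the hit set", {
  withr::local_seed(9)
  seqn <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  p <- bundled_motifs()$GATA
  L <- ncol(p$prob)
  fwd <- scan_pwm(seqn, p, threshold_fraction = 0.75, collapse = FALSE)
  rev <- scan_pwm(revcomp_chr(seqn), p, threshold_fraction = 0.75,
                  collapse = FALSE)
  mirrored <- tibble::tibble(
    position = nchar(seqn) - L - rev$position,
    strand = ifelse(rev$strand == "+", "-", "+"),
    score = rev$score)
  mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
  expect_equal(fwd$position, mirrored$position)
  expect_equal(fwd$strand, mirrored$strand)
  expect_equal(fwd$score, mirrored$score, tolerance = 1e-9)
})

test_that("nearby same-strand hits collapse to the best-scoring one", {
  # a homopolymer motif makes every window of a run a hit; runs collapse
  # to a single best (leftmost on ties) hit per PWM length
  pa <- pwm("AA", matrix(c(20, 0, 0, 0, 20, 0, 0, 0), nrow = 4))
  seqn <- "GGAAAAAGG"
  all_hits <- scan_pwm(seqn, pa, threshold_fraction = 0.95,
                       collapse = FALSE)
  all_fwd <- all_hits[all_hits$strand == "+", ]
  expect_equal(all_fwd$position, 2:5)
  collapsed <- scan_pwm(seqn, pa, threshold_fraction = 0.95)
  fwd <- collapsed[collapsed$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$position, 2L)
  expect_equal(max(all_fwd$score), max(fwd$score))
})

test_that("motif density profiles localise planted instances", {
  withr::local_seed(44)
  p <- bundled_motifs()$TEAD
  cons <- pwm_consensus(p)
  n <- 40
  # A/C background: the TEAD consensus (and its reverse complement)
  # needs G/T bases, so the only exact-threshold hits are the plants
  base <- paste(sample(c("A", "C"), 40 * 2000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = base))
  centers <- (seq_len(n) - 1L) * 2000L + 1000L
  offsets <- sample(-80:60, n, replace = TRUE)
  for (i in seq_len(n)) {
    Biostrings::subseq(genome[[1]], centers[i] + offsets[i] + 1L,
                       centers[i] + offsets[i] + nchar(cons)) <-
      Biostrings::DNAString(cons)
  }
  anchors <- tibble::tibble(chrom = "chr1", start = centers - 200L,
                            end = centers + 200L,
                            name = sprintf("a%02d", 1:n), score = 1,
                            strand = ".", summit = 200L)
  dens <- density_profile(anchors, genome, p, flank = 200, bin_size = 10,
                          row_window = 1, threshold_fraction = 1)
  # per-row hit histogram equals the planted offsets exactly
  for (i in seq_len(n)) {
    want <- rep(0L, ncol(dens$counts))
    want[(offsets[i] + 200) %/% 10 + 1] <- 1L
    expect_equal(dens$counts[i, ], want)
  }
  # integrating density x bin width over bins = mean hits per peak
  full <- density_profile(anchors, genome, p, flank = 200, bin_size = 10,
                          row_window = n, threshold_fraction = 1)
  expect_equal(sum(full$values[1, ] * 10), 1)
})

test_that("an anchor-centred plant puts the density peak at the central bin", {
  p <- bundled_motifs()$AP1
  cons <- pwm_consensus(p)
  n <- 30
  base <- paste(rep("C", 30 * 1000), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = base))
  centers <- (seq_len(n) - 1L) * 1000L + 500L
  for (i in seq_len(n)) {
    Biostrings::subseq(genome[[1]], centers[i] + 1L,
                       centers[i] + nchar(cons)) <- Biostrings::DNAString(cons)
  }
  anchors <- tibble::tibble(chrom = "chr1", start = centers - 100L,
                            end = centers + 100L,
                            name = sprintf("a%02d", 1:n), score = 1,
                            strand = ".", summit = 100L)
  dens <- density_profile(anchors, genome, p, flank = 100, bin_size = 10,
                          row_window = n)
  peak_bin <- which.max(colSums(dens$values))
  central <- which(dens$bin_offsets == 0)
  expect_lte(abs(peak_bin - central), 1)
})

test_that("two-sided hypergeometric p-values are exact", {
  # spot value: k = 5 of 5 draws; the equally improbable k = 0 outcome
  # joins the two-sided sum, so p = 2 / choose(10, 5)
  expect_equal(enrichment_test(5, 5, 5, 10), 2 / choose(10, 5),
               tolerance = 1e-12)
  # against full subset enumeration for small universes
  withr::local_seed(2)
  for (rep in 1:10) {
    N <- sample(6:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    hits <- c(rep(TRUE, K), rep(FALSE, N - K))
    subsets <- utils::combn(N, n)
    ks <- colSums(matrix(hits[subsets], nrow = n))
    k_obs <- ks[1]
    freq <- table(ks) / ncol(subsets)
    p_enum <- sum(freq[freq <= freq[[as.character(k_obs)]] * (1 + 1e-9)])
    expect_equal(enrichment_test(k_obs, n, K, N), p_enum,
                 tolerance = 1e-9)
  }
})

test_that("group enrichment quantifies fractions, folds and p-values", {
  withr::local_seed(12)
  p <- bundled_motifs()$GATA
  cons <- pwm_consensus(p)
  mk_peak_seq <- function(with_motif) {
    s <- sample(c("A", "C"), 60, TRUE)  # AC alphabet cannot hit GATA
    if (with_motif) s[20:28] <- strsplit(cons, "")[[1]]
    paste(s, collapse = "")
  }
  seqs <- c(vapply(1:20, function(i) mk_peak_seq(TRUE), ""),
            vapply(1:40, function(i) mk_peak_seq(i <= 8), ""))
  genome <- Biostrings::DNAStringSet(
    c(chr1 = paste(seqs, collapse = paste(rep("A", 20), collapse = ""))))
  starts <- (seq_len(60) - 1L) * 80L
  peaks <- tibble::tibble(chrom = "chr1", start = starts,
                          end = starts + 60L,
                          name = sprintf("p%02d", 1:60), score = 1,
                          strand = ".", summit = 30L)
  res <- group_enrichment(peaks[1:20, ], peaks[21:60, ], genome, p)
  expect_equal(res$fraction_with_hit, 1)
  expect_equal(res$background_fraction, 0.2)
  expect_equal(res$fold_vs_background, 5)
  expect_equal(res$p_value, enrichment_test(20, 20, 28, 60))
  expect_error(group_enrichment(peaks[1:20, ], peaks[10:60, ], genome, p),
               "disjoint")
})

test_that("resampled-group enrichment p-values are null-calibrated", {
  # universe large enough that the discrete p-value lattice is finer
  # than the KS band
  withr::local_seed(99)
  total <- 16000
  hits_total <- 4800
  group_size <- 1600
  hit <- c(rep(TRUE, hits_total), rep(FALSE, total - hits_total))
  pvals <- replicate(1000, {
    k <- sum(hit[sample.int(total, group_size)])
    enrichment_test(k, group_size, hits_total, total)
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value,
            0.01)
})
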