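#' Log-odds score matrix for a PWM
#'
#' @param x a [pwm()].
#' @return a 4 x L matrix of `log2(p / background)` scores in bits.
#' @export
log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  if (any(x$prob == 0)) {
    abort("PWM contains zero probabilities; rebuild with a pseudocount")
  }
  log2(x$prob / x$background)
}

# base encoding: A=1 C=2 G=3 T=4, anything else 0 (scores -Inf-like)
dna_code <- local({
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  function(seq) {
    if (methods::is(seq, "XString")) seq <- as.character(seq)
    lut[utf8ToInt(seq)]
  }
})

# score every window of `code` against a 4 x L log-odds matrix;
# windows containing non-ACGT bases score below any threshold
score_windows <- function(code, lodds) {
  L <- ncol(lodds)
  n <- length(code) - L + 1L
  if (n < 1) abort("sequence shorter than PWM")
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- unname(c(-1e9, lodds[, j]))
    sc <- sc + v[code[j:(j + n - 1L)] + 1L]
  }
  sc
}

# reverse-complement of a log-odds matrix: complement bases (reverse row
# order A<->T, C<->G) and reverse positions
revcomp_lodds <- function(lodds) lodds[4:1, rev(seq_len(ncol(lodds))), drop = FALSE]

# collapse hits on one strand: hits closer than one PWM length chain into
# clusters, and only the best-scoring hit per cluster is kept (leftmost on
# score ties)
collapse_strand <- function(hits, width) {
  if (nrow(hits) < 2) return(hits)
  hits <- hits[order(hits$position), , drop = FALSE]
  cl <- cumsum(c(1L, diff(hits$position) >= width))
  keep <- unlist(lapply(split(seq_len(nrow(hits)), cl), function(i) {
    i[which.max(hits$score[i])]
  }), use.names = FALSE)
  hits[sort(keep), , drop = FALSE]
}

#' Scan a sequence with a PWM on both strands
#'
#' Windows scoring at least `threshold_fraction` of the way from the
#' minimum to the maximum attainable log-odds score are reported.
#' Reverse-strand hits are reported at their forward-strand start
#' coordinate. Overlapping hits on the same strand within one PWM length
#' are collapsed to the best-scoring one (disable with
#' `collapse = FALSE`).
#'
#' @param sequence a character scalar or [Biostrings::DNAString].
#' @param x a [pwm()].
#' @param threshold_fraction position of the score threshold within the
#'   attainable score range, in (0, 1].
#' @param collapse collapse nearby same-strand hits (default TRUE).
#' @return tibble with columns `pwm`, `position` (0-based start on the
#'   forward strand), `strand`, `score` (bits).
#' @export
scan_pwm <- function(sequence, x, threshold_fraction = 0.8, collapse = TRUE) {
  stopifnot(inherits(x, "pwm"))
  if (threshold_fraction <= 0 || threshold_fraction > 1) {
    abort("`threshold_fraction` must be in (0, 1]")
  }
  lodds <- log_odds(x)
  code <- dna_code(sequence)
  scan_code(code, lodds, threshold_fraction, collapse, x$name)
}

# core scanner over an encoded sequence (shared with density_profile)
scan_code <- function(code, lodds, threshold_fraction, collapse, name) {
  smax <- sum(apply(lodds, 2, max))
  smin <- sum(apply(lodds, 2, min))
  thr <- smin + threshold_fraction * (smax - smin)
  L <- ncol(lodds)
  fwd <- score_windows(code, lodds)
  rev <- score_windows(code, revcomp_lodds(lodds))
  one <- function(sc, strand) {
    i <- which(sc >= thr - 1e-9)
    tibble(position = i - 1L, strand = strand, score = sc[i])
  }
  hits <- bind_rows(one(fwd, "+"), one(rev, "-"))
  if (collapse && nrow(hits) > 1) {
    hits <- bind_rows(lapply(split(hits, hits$strand), collapse_strand,
                             width = L))
  }
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  tibble(pwm = rep(name, nrow(hits)), position = hits$position,
         strand = hits$strand, score = hits$score)
}

#' Motif density along ranked anchors
#'
#' Computes, on the same row order and positional bins as the signal
#' heatmaps, the density of motif-hit starts (hits per bp per peak) in a
#' rolling window of ranked rows, so motif occurrence can be read along
#' the fold-difference ranking.
#'
#' @param anchors tibble of peaks carrying the shared ranked row order
#'   (rows are used in the order given; a `name` column labels them).
#' @param genome a [Biostrings::DNAStringSet].
#' @param x a [pwm()].
#' @param flank half-width of the window around each anchor centre (bp).
#' @param bin_size bin width in bp; must divide `flank`.
#' @param row_window number of ranked rows in the rolling average.
#' @param threshold_fraction,collapse passed to the scanner.
#' @return an object of class `motif_density` with elements `values`
#'   (rows x bins density matrix), `counts` (raw per-row hit counts),
#'   `row_order`, `bin_offsets` (bin start offsets from the anchor
#'   centre), `bin_size`, `flank`, `pwm`, `row_window`.
#' @export
density_profile <- function(anchors, genome, x, flank = 3000, bin_size = 10,
                            row_window = 100, threshold_fraction = 0.8,
                            collapse = TRUE) {
  anchors <- assert_peaks(anchors, "anchors")
  stopifnot(inherits(x, "pwm"))
  if (flank %% bin_size != 0) abort("`flank` must be a multiple of `bin_size`")
  lodds <- log_odds(x)
  L <- ncol(lodds)
  nb <- as.integer(2 * flank / bin_size)
  centers <- peak_center(anchors)
  counts <- matrix(0L, nrow = nrow(anchors), ncol = nb)
  seq_lens <- setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(nrow(anchors))) {
    chr <- anchors$chrom[i]
    if (!chr %in% names(seq_lens)) {
      abort(sprintf("chromosome '%s' absent from genome", chr))
    }
    ws <- max(0L, centers[i] - flank)
    we <- min(seq_lens[[chr]], centers[i] + flank + L - 1L)
    if (we - ws < L) next
    code <- dna_code(Biostrings::subseq(genome[[chr]], ws + 1L, we))
    hits <- scan_code(code, lodds, threshold_fraction, collapse, x$name)
    if (nrow(hits) == 0) next
    off <- ws + hits$position - centers[i]
    off <- off[off >= -flank & off < flank]
    if (length(off)) {
      tab <- tabulate((off + flank) %/% bin_size + 1L, nbins = nb)
      counts[i, ] <- counts[i, ] + tab
    }
  }
  values <- rolling_row_mean(counts, row_window) / bin_size
  structure(list(values = values, counts = counts,
                 row_order = anchors$name,
                 bin_offsets = -flank + (seq_len(nb) - 1L) * bin_size,
                 bin_size = bin_size, flank = flank, pwm = x$name,
                 row_window = row_window),
            class = "motif_density")
}

#' @export
print.motif_density <- function(x, ...) {
  cat(sprintf("<motif_density> %s: %d rows x %d bins (bin %d bp, flank %d bp)\n",
              x$pwm, nrow(x$values), ncol(x$values), x$bin_size, x$flank))
  invisible(x)
}

#' Two-sided hypergeometric enrichment test
#'
#' Tests whether `k` hit-carrying peaks among a group of `group_size`
#' peaks is surprising given `hits_total` hit-carrying peaks among
#' `total` peaks, two-sided by the minimum-likelihood rule (every
#' outcome at most as probable as the observed one contributes).
#'
#' @param k hit-carrying peaks in the group.
#' @param group_size peaks in the group.
#' @param hits_total hit-carrying peaks overall.
#' @param total peaks overall (group plus background).
#' @return two-sided p-value.
#' @export
enrichment_test <- function(k, group_size, hits_total, total) {
  stopifnot(k >= 0, k <= group_size, group_size <= total, hits_total <= total)
  supp <- max(0, group_size - (total - hits_total)):min(group_size, hits_total)
  d <- dhyper(supp, hits_total, total - hits_total, group_size)
  d0 <- dhyper(k, hits_total, total - hits_total, group_size)
  min(1, sum(d[d <= d0 * (1 + 1e-7)]))
}

#' Motif enrichment of a peak group against background peaks
#'
#' Scans each peak's own sequence for the motif and compares the fraction
#' of hit-carrying peaks between a group and a disjoint background set.
#'
#' @param group_peaks,background_peaks disjoint tibbles of peaks.
#' @param genome a [Biostrings::DNAStringSet].
#' @param x a [pwm()] or named list of them.
#' @param threshold_fraction,collapse passed to [scan_pwm()].
#' @return a tibble with one row per motif: fraction of group peaks with
#'   a hit, the background fraction, the fold ratio and the two-sided
#'   hypergeometric p-value.
#' @export
group_enrichment <- function(group_peaks, background_peaks, genome, x,
                             threshold_fraction = 0.8, collapse = TRUE) {
  group_peaks <- assert_peaks(group_peaks, "group_peaks")
  background_peaks <- assert_peaks(background_peaks, "background_peaks")
  if (nrow(group_peaks) == 0 || nrow(background_peaks) == 0) {
    abort("group and background peak sets must be nonempty")
  }
  if (peaks_overlap_any(group_peaks, background_peaks)) {
    abort("group and background peak sets must be disjoint")
  }
  pwms <- if (inherits(x, "pwm")) setNames(list(x), x$name) else x
  both <- bind_rows(group_peaks, background_peaks)
  seqs <- peak_sequences(both, genome)
  codes <- lapply(seqs, dna_code)
  ng <- nrow(group_peaks)
  purrr::map_dfr(pwms, function(p) {
    lodds <- log_odds(p)
    hit <- vapply(codes, function(code) {
      if (length(code) < ncol(lodds)) return(FALSE)
      nrow(scan_code(code, lodds, threshold_fraction, collapse, p$name)) > 0
    }, logical(1))
    k <- sum(hit[seq_len(ng)])
    K <- sum(hit)
    frac <- k / ng
    bg_frac <- (K - k) / (length(hit) - ng)
    tibble(pwm = p$name, n_group = ng, n_with_hit = k,
           fraction_with_hit = frac, background_fraction = bg_frac,
           fold_vs_background = ifelse(bg_frac > 0, frac / bg_frac, Inf),
           p_value = enrichment_test(k, ng, K, length(hit)))
  })
}

peak_sequences <- function(peaks, genome) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  lapply(seq_len(nrow(peaks)), function(i) {
    chr <- peaks$chrom[i]
    if (!chr %in% names(lens)) {
      abort(sprintf("chromosome '%s' absent from genome", chr))
    }
    s <- max(0L, peaks$start[i])
    e <- min(lens[[chr]], peaks$end[i])
    as.character(Biostrings::subseq(genome[[chr]], s + 1L, e))
  })
}

# logical vector: which rows of `a` overlap any interval of `b`
overlaps_set <- function(a, b) {
  out <- logical(nrow(a))
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == chr)
    bi <- b[b$chrom == chr, , drop = FALSE]
    out[ai] <- IRanges::countOverlaps(
      IRanges::IRanges(a$start[ai] + 1L, a$end[ai]),
      IRanges::IRanges(bi$start + 1L, bi$end)) > 0
  }
  out
}

peaks_overlap_any <- function(a, b) {
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == chr, ]
    bi <- b[b$chrom == chr, ]
    ov <- IRanges::countOverlaps(
      IRanges::IRanges(ai$start + 1L, ai$end),
      IRanges::IRanges(bi$start + 1L, bi$end))
    if (any(ov > 0)) return(TRUE)
  }
  FALSE
}
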