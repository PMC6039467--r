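#' Union of two peak sets
#'
#' Overlapping or bookended intervals across the two sets are merged into
#' one union peak. The merged summit is taken from the highest-scoring
#' contributor that has one; otherwise the union midpoint is used. The
#' merged score is the contributor maximum.
#'
#' @param peaks_a,peaks_b tibbles of peaks.
#' @return a sorted tibble of union peaks named `union_1` ... `union_N`.
#' @export
union_peaks <- function(peaks_a, peaks_b) {
  peaks_a <- assert_peaks(peaks_a, "peaks_a")
  peaks_b <- assert_peaks(peaks_b, "peaks_b")
  all <- bind_rows(peaks_a, peaks_b)
  if (nrow(all) == 0) return(all)
  out <- purrr::map_dfr(sort(unique(all$chrom)), function(chr) {
    p <- all[all$chrom == chr, , drop = FALSE]
    ir <- IRanges::IRanges(p$start + 1L, p$end)
    red <- IRanges::reduce(ir)  # merges bookended neighbours too
    hit <- IRanges::findOverlaps(ir, red)
    member <- S4Vectors::subjectHits(hit)
    summit <- score <- numeric(length(red))
    for (g in seq_along(red)) {
      rows <- which(member == g)
      score[g] <- max(p$score[rows])
      with_summit <- rows[!is.na(p$summit[rows])]
      if (length(with_summit)) {
        best <- with_summit[which.max(p$score[with_summit])]
        # summit re-expressed relative to the merged start
        summit[g] <- p$start[best] + p$summit[best] -
          (IRanges::start(red)[g] - 1L)
      } else {
        summit[g] <- IRanges::width(red)[g] %/% 2L
      }
    }
    tibble(chrom = chr, start = IRanges::start(red) - 1L,
           end = IRanges::end(red), name = NA_character_, score = score,
           strand = ".", summit = as.integer(summit))
  })
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  out$name <- sprintf("union_%d", seq_len(nrow(out)))
  out
}

#' Summit-centred signal counts per peak
#'
#' Sums track signal in a window of `summit +/- halfwidth` around each
#' peak (summit when present, interval midpoint otherwise), clipped at
#' chromosome ends.
#'
#' @param track a [coverage_track()].
#' @param peaks tibble of peaks.
#' @param halfwidth counting half-window in bp (default 200).
#' @return numeric vector of raw counts, one per peak.
#' @export
quantify_signal <- function(track, peaks, halfwidth = 200) {
  peaks <- assert_peaks(peaks)
  if (halfwidth < 0) abort("`halfwidth` must be >= 0")
  centers <- peak_center(peaks)
  out <- numeric(nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == chr)
    rle <- track_chrom(track, chr)
    out[idx] <- rle_window_sum(rle, centers[idx] - halfwidth,
                               centers[idx] + halfwidth)
  }
  out
}

#' Counts-per-million normalisation
#'
#' @param raw raw signal counts.
#' @param library_size total raw fragment count of the library.
#' @return `raw * 1e6 / library_size`.
#' @export
normalize_cpm <- function(raw, library_size) {
  if (length(library_size) != 1 || library_size <= 0) {
    abort("`library_size` must be a single positive number")
  }
  raw * 1e6 / library_size
}

#' Classify peaks into condition-specific and shared groups
#'
#' A peak is specific to one sample when its fold difference exceeds the
#' threshold in that direction; everything else is shared. Folds are
#' computed as `(cpm_a + pc) / (cpm_b + pc)` so that peaks absent in one
#' sample (zero signal) still classify, landing with the "reduced more
#' than 2-fold" class.
#'
#' @param cpm_a,cpm_b normalised counts for the two samples.
#' @param fold_threshold specificity threshold (> 1); default 2.
#' @param pseudocount CPM pseudocount; default 0.5.
#' @return tibble with columns `cpm_a`, `cpm_b`, `fold` and `group`
#'   (factor with levels `A_specific`, `shared`, `B_specific`).
#' @export
classify_specificity <- function(cpm_a, cpm_b, fold_threshold = 2,
                                 pseudocount = 0.5) {
  if (fold_threshold <= 1) abort("`fold_threshold` must be > 1")
  if (any(cpm_a < 0) || any(cpm_b < 0)) abort("CPM values must be >= 0")
  fold <- (cpm_a + pseudocount) / (cpm_b + pseudocount)
  group <- factor(
    ifelse(fold > fold_threshold, "A_specific",
           ifelse(fold < 1 / fold_threshold, "B_specific", "shared")),
    levels = c("A_specific", "shared", "B_specific")
  )
  tibble(cpm_a = cpm_a, cpm_b = cpm_b, fold = fold, group = group)
}

#' Rank comparison records by fold difference
#'
#' Descending fold, ties broken by total signal (`cpm_a + cpm_b`,
#' descending) and then genomic position, so the resulting order is a
#' deterministic permutation. This order is the shared row coordinate
#' reused by every downstream heatmap and motif-density profile.
#'
#' @param records tibble with columns `fold`, `cpm_a`, `cpm_b`, `chrom`,
#'   `start`.
#' @return the records reordered, with a `rank` column (1 = largest fold).
#' @export
rank_by_fold <- function(records) {
  out <- arrange(records, desc(.data$fold),
                 desc(.data$cpm_a + .data$cpm_b), .data$chrom, .data$start)
  out$rank <- seq_len(nrow(out))
  out
}

#' Pairwise quantitative comparison of a factor's binding
#'
#' The engine behind condition-versus-condition binding analyses: merges
#' the two peak sets into union peaks, counts normalised signal in
#' summit-centred windows from both tracks, computes fold differences
#' with a pseudocount, classifies peaks into A-specific / shared /
#' B-specific groups and ranks all union peaks by descending fold.
#'
#' @param peaks_a,peaks_b peak sets for samples A and B.
#' @param track_a,track_b [coverage_track()]s for the two samples.
#' @param halfwidth summit-centred counting half-window (bp).
#' @param fold_threshold,pseudocount see [classify_specificity()].
#' @param labels length-2 character, display names of the two samples.
#' @return an object of class `peak_comparison`; see [tidy()] for the
#'   per-peak records and [glance()] for group sizes.
#' @export
compare_peaks <- function(peaks_a, peaks_b, track_a, track_b,
                          halfwidth = 200, fold_threshold = 2,
                          pseudocount = 0.5, labels = c("A", "B")) {
  union <- union_peaks(peaks_a, peaks_b)
  raw_a <- quantify_signal(track_a, union, halfwidth)
  raw_b <- quantify_signal(track_b, union, halfwidth)
  cpm_a <- normalize_cpm(raw_a, track_a$library_size)
  cpm_b <- normalize_cpm(raw_b, track_b$library_size)
  cls <- classify_specificity(cpm_a, cpm_b, fold_threshold, pseudocount)
  records <- bind_cols(union, cls[c("cpm_a", "cpm_b", "fold", "group")])
  records <- rank_by_fold(records)
  structure(list(records = records,
                 params = list(halfwidth = halfwidth,
                               fold_threshold = fold_threshold,
                               pseudocount = pseudocount, labels = labels)),
            class = "peak_comparison")
}

#' @export
print.peak_comparison <- function(x, ...) {
  g <- table(x$records$group)
  cat(sprintf(
    "<peak_comparison> %s vs %s: %d union peaks (%d %s-specific, %d shared, %d %s-specific)\n",
    x$params$labels[1], x$params$labels[2], nrow(x$records),
    g[["A_specific"]], x$params$labels[1], g[["shared"]],
    g[["B_specific"]], x$params$labels[2]))
  invisible(x)
}

#' Tidy a peak comparison
#'
#' @param x a `peak_comparison`.
#' @param ... unused.
#' @return the ranked per-union-peak records as a tibble.
#' @method tidy peak_comparison
#' @export
tidy.peak_comparison <- function(x, ...) x$records

#' One-row summary of a peak comparison
#'
#' @param x a `peak_comparison`.
#' @param ... unused.
#' @return tibble with union-peak and group counts.
#' @method glance peak_comparison
#' @export
glance.peak_comparison <- function(x, ...) {
  g <- table(x$records$group)
  tibble(n_union = nrow(x$records),
         n_a_specific = as.integer(g[["A_specific"]]),
         n_shared = as.integer(g[["shared"]]),
         n_b_specific = as.integer(g[["B_specific"]]),
         fold_threshold = x$params$fold_threshold)
}
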