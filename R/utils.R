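# internal helpers shared across modules

# Largest-remainder allocation of `n` items across named fractions.
# Guarantees the counts sum to n and are reproducible (ties broken by
# position, not by RNG).
allocate_counts <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("fractions must sum to 1")
  }
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Rolling mean over rows of a matrix with a centred window; partial windows
# at the edges are averaged over the rows actually available, so column sums
# are preserved in the interior and no row is dropped.
rolling_row_mean <- function(mat, window) {
  n <- nrow(mat)
  if (window <= 1 || n <= 1) return(mat)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  cs <- rbind(0, apply(mat, 2, cumsum))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  dimnames(out) <- dimnames(mat)
  out
}

# Sum of an Rle coverage vector over [start, end) given in 0-based
# half-open coordinates; regions outside [0, length) contribute 0.
rle_window_sum <- function(rle, start, end) {
  len <- length(rle)
  s <- pmax(start, 0L) + 1L       # to 1-based inclusive
  e <- pmin(end, len)             # 0-based exclusive == 1-based inclusive end
  keep <- s <= e
  out <- numeric(length(start))
  if (any(keep)) {
    v <- IRanges::Views(rle, start = s[keep], end = e[keep])
    out[keep] <- IRanges::viewSums(v)
  }
  out
}

# sample() without the scalar-x surprise: always samples from the
# elements of x, even when x has length 1
safe_sample <- function(x, size) x[sample.int(length(x), size)]

peak_center <- function(peaks) {
  ifelse(!is.na(peaks$summit %||% NA), peaks$start + peaks$summit,
         (peaks$start + peaks$end) %/% 2)
}

assert_peaks <- function(peaks, arg = "peaks") {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks))) {
    abort(sprintf("`%s` must be a data frame with columns chrom/start/end", arg))
  }
  if (any(peaks$start < 0) || any(peaks$start >= peaks$end)) {
    abort(sprintf("`%s` has invalid intervals (need 0 <= start < end)", arg))
  }
  peaks <- as_tibble(peaks)
  if (!"summit" %in% names(peaks)) peaks$summit <- NA_integer_
  if (!"score" %in% names(peaks)) peaks$score <- 0
  if (!"name" %in% names(peaks)) {
    peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  }
  if (!"strand" %in% names(peaks)) peaks$strand <- "."
  peaks
}
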