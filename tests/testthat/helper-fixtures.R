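# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (per-base loops, all-pairs scans) so they share no
# code with the implementation they check.

tiny_config <- function(..., seed = 1) {
  scenario_config(genome_length = 1.5e6, n_genes = 60, n_sites = 200,
                  seed = seed, ...)
}

const_track <- function(value, len = 5000, chrom = "chr1",
                        library_size = 1e6) {
  coverage_track(setNames(list(rep(value, len)), chrom),
                 library_size = library_size)
}

random_track <- function(len = 5000, chrom = "chr1", library_size = 1e6) {
  coverage_track(setNames(list(round(runif(len) * 5)), chrom),
                 library_size = library_size)
}

random_peaks <- function(n, chrom_len = 1e5, width_range = c(50, 500),
                         chroms = "chr1", with_summit = TRUE) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s <- sample.int(chrom_len - max(w), n, replace = TRUE) - 1L
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = s, end = s + w,
    name = sprintf("p%04d", seq_len(n)),
    score = round(runif(n) * 100),
    strand = ".",
    summit = if (with_summit) w %/% 2L else NA_integer_)
}

# O(n^2) interval merge: enumerate every overlapping-or-bookended pair
# with an all-against-all comparison, then take connected components by
# union-find; components give the merged intervals
bf_merge <- function(peaks) {
  n <- nrow(peaks)
  same_chr <- outer(peaks$chrom, peaks$chrom, "==")
  touch <- outer(peaks$start, peaks$end, "<=") &
    t(outer(peaks$start, peaks$end, "<=")) & same_chr
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  pairs <- which(touch & upper.tri(touch), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(n), find, 0L)
  out <- do.call(rbind, lapply(split(seq_len(n), comp), function(rows) {
    data.frame(chrom = peaks$chrom[rows[1]],
               start = min(peaks$start[rows]),
               end = max(peaks$end[rows]))
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# per-base signal sum over [start, end) against a plain numeric vector
bf_window_sum <- function(signal, start, end) {
  lo <- max(start, 0) + 1
  hi <- min(end, length(signal))
  if (lo > hi) return(0)
  sum(signal[lo:hi])
}

# all-pairs genomic location labels
bf_location <- function(peaks, genes, promoter_window = 2000) {
  vapply(seq_len(nrow(peaks)), function(i) {
    cen <- if (!is.na(peaks$summit[i])) peaks$start[i] + peaks$summit[i] else
      (peaks$start[i] + peaks$end[i]) %/% 2
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return("intergenic")
    if (any(abs(g$tss - cen) <= promoter_window)) return("promoter")
    if (any(g$start <= cen & cen < g$end)) return("intragenic")
    "intergenic"
  }, "")
}

# all-pairs nearest-TSS assignment with the lexicographic tie rule
bf_assign <- function(peaks, genes, max_distance = 1e5) {
  vapply(seq_len(nrow(peaks)), function(i) {
    cen <- if (!is.na(peaks$summit[i])) peaks$start[i] + peaks$summit[i] else
      (peaks$start[i] + peaks$end[i]) %/% 2
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NA_character_)
    d <- abs(g$tss - cen)
    if (min(d) > max_distance) return(NA_character_)
    min(g$gene_id[d == min(d)])
  }, "")
}

# all-pairs membership of merged loci in three peak sets
bf_venn_regions <- function(loci, sets) {
  vapply(seq_len(nrow(loci)), function(i) {
    memb <- vapply(sets, function(s) {
      any(s$chrom == loci$chrom[i] & s$start < loci$end[i] &
            loci$start[i] < s$end)
    }, logical(1))
    paste0(c("A", "B", "C")[memb], collapse = "")
  }, "")
}

# brute-force PWM score of one window (character vector of bases)
bf_score <- function(bases, lodds) {
  sum(vapply(seq_along(bases), function(j) {
    lodds[match(bases[j], c("A", "C", "G", "T")), j]
  }, 0))
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# brute-force average-linkage agglomeration over a distance matrix,
# returning the sequence of merge heights
bf_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
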