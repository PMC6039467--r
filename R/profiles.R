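#' Anchor-centred signal matrix
#'
#' Builds a peaks-by-position matrix of mean per-bp signal around each
#' anchor centre (summit when present, interval midpoint otherwise).
#' Rows keep the order of `anchors`, which is the shared ranked row
#' coordinate reused across tracks; bins clipped at chromosome ends are
#' filled with 0.
#'
#' @param track a [coverage_track()].
#' @param anchors tibble of peaks in a fixed (typically fold-ranked)
#'   order.
#' @param flank half-width of the window (bp); must be a multiple of
#'   `bin_size`.
#' @param bin_size bin width in bp (default 10).
#' @param normalize `"cpm"` scales the signal by `1e6 / library_size`;
#'   `"none"` uses the raw track values.
#' @return an object of class `anchor_matrix` with elements `values`
#'   (rows x bins), `row_order`, `bin_offsets` (bin start offsets from
#'   the anchor centre), `bin_size` and `flank`.
#' @export
anchored_matrix <- function(track, anchors, flank = 1000, bin_size = 10,
                            normalize = c("cpm", "none")) {
  anchors <- assert_peaks(anchors, "anchors")
  normalize <- match.arg(normalize)
  if (flank %% bin_size != 0) abort("`flank` must be a multiple of `bin_size`")
  nb <- as.integer(2 * flank / bin_size)
  centers <- peak_center(anchors)
  values <- matrix(0, nrow = nrow(anchors), ncol = nb)
  offsets <- -flank + (seq_len(nb) - 1L) * bin_size
  for (chr in unique(anchors$chrom)) {
    rle <- track_chrom(track, chr)
    idx <- which(anchors$chrom == chr)
    starts <- rep(centers[idx], each = nb) +
      rep(offsets, times = length(idx))
    sums <- rle_window_sum(rle, starts, starts + bin_size)
    values[idx, ] <- matrix(sums, nrow = length(idx), ncol = nb, byrow = TRUE)
  }
  values <- values / bin_size
  if (normalize == "cpm") values <- values * 1e6 / track$library_size
  structure(list(values = values, row_order = anchors$name,
                 bin_offsets = offsets, bin_size = bin_size, flank = flank,
                 normalize = normalize),
            class = "anchor_matrix")
}

#' @export
print.anchor_matrix <- function(x, ...) {
  cat(sprintf("<anchor_matrix> %d rows x %d bins (bin %d bp, flank %d bp, %s)\n",
              nrow(x$values), ncol(x$values), x$bin_size, x$flank,
              x$normalize))
  invisible(x)
}

#' Tidy an anchor matrix into long form
#'
#' @param x an `anchor_matrix` or `motif_density`.
#' @param ... unused.
#' @return tibble with columns `row` (anchor name), `rank`, `offset`
#'   (bin start relative to the anchor centre) and `value`.
#' @method tidy anchor_matrix
#' @export
tidy.anchor_matrix <- function(x, ...) {
  tibble(
    row = rep(x$row_order, times = ncol(x$values)),
    rank = rep(seq_along(x$row_order), times = ncol(x$values)),
    offset = rep(x$bin_offsets, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' @rdname tidy.anchor_matrix
#' @method tidy motif_density
#' @export
tidy.motif_density <- tidy.anchor_matrix

#' Average signal profile over a subset of ranked rows
#'
#' Column means of an anchor-centred matrix over a row subset; selecting
#' specificity groups reproduces the group-wise average-profile panels.
#'
#' @param x an `anchor_matrix` (or `motif_density`).
#' @param rows anchor names or row indices; all rows when NULL.
#' @return tibble with columns `offset` and `value`, plus an `n_rows`
#'   attribute.
#' @export
average_profile <- function(x, rows = NULL) {
  idx <- if (is.null(rows)) {
    seq_along(x$row_order)
  } else if (is.numeric(rows)) {
    as.integer(rows)
  } else {
    match(rows, x$row_order)
  }
  if (length(idx) == 0 || anyNA(idx)) {
    abort("`rows` must be a nonempty subset of the matrix rows")
  }
  out <- tibble(offset = x$bin_offsets,
                value = colMeans(x$values[idx, , drop = FALSE]))
  attr(out, "n_rows") <- length(idx)
  out
}

#' Scaled gene-body metagene profile
#'
#' Rescales every gene body onto a fixed number of bins, adds fixed-bp
#' flanks, reverses minus-strand genes, and averages within gene groups.
#' Genes shorter than `body_bins` bp are skipped with a warning.
#'
#' @param track a [coverage_track()].
#' @param genes tibble of gene models (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param groups optional character vector (or factor), one group label
#'   per gene; all genes form one group when NULL.
#' @param body_bins bins the body is rescaled onto (default 100).
#' @param flank flank size in bp (default 2000).
#' @param flank_bins bins per flank (default 20).
#' @param normalize as in [anchored_matrix()].
#' @return an object of class `metagene_profile`: `profile` is a tibble
#'   with `group`, `bin`, `zone` (upstream/body/downstream) and `value`
#'   (mean per-bp signal); `gene_values` keeps the per-gene matrix.
#' @export
metagene <- function(track, genes, groups = NULL, body_bins = 100,
                     flank = 2000, flank_bins = 20,
                     normalize = c("cpm", "none")) {
  normalize <- match.arg(normalize)
  if (flank %% flank_bins != 0) {
    abort("`flank` must be a multiple of `flank_bins`")
  }
  groups <- as.character(groups %||% rep("all", nrow(genes)))
  stopifnot(length(groups) == nrow(genes))
  fb <- flank %/% flank_bins
  nb <- 2L * flank_bins + body_bins
  scale <- if (normalize == "cpm") 1e6 / track$library_size else 1
  lens <- genes$end - genes$start
  short <- lens < body_bins
  if (any(short)) {
    warn(sprintf("skipping %d gene(s) shorter than %d bp", sum(short),
                 body_bins))
  }
  vals <- matrix(NA_real_, nrow = nrow(genes), ncol = nb)
  for (i in which(!short)) {
    rle <- track_chrom(track, genes$chrom[i])
    s <- genes$start[i]; e <- genes$end[i]; L <- e - s
    # body bin k covers [s + floor(k L / B), s + floor((k+1) L / B))
    cuts <- s + floor((0:body_bins) * L / body_bins)
    body <- rle_window_sum(rle, cuts[-(body_bins + 1)], cuts[-1]) /
      diff(cuts)
    up_starts <- s - flank + (seq_len(flank_bins) - 1L) * fb
    up <- rle_window_sum(rle, up_starts, up_starts + fb) / fb
    dn_starts <- e + (seq_len(flank_bins) - 1L) * fb
    dn <- rle_window_sum(rle, dn_starts, dn_starts + fb) / fb
    v <- c(up, body, dn) * scale
    if (genes$strand[i] == "-") v <- rev(v)
    vals[i, ] <- v
  }
  zone <- rep(c("upstream", "body", "downstream"),
              c(flank_bins, body_bins, flank_bins))
  prof <- purrr::map_dfr(sort(unique(groups[!short])), function(g) {
    rows <- which(groups == g & !short)
    tibble(group = g, bin = seq_len(nb), zone = zone,
           value = colMeans(vals[rows, , drop = FALSE]), n_genes = length(rows))
  })
  structure(list(profile = prof, gene_values = vals, groups = groups,
                 params = list(body_bins = body_bins, flank = flank,
                               flank_bins = flank_bins,
                               normalize = normalize)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d group(s), %d genes, %d bins\n",
              length(unique(x$profile$group)), nrow(x$gene_values),
              2L * x$params$flank_bins + x$params$body_bins))
  invisible(x)
}

#' Classify peaks by genomic location relative to gene models
#'
#' A peak is proximal (promoter) when its centre lies within
#' `promoter_window` bp of any TSS; otherwise it is intragenic when the
#' centre falls inside any gene span, else intergenic. Distal means "not
#' proximal".
#'
#' @param peaks tibble of peaks.
#' @param genes tibble of gene models with a `tss` column.
#' @param promoter_window promoter half-width around the TSS (bp).
#' @return the peaks with added columns `location` (promoter /
#'   intragenic / intergenic) and `proximal` (logical); the location
#'   fractions are attached as attribute `"fractions"`.
#' @export
genomic_location <- function(peaks, genes, promoter_window = 2000) {
  peaks <- assert_peaks(peaks)
  centers <- peak_center(peaks)
  location <- rep("intergenic", nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == chr)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0) next
    cpt <- IRanges::IRanges(centers[idx] + 1L, width = 1L)
    in_gene <- IRanges::countOverlaps(
      cpt, IRanges::IRanges(g$start + 1L, g$end)) > 0
    near_tss <- IRanges::countOverlaps(
      cpt, IRanges::IRanges(g$tss - promoter_window + 1L,
                            g$tss + promoter_window + 1L)) > 0
    location[idx][in_gene] <- "intragenic"
    location[idx][near_tss] <- "promoter"
  }
  out <- mutate(peaks, location = location, proximal = location == "promoter")
  attr(out, "fractions") <- c(
    proximal = mean(out$proximal),
    distal = mean(!out$proximal),
    promoter = mean(location == "promoter"),
    intragenic = mean(location == "intragenic"),
    intergenic = mean(location == "intergenic")
  )
  out
}
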