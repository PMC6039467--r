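#' Coverage track container
#'
#' A coverage track stores base-resolution signal per chromosome as
#' run-length-encoded vectors plus the library size (total raw fragment
#' count) used for counts-per-million normalization. All coordinates in
#' the package are 0-based half-open; conversion to 1-based happens only
#' at file boundaries.
#'
#' @param cov named list of per-chromosome signal, each an
#'   [S4Vectors::Rle] or plain numeric vector (1 bp resolution).
#' @param library_size total raw fragment count behind the track; used by
#'   [normalize_cpm()] and CPM-scaled matrices. Defaults to the total
#'   signal area when not supplied.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(cov, library_size = NULL) {
  if (!is.list(cov) || is.null(names(cov)) || any(names(cov) == "")) {
    abort("`cov` must be a named list of per-chromosome signal vectors")
  }
  cov <- lapply(cov, function(x) {
    x <- if (methods::is(x, "Rle")) x else S4Vectors::Rle(as.numeric(x))
    if (any(S4Vectors::runValue(x) < 0)) abort("coverage signal must be >= 0")
    x
  })
  area <- sum(vapply(cov, function(x) sum(as.numeric(S4Vectors::runValue(x)) *
                                            S4Vectors::runLength(x)), 0))
  structure(
    list(cov = cov, library_size = library_size %||% area, resolution = 1L),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  lens <- vapply(x$cov, length, 0L)
  cat(sprintf("<coverage_track> %d chromosome(s), %s bp, library size %.6g\n",
              length(lens), format(sum(lens), big.mark = ","), x$library_size))
  invisible(x)
}

#' Build a coverage track by piling up fragments
#'
#' Fragments are half-open intervals; the pileup counts, at every base,
#' how many fragments cover it.
#'
#' @param fragments tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param library_size raw fragment count; defaults to `nrow(fragments)`.
#' @return a [coverage_track()].
#' @export
track_from_fragments <- function(fragments, chrom_lengths,
                                 library_size = nrow(fragments)) {
  cov <- lapply(names(chrom_lengths), function(chr) {
    f <- fragments[fragments$chrom == chr, , drop = FALSE]
    len <- chrom_lengths[[chr]]
    if (nrow(f) == 0) return(S4Vectors::Rle(0, len))
    s <- pmax(f$start, 0L)
    e <- pmin(f$end, len)
    keep <- s < e
    ir <- IRanges::IRanges(start = s[keep] + 1L, end = e[keep])
    IRanges::coverage(ir, width = len)
  })
  names(cov) <- names(chrom_lengths)
  coverage_track(cov, library_size = library_size)
}

track_chrom <- function(track, chrom) {
  if (!chrom %in% names(track$cov)) {
    abort(sprintf("chromosome '%s' absent from coverage track", chrom))
  }
  track$cov[[chrom]]
}
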