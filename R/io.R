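#' Read and write peak files (BED6 / narrowPeak)
#'
#' Peaks are tibbles with columns `chrom`, `start`, `end`, `name`,
#' `score`, `strand` and (optionally) `summit`, the offset of the peak
#' summit from `start`. Coordinates are 0-based half-open as in BED.
#' narrowPeak input (10 columns) takes the summit from column 10; a
#' summit of -1 is read as missing.
#'
#' @param path file path.
#' @return `read_bed()`: a tibble of peaks sorted as on disk.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character(),
                  summit = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("%s: malformed BED line %d (fewer than 3 fields)",
                  path, which(nf < 3)[1]))
  }
  ncol <- min(nf)
  get <- function(i) vapply(fields, `[[`, "", i)
  out <- tibble(
    chrom = get(1),
    start = suppressWarnings(as.integer(get(2))),
    end = suppressWarnings(as.integer(get(3)))
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                 out$start >= out$end)
  if (length(bad)) {
    abort(sprintf("%s: malformed BED line %d (bad coordinates)", path, bad[1]))
  }
  out$name <- if (ncol >= 4) get(4) else sprintf("peak_%d", seq_len(nrow(out)))
  out$score <- if (ncol >= 5) as.numeric(get(5)) else 0
  out$strand <- if (ncol >= 6) get(6) else "."
  if (ncol >= 10) {
    summit <- as.integer(get(10))
    out$summit <- ifelse(summit < 0, NA_integer_, summit)
  } else {
    out$summit <- NA_integer_
  }
  out
}

#' @param peaks tibble of peaks (see `read_bed()`).
#' @param narrowpeak write 10-column narrowPeak (keeps the summit) instead
#'   of BED6.
#' @rdname read_bed
#' @export
write_bed <- function(peaks, path, narrowpeak = FALSE) {
  peaks <- assert_peaks(peaks)
  score <- ifelse(peaks$score == round(peaks$score),
                  sprintf("%d", as.integer(round(peaks$score))),
                  sprintf("%g", peaks$score))
  base <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", peaks$chrom, peaks$start,
                  peaks$end, peaks$name, score, peaks$strand)
  if (narrowpeak) {
    summit <- ifelse(is.na(peaks$summit), -1L, peaks$summit)
    base <- sprintf("%s\t0\t-1\t-1\t%d", base, summit)
  }
  writeLines(base, path)
  invisible(path)
}

#' Read and write bedGraph coverage
#'
#' Gaps between bedGraph intervals are read as signal 0; overlapping
#' intervals are rejected. `write_bedgraph()` emits one line per
#' non-zero run.
#'
#' @param path file path.
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   absent each chromosome extends to its last covered base.
#' @param library_size raw fragment count behind the track; defaults to
#'   the total signal area (see [coverage_track()]).
#' @return `read_bedgraph()`: a [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL, library_size = NULL) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "ciid", progress = FALSE,
                        comment = "#")
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    abort(sprintf("%s: malformed bedGraph line %d", path, bad[1]))
  }
  chroms <- names(chrom_lengths) %||% unique(df$chrom)
  cov <- lapply(chroms, function(chr) {
    d <- df[df$chrom == chr, , drop = FALSE]
    len <- chrom_lengths[[chr]] %||% (if (nrow(d)) max(d$end) else 1L)
    if (nrow(d)) {
      d <- d[order(d$start), , drop = FALSE]
      if (any(d$start[-1] < d$end[-nrow(d)])) {
        i <- which(d$start[-1] < d$end[-nrow(d)])[1]
        abort(sprintf("%s: overlapping bedGraph intervals on %s at %d",
                      path, chr, d$start[i + 1]))
      }
      if (any(d$end > len)) abort(sprintf("%s: interval beyond end of %s",
                                          path, chr))
    }
    x <- S4Vectors::Rle(0, len)
    if (nrow(d)) {
      x[IRanges::IRanges(d$start + 1L, d$end)] <-
        S4Vectors::Rle(rep(d$value, d$end - d$start))
    }
    x
  })
  names(cov) <- chroms
  coverage_track(cov, library_size = library_size)
}

#' @param track a [coverage_track()].
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chr in names(track$cov)) {
    x <- track$cov[[chr]]
    ends <- cumsum(S4Vectors::runLength(x))
    starts <- ends - S4Vectors::runLength(x)  # 0-based
    vals <- S4Vectors::runValue(x)
    keep <- vals != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%g", chr, starts[keep], ends[keep],
                         vals[keep]), con)
    }
  }
  invisible(path)
}

#' Read and write FASTA genome sequence
#'
#' Thin wrappers around Biostrings keeping the package's tibble-first
#' surface consistent.
#'
#' @param path file path.
#' @return `read_fasta()`: a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @param genome a [Biostrings::DNAStringSet].
#' @rdname read_fasta
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Read and write gene model tables
#'
#' Gene models are tibbles with columns `gene_id`, `chrom`, `start`,
#' `end`, `strand` and `tss`. The TSS is `start` for `+` genes and
#' `end - 1` for `-` genes (0-based).
#'
#' @param path TSV file with a header row.
#' @return `read_gene_table()`: a tibble of gene models.
#' @export
read_gene_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", chrom = "c", start = "i", end = "i", strand = "c",
    tss = "i", .default = "?"), progress = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: gene table must have columns %s", path,
                  paste(need, collapse = ", ")))
  }
  exp_tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  if (any(df$tss != exp_tss)) {
    abort(sprintf("%s: line %d: tss inconsistent with strand convention",
                  path, which(df$tss != exp_tss)[1] + 1L))
  }
  df
}

#' @param genes tibble of gene models.
#' @rdname read_gene_table
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path, progress = FALSE)
  invisible(path)
}
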