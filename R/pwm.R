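#' Position weight matrices
#'
#' A `pwm` stores per-position base probabilities (rows A, C, G, T) plus a
#' background distribution. Count matrices are regularised by adding a
#' pseudocount to every cell before normalisation, so log-odds scores are
#' always finite.
#'
#' @param name motif name.
#' @param counts 4 x L numeric matrix of base counts (rows A, C, G, T) or
#'   an already-normalised probability matrix (set `pseudocount = 0`).
#' @param pseudocount value added to every cell before normalisation
#'   (default 0.25).
#' @param background base composition used for log-odds scoring; uniform
#'   by default.
#' @return an object of class `pwm` with elements `name`, `prob`
#'   (4 x L probability matrix) and `background`.
#' @export
pwm <- function(name, counts, pseudocount = 0.25,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("`counts` must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) abort("`counts` must be nonnegative")
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  prob <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  if (any(colSums(counts) + 4 * pseudocount == 0)) {
    abort("empty PFM column with zero pseudocount")
  }
  rownames(prob) <- c("A", "C", "G", "T")
  structure(list(name = name, prob = prob,
                 background = setNames(background, c("A", "C", "G", "T"))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%d bp), consensus %s\n", x$name, ncol(x$prob),
              pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' The most probable base at each position; ties resolve to the first of
#' A, C, G, T.
#'
#' @param x a [pwm()].
#' @return a character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$prob)[apply(x$prob, 2, which.max)], collapse = "")
}

#' Read and write JASPAR-format PFM files
#'
#' Parses the JASPAR 2016 text layout: a `>name` header line followed by
#' four rows `A [ n n ... ]` through `T [ ... ]`. Counts are converted to
#' probabilities with [pwm()]'s pseudocount rule.
#'
#' @param path file path.
#' @param pseudocount,background passed to [pwm()].
#' @return `read_pfm()`: a named list of [pwm()] objects.
#' @export
read_pfm <- function(path, pseudocount = 0.25,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort(sprintf("%s: no PFM records found", path))
  out <- lapply(seq_along(starts), function(i) {
    from <- starts[i]
    if (from + 4 > length(lines)) {
      abort(sprintf("%s: truncated PFM record at line %d", path, from))
    }
    name <- sub("^>\\s*", "", lines[from])
    name <- strsplit(name, "\\s+")[[1]][1]
    rows <- lapply(lines[from + 1:4], function(l) {
      nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("%s: ragged PFM record '%s'", path, name))
    }
    counts <- do.call(rbind, rows)
    pwm(name, counts, pseudocount = pseudocount, background = background)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' @param pfms named list of [pwm()] objects or raw 4 x L count matrices.
#' @rdname read_pfm
#' @export
write_pfm <- function(pfms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(pfms)) {
    m <- pfms[[nm]]
    mat <- if (inherits(m, "pwm")) round(m$prob * 100) else as.matrix(m)
    writeLines(sprintf(">%s", nm), con)
    for (i in 1:4) {
      writeLines(sprintf("%s [ %s ]", c("A", "C", "G", "T")[i],
                         paste(format(mat[i, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Bundled regulatory motif set
#'
#' Loads the package's editable JASPAR-format catalogue of the core
#' motifs used by the synthetic scenario and the examples: RUNX, ETS
#' (ERG/FLI-like), GATA, AP1, TEAD and the ETS::RUNX composite (ETS and
#' RUNX cores on the same strand separated by a 2 bp spacer, shipped as
#' one concatenated matrix).
#'
#' @inheritParams read_pfm
#' @return a named list of [pwm()] objects.
#' @export
bundled_motifs <- function(pseudocount = 0.25) {
  read_pfm(system.file("extdata", "motifs", "core_motifs.jaspar",
                       package = "tfreloc", mustWork = TRUE),
           pseudocount = pseudocount)
}
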