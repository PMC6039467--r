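#' Fragments per kilobase per million (FPKM)
#'
#' @param counts raw fragment counts.
#' @param gene_length_bp gene lengths in bp.
#' @param library_size total mapped fragments of the library.
#' @return `counts * 1e9 / (gene_length_bp * library_size)`.
#' @export
fpkm <- function(counts, gene_length_bp, library_size) {
  if (any(gene_length_bp <= 0)) abort("gene lengths must be > 0")
  if (length(library_size) != 1 || library_size <= 0) {
    abort("`library_size` must be a single positive number")
  }
  counts * 1e9 / (as.numeric(gene_length_bp) * as.numeric(library_size))
}

#' FPKM table from a counts table
#'
#' Converts a wide counts table (one column per sample) to per-sample
#' FPKM, using each sample's column sum as its library size, and
#' averages replicates into per-condition FPKM.
#'
#' @param counts tibble with columns `gene_id`, `length` and one count
#'   column per sample.
#' @param samples tibble with columns `sample` and `condition` mapping
#'   count columns to conditions.
#' @return a list with `fpkm` (per-sample) and `condition_fpkm`
#'   (replicate-averaged) tibbles, both keyed by `gene_id`.
#' @export
fpkm_table <- function(counts, samples) {
  missing <- setdiff(samples$sample, names(counts))
  if (length(missing)) {
    abort(sprintf("count columns missing for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  per_sample <- counts["gene_id"]
  for (s in samples$sample) {
    per_sample[[s]] <- fpkm(counts[[s]], counts$length, sum(counts[[s]]))
  }
  cond <- counts["gene_id"]
  for (cn in unique(samples$condition)) {
    cols <- samples$sample[samples$condition == cn]
    cond[[cn]] <- rowMeans(as.matrix(per_sample[cols]))
  }
  list(fpkm = per_sample, condition_fpkm = cond)
}

cond_matrix <- function(condition_fpkm) {
  m <- as.matrix(condition_fpkm[setdiff(names(condition_fpkm), "gene_id")])
  rownames(m) <- condition_fpkm$gene_id
  m
}

#' Call differentially expressed genes by pairwise fold change
#'
#' A gene is differential when its largest pairwise fold change between
#' condition means (with an FPKM pseudocount) reaches the threshold and
#' its largest condition FPKM passes the expression floor.
#'
#' @param condition_fpkm tibble of per-condition mean FPKM (`gene_id`
#'   plus one column per condition).
#' @param threshold fold-change threshold (default 2).
#' @param min_expr minimum condition FPKM (default 1).
#' @param pseudocount FPKM pseudocount for fold computation (default 1).
#' @return tibble with `gene_id`, `max_fold`, `max_fpkm`, `differential`.
#' @export
call_differential <- function(condition_fpkm, threshold = 2, min_expr = 1,
                              pseudocount = 1) {
  m <- cond_matrix(condition_fpkm)
  if (ncol(m) < 2) abort("need at least two conditions")
  mp <- m + pseudocount
  max_fold <- unname(apply(mp, 1, max) / apply(mp, 1, min))
  max_fpkm <- unname(apply(m, 1, max))
  tibble(gene_id = condition_fpkm$gene_id, max_fold = max_fold,
         max_fpkm = max_fpkm,
         differential = max_fold >= threshold & max_fpkm >= min_expr)
}

#' 0/1/2 expression-response codes
#'
#' Encodes each gene's behaviour across two pairwise comparisons as a
#' two-character string: `1` = up (fold at or above the threshold),
#' `0` = down (fold at or below its reciprocal), `2` = unchanged. With
#' the default comparisons (induced vs control, then inhibitor-treated
#' vs induced) differential genes fall into the 8 codes other than
#' `"22"`; for example `"10"` marks genes activated by induction and
#' lost again under the inhibitor.
#'
#' @param condition_fpkm tibble of per-condition mean FPKM.
#' @param comparisons list of length-2 character vectors
#'   `c(numerator, denominator)`; default
#'   `list(c("Dox", "noDox"), c("Dox_JQ1", "Dox"))`.
#' @param threshold fold-change threshold (default 2).
#' @param pseudocount FPKM pseudocount (default 1).
#' @return tibble with `gene_id`, per-comparison folds (`fc1`, `fc2`,
#'   ...) and the `code` string.
#' @export
code_genes <- function(condition_fpkm,
                       comparisons = list(c("Dox", "noDox"),
                                          c("Dox_JQ1", "Dox")),
                       threshold = 2, pseudocount = 1) {
  m <- cond_matrix(condition_fpkm)
  out <- tibble(gene_id = condition_fpkm$gene_id)
  digits <- matrix("", nrow(m), length(comparisons))
  for (i in seq_along(comparisons)) {
    cmp <- comparisons[[i]]
    if (!all(cmp %in% colnames(m))) {
      abort(sprintf("unknown condition name(s): %s",
                    paste(setdiff(cmp, colnames(m)), collapse = ", ")))
    }
    fc <- (m[, cmp[1]] + pseudocount) / (m[, cmp[2]] + pseudocount)
    out[[paste0("fc", i)]] <- unname(fc)
    digits[, i] <- ifelse(fc >= threshold, "1",
                          ifelse(fc <= 1 / threshold, "0", "2"))
  }
  out$code <- apply(digits, 1, paste, collapse = "")
  out
}

#' Hierarchical clustering of genes on log2 expression
#'
#' Agglomerative clustering with distance `1 - Pearson correlation` and
#' average linkage. Zero-variance rows have undefined correlation and
#' are placed at distance 1 from everything.
#'
#' @param mat numeric matrix, genes x samples (typically
#'   `log2(FPKM + 1)` of the differential genes).
#' @return a list of class `gene_clustering` with the `hclust` object
#'   and the leaf `order` (row names in dendrogram order).
#' @export
cluster_genes <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) abort("need at least two rows to cluster")
  suppressWarnings(r <- cor(t(mat)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  d <- as.dist(1 - r)
  hc <- hclust(d, method = "average")
  structure(list(hclust = hc,
                 order = (rownames(mat) %||%
                            as.character(seq_len(nrow(mat))))[hc$order]),
            class = "gene_clustering")
}

#' @export
print.gene_clustering <- function(x, ...) {
  cat(sprintf("<gene_clustering> %d leaves (1 - Pearson, average linkage)\n",
              length(x$order)))
  invisible(x)
}

#' Pearson correlation between samples, with clustering
#'
#' Correlates samples over a shared feature space (normalised counts on
#' union peaks for ChIP samples; `log2(FPKM + 1)` of differential genes
#' for RNA samples) and clusters the resulting matrix like
#' [cluster_genes()].
#'
#' @param mat numeric matrix, samples x features.
#' @return a list of class `sample_correlation` with the symmetric
#'   `correlation` matrix, the `hclust` object and the sample `order`.
#' @export
sample_correlation <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("S%d", seq_len(nrow(mat)))
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance sample(s): %s",
                  paste(rownames(mat)[sds == 0], collapse = ", ")))
  }
  r <- cor(t(mat))
  hc <- hclust(as.dist(1 - r), method = "average")
  structure(list(correlation = r, hclust = hc,
                 order = rownames(mat)[hc$order]),
            class = "sample_correlation")
}

#' @export
print.sample_correlation <- function(x, ...) {
  cat(sprintf("<sample_correlation> %d samples; order: %s\n",
              nrow(x$correlation), paste(x$order, collapse = ", ")))
  invisible(x)
}
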