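#' Three-set peak-overlap grouping
#'
#' Overlaps three peak sets (typically: pre-induction factor binding,
#' post-induction factor binding, and the induced factor itself) on
#' merged union loci, so that a locus counts once however many raw peaks
#' cover it. Overlap means at least 1 bp of intersection. Venn regions
#' map onto analysis groups 1-5 by default as: Group 1 = A only,
#' Group 2 = A and B without C, Group 3 = A and B and C,
#' Group 4 = B and C without A, Group 5 = C only; the A-and-C-only and
#' B-only residual regions are reported unlabeled. The mapping is
#' configurable.
#'
#' @param peaks_a,peaks_b,peaks_c the three peak sets.
#' @param labels length-3 character, display names for the sets.
#' @param mapping named character vector region -> group id; regions are
#'   spelled with the letters A, B, C (e.g. `"AB"`, `"ABC"`).
#' @return an object of class `overlap_groups`: `loci` is a tibble of
#'   merged union loci with membership flags, `region` and `group`
#'   columns; [glance()] gives the region/group sizes.
#' @export
venn_groups <- function(peaks_a, peaks_b, peaks_c,
                        labels = c("A", "B", "C"),
                        mapping = c(A = 1, AB = 2, ABC = 3, BC = 4, C = 5)) {
  sets <- list(assert_peaks(peaks_a, "peaks_a"),
               assert_peaks(peaks_b, "peaks_b"),
               assert_peaks(peaks_c, "peaks_c"))
  all <- bind_rows(sets)
  loci <- purrr::map_dfr(sort(unique(all$chrom)), function(chr) {
    p <- all[all$chrom == chr, , drop = FALSE]
    red <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end),
                           min.gapwidth = 0L)
    member <- vapply(sets, function(s) {
      si <- s[s$chrom == chr, , drop = FALSE]
      IRanges::countOverlaps(red, IRanges::IRanges(si$start + 1L, si$end)) > 0
    }, logical(length(red)))
    member <- matrix(member, ncol = 3)
    tibble(chrom = chr, start = IRanges::start(red) - 1L,
           end = IRanges::end(red), in_a = member[, 1], in_b = member[, 2],
           in_c = member[, 3])
  })
  loci$name <- sprintf("locus_%d", seq_len(nrow(loci)))
  loci$region <- paste0(ifelse(loci$in_a, "A", ""),
                        ifelse(loci$in_b, "B", ""),
                        ifelse(loci$in_c, "C", ""))
  loci$group <- unname(mapping[loci$region])
  structure(list(loci = loci, labels = labels, mapping = mapping),
            class = "overlap_groups")
}

#' @export
print.overlap_groups <- function(x, ...) {
  cat(sprintf("<overlap_groups> %s / %s / %s: %d union loci\n",
              x$labels[1], x$labels[2], x$labels[3], nrow(x$loci)))
  sizes <- group_sizes(x)
  for (i in seq_len(nrow(sizes))) {
    cat(sprintf("  Group %s (%s): %d loci\n", sizes$group[i],
                sizes$region[i], sizes$n[i]))
  }
  invisible(x)
}

#' @rdname venn_groups
#' @param x an `overlap_groups` object.
#' @export
group_sizes <- function(x) {
  out <- count(x$loci, .data$group, .data$region, name = "n")
  arrange(out, is.na(.data$group), .data$group, .data$region)
}

#' @method tidy overlap_groups
#' @export
tidy.overlap_groups <- function(x, ...) x$loci

#' @method glance overlap_groups
#' @export
glance.overlap_groups <- function(x, ...) {
  s <- group_sizes(x)
  lab <- ifelse(is.na(s$group), paste0("region_", s$region),
                paste0("group_", s$group))
  out <- as_tibble(as.list(setNames(s$n, lab)))
  out$n_loci <- nrow(x$loci)
  out
}

#' Estimate the relocation fraction from overlap groups
#'
#' Under the relocation model, sites the factor abandoned reappear as de
#' novo peaks at induced-factor sites (Group 4), while non-relocating
#' sites stay bound away from the induced factor (Group 2). The
#' relocated fraction is therefore estimated as
#' `|Group 4| / (|Group 4| + |Group 2|)`.
#'
#' @param x an `overlap_groups` from [venn_groups()].
#' @return the estimated relocation fraction.
#' @export
estimate_relocation <- function(x) {
  stopifnot(inherits(x, "overlap_groups"))
  n4 <- sum(x$loci$group %in% 4)
  n2 <- sum(x$loci$group %in% 2)
  if (n4 + n2 == 0) abort("groups 2 and 4 are both empty; estimate undefined")
  n4 / (n4 + n2)
}

#' Assign peaks to the gene with the nearest TSS
#'
#' Each peak is assigned to the gene whose TSS is closest to the peak
#' centre, within `max_distance`; equidistant ties go to the
#' lexicographically smaller `gene_id`. Peaks with no gene in range are
#' kept with `gene_id = NA`.
#'
#' @param peaks tibble of peaks.
#' @param genes tibble of gene models with `tss`.
#' @param max_distance assignment cap in bp (default 100 kb).
#' @return the peaks with added `gene_id` and `tss_distance` columns.
#' @export
assign_genes <- function(peaks, genes, max_distance = 1e5) {
  peaks <- assert_peaks(peaks)
  centers <- peak_center(peaks)
  gene_id <- rep(NA_character_, nrow(peaks))
  distance <- rep(NA_integer_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == chr)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0) next
    ord <- order(g$tss, g$gene_id)
    ts <- g$tss[ord]
    ids <- g$gene_id[ord]
    # start index of each run of equal TSS values (run sorted by gene_id,
    # so the run start holds the lexicographically smallest id)
    new_run <- c(TRUE, ts[-1] != ts[-length(ts)])
    run_start <- which(new_run)[cumsum(new_run)]
    for (i in idx) {
      cen <- centers[i]
      fi <- findInterval(cen, ts)
      cand <- unique(c(if (fi >= 1) run_start[fi],
                       if (fi < length(ts)) run_start[fi + 1]))
      d <- abs(ts[cand] - cen)
      best <- cand[d == min(d)]
      if (min(d) <= max_distance) {
        gene_id[i] <- min(ids[best])
        distance[i] <- min(d)
      }
    }
  }
  mutate(peaks, gene_id = gene_id, tss_distance = distance)
}

#' Cross-tabulate overlap groups with expression responses
#'
#' Joins peak-overlap groups to gene responses: each group's member loci
#' are mapped to genes (via [assign_genes()] output) and the
#' differentially expressed genes and their response codes are counted
#' per group. A gene counts once per group even when several member loci
#' map to it; the same gene may appear in several groups.
#'
#' @param x an `overlap_groups` from [venn_groups()].
#' @param assignments output of [assign_genes()] run on `x$loci` (or any
#'   tibble with `name` and `gene_id` matching the loci).
#' @param codes tibble with `gene_id` and `code` columns (see
#'   [code_genes()]).
#' @param differential character vector of differential gene ids;
#'   defaults to genes whose code is not `"22"`.
#' @return an object of class `overlap_crosstab`: `summary` has one row
#'   per group (peaks, genes, differential genes); `code_counts` has the
#'   per-group response-code histogram.
#' @export
cross_tab <- function(x, assignments, codes, differential = NULL) {
  stopifnot(inherits(x, "overlap_groups"))
  differential <- differential %||% codes$gene_id[codes$code != "22"]
  loci <- left_join(x$loci, assignments[c("name", "gene_id")], by = "name")
  groups <- sort(unique(loci$group[!is.na(loci$group)]))
  summary <- purrr::map_dfr(groups, function(g) {
    m <- loci[loci$group %in% g, , drop = FALSE]
    genes <- unique(m$gene_id[!is.na(m$gene_id)])
    tibble(group = g, n_peaks = nrow(m), n_genes = length(genes),
           n_differential = length(intersect(genes, differential)))
  })
  code_counts <- purrr::map_dfr(groups, function(g) {
    m <- loci[loci$group %in% g, , drop = FALSE]
    genes <- intersect(unique(m$gene_id[!is.na(m$gene_id)]), differential)
    cc <- codes[codes$gene_id %in% genes, , drop = FALSE]
    if (nrow(cc) == 0) return(tibble(group = integer(), code = character(),
                                     n = integer()))
    out <- count(cc, .data$code, name = "n")
    tibble(group = g, code = out$code, n = out$n)
  })
  structure(list(summary = summary, code_counts = code_counts),
            class = "overlap_crosstab")
}

#' @export
print.overlap_crosstab <- function(x, ...) {
  cat("<overlap_crosstab>\n")
  print(x$summary)
  invisible(x)
}
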