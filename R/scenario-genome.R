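# Internal geometry of the per-gene blocks on chromosome 1.
# Distal linked sites sit 2.8-4.5 kb from their gene's TSS (outside any
# conventional promoter window but well inside nearest-TSS assignment
# range); every other gene's TSS is >= 5 kb away by construction.
DIST_OFF_MIN <- 2800L
DIST_OFF_MAX <- 4500L

block_geometry <- function(config) {
  b <- config$block_length
  len_max <- config$gene_length_range[2]
  sw <- config$site_width
  tss_plus <- DIST_OFF_MAX + sw %/% 2 + config$fragment_length
  tss_minus <- len_max - 1L
  if (b < tss_plus + len_max ||
      b < tss_minus + DIST_OFF_MAX + sw %/% 2 + config$fragment_length ||
      b < 9600L) {
    abort("config infeasible: block_length too small for gene + linked site")
  }
  list(tss_plus = as.integer(tss_plus), tss_minus = as.integer(tss_minus))
}

site_roles <- function(conditions) {
  list(ctrl = conditions[1], ind = conditions[2],
       ctrl_i = if (length(conditions) >= 3) conditions[3] else NULL,
       ind_i = if (length(conditions) >= 4) conditions[4] else NULL)
}

#' Build the synthetic genome, gene models and site catalogue
#'
#' Lays out one genomic block per gene on chromosome 1 (gene body plus,
#' for linked genes, a regulatory site either at the TSS or 2.8-4.5 kb
#' away), scatters the remaining unlinked sites over the other
#' chromosomes, samples occupancy strengths and relocation/priming
#' flags, plants motif instances according to each site's class, and
#' synthesises the random background sequence with the motifs written
#' in at their recorded offsets. Everything is a deterministic function
#' of the configuration.
#'
#' @param config a [scenario_config()].
#' @param motifs named list of [pwm()]s used for planting; defaults to
#'   the bundled catalogue.
#' @return a list with `genome` (a [Biostrings::DNAStringSet]) and
#'   `truth` (a `scenario_truth`: `site_table`, `gene_table`,
#'   `motif_table`, `occupancy`, `chrom_lengths`,
#'   `true_relocation_fraction`).
#' @export
build_genome <- function(config, motifs = bundled_motifs()) {
  stopifnot(inherits(config, "scenario_config"))
  truth <- withr::with_seed(config$seed + 1L, plan_scenario(config))
  genome <- withr::with_seed(config$seed + 2L,
                             synthesize_sequence(truth, motifs))
  list(genome = genome, truth = truth)
}

plan_scenario <- function(config) {
  classes <- names(config$site_class_fractions)
  n_by_class <- setNames(
    allocate_counts(config$n_sites, config$site_class_fractions), classes)
  n_prom <- n_by_class[["promoter"]]
  if (n_prom > config$n_genes) {
    abort("config infeasible: more promoter-class sites than genes")
  }
  geo <- block_geometry(config)
  sw <- config$site_width

  # gene classes: every promoter site gets a gene; a fraction of the
  # remaining genes link to distal sites; the rest are unlinked controls
  n_rest <- config$n_genes - n_prom
  distal_classes <- setdiff(classes, "promoter")
  n_distal_linked <- round(config$linked_gene_fraction * n_rest)
  distal_frac <- config$site_class_fractions[distal_classes]
  n_link_by_class <- setNames(
    allocate_counts(n_distal_linked, distal_frac / sum(distal_frac)),
    distal_classes)
  if (any(n_link_by_class > n_by_class[distal_classes])) {
    abort("config infeasible: more linked genes than sites in a class")
  }
  gene_class <- sample(c(rep("promoter", n_prom),
                         rep(distal_classes, n_link_by_class),
                         rep("none", n_rest - n_distal_linked)))
  gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gene_len <- sample(seq(config$gene_length_range[1],
                         config$gene_length_range[2]),
                     config$n_genes, replace = TRUE)

  block_start <- (seq_len(config$n_genes) - 1L) * config$block_length
  tss <- ifelse(gene_strand == "+", block_start + geo$tss_plus,
                block_start + geo$tss_minus)
  gstart <- ifelse(gene_strand == "+", tss, tss + 1L - gene_len)
  gend <- gstart + gene_len
  gene_table <- tibble(
    gene_id = sprintf("g%04d", seq_len(config$n_genes)),
    chrom = "chr1", start = as.integer(gstart), end = as.integer(gend),
    strand = gene_strand, tss = as.integer(tss),
    length = as.integer(gene_len), class = gene_class)

  # linked sites on chr1
  linked <- which(gene_class != "none")
  dist_off <- sample(DIST_OFF_MIN:DIST_OFF_MAX, length(linked),
                     replace = TRUE)
  center <- integer(length(linked))
  for (k in seq_along(linked)) {
    i <- linked[k]
    center[k] <- if (gene_class[i] == "promoter") {
      tss[i]
    } else if (gene_strand[i] == "+") tss[i] - dist_off[k] else
      tss[i] + dist_off[k]
  }
  linked_sites <- tibble(
    chrom = "chr1", start = as.integer(center - sw %/% 2),
    class = gene_class[linked],
    linked_gene = gene_table$gene_id[linked])

  # unlinked sites on the remaining chromosomes
  chr1_len <- config$n_genes * config$block_length
  if (chr1_len > config$genome_length) {
    abort("config infeasible: gene blocks exceed genome_length")
  }
  n_unlinked <- config$n_sites - nrow(linked_sites)
  if (config$n_chromosomes == 1) {
    regions <- tibble(chrom = "chr1", region_start = chr1_len,
                      region_len = config$genome_length - chr1_len)
    chrom_lengths <- c(chr1 = config$genome_length)
  } else {
    extra <- (config$genome_length - chr1_len) %/%
      (config$n_chromosomes - 1L)
    regions <- tibble(chrom = sprintf("chr%d", 1L +
                                        seq_len(config$n_chromosomes - 1L)),
                      region_start = 0L, region_len = extra)
    chrom_lengths <- c(chr1 = chr1_len,
                       setNames(rep(extra, config$n_chromosomes - 1L),
                                regions$chrom))
  }
  per_region <- allocate_counts(n_unlinked,
                                regions$region_len / sum(regions$region_len))
  unlinked_sites <- purrr::map_dfr(seq_len(nrow(regions)), function(r) {
    k <- per_region[r]
    if (k == 0) return(NULL)
    spacing <- regions$region_len[r] %/% k
    if (spacing < sw + 2L * config$fragment_length) {
      abort("config infeasible: unlinked sites do not fit without overlap")
    }
    jitter <- sample.int(spacing - sw, k, replace = TRUE) - 1L
    tibble(chrom = regions$chrom[r],
           start = as.integer(regions$region_start[r] +
                                (seq_len(k) - 1L) * spacing + jitter),
           class = NA_character_, linked_gene = NA_character_)
  })
  # unlinked class labels fill whatever the linked sites did not consume
  remaining <- n_by_class
  for (cl in names(remaining)) {
    remaining[cl] <- remaining[cl] - sum(linked_sites$class == cl)
  }
  if (remaining[["promoter"]] > 0) {
    abort("config infeasible: promoter-class sites left without a gene")
  }
  unlinked_sites$class <- sample(rep(names(remaining), remaining))

  sites <- bind_rows(linked_sites, unlinked_sites)
  sites <- mutate(sites, end = .data$start + sw,
                  summit = sw %/% 2L,
                  site_id = sprintf("s%04d", seq_len(nrow(sites))))
  sites$strength <- sample(config$strength_levels, nrow(sites),
                           replace = TRUE, prob = config$strength_probs)

  # relocation, priming and inhibitor-loss flags
  is_eg <- sites$class == "ETS_GATA"
  is_er <- sites$class == "ETS_RUNX"
  n_rel <- round(config$relocation_fraction * sum(is_eg))
  sites$relocating <- FALSE
  sites$relocating[safe_sample(which(is_eg), n_rel)] <- TRUE
  sites$primed <- FALSE
  sites$primed[safe_sample(which(is_er),
                           round(config$primed_fraction * sum(is_er)))] <- TRUE
  free_er <- which(is_er & !sites$primed)
  if (length(free_er) < n_rel) {
    abort("config infeasible: not enough un-primed ETS_RUNX sites to relocate to")
  }
  sites$relocated_to <- FALSE
  sites$relocated_to[safe_sample(free_er, n_rel)] <- TRUE
  inducible <- which(sites$class %in% c("ETS_RUNX", "RUNX_only", "promoter"))
  sites$jq1_lost <- FALSE
  sites$jq1_lost[safe_sample(inducible,
                             round(config$jq1_loss_fraction *
                                     length(inducible)))] <- TRUE
  sites$subclass <- site_subclass(sites)

  gene_table <- left_join(
    gene_table,
    rename(sites[!is.na(sites$linked_gene),
                 c("linked_gene", "site_id", "subclass")],
           gene_id = "linked_gene", linked_site = "site_id"),
    by = "gene_id")
  gene_table$subclass[is.na(gene_table$subclass)] <- "none"
  coupling <- config$expression_coupling
  missing <- setdiff(unique(gene_table$subclass), names(coupling))
  if (length(missing)) {
    abort(sprintf("expression_coupling lacks subclass(es): %s",
                  paste(missing, collapse = ", ")))
  }
  gene_table$code <- unname(coupling[gene_table$subclass])

  motif_table <- plan_motifs(sites, sw)
  occupancy <- build_occupancy(sites, config)

  structure(list(
    site_table = select(sites, "site_id", "chrom", "start", "end", "summit",
                        "class", "subclass", "strength", "linked_gene",
                        "relocating", "primed", "relocated_to", "jq1_lost"),
    gene_table = gene_table,
    motif_table = motif_table,
    occupancy = occupancy,
    chrom_lengths = chrom_lengths,
    conditions = config$conditions,
    factors = c("pioneer", "induced", "cofactor", "elongation"),
    true_relocation_fraction = if (sum(is_eg) > 0) n_rel / sum(is_eg) else NA
  ), class = "scenario_truth")
}

site_subclass <- function(sites) {
  dplyr::case_when(
    sites$class == "ETS_GATA" & sites$relocating ~ "ETS_GATA_relocating",
    sites$class == "ETS_GATA" ~ "ETS_GATA_static",
    sites$class == "ETS_RUNX" & sites$relocated_to ~ "ETS_RUNX_relocated_to",
    sites$class == "ETS_RUNX" & sites$primed ~ "ETS_RUNX_primed",
    sites$class == "ETS_RUNX" ~ "ETS_RUNX_other",
    sites$class == "RUNX_only" & sites$jq1_lost ~ "RUNX_only_jq1_lost",
    sites$class == "RUNX_only" ~ "RUNX_only_retained",
    TRUE ~ sites$class
  )
}

# class-specific motif planting; offsets are relative to the site start
plan_motifs <- function(sites, sw) {
  cen <- sw %/% 2L
  one <- function(idx, motif, lo, hi) {
    if (length(idx) == 0) return(NULL)
    tibble(site_id = sites$site_id[idx], motif = motif,
           offset = as.integer(cen + sample(lo:hi, length(idx),
                                            replace = TRUE)),
           strand = "+")
  }
  bind_rows(
    one(which(sites$class == "ETS_GATA"), "ETS", -60, -15),
    one(which(sites$class == "ETS_GATA"), "GATA", 15, 60),
    one(which(sites$class == "ETS_RUNX"), "ETS_RUNX", -40, 25),
    one(which(sites$class == "RUNX_only"), "RUNX", -50, 50),
    one(which(sites$class == "TEAD"), "TEAD", -50, 50),
    one(which(sites$class == "promoter"), "ETS", -60, -15),
    one(which(sites$class == "promoter"), "RUNX", 15, 60)
  )
}

build_occupancy <- function(sites, config) {
  roles <- site_roles(config$conditions)
  s <- sites$strength
  cls <- sites$class
  masks <- list(
    pioneer = list(
      ctrl = cls == "ETS_GATA" | sites$primed,
      ind = (cls == "ETS_GATA" & !sites$relocating) | sites$primed |
        sites$relocated_to,
      ctrl_i = cls == "ETS_GATA" | sites$primed,
      ind_i = cls == "ETS_GATA" | sites$primed | cls == "TEAD"),
    induced = list(
      ctrl = rep(FALSE, nrow(sites)),
      ind = cls %in% c("ETS_RUNX", "RUNX_only", "promoter"),
      ctrl_i = rep(FALSE, nrow(sites)),
      ind_i = cls %in% c("ETS_RUNX", "RUNX_only", "promoter") &
        !sites$jq1_lost),
    cofactor = list(
      ctrl = cls == "promoter",
      ind = cls == "promoter" | sites$primed | sites$relocated_to,
      ctrl_i = cls == "promoter",
      ind_i = cls == "promoter" | (sites$primed & !sites$jq1_lost) |
        cls == "TEAD")
  )
  purrr::map_dfr(names(masks), function(fac) {
    purrr::map_dfr(names(roles), function(role) {
      cond <- roles[[role]]
      if (is.null(cond)) return(NULL)
      tibble(site_id = sites$site_id, factor = fac, condition = cond,
             occupancy = ifelse(masks[[fac]][[role]], s, 0))
    })
  })
}

synthesize_sequence <- function(truth, motifs) {
  needed <- setdiff(unique(truth$motif_table$motif), names(motifs))
  if (length(needed)) {
    abort(sprintf("planting motif(s) missing from catalogue: %s",
                  paste(needed, collapse = ", ")))
  }
  consensus <- lapply(motifs, function(p) {
    strsplit(pwm_consensus(p), "")[[1]]
  })
  seqs <- lapply(names(truth$chrom_lengths), function(chr) {
    len <- truth$chrom_lengths[[chr]]
    base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    sites <- truth$site_table[truth$site_table$chrom == chr, , drop = FALSE]
    mt <- truth$motif_table[truth$motif_table$site_id %in% sites$site_id, ,
                            drop = FALSE]
    if (nrow(mt)) {
      mt <- left_join(mt, sites[c("site_id", "start")], by = "site_id")
      for (i in seq_len(nrow(mt))) {
        letters <- consensus[[mt$motif[i]]]
        pos <- mt$start[i] + mt$offset[i]
        base[(pos + 1L):(pos + length(letters))] <- letters
      }
    }
    paste(base, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(truth$chrom_lengths)
  out
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf(
    "<scenario_truth> %d sites, %d genes, %d chromosome(s), relocation %.3f\n",
    nrow(x$site_table), nrow(x$gene_table), length(x$chrom_lengths),
    x$true_relocation_fraction))
  invisible(x)
}
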