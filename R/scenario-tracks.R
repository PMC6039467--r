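# per-condition expression multipliers implied by a response code:
# first digit induced-vs-control, second inhibitor-vs-induced
code_multipliers <- function(code, fold, conditions) {
  digit_mult <- function(d) switch(d, "1" = fold, "0" = 1 / fold, "2" = 1)
  d <- strsplit(code, "")[[1]]
  roles <- site_roles(conditions)
  m <- setNames(rep(1, length(conditions)), conditions)
  m[roles$ind] <- digit_mult(d[1])
  if (!is.null(roles$ind_i)) m[roles$ind_i] <- digit_mult(d[1]) *
      digit_mult(d[2])
  m
}

# Multipliers are peak-anchored: each gene's sampled baseline is its
# expression in the condition where it is most active, and the coded
# fold changes step down from there. Responding genes therefore reach,
# rather than exceed, the expression scale of the stable transcriptome
# (repressed genes start high and are switched off; induced genes start
# low and are switched on), which keeps library composition stable
# across conditions -- the regime in which FPKM fold changes are
# faithful.
gene_condition_multipliers <- function(truth, config) {
  mm <- t(vapply(truth$gene_table$code, code_multipliers,
                 numeric(length(config$conditions)),
                 fold = config$expression$fold,
                 conditions = config$conditions))
  mm <- mm / apply(mm, 1, max)
  rownames(mm) <- truth$gene_table$gene_id
  mm
}

#' Peak sets implied by the scenario truth
#'
#' Every site occupied by a factor in a condition contributes its
#' interval to that factor/condition peak set; the score is the
#' occupancy strength. The gene-body elongation mark has no site peaks.
#'
#' @param truth a `scenario_truth`.
#' @return nested list `peaks[[factor]][[condition]]` of peak tibbles.
#' @export
peak_sets <- function(truth) {
  st <- truth$site_table
  occ <- truth$occupancy
  out <- list()
  for (fac in unique(occ$factor)) {
    out[[fac]] <- list()
    for (cond in truth$conditions) {
      o <- occ[occ$factor == fac & occ$condition == cond &
                 occ$occupancy > 0, , drop = FALSE]
      rows <- st[match(o$site_id, st$site_id), , drop = FALSE]
      out[[fac]][[cond]] <- tibble(
        chrom = rows$chrom, start = rows$start, end = rows$end,
        name = rows$site_id, score = o$occupancy, strand = ".",
        summit = rows$summit)
    }
  }
  out
}

#' Simulate coverage tracks and peak sets from the scenario truth
#'
#' For each site-binding factor and condition, fragment counts per
#' occupied site are Poisson with mean `depth_per_site * occupancy`;
#' fragment midpoints are uniform within the site and each fragment
#' covers `fragment_length` bp. Uniform background fragments are added
#' at `background_rate` per kb. The elongation mark instead lays
#' fragments over gene bodies at a rate proportional to each gene's
#' condition-specific expression multiplier. Peak sets are the
#' occupied-site intervals (see [peak_sets()]).
#'
#' @param truth a `scenario_truth` from [build_genome()].
#' @param config the matching [scenario_config()].
#' @return list with `tracks` (nested `[[factor]][[condition]]` of
#'   [coverage_track()]s) and `peaks` (nested list of peak tibbles).
#' @export
simulate_tracks <- function(truth, config) {
  stopifnot(inherits(truth, "scenario_truth"))
  withr::with_seed(config$seed + 3L, {
    fl <- config$fragment_length
    half <- fl %/% 2L
    mk_frags <- function(chrom, mid) {
      tibble(chrom = chrom, start = as.integer(round(mid)) - half,
             end = as.integer(round(mid)) - half + fl)
    }
    empty_frags <- function() {
      tibble(chrom = character(), start = integer(), end = integer())
    }
    background <- function() {
      purrr::map_dfr(names(truth$chrom_lengths), function(chr) {
        len <- truth$chrom_lengths[[chr]]
        n <- rpois(1, config$background_rate * len / 1000)
        if (n == 0) return(NULL)
        mk_frags(chr, runif(n, 0, len))
      })
    }
    st <- truth$site_table
    tracks <- list()
    for (fac in setdiff(truth$factors, "elongation")) {
      tracks[[fac]] <- list()
      for (cond in truth$conditions) {
        o <- truth$occupancy
        o <- o[o$factor == fac & o$condition == cond & o$occupancy > 0, ,
               drop = FALSE]
        rows <- match(o$site_id, st$site_id)
        n_per_site <- rpois(nrow(o), config$depth_per_site * o$occupancy)
        idx <- rep(seq_len(nrow(o)), n_per_site)
        site_frags <- if (length(idx)) {
          mk_frags(st$chrom[rows][idx],
                   runif(length(idx), st$start[rows][idx],
                         st$end[rows][idx]))
        } else NULL
        frags <- bind_rows(empty_frags(), site_frags, background())
        tracks[[fac]][[cond]] <- track_from_fragments(
          frags, truth$chrom_lengths)
      }
    }
    # elongation mark over gene bodies, coupled to expression
    mult <- gene_condition_multipliers(truth, config)
    g <- truth$gene_table
    tracks[["elongation"]] <- list()
    for (cond in truth$conditions) {
      n_per_gene <- rpois(nrow(g), config$depth_per_site * mult[, cond] *
                            g$length / 1000)
      idx <- rep(seq_len(nrow(g)), n_per_gene)
      gene_frags <- if (length(idx)) {
        mk_frags(g$chrom[idx], runif(length(idx), g$start[idx], g$end[idx]))
      } else NULL
      tracks[["elongation"]][[cond]] <- track_from_fragments(
        bind_rows(empty_frags(), gene_frags, background()),
        truth$chrom_lengths)
    }
    list(tracks = tracks, peaks = peak_sets(truth))
  })
}

#' Simulate the expression tables of the scenario
#'
#' Per-gene counts are negative binomial around a lognormal baseline
#' scaled by the condition multiplier that each gene's true response
#' code implies, with at least two replicates per condition; coded
#' changes are realised at the configured fold separation and "2"
#' (unchanged) comparisons at fold 1. FPKM columns are derived with
#' [fpkm_table()].
#'
#' @param truth a `scenario_truth`.
#' @param config the matching [scenario_config()].
#' @return list with `counts` (gene_id, length, one column per sample),
#'   `samples` (sample/condition/replicate map), `fpkm`,
#'   `condition_fpkm` and the generator's `differential` gene ids (true
#'   code other than "22").
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "scenario_truth"))
  withr::with_seed(config$seed + 4L, {
    ex <- config$expression
    g <- truth$gene_table
    mult <- gene_condition_multipliers(truth, config)
    baseline <- rlnorm(nrow(g), ex$baseline_meanlog, ex$baseline_sdlog)
    samples <- tidyr::expand_grid(condition = config$conditions,
                                  replicate = seq_len(ex$n_replicates))
    samples$sample <- sprintf("%s_rep%d", samples$condition,
                              samples$replicate)
    counts <- tibble(gene_id = g$gene_id, length = g$length)
    for (i in seq_len(nrow(samples))) {
      mu <- baseline * mult[, samples$condition[i]]
      counts[[samples$sample[i]]] <- if (ex$dispersion > 0) {
        rnbinom(length(mu), mu = mu, size = 1 / ex$dispersion)
      } else {
        rpois(length(mu), mu)
      }
    }
    ft <- fpkm_table(counts, samples)
    list(counts = counts, samples = samples, fpkm = ft$fpkm,
         condition_fpkm = ft$condition_fpkm,
         differential = g$gene_id[g$code != "22"])
  })
}

#' Simulate a complete relocation scenario
#'
#' Runs [build_genome()], [simulate_tracks()] and
#' [simulate_expression()] under one configuration and returns
#' everything the pipeline consumes, alongside the ground truth.
#'
#' @param config a [scenario_config()].
#' @param motifs planting motif catalogue; defaults to the bundled set.
#' @return an object of class `relocation_scenario` with elements
#'   `config`, `genome`, `truth`, `tracks`, `peaks`, `expression` and
#'   `motifs`.
#' @export
simulate_scenario <- function(config = scenario_config(),
                              motifs = bundled_motifs()) {
  bg <- build_genome(config, motifs)
  tk <- simulate_tracks(bg$truth, config)
  ex <- simulate_expression(bg$truth, config)
  structure(list(config = config, genome = bg$genome, truth = bg$truth,
                 tracks = tk$tracks, peaks = tk$peaks, expression = ex,
                 motifs = motifs),
            class = "relocation_scenario")
}

#' @export
print.relocation_scenario <- function(x, ...) {
  cat(sprintf(
    "<relocation_scenario> seed %d: %d sites, %d genes, %d factors x %d conditions\n",
    x$config$seed, nrow(x$truth$site_table), nrow(x$truth$gene_table),
    length(x$tracks), length(x$config$conditions)))
  invisible(x)
}

#' Write a simulated scenario to disk
#'
#' Emits the standard-format artifacts of the scenario under one
#' directory: genome FASTA, gene-model TSV, per-factor/condition peak
#' BED and coverage bedGraph, counts and FPKM TSV, the planting motifs
#' in JASPAR format, the configuration YAML and the ground truth as
#' JSON.
#'
#' @param scenario a `relocation_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "relocation_scenario"))
  dir.create(file.path(dir, "tracks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  write_fasta(scenario$genome, file.path(dir, "genome.fa"))
  write_gene_table(scenario$truth$gene_table[
    c("gene_id", "chrom", "start", "end", "strand", "tss", "length")],
    file.path(dir, "genes.tsv"))
  for (fac in names(scenario$tracks)) {
    for (cond in names(scenario$tracks[[fac]])) {
      write_bedgraph(scenario$tracks[[fac]][[cond]],
                     file.path(dir, "tracks",
                               sprintf("%s_%s.bedGraph", fac, cond)))
    }
  }
  for (fac in names(scenario$peaks)) {
    for (cond in names(scenario$peaks[[fac]])) {
      write_bed(scenario$peaks[[fac]][[cond]],
                file.path(dir, "peaks", sprintf("%s_%s.bed", fac, cond)),
                narrowpeak = TRUE)
    }
  }
  readr::write_tsv(scenario$expression$counts, file.path(dir, "counts.tsv"),
                   progress = FALSE)
  readr::write_tsv(scenario$expression$fpkm, file.path(dir, "fpkm.tsv"),
                   progress = FALSE)
  write_pfm(scenario$motifs, file.path(dir, "motifs.jaspar"))
  write_scenario_config(scenario$config, file.path(dir, "config.yaml"))
  truth <- scenario$truth
  truth$chrom_lengths <- as.list(truth$chrom_lengths)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
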