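#' Default site-class to response-code coupling
#'
#' Maps each regulatory-site subclass of the synthetic scenario onto the
#' two-character 0/1/2 expression-response code its linked gene realises
#' (first digit: induced vs control; second digit: inhibitor-treated vs
#' induced). The defaults encode the relocation biology: genes whose
#' enhancer loses the pioneer factor go down on induction and recover
#' when relocation is blocked (`"01"`); genes at relocated-to composite
#' sites are activated by induction and lost under the inhibitor
#' (`"10"`); primed composite sites stay up (`"12"`); repressed sites
#' split by whether the induced factor survives the inhibitor (`"02"` /
#' `"01"`); aberrantly gained TEAD sites respond only to the inhibitor
#' (`"21"`). Promoter-class sites sit at genes whose expression the
#' induction leaves unchanged (the proximal compartment responds little),
#' and genes without any linked site are unchanged controls (`"22"`).
#'
#' @return named character vector, subclass -> code.
#' @export
default_expression_coupling <- function() {
  c(ETS_GATA_relocating   = "01",
    ETS_GATA_static       = "22",
    ETS_RUNX_relocated_to = "10",
    ETS_RUNX_primed       = "12",
    ETS_RUNX_other        = "11",
    RUNX_only_jq1_lost    = "01",
    RUNX_only_retained    = "02",
    TEAD                  = "21",
    promoter              = "22",
    none                  = "22")
}

#' Configuration of the synthetic relocation scenario
#'
#' Bundles and validates every parameter of the synthetic-data
#' generator: genome and site-catalogue sizing, the class composition of
#' regulatory sites, the relocation fraction, sequencing depth and
#' noise, and the coupling between site classes and expression-response
#' codes. Defaults describe the study conditions the package is
#' validated under: a 10 Mb genome with 2,000 sites, 60% of
#' pioneer-occupied ETS/GATA sites relocating on induction, four
#' conditions crossing induction with an inhibitor, 30 expected
#' fragments per occupied site.
#'
#' @param genome_length total genome size in bp.
#' @param n_chromosomes number of chromosomes; chromosome 1 carries the
#'   genes and their linked sites, the rest carry unlinked sites.
#' @param n_genes number of genes.
#' @param n_sites number of regulatory sites.
#' @param site_class_fractions named fractions over the five site
#'   classes `ETS_GATA`, `ETS_RUNX`, `RUNX_only`, `TEAD`, `promoter`;
#'   must sum to 1.
#' @param relocation_fraction fraction in `[0, 1]` of pioneer-occupied
#'   ETS_GATA sites whose occupancy moves to ETS_RUNX sites on
#'   induction.
#' @param conditions ordered condition names; the first is the
#'   un-induced control, the second the induced state, then the two
#'   inhibitor arms.
#' @param depth_per_site expected fragments per occupied site at
#'   strength 1.
#' @param fragment_length simulated fragment length in bp.
#' @param background_rate background fragments per kb of genome.
#' @param expression_coupling subclass -> response-code map; see
#'   [default_expression_coupling()].
#' @param linked_gene_fraction fraction of the genes left after promoter
#'   assignment that are linked to a distal site.
#' @param primed_fraction fraction of ETS_RUNX sites already bound by
#'   the pioneer factor before induction.
#' @param jq1_loss_fraction fraction of induced-factor sites losing that
#'   factor under the inhibitor.
#' @param site_width regulatory-site width in bp.
#' @param block_length per-gene genomic block on chromosome 1 (bp).
#' @param gene_length_range min/max gene-body length (bp).
#' @param strength_levels,strength_probs occupancy strength multipliers
#'   and their sampling probabilities; the strength continuum drives the
#'   fold-difference ranking downstream.
#' @param expression list of expression-noise parameters: `fold` (mean
#'   separation realised for coded changes), `dispersion` (negative
#'   binomial), `n_replicates`, `baseline_meanlog`, `baseline_sdlog`.
#' @param seed integer seed; every emitted artifact is a deterministic
#'   function of the configuration including this seed.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(genome_length = 1e7,
                            n_chromosomes = 2,
                            n_genes = 600,
                            n_sites = 2000,
                            site_class_fractions = c(
                              ETS_GATA = 0.30, ETS_RUNX = 0.30,
                              RUNX_only = 0.15, TEAD = 0.10,
                              promoter = 0.15),
                            relocation_fraction = 0.6,
                            conditions = c("noDox", "Dox", "noDox_JQ1",
                                           "Dox_JQ1"),
                            depth_per_site = 30,
                            fragment_length = 200,
                            background_rate = 0.1,
                            expression_coupling = default_expression_coupling(),
                            linked_gene_fraction = 0.6,
                            primed_fraction = 0.25,
                            jq1_loss_fraction = 0.3,
                            site_width = 400,
                            block_length = 12000,
                            gene_length_range = c(2000, 5000),
                            strength_levels = c(0.5, 1, 2),
                            strength_probs = c(0.25, 0.5, 0.25),
                            expression = list(),
                            seed = 1) {
  classes <- c("ETS_GATA", "ETS_RUNX", "RUNX_only", "TEAD", "promoter")
  site_class_fractions <- unlist(site_class_fractions)
  if (!setequal(names(site_class_fractions), classes)) {
    abort(sprintf("site_class_fractions must name exactly: %s",
                  paste(classes, collapse = ", ")))
  }
  site_class_fractions <- site_class_fractions[classes]
  if (abs(sum(site_class_fractions) - 1) > 1e-9) {
    abort("site_class_fractions must sum to 1")
  }
  if (relocation_fraction < 0 || relocation_fraction > 1) {
    abort("relocation_fraction must be in [0, 1]")
  }
  counts <- c(genome_length, n_chromosomes, n_genes, n_sites,
              depth_per_site, fragment_length)
  if (any(counts <= 0)) abort("sizes, counts and depths must be > 0")
  if (background_rate < 0) abort("background_rate must be >= 0")
  if (genome_length < n_sites * 10 * fragment_length) {
    abort(paste("config infeasible: genome_length must be at least",
                "n_sites * 10 * fragment_length to avoid forced overlap"))
  }
  if (length(conditions) < 2) abort("need at least two conditions")
  expr_defaults <- list(fold = 5, dispersion = 0.05, n_replicates = 3,
                        baseline_meanlog = log(500), baseline_sdlog = 0.5)
  expression <- utils::modifyList(expr_defaults, as.list(expression))
  if (expression$n_replicates < 2) abort("need >= 2 replicates per condition")
  stopifnot(length(strength_levels) == length(strength_probs))
  structure(list(
    genome_length = as.integer(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    n_genes = as.integer(n_genes),
    n_sites = as.integer(n_sites),
    site_class_fractions = site_class_fractions,
    relocation_fraction = relocation_fraction,
    conditions = conditions,
    depth_per_site = depth_per_site,
    fragment_length = as.integer(fragment_length),
    background_rate = background_rate,
    expression_coupling = expression_coupling,
    linked_gene_fraction = linked_gene_fraction,
    primed_fraction = primed_fraction,
    jq1_loss_fraction = jq1_loss_fraction,
    site_width = as.integer(site_width),
    block_length = as.integer(block_length),
    gene_length_range = as.integer(gene_length_range),
    strength_levels = strength_levels,
    strength_probs = strength_probs,
    expression = expression,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %.3g Mb genome, %d sites, %d genes, relocation %.2f, seed %d\n",
    x$genome_length / 1e6, x$n_sites, x$n_genes, x$relocation_fraction,
    x$seed))
  invisible(x)
}

#' Read a scenario configuration from YAML
#'
#' Reads a YAML document whose keys are the arguments of
#' [scenario_config()]; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("%s: unknown configuration key(s): %s", path,
                  paste(bad, collapse = ", ")))
  }
  for (nm in c("site_class_fractions", "expression_coupling")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  }
  do.call(scenario_config, vals)
}

#' @param config a `scenario_config`.
#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  vals <- unclass(config)
  vals$site_class_fractions <- as.list(vals$site_class_fractions)
  vals$expression_coupling <- as.list(vals$expression_coupling)
  yaml::write_yaml(vals, path)
  invisible(path)
}
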