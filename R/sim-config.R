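#' Simulation configuration for synthetic structured cohorts
#'
#' Bundles every parameter of the cohort generator into a validated object.
#' A `sim_config` (including its `seed`) fully determines the generated
#' cohort: rerunning [simulate_cohort()] on an identical config yields
#' bit-identical output.
#'
#' @param seed Integer seed for all randomness in the generator.
#' @param n_ancestral_haps Number of founder haplotypes drawn per
#'   subpopulation. Also sets the lower truncation of the ancestral site
#'   frequency spectrum at `1/(2 * n_ancestral_haps)`.
#' @param n_sites Number of segregating sites to simulate.
#' @param region_length Length of the simulated region in base pairs; site
#'   positions are drawn uniformly (without replacement) on `1:region_length`.
#' @param sfs_alpha Exponent of the ancestral frequency distribution: density
#'   proportional to `x^(-sfs_alpha)` truncated to
#'   `[1/(2 * n_ancestral_haps), 0.5]`. `0` gives a uniform spectrum; `1`
#'   approximates the neutral spectrum.
#' @param fst_per_pop Numeric vector of Balding-Nichols divergence values in
#'   `[0, 1)`, one per subpopulation.
#' @param recomb_rate Per-base switch probability of the recombinant-mosaic
#'   copying process (probability of switching founder between adjacent sites
#'   is `1 - exp(-recomb_rate * distance)`).
#' @param flip_rate Per-site allele flip probability applied during copying
#'   (a mutation surrogate).
#' @param pop_sizes Integer vector of diploid sample counts per
#'   subpopulation (same length as `fst_per_pop`).
#' @param admixed_fraction Fraction of target individuals that are admixed
#'   between the first two subpopulations.
#' @param admix_q Ancestry proportion (first subpopulation) for admixed
#'   individuals.
#' @param array_maf_min Minimum cohort MAF for a site to be "typed" on the
#'   simulated genotyping array.
#' @param array_spacing Keep every `array_spacing`-th eligible site on the
#'   array.
#' @param case_fraction Expected phenotype prevalence.
#' @param causal_effects Optional two-column matrix or data.frame
#'   `(site, beta)` of causal site indices and allelic log-odds; `NULL` for a
#'   null phenotype model.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_sites = 200, pop_sizes = c(20, 20))
#' cfg$n_sites
#' @export
sim_config <- function(seed = 1L,
                       n_ancestral_haps = 100L,
                       n_sites = 1000L,
                       region_length = 2e6,
                       sfs_alpha = 1,
                       fst_per_pop = c(0.05, 0.05),
                       recomb_rate = 1e-5,
                       flip_rate = 1e-3,
                       pop_sizes = c(50L, 50L),
                       admixed_fraction = 0,
                       admix_q = 0.5,
                       array_maf_min = 0.05,
                       array_spacing = 3L,
                       case_fraction = 0.3,
                       causal_effects = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    n_ancestral_haps = as.integer(n_ancestral_haps),
    n_sites = as.integer(n_sites),
    region_length = as.numeric(region_length),
    sfs_alpha = as.numeric(sfs_alpha),
    fst_per_pop = as.numeric(fst_per_pop),
    recomb_rate = as.numeric(recomb_rate),
    flip_rate = as.numeric(flip_rate),
    pop_sizes = as.integer(pop_sizes),
    admixed_fraction = as.numeric(admixed_fraction),
    admix_q = as.numeric(admix_q),
    array_maf_min = as.numeric(array_maf_min),
    array_spacing = as.integer(array_spacing),
    case_fraction = as.numeric(case_fraction),
    causal_effects = causal_effects
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!all(ok)) stop("sim_config: ", msg, call. = FALSE)
  chk(cfg$n_ancestral_haps >= 2, "n_ancestral_haps must be >= 2")
  chk(cfg$n_sites >= 1, "n_sites must be positive")
  chk(cfg$region_length >= cfg$n_sites, "region_length must allow n_sites distinct positions")
  chk(cfg$sfs_alpha >= 0, "sfs_alpha must be >= 0")
  chk(cfg$fst_per_pop >= 0 & cfg$fst_per_pop < 1, "fst values must lie in [0, 1)")
  chk(cfg$recomb_rate >= 0, "recomb_rate must be >= 0")
  chk(cfg$flip_rate >= 0 & cfg$flip_rate <= 1, "flip_rate must lie in [0, 1]")
  chk(length(cfg$pop_sizes) == length(cfg$fst_per_pop),
      "pop_sizes and fst_per_pop must have equal length")
  chk(cfg$pop_sizes >= 1, "pop_sizes must be positive")
  chk(cfg$admixed_fraction >= 0 & cfg$admixed_fraction <= 1,
      "admixed_fraction must lie in [0, 1]")
  chk(cfg$admix_q >= 0 & cfg$admix_q <= 1, "admix_q must lie in [0, 1]")
  chk(cfg$array_maf_min >= 0 & cfg$array_maf_min <= 0.5,
      "array_maf_min must lie in [0, 0.5]")
  chk(cfg$array_spacing >= 1, "array_spacing must be >= 1")
  chk(cfg$case_fraction > 0 & cfg$case_fraction < 1,
      "case_fraction must lie in (0, 1)")
  if (!is.null(cfg$causal_effects)) {
    ce <- as.data.frame(cfg$causal_effects)
    chk(ncol(ce) >= 2, "causal_effects needs columns (site, beta)")
    chk(ce[[1]] >= 1 & ce[[1]] <= cfg$n_sites, "causal site index out of range")
  }
  cfg
}

#' Read or write a simulation config as YAML
#'
#' @param cfg A [sim_config()] object.
#' @param path File path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  x <- unclass(cfg)
  if (!is.null(x$causal_effects)) {
    ce <- as.data.frame(x$causal_effects)
    x$causal_effects <- list(site = as.integer(ce[[1]]), beta = as.numeric(ce[[2]]))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  ce <- x$causal_effects
  if (!is.null(ce)) ce <- data.frame(site = ce$site, beta = ce$beta)
  x$causal_effects <- NULL
  do.call(sim_config, c(x, list(causal_effects = ce)))
}
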