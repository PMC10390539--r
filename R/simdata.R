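#' Draw ancestral allele frequencies from a truncated power-law spectrum
#'
#' Samples `cfg$n_sites` frequencies i.i.d. from a density proportional to
#' `x^(-sfs_alpha)` truncated to `[1/(2 * n_ancestral_haps), 0.5]`, by
#' inversion of the closed-form CDF. `sfs_alpha = 0` is uniform on the
#' truncation interval; `sfs_alpha = 1` approximates the neutral site
#' frequency spectrum.
#'
#' @param cfg A [sim_config()].
#' @return Numeric vector of length `cfg$n_sites`, each value inside the
#'   truncation interval.
#' @export
draw_ancestral_frequencies <- function(cfg) {
  validate_sim_config(cfg)
  lo <- 1 / (2 * cfg$n_ancestral_haps)
  hi <- 0.5
  a <- cfg$sfs_alpha
  u <- runif(cfg$n_sites)
  if (abs(a - 1) < 1e-12) {
    # CDF proportional to log(x/lo)
    p <- lo * (hi / lo)^u
  } else {
    b <- 1 - a
    p <- (lo^b + u * (hi^b - lo^b))^(1 / b)
  }
  pmin(pmax(p, lo), hi)
}

#' Draw subpopulation allele frequencies under the Balding-Nichols model
#'
#' Given ancestral frequencies `p` and a divergence parameter `fst`, draws
#' per-site subpopulation frequencies from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`. `fst = 0` returns `p`
#' unchanged; `fst = 1` is a degenerate Beta and is an error.
#'
#' @param p Numeric vector of ancestral frequencies in (0, 1).
#' @param fst Divergence in `[0, 1)`.
#' @return Numeric vector of subpopulation frequencies, same length as `p`.
#' @export
draw_bn_frequencies <- function(p, fst) {
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)", call. = FALSE)
  if (fst == 0) return(p)
  k <- (1 - fst) / fst
  rbeta(length(p), p * k, (1 - p) * k)
}

new_haplotype_panel <- function(variants, haplotypes, pop) {
  stopifnot(nrow(variants) == ncol(haplotypes), length(pop) == nrow(haplotypes))
  structure(list(variants = variants, haplotypes = haplotypes, pop = pop),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d sites (pops: %s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              paste(unique(x$pop), collapse = ", ")))
  invisible(x)
}

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

# Recombinant-mosaic copying: each output haplotype copies a founder,
# switching founder between adjacent sites with probability
# 1 - exp(-recomb_rate * distance) (new founder uniform over all founders),
# and flipping the copied allele with probability flip_rate.
mosaic_haplotypes <- function(founders, positions, n_out, recomb_rate, flip_rate) {
  k0 <- nrow(founders)
  m <- ncol(founders)
  stopifnot(length(positions) == m, k0 >= 1)
  s <- if (m > 1) 1 - exp(-recomb_rate * diff(positions)) else numeric(0)
  out <- matrix(0L, nrow = n_out, ncol = m)
  for (h in seq_len(n_out)) {
    start <- sample.int(k0, 1)
    if (m > 1) {
      sw <- runif(m - 1) < s
      # founder is constant between switch points
      idx <- c(1L, which(sw) + 1L)
      founder_at <- c(start,
                      if (length(idx) > 1)
                        sample.int(k0, length(idx) - 1L, replace = TRUE))
      path <- founder_at[findInterval(seq_len(m), idx)]
    } else {
      path <- start
    }
    hap <- founders[cbind(path, seq_len(m))]
    if (flip_rate > 0) {
      fl <- runif(m) < flip_rate
      hap[fl] <- 1L - hap[fl]
    }
    out[h, ] <- hap
  }
  out
}

#' Simulate a subpopulation haplotype panel
#'
#' Draws per-site subpopulation frequencies from the Balding-Nichols model
#' around `ancestral_freqs`, draws `cfg$n_ancestral_haps` founder haplotypes
#' i.i.d. Bernoulli at those frequencies, and emits `n_haps` recombinant
#' mosaics of the founders (switch probability
#' `1 - exp(-recomb_rate * distance)` between adjacent sites, per-site allele
#' flip probability `flip_rate`).
#'
#' @param ancestral_freqs Ancestral allele frequencies (length `n_sites`).
#' @param fst Balding-Nichols divergence in `[0, 1)`.
#' @param cfg A [sim_config()].
#' @param variants Variant table (`chrom`, `pos`, `ref`, `alt`, `vclass`); if
#'   `NULL` a default SNP table on chromosome `"1"` is built.
#' @param n_haps Number of output haplotypes (default: founders themselves
#'   are returned as the panel).
#' @param pop Population label recorded on each haplotype.
#' @param u_field Optional matrix of `n_ancestral_haps` x `length(ancestral_freqs)`
#'   uniforms used to threshold the founder Bernoulli draws
#'   (`founder = u < freq`). Passing the same field to several
#'   subpopulations couples their founder pools — haplotypes then diverge
#'   only where the Balding-Nichols frequencies disagree, emulating shared
#'   ancestry between related populations — without changing any single
#'   panel's marginal distribution. `NULL` draws independent founders.
#' @return A `haplotype_panel` with an extra attribute `subpop_freqs` (the
#'   Balding-Nichols frequency draw) and `founders` (the founder matrix).
#' @export
simulate_subpopulation_panel <- function(ancestral_freqs, fst, cfg,
                                         variants = NULL,
                                         n_haps = cfg$n_ancestral_haps,
                                         pop = "pop",
                                         u_field = NULL) {
  validate_sim_config(cfg)
  m <- length(ancestral_freqs)
  if (is.null(variants)) variants <- default_variant_table(m, cfg$region_length)
  pf <- draw_bn_frequencies(ancestral_freqs, fst)
  if (is.null(u_field))
    u_field <- matrix(runif(cfg$n_ancestral_haps * m), cfg$n_ancestral_haps, m)
  stopifnot(nrow(u_field) == cfg$n_ancestral_haps, ncol(u_field) == m)
  founders <- matrix(0L, cfg$n_ancestral_haps, m)
  founders[u_field < rep(pf, each = cfg$n_ancestral_haps)] <- 1L
  haps <- mosaic_haplotypes(founders, variants$pos, n_haps,
                            cfg$recomb_rate, cfg$flip_rate)
  panel <- new_haplotype_panel(variants, haps, rep(pop, n_haps))
  attr(panel, "subpop_freqs") <- pf
  attr(panel, "founders") <- founders
  panel
}

default_variant_table <- function(m, region_length = max(m, 1) * 2000) {
  pos <- sort(sample.int(region_length, m))
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  data.frame(chrom = "1", pos = pos, ref = ref, alt = unname(alt),
             vclass = "SNP", stringsAsFactors = FALSE)
}

#' Simulate one admixed diploid individual
#'
#' Each of the two haplotypes is generated from `panelA`'s mosaic process
#' with probability `q`, otherwise from `panelB`'s. The haplotypes of the
#' chosen panel act as founders for the mosaic. The true ancestry of each
#' haplotype is recorded.
#'
#' @param panelA,panelB `haplotype_panel` objects over the same variants.
#' @param q Probability that a haplotype descends from `panelA`.
#' @param cfg A [sim_config()] (supplies `recomb_rate`, `flip_rate`).
#' @return List with `haps` (2 x M matrix), `genotype` (length-M 0/1/2),
#'   and `ancestry` (length-2 character, `"A"` or `"B"`).
#' @export
simulate_admixed_individual <- function(panelA, panelB, q, cfg) {
  if (q < 0 || q > 1) stop("q must lie in [0, 1]", call. = FALSE)
  stopifnot(ncol(panelA$haplotypes) == ncol(panelB$haplotypes))
  pos <- panelA$variants$pos
  anc <- ifelse(runif(2) < q, "A", "B")
  haps <- matrix(0L, 2, ncol(panelA$haplotypes))
  for (j in 1:2) {
    src <- if (anc[j] == "A") panelA else panelB
    haps[j, ] <- mosaic_haplotypes(src$haplotypes, pos, 1L,
                                   cfg$recomb_rate, cfg$flip_rate)
  }
  list(haps = haps, genotype = as.integer(haps[1, ] + haps[2, ]), ancestry = anc)
}

#' Select typed (array) sites from truth genotypes
#'
#' The typed set is every `cfg$array_spacing`-th site among sites with cohort
#' MAF at least `cfg$array_maf_min`, in coordinate order. The complement is
#' the untyped evaluation set.
#'
#' @param G Genotype matrix, samples x variants, values 0/1/2.
#' @param cfg A [sim_config()].
#' @return Integer vector of typed site indices (columns of `G`).
#' @export
mask_to_array <- function(G, cfg) {
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  eligible <- which(maf >= cfg$array_maf_min)
  if (length(eligible) == 0)
    stop("mask_to_array: empty typed set; imputation impossible", call. = FALSE)
  typed <- eligible[seq(1, length(eligible), by = cfg$array_spacing)]
  typed
}

#' Simulate binary phenotypes under a logistic model
#'
#' `logit P(case) = b0 + sum(beta * dosage)` with `b0` chosen by bisection so
#' that the expected prevalence over the cohort equals `cfg$case_fraction`.
#' With no causal effects the model is null: cases are Bernoulli draws at the
#' target prevalence.
#'
#' @param G Genotype/dosage matrix, samples x variants.
#' @param cfg A [sim_config()] with optional `causal_effects` (site, beta).
#' @return Integer 0/1 vector of length `nrow(G)`.
#' @export
simulate_phenotypes <- function(G, cfg) {
  n <- nrow(G)
  ce <- cfg$causal_effects
  if (is.null(ce) || nrow(as.data.frame(ce)) == 0)
    return(rbinom(n, 1L, cfg$case_fraction))
  ce <- as.data.frame(ce)
  if (any(ce[[1]] < 1 | ce[[1]] > ncol(G)))
    stop("causal site index out of range", call. = FALSE)
  eta <- as.numeric(G[, ce[[1]], drop = FALSE] %*% ce[[2]])
  f <- function(b0) mean(plogis(b0 + eta)) - cfg$case_fraction
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("requested prevalence unattainable under the effect model", call. = FALSE)
  b0 <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  rbinom(n, 1L, plogis(b0 + eta))
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates the full generative model: shared variant map and ancestral
#' frequencies, per-subpopulation Balding-Nichols divergence with founder
#' haplotypes, reference panels and target individuals as recombinant
#' mosaics of those founders, optional admixed targets mixing the first two
#' subpopulations, an array mask, and phenotypes. Everything is a pure
#' function of `cfg` (and `n_ref_haps`): identical inputs give bit-identical
#' output.
#'
#' @param cfg A [sim_config()].
#' @param n_ref_haps Number of reference haplotypes emitted per
#'   subpopulation panel.
#' @return A `sim_cohort` list: `variants`, `af_ancestral`, `panels` (one
#'   `haplotype_panel` per subpopulation), `target_haps` (2N x M phased),
#'   `truth_G` (N x M), `samples`, `pop`, `q_true` (true first-population
#'   ancestry fraction per individual), `typed_idx`, `phenotype`, `cfg`.
#' @export
simulate_cohort <- function(cfg, n_ref_haps = 60L) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  m <- cfg$n_sites
  variants <- default_variant_table(m, cfg$region_length)
  p_anc <- draw_ancestral_frequencies(cfg)
  n_pop <- length(cfg$pop_sizes)
  pop_names <- paste0("POP", seq_len(n_pop))

  # shared uniform field couples the founder pools: subpopulations share
  # haplotype structure and diverge only where their BN frequencies differ
  u_field <- matrix(runif(cfg$n_ancestral_haps * m), cfg$n_ancestral_haps, m)
  panels <- vector("list", n_pop)
  founders <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    panels[[i]] <- simulate_subpopulation_panel(
      p_anc, cfg$fst_per_pop[i], cfg, variants = variants,
      n_haps = n_ref_haps, pop = pop_names[i], u_field = u_field)
    founders[[i]] <- attr(panels[[i]], "founders")
  }
  names(panels) <- pop_names

  n_total <- sum(cfg$pop_sizes)
  pop_of <- rep(pop_names, cfg$pop_sizes)
  n_admixed <- if (n_pop >= 2) round(cfg$admixed_fraction * n_total) else 0L
  is_admixed <- seq_len(n_total) > (n_total - n_admixed)

  target_haps <- matrix(0L, nrow = 2 * n_total, ncol = m)
  q_true <- numeric(n_total)
  for (ind in seq_len(n_total)) {
    rows <- c(2 * ind - 1, 2 * ind)
    if (is_admixed[ind]) {
      anc <- ifelse(runif(2) < cfg$admix_q, 1L, 2L)
      for (j in 1:2)
        target_haps[rows[j], ] <- mosaic_haplotypes(
          founders[[anc[j]]], variants$pos, 1L, cfg$recomb_rate, cfg$flip_rate)
      q_true[ind] <- mean(anc == 1L)
      pop_of[ind] <- "ADMIX"
    } else {
      i <- match(pop_of[ind], pop_names)
      target_haps[rows, ] <- mosaic_haplotypes(
        founders[[i]], variants$pos, 2L, cfg$recomb_rate, cfg$flip_rate)
      q_true[ind] <- if (i == 1L) 1 else 0
    }
  }
  truth_G <- target_haps[seq(1, 2 * n_total, by = 2), , drop = FALSE] +
    target_haps[seq(2, 2 * n_total, by = 2), , drop = FALSE]
  storage.mode(truth_G) <- "integer"
  samples <- sprintf("S%04d", seq_len(n_total))
  rownames(truth_G) <- samples

  typed_idx <- mask_to_array(truth_G, cfg)
  phenotype <- simulate_phenotypes(truth_G, cfg)

  structure(list(variants = variants, af_ancestral = p_anc, panels = panels,
                 target_haps = target_haps, truth_G = truth_G,
                 samples = samples, pop = pop_of, q_true = q_true,
                 typed_idx = typed_idx, phenotype = phenotype, cfg = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d individuals x %d sites (%d typed), %d panels\n",
              nrow(x$truth_G), ncol(x$truth_G), length(x$typed_idx),
              length(x$panels)))
  invisible(x)
}

#' Write a simulated cohort to VCF/TSV files
#'
#' Emits the truth VCF (phased GT), one phased panel VCF per subpopulation,
#' the array VCF (unphased GT restricted to typed sites), the
#' allele-frequency table (`CHROM POS REF ALT AF`, gnomAD role), the
#' phenotype table (`SAMPLE STATUS`), and the YAML config. Reading the VCFs
#' back reproduces the genotype matrices exactly.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohort$variants
  paths <- list(
    truth = file.path(dir, "truth.vcf"),
    array = file.path(dir, "array.vcf"),
    af = file.path(dir, "af_table.tsv"),
    pheno = file.path(dir, "phenotypes.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_vcf_haps(paths$truth, v, cohort$target_haps, cohort$samples)
  typed <- cohort$typed_idx
  write_vcf_geno(paths$array, v[typed, , drop = FALSE],
                 cohort$truth_G[, typed, drop = FALSE], cohort$samples)
  for (nm in names(cohort$panels)) {
    p <- cohort$panels[[nm]]
    paths[[paste0("panel_", nm)]] <- file.path(dir, sprintf("panel_%s.vcf", nm))
    hap_ids <- sprintf("%s_%03d", nm, seq_len(nrow(p$haplotypes) / 2))
    write_vcf_haps(paths[[paste0("panel_", nm)]], p$variants, p$haplotypes, hap_ids)
  }
  af <- data.frame(CHROM = v$chrom, POS = v$pos, REF = v$ref, ALT = v$alt,
                   AF = cohort$af_ancestral)
  write.table(af, paths$af, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(SAMPLE = cohort$samples, STATUS = cohort$phenotype)
  write.table(ph, paths$pheno, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sim_config(cohort$cfg, paths$config)
  invisible(paths)
}
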