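#' Parameters of the Li-Stephens copying model
#'
#' The imputer models a target haplotype as a recombinant, slightly mutated
#' mosaic of the `K` reference haplotypes. Between adjacent sites at
#' distance `d` the copied haplotype switches with probability
#' `s = 1 - exp(-rho * d / K)` (switching lands on each state with
#' probability `s / K`); at typed sites the observed allele matches the
#' copied haplotype with probability `1 - err`.
#'
#' @param err Emission mismatch probability in (0, 0.5).
#' @param rho Per-base recombination intensity. `NULL` (default)
#'   auto-calibrates per panel so that the expected number of copying
#'   switches is about one per 10,000 sites.
#' @return An `ls_params` list.
#' @export
ls_params <- function(err = 0.01, rho = NULL) {
  if (err <= 0 || err >= 0.5) stop("err must lie in (0, 0.5)", call. = FALSE)
  if (!is.null(rho) && rho <= 0) stop("rho must be positive", call. = FALSE)
  structure(list(err = err, rho = rho), class = "ls_params")
}

resolve_rho <- function(params, panel_haps, pos) {
  if (!is.null(params$rho)) return(params$rho)
  k <- nrow(panel_haps)
  m <- length(pos)
  total_d <- max(sum(pmax(diff(pos), 1)), 1)
  # expected switches ~ rho * total_d / K == m / 1e4
  k * (m / 1e4) / total_d
}

as_panel_haps <- function(panel) {
  if (inherits(panel, "haplotype_panel")) panel$haplotypes else panel
}

#' Copying-state posteriors and allele probabilities for one haplotype
#'
#' Runs the scaled forward-backward algorithm over the full panel site
#' lattice: typed sites emit the observed target allele, untyped sites emit
#' uniformly. The alt-allele probability at site `m` is
#' `sum_k gamma_k(m) * panel_k(m)`, with the mismatch correction
#' `(1 - err) * p + err * (1 - p)` applied at typed sites.
#'
#' @param target_alleles Observed 0/1 alleles at the typed sites.
#' @param typed_idx Indices (columns of the panel) of the typed sites,
#'   strictly increasing; must be a subset of the panel sites.
#' @param panel A `haplotype_panel` or K x M 0/1 matrix.
#' @param params [ls_params()].
#' @param pos Optional site positions (default: taken from the panel's
#'   variant table, else `1:M`).
#' @return List: `gamma` (M x K posterior matrix, rows sum to 1) and
#'   `allele_prob` (length M).
#' @export
ls_posteriors <- function(target_alleles, typed_idx, panel, params = ls_params(),
                          pos = NULL) {
  haps <- as_panel_haps(panel)
  if (is.null(dim(haps)) || nrow(haps) == 0)
    stop("ls_posteriors: empty reference panel", call. = FALSE)
  m <- ncol(haps)
  if (is.null(pos)) {
    pos <- if (inherits(panel, "haplotype_panel")) panel$variants$pos else seq_len(m)
  }
  typed_idx <- as.integer(typed_idx)
  if (length(typed_idx) != length(target_alleles))
    stop("target_alleles and typed_idx lengths differ", call. = FALSE)
  if (any(typed_idx < 1 | typed_idx > m))
    stop("typed site outside the panel site lattice", call. = FALSE)
  if (is.unsorted(typed_idx, strictly = TRUE))
    stop("typed_idx must be strictly increasing", call. = FALSE)
  rho <- resolve_rho(params, haps, pos)
  storage.mode(haps) <- "integer"
  gamma <- .ls_fb_cpp(haps, as.numeric(pos), typed_idx - 1L,
                      as.integer(target_alleles), rho, params$err)
  p <- rowSums(gamma * t(haps))
  p[typed_idx] <- (1 - params$err) * p[typed_idx] + params$err * (1 - p[typed_idx])
  list(gamma = gamma, allele_prob = pmin(pmax(p, 0), 1))
}

#' Impute one pre-phased diploid individual
#'
#' Runs [ls_posteriors()] on each haplotype. With haploid alt probabilities
#' `a1, a2`, the genotype probabilities are
#' `((1-a1)(1-a2), a1(1-a2) + a2(1-a1), a1 a2)` and the dosage is
#' `a1 + a2`. Typed sites keep the observed genotype as the hard call.
#'
#' @param hap1,hap2 Observed 0/1 alleles of the two haplotypes at the typed
#'   sites.
#' @param typed_idx Typed site indices into the panel lattice.
#' @param panel `haplotype_panel` or K x M matrix.
#' @param params [ls_params()].
#' @param pos Optional site positions.
#' @return List: `dosage` (length M), `probs` (M x 3), `hard_call`
#'   (length M), `hap_probs` (2 x M haploid alt probabilities).
#' @export
impute_diploid <- function(hap1, hap2, typed_idx, panel, params = ls_params(),
                           pos = NULL) {
  a1 <- ls_posteriors(hap1, typed_idx, panel, params, pos)$allele_prob
  a2 <- ls_posteriors(hap2, typed_idx, panel, params, pos)$allele_prob
  probs <- cbind((1 - a1) * (1 - a2), a1 * (1 - a2) + a2 * (1 - a1), a1 * a2)
  hc <- hard_call(probs)
  hc[typed_idx] <- as.integer(hap1 + hap2)
  list(dosage = a1 + a2, probs = probs, hard_call = hc,
       hap_probs = rbind(a1, a2))
}

#' Hard-call genotypes from posterior probabilities
#'
#' Argmax over the genotype-probability triple; ties break toward the
#' smaller genotype code.
#'
#' @param probs Numeric triple, or an n x 3 matrix of triples.
#' @return Integer genotype(s) in 0/1/2.
#' @export
hard_call <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  stopifnot(ncol(probs) == 3)
  as.integer(max.col(probs, ties.method = "first") - 1L)
}

#' Minimac-style estimated R-squared for one variant
#'
#' The ratio of the empirical variance of the haploid alt-allele
#' probabilities (denominator `2N`) to the binomial variance
#' `p_hat (1 - p_hat)` expected if alleles were known. Monomorphic variants
#' (`p_hat (1 - p_hat) = 0`) get 0; the result is clipped to `[0, 1]`.
#'
#' @param hap_probs Haploid alt-allele probabilities across the `2N` target
#'   haplotypes at one variant.
#' @return Estimated R-squared in `[0, 1]`.
#' @export
estimate_r2 <- function(hap_probs) {
  if (length(hap_probs) < 2) stop("estimate_r2: need at least 2 haplotypes", call. = FALSE)
  p <- mean(hap_probs)
  denom <- p * (1 - p)
  if (denom <= 0) return(0)
  v <- mean((hap_probs - p)^2)
  min(max(v / denom, 0), 1)
}

new_imputed_dataset <- function(variants, dosages, genotype_probs, hard_calls,
                                est_r2, typed_flag, samples) {
  structure(list(variants = variants, dosages = dosages,
                 genotype_probs = genotype_probs, hard_calls = hard_calls,
                 est_r2 = est_r2, typed_flag = typed_flag, samples = samples),
            class = "imputed_dataset")
}

#' @export
print.imputed_dataset <- function(x, ...) {
  cat(sprintf("imputed_dataset: %d samples x %d variants (%d typed), median R2 %.3f\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$typed_flag),
              median(x$est_r2)))
  invisible(x)
}

#' Impute a cohort of pre-phased targets against a reference panel
#'
#' Applies [impute_diploid()] to every target individual and assembles an
#' `imputed_dataset`: dosages, genotype probabilities, hard calls, a
#' per-variant Minimac-style estimated R-squared computed from the haploid
#' allele probabilities of all `2N` target haplotypes, and a typed flag.
#'
#' @param target_haps 2N x T matrix of observed target alleles at the typed
#'   sites (rows `2i-1, 2i` = haplotypes of individual `i`), or a 2N x M
#'   matrix from which the typed columns are taken.
#' @param typed_idx Typed site indices into the panel lattice.
#' @param panel `haplotype_panel` (supplies variants/positions) or matrix.
#' @param params [ls_params()].
#' @param samples Optional sample names.
#' @return An `imputed_dataset`.
#' @export
impute_cohort <- function(target_haps, typed_idx, panel, params = ls_params(),
                          samples = NULL) {
  haps <- as_panel_haps(panel)
  m <- ncol(haps)
  if (ncol(target_haps) == m) {
    target_haps <- target_haps[, typed_idx, drop = FALSE]
  } else if (ncol(target_haps) != length(typed_idx)) {
    stop("target_haps must cover the typed sites or the full lattice", call. = FALSE)
  }
  n <- nrow(target_haps) / 2
  if (n != floor(n)) stop("target_haps must have an even number of rows", call. = FALSE)
  n <- as.integer(n)
  variants <- if (inherits(panel, "haplotype_panel")) panel$variants else
    default_minimal_variants(m)
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(n))

  dosages <- matrix(0, n, m, dimnames = list(samples, NULL))
  hard <- matrix(0L, n, m, dimnames = list(samples, NULL))
  probs <- array(0, c(n, m, 3))
  hapP <- matrix(0, 2 * n, m)
  for (i in seq_len(n)) {
    r <- impute_diploid(target_haps[2 * i - 1, ], target_haps[2 * i, ],
                        typed_idx, panel, params)
    dosages[i, ] <- r$dosage
    hard[i, ] <- r$hard_call
    probs[i, , ] <- r$probs
    hapP[c(2 * i - 1, 2 * i), ] <- r$hap_probs
  }
  r2 <- apply(hapP, 2, estimate_r2)
  typed <- rep(FALSE, m); typed[typed_idx] <- TRUE
  new_imputed_dataset(variants, dosages, probs, hard, r2, typed, samples)
}

default_minimal_variants <- function(m) {
  data.frame(chrom = "1", pos = seq_len(m), ref = "A", alt = "G",
             vclass = "SNP", stringsAsFactors = FALSE)
}
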