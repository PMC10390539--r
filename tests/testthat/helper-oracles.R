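# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithmic routes.

# Exhaustive path-sum posterior for the haplotype-copying HMM: enumerates
# all K^M copying paths and sums joint probabilities.
oracle_ls_posteriors <- function(obs, typed_idx, panel, pos, rho, err) {
  K <- nrow(panel); M <- ncol(panel)
  typed_at <- rep(NA_integer_, M); typed_at[typed_idx] <- obs
  s <- c(NA, 1 - exp(-rho * pmax(diff(pos), 1) / K))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))
  w <- rep(1 / K, nrow(paths))
  for (m in seq_len(M)) {
    if (!is.na(typed_at[m]))
      w <- w * ifelse(panel[cbind(paths[, m], m)] == typed_at[m], 1 - err, err)
    if (m > 1) {
      stay <- paths[, m] == paths[, m - 1]
      w <- w * ifelse(stay, 1 - s[m] + s[m] / K, s[m] / K)
    }
  }
  gamma <- matrix(0, M, K)
  for (m in seq_len(M)) for (k in seq_len(K))
    gamma[m, k] <- sum(w[paths[, m] == k])
  gamma / rowSums(gamma)
}

# HWE configuration probabilities by the direct log-factorial formula
# (vs the package's adjacent-ratio recurrence).
oracle_hwe_pvalues <- function(n, n_minor) {
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  hom_min <- (n_minor - hets) / 2
  hom_maj <- n - hets - hom_min
  lp <- lgamma(n + 1) - lgamma(hom_maj + 1) - lgamma(hets + 1) -
    lgamma(hom_min + 1) + hets * log(2) +
    lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  pv <- vapply(seq_along(hets), function(i)
    min(sum(pr[pr <= pr[i] * (1 + 1e-9)]), 1), numeric(1))
  list(hets = hets, hom_min = hom_min, hom_maj = hom_maj, p = pv)
}

# Cochran-Armitage trend chi-square from the 2x3 contingency table.
oracle_trend_chisq <- function(g, y) {
  tab <- table(factor(y, 0:1), factor(g, 0:2))
  w <- 0:2; N <- sum(tab); R <- sum(tab[2, ])
  cs <- colSums(tab)
  Tstat <- sum(w * tab[2, ]) - R * sum(w * cs) / N
  Vt <- R * (N - R) / N * (sum(w^2 * cs) - sum(w * cs)^2 / N) / N
  Tstat^2 / Vt
}

# Hudson-style FST from two subpopulation frequency vectors (true
# frequencies: no sampling correction needed).
oracle_hudson_fst <- function(p1, p2) {
  sum((p1 - p2)^2) / sum(p1 * (1 - p2) + p2 * (1 - p1))
}

# GRM entry by the direct per-pair formula.
oracle_grm <- function(G) {
  p <- colMeans(G) / 2
  keep <- p > 0 & p < 1
  G <- G[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(G); M <- ncol(G)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n))
    A[j, k] <- mean((G[j, ] - 2 * p) * (G[k, ] - 2 * p) / (2 * p * (1 - p)))
  A
}

# A small standard cohort for cross-module tests.
small_cohort <- function(seed = 1, n_sites = 400, pop_sizes = c(20, 20),
                         n_ref_haps = 120, ...) {
  cfg <- sim_config(seed = seed, n_sites = n_sites, pop_sizes = pop_sizes,
                    region_length = 2e6, recomb_rate = 3e-6,
                    n_ancestral_haps = 100, ...)
  simulate_cohort(cfg, n_ref_haps = n_ref_haps)
}

# One matched-vs-mismatched replicate of the panel experiment; used by the
# acceptance suite and by the replicate-level unit checks.
panel_experiment_rep <- function(seed, n_sites = 3000, n_targets = 25,
                                 n_ref_haps = 200, fst = 0.05) {
  cfg <- sim_config(seed = seed, n_sites = n_sites,
                    pop_sizes = c(n_targets, n_targets), region_length = 6e6,
                    recomb_rate = 3e-6, n_ancestral_haps = 100,
                    fst_per_pop = c(fst, fst))
  co <- simulate_cohort(cfg, n_ref_haps = n_ref_haps)
  typed <- co$typed_idx
  ev <- setdiff(seq_len(n_sites), typed)
  ia <- which(co$pop == "POP1")
  hr <- as.vector(rbind(2 * ia - 1, 2 * ia))
  params <- ls_params(err = 0.01, rho = n_ref_haps * cfg$recomb_rate)
  impA <- impute_cohort(co$target_haps[hr, ], typed, co$panels$POP1, params,
                        samples = co$samples[ia])
  impB <- impute_cohort(co$target_haps[hr, ], typed, co$panels$POP2, params,
                        samples = co$samples[ia])
  truth <- co$truth_G[ia, , drop = FALSE]
  gA <- gcr_per_sample(impA$hard_calls, truth, ev)
  gB <- gcr_per_sample(impB$hard_calls, truth, ev)
  r2 <- pooled_r2_by_bin(impB$dosages[, ev, drop = FALSE],
                         truth[, ev, drop = FALSE], co$af_ancestral[ev])$r2
  strat <- gcr_by_stratum(impA, truth, ev)
  list(cohort = co, impA = impA, impB = impB, truth = truth, eval_idx = ev,
       gcr_matched = gA, gcr_mismatched = gB,
       r2_bins = r2,
       gcr_highconf = median(strat[[5]]$gcr, na.rm = TRUE),
       gcr_overall = median(gA, na.rm = TRUE))
}

# Memoized 20-replicate experiment shared by several acceptance blocks.
.exp_cache <- new.env(parent = emptyenv())
panel_experiment_20 <- function() {
  if (is.null(.exp_cache$res)) {
    .exp_cache$res <- lapply(1:20, function(s) {
      r <- panel_experiment_rep(1000 + s)
      r$cohort <- NULL; r$impA <- NULL; r$impB <- NULL; r$truth <- NULL
      r
    })
  }
  .exp_cache$res
}
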