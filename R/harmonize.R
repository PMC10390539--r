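REVCOMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_allele <- function(a) {
  out <- REVCOMP[a]
  if (any(is.na(out))) stop("malformed allele: ", paste(a[is.na(out)], collapse = ","),
                            call. = FALSE)
  unname(out)
}

is_palindromic <- function(ref, alt) revcomp_allele(ref) == alt

#' Classify one array/panel variant pair for harmonization
#'
#' Reconciles an array record with the matching panel record (same
#' chromosome and position): keep as is, flip strand (reverse-complement),
#' swap ref/alt, both, or exclude. Palindromic (A/T, C/G) pairs are
#' strand-ambiguous and are resolved by allele frequency: excluded when
#' either MAF is at least `palindromic_maf_max`, otherwise oriented by
#' which side of 0.5 the frequencies fall on. After orientation, pairs
#' whose allele frequencies still differ by more than `af_diff_max` are
#' excluded as discrepant.
#'
#' @param array_rec,panel_rec Lists/rows with `ref`, `alt`, `af`
#'   (alt-allele frequency).
#' @param af_diff_max Maximum post-orientation allele-frequency difference.
#' @param palindromic_maf_max MAF ceiling for keeping palindromic pairs.
#' @return List with `action` (one of `keep`, `strand_flip`, `allele_swap`,
#'   `flip_and_swap`, `exclude`) and `reason` (`NA` unless excluded).
#' @export
classify_variant <- function(array_rec, panel_rec, af_diff_max = 0.20,
                             palindromic_maf_max = 0.40) {
  ra <- toupper(array_rec$ref); aa <- toupper(array_rec$alt)
  rp <- toupper(panel_rec$ref); ap <- toupper(panel_rec$alt)
  ok <- function(x) x %in% names(REVCOMP)
  if (!all(ok(c(ra, aa, rp, ap))))
    stop("malformed alleles (SNPs with A/C/G/T expected)", call. = FALSE)
  res <- function(action, reason = NA_character_)
    list(action = action, reason = reason)

  af_a <- array_rec$af; af_p <- panel_rec$af

  if (is_palindromic(ra, aa)) {
    if (!is_palindromic(rp, ap) || !setequal(c(ra, aa), c(rp, ap)))
      return(res("exclude", "allele_mismatch"))
    maf_a <- min(af_a, 1 - af_a); maf_p <- min(af_p, 1 - af_p)
    if (maf_a >= palindromic_maf_max || maf_p >= palindromic_maf_max)
      return(res("exclude", "palindromic_ambiguous"))
    same_side <- (af_a < 0.5) == (af_p < 0.5)
    # for a palindrome, written alleles are preserved by {keep, flip_and_swap}
    # and exchanged by {strand_flip, allele_swap}; the AF side picks within
    # each pair
    action <- if (ra == rp) {
      if (same_side) "keep" else "flip_and_swap"
    } else {
      if (same_side) "strand_flip" else "allele_swap"
    }
    af_oriented <- if (action %in% c("allele_swap", "flip_and_swap")) 1 - af_a else af_a
    if (abs(af_oriented - af_p) > af_diff_max)
      return(res("exclude", "af_discrepant"))
    return(res(action))
  }

  fra <- revcomp_allele(ra); faa <- revcomp_allele(aa)
  action <- if (ra == rp && aa == ap) "keep"
    else if (fra == rp && faa == ap) "strand_flip"
    else if (ra == ap && aa == rp) "allele_swap"
    else if (fra == ap && faa == rp) "flip_and_swap"
    else return(res("exclude", "allele_mismatch"))
  af_oriented <- if (action %in% c("allele_swap", "flip_and_swap")) 1 - af_a else af_a
  if (abs(af_oriented - af_p) > af_diff_max)
    return(res("exclude", "af_discrepant"))
  res(action)
}

#' Harmonize an array variant table against a panel table
#'
#' Matches records on (chrom, pos); unmatched array records are excluded
#' with reason `position_mismatch`, duplicated array positions with reason
#' `duplicate`, and matched pairs are classified by [classify_variant()].
#'
#' @param array_tab,panel_tab Data frames with `chrom`, `pos`, `ref`,
#'   `alt`, `af`.
#' @inheritParams classify_variant
#' @return Data frame: array record columns plus `action` and `reason`.
#' @export
harmonize_variants <- function(array_tab, panel_tab, af_diff_max = 0.20,
                               palindromic_maf_max = 0.40) {
  key_a <- paste(array_tab$chrom, array_tab$pos)
  key_p <- paste(panel_tab$chrom, panel_tab$pos)
  action <- character(nrow(array_tab)); reason <- rep(NA_character_, nrow(array_tab))
  dup <- duplicated(key_a) | duplicated(key_a, fromLast = TRUE)
  for (i in seq_len(nrow(array_tab))) {
    if (dup[i]) { action[i] <- "exclude"; reason[i] <- "duplicate"; next }
    j <- match(key_a[i], key_p)
    if (is.na(j)) { action[i] <- "exclude"; reason[i] <- "position_mismatch"; next }
    cl <- classify_variant(array_tab[i, ], panel_tab[j, ],
                           af_diff_max, palindromic_maf_max)
    action[i] <- cl$action; reason[i] <- cl$reason
  }
  cbind(array_tab, action = action, reason = reason)
}

#' Apply a harmonization action to an array record
#'
#' Returns the record re-oriented to the panel convention: strand flips
#' reverse-complement both alleles, allele swaps exchange ref/alt and
#' complement the allele frequency.
#'
#' @param rec List/row with `ref`, `alt`, `af`.
#' @param action A `classify_variant()` action.
#' @return The oriented record (unchanged for `keep`; `NULL` for `exclude`).
#' @export
apply_harmonization <- function(rec, action) {
  if (action == "exclude") return(NULL)
  if (action %in% c("strand_flip", "flip_and_swap")) {
    rec$ref <- revcomp_allele(rec$ref); rec$alt <- revcomp_allele(rec$alt)
  }
  if (action %in% c("allele_swap", "flip_and_swap")) {
    tmp <- rec$ref; rec$ref <- rec$alt; rec$alt <- tmp
    rec$af <- 1 - rec$af
  }
  rec
}

#' Remove samples by genotype missingness
#'
#' A sample is removed iff its fraction of missing calls is strictly
#' greater than `max_miss`.
#'
#' @param G Genotype matrix (samples x variants), `NA` = missing.
#' @param max_miss Missingness ceiling (strict inequality).
#' @return List: `kept` (row indices), `report` (data frame of removals).
#' @export
sample_missingness_filter <- function(G, max_miss = 0.05) {
  miss <- rowMeans(is.na(G))
  drop <- which(miss > max_miss)
  list(kept = setdiff(seq_len(nrow(G)), drop),
       report = data.frame(sample = rownames(G)[drop] %||% as.character(drop),
                           reason = rep("missingness", length(drop)),
                           value = miss[drop], row.names = NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genomic relatedness matrix (GCTA-style standardized GRM)
#'
#' `A_jk = (1/M') sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over polymorphic sites `M'`; missing genotypes contribute nothing and
#' each pair is scaled by its number of complete polymorphic sites.
#'
#' @param G Genotype matrix (samples x variants, 0/1/2, `NA` allowed).
#' @return Symmetric n x n relatedness matrix.
#' @export
grm_matrix <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all sites monomorphic; relatedness undefined", call. = FALSE)
  Gp <- G[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(Gp, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  miss <- is.na(Z)
  Z[miss] <- 0
  num <- Z %*% t(Z)
  mcount <- (!miss) %*% t(!miss)  # complete polymorphic sites per pair
  A <- num / pmax(mcount, 1)
  A[mcount == 0] <- NA
  A
}

#' Prune related samples
#'
#' Iteratively removes the sample participating in the most pairs with
#' relatedness above `cutoff` (ties broken by higher missingness, then by
#' later sample order) until no pair exceeds the cutoff.
#'
#' @param G Genotype matrix (samples x variants).
#' @param cutoff Relatedness threshold (pairs with `A > cutoff` offend).
#' @return List: `kept` (row indices), `removed`, `report`, `A` (the GRM).
#' @export
relatedness_prune <- function(G, cutoff = 0.5) {
  if (nrow(G) < 2) stop("need at least 2 samples", call. = FALSE)
  A <- grm_matrix(G)
  miss <- rowMeans(is.na(G))
  active <- rep(TRUE, nrow(G))
  removed <- integer(0)
  repeat {
    Aw <- A; diag(Aw) <- NA
    Aw[!active, ] <- NA; Aw[, !active] <- NA
    offending <- which(Aw > cutoff, arr.ind = TRUE)
    if (nrow(offending) == 0) break
    counts <- tabulate(offending[, 1], nbins = nrow(G))
    cand <- which(counts == max(counts))
    if (length(cand) > 1) cand <- cand[miss[cand] == max(miss[cand])]
    drop <- max(cand)  # later sample order last tie-break
    active[drop] <- FALSE
    removed <- c(removed, drop)
  }
  list(kept = which(active), removed = removed,
       report = data.frame(sample = rownames(G)[removed] %||% as.character(removed),
                           reason = rep("relatedness", length(removed)),
                           row.names = NULL),
       A = A)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact conditional test: all heterozygote counts consistent
#' with the observed allele counts are enumerated, each configuration is
#' weighted by its probability under the hypergeometric null of
#' Hardy-Weinberg equilibrium, and the p-value is the total probability of
#' configurations no more likely than the observed one. Monomorphic sites
#' return 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (hom-ref, het, hom-alt).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("empty genotype table", call. = FALSE)
  n_alt <- 2 * n_aa + n_Aa
  probs <- hwe_het_distribution(n, min(n_alt, 2 * n - n_alt))
  obs_p <- probs[as.character(n_Aa)]
  if (is.na(obs_p)) stop("inconsistent genotype counts", call. = FALSE)
  # "<=" with a small relative tolerance so exact rational ties are kept
  # together regardless of floating-point evaluation order
  min(sum(probs[probs <= obs_p * (1 + 1e-9)]), 1)
}

# Distribution of the heterozygote count given n genotypes and n_minor
# minor alleles, by the standard stable recurrence (ratios of adjacent
# configuration probabilities), normalized at the end.
hwe_het_distribution <- function(n, n_minor) {
  if (n_minor == 0) return(setNames(1, "0"))
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i]
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    # P(h) / P(h-2) = 4 * (hom_min + 1) * (hom_maj + 1) / (h * (h - 1))
    lp[i] <- lp[i - 1] + log(4 * (hom_min + 1) * (hom_maj + 1)) - log(h) - log(h - 1)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  setNames(p, as.character(hets))
}

#' Site-level QC of truth (WGS) genotypes
#'
#' Drops sites with a non-PASS FILTER, site missingness strictly greater
#' than `max_site_miss`, or a Hardy-Weinberg exact p-value below
#' `hwe_p_min`. Site order is preserved.
#'
#' @param G Genotype matrix (samples x variants).
#' @param filter Per-variant FILTER strings (`"PASS"` or `"."` pass).
#' @param max_site_miss Missingness ceiling (strict inequality).
#' @param hwe_p_min Minimum HWE exact p-value.
#' @return List: `kept` (column indices), `report` (removed sites with
#'   reasons), `thresholds`.
#' @export
wgs_site_qc <- function(G, filter = NULL, max_site_miss = 0.10, hwe_p_min = 1e-6) {
  m <- ncol(G)
  if (is.null(filter)) filter <- rep("PASS", m)
  reason <- rep(NA_character_, m)
  fail_filter <- !(filter %in% c("PASS", "."))
  reason[fail_filter] <- "filter"
  miss <- colMeans(is.na(G))
  fail_miss <- is.na(reason) & miss > max_site_miss
  reason[fail_miss] <- "missingness"
  for (j in which(is.na(reason))) {
    g <- G[, j]
    p <- hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                        sum(g == 2, na.rm = TRUE))
    if (p < hwe_p_min) reason[j] <- "hwe"
  }
  kept <- which(is.na(reason))
  list(kept = kept,
       report = data.frame(site = which(!is.na(reason)),
                           reason = reason[!is.na(reason)], row.names = NULL),
       thresholds = list(max_site_miss = max_site_miss, hwe_p_min = hwe_p_min))
}

#' Intersect evaluation sites across imputed datasets and QCed truth
#'
#' Evaluation sites are the variants (keyed by chrom:pos:ref:alt) present
#' in the QC-passing truth set and in every imputed dataset, ordered by
#' coordinate.
#'
#' @param imputed_list List of `imputed_dataset` objects (or variant
#'   tables).
#' @param truth_variants QCed truth variant table.
#' @return Character vector of variant keys (possibly empty, with a
#'   warning).
#' @export
intersect_evaluation_sites <- function(imputed_list, truth_variants) {
  keys <- variant_key(truth_variants)
  ord_tab <- truth_variants
  for (imp in imputed_list) {
    v <- if (inherits(imp, "imputed_dataset")) imp$variants else imp
    keys <- intersect(keys, variant_key(v))
  }
  if (length(keys) == 0) {
    warning("empty evaluation-site intersection")
    return(character(0))
  }
  sel <- ord_tab[variant_key(ord_tab) %in% keys, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$pos), , drop = FALSE]
  variant_key(sel)
}
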