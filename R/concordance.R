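#' Allele-frequency bin specification
#'
#' Bins are defined by a strictly decreasing vector of edges. With edges
#' `e1 > e2 > ... > eL` the bins are `[e2, e1]`, `[e3, e2)`, ...,
#' `(0, eL)` plus the final catch-all below the last edge. The coarse
#' default `{1, 0.05, 0.01}` gives common `[0.05, 1]`, low-frequency
#' `[0.01, 0.05)` and rare `(0, 0.01)` variants; the fine default subdivides
#' the rare range at 0.001 steps.
#'
#' @param edges Strictly decreasing numeric vector of bin edges, or one of
#'   the shorthand names `"coarse"` / `"fine"`.
#' @return A `bin_spec` object with `edges` and human-readable `labels`.
#' @export
bin_spec <- function(edges = "coarse") {
  if (is.character(edges)) {
    edges <- switch(match.arg(edges, c("coarse", "fine")),
                    coarse = c(1, 0.05, 0.01),
                    fine = c(0.01, 0.009, 0.008, 0.007, 0.006, 0.005,
                             0.004, 0.003, 0.002, 0.001))
  }
  if (any(diff(edges) >= 0)) stop("bin edges must be strictly decreasing", call. = FALSE)
  L <- length(edges)
  labels <- c(sprintf("[%g,%g]", edges[2], edges[1]),
              if (L > 2) sprintf("[%g,%g)", edges[-(1:2)], edges[2:(L - 1)]),
              sprintf("(0,%g)", edges[L]))
  structure(list(edges = edges, labels = labels), class = "bin_spec")
}

#' Assign allele frequencies to bins
#'
#' @param af Numeric vector of allele frequencies in (0, 1].
#' @param bins A [bin_spec()].
#' @return Factor of bin labels (`NA` for frequencies above the top edge
#'   or non-positive).
#' @export
bin_af <- function(af, bins = bin_spec()) {
  e <- bins$edges
  idx <- rep(NA_integer_, length(af))
  ok <- !is.na(af) & af > 0 & af <= e[1]
  # bin i: af in [e[i+1], e[i]), top bin closed at e[1], catch-all below e[L]
  idx[ok] <- findInterval(-af[ok], -e, left.open = TRUE)
  idx[ok & af == e[1]] <- 1L
  factor(bins$labels[idx], levels = bins$labels)
}

#' Per-sample genotype concordance rate
#'
#' `GCR_s` is the fraction of evaluation sites at which the imputed
#' hard-call diploid genotype equals the truth genotype, among sites where
#' the truth is non-missing for that sample. Missing imputed calls count
#' as discordant; samples with an empty denominator get `NA`.
#'
#' @param imputed_hc Imputed hard-call matrix (samples x variants).
#' @param truth_G Truth genotype matrix (same shape; `NA` = missing truth).
#' @param eval_idx Column indices of the evaluation sites (default: all).
#' @return Named numeric vector of per-sample GCRs.
#' @export
gcr_per_sample <- function(imputed_hc, truth_G, eval_idx = NULL) {
  stopifnot(all(dim(imputed_hc) == dim(truth_G)))
  if (!is.null(eval_idx)) {
    imputed_hc <- imputed_hc[, eval_idx, drop = FALSE]
    truth_G <- truth_G[, eval_idx, drop = FALSE]
  }
  ok <- !is.na(truth_G)
  match_ <- (imputed_hc == truth_G) & !is.na(imputed_hc) & ok
  denom <- rowSums(ok)
  gcr <- ifelse(denom > 0, rowSums(match_) / denom, NA_real_)
  names(gcr) <- rownames(truth_G)
  gcr
}

#' Pooled squared Pearson correlation per allele-frequency bin
#'
#' Within each AF bin, all (sample, variant) dosage pairs across the bin's
#' variants are pooled and the squared Pearson correlation between imputed
#' and truth dosage is computed. Bins that are empty or have zero variance
#' on either axis are reported as `NA` (undefined), never 0.
#'
#' @param dosages Imputed dosage matrix (samples x variants).
#' @param truth_G Truth genotype matrix (same shape).
#' @param af Per-variant allele frequency used for bin membership (the
#'   external AF-table role).
#' @param bins A [bin_spec()].
#' @param fold_maf If `TRUE`, fold `af` to minor-allele frequency before
#'   binning (default uses the unfolded alt/total frequency).
#' @return Data frame: `bin`, `n_variants`, `n_pairs`, `r2`.
#' @export
pooled_r2_by_bin <- function(dosages, truth_G, af, bins = bin_spec(),
                             fold_maf = FALSE) {
  stopifnot(ncol(dosages) == length(af), all(dim(dosages) == dim(truth_G)))
  if (fold_maf) af <- pmin(af, 1 - af)
  bin <- bin_af(af, bins)
  out <- data.frame(bin = bins$labels, n_variants = 0L, n_pairs = 0L,
                    r2 = NA_real_)
  for (i in seq_along(bins$labels)) {
    j <- which(!is.na(bin) & bin == bins$labels[i])
    out$n_variants[i] <- length(j)
    if (length(j) == 0) next
    x <- as.vector(dosages[, j, drop = FALSE])
    y <- as.vector(truth_G[, j, drop = FALSE])
    ok <- !is.na(x) & !is.na(y)
    out$n_pairs[i] <- sum(ok)
    if (sum(ok) >= 2 && var(x[ok]) > 0 && var(y[ok]) > 0)
      out$r2[i] <- cor(x[ok], y[ok])^2
  }
  out
}

#' Per-variant squared correlation between imputed and truth dosages
#'
#' @inheritParams pooled_r2_by_bin
#' @return Numeric vector (length = variants); `NA` where either axis has
#'   zero variance.
#' @export
per_variant_r2 <- function(dosages, truth_G) {
  vapply(seq_len(ncol(dosages)), function(j) {
    x <- dosages[, j]; y <- truth_G[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])^2
  }, numeric(1))
}

#' Variant yields at estimated-R2 cutoffs
#'
#' For each cutoff `c`, counts variants with estimated R2 at least `c`
#' (the `none` cutoff counts everything), split by variant class.
#'
#' @param imp An `imputed_dataset`.
#' @param cutoffs Numeric cutoffs applied as `R2 >= c`.
#' @return Data frame: `cutoff`, `SNP`, `INDEL`, `total`; counts are
#'   non-increasing down the table.
#' @export
yield_by_cutoff <- function(imp, cutoffs = c(0.2, 0.4, 0.6, 0.8)) {
  vclass <- imp$variants$vclass
  r2 <- imp$est_r2
  rows <- lapply(c(NA, cutoffs), function(cc) {
    sel <- if (is.na(cc)) rep(TRUE, length(r2)) else r2 >= cc
    data.frame(cutoff = if (is.na(cc)) "none" else sprintf(">=%g", cc),
               SNP = sum(sel & vclass == "SNP"),
               INDEL = sum(sel & vclass == "INDEL"),
               total = sum(sel))
  })
  do.call(rbind, rows)
}

r2_strata_labels <- c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)", "[0.8,1]")

r2_stratum_of <- function(r2) {
  idx <- findInterval(r2, c(0, 0.2, 0.4, 0.6, 0.8))
  idx[r2 >= 1] <- 5L
  factor(r2_strata_labels[idx], levels = r2_strata_labels)
}

#' Distribution of variants over estimated-R2 strata
#'
#' Strata are `[0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8), [0.8,1]`
#' (half-open except the last, which is closed at 1).
#'
#' @param imp An `imputed_dataset` (or numeric vector of R2 values).
#' @return Data frame: `stratum`, `n`, `fraction` (fractions sum to 1).
#' @export
r2_histogram <- function(imp) {
  r2 <- if (inherits(imp, "imputed_dataset")) imp$est_r2 else imp
  s <- r2_stratum_of(r2)
  n <- as.integer(table(s))
  data.frame(stratum = r2_strata_labels, n = n, fraction = n / length(r2))
}

#' Per-sample GCR stratified by imputation confidence
#'
#' Recomputes [gcr_per_sample()] restricted to the evaluation variants in
#' each estimated-R2 stratum. Empty strata yield `NA` GCRs with
#' `n_variants = 0` rather than NaN arithmetic.
#'
#' @param imp An `imputed_dataset`.
#' @param truth_G Truth genotype matrix aligned to `imp` columns.
#' @param eval_idx Evaluation-site column indices (default: all).
#' @return List of per-stratum results: `stratum`, `n_variants`, `gcr`
#'   (named vector).
#' @export
gcr_by_stratum <- function(imp, truth_G, eval_idx = NULL) {
  if (is.null(eval_idx)) eval_idx <- seq_len(ncol(truth_G))
  strata <- r2_stratum_of(imp$est_r2)
  lapply(seq_along(r2_strata_labels), function(i) {
    idx <- intersect(eval_idx, which(!is.na(strata) & strata == r2_strata_labels[i]))
    gcr <- if (length(idx) == 0) {
      setNames(rep(NA_real_, nrow(truth_G)), rownames(truth_G))
    } else {
      gcr_per_sample(imp$hard_calls, truth_G, idx)
    }
    list(stratum = r2_strata_labels[i], n_variants = length(idx), gcr = gcr)
  })
}

#' Full concordance report for one imputed dataset
#'
#' Convenience wrapper producing the per-sample GCR with cohort summary,
#' per-AF-bin pooled r-squared, R2-cutoff yields, the R2 histogram, and
#' confidence-stratified GCR.
#'
#' @param imp An `imputed_dataset`.
#' @param truth_G Truth genotypes aligned to `imp` columns.
#' @param af Per-variant allele frequencies for binning.
#' @param eval_idx Evaluation-site indices (default: all untyped sites).
#' @param bins A [bin_spec()].
#' @return A `concordance_report` list.
#' @export
concordance_report <- function(imp, truth_G, af, eval_idx = NULL,
                               bins = bin_spec()) {
  if (is.null(eval_idx)) eval_idx <- which(!imp$typed_flag)
  gcr <- gcr_per_sample(imp$hard_calls, truth_G, eval_idx)
  q <- quantile(gcr, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
  structure(list(
    per_sample_gcr = gcr,
    summary = c(min = q[[1]], q1 = q[[2]], median = q[[3]], q3 = q[[4]], max = q[[5]]),
    per_bin_r2 = pooled_r2_by_bin(imp$dosages[, eval_idx, drop = FALSE],
                                  truth_G[, eval_idx, drop = FALSE],
                                  af[eval_idx], bins),
    yields = yield_by_cutoff(imp),
    r2_hist = r2_histogram(imp),
    by_stratum = gcr_by_stratum(imp, truth_G, eval_idx),
    n_eval_sites = length(eval_idx)), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance_report: %d eval sites; GCR median %.4f (Q1 %.4f, Q3 %.4f)\n",
              x$n_eval_sites, x$summary["median"], x$summary["q1"], x$summary["q3"]))
  print(x$per_bin_r2)
  invisible(x)
}
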