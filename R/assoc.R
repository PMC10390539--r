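#' Score test for case-control association on dosages
#'
#' Fits the logistic null model (intercept plus covariates) and tests the
#' dosage by the 1-df score statistic
#' `U^2 / Var(U)` with `U = sum d_i (y_i - yhat_i)` and
#' `Var = d'Wd - d'WX (X'WX)^{-1} X'Wd`, `W = diag(yhat (1 - yhat))`.
#' This is the additive expected-dosage frequentist test; on hard 0/1/2
#' genotypes with no covariates it reduces exactly to the Cochran-Armitage
#' trend chi-square. Zero-variance (monomorphic) dosages return statistic 0
#' and p = 1.
#'
#' @param dosage Numeric vector in `[0, 2]`.
#' @param y Binary 0/1 phenotype vector.
#' @param covar Optional covariate matrix (columns = covariates); an
#'   intercept is always included. Rank-deficient columns are dropped.
#' @return List: `stat`, `p`, `direction` (sign of `U`), `n`.
#' @export
score_test <- function(dosage, y, covar = NULL) {
  ok <- !is.na(dosage) & !is.na(y)
  if (!is.null(covar)) {
    covar <- as.matrix(covar)
    ok <- ok & complete.cases(covar)
    covar <- covar[ok, , drop = FALSE]
  }
  d <- dosage[ok]; y <- y[ok]
  n <- length(y)
  if (n < 10) stop("score_test: need at least 10 complete observations", call. = FALSE)
  if (length(unique(y)) < 2) stop("score_test: one phenotype class absent", call. = FALSE)
  X <- cbind(`(Intercept)` = rep(1, n), covar)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  fit <- glm.fit(X, y, family = binomial(),
                 control = list(epsilon = 1e-14, maxit = 200))
  if (!is.null(covar) && ncol(X) > 1 && !fit$converged)
    stop("score_test: null model did not converge", call. = FALSE)
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  U <- sum(d * (y - mu))
  XtWX <- crossprod(X, X * w)
  XtWd <- crossprod(X, d * w)
  V <- sum(w * d^2) - as.numeric(crossprod(XtWd, solve(XtWX, XtWd)))
  if (!is.finite(V) || V < 1e-12)
    return(list(stat = 0, p = 1, direction = 0, n = n))
  stat <- U^2 / V
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       direction = sign(U), n = n)
}

#' Genome-wide dosage association scan
#'
#' Runs [score_test()] on every variant passing the estimated-R2 and MAF
#' filters, matching samples between the imputed dataset and the phenotype
#' table by sample id.
#'
#' @param imp An `imputed_dataset`.
#' @param pheno Data frame with `SAMPLE` and `STATUS` (0/1) columns, or a
#'   named 0/1 vector.
#' @param covar Optional covariate matrix (rows aligned to `pheno`).
#' @param min_info Minimum estimated R2 for a variant to be tested.
#' @param min_maf Minimum dosage-based MAF.
#' @return An `assoc_result`: per-variant table (`chrom`, `pos`, `ref`,
#'   `alt`, `stat`, `p`, `direction`, `n`, `info`, `tested`) and filter
#'   counts.
#' @export
genome_scan <- function(imp, pheno, covar = NULL, min_info = 0, min_maf = 0.01) {
  if (is.data.frame(pheno)) pheno <- setNames(pheno$STATUS, pheno$SAMPLE)
  ids <- intersect(imp$samples, names(pheno))
  if (length(ids) == 0) stop("no overlapping samples between dosages and phenotypes",
                             call. = FALSE)
  rows <- match(ids, imp$samples)
  y <- as.numeric(pheno[ids])
  D <- imp$dosages[rows, , drop = FALSE]
  af <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  tested <- imp$est_r2 >= min_info & maf >= min_maf
  tab <- imp$variants[, c("chrom", "pos", "ref", "alt")]
  tab$stat <- NA_real_; tab$p <- NA_real_; tab$direction <- NA_real_
  tab$n <- NA_integer_; tab$info <- imp$est_r2; tab$tested <- tested
  for (j in which(tested)) {
    st <- score_test(D[, j], y, covar)
    tab$stat[j] <- st$stat; tab$p[j] <- st$p
    tab$direction[j] <- st$direction; tab$n[j] <- st$n
  }
  structure(list(table = tab,
                 n_tested = sum(tested),
                 n_filtered_info = sum(imp$est_r2 < min_info),
                 n_filtered_maf = sum(maf < min_maf & imp$est_r2 >= min_info),
                 min_info = min_info, min_maf = min_maf),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result: %d variants tested (min p %.3g)\n",
              x$n_tested, suppressWarnings(min(x$table$p, na.rm = TRUE))))
  invisible(x)
}

#' Greedy lead-signal extraction at a significance threshold
#'
#' Among variants with `p < threshold`, the smallest-p variant seeds a
#' region of `window_bp` on either side (same chromosome); absorbed
#' variants are removed and the process repeats. Output is independent of
#' input row order.
#'
#' @param tab Per-variant association table (an `assoc_result` or its
#'   `table`).
#' @param threshold Genome-wide significance threshold on p.
#' @param window_bp Half-width of a lead-signal region in base pairs.
#' @return Data frame of lead signals: `chrom`, `pos`, `ref`, `alt`, `p`,
#'   `n_partners` (other significant variants absorbed into the region).
#' @export
find_lead_signals <- function(tab, threshold = 5e-8, window_bp = 1e6) {
  if (inherits(tab, "assoc_result")) tab <- tab$table
  sig <- tab[!is.na(tab$p) & tab$p < threshold, , drop = FALSE]
  sig <- sig[order(sig$p, sig$chrom, sig$pos), , drop = FALSE]
  leads <- sig[0, , drop = FALSE]
  n_partners <- integer(0)
  while (nrow(sig) > 0) {
    lead <- sig[1, , drop = FALSE]
    inreg <- sig$chrom == lead$chrom & abs(sig$pos - lead$pos) <= window_bp
    leads <- rbind(leads, lead)
    n_partners <- c(n_partners, sum(inreg) - 1L)
    sig <- sig[!inreg, , drop = FALSE]
  }
  if (nrow(leads) > 0) {
    leads$n_partners <- n_partners
    leads <- leads[order(leads$chrom, leads$pos), , drop = FALSE]
    rownames(leads) <- NULL
  }
  leads
}

#' Pairwise LD as squared genotype correlation
#'
#' Composite LD: the squared Pearson correlation between the two genotype
#' (dosage) vectors over pairwise-complete samples. `NA` if either variant
#' is monomorphic.
#'
#' @param ga,gb Genotype/dosage vectors of the two variants.
#' @return Squared correlation in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  if (!any(ok)) stop("ld_r2: no complete pairs", call. = FALSE)
  if (var(ga[ok]) == 0 || var(gb[ok]) == 0) return(NA_real_)
  cor(ga[ok], gb[ok])^2
}
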