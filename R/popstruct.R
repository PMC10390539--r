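#' LD pruning by sliding-window pairwise correlation
#'
#' A window of `window` variants advances by `step`. Within each window,
#' while any kept pair of variants has squared genotype correlation above
#' `r2_max`, the member of the first offending pair (scan order by
#' position) with the smaller MAF is removed (ties remove the later
#' position). Monomorphic variants never participate in correlations and
#' are never removed.
#'
#' @param G Genotype matrix (samples x variants, 0/1/2, `NA` allowed;
#'   correlations are pairwise-complete).
#' @param window Window size in variants.
#' @param step Window advance in variants.
#' @param r2_max Squared-correlation ceiling.
#' @return Integer vector of kept variant (column) indices.
#' @export
ld_prune <- function(G, window = 50, step = 10, r2_max = 0.2) {
  m <- ncol(G)
  if (m < 1) stop("ld_prune: no variants", call. = FALSE)
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- rep(TRUE, m)
  starts <- seq(1, max(m - 1, 1), by = step)
  for (st in starts) {
    idx <- st:min(st + window - 1, m)
    idx <- idx[keep[idx] & maf[idx] > 0]
    if (length(idx) < 2) next
    repeat {
      cc <- suppressWarnings(cor(G[, idx, drop = FALSE],
                                 use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      diag(cc) <- 0
      r2 <- cc^2
      off <- which(r2 > r2_max, arr.ind = TRUE)
      if (nrow(off) == 0) break
      off <- off[off[, 1] < off[, 2], , drop = FALSE]
      off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
      a <- idx[off[1, 1]]; b <- idx[off[1, 2]]
      drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
      keep[drop] <- FALSE
      idx <- setdiff(idx, drop)
      if (length(idx) < 2) break
    }
  }
  which(keep)
}

#' Identity-by-state distance matrix
#'
#' `D_jk = 1 - (shared allele count) / (2 * complete sites)`, where the
#' shared count at a site is `2 - |x_j - x_k|`. Identical samples are at
#' distance 0; opposite homozygotes at every site are at distance 1.
#'
#' @param G Genotype matrix (samples x variants, `NA` allowed; each pair
#'   uses its complete sites).
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
ibs_distance <- function(G) {
  n <- nrow(G)
  if (n < 2) stop("ibs_distance: need at least 2 samples", call. = FALSE)
  if (!anyNA(G)) {
    D <- as.matrix(dist(G, method = "manhattan")) / (2 * ncol(G))
  } else {
    D <- matrix(0, n, n)
    for (j in 1:(n - 1)) for (k in (j + 1):n) {
      ok <- !is.na(G[j, ]) & !is.na(G[k, ])
      if (!any(ok)) stop("ibs_distance: sample pair with no complete sites",
                         call. = FALSE)
      D[j, k] <- D[k, j] <- sum(abs(G[j, ok] - G[k, ok])) / (2 * sum(ok))
    }
  }
  dimnames(D) <- list(rownames(G), rownames(G))
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds on the top `d`
#' eigenvectors scaled by the square roots of their (nonnegative-clipped)
#' eigenvalues. Axis signs follow the convention that the first nonzero
#' loading of each axis is positive.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param d Number of output dimensions (`d <= n - 1`).
#' @return An `mds_result`: `coordinates` (n x d, column means 0),
#'   `eigenvalues` (descending), `n_markers_used` (`NA` unless set by the
#'   caller).
#' @export
classical_mds <- function(D, d = 2) {
  n <- nrow(D)
  if (d > n - 1) stop("classical_mds: d must be <= n - 1", call. = FALSE)
  fit <- cmdscale(as.dist(D), k = d, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < d)  # rank-deficient configurations pad with zeros
    coords <- cbind(coords, matrix(0, n, d - ncol(coords)))
  for (j in seq_len(d)) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  coords <- sweep(coords, 2, colMeans(coords))
  rownames(coords) <- rownames(D)
  structure(list(coordinates = coords,
                 eigenvalues = sort(fit$eig, decreasing = TRUE)[seq_len(d)],
                 n_markers_used = NA_integer_),
            class = "mds_result")
}

#' MDS of genotypes after LD pruning
#'
#' Convenience pipeline: [ld_prune()], [ibs_distance()] on the pruned
#' markers, then [classical_mds()].
#'
#' @param G Genotype matrix (samples x variants).
#' @param d Output dimensions.
#' @param window,step,r2_max Pruning parameters (see [ld_prune()]).
#' @return An `mds_result` with `n_markers_used` filled in.
#' @export
mds_pipeline <- function(G, d = 2, window = 50, step = 10, r2_max = 0.2) {
  kept <- ld_prune(G, window, step, r2_max)
  res <- classical_mds(ibs_distance(G[, kept, drop = FALSE]), d)
  res$n_markers_used <- length(kept)
  res
}

#' Admixture proportions by EM under the binomial likelihood
#'
#' Maximizes
#' `L = sum_im [ g_im log(sum_k q_ik f_km) + (2 - g_im) log(1 - sum_k q_ik f_km) ]`
#' over ancestry proportions `Q` (rows on the simplex) and ancestral allele
#' frequencies `F`, using the classic multiplicative EM updates from
#' expected ancestry-of-allele counts. The likelihood is non-decreasing at
#' every iteration; several random restarts are run and the best kept.
#'
#' @param G Genotype matrix (samples x variants, 0/1/2, `NA` terms dropped
#'   from the likelihood).
#' @param K Number of ancestral populations.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Stop when the log-likelihood gain drops below `tol`.
#' @param n_starts Number of random restarts.
#' @param seed Optional seed for the restarts.
#' @return An `admixture_fit`: `Q` (n x K), `F` (K x M), `loglik_trace`,
#'   `loglik`, `converged`.
#' @export
admixture_em <- function(G, K = 2, max_iter = 2000, tol = 1e-6, n_starts = 3,
                         seed = NULL) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(G); m <- ncol(G)
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0
  af <- colMeans(G, na.rm = TRUE) / 2

  if (K == 1) {
    f <- matrix(pmin(pmax(af, 1e-6), 1 - 1e-6), 1, m)
    q <- matrix(1, n, 1)
    ll <- admixture_loglik(G0, obs, q, f)
    return(structure(list(Q = q, F = f, loglik_trace = ll, loglik = ll,
                          converged = TRUE), class = "admixture_fit"))
  }

  Gi <- G
  storage.mode(Gi) <- "integer"
  best <- NULL
  for (s in seq_len(n_starts)) {
    q <- matrix(runif(n * K), n, K); q <- q / rowSums(q)
    f <- matrix(pmin(pmax(rep(af, each = K) + runif(K * m, -0.1, 0.1), 0.05),
                     0.95), K, m)
    em <- .admixture_em_cpp(Gi, q, f, as.integer(max_iter), tol)
    fit <- list(Q = em$Q, F = em$F, loglik_trace = em$trace,
                loglik = em$trace[length(em$trace)], converged = em$converged)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(best, class = "admixture_fit")
}

admixture_loglik <- function(G0, obs, q, f) {
  P <- q %*% f
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  sum((G0 * log(P) + (2 - G0) * log(1 - P))[obs])
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K=%d, n=%d, loglik %.2f (%s)\n",
              ncol(x$Q), nrow(x$Q), x$loglik,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Align the columns of an estimated Q matrix to a truth vector
#'
#' With K = 2 the component labels are arbitrary; this picks the column of
#' `Q` whose correlation with `q_true` is highest (flipping if needed) and
#' returns the aligned first-ancestry proportion.
#'
#' @param Q n x 2 ancestry-proportion matrix.
#' @param q_true Length-n truth vector for the first ancestry.
#' @return Numeric vector: the aligned column of `Q`.
#' @export
align_q <- function(Q, q_true) {
  stopifnot(ncol(Q) == 2)
  cc <- suppressWarnings(c(cor(Q[, 1], q_true), cor(Q[, 2], q_true)))
  cc[is.na(cc)] <- -Inf
  if (cc[1] >= cc[2]) Q[, 1] else Q[, 2]
}
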