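test_that("GCR counts identical diploid genotypes over non-missing truth", {
  truth <- matrix(rep(0:2, length.out = 300), 3, 100)
  expect_identical(unname(gcr_per_sample(truth, truth)), rep(1, 3))
  imp <- truth
  imp[1, 1:3] <- (truth[1, 1:3] + 1) %% 3
  g <- gcr_per_sample(imp, truth)
  expect_equal(unname(g[1]), 0.97)
  # missing truth drops from the denominator; missing imputed is discordant
  truth[2, 1:10] <- NA
  imp2 <- truth; imp2[2, 11] <- NA
  g2 <- gcr_per_sample(imp2, truth)
  expect_equal(unname(g2[2]), 89 / 90)
  # GCR = 1 - discordance fraction
  disc <- rowMeans(imp != truth, na.rm = TRUE)
  expect_equal(unname(gcr_per_sample(imp, truth)[1]), 1 - 3 / 100)
  # all-missing truth row is flagged undefined
  truth[3, ] <- NA
  expect_true(is.na(gcr_per_sample(imp2, truth)[3]))
})

test_that("cohort mean GCR under symmetric corruption matches the closed form", {
  set.seed(401)
  n <- 50; m <- 1e4; e <- 0.03
  truth <- matrix(rbinom(n * m, 2, 0.3), n, m)
  corrupt <- truth
  flip <- matrix(runif(n * m) < e, n, m)
  shift <- matrix(sample(1:2, n * m, replace = TRUE), n, m)
  corrupt[flip] <- (truth[flip] + shift[flip]) %% 3
  g <- gcr_per_sample(corrupt, truth)
  se <- sqrt(e * (1 - e) / (n * m))
  expect_lt(abs(mean(g) - (1 - e)), 3 * se)
})

test_that("AF binning respects the edge conventions", {
  b <- bin_spec("coarse")
  expect_identical(as.character(bin_af(c(1, 0.05, 0.049, 0.01, 0.0099, 1e-4), b)),
                   c("[0.05,1]", "[0.05,1]", "[0.01,0.05)", "[0.01,0.05)",
                     "(0,0.01)", "(0,0.01)"))
  expect_true(is.na(bin_af(0, b)))
  bf <- bin_spec("fine")
  expect_length(bf$labels, 10)
  expect_identical(as.character(bin_af(0.0095, bf)), "[0.009,0.01]")
  expect_error(bin_spec(c(0.01, 0.05)), "decreasing")
})

test_that("pooled per-bin r2 behaves at the extremes and under attenuation", {
  set.seed(402)
  n <- 40; m <- 300
  af <- runif(m, 0.06, 0.5)   # all in the common bin
  truth <- sapply(af, function(p) rbinom(n, 2, p))
  res <- pooled_r2_by_bin(truth, truth, af)
  expect_equal(res$r2[1], 1)
  expect_true(is.na(res$r2[2]))  # empty bin undefined, not zero
  expect_identical(res$n_variants[2], 0L)
  # permuted dosages: no association. A narrow AF band keeps the pooled
  # statistic free of the between-variant mean structure, which is shared
  # by both axes and would otherwise floor the pooled r2 near
  # (b/(w+b))^2 even under independence.
  af_flat <- rep(0.3, m)
  truth_flat <- matrix(rbinom(n * m, 2, 0.3), n, m)
  perm <- truth_flat[sample(n), ]
  res_p <- pooled_r2_by_bin(perm, truth_flat, af_flat)
  expect_lt(res_p$r2[1], 0.01)
  # corruption model: dosage = truth w.p. 1-e else resampled iid from the
  # variant's genotype distribution. Pooling across variants keeps the
  # between-variant mean differences on both axes, so
  #   r = ((1-e) w + b) / (w + b),
  # with w the mean within-variant variance and b the variance of the
  # per-variant means.
  e <- 0.2
  corrupt <- truth
  swap <- matrix(runif(n * m) < e, n, m)
  repl <- sapply(af, function(p) rbinom(n, 2, p))
  corrupt[swap] <- repl[swap]
  res_a <- pooled_r2_by_bin(corrupt, truth, af)
  w_v <- mean(apply(truth, 2, var))
  b_v <- var(colMeans(truth))
  r_expect <- ((1 - e) * w_v + b_v) / (w_v + b_v)
  expect_lt(abs(res_a$r2[1] - r_expect^2), 0.02)
  # invariant to variant and sample order
  ov <- sample(m); os <- sample(n)
  res_o <- pooled_r2_by_bin(truth[os, ov], truth[os, ov], af[ov])
  expect_equal(res_o$r2[1], 1)
})

test_that("yield tables count variants at R2 cutoffs by class", {
  imp <- list(variants = data.frame(vclass = rep("SNP", 5)),
              est_r2 = c(0.1, 0.3, 0.5, 0.7, 0.9))
  class(imp) <- "imputed_dataset"
  y <- yield_by_cutoff(imp)
  expect_identical(y$total, c(5L, 4L, 3L, 2L, 1L))
  expect_identical(y$SNP, y$total)
  expect_true(all(diff(y$total) <= 0))
  # brute-force recount on random values
  set.seed(403)
  imp2 <- list(variants = data.frame(vclass = sample(c("SNP", "INDEL"), 200,
                                                     replace = TRUE)),
               est_r2 = runif(200))
  class(imp2) <- "imputed_dataset"
  y2 <- yield_by_cutoff(imp2)
  for (i in seq_along(c(NA, 0.2, 0.4, 0.6, 0.8))) {
    cc <- c(NA, 0.2, 0.4, 0.6, 0.8)[i]
    sel <- if (is.na(cc)) rep(TRUE, 200) else imp2$est_r2 >= cc
    expect_identical(y2$total[i], sum(sel))
    expect_identical(y2$SNP[i], sum(sel & imp2$variants$vclass == "SNP"))
  }
})

test_that("R2 histogram strata are half-open with a closed top", {
  h1 <- r2_histogram(rep(1, 10))
  expect_equal(h1$fraction[5], 1)
  h2 <- r2_histogram(0.2)
  expect_identical(h2$n[2], 1L)
  set.seed(404)
  h3 <- r2_histogram(runif(2e4))
  expect_equal(sum(h3$fraction), 1)
  expect_lt(max(abs(h3$fraction - 0.2)), 3 * sqrt(0.2 * 0.8 / 2e4))
})

test_that("confidence-stratified GCR is consistent with the overall GCR", {
  rep1 <- panel_experiment_rep(999)
  strat <- gcr_by_stratum(rep1$impA, rep1$truth, rep1$eval_idx)
  expect_identical(sum(vapply(strat, `[[`, 0L, "n_variants")),
                   length(rep1$eval_idx))
  # a stratum with no variants is flagged undefined
  empty <- strat[vapply(strat, `[[`, 0L, "n_variants") == 0]
  for (s in empty) expect_true(all(is.na(s$gcr)))
  # the high-confidence stratum does at least as well as the whole set
  expect_gte(rep1$gcr_highconf, rep1$gcr_overall)
  # the union of strata reproduces gcr_per_sample
  total_match <- 0; total_n <- 0
  for (s in strat) if (s$n_variants > 0) {
    total_match <- total_match + s$n_variants * mean(s$gcr)
    total_n <- total_n + s$n_variants
  }
  overall <- gcr_per_sample(rep1$impA$hard_calls, rep1$truth, rep1$eval_idx)
  expect_equal(total_match / total_n, mean(overall), tolerance = 1e-12)
})
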