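rec <- function(ref, alt, af) list(ref = ref, alt = alt, af = af)

test_that("variant classification covers strand, swap and palindrome rules", {
  expect_identical(classify_variant(rec("A", "G", 0.30), rec("A", "G", 0.31))$action,
                   "keep")
  expect_identical(classify_variant(rec("A", "G", 0.30), rec("T", "C", 0.31))$action,
                   "strand_flip")
  expect_identical(classify_variant(rec("A", "G", 0.30), rec("G", "A", 0.69))$action,
                   "allele_swap")
  expect_identical(classify_variant(rec("A", "G", 0.30), rec("C", "T", 0.72))$action,
                   "flip_and_swap")
  pal <- classify_variant(rec("A", "T", 0.48), rec("A", "T", 0.47),
                          palindromic_maf_max = 0.40)
  expect_identical(pal$action, "exclude")
  expect_identical(pal$reason, "palindromic_ambiguous")
  # low-MAF palindrome with consistent orientation is kept
  expect_identical(classify_variant(rec("C", "G", 0.10), rec("C", "G", 0.12))$action,
                   "keep")
  expect_identical(classify_variant(rec("C", "G", 0.10), rec("G", "C", 0.91))$action,
                   "allele_swap")
  afd <- classify_variant(rec("A", "G", 0.05), rec("A", "G", 0.45))
  expect_identical(afd$reason, "af_discrepant")
  mm <- classify_variant(rec("A", "G", 0.3), rec("A", "C", 0.3))
  expect_identical(mm$reason, "allele_mismatch")
  expect_error(classify_variant(rec("A", "GT", 0.3), rec("A", "G", 0.3)),
               "malformed")
})

test_that("applying the returned action reproduces the panel orientation", {
  set.seed(301)
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  for (i in 1:300) {
    ref_p <- sample(bases, 1)
    alt_p <- sample(setdiff(bases, ref_p), 1)
    af_p <- runif(1, 0.02, 0.98)
    # derive an array record by a random orientation scramble + AF noise
    op <- sample(c("same", "flip", "swap", "both"), 1)
    r <- list(ref = ref_p, alt = alt_p, af = min(max(af_p + runif(1, -0.1, 0.1),
                                                     0.01), 0.99))
    if (op %in% c("swap", "both")) {
      r <- list(ref = r$alt, alt = r$ref, af = 1 - r$af)
    }
    if (op %in% c("flip", "both")) {
      r <- list(ref = chartr("ACGT", "TGCA", r$ref),
                alt = chartr("ACGT", "TGCA", r$alt), af = r$af)
    }
    cl <- classify_variant(r, rec(ref_p, alt_p, af_p))
    if (cl$action == "exclude") next
    fixed <- apply_harmonization(r, cl$action)
    expect_identical(c(fixed$ref, fixed$alt), c(ref_p, alt_p))
    expect_lte(abs(fixed$af - af_p), 0.20 + 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)
})

test_that("sample missingness uses a strict threshold", {
  G <- matrix(0, 3, 100)
  G[1, 1:6] <- NA   # 6% -> removed
  G[2, 1:5] <- NA   # exactly 5% -> kept
  res <- sample_missingness_filter(G, max_miss = 0.05)
  expect_identical(res$kept, c(2L, 3L))
  expect_identical(res$report$reason, "missingness")
  res0 <- sample_missingness_filter(matrix(1, 4, 10))
  expect_identical(res0$kept, 1:4)
  # idempotence
  res2 <- sample_missingness_filter(G[res$kept, , drop = FALSE], max_miss = 0.05)
  expect_identical(res2$kept, seq_along(res$kept))
})

test_that("the GRM matches the direct formula and flags duplicates and kin", {
  set.seed(302)
  G <- matrix(sample(0:2, 12, replace = TRUE), 3, 4)
  G[1, 1] <- 0; G[2, 1] <- 1; G[3, 1] <- 2  # ensure a polymorphic site
  expect_equal(grm_matrix(G), oracle_grm(G), tolerance = 1e-12)

  # duplicated sample: exactly one of the pair is removed
  H <- matrix(rbinom(40 * 500, 2, 0.3), 40, 500)
  H[2, ] <- H[1, ]
  pr <- relatedness_prune(H, cutoff = 0.5)
  expect_length(intersect(c(1L, 2L), pr$kept), 1)
  expect_true(all(setdiff(3:40, pr$kept) == 0 | length(pr$removed) >= 1))

  # parent-offspring relatedness concentrates near 0.5, unrelated near 0
  # (a block of unrelated samples keeps the allele-frequency estimates
  # honest: with few samples the sample-AF GRM is shrunk by ~ -1/(n-1))
  set.seed(303)
  m <- 5000
  p <- runif(m, 0.1, 0.9)
  hap <- function() rbinom(m, 1, p)
  father <- list(hap(), hap()); mother <- list(hap(), hap())
  child <- father[[1]] + mother[[1]]
  others <- t(replicate(60, hap() + hap()))
  Gfam <- rbind(father[[1]] + father[[2]], mother[[1]] + mother[[2]], child,
                others)
  A <- grm_matrix(Gfam)
  related <- c(A[1, 3], A[2, 3])
  unrelated <- c(A[1, 2], A[1, 4], A[2, 5], A[3, 4], A[10, 11])
  expect_gt(min(related), 0.35)
  expect_lt(max(abs(unrelated)), 0.15)
  # off-diagonal relatedness of unrelated samples centers on zero
  set.seed(304)
  U <- t(replicate(200, rbinom(1e4, 2, runif(1e4, 0.1, 0.9))))
  AU <- grm_matrix(U)
  expect_lt(abs(mean(AU[upper.tri(AU)])), 0.01)
})

test_that("HWE exact p-values match the enumeration oracle", {
  expect_identical(hwe_exact_test(50, 0, 0), 1)
  o100 <- oracle_hwe_pvalues(100, 100)
  p_het_excess <- hwe_exact_test(0, 100, 0)
  expect_lt(p_het_excess, 1e-6)
  expect_equal(p_het_excess, o100$p[o100$hets == 100], tolerance = 1e-12)
  o <- oracle_hwe_pvalues(100, 2 * 31 + 48)
  expect_equal(hwe_exact_test(21, 48, 31), o$p[o$hets == 48], tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 2, 3), "negative")
  # exhaustive small sweep (full sweep to 200 in the acceptance suite)
  worst <- 0
  for (n in 1:60) for (nm in 0:n) {
    o <- oracle_hwe_pvalues(n, nm)
    for (i in seq_along(o$hets)) {
      worst <- max(worst, abs(hwe_exact_test(o$hom_maj[i], o$hets[i], o$hom_min[i]) -
                                o$p[i]))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("site QC removes failed-filter, missing and HWE-violating sites", {
  set.seed(305)
  G <- matrix(rbinom(50 * 6, 2, 0.4), 50, 6)
  G[1:6, 2] <- NA                   # 12% missing -> removed
  G[, 3] <- 1                       # all het -> extreme HWE violation
  filt <- c("PASS", "PASS", "PASS", "LowQual", ".", "PASS")
  qc <- wgs_site_qc(G, filt)
  expect_true(all(c(2L, 3L, 4L) %in% qc$report$site))
  expect_identical(qc$report$reason[qc$report$site == 2], "missingness")
  expect_identical(qc$report$reason[qc$report$site == 3], "hwe")
  expect_identical(qc$report$reason[qc$report$site == 4], "filter")
  expect_true(all(c(1L, 5L, 6L) %in% qc$kept) || length(qc$kept) >= 2)
  # idempotent on clean data
  clean <- wgs_site_qc(G[, qc$kept, drop = FALSE], rep("PASS", length(qc$kept)))
  expect_identical(clean$kept, seq_along(qc$kept))
})

test_that("evaluation sites are the coordinate-ordered four-way intersection", {
  v <- function(pos, chrom = "1")
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G", vclass = "SNP")
  truth <- v(c(10, 20, 30, 40))
  expect_identical(intersect_evaluation_sites(list(truth, truth), truth),
                   variant_key(truth))
  drop1 <- v(c(10, 30, 40))
  expect_identical(intersect_evaluation_sites(list(drop1), truth),
                   variant_key(v(c(10, 30, 40))))
  expect_warning(out <- intersect_evaluation_sites(list(v(99)), truth), "empty")
  expect_length(out, 0)
})
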