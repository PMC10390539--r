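test_that("ancestral frequency spectrum follows the truncated power law", {
  set.seed(101)
  lo <- 1 / 200
  cfg0 <- sim_config(seed = 1, n_sites = 1e5, region_length = 1e6,
                     sfs_alpha = 0, n_ancestral_haps = 100)
  p0 <- draw_ancestral_frequencies(cfg0)
  expect_true(all(p0 >= lo & p0 <= 0.5))
  ks <- suppressWarnings(stats::ks.test(p0, "punif", min = lo, max = 0.5))
  expect_gt(ks$p.value, 0.01)

  cfg1 <- sim_config(seed = 1, n_sites = 1e5, region_length = 1e6,
                     sfs_alpha = 1, n_ancestral_haps = 100)
  p1 <- draw_ancestral_frequencies(cfg1)
  grid <- seq(lo, 0.5, length.out = 200)
  cdf_true <- log(grid / lo) / log(0.5 / lo)
  cdf_emp <- stats::ecdf(p1)(grid)
  expect_lt(max(abs(cdf_emp - cdf_true)), 0.01)

  cfg_one <- sim_config(seed = 5, n_sites = 1, region_length = 10)
  p_one <- draw_ancestral_frequencies(cfg_one)
  expect_length(p_one, 1)
  expect_true(p_one >= lo && p_one <= 0.5)
})

test_that("Balding-Nichols drift has the right FST and conserves frequency", {
  set.seed(102)
  p <- runif(5e4, 0.05, 0.5)
  expect_identical(draw_bn_frequencies(p, 0), p)
  expect_error(draw_bn_frequencies(p, 1), "fst")
  p1 <- draw_bn_frequencies(p, 0.05)
  p2 <- draw_bn_frequencies(p, 0.05)
  expect_true(oracle_hudson_fst(p1, p2) > 0.04 && oracle_hudson_fst(p1, p2) < 0.06)
  # frequency conservation: E[p_sub] = p (average over 300 replicate draws)
  set.seed(103)
  psub <- replicate(300, draw_bn_frequencies(rep(0.3, 50), 0.2))
  expect_lt(max(abs(rowMeans(psub) - 0.3)), 0.03)
})

test_that("mosaic copying degenerates to founder copies without drift or flips", {
  set.seed(104)
  cfg <- sim_config(seed = 1, n_sites = 100, region_length = 1e5,
                    recomb_rate = 0, flip_rate = 0, n_ancestral_haps = 10)
  pan <- simulate_subpopulation_panel(draw_ancestral_frequencies(cfg), 0, cfg,
                                      n_haps = 20)
  founders <- attr(pan, "founders")
  for (h in seq_len(nrow(pan$haplotypes))) {
    hits <- apply(founders, 1, function(f) all(f == pan$haplotypes[h, ]))
    expect_true(any(hits))
  }
})

test_that("flip_rate 0.5 destroys the founder signal", {
  set.seed(105)
  cfg <- sim_config(seed = 1, n_sites = 2000, region_length = 1e6,
                    recomb_rate = 0, flip_rate = 0.5, n_ancestral_haps = 2)
  pan <- simulate_subpopulation_panel(rep(0.5, 2000), 0, cfg, n_haps = 40)
  founders <- attr(pan, "founders")
  cc <- abs(cor(t(pan$haplotypes), t(founders)))
  expect_lt(mean(cc), 0.05)
})

test_that("admixed individuals mix the two panels at rate q", {
  set.seed(106)
  cfg <- sim_config(seed = 1, n_sites = 50, region_length = 1e5)
  pA <- simulate_subpopulation_panel(rep(0.3, 50), 0, cfg, n_haps = 10, pop = "A")
  pB <- simulate_subpopulation_panel(rep(0.3, 50), 0, cfg,
                                     variants = pA$variants, n_haps = 10, pop = "B")
  expect_true(all(simulate_admixed_individual(pA, pB, 1, cfg)$ancestry == "A"))
  expect_true(all(simulate_admixed_individual(pA, pB, 0, cfg)$ancestry == "B"))
  anc <- replicate(300, simulate_admixed_individual(pA, pB, 0.5, cfg)$ancestry)
  frac <- mean(anc == "A")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 600))
  expect_error(simulate_admixed_individual(pA, pB, 1.5, cfg), "q")
})

test_that("array masking keeps every m-th eligible site", {
  G <- rbind(rep(0:1, 50), rep(1, 100), rep(0:1, 50), rep(1:0, 50))  # MAF 0.375
  cfg_all <- sim_config(seed = 1, n_sites = 100, region_length = 1000,
                        array_maf_min = 0, array_spacing = 1)
  expect_identical(mask_to_array(G, cfg_all), 1:100)
  cfg5 <- sim_config(seed = 1, n_sites = 100, region_length = 1000,
                     array_maf_min = 0, array_spacing = 5)
  expect_length(mask_to_array(G, cfg5), 20)
  # sites below the MAF floor are never typed
  G2 <- cbind(matrix(rep(c(0, 1), 50), 10, 10),           # common
              matrix(c(1, rep(0, 9)), 10, 10))            # MAF 0.05... per col
  G2[, 11:20] <- 0; G2[1, 11:20] <- 1                     # MAF 0.05 per column
  G2[1, 15:20] <- 0                                       # those now monomorphic
  cfgm <- sim_config(seed = 1, n_sites = 20, region_length = 100,
                     array_maf_min = 0.06, array_spacing = 1)
  typed <- mask_to_array(G2, cfgm)
  maf <- pmin(colMeans(G2) / 2, 1 - colMeans(G2) / 2)
  expect_true(all(maf[typed] >= 0.06))
  cfg_empty <- sim_config(seed = 1, n_sites = 20, region_length = 100,
                          array_maf_min = 0.49, array_spacing = 1)
  expect_error(mask_to_array(G2, cfg_empty), "empty")
})

test_that("phenotype model hits the target prevalence", {
  set.seed(107)
  G <- matrix(rbinom(5000 * 5, 2, 0.3), 5000, 5)
  cfg_null <- sim_config(seed = 1, n_sites = 5, region_length = 100,
                         case_fraction = 0.3)
  y <- simulate_phenotypes(G, cfg_null)
  expect_lt(abs(mean(y) - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
  # calibrated intercept under strong effects
  cfg_eff <- sim_config(seed = 1, n_sites = 5, region_length = 100,
                        case_fraction = 0.3,
                        causal_effects = data.frame(site = c(1, 3),
                                                    beta = c(0.5, -0.4)))
  y2 <- simulate_phenotypes(G, cfg_eff)
  expect_lt(abs(mean(y2) - 0.3), 0.05)
  # near-infinite effect: alt carriers are nearly all cases
  cfg_inf <- sim_config(seed = 1, n_sites = 5, region_length = 100,
                        case_fraction = 0.5,
                        causal_effects = data.frame(site = 2, beta = 10))
  y3 <- simulate_phenotypes(G, cfg_inf)
  carriers <- G[, 2] > 0
  expect_gt(mean(y3[carriers]), 0.95)
})

test_that("cohort generation is a pure function of the config", {
  cfg <- sim_config(seed = 42, n_sites = 150, pop_sizes = c(8, 8),
                    region_length = 5e5, admixed_fraction = 0.25)
  co1 <- simulate_cohort(cfg, n_ref_haps = 30)
  co2 <- simulate_cohort(cfg, n_ref_haps = 30)
  expect_identical(co1, co2)
  expect_true(all(diff(co1$variants$pos) > 0))
  expect_true(all(co1$target_haps %in% 0:1))
  expect_identical(dim(co1$truth_G), c(16L, 150L))
  expect_true(all(co1$pop[co1$q_true > 0 & co1$q_true < 1] == "ADMIX"))
})

test_that("written cohorts round-trip exactly through VCF/TSV", {
  dir <- withr::local_tempdir()
  co <- small_cohort(seed = 3, n_sites = 120, pop_sizes = c(6, 6),
                     n_ref_haps = 20)
  paths <- write_cohort(co, dir)
  tr <- read_vcf_haps(paths$truth)
  expect_identical(unname(tr$haps), unname(co$target_haps))
  expect_identical(tr$variants$pos, co$variants$pos)
  expect_true(all(diff(tr$variants$pos) > 0))
  arr <- read_vcf_geno(paths$array)
  expect_identical(unname(arr$G),
                   unname(co$truth_G[, co$typed_idx, drop = FALSE]))
  expect_false(arr$phased)
  pan <- read_vcf_haps(paths$panel_POP1)
  expect_identical(unname(pan$haps), unname(co$panels$POP1$haplotypes))
  af <- read_af_table(paths$af)
  expect_identical(nrow(af), nrow(co$variants))
  expect_equal(af$AF, co$af_ancestral, tolerance = 1e-12)
  ph <- read_phenotypes(paths$pheno)
  expect_identical(ph$STATUS, co$phenotype)
  cfg2 <- read_sim_config(paths$config)
  expect_equal(unclass(cfg2), unclass(co$cfg))
})
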