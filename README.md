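# panelbench

Reference-panel benchmarking for genotype imputation accuracy.

Genotype imputation fills in the variants a genotyping array did not
measure by copying haplotype segments from a sequenced reference panel.
For cohorts that are underrepresented in the big public panels, the choice
of panel drives both how many variants you get and how accurate they are —
and a small, ancestrally matched panel can beat a much larger mismatched
one, especially for rare variants. `panelbench` implements the full
evaluation pipeline for this question as a tested R package, together with
a synthetic structured-population generator and a minimal Li–Stephens
imputer so that every stage runs and can be audited at desk scale, offline.

**For whom:** statistical geneticists and pipeline developers who want a
transparent, fully seeded testbed for imputation-accuracy methodology —
not a replacement for production imputation servers.

## What is inside

| Area | Functions |
| --- | --- |
| Synthetic cohorts | `sim_config()`, `simulate_cohort()`, `simulate_subpopulation_panel()`, `simulate_admixed_individual()`, `mask_to_array()`, `simulate_phenotypes()`, `write_cohort()` |
| Li–Stephens imputer | `ls_params()`, `ls_posteriors()`, `impute_diploid()`, `impute_cohort()`, `hard_call()`, `estimate_r2()` |
| Harmonization & QC | `classify_variant()`, `harmonize_variants()`, `sample_missingness_filter()`, `relatedness_prune()`, `hwe_exact_test()`, `wgs_site_qc()`, `intersect_evaluation_sites()` |
| Accuracy metrics | `gcr_per_sample()`, `pooled_r2_by_bin()`, `yield_by_cutoff()`, `r2_histogram()`, `gcr_by_stratum()`, `concordance_report()` |
| Population structure | `ld_prune()`, `ibs_distance()`, `classical_mds()`, `mds_pipeline()`, `admixture_em()` |
| Association | `score_test()`, `genome_scan()`, `find_lead_signals()`, `ld_r2()` |
| CLI | `run_panelbench()` and the `panelbench` script (`simulate`, `impute`, `harmonize`, `qc-wgs`, `concord`, `popstruct`, `assoc`) |

The core model: a target haplotype is a recombinant, slightly mutated
mosaic of the K reference haplotypes (hidden state = copied haplotype;
switch probability `1 − exp(−ρd/K)` between adjacent sites; emission
mismatch ε at typed sites). Accuracy is measured as the per-sample
genotype concordance rate (GCR) against truth genotypes and as the pooled
squared Pearson correlation between imputed dosage and truth within
allele-frequency bins (common ≥ 0.05, low-frequency [0.01, 0.05), rare
< 0.01). Per-variant confidence is the Minimac-style estimated R²: the
variance of the haploid allele probabilities over its binomial
expectation. See `vignettes/panel-benchmarking.Rmd` for the model,
assumptions and design decisions.

## A worked example

Simulate two populations at F_ST = 0.05 sharing ancestry, impute the
population-A targets once with their own panel and once with the
population-B panel of equal size (200 haplotypes each), and compare:

```r
library(panelbench)

cfg <- sim_config(seed = 1, n_sites = 1000, pop_sizes = c(25, 25),
                  fst_per_pop = c(0.05, 0.05), region_length = 2e6,
                  recomb_rate = 3e-6)
co <- simulate_cohort(cfg, n_ref_haps = 200)

ia <- which(co$pop == "POP1")
hr <- as.vector(rbind(2 * ia - 1, 2 * ia))
params <- ls_params(err = 0.01, rho = 200 * cfg$recomb_rate)
impA <- impute_cohort(co$target_haps[hr, ], co$typed_idx, co$panels$POP1, params)
impB <- impute_cohort(co$target_haps[hr, ], co$typed_idx, co$panels$POP2, params)

ev <- setdiff(seq_len(cfg$n_sites), co$typed_idx)  # untyped evaluation sites
median(gcr_per_sample(impA$hard_calls, co$truth_G[ia, ], ev))
#> [1] 0.9295261
median(gcr_per_sample(impB$hard_calls, co$truth_G[ia, ], ev))
#> [1] 0.8420413
pooled_r2_by_bin(impB$dosages[, ev], co$truth_G[ia, ev], co$af_ancestral[ev])
#>           bin n_variants n_pairs          r2
#> 1    [0.05,1]        362    9050 0.198665160
#> 2 [0.01,0.05)        339    8475 0.020121277
#> 3    (0,0.01)        122    3050 0.002228298
```

The matched panel is ~9 GCR points better than the mismatched panel of the
same size, and the mismatched panel's dosage accuracy collapses from
common to rare variants — the two qualitative signatures the package is
built to measure. Confidence stratification comes from the same objects:

```r
yield_by_cutoff(impA)
#>   cutoff  SNP INDEL total
#> 1   none 1000     0  1000
#> 2  >=0.2  634     0   634
#> 3  >=0.4  608     0   608
#> 4  >=0.6  520     0   520
#> 5  >=0.8  243     0   243
```

The same pipeline is scriptable from a shell (`exec/panelbench` after
install): `panelbench simulate --config cfg.yaml --out sim/`, then
`panelbench impute`, `panelbench concord`, `panelbench popstruct`,
`panelbench assoc`; all reports are TSV and byte-reproducible given the
same config and seed.

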