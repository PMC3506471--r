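# ovipred

Pedigree and genomic prediction for multi-breed sheep populations.

## The problem

Carcass and meat-quality traits (eye muscle depth, fat depth, intramuscular
fat, lean meat yield, omega-3 content, ...) can only be measured at
slaughter, so breeding candidates cannot be phenotyped for them. Genomic
selection trains a prediction equation on a *reference population* with both
SNP genotypes and phenotypes, then scores young animals from genotypes
alone. In the Australian sheep industry that reference is multi-breed: a
Merino-dominated base with crossbred progeny of meat-breed sires (Border
Leicester, Polled Dorset, White Suffolk, Texel, Suffolk) on Merino-type
ewes. The honest way to measure how well this works for a future candidate
is *across-sire-family* cross-validation: whole sire families are withheld,
so no half-sib of a validation animal ever sits in the reference set.

`ovipred` implements the whole evaluation chain, for methodologists and
breeding-program analysts:

* **Synthetic multi-breed data** — Balding–Nichols breed allele
  frequencies, a two-cohort crossbreeding pedigree, gene-drop genotypes
  with Haldane recombination, four-class mixture marker effects, and
  phenotypes with calibrated heritability (`simulate_dataset()`).
* **Genotype QC** — call-rate, MAF, Hardy–Weinberg, LD-pruning and
  animal-level filters with an auditable report, plus mean-dosage
  imputation (`run_qc()`).
* **Relationships** — tabular-method `A`, Yang-style or
  standardised-dosage `G`, pedigree breed composition `Q`
  (`build_nrm()`, `build_grm()`, `breed_composition()`).
* **Mixed models** — REML variance components (spectral fast path,
  Fisher scoring for multiple terms), Henderson mixed-model equations,
  GBLUP prediction, fixed-effect adjustment (`reml_fit()`, `solve_mme()`,
  `gblup_predict()`, `adjust_phenotypes()`).
* **BayesR** — a compiled Gibbs sampler for marker effects drawn from a
  four-component normal mixture with variances
  `(0, 1e-4, 1e-3, 1e-2) * sigma_g2` (`run_bayesr()`).
* **Cross-validation** — family-atomic subset designs, leakage-proof fold
  execution for BLUP/GBLUP/BayesR, accuracy (`r/h`), bias regressions and
  relatedness summaries per sire-breed group (`make_subsets()`,
  `cv_run()`, `summarise_cv()`).

The models are the standard animal-model family: pedigree BLUP
`y = 1μ + Xb + Za + ZQq + e` with `a ~ N(0, σa²A)`; GBLUP adds
`g ~ N(0, σg²G)`; BayesR analyses adjusted phenotypes
`y* = 1μ + Za + Wm + e` with mixture-distributed marker effects `m`.
See `vignettes/multibreed-genomic-prediction.Rmd` for the full account.

## Worked example

```r
library(ovipred)
cfg <- sim_config(n_snp = 500, n_chromosomes = 10, n_sires_A = 20,
                  family_size_A = 30, n_sires_B = 10, family_size_B = 30,
                  h2 = 0.3, seed = 1)
sim <- simulate_dataset(cfg)
#> <sim_dataset> 1364 animals (929 phenotyped) x 500 SNP

qc <- run_qc(inject_missingness_and_contamination(sim$dosages,
                                                  missing_rate = 0.01, seed = 2))
qc$report
#> <qc_report> SNP 500 -> 497; animals 1364 -> 1364
#>   snp_call_rate          removed 0
#>   maf                    removed 3
#>   ...

data   <- prepare_cv_data(sim)
design <- make_subsets(sim$pedigree, target_size = 150, seed = 3)
#> <cv_design> 4 subsets (sizes 157, 161, 162, 149); 300 always-reference animals

res <- cv_run(data, design, methods = c("BLUP", "GBLUP"),
              spec = model_spec(covariates = NULL))
subset(summarise_cv(res), breed_group == "ALL")
#>   method  response breed_group mean_accuracy mean_slope se_accuracy se_slope
#> 1   BLUP  adjusted         ALL         0.338      1.029      0.0297   0.1586
#> 2  GBLUP  adjusted         ALL         0.364      0.763      0.0670   0.1890
#> 3   BLUP phenotype         ALL         0.327      1.098      0.0206   0.0383
#> 4  GBLUP phenotype         ALL         0.413      0.975      0.0665   0.2057
res$h2_model1
#> [1] 0.376
```

Reading the output: accuracy is the Pearson correlation between
predictions and (adjusted) phenotypes divided by `h = sqrt(h²)` from the
pedigree model (here REML gives `h² = 0.376` for a trait simulated at
0.3), so it estimates the correlation with true breeding values; GBLUP
beats pedigree BLUP across sire families, by more on the phenotype
response. A bias slope of 1 means calibrated predictions — note the
over-dispersion (0.76) for GBLUP scored against *adjusted* phenotypes,
which arises because the pooled-frequency `G` carries between-breed
genetic variance that the breed adjustment removes; that combination is
genuinely biased in this design, and the vignette discusses why.

## Command line

Data-level stages are scriptable:

```sh
Rscript -e 'ovipred::run_cli()' simulate --config cfg.json --out simdir
Rscript -e 'ovipred::run_cli()' qc --dosage simdir/dosages.txt --out qcdir
Rscript -e 'ovipred::run_cli()' grm --dosage qcdir/dosages_qc.txt --out G.csv
Rscript -e 'ovipred::run_cli()' bayesr --ystar ystar.csv --dosage qcdir/dosages_qc.txt --out bayesdir
```

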