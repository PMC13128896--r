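# methylwave

Stratified DNA methylation age clocks with wave-phase discovery.

## What problem this addresses

DNA methylation drifts with age in a highly reproducible way, and
*epigenetic clocks* — regressions from CpG beta-values to age — are the
workhorse biomarker built on that drift. Most clocks are regularized linear
models; they miss non-linear trajectories and say nothing about *when* in
life the methylome reorganizes. methylwave is a toolkit for researchers who
want to (a) build a non-linear clock from EPIC-style beta matrices with
age- and sex-stratified feature selection, (b) quantify cross-cohort
generalization honestly via leave-one-cohort-out (LOCO) ensembling, and
(c) interrogate the trained clock with Shapley-style attributions to find
*aging phases*: contiguous runs of age bins whose CpG-influence profiles
cluster together, separated by transition boundaries ("epigenetic waves"),
with multiscale-bootstrap support values and sex-stratified comparison.

The core objects and statistics:

* per-stratum Spearman selection: within each (age-bin x sex) stratum the
  top fraction of CpGs by |rho(beta, age)| is kept and the strata unioned
  (`stratified_correlations()`, `select_features()`);
* a seeded feed-forward regressor f(beta, sex) -> age trained with Adam,
  dropout and L2, one submodel per held-out cohort, ensemble = mean
  (`train_mlp()`, `loco_train()`, `predict_age()`);
* expected-gradients attribution
  phi_i = E_{x'~bg, a~U(0,1)}[(x_i - x'_i) df/dx_i(x' + a(x - x'))],
  exact for linear models, aggregated into five-year age-bin profiles
  (`explain()`, `bin_profiles()`);
* Ward.D2 clustering of bins with AU/BP edge support from multiscale
  bootstrap of the CpG axis, fixed-height phase cuts, and per-sex
  supported-phase counts (`multiscale_bootstrap()`, `cut_phases()`,
  `compare_sex_phases()`);
* the standard calibration panel — MAE, MedAE, RMSE, bias, Pearson r,
  Spearman rho, R^2 (= r^2), slope/intercept of predicted on chronological
  age, and the SD of age acceleration — plus leukocyte cell-composition
  sensitivity analysis (`calibration_metrics()`, `rank_clocks()`,
  `cell_adjustment()`).

A seeded synthetic-methylome generator (`simulate_cohort()`) plants known
age-trajectory CpG classes, sex effects, cohort shifts and phase
boundaries, so every stage of the pipeline can be tested against ground
truth. See `vignettes/methylwave-methods.Rmd` for the models, parameter
rationale, and what the synthetic world does and does not establish.

## Worked example

```r
library(methylwave)

# a synthetic 3-cohort world with planted phase boundaries at 35/45/65
sim <- simulate_cohort(sim_config(seed = 1))
dim(sim$beta)          # 1500 CpGs x 600 samples

# stratified selection: top 1% per (age-bin x sex) stratum, unioned
tab <- stratified_correlations(sim$beta, sim$meta, stratum_scheme())
fs  <- select_features(tab, fraction = 0.01)
fs
#> feature_set: 112 CpGs from 8 strata

# LOCO ensemble on (selected CpGs + sex)
X   <- make_design(sim$beta, sim$meta, fs)
ens <- loco_train(X, sim$meta$age, sim$meta$cohort,
                  small_model_config(epochs = 600))
ens
#> loco_ensemble: 3 submodels; mean holdout MAE 1.921 years

# calibration of the ensemble predictions
calibration_metrics(predict_age(ens, X), sim$meta$age)
#> calibration: n=600 MAE=1.46 RMSE=1.81 bias=0.04 r=0.997 slope=0.993

# attribution -> age-bin profiles -> supported dendrogram -> 4 phases
attr <- explain(ens, X, n_steps = 150, n_background = 75, seed = 1)
prof <- bin_profiles(attr, sim$meta)
sdnd <- multiscale_bootstrap(prof, B = 200, seed = 1)
cut_phases(sdnd, k = 4)
#> phase_assignment: 4 phases at cut height 3.2826 ( 0 supported )
```

The phase table maps each five-year age bin to a phase. On this seed the
k = 4 cut recovers the planted partition (bins below 35, 35-44, 45-64, 65
and above) up to the single transitional bin 30-34 (adjusted Rand index
0.86 against the planted truth), and no phase edge reaches AU >= 0.95: in
the package-default world smooth age trajectories dominate the planted
boundary steps, which bounds both the cut accuracy and the bootstrap
support the attribution route can earn. The methods vignette explains this
redundancy effect and the boundary-dominant world in which the same
pipeline recovers the planted partition exactly (mean adjusted Rand index
above 0.9 over 20 seeds, measured by the acceptance suite).

Numbers shown are the output of this exact script on this package version
(seeded); the holdout MAE is measured on cohorts excluded from training.

## Command line

```sh
bin=$(Rscript -e 'cat(system.file("exec", "methylwave", package = "methylwave"))')
Rscript "$bin" simulate --out sim/ --seed 2
Rscript "$bin" select-features --beta sim/beta.tsv --meta sim/meta.csv --out features.txt
Rscript "$bin" train --beta sim/beta.tsv --meta sim/meta.csv \
        --features features.txt --out model/
Rscript "$bin" predict --model model/ --beta sim/beta.tsv \
        --meta sim/meta.csv --out predictions.csv
Rscript "$bin" phases --attributions attr.tsv --meta sim/meta.csv --out phases/
Rscript "$bin" run-all --config pipeline.yaml --out run1/
```

Every stage reads the previous stage's serialized artifacts, and `run-all`
drives the whole pipeline from a YAML config with a single global seed that
fans out to per-stage seeds; the run manifest records seeds and artifact
hashes so silent input changes are detectable.

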