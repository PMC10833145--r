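# morphsample

Two-dimensional geometric morphometrics with an emphasis on study
design: how many specimens, which views, and which skeletal elements
does it take to estimate mean shape, shape variance, and size reliably?

The package is aimed at morphologists running landmark-based analyses
of museum samples (the built-in synthetic data emulates intraspecific
samples of vespertilionid bat skulls in lateral cranial, ventral
cranial, and lateral mandibular views), and at anyone who wants to run
a rarefaction-style pilot analysis before committing to a digitizing
campaign.

## What it implements

* **Superimposition.** Generalized Procrustes analysis (`gpa()`):
  every configuration is centered, scaled to unit centroid size
  `CS = sqrt(sum_i ||p_i - p̄||²)`, and iteratively rotated onto the
  consensus (partial Procrustes superimposition, reflections
  disallowed). Semilandmarks on curves are slid by the thin-plate-spline
  **bending energy** criterion: each sliding point moves along its
  neighbour chord by the amount minimizing `h'Bh`, where `B` is the
  bending-energy matrix of the consensus, solved jointly per specimen.
* **TPS machinery.** Bending-energy matrices, exact TPS interpolating
  warps and D'Arcy Thompson deformation grids
  (`bending_energy_matrix()`, `tps_warp()`, `deformation_grid()`).
* **Statistics.** Shape PCA (`pca_shape()`); Procrustes ANOVA with
  sequential sums of squares over all coordinates and
  residual-randomization permutation (RRPP) significance
  (`proc_anova_rrpp()`); Procrustes-variance dispersion tests
  (`dispersion_test()`); two-block partial least squares with the
  `rPLS` statistic (`two_block_pls()`); one-way ANOVA + Tukey HSD
  (`anova_tukey()`); a sexual size/shape dimorphism battery with
  balanced resampling (`sexual_dimorphism_suite()`).
* **The rarefaction experiment.** `run_rarefaction()` repeatedly
  subsamples a dataset into fraction bins (100/75/50/25/10% by
  default), re-runs GPA + sliding inside every subsample, and records
  each subsample's consensus shape, mean log10 centroid size, and
  partial Procrustes distance to the full-sample ("true") mean, under
  a fully reproducible per-draw seed schedule.
  `summarize_rarefaction()` runs the comparison battery (ANOVAs +
  Tukey, dispersion tests, convex hulls of subsample means in the
  full-sample PC space).
* **Synthetic data.** `generate_dataset()` draws landmark datasets
  with known truth: isotropic digitizing noise, log-normal centroid
  sizes, allometry, and sex/species shape offsets built from smooth
  principal warps of the template, so every estimator in the package
  can be validated against its generating parameters.
* **I/O.** TPS files in the tpsDIG dialect (`read_tps()`,
  `write_tps()`), slider and classifier tables as CSV, plus
  config-driven pipeline wrappers (`pipeline_gpa()`,
  `pipeline_rarefy()`, `pipeline_concordance()`,
  `pipeline_dimorphism()`, `pipeline_simulate()`) and a thin CLI at
  `inst/cli/morphsample.R`.

## Worked example

```r
library(morphsample)

d <- generate_dataset(generator_spec(seed = 42))  # 48 F + 24 M, lateral view
g <- gpa(d)                                       # GPA + bending-energy sliding
g
#> GPA result: 72 specimens, 29 landmarks
#>   iterations: 13, final change: 2.81e-13, semilandmarks slid: TRUE

rec  <- run_rarefaction(d, T = 100, base_seed = 42)
summ <- summarize_rarefaction(rec, n_perm = 200, seed = 42)
summ
#> Rarefaction summary
#>    bin fraction  m n_records mean_dist  sd_dist mean_mlcs  sd_mlcs hull_area
#> 1 100%     1.00 72       100  0.000000 0.000000     1.522 0.000000 0.0000000
#> 2  75%     0.75 54       100  0.008743 0.002610     1.523 0.002115 0.0001991
#> 3  50%     0.50 36       100  0.014912 0.003769     1.523 0.003543 0.0004816
#> 4  25%     0.25 18       100  0.024531 0.004474     1.523 0.006991 0.0015972
#> 5  10%     0.10  7       100  0.039661 0.005713     1.523 0.011796 0.0031154
#>
#> Centroid-size ANOVA across bins: p = 0.8087
#> Distance-to-true-mean ANOVA across bins: p = 3.355e-183
```

Reading: the mean Procrustes distance of a subsample's consensus from
the full-sample consensus grows steadily as the sample shrinks (0.0087
at 75% of the data, 0.040 at 10%), and so do the dispersion of
subsample means and their convex-hull areas in PC space — mean *shape*
degrades with sample size. Mean *centroid size*, by contrast, stays
unbiased (across-bin ANOVA p = 0.81): size can be estimated well from
few specimens.

```r
sexual_dimorphism_suite(d, n_perm = 999, seed = 42)
#> Sexual shape dimorphism (shape ~ size + sex):
#> Procrustes ANOVA (sequential SS, RRPP, 999 permutations)
#>           df      SS       MS      F      R2      Z        p
#> size       1 0.12031 0.120313 20.470 0.22046 47.271 0.001001
#> sex        1 0.01987 0.019872  3.381 0.03641  7.731 0.001001
#> Residuals 69 0.40555 0.005878     NA 0.74313     NA       NA
#> Total     71 0.54574       NA     NA 1.00000     NA       NA
#>
#> Sexual size dimorphism (log10 CS ~ sex): F = 13.42, p = 0.0004794
```

Here allometry accounts for ~22% of shape variance; after size is
factored out, sex explains ~3.6% (significant but small — typical for
cryptic sexual shape dimorphism), and females are significantly larger.

See `vignette` source `vignettes/morphsample-methods.Rmd` for the full
account of the model, its assumptions, and the numerical choices.

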