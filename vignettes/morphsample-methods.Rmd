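---
title: "Methods: superimposition, sliding, permutation inference, and the rarefaction experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: superimposition, sliding, permutation inference, and the rarefaction experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphsample)
```

This vignette is the package's account of its own methods: the models
and procedures, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## 1. Superimposition

### Partial Procrustes superimposition

A configuration is a `k x 2` matrix of landmark coordinates. Size is
measured by centroid size, `CS = sqrt(sum_i ||p_i - centroid||^2)`,
the standard geometric-morphometric size variable, which is invariant
to rotation and translation and is the quantity divided out by
superimposition. `gpa()` performs *partial* Procrustes
superimposition: every configuration is centered, scaled to `CS = 1`,
and rotated onto the consensus; there is no per-specimen optimal
rescaling during the rotation step. Reflections are disallowed
(`det(R) = +1`): specimens digitized in a consistent orientation should
never be mirror-matched, and allowing reflections would silently mask
digitizing errors. Reflection-permitting alignment remains available
through `opa_align(..., allow_reflection = TRUE)` for diagnostic use.

The optimal 2D rotation has a closed form: with cross-products
`a = sum(x_t x_r + y_t y_r)` and `b = sum(y_t x_r - x_t y_r)` the
optimal angle is `atan2(b, a)`. The GPA inner loop uses this form
(vectorized over specimens); `opa_align()` uses the equivalent SVD
solution with determinant sign correction. The two are checked against
a brute-force rotation-angle grid search in the test suite.

Iteration: the consensus is initialized as the first (unit-scaled)
specimen, all specimens are rotated onto it, and the consensus is
recomputed (and rescaled to unit size for use as the next rotation
target) until its summed squared change falls below `tol = 1e-10`,
with a ceiling of `max_iter = 100`; convergence typically takes well
under ten iterations. The *reported* consensus is the plain
coordinate-wise mean of the aligned specimens after the final
iteration, so `consensus == mean_shape(aligned)` holds exactly.

No projection into a linear tangent space is applied; the statistical
layer operates on the superimposed coordinates directly. At the small
shape variation the package targets (intraspecific skull variation,
Procrustes distances of order 0.01–0.1) the difference between
spherical and tangent coordinates is far below the effects of
interest; the choice is recorded here for reproducibility.

### Bending-energy sliding of semilandmarks

Semilandmarks mark positions along homologous curves; their exact
position *along* the curve is arbitrary. During superimposition each
sliding point is therefore displaced along its tangent direction — the
unit chord from its `before` to its `after` neighbour — by the amount
that minimizes the thin-plate-spline bending energy of the
specimen-to-consensus deformation. With the consensus bending-energy
matrix `B` (kernel `U(r) = r^2 log r^2`), displacement vector `v`, and
tangent matrix `T`, the slide amounts solve the linear system
`t = -(T'GT)^{-1} T'G v` with `G = B ⊕ B`, jointly for all sliders of
a specimen. The bending-energy matrix is always that of the current
consensus, not per-specimen matrices, and the consensus is recomputed
between passes. Five sliding passes are interleaved with full GPA
passes by default (`slide_passes = 5`), stopping early if the total
slide displacement drops below tolerance.

Two properties are guaranteed and tested: the sliding step itself
never moves fixed landmarks, and each pass is non-increasing in
bending energy.

**Numerical choice — trust region.** The joint bending-energy
minimizer has a near-zero-energy mode: a whole curve drifting
collectively along itself costs almost no bending (measured Hessian
condition number of order 10^3–10^4 on the built-in templates).
Un-damped Newton steps along this mode are set by noise, not signal,
and iterating them can carry a subsample to a different sliding
equilibrium than the full sample. Each specimen's slide vector is
therefore uniformly scaled so that no semilandmark moves more than
`cap = 0.5` of its smallest half-chord in a single pass. A scaled
Newton step on a convex quadratic is still a descent step, so energy
monotonicity is untouched, and ordinary (small) slides are unaffected
to machine precision. Tangent directions use the neighbour chord
(secant) rather than a fitted spline tangent: for sparse curves the
secant is the robust standard choice. The alternative
minimum-Procrustes-distance sliding criterion is deliberately not
implemented.

## 2. Statistical layer

### Shape PCA

`pca_shape()` is an eigen-decomposition of the covariance matrix of
the flattened superimposed coordinates (x-block then y-block), with no
variable scaling. Components span the non-degenerate directions only
(at most `min(n - 1, 2k)`, in practice `2k - 4` after
superimposition), so reconstruction from all components is exact.
Components explaining more than 10% of variance are a useful reporting
threshold, but nothing downstream is truncated to them.

### Procrustes ANOVA with RRPP

`proc_anova_rrpp()` decomposes shape variation by sequential (type I)
sums of squares over all coordinates: for term *i*,
`SS_i = ||(H_i - H_{i-1}) Y||_F^2` with `H_i` the hat matrix of the
model containing terms `1..i`. `F_i = (SS_i/df_i) / MS_residual` uses
the residual of the *full* model. Significance comes from
residual-randomization permutation: the residuals of the reduced model
(terms `1..i-1`) are permuted across specimens, added back to the
reduced-model fitted values, and the term's F is recomputed; the
p-value is the proportion of the permutation distribution — observed
arrangement included, so `p >= 1/n_perm` — at or above the observed F.
Effect sizes are `R^2 = SS/SS_total` and the standard deviate Z of the
observed F against the permuted distribution. Defaults: `n_perm =
1000` total. The model formulas used by the dimorphism and species
batteries enter size (log10 CS) before the grouping factor, so group
terms are always tested after allometry is accounted for, and no
size-by-group interaction is fitted. With a scalar response and one
factor the machinery reduces exactly to classical one-way ANOVA, which
the tests assert.

### Dispersion, PLS, ANOVA/Tukey

`dispersion_test()` compares each group's Procrustes variance (mean
squared distance of members from their group mean); the pairwise
statistic is `|var_i - var_j|` and the null is built by permuting
group labels. `two_block_pls()` decomposes the cross-block covariance
by SVD; `rPLS` is the absolute correlation of the first paired axis
scores (so `rPLS` is in `[0, 1]` and invariant to orthogonal rotation
of either block), with significance by permuting rows of the second
block. `anova_tukey()` delegates to `stats::aov()`/`stats::TukeyHSD()`
(Tukey-Kramer standard errors for unbalanced groups); degenerate
zero-residual inputs return p = 1 (all values identical) or p = 0
(perfect separation) with a warning rather than `NaN`.

All permutation tests are bit-reproducible given `(seed, n_perm)`, and
every result object records both.

## 3. The rarefaction experiment

`run_rarefaction()` draws, for each fraction bin (default 100, 75, 50,
25, 10%) and iteration, a without-replacement subsample of
`round-half-up(fraction * n)` specimens (so 10% of 72 is 7 and of 81
is 8), runs a complete GPA — including sliding, by default — on the
subsample alone, and records its consensus, its mean log10 centroid
size, and the partial Procrustes distance between its consensus and
the full-sample consensus, which plays the role of the "true" mean.
Each draw's seed is `base_seed * 1e6 + bin_index * 1e4 + iteration`,
recorded in the output (hence `base_seed <= 2000`, keeping seeds below
2^31). The 100% bin is by construction identical in every iteration
with distance zero; it is computed once and replicated.

Sliding inside every subsample (toggleable via `slide`) treats each
subsample as a self-contained study — the scenario the experiment
models; centroid sizes are always computed from the raw coordinates,
so they are identical whether or not sliding is enabled, and
`do_shapes = FALSE` is an exact fast path when only size questions are
asked.

`summarize_rarefaction()` applies the comparison battery: ANOVA +
Tukey of mean log CS across bins (100% bin included); ANOVA + Tukey of
distance-to-true across bins, with the degenerate all-zero 100% bin
excluded by default; a pairwise dispersion test of subsample means
across bins; and projection of all subsample means (each re-aligned to
the full consensus, since every subsample GPA has arbitrary
orientation) into the full-sample PC space, with per-bin convex hulls.
Treating each permuted subsample as one observation replicates the
published form of this battery and is acknowledged pseudo-replication:
iterations within a bin share specimens, so these p-values describe
this experiment, not independent samples. Under the isotropic
generator, the expected squared distance of a subsample mean from the
true mean is proportional to `1/m - 1/n`; the acceptance script fits
this law and reports its R².

`pc1_grids_for_iterations()` rebuilds selected subsamples, runs their
own PCA, and exports TPS deformation grids from the subsample
consensus to its PC1 extremes alongside the full-sample grids;
`grid_field_correlation()` quantifies their agreement (orientation of
a PC is arbitrary, so the sign yielding the larger magnitude is
reported).

## 4. The synthetic-data generator

`generate_dataset()` emulates the structure of an intraspecific
museum sample digitized in one view. Specimen *i* of group *g* is

```
coords_i = CS_i * R(theta_i) * (template + offset_g
           + slope * (log10 CS_i - mean) * allometry + eps_i) + t_i
```

with isotropic Gaussian landmark noise `eps`, random rotation and
translation, and log-normal centroid sizes. Built-in templates carry
the three digitizing layouts used throughout: lateral cranium (14
landmarks + one 15-point curve), ventral cranium (19 + 6), mandible
(10 + curves of 6, 6, and 18), each with anchored slider tables so
every semilandmark slides.

Defaults (one decision, stated here, not revisited): 48 females and 24
males; mean log10 CS 1.5 (about 32 mm) with sd 0.03 (~7% CV); females
larger by 0.03 log10 units (~7%); landmark noise sd 0.01 per
coordinate in units of template centroid size (1% of CS, a realistic
digitizing error); allometry slope 1.2 shape units per log10 CS unit
(~15–20% of shape variance, ordinary for skulls); sex shape offset of
norm 0.025, which yields a sex term of a few percent of total shape
variance after size — deliberately borderline-significant at n = 72,
the regime where view and sample-size choices genuinely change
conclusions. `generate_two_species_overlap()` adds a smaller congener
(default 22 specimens) whose shape offset (norm 0.005, half the noise
sd) leaves its shape space nested inside the larger species' — a
morphologically cryptic pair.

Two design choices matter for validation. First, effect vectors
(allometry, sex, species) are random combinations of the template's
*smoothest* non-affine principal warps — the lowest-eigenvalue
eigenvectors of the bending-energy matrix — rather than white-noise
vectors: biological shape effects are smooth, large-scale
deformations, and rough effect vectors would be partially absorbed by
semilandmark sliding, which by construction treats high-frequency
along-curve displacement as nuisance. Second, effect vectors are
orthogonalized against the template's similarity directions
(translations, rotation, scaling) *and* against the slide tangents of
the semilandmarks, so the injected truth lies exactly in the subspace
a Procrustes-plus-sliding analysis can estimate. Recovery comparisons
are made in that subspace: the estimated allometry vector is rotated
from the arbitrary consensus orientation into the template frame and
projected off the slide tangents before its direction cosine is taken.

What the generator does *not* emulate: correlated (anisotropic or
landmark-specific) digitizing error, inter-observer effects,
geographic or temporal structure, asymmetry, and curve resampling
error. Tests passing on this generator therefore validate the
estimators and the experiment's logic, not the full error structure of
real museum data.

## 5. Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the experiments at sizes
chosen to make their statistical assertions meaningful while staying
quick on a single CPU: rarefaction experiments at T = 200 iterations
per bin (with 20 and 50 replicate experiments for the dispersion and
centroid-size properties), permutation-calibration studies of 200–500
null datasets with `n_perm = 200`, and parameter-recovery checks at
n = 80. At these sizes the binomial uncertainty of a 5% rejection rate
is about ±1 percentage point (500 simulations), which is what the
calibration bands assert. Every stochastic step derives from an
explicit seed; the acceptance script threads a single `--seed` through
all of them.

## 6. Known limitations

* 2D only; no 3D rotation, surface semilandmarks, or Morphologika/NTS
  readers.
* Bending-energy sliding is the only sliding criterion; its collective
  drift mode is controlled by a trust region (Section 1), not removed —
  reported semilandmark positions along a curve should not be
  over-interpreted.
* The distance ANOVA across rarefaction bins inherits the
  pseudo-replication of the published battery (Section 3).
* Tangent-space projection is not applied; at very large shape
  variation (Procrustes distances approaching 1) the linear statistics
  would need it.
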