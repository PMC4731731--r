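# pspica

Likelihood-based independent component analysis with nonparametric
source densities estimated by **P-spline histogram smoothing**, and a
**parcellation** variant that lets the source densities differ across
brain regions.

## The problem

Spatial group ICA models multi-subject fMRI (or any mixed-signal
matrix) as

```
X = A S,        B = A⁻¹,        S = B X
```

with `X` a `Q × V` matrix (rows: reduced dimensions/channels, columns:
voxels), `A` a full-rank mixing matrix whose columns are component time
courses, and the rows of `S` independent spatial maps.  Most ICA
algorithms hunt for marginal non-Gaussianity of the rows of `S`.  That
fails in a regime that matters for brain imaging: sources whose
*overall* distribution is close to Gaussian but whose distribution
*differs by region* (active networks are spatially confined).  `pspica`
instead maximizes the joint log-likelihood

```
L(B, f) = Σ_v Σ_q log f_q(B[q,] X[,v]) + V log|det B|
```

where each density `f_q` — or each region-specific density `f_iq` under
a parcellation — is estimated from the current unmixed sources by an
exceedingly simple and fast device: bin the values into an equidistant
histogram, model the bin counts as Poisson with a log-linear cubic
B-spline intensity, and smooth with a second-order difference penalty
(the Eilers–Marx P-spline).  The log-density is then a spline, so the
score function and its derivative — everything a Newton-Raphson update
of `B` needs — are analytic.  Convergence is declared on the Amari
distance between successive unmixing matrices, a metric blind to the
permutation and scaling indeterminacies of ICA.

Who this is for: anyone separating mixed signals where source
distributions are unknown, heavy-tailed, or region-structured —
resting-state fMRI networks being the motivating case — and anyone who
wants a fully specified likelihood (for model comparison or further
inference) rather than a contrast function.

## Worked example

Two dependent, marginally near-Gaussian sources built on the
standard-normal decile strata — uniform within each stratum for one
component, truncated Laplace for the other — mixed by
`A = [[2, 1], [3, 2]]`.  This is exactly the regime where
non-Gaussianity-seeking ICA breaks and region-specific densities
rescue the fit:

```r
library(pspica)

sim <- sim_setting2(V = 10000, seed = 11)     # labels = the 10 strata
fit_region <- pspica(sim$X, parcellation = sim$labels,
                     config = ica_config(max_iter = 60))
fit_global <- pspica(sim$X, config = ica_config(max_iter = 60))
base       <- fastica_ref(sim$X, 2, seed = 11)

amari_error(fit_region$B, sim$A_true[[1]])   # 0.0129
amari_error(fit_global$B, sim$A_true[[1]])   # 0.455
amari_error(base$B,       sim$A_true[[1]])   # 0.768

spatial_correlation(fit_region$S, sim$S_true)  # 0.999997 0.99999 (matched |r|)
```

The Amari error is ~0 only when the estimated unmixing inverts the true
mixing up to row order and scale: the parcellation fit recovers the
mixing essentially exactly (0.013), while the same likelihood with one
global density per component (0.455) and the fixed-point baseline
(0.768) are badly biased — they only see the near-Gaussian marginals.

Multi-subject data go through two-stage SVD reduction and
back-reconstruction of per-subject mixing matrices:

```r
sim3 <- sim_setting3(V = 10000, seed = 11)
gfit <- group_pspica(sim3$subjects, Q = 2, parcellation = sim3$labels,
                     config = ica_config(max_iter = 60))
spatial_correlation(gfit$S, sim3$S_true)     # 0.99999 0.99999
gfit$subject_mixing                          # three 2 × 2 estimates of A₁, A₂, A₃
```

A command-line front end (`inst/cli/pspica.R`) exposes `simulate`,
`fit` (delimited matrices or 4D NIfTI + mask, optional `--parcellation`
label volume), `benchmark`, and `density-fit`.

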