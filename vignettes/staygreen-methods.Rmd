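---
title: "Modeling stay-green: spatial correction, growth curves, G x E and haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stay-green: spatial correction, growth curves, G x E and haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(staygreen)
```

## The problem

Stay-green — delayed canopy senescence after flowering — extends the
photosynthetic duration of a cereal crop during grain filling and has been
linked to yield under water limitation. Quantifying it in a breeding panel
requires a chain of models: multi-temporal canopy reflectance (NDRE) per
field plot must be cleaned of spatial field trends, summarized into smooth
senescence trajectories per genotype, compared across environments with an
explicit genotype-by-environment (G x E) covariance, and finally mapped to
haplotypes a breeder can select on. This package implements that chain
end-to-end, together with a synthetic trial generator whose ground truth
makes every stage testable by parameter recovery.

## Stage 1: spatial correction

Each flight (timepoint) of each trial is analyzed on the plot grid with two
candidate mixed models:

* **SpATS-style P-spline model** — intercept + flowering group (fixed),
  random genotype, row and column effects, and a tensor-product
  two-dimensional P-spline surface `f(u, v)` (cubic B-splines, second-order
  difference penalty, about one marginal knot per two rows/columns),
  REML-smoothed. The default engine is `mgcv::gam()`; an internal dense
  REML engine fits the same model through its PS-ANOVA mixed-model
  decomposition and is used where exact likelihood comparisons between
  nested fits are needed.
* **AR1 x AR1 linear mixed model** — the same fixed and random design with
  a separable first-order autoregressive residual correlation over rows and
  columns, `corr(e_i, e_j) = rho_r^|dr| * rho_c^|dc|`, fitted by direct
  REML maximization (`reml_lmm()`).

Per flight, the *spatially corrected* value is the observation minus the
estimated spatial and design effects, so corrected + removed = observed
exactly — an identity the tests assert at machine precision. Broad-sense
heritability per flight uses the generalized prediction-error-variance
form `h2 = 1 - A_tt / (2 * sigma2_g)`, with `A_tt` the average PEV of
genotype-difference BLUPs; the SpATS fit also exposes the
effective-dimension form `ED_genotype / (n_genotypes - 1)`. The vote uses
the PEV form for both models so the two candidates are compared on the
same scale. The model with the higher heritability at more flights wins; a
tied vote goes to the higher mean, and a remaining tie to the P-spline
model.

Two caveats worth knowing. First, with a flowering-group fixed effect and
genotype random, the heritability of a noise-free trial does not reach 1:
BLUP differences across flowering groups retain the group-mean estimation
variance, which is itself driven by genetic variance, capping `h2` near
`1 - k / n`. Second, under this generator's smooth surfaces the two
spatial models are near-equivalent and the AR1 model often attains a
slightly higher generalized heritability; which model wins is
data-dependent, so the package tests the voting rule itself rather than a
fixed winner.

Yield receives the AR1 model with genotype *fixed*, giving per-genotype
BLUEs (t/ha); the companion genotype-random fit supplies its generalized
heritability.

## Stage 2: hierarchical growth curves

Spatially corrected NDRE is modeled over thermal time (growing degree
days, base 0 degrees C — the common barley convention, configurable) with a
three-level nested P-spline,

`y_pgi(t) = f_p(t) + f_pg(t) + f_pgi(t) + e`,

population curve plus genotype and plot (individual) smooth deviations.
The population basis is cubic with a second-order difference penalty and
seven equally spaced interior knots on the trial's observed thermal-time
range (the knot count is configurable; "seven knots" is read as seven
interior knots). The deviation levels use a nested coarser basis sized to
the flight count (the largest of 7, 3, 1 interior knots not exceeding the
number of distinct timepoints minus two): with only three or four flights,
eleven coefficients per genotype are unsupportable and the restricted
likelihood would simply shrink the whole level away, whereas a basis the
data can fill keeps the genotype signal. Because the coarse knots nest
inside the population knots, deviation coefficients convert exactly into
population-basis coefficients, so all downstream derivative and integral
identities are unaffected. The fit is penalized least squares in mixed-model form: the
population penalty null space (constant + linear) is fixed; all other
coefficients become proper random effects after a Demmler–Reinsch rotation
of the penalty, each level carrying a wiggle and a null-space smoothing
parameter estimated by REML from one sparse Cholesky factorization per
candidate (`Matrix`). The optimizer is bounded L-BFGS-B on the log
smoothing parameters; bounds at e^±20 prevent drift along the flat
direction that appears when a level (typically the plot level in lightly
replicated trials) is superfluous. One population per trial is used; the
stage-1 standard errors are not propagated (unweighted second stage), in
keeping with the pseudo-two-stage design.

A property worth knowing when reading outputs: with only three or four
flights the REML-optimal smoothing shrinks genotype deviation *scale*
heavily (classic BLUP attenuation — the restricted likelihood verifiably
prefers it; genotype rankings are preserved, with truth correlations near
0.9 in recovery checks, but the spread of extracted traits from sparsely
flown trials understates the true genetic spread). Densely flown trials
are much less affected. Cross-environment analyses downstream are
correlation- and polarity-based, so they are robust to this per-trial
scale attenuation.

Because every fitted curve is a plain B-spline coefficient vector,
derivatives and integrals are exact:

* `scsAUC` = integral of the genotype curve over the grain-filling window
  (NDRE x GDD; larger = more retained greenness),
* `d1AUC` = integral of the first derivative = `f(end) - f(start)`
  (fundamental-theorem identity, asserted in tests),
* `rAUC` = integral of |f'|, so larger means more total senescence; the
  sign convention makes a *negative* effect on rAUC beneficial. Both the
  absolute (`rAUC`) and signed (`rAUC_signed`) variants are reported; the
  absolute integral is computed exactly by locating the sign changes of
  the piecewise-quadratic derivative.

The grain-filling window is per-trial configuration (the generator's
default is 1500–1950 GDD); no fixed window is asserted.

## Stage 3: multi-environment analysis

The genotype x environment table of scsAUC values is treated as iid draws
per genotype from `N(tau, Sigma)` — spatial correction is already done, so
no trial-specific design effects enter — and `Sigma` is estimated by REML
under DIAG, CorV (one variance, one correlation), CorH (heterogeneous
variances, one correlation) and FA(k) structures, `Sigma = Lambda Lambda' +
Psi`. Missing cells are marginalized by missingness pattern. The
likelihood is maximized numerically (BFGS with a Nelder–Mead polish,
moment-based starts plus jittered restarts; FA loadings are parameterized
with the upper-triangle zero constraint, giving `E*k - k(k-1)/2 + E` free
parameters, and `AIC = -2 logL + 2p` with that count).

After fitting, loadings are SVD-rotated to principal orientation and each
factor's sign is flipped so its largest-magnitude loading is positive.
iClass polarity strings (per environment, 'P' for a non-negative loading,
'N' otherwise) are therefore convention-relative; a zero loading counts as
'P' so the labeling is deterministic. Model selection keeps fits within an
AIC window (default 10) of the best and picks the highest percent variance
accounted, `100 * lambda_jk^2 / (sum_k lambda_jk^2 + psi_j)` summed over
factors and averaged over environments — with one refinement: because that
percentage is monotone non-decreasing in k, a smaller model within 2
percentage points of the best is preferred, which keeps the selected order
at the simulated rank in recovery tests instead of drifting up by
fractions of a point.

iClass BLUEs are the genotype's predicted environment effects (conditional
means under the fitted `Sigma`, plus environment means) averaged over the
iClass's member environments.

Genetic correlation between scsAUC and yield is estimated per environment
from a bivariate mixed model with a VanRaden kinship matrix (`G = W W' /
(2 sum p(1-p))` on mean-imputed, centered dosages; a small ridge
stabilizes inversion): `r_g = sigma_g12 / sqrt(sigma_g1^2 sigma_g2^2)`,
computed via the eigendecomposition of G so each eigencomponent
contributes an independent 2 x 2 likelihood term. The study's own
correlation came from one joint multi-environment multi-trait fit; the
per-environment bivariate fit here is a documented simplification and
equivalence is not claimed. Phenotypic correlation is the Pearson
correlation of the BLUEs.

## Stage 4: haplotypes

Markers are curated by the panel's rules — minor allele frequency of at
most 0.05 removed (boundary inclusive), heterozygosity above 10% removed
(boundary exclusive), missing dosages mean-imputed afterwards. Diversity
is summarized by Rogers' distance (per locus, the Euclidean distance
between the two individuals' allele-frequency vectors scaled by 1/sqrt(2);
for biallelic dosages this reduces to |d1 - d2| / 2), principal
coordinates of the distance matrix and UPGMA clustering.

LD blocks come from a greedy left-to-right scan within each chromosome:
the current block extends while the candidate's squared dosage correlation
with the block *anchor* (first member) reaches the threshold (0.7), with
up to `tolerance` (2) below-threshold markers absorbed per block; the
first marker that would exceed the tolerance opens a new block. This is
one deterministic reading of an ambiguous published rule; block counts are
sensitive to it, so no specific block count is asserted anywhere. Blocks
partition the curated markers by construction.

Marker effects come from ridge-regression BLUP on column-centered dosages,
with the shrinkage `lambda = sigma2_e / sigma2_u` REML-estimated through
the eigendecomposition of the genotype kernel. A haplotype's localGEBV is
the sum over the block's markers of effect x centered dosage encoded by
its string — the same centering as the ridge fit, which makes the
decomposition exact: per genotype, localGEBVs over all blocks sum to the
full GEBV at machine precision (a key tested identity). Per block, the
variance of effects across distinct non-heterozygous haplotypes
(unweighted; a carrier-weighted option exists) is min–max scaled
genome-wide to [0, 1]; blocks at or above 0.3 are significant, and
haplotypes are beneficial when their effect is positive for scsAUC or
negative for rAUC. Stacking counts, per genotype, the significant blocks
carrying a beneficial haplotype and summarizes mean trait value by count,
with the linear-trend slope computed by regressing the genotype trait
value on the count (equivalent to a group-size-weighted fit on the group
means).

## The synthetic generator

`sim_config()` defaults are the study conditions: 397 inbred genotypes in
3 ancestry clusters; 7 chromosomes x 765 two-marker founder blocks
(~10,700 raw SNPs, of which a `rare_frac` = 0.47 share is simulated below
the MAF threshold so curation leaves roughly 5,700 markers in ~2,850
blocks); six environments named after the study's trials with 3, 3, 3, 4,
7 and 3 post-flowering flights — dense schedules span anthesis to maturity
(1480–2050 GDD) while sparse ones concentrate on grain filling
(1550–1950 GDD), matching how such trials are flown; 30% plot replication
in two half-field blocks; smooth random spatial surfaces (sd 0.02 NDRE);
AR1-in-time residuals (rho 0.3, sd 0.015); and yield with plot-level
heritability 0.8. Senescence is a four-parameter logistic decline in
thermal time (upper asymptote 0.45 NDRE, lower 0.05, scale 60 GDD); all
genetic effects act as shifts of the inflection point, scaled so one unit
of effect equals one unit of scsAUC. Genetic architecture: six causal
blocks of effect +2.5 scsAUC units each (one per chromosome 1–6), a
genome-wide polygenic background (sd 4), and factor-analytic G x E
deviations (`Lambda f + delta`, loadings of order 6–12 scsAUC units with a
mixed-sign second factor, specific variances 3) on top. Together these put
the inflection-time spread near 25–35 GDD — a realistic maturity spread
for a diverse panel — and the trait-level heritability in the published
0.6–0.99 range. The target stay-green/yield genetic correlation (default
0.7, inside the study's reported 0.33–0.79 range) is imposed *exactly* on
the marker-genetic values by empirical orthogonalization, which is what a
kinship-based estimator can recover; the factor-analytic deviations are
deliberately not marker-associated and act as non-marker genetic variance.

What the generator does **not** emulate: weather-driven senescence
dynamics, curve-shape genetic variation beyond inflection shifts,
selection or pedigree structure, genotype-by-management interactions, and
measurement artifacts of real UAV imagery (registration error, mixed
pixels, incomplete flights). Passing recovery tests therefore shows the
estimators are correct under the stated statistical structure, not that
real trials satisfy that structure.

## Numerical choices and degenerate inputs

* REML optimizers work on log variance ratios (and atanh-scaled
  correlations); Cholesky failures return a large penalty value rather
  than aborting, and non-finite inputs are rejected up front.
* A zero genetic variance returns heritability 0 with a warning; a single
  LD block makes the scaled variance undefined and is reported as 1 with a
  warning; an all-equal block-variance vector scales to 0.
* Exact-zero FA loadings take polarity 'P'; model-selection ties go to
  fewer parameters, then lower AIC.
* Missing plots are dropped from a flight's fit, never imputed; missing
  genotype x environment cells are marginalized in the MET likelihood.
* Fits are deterministic given the configuration seed; multi-start
  optimizers derive their jitter from a caller-supplied seed.

## Problem sizes used in the packaged checks

The test-suite and acceptance computations run the generator at reduced
but structurally faithful sizes, chosen so each estimator operates in the
regime where its asymptotics hold: covariance recovery at n = 400
genotypes x 6 environments; AR1 recovery on a 20 x 13 grid; heritability
and BLUE accuracy at n = 300 with 30–50% replication; surface recovery at
n = 150 plots per flight; LD-block and stacking recovery at n = 250–400
genotypes with 2–3-marker blocks. The `analysis/` scripts run the full
study-scale simulation.

## Known limitations

* The AR1 model requires unique (row, column) positions; irregular
  layouts fall back to the P-spline model.
* The MET stage is strictly two-stage: stage-1 uncertainty is ignored
  (optional 1/SE^2 weights are accepted but not default).
* The per-environment bivariate genetic correlation is a simplification
  of a joint multi-environment multi-trait fit.
* The LD-block scan rule is one of several defensible readings of
  "marker tolerance"; downstream block counts depend on it.
* Heterozygous haplotype strings are excluded from block-variance
  computation (carriers still receive localGEBVs); this is appropriate
  for inbred panels and would need revisiting for outbred material.
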