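---
title: "Quantifying humidity-dependent wound self-sealing in succulent leaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying humidity-dependent wound self-sealing in succulent leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylloseal)
```

## The phenomenon and the measurement

Succulent leaves of some ice plants seal transversal wounds within minutes:
the whole leaf bends until the fissure closes.  The movement is driven by
evaporation-dependent turgor changes in the parenchyma and chlorenchyma cells
exposed at the wound, assisted by growth-induced pre-stresses in the leaf's
five concentric tissue layers.  Because evaporation depends on the humidity
at the wound, the bending response does too: dry air closes the wound
fastest, water-saturated air barely moves it, and a liquid water droplet on
the wound reverses the movement (the fissure opens).

The standard laboratory protocol films the wounded leaf at one frame every
30 s for 55 min and tracks three labelled points: near the leaf base (1),
next to the injury (2) and at the tip (3).  With point 2 as origin, `alpha`
is the orientation of the base line (2 to 1) against the horizontal and `beta`
that of the tip line (2 to 3).  The *actual bending angle*

$$\delta = \beta - \alpha$$

removes rigid motion of the leaf base, and the *relative bending angle*

$$\gamma_n = \delta_n - \delta_0$$

subtracts the pre-injury bend, so that `gamma` is exactly zero before
wounding, positive while the lesion closes and negative when it opens.
`gamma` at 1, 5, 10, 20, 40 and 55 min is the self-sealing efficiency
metric that feeds the statistics.

### Angle conventions

The tracked lines are undirected, so `alpha` and `beta` are *line* angles on
(-90, 90] degrees, and `delta` is wrapped onto the same range.  This makes
`delta` and `gamma` invariant under rigid motion and uniform scaling of the
whole configuration - the properties the tests assert to 1e-9 degrees - at
the price of ambiguity for bending beyond 90 degrees, far outside observed
magnitudes.  A continuity check rejects series whose `delta` jumps by 90
degrees or more between consecutive frames rather than silently unwrapping
them.  Image-frame coordinates (y axis pointing down) are declared in the
track file header and mirrored on ingestion, so closure keeps a positive
sign either way; `flip_sign` in `track_angles()` covers wounds on the
opposite flank.  Evaluation times are mapped to the nearest frame, with ties
broken toward the earlier frame, and the chosen frame is reported so the
mapping stays auditable.

## The synthetic experiment generator

`sealing_scenario()` encodes the full humidity x time design: 4 conditions
(24 %, 49 %, 100 % relative humidity, water droplet) x 6 evaluation times x
17 leaves, one frame per 30 s over 55 min.  The latent angle follows a
saturating exponential

$$\gamma_{sc}(t) = (\gamma^\infty_c + b_s)\,\bigl(1 - e^{-t/\tau_c}\bigr),$$

the simplest two-parameter curve with the observed behaviour (monotone rise
to a condition-dependent plateau).  The subject effect $b_s \sim N(0,
\sigma_s^2)$ is an additive offset on the asymptote shared across a leaf's
conditions, which yields a well-defined fully crossed repeated-measures
structure.  Default condition parameters are $\gamma^\infty$ = 18, 10, 2,
-12 degrees and $\tau$ = 8, 12, 20, 6 min for 24 %, 49 %, 100 % and droplet:
plausible shapes of the right sign, order and magnitude, deliberately *not*
calibrated to any published figure, so recovery tests always compare against
the generator's own ground truth.  Emitted coordinates realise the latent
angle exactly: point 2 sits at a fixed hinge, point 1 on a base ray with a
smooth sinusoidal drift (default amplitude 1 degree, emulating rigid motion
of the whole leaf), point 3 on a tip ray at `delta_0 + gamma(t)` from the
base ray; i.i.d. Gaussian noise (default 0.02 mm on 10-15 mm arms, i.e.
roughly 0.1-0.2 degrees of angle noise) is added to every coordinate.
Identical seeds give byte-identical exports.

What the generator does *not* emulate: pixel-level tracking error models,
autocorrelated drift, missing frames, or leaves that leave the focal plane.
Passing recovery tests therefore demonstrate the correctness of the
analysis chain, not robustness to every failure mode of real video
tracking.

The tensile generator grows displacement at `strain_rate * L0` per second
(defaults 0.002 1/s, 5 Hz sampling, matching the laboratory protocol) and
builds the stress curve from a linear segment of slope `true_E` up to a
yield point at 60 % of `true_strength`, a slope-continuous concave quadratic
that attains `true_strength` exactly, and a plateau - so strength recovery
is exact by construction and modulus recovery is a genuine test of the
window detector.  Default ground truth (E = 0.72 MPa, strength = 0.09 MPa,
Poisson 0.28, 1.5 mm circular cross-section) sits at the published medians
for whole leaves, i.e. in the physically relevant regime.

## Tensile analysis

Cross-sections are ellipses, $A = \pi a b$, averaged over five stations
along the leaf (a rectangle mode covers epidermis strips); engineering
stress and strain are $\sigma_i = F_i/\bar A$ and $\varepsilon_i = \Delta
L_i/L_0$; tensile strength is $\sigma_{max} = \max(F)/\bar A$, using the
pre-rupture peak; Poisson's ratio is the transverse/axial strain quotient
between the first and last image of the linear-elastic range.  Tapered
vascular strands use the circular cross-section from their basal radius.

The elastic modulus is the slope of the initial linear part of the
stress-strain curve.  Since no criterion for "initial linear part" is
standard, the detector scans prefix windows from the low-strain end and
keeps the longest window whose least-squares line reaches a coefficient of
determination of at least `r2_threshold` - deterministic and fully
auditable (window bounds and R^2 are returned).  The default threshold is
`1 - 1e-6`: prefix R^2 reacts slowly to the gentle onset of yielding, and
looser thresholds (we measured 2.7 % modulus bias at 0.999 on the noiseless
reference curve, versus 0.04 % at the default) would silently blend
post-yield points into the fit.  For noisy records the threshold *must* be
relaxed to roughly the R^2 the noise itself permits,
$1 - \sigma^2_{noise}/\sigma^2_{signal}$; the error message says so.

## The turgor-based tissue modulus

Parenchyma and chlorenchyma are too soft and too wet to test in isolation;
their stiffness is instead computed from single-cell measurements.  The
tissue modulus is modelled as two additive contributions,

$$E_{tissue} = c_P\,P \;+\; c_w\,\frac{t_{cw}}{d_c}\,E_{cw},$$

a turgor term linear in the cell pressure `P` (a fluid-filled thin-walled
cell stiffens in proportion to its internal pressure) and a wall term
proportional to the wall volume fraction `t_cw/d_c` and the wall modulus
`E_cw` (the load path through the wall network).  The default order-unity
coefficients $c_P = 4$ and $c_w = 3$ are fixed for approximately
isodiametric, thin-walled, turgid cells and are gated by a checkpoint test:
at the published median parameters (P = 0.042 MPa, d_c = 77 um, t_cw =
0.42 um, nu = 0.28, E_cw = 5.00 MPa) the model must return 0.25 MPa to two
decimals.  Both coefficients are exposed as arguments.  A known limitation:
Poisson's ratio is validated and carried through but does not enter the
default form; variants of this relation in the literature differ precisely
in how `nu` modulates the two terms, and the checkpoint cannot distinguish
them.  The affine-in-P and monotone-in-geometry contracts hold for any such
variant and are what the property tests pin down.

Morphometric companions: the net of peripheral vascular bundles is converted
to a continuous ring of equal total area ($t = \sum A_i / 2\pi r$);
histological shrinkage of succulent parenchymatous tissue (about 15 % in
linear dimension during thin-section preparation) is undone by
`measured / (1 - f)` - treated as a linear, not areal, correction, and
configurable since the measurement protocol does not fix it.  Absolute
humidity scales a known saturation content by relative humidity, or derives
it from temperature via the Magnus approximation (constants 6.1094 hPa,
17.625, 243.04 degC - one published set, fixed for reproducibility) and the
ideal-gas law; at 22 degC this reproduces the 19.41 g/m^3 saturation content
the standard humidity table implies to within 0.2 %.

## Rank-based repeated-measures inference

Bending angles are bounded, skewed and heteroscedastic across conditions, so
the factorial analysis runs on ranks: all `4 x 6 x n` values are pooled and
ranked once (average ranks for ties), then a two-way ANOVA with *both*
factors within subject partitions the sums of squares, with the
factor x subject interactions as error terms:

| effect           | df1          | df2                   |
|------------------|--------------|-----------------------|
| condition        | a - 1        | (a - 1)(n - 1)        |
| time             | b - 1        | (b - 1)(n - 1)        |
| condition x time | (a - 1)(b - 1) | (a - 1)(b - 1)(n - 1) |

For the standard design (a = 4, b = 6, n = 17) this gives the familiar
(3, 48), (5, 80) and (15, 240) patterns.  Global ranking is the default
because it is the plain reading of "ANOVA on rank-transformed data"; the
`per-effect` option implements the aligned-rank transform (strip the other
effects' estimates, rank the aligned values, refit) for users who want
effect-wise rank tests.  Sphericity is assessed per effect from the
covariance of orthonormal-contrast scores: Mauchly's W with the Box
chi-square approximation (including the second-order term; note that
software packages differ in the last digit of this p-value by convention)
and the Greenhouse-Geisser epsilon, with both uncorrected and
epsilon-corrected p-values reported.  Post-hoc comparisons are paired
Student t-tests on subject means marginalised over the other factor, on the
rank scale, Bonferroni-adjusted with `m = k(k-1)/2`; the choice of paired
tests on the rank scale follows from the within-subject design and the rank
transform already adopted for the omnibus test.

Companions used in the tissue analyses: Spearman's rho as rank-then-Pearson
with an exact permutation p for n <= 9; the Wilcoxon-Mann-Whitney test with
W equal to the first sample's Mann-Whitney U (the convention of R's
`wilcox.test`, the software the protocol itself prescribes), exact by
enumeration for n1 + n2 <= 12 and tie-corrected normal approximation with
continuity correction otherwise; medians and IQRs with type-7 quantiles
(linear interpolation between closest order statistics), fixed and
documented because quantile conventions differ.

## Validation strategy and problem sizes

Every stage is tested against an independent oracle: the ANOVA against a
brute-force sums-of-squares computation from cell and marginal means (100
random designs, agreement to 1e-8, plus spot agreement with `aov` error
strata and `car::Anova` sphericity output), the window detector against an
exhaustive per-window `lm` scan, the exact nonparametric p-values against
closed-form null distributions, and the kinematics against closed-form
evaluation of the latent model.  Calibration of the test statistics is
checked by simulation: under a null scenario (all asymptotes zero, equal
time constants, so conditions are exchangeable) the condition effect rejects
at 5.3 % over 1,000 seeded replicates, inside the exact binomial 99 % band
around 0.05; a fully quiet scenario stays free of any flagged effect in
95 of 100 replicates on the sphericity-corrected p-values.  Null replicates
run on the evaluation-time frame grid (7 frames per series instead of 111),
which leaves the recovered angles unchanged at those times and keeps the
whole suite around a minute.

## Known limitations

* The tissue-modulus coefficients are calibrated against a single published
  checkpoint; data spanning a range of turgor would be needed to identify
  the `nu`-dependence.
* Global ranking makes the three F-tests mutually dependent in ways the
  nominal F reference does not model; the null simulations above bound the
  practical consequence for the condition effect.
* The generator's subject effect enters only the asymptote; leaves with
  subject-specific time constants would violate sphericity more strongly
  than the default scenario does.
* `delta` beyond +/-90 degrees is rejected, not unwrapped; leaves that fold
  completely over need a different parameterisation.
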