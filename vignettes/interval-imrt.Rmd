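---
title: "Interval-valued dose and robust IMRT planning with intervalRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-valued dose and robust IMRT planning with intervalRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intervalRT)
```

## The problem

IMRT optimizes a nonnegative fluence vector $x$ (one weight per beamlet,
or *bixel*) so that the dose $d = Dx$ conforms to a prescription on the
clinical target volume (CTV) while sparing organs at risk (OARs). The dose
actually delivered depends on patient positioning: a rigid setup error
$\delta$ changes the dose-influence matrix to $D_\delta$. Classical
planning absorbs this by expanding the CTV into a planning target volume
(PTV); worst-case (minimax) planning optimizes the worst discrete
scenario. Both are extremes: margins ignore the structure of the error
distribution, minimax over-weights rare large errors.

`intervalRT` instead carries, for every voxel $i$, a dose *interval*
$[d_{c,i}(x),\, d_{r,i}(x)]$ — the mean and standard deviation of the
scenario doses:

$$d_c(x) = \sum_k w_k D_k x = D_c x, \qquad
  d_{r,i}(x)^2 = \sum_k w_k \big((D_k - D_c)x\big)_i^2 .$$

The deviation form on the right is how the package evaluates the radius:
it is algebraically identical to $E[d^2] - E[d]^2$ but numerically stable;
negative round-off is clamped at zero (tolerance $10^{-12}$ relative).

## The CTV objective and $\theta$

Target coverage is scored with the Bertoluzza distance between intervals,
$\lVert\Delta_\theta(X,Y)\rVert = \sqrt{(x_c-y_c)^2 + \theta (x_r-y_r)^2}$,
against the degenerate prescription interval $[p, 0]$:

$$F_{CTV}(x) = \sum_{i \in CTV} (d_{c,i}(x) - p)^2 + \theta\, d_{r,i}(x)^2 .$$

$\theta \ge 0$ is the single robustness dial: $\theta = 0$ optimizes only
the expected dose, $\theta = 1$ weights accuracy and spread equally, large
$\theta$ suppresses spread at the expense of nominal accuracy. The package
default is $\theta = 10$. At fixed $x$ the composite objective is
non-decreasing in $\theta$ (the spread term is a sum of squares), which the
test suite asserts; across *optimized* plans the mean CTV dose standard
deviation decreases as $\theta$ grows.

OAR, body and conformity-ring penalties are evaluated on the upper bound
$\bar d = d_c + d_r$ — a conservative closure, since every penalty used
there is monotone in dose. The CTV minimum-dose penalty is evaluated on the
lower bound $d_c - d_r$, the CTV maximum-dose and DVH penalties on
$\bar d$. The CTV squared-deviation row of the objective table is subsumed
by $F_{CTV}$ in interval mode; its weight $\omega_{CTV}$ defaults to 1,
which under the package's voxel-mean aggregation puts the Bertoluzza term
on the same footing as the other structure weights (2–100). Penalties are
voxel means, not sums, so weights are grid-resolution independent.

## Scenario sets

Setup errors are zero-mean uncorrelated Gaussians with
$\sigma = (5, 10, 5)$ mm in the left–right, anterior–posterior and
inferior–superior directions (a clinically characterized prostate setup
error magnitude). Two finite sets are drawn from this distribution:

* **Optimization set** (13 scenarios): the nominal scenario plus four
  single-axis shifts per axis at $\pm 0.5\sigma$ and $\pm 1.0\sigma$.
* **Evaluation grid** ($5^3 = 125$ scenarios): the Cartesian product of
  $\{-1.5, -0.75, 0, 0.75, 1.5\}\sigma$ per axis.

Weights are proportional to the Gaussian density at each shift,
renormalized over the finite set — the density itself fixes only relative
weights, and renormalization is the natural closure; this is a design
choice, flagged as such. The two sets are tagged, and the evaluation
routines refuse a set tagged for optimization: planning never gets to
grade itself on its own scenarios.

## SVD compression of the radius

Storing all $K$ scenario matrices (or worse, per-voxel covariance blocks)
does not scale. The package stacks the weighted deviations
$E_k = \sqrt{w_k}(D_k - D_c)$ along the *scenario axis* and
eigendecomposes the small $K \times K$ Gram matrix of the stack, giving
singular values $\sigma_r$ and sparse mode matrices $\Phi_r$ with

$$d_{r,i}(x)^2 = \sum_{r \le k} \sigma_r^2 (\Phi_r x)_i^2 ,$$

exact when all positive singular values are kept, and truncated at the
smallest $k$ whose cumulative $\sigma_r^2$ fraction reaches the variance
threshold (default 0.99). Dropping modes can only shrink the squared
radius (it is a sum of nonnegative terms), so truncation errs on the
optimistic side for spread — at 99% retained variance the effect is
marginal, and the retained fraction is stored on the model object.
Eigenvalues that are pure round-off are recognized by comparison with the
weighted squared norm of the scenario matrices themselves ($10^{-24}$
relative), so identical scenarios compress to rank 0 rather than to noise
modes. On the packaged phantom the 13-scenario set compresses to rank 6.

## The phantom and the toy dose engine

The phantom generator emulates a prostate-like axial geometry: an
elliptical body contour, an ellipsoidal CTV, a bladder anterior and a
rectum posterior of it, by default on a single-slice $60 \times 60$ grid
at 3 mm spacing (fast enough that the whole four-model comparison runs in
under a minute). Organ centers and semi-axes are jittered by a seeded
uniform perturbation ($\pm 2$ mm, $\pm 5\%$) so different seeds emulate
different patients; the gaps in the default geometry guarantee the CTV
never overlaps an OAR. The PTV is an anisotropic, AP-asymmetric
ellipsoidal expansion of the CTV — margins (7, 7-4, 7) mm, with the
anterior-or-posterior semi-axis selected by the sign of the displacement —
matching common treatment-planning practice and testable against an
exhaustive scan. Conformity rings (0–20 mm and 20–50 mm from the CTV
surface, half-open bands) are grown from the structure each model actually
targets; the anchor is configurable.

The dose engine is a deliberately simple stand-in for a clinical
pencil-beam algorithm: parallel beams at the nine standard prostate gantry
angles (0°–320° by 40°), each bixel an exponentially attenuated Gaussian
pencil $\exp(-\mu\, \mathrm{depth})\, \exp(-\mathrm{lat}^2 / 2\sigma_{pen}^2)$
with $\mu = 0.005\,\mathrm{mm}^{-1}$ and $\sigma_{pen} = 3$ mm. Depth is
the body path length upstream of the voxel (ray marching at half-voxel
steps); divergence and heterogeneity are ignored. Scenario doses are
*recomputed with the isocenter translated by $-\delta$* — exact for this
engine — rather than interpolated from the nominal dose grid, so
interpolation error never contaminates tests of the interval machinery.
Entries below $10^{-4}$ of their column maximum are dropped. On
single-slice grids the bixels are z-invariant line pencils (an
infinite-cylinder idealization), so inferior–superior shifts leave the
dose unchanged; the 13- and 125-scenario sets are kept intact and the
engine simply caches the repeated matrices. Bixels cover the target
projection plus $3\sigma_{pen}$, which bounds the problem size.

What the synthetic setup does *not* emulate: CT density heterogeneity,
beam divergence, scatter, inter-fraction anatomy change, and the absolute
dosimetry of clinical cases. Passing tests therefore demonstrate the
correctness and qualitative behavior of the method — the robustness
ordering of the four models, the effect of $\theta$ — not clinical dose
metrics; absolute RI and VxGy values on real patients additionally depend
on the evaluation constants $c_1, c_2$ below.

## Optimization

All four composite objectives expose analytic gradients (verified against
central differences to $10^{-5}$ relative error; the DVH penalties are
piecewise smooth, so the check uses a step small enough not to straddle
active-set boundaries). The solver is projected quasi-Newton (L-BFGS-B
with lower bound 0), initialized with the uniform fluence scaled so the
mean CTV center dose equals the prescription — reproducible and seed-free.
The minimax model uses a log-sum-exp smoothed maximum with inverse
temperature $\beta = 10^3$ so the same solver applies; the smoothed value
exceeds the hard maximum by at most $\log K / \beta$, and a hard-max
evaluation is available. A start that is already first-order stationary
returns immediately.

The bladder and rectum DVH objectives ("keep V60Gy / V40Gy below the
pulled fraction") take their allowed volume fractions from a preliminary
nominal CTV-only optimization — each model is asked not to exceed what a
plan that ignores the OARs already achieves. Ring DVH objectives carry a
volume fraction of 0, under which the DVH penalty reduces exactly to the
maximum-dose penalty.

## Evaluation

Plans are always evaluated on the 125-scenario grid: per-voxel expected
dose and standard deviation, the $\Delta$-map
$\Delta_i = ((E(d_i)-p)/(c_1 p))^2 + (std(d_i)/(c_2 p))^2$ over the CTV,
the robustness index $RI = |\{i : \Delta_i < 1\}| / |CTV|$ (strict
inequality), confidence-band DVHs (nominal curve, weighted-mean curve,
one-standard-deviation band; 0.1 Gy bins from 0 to $1.2p$), and the price
of robustness as V60Gy bladder / V40Gy rectum at the nominal scenario
(closed thresholds: "x Gy or higher"). The constants $c_1 = c_2 = 0.05$ —
a 5%-of-prescription tolerance per component — are package defaults, made
explicit in every report precisely because published robustness indices
depend on them and they are rarely stated.

## Numerical choices, in one place

* Radius round-off clamped at 0; SVD noise floor $10^{-24}$ of the
  weighted scenario-matrix norm; full-rank reconstruction verified to
  $10^{-10}$ relative error.
* Sparsity floor $10^{-4}$ per Dij column.
* Gradient checks: central differences, relative step $10^{-6}$.
* L-BFGS-B: up to 400 iterations for plan runs; deterministic throughout —
  the only randomness in the package is the phantom jitter, driven by the
  config seed.
* Problem sizes: default study runs use the $60 \times 60$ single-slice
  phantom (~130 bixels, 3600 voxels); objective/gradient verification uses
  a coarser $30 \times 30$ setup with three beams.

## Known limitations

The engine's simplifications (above) make absolute OAR percentages higher
than clinical values — the rectum sits directly in several beam paths of a
single-slice geometry with no room to dodge in z. The minimax model
optimizes the 13-scenario worst case but is evaluated on shifts up to
$1.5\sigma$, beyond its optimization horizon, mirroring the usual
optimistic bias of scenario-based worst-case planning. The literal
per-mode rank-1 factorization that would compress storage further (one
$n$-vector and one $m$-vector per mode) is not implemented; modes are kept
as sparse $n \times m$ matrices, which at desk scale is already a
$K/k$-fold saving over storing the scenario stack.
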