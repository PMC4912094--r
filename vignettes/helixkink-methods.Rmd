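---
title: "Measuring helix kinks with confidence intervals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring helix kinks with confidence intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixkink)
```

## The measurement model

An alpha-helix is locally well approximated by a cylinder: the backbone
atoms of each residue type (N, CA, C, O) sit at characteristic radii
around a common axis. `helixkink` exploits this by fitting a cylinder to
every six-residue window of a helix — 24 backbone atoms — and scoring the
fit by

$$ r = \sqrt{\tfrac{1}{m}\sum_{i=1}^{m}(d_i - \bar d)^2}, \qquad m = 24, $$

where $d_i$ is the shortest distance from atom $i$ to the candidate axis
and $\bar d$ is the mean of those distances. Minimising $r$ over axis
position and direction yields the local helix axis; note that the mean
radius $\bar d$ is free per segment (it is re-estimated inside the
objective), so the fit measures *cylindricality*, not agreement with any
fixed radius. Because the four atom types sit at different radii
(roughly 1.55–2.28 Å), $r$ is strictly positive even for a geometrically
perfect helix: the two flanking fits at any site of the ideal helix sum
to about 0.56 Å, comfortably above the 0.27 Å floor that the method
guarantees.

The kink angle at site $s$ (0-based residue index within the helix) is
the angle between the axes fitted to the two *disjoint* windows
$s-5,\dots,s$ and $s+1,\dots,s+6$, both oriented N→C, and is assigned to
the final residue of the first window. A helix of length $L$ therefore
has sites $s = 5,\dots,L-7$, and only helices of 12 or more residues can
be analysed at all. Angles are reported in degrees in $[0,180]$; no
swivel or directionality is measured — the angle is a magnitude.

Assumptions worth keeping in mind: the segment convention treats six
residues as "locally straight", so gradual curvature distributed over
many residues registers as a series of small angles rather than one
kink; and a poorly helical segment (unwound turn, pi-bulge) simply
produces a poor fit, which the error model below turns into a wide
confidence interval rather than a hard failure.

### Optimiser and numerical choices

The axis is parameterised as a direction (two gnomonic parameters around
an initial guess) plus a two-dimensional offset in the plane normal to
it. The initial direction is the principal axis of the 24 atoms through
their centroid — already within a few degrees of the optimum for
anything helix-like — refined by Nelder–Mead and then a BFGS polish
(relative tolerance $10^{-14}$, finite-difference step $10^{-6}$).

One deliberate subtlety: before optimisation the atoms are rotated into
a *canonical local frame* derived from the points themselves (principal
axis oriented N→C as $+z$, the first atom's radial direction as $+x$).
Any rigid motion of the input then produces numerically identical local
coordinates, so the optimiser takes an identical path and measured
angles are reproducible under rotation and translation to below
$10^{-6}$ degrees — which the test suite asserts over 100 random rigid
motions. Reflections and residue-order reversal preserve angles too, but
only to ordinary convergence precision (~$10^{-4}$ degrees), because the
mirrored optimisation path is not bitwise identical.

Degenerate inputs (collinear or coincident atoms, where the axis is
ill-defined) are rejected with an error; anything with two distinct
principal components proceeds. The fit direction is disambiguated by
requiring a positive dot product with the first-to-last-residue
displacement; without this, angles between undirected lines would fold
at 90°.

## The error model

The half-width of the 95% confidence interval on a measured angle is
predicted from the summed fit quality of the two flanking cylinders:

$$ \varepsilon = a\,\ln(r_n + r_c - c) + b, $$

with shipped coefficients $a = 6.349$°, $b = 13.15$°, $c = 0.2937$ Å.
The interval is $\theta \pm \varepsilon$. Intuitively: the worse the two
local fits, the less the two axes constrain the angle between them.

The raw curve diverges to $-\infty$ as $r_n + r_c \to c^+$, and the sum
can physically fall *below* $c$ (the ideal-helix floor is ~0.27 Å per
pair of fits... indeed 0.27 < 0.2937). Two clamps make the map total and
sane: the sum is floored at `floor_sum_r` (default $c + 0.01$ Å) and the
resulting $\varepsilon$ is floored at 0. The result is non-negative and
monotone non-decreasing in $r_n + r_c$. An $\varepsilon$ of zero simply
means "fit better than the calibration can resolve"; in practice
measured helices sit well above the floor.

### Calibration by perturbation simulation

`calibrate_error_model()` re-derives $(a, b, c)$ from simulation. For a
kink with well-fitted cylinders, the fitted axes are taken to define the
*true* angle. Each cylinder is then independently rotated about its own
midpoint (the segment centroid projected onto the axis) by a random
rotation — axis uniform on the sphere, tilt uniform in $(0, 15°]$ — and
the angle is re-measured from the rotated, non-optimal axes. The
degraded fit quality of each segment against its rotated axis is
recomputed with a re-estimated mean radius. Each sample records
$\alpha = \theta - \theta_{\text{true}}$ and the perturbed $r_n + r_c$.

Samples are drawn from synthetic kinks at 15°, 20°, 30°, 40° and 50° —
all above the 10° cutoff below which $\alpha$ stops depending on
$r_n + r_c$ alone, so smaller kinks are excluded from calibration. This
synthetic set is a stand-in for a curated set of well-fitted real kinks;
it covers the same angle range with ideal geometry.

Samples are binned by $r_n + r_c$ (0.05 Å bins); the 95th percentile of
$|\alpha|$ per bin (linear interpolation between order statistics) is
the bin's $\varepsilon$; and the log curve is least-squares fitted
through the bin midpoints with Levenberg–Marquardt, constraining
$c < \min x$.

Two properties of this simulation deserve honesty:

* **Small positive bias.** Tilting both axes by bounded random rotations
  increases the expected angle at second order
  ($E[\cos\theta'] = \cos\theta \cdot E[\cos\beta] < \cos\theta$), so
  $\alpha$ has mean ≈ +0.7° at the default 15° tilt bound rather than
  exactly zero. The distribution is symmetric about its centre (two-sided
  KS between centred $\alpha$ and its negation is not rejected at 1% on
  10,000 samples). The bias is several times smaller than the smallest
  $\varepsilon$ the model reports (~5°) and is absorbed by the percentile
  calibration, which uses $|\alpha|$.
* **Bin occupancy.** A 95th percentile needs on the order of a thousand
  samples to be stable: with ~100-sample bins, tail-bin $\varepsilon$
  estimates wobble enough that fresh-sample coverage can drift ~3% off
  the nominal 95%. The default merge threshold is 100 samples per bin
  (adequate for exploratory runs), but the full-scale calibration used
  by the tests and the acceptance script merges bins below 1,000
  samples; at that occupancy the per-bin coverage of fresh, independently
  seeded samples stays within ±2% of 95% across seeds.

The tilt bound (15°), the number of perturbations per kink and the bin
width are engineering choices — the underlying idea only requires "a
random rotation" — chosen so the perturbed $r_n + r_c$ spans the range
where real measurements live (~0.55–1.1 Å) and each bin is well
populated.

## Conservation classification

Two homologous helices are compared at the pair's *most disrupted site*:
the site of the greatest angle in either helix. The partner contributes
its largest angle within ±4 alignment columns (kink positions are fuzzy
and alignments imperfect); if gaps leave no angle in that window the
pair is removed, with a warning naming the rule. With
$\theta_{\max} \ge \theta_{\min}$ and errors $\varepsilon_1,
\varepsilon_2$, the classes partition all pairs at the 20° kink
threshold:

* **Conserved Straight** — $\theta_{\max} < 20°$;
* **Conserved Kinked** — $\theta_{\min} > 20°$ and
  $\theta_{\max}-\theta_{\min} < \varepsilon_1+\varepsilon_2$;
* **Not Conserved** — $\theta_{\max} > 20°$ and
  $\theta_{\max}-\theta_{\min} > \varepsilon_1+\varepsilon_2$;
* **Other** — everything else (boundary and mixed cases).

The classification depends only on the ordered pair, so it is invariant
under swapping the helices, and shrinking the errors can only move pairs
away from the conserved-kinked side — both properties are asserted
exhaustively over a grid in the tests. The 20° threshold is a named
configuration constant (`kink_threshold`), defaulted but not hard-coded.

For families (≥ 5 members sharing an alignment), each member's angles
are first smoothed by a 3-column maximum — the smoothed angle at column
$c$ is the largest available angle at $c-1,c,c+1$ — absorbing one-column
alignment error. The most disrupted site is the column with the highest
mean smoothed angle among columns with at least 5 angles; ties resolve
to the smallest column (note that max-smoothing makes identical members
tie across the three columns around a shared kink, so the flagged site
can sit one column N-terminal of the literal kink). At that column the
family records the median angle, the standard deviation ($n-1$
denominator) and the mean error $\mu_\varepsilon$. The family branches
mirror the pair rules: conserved (straight or kinked by the median
against 20°) when $\sigma_\theta \le \mu_\varepsilon$, Not Conserved when
$\sigma_\theta > \mu_\varepsilon$ and the maximum angle exceeds 20°, and
Other otherwise; ties on $\sigma_\theta = \mu_\varepsilon$ fall on the
conserved side. This mirroring is a design choice made where the exact
branch boundaries were open; it reproduces the expected behaviour on
tightly grouped kinked families (small $\sigma$, conserved) versus
wide-spread ones (Not Conserved).

Supporting statistics follow the same alignment conventions: sequence
identity ignores columns where either sequence is gapped; neighbouring
sequence identity restricts to the union of the two helices' 4 Å contact
residues (an empty union is reported as missing, never 0); family
identity is the mean over member pairs; and site–site Spearman
correlations use average ranks and require ≥ 5 paired members. Candidate
helix families are pruned by the >90%-connectivity loop (iteratively
dropping the lowest-connectivity member, ties to the lexicographically
smallest id, so the result is order-independent), discarding families
below 5 members.

## The synthetic-helix generator

`generate_ideal_helix()` places N, CA, C and O on coaxial cylinders with
a rise of 1.5 Å and a twist of 100° per residue. The per-atom radii and
the phase/rise offsets of N, C and O relative to CA were computed once
from a backbone built by internal coordinates at $\varphi = -57°$,
$\psi = -47°$, $\omega = 180°$ with standard bond geometry, then frozen
as constants. This *is* the package's definition of "ideal": a
geometrically regular helix, deliberately not any particular crystal
structure. `generate_kinked_helix()` joins two ideal arms at a chosen
residue, rotating the C-terminal arm about an axis through the junction
perpendicular to the N-arm axis, shares the junction residue, and can
add seeded isotropic Gaussian coordinate noise.

What the generator emulates: known-angle kinks at known positions,
graded fit degradation with noise, and whole aligned families with a
designed angle spectrum (hence a designed conservation class). What it
does not emulate: sidechains, sequence-dependent geometry (proline
kinks, pi-bulges, 3₁₀ ends), smooth curvature, gaps arising from real
structural alignment, or crystallographic pathologies. Passing tests
therefore demonstrate that the geometry, calibration and classification
machinery is correct, not that any biological claim about real
structures holds; real-data behaviour additionally depends on annotation
quality and alignment quality, which enter as inputs.

## Problem sizes and runtime

The test suite measures profiles on 12–20-residue helices, checks the
optimiser against a brute-force direction-grid oracle (2° coarse grid
with per-direction position optimisation, refined at 0.2° — a single 2°
grid cannot certify $r$ to the $10^{-3}$ Å level) on 20+ random
segments, and exercises calibration at 2,000 perturbations per kink for
module tests and 10,000 per kink (five kinks, twice: calibration plus
fresh coverage samples) for the acceptance checks. The full suite runs
in about five minutes on one CPU; the acceptance script in about twenty
seconds. All randomness is seeded, and seeded runs are byte-identical.

## Known limitations

* Angles are magnitudes; swivel direction and hydrogen-bond geometry are
  out of scope, so "conserved kinked" helices may still differ in kink
  direction.
* The error model is heuristic: calibrated on ideal synthetic kinks
  above 10°, it extrapolates to small angles and to fit qualities beyond
  the calibration range by clamping and by the fitted log curve.
* Helix annotation is consumed as input (a sidecar table); the built-in
  fixtures are not a secondary-structure assignment method.
* The pair window and smoothing operate on alignment columns, not on
  each helix's own residue numbering; with very gappy alignments the ±4
  column window is conservative.
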