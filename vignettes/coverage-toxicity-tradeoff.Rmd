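---
title: "Wish-list planning and the coverage-toxicity trade-off: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wish-list planning and the coverage-toxicity trade-off: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In prostate radiotherapy with a simultaneously integrated boost, two nested
planning target volumes are treated: PTV_High (prostate plus a 5-6 mm
margin, prescribed 64.6 Gy) and PTV_Low (prostate plus seminal vesicles
plus an 8-10 mm margin, prescribed 57.76 Gy), delivered in 19 fractions.
The posterior surface of PTV_Low typically overlaps the anterior rectal
wall, so full (>= 99 %) coverage of PTV_Low forces high rectal dose and
with it a higher predicted probability of grade >= 2 late gastro-intestinal
(GI) toxicity. `prioplan` implements an automated workflow that makes this
trade-off explicit: for each (synthetic) patient it generates one *clinical
plan* with full PTV_Low coverage plus six plans with progressively relaxed
coverage, evaluates each with a logistic NTCP model that includes diabetes
as a non-dosimetric risk factor, and summarises the resulting
coverage-toxicity curves per patient and per cohort.

## Cost functions

All plans are produced by constrained convex optimization of non-negative
beamlet weights $w$ under a linear dose model $d = A w$, where $A$ is the
dose-influence matrix. The wish-list (the declarative planning protocol)
uses five cost functions:

* **LTCP** (logarithmic tumour control probability), the convex coverage
  surrogate $\mathrm{LTCP} = \frac{1}{m}\sum_{j=1}^m e^{-\alpha (d_j - PD)}$
  over the $m$ target voxels with prescription $PD$ and cell sensitivity
  $\alpha$. Uniform dose at the prescription gives 1; cold voxels dominate
  exponentially.
* **gEUD(k)**, the $k$-power mean of voxel doses,
  $\left(\frac{1}{m}\sum_j d_j^k\right)^{1/k}$; $k = 7.7$ for rectum,
  matching the volume effect of the toxicity model.
* mean, maximum and minimum dose (maximum/minimum implemented exactly as
  voxelwise linear constraints, never as smoothed surrogates).

The toxicity model is a multivariate logistic regression for grade >= 2
late GI toxicity:

$$\mathrm{NTCP} = \frac{1}{1 + e^{-S}}, \qquad
S = -6.362 + 2.083\,B + 0.608\,D + 0.406\,T + 0.084\,E,$$

with $B$ baseline GI symptoms (0/1), $D$ diabetes (0/1), $T$ high-risk
treatment group (0/1), and $E$ the rectum gEUD(7.7) of the voxelwise EQD2
dose. The published rendering of the model is typographically ambiguous
about signs; we adopt the standard logistic orientation above because all
coefficients then act as risk factors (the direction the source analyses
report) and a rectum $E$ of 55-60 Gy yields the 13-22 % no-diabetes
probabilities those analyses describe. The EQD2 conversion uses the
linear-quadratic model per voxel,
$\mathrm{EQD2}_j = D_j\,(D_j/n + \alpha/\beta)/(2 + \alpha/\beta)$ with
$n = 19$ fractions and $\alpha/\beta = 3$ Gy, the conventional late-rectal
value; the source model does not state its $\alpha/\beta$, so the value is
a configurable default. The rectum gEUD used *inside the optimizer*
(priority 4) acts on physical dose; the EQD2 conversion enters only the
NTCP evaluation, mirroring the stated practice that the NTCP expression
itself is not used as a planning cost.

## The wish-list and its lexicographic solution

The protocol consists of 9 hard constraints (PTV maxima and means, an
intermediate-dose structure `PTV_Low` minus the 2.5 mm-expanded
`PTV_High`, conformality shell at 50 mm, rectum/anus/patient maxima, CTV
minimum doses that guarantee 100 % CTV coverage in every plan) and 13
prioritized objectives (coverage LTCPs at priorities 1-3, rectum gEUD(7.7)
at priority 4, conformality shell and entrance-dose maxima, rectum / anus
/ bladder mean doses, hip maxima). Objectives carry a *goal* and a
*sufficient* value.

Solving is sequential: objectives are minimized in priority order (ties
jointly, as an equally weighted sum, which makes the result independent of
the order of equal-priority rows), always subject to all hard constraints
and to the bounds accumulated so far. After each priority the attained
value $v$ is frozen as a constraint at
$\max(v, \text{sufficient}) \cdot (1 + \delta)$ with relative slack
$\delta = 10^{-3}$: exact equality would leave lower priorities no
numerical room, and flooring the bound at the sufficient value is what
releases head-room when an objective lands below its goal. Minimization
may stop early once the sufficient value is reached; since the imposed
bound is floored there anyway, this changes nothing downstream and avoids
buying precision no later stage can use.

The engine is a purpose-built log-barrier interior-point method: damped
Newton with Jacobi equilibration and iterative refinement, exact
fraction-to-boundary step limits, a geometric barrier ladder that tracks
the objective scale during the astronomically large LTCP descents, lazy
row activation for voxelwise constraints on large structures (with
full-row verification and re-solve rounds), and epigraph variables for
max-dose objectives, warm-started through a smooth soft-max surrogate.
Before the priority sequence, a soft-minimax feasibility pass drives every
enabled coverage LTCP to its sufficient value under the hard constraints;
because each coverage objective then starts at or below its sufficient
value, the expensive pattern "priority 1 wrecks PTV_Low coverage,
priority 3 slowly recovers it" never arises. The lexicographic result does
not depend on the starting point (all subproblems are convex), so these
warm starts are pure acceleration.

## The seven-plan workflow

Per patient:

1. derive planning structures; measure the rectum-PTV_Low overlap
   (percent of *rectum* volume inside PTV_Low -- the denominator follows
   the overlap-regression convention, as the protocol text itself is
   ambiguous);
2. select the PRV margin: 25 / 20 / 15 / 10 mm for overlap < 4 / < 6 /
   < 7 / >= 7 %. Exactly 7 % (undefined in the prose rule) is assigned to
   the 10 mm class, i.e. the rule reads "< 7, else";
3. solve the clinical plan (priority-2 disabled, priority-3 LTCP on the
   *entire* PTV_Low with goal X = 0.4);
4. solve six reduced plans: priority 2 covers `PTV_Low` minus the
   `RectumPRV` (the overlap expanded by the selected margin) with goal
   0.4; priority 3 recovers coverage of the full PTV_Low only up to the
   plan-specific goal X; the bladder mean-dose objective is replaced by a
   hard constraint at the clinical plan's bladder mean (plus the solver
   slack, so the clinical plan itself remains a strictly feasible warm
   start);
5. evaluate coverage (V95), rectum gEUD-EQD2 and NTCP with/without
   diabetes per plan; interpolate NTCP piecewise-linearly at integer
   coverage levels 99 ... 90 (no extrapolation beyond the achieved range;
   infeasible or non-monotone rungs are dropped with a warning).

The six X values are patient-independent. Because cold voxels enter the
LTCP exponentially, coverage responds to X on a logarithmic scale; the
shipped ladder $X \in \{2, 10, 60, 400, 3\cdot10^3, 3\cdot10^4\}$ was
calibrated once on the default synthetic cohort so that realized coverages
span roughly 99 % down to the patient-specific floor (low 90s), then
frozen. The floor is anatomy-limited: voxels inside or near CTV_Low and
PTV_High stay pinned by the CTV minimum-dose constraints and the
PTV_High coverage bound, so not every patient can reach 90 % -- the same
behaviour the clinical workflow reports for some patients.

Cohort analyses: per-level mean and sample SD (n-1) of NTCP under the
all-diabetic and none-diabetic assumptions; per-patient NTCP reduction
relative to the 99 % level; ordinary least squares of reduction against
overlap percentage at the 95 % and 90 % levels (slope, intercept, R^2;
flagged degenerate when overlaps do not vary); and the diabetes
compensation level -- the largest coverage at which the with-diabetes NTCP
falls to or below the no-diabetes NTCP at 99 % coverage, with the residual
gap when no achieved level compensates.

## The synthetic pelvic phantom

Real patient data are not consumed; a seeded generator builds voxelized
pelvic analogs: prostate (CTV_High) and bladder as ellipsoids, seminal
vesicles as two posterolateral-superior lobes unioned with the prostate
into CTV_Low, rectum and anus as tubes, hips as spheres, all inside an
elliptic external contour on a 64 x 64 x 16 grid of 2.5 x 2.5 x 4 mm
voxels. The vesicle lobes are deliberately the posterior-most part of
CTV_Low: the rectum-proximity parameter (the sampled gap between the
posterior CTV_Low surface and the anterior rectum wall, 1-16 mm) then
controls the PTV_Low-rectum overlap in a region *not* shadowed by
PTV_High, which is what makes deep coverage reductions geometrically
possible -- the feature of real anatomy that drives the whole trade-off.
Gaps above the PTV_Low margin give zero overlap (the "no benefit from
coverage loss" patient type); smaller gaps span the PRV margin classes.
Organ dimensions are drawn per patient from documented ranges; everything
is a pure function of (seed, parameters).

The dose model is an emulation, not delivery physics: 12 equi-angular
coplanar beams of 7 mm rectangular beamlets, exponential depth attenuation
(0.004 per mm, the megavoltage ballpark) and a Gaussian-blurred edge
profile (sigma 2.5 mm). Beamlet grids cover the projection of CTV_Low
expanded by 10 mm, with one extra beamlet row beyond the span so edge
voxels sit under a flat part of the outermost beamlet rather than in its
half-profile (without this, the axial target edges are systematically
starved, since coplanar beams cannot compensate axially). What the
emulation reproduces: cross-fire dose concentration, depth falloff,
penumbra-limited conformality, and the competition between coverage and
rectal sparing. What it does not: arc delivery, scatter, heterogeneity,
deliverability constraints -- so absolute dosimetric values are
plausible-looking but synthetic, and passing tests demonstrate the
*machinery and its qualitative behaviour*, not clinical accuracy.

## Numerical choices

* Distance transforms (mask expansion, shells, entrance band) use an
  exact anisotropy-aware Euclidean distance transform in C++; expansion
  by 0 mm is the identity, and compositions agree with summed margins to
  within one voxel diagonal.
* Shell band width 5 mm (the protocol defines shell distances, not
  thickness); entrance-dose region = the 10 mm band inside the external
  surface minus PTV_Low expanded by 50 mm (the protocol names the
  structure without defining it).
* Solver defaults: conversion slack delta = 1e-3, duality-gap target 1e-4
  (relative), Newton cap 30 per barrier stage with up to 4 re-centering
  retries, barrier reduction factor 20, initial barrier parameter scaled
  30x above the classical objective/constraint balance to re-centre
  warm-started iterates away from the previous priority's active bounds.
  These give per-priority attained values well inside the delta-slack
  that dominates plan-to-plan differences. The micro-instance oracle
  tests run with tighter settings (gap 1e-8) and verify 1e-4 agreement
  with brute-force search.
* Degenerate inputs: empty derived structures are skipped with a note in
  the plan (a shell can fall entirely outside a small phantom);
  infeasible hard-constraint sets produce a structured report naming the
  mutually blocking constraints found by a greedy relaxation probe;
  zero-overlap patients produce an empty PRV, so the reduced plans
  coincide with the clinical plan and the trade-off curve is flagged
  missing rather than extrapolated.

## Problem sizes used in the shipped tests

The package defaults (64 x 64 x 16 grid, 12 beams) are sized for
interactive single-patient studies. The test suite exercises the identical
code paths at reduced size, a deliberate choice documented here: geometry
and dosimetry tests run on a 44 x 44 x 12 grid; the seven-plan workflow
and the cohort-level analyses run on a five-patient mini-cohort at
36 x 36 x 10 resolution with 12 beams of 8 mm beamlets. Patient one runs
the full six-rung ladder; the other overlapping patients run a two-rung
ladder spanning the same coverage range; the zero-overlap patients run a
single deep rung, since with an empty PRV all their plans coincide. A
patient whose plans all remain at full coverage has, by construction, a
flat NTCP-versus-coverage relation, and the cohort analyses treat it as
such (constant curve at the clinical value) rather than excluding it --
this is how the no-overlap patient enters the overlap regression at zero
reduction. The mini-cohort contains two zero-overlap patients and
overlaps spanning the 25 and 10 mm PRV-margin classes.

## Known limitations

* The NTCP coefficients are frozen from the published fit; refitting or
  alternative toxicity models are out of scope.
* The beam model's absolute dose levels (hence absolute NTCP values) are
  synthetic; only within-cohort contrasts are meaningful.
* The lexicographic engine accepts ~0.1-1 % objective suboptimality at
  production sizes in exchange for runtime; the delta-slack conversion
  makes this invisible to lower priorities, but reported attained values
  inherit it.
* Beam-angle optimization, deliverability, DICOM-RT and any wish-list
  tuning beyond the shipped protocol are out of scope.
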