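---
title: "Supervised-clustering pseudoreference quantification for dynamic TSPO PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised-clustering pseudoreference quantification for dynamic TSPO PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcaPET)
```

## The quantification problem

TSPO radiotracers bind to activated glia throughout the brain, so there is
no anatomical region free of specific binding to serve as a reference
tissue, and full quantification classically requires an arterial input
function (AIF). The supervised clustering algorithm (SVCA) instead
*derives* a pseudoreference region from the scan itself: voxels whose
kinetics are dominated by the low-binding gray-matter shape are treated as
having negligible specific binding, and their average curve substitutes
for a reference tissue in graphical analysis. This package implements the
two SVCA stages, the Logan-family quantification around them, the
test-retest reliability battery, and a synthetic-data module that makes
every stage testable against known kinetic ground truth.

## Models

### Compartmental simulation

Tissue curves are generated from the standard one- and two-tissue
compartment models. With plasma input $C_p(t)$, influx $K_1$
(mL·cm$^{-3}$·min$^{-1}$) and rate constants $k_2, k_3, k_4$ (min$^{-1}$),
the impulse response is mono- or bi-exponential and the total distribution
volume has the closed form

$$V_T = \frac{K_1}{k_2}\left(1 + \frac{k_3}{k_4}\right),$$

($K_1/k_2$ for the one-tissue case). The measured voxel signal mixes in a
fractional blood volume $v_B$: $C_{pet} = (1 - v_B)\,C_T + v_B\,C_B$. The
plasma input is a tri-exponential bolus model (linear rise times the
fastest exponential plus two washout terms), the standard parametric form
for bolus injections; the same curve stands in for whole blood, since the
pipeline consumes an already-corrected AIF and no metabolite/plasma split
is simulated. Convolution runs on a 1-s internal grid (the shortest frame
is 10 s) with trapezoid end-point correction; against a stiff ODE solution
of the same system the curves agree to well under 0.5%.

### SVCA

Stage 1 normalizes each training scan framewise — subtract the mean and
divide by the SD over the brain-mask voxels of that frame — which removes
dose and scanner scaling and leaves unitless kinetic *shapes*. Within-mask
mean curves for the four kinetic classes (low-binding GM, WM, thalamus,
blood, the last from a carotid mask as an image-derived input surrogate)
are linearly interpolated onto a common frame-midpoint grid (default: the
32-frame schedule's midpoints) and averaged over subjects.

Stage 2 fits every brain voxel of a normalized scan by non-negative least
squares against the four class curves and computes the GM ratio
$w_{GM}/\sum_k w_k$. Voxels with ratio strictly above 0.9 form the
pseudoreference; their mean curve is taken from the *original* (kBq/mL)
image. The NNLS weighting on framewise-normalized curves, with no
additional per-curve magnitude scaling, is the established SVCA
formulation; raw-weight ratios are scale-invariant, so this choice only
matters through the relative amplitudes of the normalized class curves.

One structural caveat found while validating on phantoms: if the class
masks partition the brain exactly, the normalized class curves are
linearly dependent (their voxel-count-weighted sum is identically zero),
so NNLS solutions are non-unique even though fitted values and GM ratios
remain well defined. Real segmentation-based class VOIs are subsets of the
brain, where this degeneracy does not arise; the solver-recovery tests
therefore use a linearly independent library built from raw class
kinetics.

### Logan graphical analysis

Plasma-input Logan regresses $\int_0^t C_T/C_T(t)$ on
$\int_0^t C_p/C_T(t)$ over frames whose *midpoint* is at or past the
equilibration time $t^* = 18$ min; the slope is $V_T$. The measured curve
is first vascular-corrected with $v_B = 0.05$,
$C_T = (C_{pet} - v_B C_B)/(1 - v_B)$, using the plasma curve for blood
unless a whole-blood TAC is supplied. Integrals are trapezoid from
injection with an initial triangle to the first midpoint; the regression is
ordinary least squares, matching standard Logan practice. The reference
Logan model replaces the plasma integral with the reference-tissue
integral and reports the slope as DVR; a $C_{ref}/k_2'$ term is available
but off by default, since the reference efflux constant is rarely known
and the published analyses this package mirrors do not describe one. With
the default settings a noiseless two-tissue target over a one-tissue
reference with true ratio 1.30 reads 1.282–1.292 depending on $v_B$
handling — a deliberate, documented property of the method rather than an
implementation error (enabling `k2prime` removes most of it). Two DVR
routes are provided, reference-Logan (`SVCA-DVR` style) and ratios of
plasma-input $V_T$ fits (`AIF-DVR` style); on noiseless phantoms they
agree within ~3%.

### Reliability battery

For paired test/retest values $T, RT$:
$TRV = 100\,(T - RT)/\left(\tfrac{T+RT}{2}\right)$, $aTRV = |TRV|$, and

$$\%RC = 100 \times 2.77 \times
  \sqrt{\frac{1}{N}\sum_j \frac{(T_j - RT_j)^2 / 2}{\left((T_j+RT_j)/2\right)^2}},$$

i.e. $1.96\sqrt{2}$ times the root-mean within-pair relative variance —
the smallest relative change detectable with >95% confidence. The printed
sources for this coefficient are ambiguous about the exact summation
normalization; this reconstruction (per-pair squared difference halved,
normalized by the squared pair mean, averaged over pairs) is adopted
because it makes the single-pair case $2.77\,|T-RT|/\bar{m}/\sqrt 2$ and is
scale-free, and it is verified against hand-computed values in the tests.
ICC is the two-way absolute-agreement single-measure form ICC(A,1) — the
standard test-retest choice among the Shrout–Fleiss variants, computed
from ANOVA mean squares. Bland–Altman differences default to percent of
the pair mean. Group comparisons use Welch's t-test, a robust default
where the source analyses do not name a test.

## The synthetic cohort: what it emulates and what it does not

`build_phantom()` draws a block-layout brain (16×16×8 voxels of 2 mm,
configurable): a GM interior, a central WM slab, an embedded thalamus
block and a small carotid column; every voxel carries exactly one class.
Default kinetics give $V_T$ = 2.0 (GM), 1.9 (WM), 2.6 (thalamus), i.e.
true DVRs 0.95 and 1.30 against GM, with GM perfusion ~3× WM ($K_1$ 0.30
vs 0.09) — the gray/white contrast that gives the classes distinct
early-phase shapes. Three stochastic layers are simulated:

* **Between-subject variability** — each subject's rate constants are
  `truth × (1 + Normal(0, 0.05))`, drawn independently per class and
  constant; 5% is a deliberately configured cohort spread (the source
  study reports none), yielding ~7% between-subject $V_T$ CV.
* **Within-class heterogeneity** — each voxel's rate constants deviate
  from its class by Gaussian factors of SD 0.1, applied through
  first-order sensitivity curves (one extra convolution per parameter,
  not per voxel). This smooth "anatomical" layer is a fixed property of a
  subject: a retest scan reuses it and redraws only the noise. It is
  essential for realism — with perfectly homogeneous classes the
  normalized scan lies exactly in the span of the class curves, NNLS
  absorbs any inter-subject mismatch, and the GM-ratio threshold selects
  either everything or nothing.
* **Frame noise** — independent Gaussian noise per voxel and frame with
  SD $= c\sqrt{\text{value}/\text{duration}}$, the usual
  count-statistics surrogate. The study default $c = 0.25$ is
  low-to-moderate: real voxelwise PET sits nearer $c$ = 0.5–1 in this
  scaling, while $c = 0.05$ keeps every frame's nominal noise SD within
  10% of the across-brain signal SD (the condition used for the
  SVCA-separation check).

Test-retest pairs add a 1% kinetic jitter between scans (same-day
physiological drift) plus fresh noise. Sites alternate, selecting the
32-frame or the 30-frame 90-min schedule.

Not simulated: reconstruction physics (attenuation, scatter, randoms,
OSEM), motion, point-spread partial-volume blur beyond finite voxels,
metabolite kinetics, lesion morphology. Passing tests therefore show that
the algorithms are correct and stable under realistic kinetic and
count-statistics variation — not that the pipeline is robust to
registration error or reconstruction artefacts.

## Study workflows and their design choices

The workflows mirror four experiment designs on a 12-subject cohort
(6 per site), with all randomness derived from one master seed:

* **Subject-count sensitivity** — group-$N$ libraries ($N$ = 7…10, drawn
  site-stratified: half WCM rounded down, remainder JHMI, which makes a
  group of 7 a 3 + 4 split) are compared with a 10-subject benchmark via
  per-class Pearson correlation and one-way ANOVA. The ANOVA treats each
  library's curve samples as one group's observations — an interpretive
  choice, since curve-level ANOVA can be defined several ways.
* **Leave-one-out** — for each held-out subject, 7- and 10-subject
  libraries from the remaining 11 produce two pseudoreference curves
  whose framewise difference is summarized as mean ± SD.
* **Independent validation** — a 7-subject training group builds the
  library; the disjoint 5 subjects are quantified by SVCA-DVR,
  AIF-DVR(GM) and AIF-DVR(SVCA). Disjointness is enforced
  programmatically. Recovery is judged against the cohort's realized
  ground truth (the generator's drawn parameters), since with 5%
  variability the realized 5-subject mean scatters around the nominal
  DVR.
* **Test-retest** — DVR parametric maps for both scans of the retest
  subjects, averaged over full regions and over spherical VOIs of 0.29,
  0.15 and 0.065 cm^3 placed at the region centroid and constrained
  inside the region (the WM region is an annulus whose centroid falls in
  the thalamus, so the nearest within-region voxel is used); the
  grid-achievable volumes are 0.288/0.152/0.064 cm^3.
* **Group comparison** — a 6-subject healthy and a 10-subject disease
  cohort (thalamic $V_T$ +15%, modelled by scaling thalamic $K_1$) are
  compared per region by Welch's t-test, with the library built from the
  main healthy cohort.

A command-line wrapper is deliberately not shipped: the package is an
analysis library, and the `run_*()` functions with a `study_config()` are
its pipeline interface.

## Numerical choices and degenerate inputs

* Frame midpoints are the single per-frame time everywhere (Logan
  inclusion at $t^*$, interpolation between the 30- and 32-frame grids).
* Interpolation across schedules is linear with constant extrapolation at
  the ends (the 30-frame grid's first midpoint lies inside the 32-frame
  grid's).
* Normalization errors out on a frame with zero within-mask SD rather
  than producing infinities; an all-zero voxel TAC yields zero weights
  with a flag; a GM-ratio selection that passes no voxel raises an error
  reporting the best observed ratio.
* Logan fits require at least two frames past $t^*$ and positive
  (corrected) tissue values there; parametric maps mark failing voxels
  `NA` and count them instead of failing.
* The spherical-VOI generator breaks distance ties lexicographically so
  masks are bit-reproducible; requested volumes below one voxel return a
  single voxel with a warning.
* Seeds: phantoms separate the anatomy seed (heterogeneity) from the
  noise seed so retest scans share anatomy; cohorts draw per-subject
  sub-seeds from one stream, making every workflow reproducible from
  `(config, seed)`.

## Known limitations

The pseudoreference is selected, not segmented, and selection interacts
with kinetics: voxels whose (simulated or real) kinetics best match the
cohort-typical GM template are favoured, which compresses per-subject DVR
extremes toward the template — visible in the validation workflow as a
~2–4% downward bias of cohort-mean SVCA-DVR and a per-subject shrinkage
of outlying DVRs. Together with the reference-Logan equilibration bias
(~1% at $t^* = 18$ min) this is the same contamination behaviour reported
for SVCA references in the imaging literature, and it is the reason the
group-comparison workflow detects a +15% simulated thalamic elevation as
a ~+7% DVR difference (directionally correct, with borderline
significance at these group sizes). Statistical power at n = 6 vs 10 is
therefore modest; the workflow reports exact p-values rather than
enforcing a significance claim. Finally, the test problem sizes — a
16×16×8 grid and 12-subject cohorts — are chosen so the full suite runs
in about a minute; they are large enough to exercise every code path and
the documented statistical behaviour, but rate estimates (recall,
correlations, p-values) carry the sampling noise of those sizes.
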