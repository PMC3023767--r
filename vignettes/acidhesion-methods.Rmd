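---
title: "Methods: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidhesion)
```

This vignette documents the models behind each analysis stage, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design choices made where the procedures admitted more
than one reasonable reading.

## Force spectroscopy

A retraction record is a force trace $F(z)$ over cantilever displacement
$z$, with adhesion negative and the free-cantilever baseline near 0 pN.
An unbinding event appears as a loading ramp of slope $-k_\mathrm{eff}$
terminating in a sharp upward jump back to baseline. Per event:

* **Rupture force** $F_R$ = mean force over `m_post` samples after the jump
  minus the force at the minimum. Default `m_post = 50` samples; the window
  starts 3 samples after the minimum (the jump is allowed to complete
  within 3 samples) and is truncated at the next event.
* **Stiffness** $k_\mathrm{eff}$ = magnitude of the least-squares slope of
  force vs *displacement* over `m_pre = 30` samples ending at the minimum.
  The slope is taken against displacement, not time, because the units of
  the loading rate (pN/nm × nm/s = pN/s) require it.
* **Effective loading rate** $F' = k_\mathrm{eff} \, v$, with $v$ the
  retraction velocity (default 5000 nm/s; spring constant ~25 pN/nm).

**Event detection.** The published analyses of such traces used
unpublished in-house scripts, so the detector here is fully specified and
parameterized: the trace is smoothed with a centred moving average
(`w = 5`, odd); any sample where the smoothed force rises by at least
$\theta$ within 3 samples is a candidate; candidates closer than the
refractory gap (3 samples) plus `w` merge into one event. The automatic
threshold is $\theta = \max(20\ \mathrm{pN},\ 4\hat\sigma)$ with
$\hat\sigma$ a robust noise SD taken from first differences of the final
fifth of the trace, $\mathrm{MAD}(\Delta F)/\sqrt2$ — first differences,
because a rupture event sitting in that tail region shifts a value-based
MAD badly but contributes only one outlying difference. The event index is
then refined on the **raw** trace: the sample preceding the largest
single-sample rise in the cluster window, then the raw minimum among the
three samples up to it. The jump is the sharpest feature of the trace, so
this localizes to within ~1 sample under 5 pN noise, whereas a raw-force
argmin wanders several samples up the shallow ramp (the ramp descends by
only ~0.6 pN/sample at typical stiffness, well below the noise). On
noiseless traces the planted minimum is recovered exactly.

**Specificity gate.** Events with $F_R > 50$ pN **and** $F' > 2000$ pN/s
(both strict, matching the ">" of the published thresholds) fall in
quadrant II and are called specific; I holds low-force/high-rate events,
IV high-force/low-rate, III the rest. Per cell, $f_b$ = specific events /
total events (cells with zero events are excluded with a warning — the
ratio is undefined for them), and $f_{b,rel} = f_b / \overline{f_b}$ over
reference-condition cells, which makes the reference mean exactly 1.
Condition summaries use the cell as the unit of replication
(SEM = SD/√n over cells); quadrant occupancies are also reported pooled
over events, since published percentages do not state which convention was
used — both are available.

## Cell migration

Tracks are 2D centroid positions at a fixed interval (default
$\Delta t = 5$ min). The MSD estimator is the **method of non-overlapping
intervals**: for interval length $n$ frames, the track is partitioned from
frame 0 into consecutive disjoint $n$-frame segments (remainder dropped),
and $\langle d^2(n\Delta t)\rangle$ is the mean squared end-to-start
displacement over those segments, $\lfloor (N{-}1)/n \rfloor$ of them.
Disjointness keeps segments independent under the model, at the cost of
few segments at long lags.

Speed is $S = \sqrt{\langle d^2(\Delta t)\rangle}/\Delta t$. The
persistent-random-walk model
$\langle d^2(t)\rangle = 2S^2P[t - P(1 - e^{-t/P})]$ is fitted by
Levenberg–Marquardt least squares with starts $S_0$ from the speed and
$P_0$ the median fitted lag, bounds $S > 0$,
$P \in (\Delta t/100,\ 100\,t_\mathrm{max})$. Only intervals with at least
2 disjoint segments are usable, and by default only the first half of the
usable intervals enter the fit: the 2–3-segment tail of the MSD curve has
variance so large that, unweighted, it dominates the residual and degrades
$R^2$ for a substantial fraction of perfectly well-formed tracks.
$R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ is computed unweighted on the
fitted points; cells with $R^2 < 0.5$ (strict) are excluded from speed
summaries, with a warning flag when fewer than 40 cells survive. For data
generated exactly from the model the fit recovers $(S, P)$ to $10^{-6}$
relative with $R^2 = 1$.

`prw_msd()` switches to the series
$S^2t^2(1 - x/3 + x^2/12)$, $x = t/P$, below $x < 10^{-4}$: the direct
expression computes $x - (1 - e^{-x})$ by catastrophic cancellation there.
Its limits are ballistic ($S^2t^2$) for $t \ll P$ and diffusive
($2S^2Pt$) for $t \gg P$; note that at $t = 1000P$ the deviation from the
diffusive asymptote is still exactly $P/t = 10^{-3}$.

## Morphodynamics

Circularity is $4\pi A/P^2$ — 1 for a circle, tending to 0 for elongated
or dendritic outlines. Polygon input uses the shoelace area and edge-sum
perimeter after a simple-polygon check; mask input uses pixel-count area
and exposed-pixel-edge perimeter (which biases circularity low on smooth
diagonal boundaries — outlines are the preferred route). The raw value is
retained; only the reported one is clipped at 1.

Kymograph edge traces give protrusion events as rising runs from a local
minimum to the peak or to a plateau onset, whichever comes first. Step
classification runs on a 3-point-smoothed trace (rising above
`plateau_tol` = 0.5 px/frame, falling below its negative, plateau
otherwise), but heights are measured on the raw trace, matching the manual
line-drawing convention the rule set describes. Boundaries are refined by
*level*: the start is the last frame still at the local baseline level,
the peak the first frame reaching the peak level (tolerance
$\max(\texttt{plateau\_tol},\ 2.5\hat\sigma)$ with $\hat\sigma$ from the
smoothing residuals) — extremum-based refinement chases noise and
systematically stretches the ramp. Events under 4 px height are discarded
(strictly "less than 4", so 4 px is kept). Velocity is height/ramp
duration (reported in px/frame and, after calibration, µm/min); lifetime
is ramp plus plateau duration in seconds. The area-oscillation routine
finds, after each media-switch timestamp, the area peak within a 60-min
window on a 3-point-smoothed series and reports time-to-peak and
peak/pre-switch ratio (time-to-peak is `NA` when the area never rises).

## Trajectory metrics

The headpiece opening distance is
$d = |\mathrm{COM}_A{\cdot}y - \mathrm{COM}_B{\cdot}y|$ between a
β-propeller portion (default selection `A:250-438`) and a hybrid-domain
portion (`B:55-106+356-434`), mass-weighted by default (geometric centers
available for XYZ inputs without masses), evaluated at every recorded
frame. $d$ is a *y-component* metric: invariant under rigid translation
and rotation about y, deliberately not under general rotations — the
coordinate axes are taken exactly as stored in the input file, and no
reorientation is attempted. Residue–ion distances use the full 3D
COM–COM distance. Replicate histograms bin each replicate's series on
shared edges, normalize each to sum 1, then average across replicates with
SEM — replicates, not frames, are the unit of replication. The default
bin width of 0.05 nm resolves mode structure separated by ~0.45 nm
while keeping per-bin counts stable at a few hundred frames per replicate.

## Statistics

Geometric MFI is $\exp(\mathrm{mean}(\log x))$; the normalized form is the
ratio of test-line to control-line mean geometric MFIs. The unpaired
t-test is the classical pooled-variance Student test (Welch behind a
flag); with zero pooled variance, $p = 1$ for equal means and a flagged 0
otherwise. The ANOVA post-test is the classical "Bonferroni post-test":
all-pairs t statistics built on the pooled within-group mean square with
$N - k$ degrees of freedom, and $p_\mathrm{adj} = \min(1, m\,p)$ — not
independent per-pair t-tests, which is why it is computed explicitly
rather than through `pairwise.t.test`.

## Synthetic data: what it emulates, and what it does not

* **Curves** are Gaussian baselines plus piecewise-linear event shapes
  (exact ramp to $-F_R$, instantaneous return), with two planted
  populations — specific (default $F_R \sim N(90, 15)$ pN,
  $k_\mathrm{eff} \sim N(0.8, 0.1)$ pN/nm) and nonspecific
  ($N(30,10)$, $N(0.2,0.05)$) — mixed with a default specific fraction of
  0.168, the measured quadrant-II occupancy on RGD cantilevers before
  receptor blocking; blocking is emulated by setting the fraction to 0.
  Noise defaults to 5 pN, a plausible instrument figure (the source
  experiments did not report theirs). Not emulated: polymer-linker
  stretching nonlinearity, cantilever hydrodynamics, multiple simultaneous
  bonds, drift. Planted minima are separated by at least three fit
  windows, so ground truth is unambiguous.
* **Tracks** integrate a two-component Ornstein–Uhlenbeck velocity process
  with the *exact* joint position–velocity transition over each frame
  interval (not an Euler step), stationary per-component velocity variance
  $S^2/2$, so the ensemble MSD matches the closed form at every lag and
  parameter-recovery tests are unbiased. Defaults $S = 1$ µm/min,
  $P = 20$ min, $\Delta t = 5$ min, 96 frames (an 8-h movie at 5-min
  framing). Not emulated: centroid-segmentation noise, cell–cell
  interactions, drift, taxis.
* **Edge traces** are piecewise-linear ramps and plateaus plus Gaussian
  positional noise; a retraction ramp of the same duration as the rise
  follows each plateau so the trace returns to baseline (protrusions must
  start from a local minimum; the rule set describes only the rise and
  plateau). Not emulated: intensity-level image formation, ruffling.
* **Frames** place two labeled atom groups so their COMs differ in y by an
  exact schedule; thermal motion is an independent rigid translation per
  *group* per frame — whole-frame jitter would cancel exactly in $d$, and
  per-atom jitter would shrink as $1/\sqrt{n_\mathrm{atoms}}$, so the
  group-level term is what actually propagates
  ($\mathrm{SD}(d) = \sqrt2\,\sigma_\mathrm{jitter}$). Not emulated: real
  protein internal dynamics.

Passing tests on these generators demonstrates the estimators' correctness
and calibration under known ground truth; it does not certify performance
on instrument data with unmodelled artefacts (baseline drift, linker
nonlinearity, segmentation noise).

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to make
binomial/SEM bands tight while staying desk-scale: 500 curves (noise 5 pN)
for detector metrics; 3000 events per gate condition; 100 replicate runs
of the 2 × 5-cell × 200-event binding-frequency design; 500-track
ensembles against the closed-form MSD; 200-track parameter recovery;
1000 short tracks against the exhaustive MSD oracle; $10^5$ permutations
for the t-test oracle; 8 replicates × 800 frames per histogram condition.
Seeds are fixed in tests and derived from `--seed` in the acceptance
script. Degenerate inputs (constant traces, zero-variance groups,
single-segment intervals, empty selections, uniform kymographs) return
flagged values or classed errors rather than NaNs, as documented per
function.

## Known limitations

* The detector assumes jumps complete within ~3 samples; instruments with
  heavy low-pass filtering would need a wider jump window.
* Mask-based perimeters are staircase lengths; circularity from masks is
  biased low relative to outline-based values.
* The PRW fit is unweighted; a weighted fit (by segment count) would be
  more efficient but would depart from the stated unweighted $R^2$
  convention.
* Opening-distance histograms inherit the bin-width/peak-position
  trade-off; reported peak positions are bin midpoints, so they carry
  half-bin (0.025 nm) quantization.
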