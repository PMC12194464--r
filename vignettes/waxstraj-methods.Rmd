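---
title: "Tissue WAXS reduction and the lipid/water biomarker: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue WAXS reduction and the lipid/water biomarker: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waxstraj)
```

## The measurement and the model

Wide-angle X-ray scattering of soft tissue probes inter-molecular
distances of a few ångström. After azimuthal integration, tissue profiles
in the 10–20.5 nm⁻¹ window are dominated by a lipid peak near
q ≈ 13.5 nm⁻¹ (inter-fatty-acid spacing) and a water peak near
q ≈ 18 nm⁻¹ (oxygen–oxygen distance of the tetrahedral network), riding on
an amorphous background. `waxstraj` models a reduced profile as

$$y(q) = \sum_{i=1}^{3} A_i\, e^{-(q-\mu_i)^2 / 2\sigma_i^2}
  + B/q^4 + C,$$

Gaussian peaks on an inverse-fourth-power amorphous term plus a constant
offset. The lipid/water biomarker is the ratio of the fitted lipid and
water *heights* ($A_\text{lipid}/A_\text{water}$); peak areas
($A\sigma\sqrt{2\pi}$) are reported alongside, since either convention can
be found in practice and the two differ when widths change. The ratio
direction is fixed (lipid/water, so disease progression *decreases* the
biomarker) and printed with every trajectory to prevent silent inversion.

### Geometry

Momentum transfer follows from $q = 4\pi\sin\theta/\lambda$ with
$\tan 2\theta = r/L$, where $r$ is the pixel's radial distance from the
beam center and $L$ the sample-to-detector distance;
$\lambda = 1.2398420/E$ (keV · nm). Defaults: $E = 12.4$ keV,
$L = 170.21$ mm, 0.172 mm square pixels (a Pilatus-class photon-counting
detector — the pitch is configurable, never hard-coded). Pixel indices are
1-based (row, col), following R matrix convention, with radial distances
evaluated at pixel centers; the beam center is fractional and may lie off
the detector. The beam center comes from the geometry config: facility
calibration against reference standards is out of scope.

The instrument's full angular range reaches well beyond the analysis
window (roughly 0.7–45 nm⁻¹ at these settings, depending on where the beam
center sits on the panel and the beam-stop size); the analysis grid below
deliberately covers only 3.25–21 nm⁻¹, where the tissue features of
interest live.

### Azimuthal integration and counting statistics

Each unmasked pixel is assigned to the q bin containing its center —
half-open bins $[q_k, q_{k+1})$, last bin closed, the bin labelled by its
midpoint. This rule is declared bit-exactly so an independent brute-force
per-pixel oracle and the vectorized production path agree identically (a
test enforces this on random frames). The bin statistic is the **mean**
counts per pixel, not the sum, so bins with different pixel populations
are comparable — the standard powder-reduction convention. Detected counts
are Poisson; the bin uncertainty is the error of the mean,
$\sigma_b = \sqrt{\sum_b N}/n_b$ in raw counts. Frames normalized by
monitor/exposure carry their cumulative scale factor so the error model
always refers back to raw counts (making integration exactly linear in
the scale, uncertainties included). Geometric (solid-angle) and absorption
corrections are exposed as optional multiplicative pixel-weight maps and
default to off; no published formula is assumed, the weight map is the
extension point.

Masks mark the beam-stop shadow (all pixels within a configurable radius
of the beam center; a radius of zero masks nothing) and listed dead
pixels, and can be dilated with a disk structuring element
($di^2+dj^2 \le r^2$) to suppress edge effects; dilation only ever adds
exclusions.

## Preprocessing

The stage order is fixed and tested: `remove_nan` → optional
`subtract_background` (quadrature uncertainties) → `restrict_q` (closed
window, default 3.25–21 nm⁻¹) → `l1_normalize`. Normalization divides
intensity and uncertainty by $\sum |I|$ *after* windowing, so unit mass
refers to the analysis window; whether normalization precedes or follows
windowing is an open convention, so the package fixes one order and makes
it inspectable. The normalizer is treated as a constant in error
propagation — its own relative variance is smaller by roughly the number
of bins. L1 mass is 1 to within 10⁻¹² and invariant under any positive
rescaling of the input.

### Automated cleaning

Manual curation of measured profiles is not reproducible, so the package
substitutes an automated, fully reported rule. A profile is dropped when

1. its fraction of finite points falls below 0.95;
2. its total absolute intensity is not positive; or
3. within its (group, lobe) stratum, the L1 distance of its normalized
   shape to the stratum's pointwise-median shape exceeds
   $k \cdot \max(\mathrm{MAD}, \mathrm{median}, s_0)$ with $k = 5$ and
   floor $s_0 = 0.1$.

The floor needs a word. Distances between unit-mass shapes are bounded by
2. Repeat measurements of the same animal cluster tightly, so the stratum
MAD of distances can collapse far below genuine between-animal
variability and a bare $k\cdot\mathrm{MAD}$ rule would discard entire
healthy animals; gross artifacts, by contrast, sit at distances of order
1. The floor (5 % of the maximum possible distance) keeps biological
variation below threshold while a profile with, say, hundredfold intensity
spikes on half its bins (distance ≈ 0.98 > 0.5) is still rejected. Every
input appears in the cleaning report exactly once, with its statistics,
the thresholds used, and the decision.

## Fitting

Weighted least squares, $\min \sum ((y - y_\text{model})/\sigma)^2$, by
Levenberg–Marquardt with analytic Jacobian and box constraints:
$A_i \ge 0$, $\sigma_i \in [0.2, 5]$ nm⁻¹, seeded centers within
±2 nm⁻¹ of their seeds, $B \ge 0$. The default fit window is the
biomarker window 10–20.5 nm⁻¹; full-window fitting is a config option.
Weights default to $1/\sigma^2$ (Poisson), with an unweighted option for
profiles lacking uncertainties. Convergence tolerance is $10^{-10}$ on
the cost, with at most $10^4$ function evaluations; non-convergence is
flagged in the result, never raised, and a singular covariance leaves
uncertainties `NA`. Parameter uncertainties come from the
Gauss–Newton covariance $(J^TWJ)^{-1}$ scaled by the reduced chi-square;
on nominal synthetic noise the 68 % intervals for peak centers cover the
truth at close to the nominal rate (a property test pins the band).

Initialization is data-driven and deterministic: centers seeded at 13.5
and 18.0 nm⁻¹ and refined to the local maximum of a 5-point running mean
within ±1.5 nm⁻¹; amplitudes from the local prominence; widths 1.0 nm⁻¹;
offset at the window minimum; $B$ by least squares of $B/q^4$ on the
lowest-q decile after offset removal.

The model's sum runs to three peaks while two suffice for the lipid/water
window, so both variants exist. The `3peak` variant adds a broad
remainder term (width 3 nm⁻¹, free position) and drops it automatically
when its amplitude does not exceed its own uncertainty, refitting with
two peaks; `fit_composite()` defaults to `3peak` (the full model), while
the pipeline driver defaults to `2peak` — on two-peak data the broad term
is dropped in virtually every fit, and the double fit would only double
the cost of a cohort run without changing the biomarker. The variant
actually kept is recorded in every fit result.

Peak assignment for the biomarker: lipid is the non-broad peak with
center in [12.0, 15.5] nm⁻¹, water in [16.5, 20.5] nm⁻¹; with several
candidates the larger amplitude wins; the broad term is never assigned.
The ratio's uncertainty uses first-order propagation,
$(\delta r/r)^2 = (\delta A_l/A_l)^2 + (\delta A_w/A_w)^2$, which a
Monte-Carlo resampling oracle confirms to within 10 % at typical
uncertainty levels.

## Trajectories

Aggregation is positions → animal → group: grid positions are averaged
within each animal's lobe first, then group mean and standard deviation
are taken over animals, so dispersion reflects biological replication
(n = animals), matching how longitudinal animal results are reported.
How the grid positions of one animal should be collapsed is not uniquely
determined by that convention; averaging before group statistics is the
package's choice. Control animals carry sacrifice days, and each
experimental day is compared against controls sacrificed that day
(pooled-control fallback, flagged). Records with unassignable peaks or
failed fits are excluded and counted in the manifest. Both the ratio
trajectory and the per-peak magnitude table are emitted, since either
view of the time course is useful.

## The synthetic cohort

The generator exists so every stage is testable with known ground truth.
Its defaults emulate the longitudinal design the package targets: five
groups (Control, days 2/4/7/16), five mice per group, left (inoculated)
and right (internal-control) lobes, 25 grid positions per lobe, profiles
on a 414-point grid spanning 3.25–21 nm⁻¹.

Healthy baseline parameters (amplitudes in arbitrary pre-normalization
units): lipid $A = 1.0$, $\mu = 13.5$, $\sigma = 1.2$; water $A = 0.6$,
$\mu = 18.0$, $\sigma = 1.4$; $B = 150$, $C = 0.05$. Widths make the
peaks resolved yet overlapping; the background contributes ≈ 32 % of the
total windowed signal (between a fifth and two fifths, as in measured
tissue profiles); the healthy lipid peak is taller than the water peak.

Disease enters as per-group multiplicative factors on the left lobe's
amplitudes — lipid 1.0, 1.0, 0.90, 0.75, 0.45 and water 1.0, 1.0, 1.12,
1.30, 1.80 for Control through Day 16 — chosen to encode the progression
narrative: day 2 indistinguishable from control, day 4 still close,
comparable peak heights at day 7 (the two heights differ by < 15 %), and
water dominant by day 16. Positions and widths stay fixed across groups:
the progression signal is a magnitude change.

Between-animal variability is lognormal on amplitudes with CV 0.15. The
log-amplitudes of the two peaks correlate at 0.64: the dominant
inter-animal effect on scattering amplitude is an overall signal scale
(sample thickness, density, positioning) that moves both peaks together,
while only the smaller composition-specific residual perturbs their
ratio. This matters for what the cohort can show: with fully independent
per-peak variability the day-2 → day-4 step would drown in ratio noise at
n = 5, and no five-animal study could claim a monotone trajectory; with a
correlated scale component the ratio CV is ≈ 0.13 and the default design
recovers a strictly decreasing left-lobe trajectory in essentially every
seeded replicate (a 50-seed acceptance test requires ≥ 95 %).

Counting noise is Poisson: the model curve is scaled to an expected total
of 10⁶ counts per profile (a realistic integrated dose for
photon-counting acquisition of ten co-added short frames) and sampled
pointwise; $\sigma = \sqrt{\max(N, 1)}$. Frames are simulated the same
way in 2D — circularly symmetric expectation, Poisson counts, beam-stop
and random dead-pixel masks. All randomness flows from one root seed
through named substreams (subjects, per-profile noise, dead pixels), so
adding a stage never shifts another stage's draws and identical seeds
give bit-identical outputs.

What the generator does **not** emulate: detector panel gaps, beam
polarization, sample-absorption physics, spatial heterogeneity within a
lobe (all positions of an animal share its true parameters), drifts in
beam flux, or the tail behavior of real manual-curation decisions.
Passing tests therefore demonstrate the pipeline's correctness and
statistical calibration under the stated model, not robustness to every
instrumental artifact of a real beamline.

A note on group sizes: a design with a handful of controls sacrificed at
each time point (rather than a control group of five) is expressible via
`cohort_spec` — control animals are assigned sacrifice days round-robin —
but the default follows the five-per-group layout.

## Numerical choices and edge cases

- Bin rule, stage order, and aggregation hierarchy are all declared and
  tested rather than left implicit.
- `q = 0` is rejected wherever $q^{-4}$ appears; frame simulation guards
  the beam-axis pixel.
- Empty integration bins yield `NaN` and are removed by `remove_nan`,
  never silently interpolated.
- Ties in peak assignment resolve by amplitude; fitted peaks are
  re-ordered by center before assignment.
- Degenerate fits (flat profiles, pure background) converge to zero
  amplitudes consistent with their uncertainties instead of failing.
- The problem sizes used in the test suite — e.g. 20-profile fitting
  replicates and 50 seeded cohorts for trajectory recovery — balance
  statistical resolution of the properties being checked against keeping
  the suite quick to run routinely.

## Known limitations

- The amorphous term is a single fixed power law; real backgrounds can
  mix powers or require measured empty-cell subtraction.
- Peak shapes are Gaussian only — no Lorentzian/Voigt option.
- No polarization correction and no 2D anisotropy analysis (patterns are
  assumed circularly symmetric).
- The L1-normalization error model ignores the normalizer's own variance
  (an $O(1/n_\text{bins})$ effect).
- Biomarker uncertainties ignore the (typically negative) correlation
  between fitted lipid and water amplitudes; the Monte-Carlo check bounds
  the error of that approximation at nominal noise.
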