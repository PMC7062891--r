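---
title: "Dissociating reward prediction errors from mean reward rates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating reward prediction errors from mean reward rates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdbold)
```

## The scientific question

Phasic dopamine signalling is classically modelled as a reward *prediction
error*: a response to changes in the expectation of impending reward, which
vanishes once rewards are fully predicted. A distinct candidate signal is the
*mean reward rate* — the time-averaged reward currently on offer — which is
motivationally relevant as the opportunity cost of not working. The two are
easily conflated in imaging experiments because more reward usually also means
more positive surprises.

`tdbold` implements a task design that pulls the two apart, together with the
full simulation and inference machinery needed to test it on synthetic
functional MRI data. The task is a cued foraging paradigm: a coloured cue (2 s)
announces whether the upcoming trial pays 1 or 20 cents per caught target; a
fixation interval (3 s) follows; then a *foraging patch* (14.5 s) in which
target dots appear rapidly (about every 1.2 s) and each caught target pays the
trial's amount; trials are separated by 10 s pauses. Twelve trials, six low and
six high reward, give a six-minute run.

The logic, formalized by a temporal-difference model below, is:

* at the **cue**, reward expectations change (if the cue is unpredictable), so
  a prediction-error signal fires there — positive for high, negative for low
  reward cues;
* during the **patch**, rewards arrive at the expected rate, so the prediction
  error hovers around zero while the *reward rate* differs twenty-fold between
  conditions. A signal tracking mean reward rates therefore separates the
  conditions exactly where a prediction-error signal does not.

Three experiment variants sharpen the dissociation: variant 1 alternates
reward levels randomly; variant 2 alternates them deterministically, making
the cue fully predictable and abolishing its prediction error; variant 3
presents the targets at regular 1250 ms intervals, removing even the
target-timing prediction errors inside the patch.

## The TD(0) model

States $s_t$ discretize the trial (cue, interval steps, patch steps, pause
steps, terminal). State values are undiscounted expected future rewards,
$V(s_t) = E[r_t + r_{t+1} + \dots]$, learned by the one-step update

$$V(s_t) \leftarrow V(s_t) + \alpha\,\delta(s_t), \qquad
\delta(s_t) = V(s_{t+1}) - V(s_t) + r_t ,$$

with the terminal value pinned to zero. When learned values predict rewards
correctly, $\delta = 0$ and the *consistency condition*
$r_t = V(s_t) - V(s_{t+1})$ holds: the reward rate equals the slope of the
value function. The same identity holds for state–action values under the
optimal policy (always click when a target appears),
$r_t = Q(s_t,a_t) - Q(s_{t+1},a_{t+1})$; `train_q_values()` verifies this
form.

Model choices that the task description leaves open, and our defaults:

* **Learning rate** `alpha = 0.1`; any value in (0, 1] converges on the
  deterministic chains, and 0.1 keeps stochastic-chain value fluctuations a
  small fraction of the 20-cent reward unit.
* **Training length**: to a maximum-update tolerance of `1e-8`, capped at
  10,000 trials. Chains involving an unpredictable cue never meet the
  tolerance (the context-state error is irreducible), so they train for the
  full cap and are flagged unconverged — by design, not failure.
* **Step grain** 250 ms inside the patch (finer than the 300 ms minimum
  inter-target interval, so a step holds at most one target); the interval
  and pause phases use the same grain for uniformity, which only adds
  zero-value states.
* **State encoding**: states are indexed by position and reward level, not by
  target occupancy — the learner knows elapsed time but not whether the next
  step pays. With irregular targets this produces the characteristic positive
  spikes at targets and negative dips at omissions that cancel on average;
  with regular targets (variant 3) the chain is deterministic and
  $\delta \equiv 0$ in the patch after convergence.
* **Predictability of the cue** (variant 2) enters as a context state that
  encodes the previous trial's reward level; under strict alternation the
  upcoming cue is then fully predicted and its $\delta$ vanishes.
* **Trace timing**: $\delta(s_t)$ belongs to the transition $s_t \to s_{t+1}$.
  The phasic response "at the cue" is the error of the transition *into* the
  cue state; `consistency_residual(at = "entry")` summarizes that convention,
  `at = "within"` the sustained-phase convention.
* **Figure-style curves**: recorded $\delta$ and $r$ impulses are averaged
  across trials and convolved with the canonical haemodynamic response
  (`smooth_trace_to_curves()`), reflecting what the model predicts for the
  BOLD signal. With full hits the ratio of the time-averaged reward curves,
  high over low patch, is exactly the payout ratio 20.

## Task timing parameters

All durations are configurable in `task_config()`; defaults are the task's
printed constants: 12 trials, 2 s cue, 3 s interval, 14.5 s patch, 10 s
pause, rewards 1 and 20 cents, targets on screen 800 ms. Irregular
inter-target intervals follow an exponential density truncated to
[300, 1800] ms whose rate is calibrated by scalar root finding so that the
truncated mean equals 1220 ms. Because 1220 ms lies above the midpoint of the
bounds, the calibrated rate is negative — a valid member of the bounded
exponential family whose density increases towards the upper bound; the
sampler uses the closed-form inverse CDF, so schedules are bit-reproducible
from their seed. Regular targets (variant 3) use a fixed 1250 ms interval.
The first target of a patch falls one sampled interval after patch onset and
targets are packed until the patch ends at its scheduled offset.

## Design matrices

First-level designs follow standard event-related modelling: boxcars (cue and
patch of each reward level) or per-target impulse events, convolved with a
canonical double-gamma haemodynamic response (peak 6 s, undershoot 16 s, unit
dispersions, 6:1 amplitude ratio, 32 s support), built on a 16-fold
oversampled grid and decimated at scan times. The kernel is scaled to unit
peak so coefficients read in signal units. Unit-area impulses are used for
events, so a single event's regressor approximates the kernel itself.
Optional slow-drift regressors use the discrete-cosine basis with a 128 s
cutoff.

Parametric modulators: trial number (mean-centred, per cue condition),
within-patch time up to the 4th-degree polynomial (mean-centred powers,
convolved, then sequentially orthogonalized against the condition's main
effect and all lower degrees), and first- versus last-quartile target
indicators. Orthogonalized polynomial columns are rescaled to unit norm —
centred 4th powers of time in seconds otherwise reach magnitudes of $10^5$
and the scale of a modulator column is statistically arbitrary.

## The synthetic BOLD cohort

No scan data accompany the study design, so the package generates its own
acceptance surface: a box phantom (default $20 \times 24 \times 18$ voxels)
with two 64-voxel cubic regions, a ventral-striatum-like box ("VS",
ventral-anterior) and a midbrain-like box ("VTA_SN", ventral-posterior), on
an RAS grid centred at the origin. Voxel sizes follow the acquisition
presets: 3 mm (variant 1) or $2 \times 2 \times 2.5$ mm (variants 2–3).

Each subject's series is baseline + planted amplitudes × design regressors
within their regions + stationary AR(1) noise (innovation sd 1% of baseline,
$\varphi = 0.2$ by default — the process the estimator assumes) + optional
sinusoidal drift. Between-subject variability adds a Gaussian deviation
(sd 0.1) to every planted amplitude, giving genuine random effects. Planted
group amplitudes default to 0.5 (high) and 0.1 (low reward) signal units;
variant 2 plants *no* cue effect, realizing the predictable-cue finding as a
ground truth to recover. Spatial smoothing uses separable Gaussian kernels
(FWHM 8 mm or 6 mm per preset) whose truncated border kernels are
Sinkhorn-balanced to doubly stochastic form, so flat images stay flat and
each volume's spatial mean is preserved.

What the generator deliberately does **not** emulate: anatomy, motion,
physiological noise, spatial noise correlation beyond the applied smoothing,
field inhomogeneity. Passing tests therefore demonstrate the correctness of
the estimation and inference machinery under the model's own assumptions,
not robustness to real-data artefacts.

## Estimation and inference

First-level fits use ordinary least squares, followed by AR(1) prewhitening
with a single coefficient pooled over voxels from the lag-1 autocorrelation
of the OLS residuals (a voxelwise option exists), and re-estimation on the
whitened system. Degrees of freedom are scans minus design rank, with no
correction for the AR estimation — a second-order effect at these series
lengths. Zero-variance voxels are masked out of t maps rather than producing
infinities.

Second-level analysis treats per-subject contrast estimates as observations:
one-sample t across subjects, or two-sample pooled-variance t for
between-experiment interactions. Corrected inference is by the maximal
statistic under permutation: random sign flips of subject maps (one-sample;
exchangeable under symmetric errors) or group-label permutation (two-sample).
Per permutation, the largest t (peak-level) and the largest supra-threshold
cluster size (cluster-level; cluster-defining p 0.001 whole-volume, 0.01 in
region-of-interest analyses) are recorded; corrected p-values use the +1
smoothing $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_{perm})$, hence
are bounded below by $1/(n_{perm}+1)$. Ties count as exceedances
(conservative), tests are one-sided, and clusters use 18-connectivity by
default (6 and 26 selectable). When $2^n$ is below the requested number of
permutations, all sign assignments are enumerated instead. The
ventral-striatum ROI is the literature box x $-12..12$, y $0..12$,
z $-12..6$ mm (5184 mm³); a surrogate midbrain box is provided for
small-volume correction without claiming equivalence to any hand-drawn mask.

Plots of the fitted signal course (`fitted_time_course()`) rebuild each
subject's trial-locked curve from the cue fit plus the patch main effect and
polynomial expansion fits, and form point-wise 90% bands as mean
± 1.645 standard errors across subjects.

## Scenario presets and problem sizes

`experiment_preset()` bundles the three variants: n = 35 / 17 / 20 subjects,
TR 2.46 / 2.85 / 2.85 s (144 or 125 scans for the 354 s run), smoothing
8 / 6 / 6 mm, random/regular alternation, irregular/regular targets, 6000
permutation samples. `run_scenario()` executes schedule → TD model → design →
cohort → first level → second level → permutation report deterministically
from one master seed; `compare_experiments()` runs the between-experiment
interaction (two runs must share one grid, so the variant-2 cohort is
resimulated with variant-1 grid settings for that analysis, mirroring the
design logic of analysing the interaction at the coarser resolution).

The package's test suite scales the expensive simulations to what a single
CPU handles comfortably while keeping the study's structure: the familywise
error calibration uses 500 null cohorts of 12 subjects at 500 permutations
(the null-cohort maps are drawn directly at the contrast-map level — under
the null hypothesis the second level sees exchangeable mean-zero maps, so
simulating the full first level would only add cost, not information); the
planted-effect recovery runs the full variant-1 and variant-2 presets at 500
permutations; and the cohort-level power property (the planted foraging
effect detected after correction in at least 80% of repeated cohorts of 17)
uses 20 unsmoothed cohorts at 199 sign flips, where detection is saturated
at the preset effect size.

## Numerical choices and degenerate inputs

* Truncated-exponential calibration by `uniroot` at tolerance 1e-14; the
  uniform limit (rate → 0) is handled explicitly.
* TD training convergence is measured as the largest within-trial value
  update; initial values 0.
* Designs are checked for full rank; rank-deficient fits name the collinear
  columns. Constant parametric modulators are dropped with a warning.
* A patch shorter than one minimal inter-target interval yields targetless
  trials with a warning, not an error.
* Cluster-defining thresholds convert an uncorrected one-sided p through the
  t distribution with the analysis' degrees of freedom.
* Permutation p-values never reach 0 by construction; identical seeds give
  bit-identical reports end to end.

## Known limitations

* The phantom is schematic; region geometry and effect sizes are free
  parameters, and recovery — not magnitude matching against any in-vivo
  statistic — is the acceptance surface.
* The pooled AR(1) coefficient underestimates serial correlation when slow
  drift is absorbed by the cosine basis; whitening remains approximately
  valid and the permutation inference does not depend on it.
* One-sample sign-flip inference assumes symmetric errors; heavy asymmetry
  would require a different exchangeability scheme.
* TD values on stochastic chains fluctuate at scale
  $\alpha \times$ per-step reward variance; the consistency residual is zero
  only in expectation there (and exactly zero on the deterministic
  variant-3 patch).
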