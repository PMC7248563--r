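---
title: "Methods: in-silico multicenter relaxometry with relaxomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico multicenter relaxometry with relaxomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`relaxomap` implements the computational core of a multicenter preclinical
relaxometry study on a fully synthetic footing: voxel-per-voxel T1 and T2
map fitting from magnitude MR series, multi-atlas maximum-probability
parcellation, and the agreement statistics used to compare imaging centers,
fitting pipelines, segmentation pipelines and repeated scans.  Everything
upstream of these steps — scanner raw-data conversion, rigid realignment,
template building, deformable registration — is deliberately out of scope;
the package consumes (or synthesizes) co-registered volumes.

# Signal models and their assumptions

**Inversion recovery (T1).**  Magnitude acquisitions carry no phase, so the
recovery curve is fitted with the three-parameter magnitude model

$$ s(\mathrm{TI}) = \left| A \left( 1 - B e^{-\mathrm{TI}/T_1} \right) \right| $$

with amplitude $A$ (proportional to proton density), inversion factor $B$
and relaxation time $T_1$.  A perfect 180° inversion gives $B = 2$; leaving
$B$ free absorbs imperfect inversion *and* incomplete longitudinal recovery
over the repetition time, which matters because at TR = 6500 ms the longest
$T_1$ values (CSF, ~2800 ms) do not recover fully.  Because the same model
generates and fits the synthetic data, this bias cancels exactly in the
round-trip experiments; on real data $B$ would soak it up approximately.

**Polarity.**  The magnitude operation folds the negative limb of the
recovery curve and creates a local minimum near the signal null.  Rather
than restoring polarity explicitly (impossible without phase), the fitter
multistarts $T_1$ from the null-point relation $T_1 = \mathrm{TI}/\ln 2$
evaluated at the observed signal minimum and its neighbouring inversion
times (3 starts by default), and keeps the lowest-residual solution.

**Multi-echo decay (T2).**  A two-parameter mono-exponential
$s(\mathrm{TE}) = A e^{-\mathrm{TE}/T_2}$, initialized by a log-linear
regression on the first half of the echo train (the late echoes are
noise-floor-dominated and would bias the initializer).  No offset term is
included by default, matching the convention that all centers fit the same
model equations.

# Default acquisition protocols

* IR T1: TI = 247, 408, 674, 1112, 1838, 3030, 5000 ms; TR = 6500 ms.
* Multi-echo T2: 28 echoes, TE = 8, 16, …, 224 ms; TR = 600 ms.

Times are always milliseconds.  A multi-echo train legitimately has
TR < max(TE) (one excitation, many echoes), so protocols only require
TR > 0.

# Optimizer backends

Both backends minimize the same per-voxel sum of squares, independently for
every voxel (no spatial coupling, which the tests verify by comparing
sub-block fits against the full fit):

* `LEAST_SQUARES_LM` — Levenberg-Marquardt via `minpack.lm::nls.lm`, with
  box constraints ($A \ge 0$, $0 \le B \le 4$, relaxation time positive).
* `SIMPLEX` — Nelder-Mead via `stats::optim`, restarted once from a
  deterministically perturbed optimum to guard against premature simplex
  collapse.

Convergence uses a relative tolerance of $10^{-6}$ and at most 500
iterations.  A brute-force reference, `grid_search_fit()`, scans relaxation
time on a 1 ms grid and solves the amplitude terms by linear least squares
per grid value; for the magnitude-IR model the linear solve enumerates the
$n+1$ monotone polarity patterns of the signed curve and evaluates the true
magnitude-model residual, so its minimum is an achievable fit.  Both
backends are required (and verified) to reach residuals at or below this
oracle on noisy voxels.

**Plausibility filter.**  Fitted values that are non-positive or exceed
3000 ms (T1) / 300 ms (T2) are marked invalid; the bound itself is kept
(the cut is strict on "greater than" — stated explicitly because the
convention is otherwise ambiguous).  Values are never altered, so the
filter is idempotent, and downstream statistics consume the validity mask
only.  Voxels whose peak signal falls below `min_signal` (by default 3×,
the background noise scale estimated from the grid's border voxels) are
skipped as background.

# The digital phantom

`make_label_phantom()` partitions an ellipsoidal "brain" envelope into the
29 study regions — 13 bilateral structures plus the 3rd-and-4th-ventricle
compartment, brain stem and cerebellar white matter — by quota-constrained
nearest-seed growth.  Region seed points sit at fixed anatomical-like
positions (mirrored across the midline for bilateral structures, slightly
jittered by the seed); voxels are claimed in order of increasing distance
by regions with remaining quota.  Class quotas reproduce the study's size
hierarchy: lateral ventricles ≈ 0.106 and the 3rd-and-4th-ventricle
compartment ≈ 0.333 of an average parenchymal region (the 3500 / 11000 /
33000-voxel proportions at full resolution), with a floor of 8 voxels per
region.  Geometry is schematic by design: the analyses downstream depend on
region sizes, adjacency and truth values, not anatomical shape.

Ground truth is piecewise constant per region, with 7 T-plausible values:
cortex $T_1 \approx$ 1840–1900 ms, white matter 1500–1550 ms, CSF
2750–2800 ms; tissue $T_2 \approx$ 36–48 ms, CSF 170–180 ms; proton
density 0.85–1.0 (CSF 1.0) times a signal scale of 1000.

# Noise and center effects

Magnitude MR noise is Rician: $\sqrt{(s + n_1)^2 + n_2^2}$ with
$n_1, n_2 \sim \mathcal N(0, \sigma^2)$ and $\sigma$ in raw signal units.
Background voxels therefore carry the analytic floor
$\sigma\sqrt{\pi/2}$, which the tests check by Monte-Carlo.

A center is modelled as a global gain, a smooth multiplicative bias field
(a sum of low-frequency random-phase cosine modes, normalized so its peak
deviation from 1 equals the requested amplitude), and additional Rician
noise.  This is a generic surrogate for coil/sequence differences, not a
physical model of any particular mechanism (e.g. stimulated echoes).
Ratio-based decay fitting is invariant to gain, so gain and smooth bias
affect amplitudes but leave the relaxation-time maps essentially unchanged
— the tests verify exact invariance of $T_1/T_2$ under global scaling.

Inter-atlas variability is emulated by `perturb_labels()`: labels are
pulled back through a smooth random displacement field with a prescribed
RMS vector amplitude (in voxels), nearest-neighbour sampled.  Zero
magnitude is the exact identity, and mean Dice against the original
decreases monotonically with amplitude.

# Label fusion and overlap metrics

"Maximum probability" fusion is a per-voxel plurality vote over hard
labels (the label probability at a voxel is its vote fraction), with
background participating as label 0.  Ties break deterministically to the
smallest label id — stated explicitly because vote counts tie easily with
small atlas sets — which also makes fusion invariant to atlas ordering.
Dice of two empty masks is defined as 1: a region absent from both
parcellations is in perfect agreement, and the 0/0 case must be defined
one way or the other.

# Agreement statistics

All SDs are sample SDs ($n-1$).  Bland-Altman limits are
$\bar d \pm 2\,\mathrm{SD}(d)$ — exactly 2, not 1.96.  The percent error
between paired measurements is the symmetric form
$|x - y| / \left( (x+y)/2 \right) \times 100$, chosen so that reports do
not depend on which pipeline is the reference; with errors at the few-%
level it differs from $|x-y|/x$ only in the second decimal.  The
scan-rescan criterion flags a region when the absolute difference of its
two means is within twice the larger of the two regional SDs (the more
conservative yardstick, since the convention does not name a scan).

Mann-Whitney and Wilcoxon signed-rank tests use exact enumeration (with
mid-ranks, so ties are exact too) up to a combined sample size of 12, and
the normal approximation with tie and continuity corrections beyond; the
exact branches are tested against independent brute-force enumeration for
all sizes ≤ 8 and against `stats::wilcox.test` in tie-free cases.
Wilcoxon drops zero differences.  Shapiro-Wilk (delegated to
`stats::shapiro.test`) gates the choice of tests at α = 0.05 per sample;
agreement reports label their primary p-value nonparametric whenever either
sample fails the gate.  Significance in inter-center reports is called at
α = 0.01.

# The study driver

`run_study()` executes the full design from one validated configuration:
one shared phantom geometry; per-subject multiplicative jitter of the truth
values (SD 3% for T1, 5% for T2 — chosen so the synthetic between-subject
regional spread is of the same order as typical in-vivo spreads of
~170 ms T1 / ~11 ms T2, without claiming to reproduce them); per-center
gain/bias/noise; a second scan for flagged subjects; every fitting pipeline
and every atlas set.  Every random draw derives its seed from the master
seed and a label path (`subject/center/scan/stage`) through a deterministic
polynomial hash, so reruns are bit-identical and adding a subject never
changes the data of existing ones.  The bias-field seed is derived from the
center only (hardware is a fixed property of a center), while noise seeds
include subject, scan and modality — a scan-rescan replicate is "same
phantom, same center effect, new noise".

Default problem sizes are chosen as desk-scale stand-ins: a 24×24×12 study
grid with 3 subjects for the full driver, 32×32×16 for single-map recovery
experiments, and the full 64×64×32 phantom for the fusion-overlap analysis.
At these sizes the complete test suite runs in about a minute.

## Verified properties, and what they do and do not show

The test suite establishes, among others: exact (<0.1%) round-trip recovery
of regional T1/T2 from noiseless simulations; regional-mean bias within 2%
(T1) and 3% (T2) under Rician noise at peak SNR 50; backend concordance
(Levenberg-Marquardt vs simplex) better than 1% mean percent error on noisy
data; optimizer residuals at or below the 1 ms grid-search oracle; fusion
identical to exhaustive vote counting; near-zero inter-center differences
when simulated centers are identical; and a minimum non-ventricle Dice
above 0.8 between independently fused 11- and 12-atlas parcellations.

The noisy recovery experiment uses a uniform-proton-density variant of the
truth table so that *every* region actually sits at the stated peak SNR;
with tissue-realistic proton densities (0.85–1.0) the effective SNR of the
shortest-$T_2$ white-matter regions drops to ~42–46 and their noise-floor
bias exceeds 3% — an expected property of mono-exponential fitting on
Rician data, worth remembering when reading real white-matter T2 values.

Because simulation and fitting share the same signal models, these checks
validate the estimation and comparison machinery, not the models'
faithfulness to any scanner.  Real acquisitions add effects that the
phantom deliberately omits: $B_1$ inhomogeneity and slice profiles,
stimulated echoes in multi-echo trains (a plausible source of
between-center T2 offsets), partial-volume mixtures at region borders,
motion and flow (especially in the ventricles), and registration error
beyond the smooth perturbation surrogate.  Passing tests therefore bound
the error contributed by the processing, not by the physics.

# Known limitations

* Phantom geometry is schematic; no anatomically faithful atlas is shipped.
* Only plurality-vote fusion is implemented (no weighted or STAPLE-style
  variants).
* The T2 model has no noise-floor offset term by default, so short-T2
  regions acquire a small positive bias at realistic SNR (quantified
  above).
* No mixed-effects modelling across subjects and no multiple-testing
  correction across regions; reports mirror the per-region, per-comparison
  convention of the study design they emulate.
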