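---
title: "Models and methods behind vigilcpt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vigilcpt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vigilcpt` analyzes sustained-attention fluctuations in continuous
performance task (CPT) data along two complementary axes: a slow linear
*vigilance decrement* in RT variability, and *infraslow oscillations*
(0.01–0.10 Hz) in the RT series itself. This vignette documents the models,
their assumptions, the tunable parameters, and the design choices made
where the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## The task and the simulator

The Vigil-style CPT presents 480 letters (85 ms stimulus, 900 ms
interstimulus interval; stimulus-onset asynchrony SOA = 985 ms). The target
is an "A" immediately followed by a "K"; there are 100 targets, balanced 25
per placement block of 120 trials, and the response is timed from the onset
of the "K".

`generate_trial_sequence()` places target pairs uniformly at random within
each placement block subject to non-overlap (pair starts at least 2 trials
apart, sampled exactly uniformly over the feasible sets via the standard
gap bijection). Filler letters are uniform over the 26-letter alphabet with
rejection of any draw that would create an accidental "A→K" bigram. The
instrument's actual filler distribution and adjacency rules are not public;
this construction is ours, chosen so that the target count is *exactly*
conserved — which the test suite checks by exhaustive bigram scan.

`simulate_session()` generates, for each non-missed target trial with
index $i$ and onset $t_i$ (s),

$$rt_i = \mu + \beta i + A \sin(2\pi f t_i + \phi)
  + \varepsilon_i + \eta_i,\qquad
  \varepsilon_i \sim N(0, \sigma_{b(i)}^2),\ \eta_i \sim Exp(\tau),$$

truncated to $[100, 1135]$ ms by resampling. The components map one-to-one
onto what the downstream analyses estimate: $\beta$ is a linear
time-on-task trend (removed by detrending before spectral analysis), the
sinusoid is the infraslow oscillation the functional tests should localize,
and the noise SD drifts linearly over the 8 analysis blocks,
$\sigma_b = \sigma + c\,\mu\,(b - 4.5)$, so that in the Gaussian regime
($\tau = 0$, $\beta = 0$) the generative CoV slope per block is exactly the
parameter `cov_trend` $= c$. With $\tau > 0$ the exponential tail inflates
all blocks' SDs and *attenuates* the realized CoV slope
(by $\approx \sigma_b / \sqrt{\sigma_b^2 + \tau^2}$); recovery simulations
therefore use $\tau = 0$, and `cov_trend` should be read as the exact CoV
slope only in that regime.

Chosen constants, where no published value exists:

* **RT floor 100 ms** — a plausible minimum motor latency; sub-floor draws
  are resampled rather than clipped so the truncated distribution is proper.
* **Commission latencies** uniform on (100, 985) ms — they are recorded but
  never enter any RT series, so only their existence matters.
* **Default group parameters** (`group_spec()`): baseline RT
  $\mu \sim N(500, 50)$ ms, within-subject noise $\sigma \sim N(55, 10)$ ms,
  exponential tail $\tau \sim N(50, 20)$ ms, 5% misses, 1% commissions,
  age $\sim N(40, 12)$ truncated to [18, 65], balanced sex. These describe
  a healthy-adult CPT cohort of the kind the task is normed on; they were
  fixed once, before any acceptance outcome was observed.
* **Oscillation phase** is uniform per participant unless fixed: group
  effects of interest are on spectral *power*, which is phase-invariant.
* **Seeding**: a master seed spawns per-participant substreams through a
  fixed counter scheme, so cohorts are reproducible and participants'
  streams are independent of cohort size or order of generation. By default
  every participant sees one shared letter sequence, as with a fixed
  instrument.

What the simulator deliberately does **not** model: letter-identity
confusability, nonlinear practice or fatigue curves, response-hand effects,
non-stationary oscillation frequency. A green recovery test therefore
establishes that the pipeline recovers the *stated* generative structure,
not that real cohorts satisfy it.

## Response classification

RT in this task classically lives in (0, 985] ms; the window is extended to
**1135 ms** (985 + 150) so that very slow lapse responses landing within
the first 150 ms of the next trial still count as hits of the eliciting
target. The classification rules (`classify_responses()`):

* a target trial is a hit iff a response latency relative to the "K" onset
  falls in (0, 1135];
* a response recorded on a non-target trial at ≤ 150 ms is attributed to
  the immediately preceding target **iff** that target has no response of
  its own (the stated purpose of the extension is to catch late lapses);
  otherwise it is a commission;
* each physical response is attributed to at most one trial; with multiple
  candidate responses the first wins (the usual signal-detection
  convention);
* commission latencies never enter the RT series — only correct responses
  do.

Sessions with fewer than 60 hits of 100 targets are excluded: the spectral
stage needs as dense a series as possible. The filter boundary (60
retained, 59 excluded) is asserted in the acceptance tests.

## Vigilance decrement

Per retained participant, CoV = sample SD / mean of hit RTs in each of 8
blocks of 60 trials (n−1 denominator; blocks partition trials by index, so
per-block hit counts vary; blocks with < 3 hits emit no row — a stability
choice, the sources being silent). Block is mean-centered (block − 4.5) so
the group main effect is evaluated at the middle of the session.

The mixed model is
`cov ~ group * block_centered + age + sex + (block_centered | participant)`,
REML, dummy-coded against a reference group (default "HC"). Fitting
delegates to `lme4` — the model contract here is the formula, coding, df
method and contrast family, not a bespoke optimizer. A singular fit is
automatically refit with uncorrelated random effects and flagged;
non-convergence is an error, never silent output.

Because `lmerTest` is not among the package's allowed dependencies,
**Satterthwaite denominator degrees of freedom are implemented in-package**
(`R/satterthwaite.R`): the REML deviance is unprofiled in
$(\theta, \sigma)$, the variance-parameter covariance is
$A = 2H^{-1}$ with $H$ the deviance Hessian (via `numDeriv`), and for a
contrast $\ell$ with $v(\theta,\sigma) = \ell^\top V \ell$,
$\mathrm{df} = 2v^2 / (g^\top A g)$, $g = \partial v$. Multi-df F tests
decompose $L V L^\top$ by its eigenvectors and pool per-direction dfs
through the $\sum \nu_i/(\nu_i-2)$ rule. The test suite validates the
implementation against the classical closed-form dfs of a balanced
random-intercept design and against Monte-Carlo type-I error of the
omnibus tests. Pairwise group contrasts (intercepts at the centered block,
and slopes) use the studentized-range (Tukey) adjustment over the
$\binom{k}{2}$ family; marginal and conditional $R^2$ follow the
variance-partition definition with the random-effect contribution computed
as $\sigma^2\,\overline{\mathrm{diag}(Z\Lambda\Lambda^\top Z^\top)}$.

## Spectral analysis

Hit RTs are sampled at the uneven times of hit targets (the "K" onsets, a
choice we fixed — the original instrument's timestamp convention is not
documented). After removing the OLS line in time, the classical normalized
Lomb–Scargle periodogram is computed with the $\tau$-shifted formula; the
normalization by the sample variance gives expectation ≈ 1 under white
noise and peak height ≈ $nA^2/(4\sigma^2)$ for an injected sinusoid of
amplitude $A$.

The frequency grid is the standard data-driven construction: $1/T$ to the
pseudo-Nyquist $n/(2T)$ in steps of $1/(\mathrm{ofac}\,T)$, ofac = 1 by
default. With ~100 hits over ~473 s this spans ≈ 0.002–0.106 Hz — covering
the infraslow band — and yields ~47–50 grid points; the exact endpoints of
the heuristic the original analyses used are not recoverable, so only the
documented construction is matched.

Two independent code paths compute the same quantity: `lomb_scargle()`
(the $\tau$ formula) and `lomb_scargle_oracle()` (explicit least-squares
fit of $a\cos + b\sin$ and the variance-explained identity). They are
algebraically identical — the $\tau$ shift merely orthogonalizes the same
two-dimensional regression — and the suite requires agreement to $10^{-8}$
relative on random instances, plus equivalence with the FFT periodogram
under even sampling.

One consequence of variance normalization worth knowing: a participant with
a strong oscillation has *depressed* normalized power away from the
oscillation frequency (the oscillation inflates $\sigma^2$). In simulated
cohorts this can make the non-oscillating group nominally "stronger" at
remote frequencies. This is a property of the normalization convention, not
a bug; band summaries should be read at the detected band.

## Functional inference

Each periodogram is smoothed by least-squares projection onto a cubic
B-spline basis. The published description of this step ("46 basis functions
with 44 knots") is arithmetically inconsistent with standard B-spline
counting, where 44 equally spaced interior knots and order 4 give
44 + 4 = 48 functions; we treat the **interior knot count (44) as the
primary control** and derive the basis size, recording it in the output
metadata. With ~49 grid points the projection is nearly interpolating,
which matches the stated intent of preserving peaks. Participants with
fewer points than basis functions get an automatically reduced basis, with
a warning and a flag.

Curves are evaluated on **200 equally spaced frequencies over the
intersection** of participants' grid ranges (individual spans differ when
early/late targets are missed). At each frequency the model
`power ~ group + age + sex` is fit across participants; the group effect's
partial F (numerator df = k − 1) is compared against the central F quantile
at α = 0.05, and significant bands are maximal contiguous runs above it.
Note the numerator df choice: k − 1 = 3 for four groups, by construction —
no attempt is made to reproduce other published df bookkeeping.
Post-hoc pairwise t-tests are run *within* the detected band by default
(the published text supports either within-band or full-grid; a `band =
NULL` flag gives the full grid), on the two groups' data only, with both an
uncorrected and a Bonferroni critical line (family size default 6 = all
pairs of four groups; configurable since the original family is unstated).

These are *pointwise* tests: under the null about α of grid frequencies are
flagged, typically as scattered one- or two-point runs, and the suite
asserts exactly that. Band detection is therefore read as "a contiguous
band covering the frequency of interest", not "no false positives
anywhere". Cluster-mass or permutation-based functional inference is out of
scope (a permutation sanity check is in the tests).

## Numerical and degenerate-input policy

* Zero-variance series (constant, or exactly linear before detrending) are
  rejected by the normalized periodogram — power is undefined — while the
  raw-power oracle returns ~0.
* Frequencies where $\sum\cos^2$ or $\sum\sin^2$ underflow contribute their
  term as 0 (relevant only at the exact Nyquist of perfectly even grids).
* CoV blocks need ≥ 3 hits; sessions need ≥ 3 points to detrend, ≥ 2
  participants per group and ≥ 2 blocks per participant for the mixed
  model. All violations are errors or flagged reductions, never silent.
* Monte-Carlo acceptance tests run at reduced replicate counts relative to
  their reference descriptions (120/120/60 instead of 200/200/100) to fit
  the suite's runtime budget; thresholds are unchanged, so the Monte-Carlo
  error is honestly wider, not re-centered.

## Known limitations

* The simulator's stationary sinusoid is the simplest realization of an
  infraslow process; real attentional fluctuations are likely broadband and
  non-stationary, so real-data bands will be wider and less sharply peaked
  than simulated ones.
* Satterthwaite dfs at singular random-effects boundaries rely on a
  pseudo-inverse of an ill-conditioned Hessian and are flagged approximate.
* The accuracy filter couples with the spectral stage: retained series have
  60–100 points, and grid resolution (1/T) varies accordingly; the common
  evaluation grid handles range differences but not resolution differences.
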