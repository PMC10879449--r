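---
title: "Estimating within-dyad RSA synchrony: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating within-dyad RSA synchrony: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Respiratory sinus arrhythmia (RSA) — the respiration-linked oscillation in
heart period — indexes parasympathetic (vagal) influence on the heart.
During a dyadic interaction, one partner's second-to-second RSA fluctuations
may predict the other partner's fluctuations one second later. We call this
lagged within-dyad coupling *synchrony*: *parent-driven* when the parent's
fluctuation predicts the child's next-second fluctuation, *child-driven* for
the reverse direction, *positive* when the prediction is same-direction and
*negative* when it is opposite-direction.

`dyadRSA` implements the full chain from beat (R-peak) time series to
cohort-level synchrony tables, and — because raw dyadic ECG corpora are
rarely shareable — a synthetic-data generator with known ground truth at
every level, so that each stage is validated by recovery of quantities it
was told to encode.

## Signal chain

**Beats to IBI.** Interbeat intervals (IBI, ms) are first differences of
beat times. Automated artifact flagging replaces manual ECG editing: an
interval is suspect when it leaves the physiologic range (default
300–1500 ms) or jumps more than 25% from the preceding accepted interval.
Runs of one or two suspect intervals are repaired by linear interpolation
between accepted neighbours; runs of three or more are treated as missing —
data that would need that much consecutive correction are not trusted — and
their time span is recorded as a missing segment. The thresholds are
configurable; they are heuristics in the tradition of standard HRV artifact
screens, not clinical facts.

**4 Hz interpolation.** The cleaned IBI sequence is cubic-spline
interpolated onto a uniform 4 Hz grid (sample *k* at *k*/4 s, half-open task
interval). The spline bridges short gaps, but interpolated values spanning a
missing segment of 10 s or longer (boundary inclusive) are masked: an
imputation stretching that far carries too little information. The masked
samples keep their grid positions so downstream bookkeeping stays exact.

**Sliding-window multitaper RSA.** For every integer second *t* a 32-s
window of samples in [*t*−16, *t*+16) is mean-detrended, multiplied by each
taper of an orthonormal bank, and the eigenspectra are averaged; integrating
the one-sided spectral density over the respiration band gives the band
power (ms²) assigned to the window's central second. RSA is the natural log
of that power, floored at a small positive constant so silent windows stay
finite. Bands: adults 0.12–0.40 Hz; children use an age-keyed configurable
table (default 0.15–0.66 Hz for ages 6–11 — a documented implementation
default, not a literature citation). A second is reported invalid whenever
any sample in the closed window [*t*−16, *t*+16] is invalid, which
propagates a masked segment exactly 16 s in each direction; estimates exist
only for *t* in [16, duration−16].

The taper bank is pluggable. Peak-matched multiple-window families are used
by some RSA toolboxes, but their construction details vary; the default
here is the DPSS (Slepian) family — time-bandwidth NW = 2, K = 3 tapers,
spectral half-bandwidth 2/32 Hz — computed from the standard tridiagonal
eigenproblem, with sine tapers as an alternative. What the package promises
is calibrated recovery of band power (a 40 ms sinusoidal modulation at
0.25 Hz must come back as ≈ 40²/2 = 800 ms²), not bit-exact agreement with
any particular toolbox.

**Stationarity screen.** Lag-1 dynamic models assume stationary series.
Each participant's RSA series is tested with the augmented Dickey-Fuller
regression at one augmentation lag, in both the single-mean and the trend
specification, on the longest contiguous valid run (the regression needs
contiguity). P-values and finite-sample critical values come from
MacKinnon's response-surface approximations. A series "meets stationarity"
if the unit root is rejected in at least one specification (the lenient,
disjunctive reading — a deliberate choice, since a single per-dyad verdict
from two models requires some combination rule), at alpha = 0.05. The
screen is advisory: flagged dyads are retained and the flag travels with
the outputs, because the dynamic model's own admissibility safeguard
(below) handles mild violations.

## The dyadic dynamic model

For the per-second RSA pair \(y_t = (p_t, c_t)'\):

\[
y_t - \mu = B\,(y_{t-1} - \mu) + \epsilon_t,\qquad
\epsilon_t \sim N(0, \Sigma),\qquad
B = \begin{pmatrix}\phi_p & \beta_{c\to p}\\ \beta_{p\to c} & \phi_c\end{pmatrix}.
\]

The means are *latent*: \(\mu\) is sampled jointly with the dynamics rather
than subtracted as an observed average, so lagged effects act on
within-person deviations without the bias that pre-centering introduces.
The first valid observation pair is conditioned on (fixed), matching the
standard conditional-likelihood treatment of lag-1 models.

Estimation is a Gibbs sampler with conditionally conjugate blocks:

* means — normal full conditional (prior \(N(0, 10^6)\) per component);
* dynamic coefficients — joint normal full conditional over the four
  entries of \(B\) (same diffuse prior);
* innovation covariance — inverse-Wishart full conditional (prior: identity
  scale, 3 degrees of freedom);
* interior missing seconds — normal full conditionals given the adjacent
  seconds (data augmentation), so missingness costs information rather than
  lag pairs.

The priors approximate "software defaults" of commercial DSEM estimators,
whose internals are not published; at these scales they are effectively
uninformative, and the conjugate-reduction test (dynamics fixed at zero)
verifies the sampler against closed-form posterior moments.

Two chains start from dispersed values (means offset by ±1 SD, innovation
variances 1× and 4× the sample variance). Every 500 iterations — after a
1000-iteration minimum chosen so that the pooled posterior holds at least
2000 draws and the 2.5%/97.5% quantiles are stable — the Gelman–Rubin
potential scale reduction factor is computed per parameter from the second
half of each chain (floored at 1); sampling stops early when all fall below
1.05, else at the configured cap with a non-convergence flag that travels
with the output.

**Admissibility safeguard.** Draws whose dynamics are explosive (spectral
radius ≥ 1) or whose *standardized* coefficients exceed 1 in magnitude are
removed from the summarized posterior and counted in `discarded_fraction`.
Standardization multiplies \(B_{ij}\) by the ratio of the implied stationary
standard deviations (predictor over outcome), obtained from the draw's own
discrete Lyapunov solution — the natural reading of "standardized
autoregressive coefficient" for a bivariate lag-1 system. On stationary
data the discard fraction is far below 1%.

**Classification.** Posterior summaries are medians with 95% equal-tailed
credible intervals over pooled post-burn-in draws (burn-in fraction 0.5).
Per direction: interval entirely above zero → positive synchrony, entirely
below → negative, containing zero (endpoints inclusive) → null.

## Cohort summaries

Analyzable Ns count dyads with usable data per task and in both tasks.
Category percentages use per-task denominators and round half away from
zero to one decimal (the rule that reproduces printed values such as
9/26 → 34.6%). Cross-task agreement per category (e.g. "child-driven
positive present?") is Cohen's kappa over dyads analyzable in both tasks,
with the large-sample normal approximation under independence for the
p-value; degenerate margins yield a flagged `NA` cell rather than an error.

## What the generator emulates — and what it does not

Ground truth is defined at the RSA level, not the ECG-voltage level. A
target per-second RSA trajectory (itself drawn from the lag-1 model, with
the initial state from the stationary distribution and Gaussian
innovations matching the fitted likelihood) is rendered as beat times by
modulating a base heart period with a respiration-frequency sinusoid of
amplitude \(A(t) = \sqrt{2\,e^{\mathrm{rsa}(t)}}\) — a sinusoid of amplitude
A has power A²/2, so local band power equals the target exactly. Artifact
corruption displaces runs of beats at a Poisson rate and deletes beats in
dropout segments, with the truth map returned for masking tests. Cohort
defaults — one ectopic event per minute in runs of 1–3 beats, and a 20%
chance per record of a single 10–18 s dropout — were chosen once to give
per-record RSA missingness from zero to a few tens of percent with a
low-single-digit mean, the range typical of task ECG in young samples;
short ectopic runs are repaired by the cleaning stage, so masked RSA comes
almost entirely from the dropouts. Cohort
assembly draws per-dyad levels, autoregression, respiratory frequencies and
base heart periods from plausible ranges (children breathe faster and have
shorter heart periods), and assigns synchrony regimes per direction from
configurable proportions; non-null cross-lags default to ±0.3, a magnitude
chosen once for detectability at T ≈ 300 s of 1 Hz data.

Not emulated: ECG waveforms, respiration signals, slow non-stationarity of
real interactions, within-task regime changes, or measurement coupling
between partners (e.g. shared movement artifact). Passing tests therefore
show that the pipeline recovers what it is specified to recover — not that
real parent–child data carry effects of this size.

## A limitation worth stating plainly

The 32-s spectral window is two orders of magnitude longer than the lag the
dynamic model targets. Adjacent-second RSA estimates share 31.75 s of data,
so pipeline-estimated series are far smoother (lag-1 autocorrelation ≈ 0.99)
than the second-scale generating process, and cross-lags fitted to them are
strongly attenuated relative to the generator's coefficients. This is a
property of every moving-window spectral RSA estimator, not of this
implementation. Consequently the parameter-recovery validation runs on
directly simulated RSA series, where ground truth lives on the modelled
scale; the end-to-end cohort run demonstrates plumbing, bookkeeping and
classification, and mostly produces null calls at the default effect size.

The smoothing has a second visible consequence: estimated-RSA series sit
close to the unit root, so the stationarity screen flags a sizable minority
of them, and the admissibility safeguard discards a large share of draws in
those fits (autoregression mass beyond the boundary) — whereas on directly
simulated stationary series the discard fraction is essentially zero. Both
numbers are reported per fit rather than hidden, and the screen remains
advisory.

## Validation problem sizes

The packaged validation studies use: cross-lag grid {−0.3, 0, +0.3} × 67
replicates (bias and 402 coverage events), 300 null-coupling replicates
(600 false-non-null events), T = 300 s per dyad, chains stopped by the
PSR rule with a 1000-iteration minimum — chain lengths scaled down from the
100,000-iteration production cap, which the sampler never needs on these
data; and 2000 random walks of length 300 for the ADF size study. All
random quantities derive from a single master seed.
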