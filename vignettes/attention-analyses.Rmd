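---
title: "Auditory attention analyses for around-the-ear EEG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditory attention analyses for around-the-ear EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(earaad)
```

`earaad` implements three complementary analyses of selective auditory
attention for multichannel ear-EEG recorded while a listener attends one of
two simultaneously presented speech streams, plus a synthetic cohort
generator that provides a fully controlled stand-in for such recordings.
This vignette explains each model, the parameters that matter, the numerical
choices, and what the synthetic data do and do not establish about real
recordings.

## The three attention measures

**Envelope-reconstruction decoding (backward model).** Cortical activity
tracks the slow amplitude envelope of attended speech more strongly than
that of ignored speech. A linear decoder maps time-lagged multichannel EEG
to the attended envelope: the envelope at time $t$ is predicted from EEG
samples at $t+\tau$ for integer lags $\tau$ spanning a short window
(positive $\tau$: the neural response lags the stimulus). With $X$ the
lagged design matrix (bias column appended) and $y$ the attended envelope,
the decoder solves

$$ w = (X^\top X + \lambda M)^{-1} X^\top y, $$

where $M$ is a banded second-difference penalty applied within each
channel's block of lag coefficients (no cross-channel coupling, bias
unpenalized), encouraging temporally smooth decoders. Reconstruction
quality is scored per 60-s segment by the Pearson correlations of the
prediction with the attended and the ignored envelope; their difference
$\mathrm{Corr}_{att}-\mathrm{Corr}_{ign}$ is the *attentional gain*, and a
segment counts as correctly classified iff the gain is strictly positive.
Decoding accuracy over leave-one-out segments is compared against the exact
binomial threshold (for 30 segments at $\alpha=0.05$: $20/30 \approx 66.7\%$).

The hyperparameters are the lag window — 47 windows of 45 ms, starting at
$-115, -100, \dots, 575$ ms — and the regularization weight
$\lambda \in \{10^{-5},\dots,10^{5}\}$, i.e. 517 grid cells. Group-level
selection takes the cell with the best grand-average accuracy (ties: lowest
grand-average MSE, then earliest grid order); individual selection applies
the same rule per subject. Because selecting hyperparameters on the same
folds that measure accuracy is optimistically biased, `nested_cv_accuracy()`
additionally holds out validation segments per repetition, selects on inner
leave-one-out folds only, and averages validation accuracy over repetitions.

**Intersubject correlation via correlated component analysis (CorrCA).**
Listeners attending the same stream exhibit correlated stimulus-locked EEG.
CorrCA finds projections $w$ maximizing between-subject over within-subject
covariance through the generalized eigenproblem $R_b w = \rho \tilde R_w w$,
with $R_b=\sum_{k\neq l}R_{kl}$, $R_w=\sum_k R_{kk}$ and
$\tilde R_w = (1-\gamma) R_w + \gamma\,(\mathrm{tr}\,R_w/D)\, I$. The
shrinkage $\gamma=0.01$ guarantees invertibility with 16 channels;
rank-truncation of $R_w$ is available as the alternative
(`rank_truncate = TRUE`). Components equal channels in number; per-subject
ISC against a group $G$ uses the symmetric ratio

$$ \rho_{k,c} = \frac{w_c^\top \big(\tfrac{1}{|G|}\sum_{l\in G}
   \tfrac{R_{kl}+R_{lk}}{2}\big) w_c}{w_c^\top \big(\tfrac{R_{kk} +
   \frac{1}{|G|}\sum_{l\in G} R_{ll}}{2}\big) w_c}, $$

which equals 1 when subject and group are identical. This normalization is a
convention (reference implementations differ in detail); it is symmetric in
the cross-covariances and correctly bounded in the degenerate cases. The
*ISC sum score* adds the three most correlated components; the projection
basis always excludes the scored subject (leave-one-subject-out). Chance
levels come from circular-shift surrogates: each subject's multichannel data
are rotated by an independent uniform offset in $[1, T-1]$ (all channels
equally, preserving within-subject structure), the full analysis is re-run
100 times, and the 95th percentiles serve as chance. Attended-direction
classification scores each subject's ISC sum against the left-attending and
right-attending groups separately and reports the ROC AUC, with chance from
1000 label permutations pooled over both classifications (the pooled
distribution matches reporting a single chance value). Spatial filters are
converted to interpretable patterns via $A = R_w W (W^\top R_w W)^{-1}$,
sign-fixed so the largest-magnitude entry of each pattern is positive (sign
is inherently ambiguous).

**Multitaper spectral entropy.** Vigilance decrements over time-on-task
express themselves as growing alpha (8–12 Hz) power, which concentrates the
8–32 Hz spectrum and lowers its normalized Shannon entropy
$H = \frac{1}{\log N}\sum_f p_f \log (1/p_f)$, with $p$ the multitaper PSD
restricted to 8–32 Hz (inclusive band edges on the native FFT grid, no
zero padding) and normalized to unit sum. Seven Slepian tapers are used;
the time-bandwidth product NW = 4 follows from $k = 2\,\mathrm{NW}-1$. The
natural logarithm is used (normalization cancels the base). Entropy and the
alpha fraction are computed per 60-s segment and channel, averaged over
non-flagged channels (a channel flagged once is excluded from all
segments), and their Spearman rank correlations against the segment index
quantify the time-on-task trends.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analyses assume:

* two independent speech-like envelopes (rectified 5 Hz-low-passed Gaussian
  noise; ≥ 95% of power below 8 Hz);
* per-subject EEG = $g_{att}\,(k \ast e_{att}) + g_{ign}\,(k \ast e_{ign})$
  through fixed cohort-level topographies, where $k$ is a
  difference-of-Gammas kernel peaking near 120 ms — inside the 95–140 ms
  group window the decoding stage should recover;
* a stimulus-locked component, shared by subjects attending the same
  stream, driven by the attended envelope through a second kernel with the
  same ~120–130 ms peak region (so all stimulus-locked energy is consistent
  with one response latency);
* 1/f background noise that is ~70% spatially shared through a
  positive-dominant mixing matrix and ~30% channel-independent — real
  referenced EEG channels correlate positively through volume conduction
  and the common reference, and the bad-channel detector relies on this;
* a 10 Hz oscillation whose amplitude grows linearly (`alpha_drift` per
  minute), driving the entropy/alpha trends;
* optional high-amplitude broadband bursts (smooth onsets, Poisson times,
  random channel subsets) for exercising artifact correction.

Defaults: 8 subjects (4 attending left), 30 min in three 10-min blocks,
16 channels at 250 Hz (a typical mobile-EEG rate that also serves the
250 Hz ISC stage directly), `gain_att = 3`, `gain_ign = 1`,
`shared_component_gain = 2`, `noise_sd = 1`, `alpha_drift = 0.04`/min,
bursts off. The gains were calibrated once against the generator's own
contracts — the attended stream must be identifiable from direct
lag-kernel cross-correlation (no decoder) in ≥ 90% of segments, and
same-stream pairs must correlate more than different-stream pairs — and
frozen; per-channel response amplitudes are roughly a third of the noise
SD, i.e. weak single-channel SNR that requires genuine spatial integration,
as in real EEG. Response topographies carry a positive common-polarity
component (evoked responses share polarity across a referenced montage),
which is also what lets the shared signal survive channel averaging.
Per-subject seeds derive deterministically from the cohort seed; every
generator is a pure function of its seeds.

What passing on this cohort does **not** show: robustness to real artifact
diversity (eye blinks, chewing, electrode drift have structure bursts lack),
to nonstationary attention switching, to inter-subject latency differences
(all subjects share one kernel), or to the much lower ISC magnitudes of real
ear-EEG. The generator is a correctness harness, not a realism claim.

## Preprocessing choices

* All filters are applied zero-phase (forward–backward); the upstream
  convention in this literature is zero-phase filtering, and the effective
  magnitude response is the square of the one-pass response (documented;
  single-pass behaviour is not offered). FIR (Hann window) filters are
  applied via exact FFT convolution with the autocorrelated kernel; edges
  are implicitly zero-padded.
* Decoding path: 0.5 Hz drift-removal highpass (4th-order Butterworth,
  zero-phase — the equivalent of a 0.25–0.75 Hz transition-band FIR) →
  ASR → 8 Hz FIR lowpass (order 100) → 2 Hz FIR highpass (order 500) →
  per-channel SD normalization → 64 Hz. Normalizing per channel (rather
  than by one global SD) preserves relative channel scaling for the spatial
  decoder; the audio normalization ("divide by the SD") is a single scalar
  because audio is one channel.
* ISC path: drift highpass → ASR → 40 Hz lowpass (order 100) → 1 Hz
  highpass (order 500) → 250 Hz, first 10-min block only (pipeline default,
  configurable).
* Downsampling is exact Fourier-domain truncation (ideal brick-wall
  anti-aliasing, output length exactly `round(n * target/current)`); it
  preserves constants and pure tones to numerical precision.
* Envelope extraction follows the exact order: divide by SD → modulus of
  the analytic signal → 8 Hz Butterworth order 3 (zero-phase) → 64 Hz.
* A constant acquisition latency is modelled as a single signed sample
  shift (`shift_latency()`, default 0 for synthetic data); beep-tone ERP
  calibration of that latency is out of scope.
* Bad-channel flagging correlates each channel, in 5-s windows, with the
  per-sample median of the other channels (for > 8 channels the all-channel
  median is used as the robust estimate — the difference is negligible at
  that montage size) and flags channels whose median windowed correlation
  falls below 0.6.

## ASR

Calibration selects 1-s windows whose per-channel RMS z-scores (robust:
median/MAD) lie within $[-3.5, 5.5]$ for ≥ 92.5% of channels, then stores
the calibration covariance, its principal square root $M$ (mixing matrix),
and per-component RMS thresholds $\mu + k\sigma$ over 0.5-s sub-windows,
with the liberal cutoff $k = 10$. Correction slides half-overlapping 0.5-s
windows, eigendecomposes each window covariance, rejects components whose
variance exceeds the calibration threshold projected into the window's
eigenbasis, and reconstructs them from the retained subspace via $M$;
windows are blended with raised-cosine weights so the output stays
continuous (no samples are removed). A window in which no component exceeds
threshold is copied through unchanged, and a recording in which no window is
modified is returned bit-identically — hence an infinite cutoff is exactly
the identity. Fidelity to any particular plugin's internals is not claimed;
the behavioural contracts (clean data essentially untouched, in-burst RMS
strongly attenuated, near-idempotence) define correctness here.

## Numerical choices and degenerate inputs

* ms→sample lag conversion rounds half away from zero; at 64 Hz a 45-ms
  window spans 3–4 taps, an accepted consequence of the native grid.
* The stated second-difference penalty (diag $[1,2,\dots,2,1]$, $-1$ on the
  first off-diagonals, per channel block) is a graph Laplacian: its null
  space is the constant lag profile within each channel. Heavy
  regularization therefore shrinks decoders *onto* that null space rather
  than to zero — the package keeps the matrix as defined (an identity
  penalty is available via `penalty = "identity"`) and documents the
  consequence. With $\lambda = 0$ a singular system falls back to the
  least-squares pseudo-inverse with a warning.
* A constant prediction has no defined correlation: the segment scores gain
  0, is flagged, and counts as incorrect (strict positive-gain rule).
* Exact label-swap antisymmetry (accuracy $a \to 1-a$) holds at the scoring
  level (same decoder, streams relabelled); retraining on the swapped
  target performs at mirror level but is not an exact reflection.
* Slepian tapers are computed from the classical symmetric tridiagonal
  eigenproblem by Sturm-count bisection plus shifted inverse iteration
  ($O(kN)$, cached per length), validated against a dense eigendecomposition
  at small lengths; minute-long 250 Hz segments are thus exact, not
  interpolated.
* Wilcoxon signed-rank comparisons drop zero differences, use the exact
  signed-rank distribution for $n \le 25$ without ties and the normal
  approximation (no continuity correction — the choice is documented, the
  reference leaves it unstated) otherwise; Spearman p-values use the
  t-approximation with average ranks for ties.
* CorrCA input covariances are symmetrized to machine precision before the
  Cholesky-based generalized eigensolve; eigenvalue order breaks component
  ties, and component signs are fixed via the pattern's largest entry.
* Circular shifts are drawn uniformly on $[1, T-1]$ with no minimum offset
  (unstated in the protocol; a zero shift is excluded by construction).

## Pipeline and problem sizes

`run_pipeline()` chains generation → preprocessing → grid decoding
(group/individual, standard and nested CV) → ISC (observed, circular-shift
null, direction classification) → entropy → cross-measure Spearman
correlations, writing CSVs and a `summary.json`. Every stochastic stage
draws its seed deterministically from the single config seed, so identical
config+seed gives byte-identical outputs. Nested cross-validation defaults
to 10 repetitions of 10 validation segments in the shipped configuration —
the selection-bias direction stabilizes well before the 50 repetitions one
would use in a full study. The determinism check runs a reduced cohort
(6 subjects, 12 min, 2 nested repetitions): bit-reproducibility is
independent of problem size. The test suite exercises the full default
conditions (8 subjects × 30 min) for the parameter-recovery, ISC and
entropy claims.

## Known limitations

* The generator shares one response kernel across subjects; individual
  hyperparameter selection can therefore not be *expected* to beat group
  selection on synthetic data (on the real phenomenon it does under
  standard CV), only the bias direction of nested vs standard CV is
  asserted.
* ISC magnitudes on the synthetic cohort are far above real ear-EEG values;
  only orderings (same > other, observed > chance, AUC > chance) transfer.
* ASR is implemented at the algorithmic level; numerical equivalence with
  any specific plugin version is out of scope.
* EDF/WAV I/O is not provided; recordings and envelopes are exchanged as
  CSV with a JSON manifest (`write_cohort()`/`read_cohort()`).
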