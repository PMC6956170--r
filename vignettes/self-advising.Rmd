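---
title: "Self-advising SVMs for myoelectric pattern recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-advising SVMs for myoelectric pattern recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsasvm)
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the parameters that matter, the
numerical and design decisions that were genuinely open, and what the
synthetic-data tests do and do not demonstrate.

## The model

A kernel SVM trained on $(x_i, y_i)$, $i = 1,\dots,N$ classifies by
$f(x) = \operatorname{sign}(h(x))$ with
$h(x) = \sum_{\alpha_i > 0} y_i \alpha_i k(x, x_i) + b$. The package
delegates the quadratic program to libsvm (through **e1071**) but owns
the model representation: support vectors, signed dual coefficients
$y_i\alpha_i$ and bias are stored per class pair, and training verifies
that decision values recomputed from the stored record agree with the
solver's to $10^{-6}$. This reconstruction contract is what makes the
solver interchangeable and the JSON model files self-contained.

**Self-advising (feature space).** After training, the misclassified
set $MD = \{ i : y_i \ne f(x_i) \}$ is extracted. Each $x_i \in MD$
gets a neighborhood length $NL(x_i)$: the kernel-induced distance
$d(u,v) = (k(u,u) + k(v,v) - 2k(u,v))^{1/2}$ to the nearest *correctly
classified* training point of a *different* label. $NL$ bounds the
region in which $x_i$'s true label is better evidence than the
boundary. A test point $x$ receives an advised weight
$AW(x) \in [0,1]$, the mean of $1 - d(x, x_i)/NL(x_i)$ over the MD
points whose neighborhood contains $x$ (zero if none). Its absolute
decision value is scaled into $[0,1]$ by the test batch's maximum. If
$AW < $ the scaled decision value the SVM label stands; otherwise the
point takes the true label of the nearest qualifying MD point.

**Label self-advising.** The LSA variant computes the same quantities
on *encoded labels*: signed binary ($-1/+1$) for two classes, one-hot
otherwise, with either plain Euclidean distance or an RBF kernel on the
encodings. Because only $L$ distinct labels exist, the advising pass
needs one distance per (class, MD point) pair rather than one per
(test point, MD point) pair — the pass is independent of the feature
dimension and of the test-set size.

The implicit assumption of both layers is that misclassified training
points are *informative* rather than pure noise: that test points
resembling them (in feature or label geometry) are at risk of the same
error. Advising is a post-processing step; the margin optimization is
never re-run, and no extra hyperparameters are introduced beyond the
base SVM's.

## Interpretation decisions

Several parts of the advising rules were genuinely open and were fixed
as follows.

- **Advised-weight normalization.** The weight is the *mean* of
  $1 - d/NL$ over qualifying MD points. This form is bounded in
  $[0,1]$, reduces to the required zero branches (empty MD, no
  qualifying point), and equals $1$ exactly when the test point
  coincides with a lone qualifying MD point. The choice is recorded in
  every advised model as `normalization = "mean"`.
- **Tie at $AW = $ scaled decision value.** The SVM branch is guarded
  by a strict "<", so equality routes to the relabel branch. This
  matters in practice: a batch always contains a point whose scaled
  value is exactly 1.
- **The test label in label space.** Label-space advising needs a label
  for the test point before one has been assigned. The base SVM's
  prediction is the only label available pre-advising, so it stands in.
- **Relabel target in label space.** For two classes label distance is
  degenerate (0 or 2), so the relabeling target among qualifying MD
  points is chosen by *feature-space* proximity; ties break toward the
  smallest MD index.
- **Multiclass decision-value proxy.** The binary rules are defined for
  a signed $h$. With one-vs-one voting the package uses the vote
  winner's minimal pairwise $|h|$ as the confidence proxy; with two
  classes this is exactly $|h|$, so the binary rule is recovered.
  Vote ties break toward the earliest class in class order.
- **MD points without contrast.** An MD point with no correctly
  classified opposite-label neighbor has no defined $NL$; it is flagged
  and excluded from advising rather than given an arbitrary radius.
- **Per-batch scaling.** Decision values are scaled within each test
  batch. A single-point batch therefore always scales to 1; the
  documentation of `scale_decision_values()` carries this caveat.

## Numerical choices

- The induced-distance radicand is clamped at 0 before the square root;
  scalar and matrix code paths share one implementation so that
  brute-force oracles and vectorized computations agree bitwise.
- Model JSON is written with 17 significant digits, the minimum that
  round-trips IEEE doubles exactly; reloaded models reproduce decision
  values bit-for-bit.
- Zero decision batches scale to zero (no 0/0), empty batches stay
  empty.
- For exact pairwise vote ties ($h = 0$) and majority-vote ties the
  earliest class in sorted class order wins, making predictions
  deterministic.

## The signal pipeline

Defaults follow common sEMG practice: a 4th-order zero-phase
Butterworth band-pass at 25–550 Hz (drift and out-of-band noise), a
zero-phase biquad notch at 50 Hz with quality factor 30 (mains line;
the bandwidth is $50/30 \approx 1.7$ Hz), and polyphase resampling from
the 2000 Hz acquisition rate to 1000 Hz with a zero-phase low-pass
guard at 90% of the target Nyquist when downsampling. 1000 Hz is the
default working rate; any other target (e.g. 1080 Hz) is a parameter.
Filter family and order are conventional choices, configurable per
call; only the band edges are structural.

Window sizes and increments are specified in *samples* (50/15 at
1000 Hz ≙ 50 ms windows hopped by 15 ms). A window's label is the
majority of its per-sample annotations, ties resolving to the earlier
label in sorted class order, and majority-rest windows are dropped —
labeling rules the continuous protocol requires but does not itself
dictate.

Time-domain features use the standard definitions; the zero-crossing
and slope-sign-change thresholds default to 1% of the window's RMS
(adaptive, so amplitude scaling does not change the counts). The
integer feature-set codes (11, 13, 14) are a provisional configuration
mapping kept in one place (`feature_code_set()`): 11 = {MAV, WL, ZC},
13 = {MAV, RMS, WL, ZC}, 14 = {MAV, RMS, WL, ZC, SSC}.

The default hyperparameter grid spans $2^{-9},\dots,2^{10}$ for both
$C$ and $\gamma$ (400 combinations); the ν grid is $0.05,\dots,0.5$ in
steps of 0.05, since ν is only meaningful below the class-balance
bound. Grid ties break toward the smaller penalty, then the smaller
$\gamma$ — the least complex model among equals. The fold-sizing helper
uses 3-fold cross-validation above $n = 1000$ and 5-fold otherwise.
$\gamma$ is never defaulted from the data dimension silently; every
model record carries its explicit value.

## What the generators emulate — and what they do not

`make_semg()` models muscle activity as envelope-modulated Gaussian
noise: per trial, a class-specific gain per channel shapes a 3 s burst
(0.25 s raised-cosine ramps) on top of baseline noise, plus a 50 Hz
sinusoid. This exercises every pipeline stage — filtering has real work
to do, windows straddle activity boundaries, features separate classes
through channel-power patterns. It does *not* model motor-unit
physiology, electrode shift, crosstalk, fatigue, or inter-subject
variability; a high cross-validated accuracy here demonstrates that the
pipeline is correct and that the classifiers separate
envelope-distinguishable classes, not that comparable accuracy would be
reached on clinical recordings.

`make_planted_fixture()` constructs the adversarial case the advising
layers exist for: three label-flipped training points inside the
opposite cluster (guaranteed members of MD) and three low-confidence
test probes beside them whose true labels match the planted points. The
generator *verifies* its own guarantees by fitting the base SVM and
running the advising pass, retrying with a derived sub-seed up to ten
times — so downstream tests exercise the intended branch or fail
loudly, never silently test the wrong one.

Problem sizes throughout the test-suite and acceptance script are desk
scale by design: blobs of 50–100 points, 50-sample oracle instances,
two repetitions of the four-class trial protocol (64 s of signal,
~1600 windows). These sizes are where brute-force oracles are exact and
the full suite stays fast, and every property asserted is
size-independent.

## Known limitations

- For two-class problems the label-space geometry is almost entirely
  degenerate ($NL \equiv 2$, every MD point qualifies), so LSA-SVM's
  weight reduces to the fraction of MD sharing the predicted label; its
  behaviour can only differ from SA-SVM through that coarser signal.
- Advising assumes MD points carry signal; on data whose
  misclassifications are pure label noise the override can hurt, which
  is why the planted fixture (informative MD) and the noisy-blob
  fixtures (noise MD) are both part of the test suite.
- The advising layers are non-iterative by design: one extraction, one
  pass, no re-advising.
- Single-point prediction with an advised model scales its own decision
  value to 1, making an override impossible; advising is intended for
  batch prediction.
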