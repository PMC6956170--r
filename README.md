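# lsasvm

Self-advised and label self-advised support vector machines for
myoelectric pattern recognition, with the full offline surface-EMG
(sEMG) pipeline around them.

## The problem

Surface EMG classifiers for rehabilitation devices (e.g. foot-drop
support after stroke) must map short windows of multichannel muscle
activity onto intended movements. A standard kernel SVM discards a
useful signal: the training points it *fails* to fit. Points that are
misclassified at training time mark regions where the decision boundary
is unreliable, and test points that resemble them tend to be
misclassified the same way.

The **self-advised SVM (SA-SVM)** mines this misclassified set (MD)
after ordinary training. For a trained decision function

$$h(x) = \sum_{\alpha_i > 0} y_i \alpha_i\, k(x, x_i) + b,\qquad
  f(x) = \operatorname{sign}(h(x)),$$

each misclassified training point $x_i \in MD$ receives a
**neighborhood length**

$$NL(x_i) = \min_j \{\, d(x_i, x_j) : j \notin MD,\ y_j \ne y_i \,\},$$

the kernel-induced distance
$d(u,v) = \sqrt{k(u,u) + k(v,v) - 2k(u,v)}$ to the nearest correctly
classified point of a different label. At test time every point gets an
**advised weight** — the mean of $1 - d(x, x_i)/NL(x_i)$ over the MD
points whose neighborhood contains it, a score in $[0,1]$ of how deep it
sits inside misclassified territory. If the advised weight reaches the
test point's scaled absolute decision value, the SVM label is overridden
with the true label of the nearest qualifying MD point.

The **label self-advised SVM (LSA-SVM)** moves the advising geometry
from feature space to *label space*: class labels are numerically
encoded (signed binary for two classes, one-hot otherwise) and both the
neighborhood lengths and the advised weights are computed on encoded
labels, using plain Euclidean distance or an RBF on labels. The advising
pass then costs one distance per (class, MD point) pair instead of one
per (test point, MD point) pair.

Around the classifiers the package ships the full offline pipeline:
band-pass (25–550 Hz) and 50 Hz notch filtering, polyphase resampling
to 1000 Hz, sliding-window segmentation, classical time-domain features
(MAV, RMS, waveform length, zero crossings, slope-sign changes, VAR,
IEMG, log detector), stratified cross-validated benchmarking of the six
classifiers (c-/ν-SVM and their SA/LSA variants), synthetic generators
for every stage, JSON model persistence and a command-line interface.

## Worked example

Four movement classes, four channels, the movement-trial protocol (3 s
activity, 5 s rest per trial, 50 Hz line interference), through the
whole pipeline:

```r
library(lsasvm)

rec <- make_semg(reps = 2, seed = 1)
rec
#> <signal_recording: 4 channel(s) x 128000 samples @ 2000 Hz (64 s), annotated>

rec <- resample_recording(notch_filter(bandpass_filter(rec)), 1000)
seg <- segment_windows(rec, window_spec(50, 15))
feats <- extract_features(seg$windows, seg$labels, feature_code_set(14),
                          channel_names = rec$channel_names)
feats
#> <labeled_dataset: 1601 samples x 20 features, 4 classes (dorsiflexion,
#>  knee_extension, knee_flexion, plantarflexion)>

benchmark(feats, c("v-svm", "v-sa-svm", "v-lsa-svm"),
          kernel = rbf_kernel(0.05), nu = 0.1, k = 3, seed = 1,
          standardize = TRUE)[, 1:4]
#>   classifier mean_accuracy sensitivity specificity
#> 1      v-svm        0.9800      0.9800      0.9933
#> 2   v-sa-svm        0.9850      0.9850      0.9950
#> 3  v-lsa-svm        0.9775      0.9775      0.9925
```

Accuracy is the 3-fold cross-validated fraction of windows labeled with
the correct movement; sensitivity/specificity are macro-averaged
one-vs-rest rates over the pooled out-of-fold predictions.

The advising mechanism itself is easiest to see on the planted fixture,
which label-flips three training points inside the opposite cluster and
places three low-confidence test probes next to them:

```r
fx <- make_planted_fixture(seed = 1)
base <- train_svm(fx$train, "c", rbf_kernel(0.5), cost = 1)
adv  <- self_advise(base, fx$train)
adv
#> <advised_fit: feature-space advising (mean normalization), |MD| = 3>
#> <svm_fit: c-SVM, rbf kernel (gamma = 0.5), C = 1, 2 classes, 1 pair machine(s)>

accuracy(fx$test$y, predict(base, fx$test$X))  # 0.9302
accuracy(fx$test$y, predict(adv,  fx$test$X))  # 0.9767
```

The three planted probes are misclassified by the base SVM and corrected
by the advising layer.

A command-line wrapper is installed as `exec/lsasvm`
(`simulate | preprocess | features | train | predict | benchmark`); run
it with `--help` for the flag reference.

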