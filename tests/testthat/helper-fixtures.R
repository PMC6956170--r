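# Shared fixtures, built in code at test time.

# Two well-separated Gaussian blobs; an SVM with moderate C fits them
# perfectly, so the misclassified set is empty.
separable_blobs <- function(seed = 1L, n = 30L) {
  make_blobs(n_per_class = n, n_classes = 2L, dim = 2L, spread = 0.5,
             seed = seed)
}

# Overlapping blobs with label noise: guarantees a nonempty
# misclassified set under a moderate-C RBF fit.
noisy_blobs <- function(seed = 7L, n = 40L) {
  make_blobs(n_per_class = n, n_classes = 2L, dim = 2L, spread = 1.4,
             label_noise = 0.1, seed = seed)
}

fit_noisy_advised <- function(seed = 7L, space = c("feature", "label")) {
  space <- match.arg(space)
  ds <- noisy_blobs(seed)
  base <- train_svm(ds, "c", rbf_kernel(0.5), cost = 1)
  adv <- if (space == "feature") self_advise(base, ds) else
    label_self_advise(base, ds)
  list(ds = ds, base = base, adv = adv)
}

# Minimal hand-built misclassified set (neighborhood_lengths and the
# weight functions only read these fields).
manual_md <- function(points, labels, indices = seq_len(nrow(points)),
                      nl = rep(NA_real_, nrow(points))) {
  structure(list(indices = indices, points = as.matrix(points),
                 labels = as.character(labels), nl = nl),
            class = "misclassified_set")
}

manual_advised <- function(kernel, md, space = "feature") {
  structure(list(base = list(kernel = kernel), md = md, space = space,
                 normalization = "mean"),
            class = "advised_fit")
}

# Single-channel recording holding a pure tone.
tone_recording <- function(freq, rate = 2000, seconds = 5) {
  t <- seq(0, seconds - 1 / rate, by = 1 / rate)
  signal_recording(matrix(sin(2 * pi * freq * t), 1L), rate)
}

# Mean power over the interior of a recording's first channel (edges
# excluded to avoid zero-phase filter transients).
interior_power <- function(rec, trim = 0.1) {
  n <- ncol(rec$data)
  lo <- max(1L, floor(trim * n)); hi <- ceiling((1 - trim) * n)
  mean(rec$data[1L, lo:hi]^2)
}

attenuation_db <- function(before, after) {
  10 * log10(interior_power(before) / interior_power(after))
}
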