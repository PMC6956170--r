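#' Gaussian-cluster classification fixture
#'
#' Samples `n_per_class` points per class from isotropic Gaussian
#' clusters, optionally flipping a fixed fraction of labels uniformly at
#' random. Ground-truth (pre-flip) labels and the flipped row indices are
#' retained so tests can reason about planted noise. Deterministic given
#' the seed.
#'
#' @param n_per_class Points per class.
#' @param n_classes Number of classes (labeled `"c1"`, `"c2"`, ...).
#' @param dim Feature dimension.
#' @param centers Optional `n_classes` x `dim` matrix of cluster centers;
#'   defaults to points on a circle of radius 4 (first two coordinates).
#' @param spread Cluster standard deviation (> 0).
#' @param label_noise Fraction in \[0, 0.5) of rows whose label is flipped
#'   to a random other class; exactly `round(label_noise * n)` rows flip.
#' @param seed Integer seed.
#' @return A [labeled_dataset()] with extra fields `true_y` (pre-flip
#'   labels) and `flipped` (flipped row indices).
#' @export
make_blobs <- function(n_per_class = 50L, n_classes = 2L, dim = 2L,
                       centers = NULL, spread = 1, label_noise = 0,
                       seed = 1L) {
  stopifnot(n_per_class >= 1L, n_classes >= 2L, dim >= 1L, spread > 0,
            label_noise >= 0, label_noise < 0.5)
  if (is.null(centers)) {
    ang <- 2 * pi * (seq_len(n_classes) - 1L) / n_classes
    centers <- matrix(0, n_classes, dim)
    centers[, 1L] <- 4 * cos(ang)
    if (dim >= 2L) centers[, 2L] <- 4 * sin(ang)
  }
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == n_classes, ncol(centers) == dim)
  classes <- paste0("c", seq_len(n_classes))
  n <- n_per_class * n_classes
  withr::with_seed(seed, {
    X <- matrix(0, n, dim)
    y <- character(n)
    row <- 1L
    for (cl in seq_len(n_classes)) {
      for (i in seq_len(n_per_class)) {
        X[row, ] <- centers[cl, ] + stats::rnorm(dim, sd = spread)
        y[row] <- classes[cl]
        row <- row + 1L
      }
    }
    true_y <- y
    n_flip <- round(label_noise * n)
    flipped <- integer(0)
    if (n_flip > 0L) {
      flipped <- sort(sample(n, n_flip))
      for (i in flipped) {
        y[i] <- sample(setdiff(classes, y[i]), 1L)
      }
    }
    ds <- labeled_dataset(X, y, classes = classes)
    ds$true_y <- true_y
    ds$flipped <- flipped
    ds
  })
}

#' Planted-misclassification fixture
#'
#' Constructs a binary train/test pair that provably exercises the
#' advising rules: at least three training points are label-flipped deep
#' inside the opposite cluster (so they land in the misclassified set
#' under the stated C and gamma), and each test point in `expected_flips`
#' sits inside the neighborhood of a misclassified point whose true label
#' corrects the base SVM's prediction while the base decision value is
#' small relative to the batch. The generator verifies these guarantees
#' by fitting the base SVM and running the feature-space advising pass,
#' retrying with a derived sub-seed up to 10 times; persistent failure is
#' an error (it signals a regression in the SVM layer, not bad luck).
#'
#' @param seed Integer seed.
#' @param C,gamma Base c-SVM parameters under which the guarantees are
#'   verified.
#' @return A list with `train` and `test` ([labeled_dataset()]s),
#'   `expected_flips` (test row indices the advising layer must correct)
#'   and `params` (the verified `C`, `gamma`).
#' @export
make_planted_fixture <- function(seed = 1L, C = 1, gamma = 0.5) {
  kernel <- rbf_kernel(gamma)
  for (attempt in 0:9) {
    sub_seed <- (seed + 7919L * attempt) %% .Machine$integer.max
    fx <- withr::with_seed(sub_seed, {
      n_clean <- 30L
      Xa <- cbind(stats::rnorm(n_clean, -2, 0.5), stats::rnorm(n_clean, 0, 0.5))
      Xb <- cbind(stats::rnorm(n_clean, 2, 0.5), stats::rnorm(n_clean, 0, 0.5))
      # planted: true cluster b geometry, labeled "a"
      n_plant <- 3L
      Xp <- cbind(stats::rnorm(n_plant, 1.1, 0.15),
                  stats::rnorm(n_plant, 0, 0.3))
      train <- labeled_dataset(rbind(Xa, Xb, Xp),
                               c(rep("a", n_clean), rep("b", n_clean),
                                 rep("a", n_plant)))
      planted_idx <- 2L * n_clean + seq_len(n_plant)
      n_test <- 20L
      Ta <- cbind(stats::rnorm(n_test, -2, 0.4), stats::rnorm(n_test, 0, 0.4))
      Tb <- cbind(stats::rnorm(n_test, 2, 0.4), stats::rnorm(n_test, 0, 0.4))
      # probes: coincide (up to jitter) with the planted points; their true
      # label is the planted ("a") label
      Tp <- Xp + matrix(stats::rnorm(2L * n_plant, 0, 0.03), n_plant)
      test <- labeled_dataset(rbind(Ta, Tb, Tp),
                              c(rep("a", n_test), rep("b", n_test),
                                rep("a", n_plant)))
      list(train = train, test = test, planted_idx = planted_idx,
           expected_flips = 2L * n_test + seq_len(n_plant))
    })
    base <- train_svm(fx$train, "c", kernel, cost = C)
    md <- find_misclassified(base, fx$train)
    if (!all(fx$planted_idx %in% md$indices)) next
    adv <- self_advise(base, fx$train)
    base_pred <- predict(base, fx$test$X)
    adv_pred <- predict(adv, fx$test$X)
    probes <- fx$expected_flips
    flips_ok <- all(base_pred[probes] == "b") && all(adv_pred[probes] == "a")
    acc_gain <- accuracy(fx$test$y, adv_pred) > accuracy(fx$test$y, base_pred)
    if (flips_ok && acc_gain) {
      return(list(train = fx$train, test = fx$test,
                  expected_flips = probes,
                  params = list(C = C, gamma = gamma)))
    }
  }
  stop("planted fixture verification failed after 10 attempts; ",
       "this indicates a regression in the SVM or advising layer",
       call. = FALSE)
}

default_activation <- function(classes, n_channels) {
  # each movement class drives one dominant muscle, with a weaker synergist
  act <- matrix(0.05, classes, n_channels)
  for (cl in seq_len(classes)) {
    act[cl, (cl - 1L) %% n_channels + 1L] <- 1
    act[cl, cl %% n_channels + 1L] <- 0.4
  }
  act
}

#' Synthetic surface-EMG recording
#'
#' Emulates the offline movement-trial protocol: per repetition each of
#' the movement classes is held for 3 s of activity followed by 5 s of
#' rest, recorded over 4 channels at 2000 Hz. Muscle activity is modeled
#' as envelope-modulated Gaussian noise (a smoothed rectangular burst
#' with 0.25 s raised-cosine ramps, scaled by a class x channel
#' activation-gain matrix) on top of baseline noise and additive 50 Hz
#' line interference. Per-sample annotations mark the active class or
#' `"rest"`, so the trial schedule is exactly reconstructible.
#'
#' @param n_channels Number of channels (default 4).
#' @param classes Number of movement classes (default 4; labeled with
#'   ankle/knee movement names, falling back to `classN`).
#' @param rate Sampling rate in Hz (default 2000, the acquisition
#'   device's rate; downsample afterwards with [resample_recording()]).
#' @param trial_active_s,trial_rest_s Seconds of activity and rest per
#'   trial (defaults 3 and 5).
#' @param reps Repetitions of the full class schedule.
#' @param activation Optional classes x channels matrix of envelope gains
#'   (>= 0); the default gives each class one dominant and one synergist
#'   channel.
#' @param line_hz,line_amp Line-interference frequency and amplitude.
#' @param noise_sd Baseline noise standard deviation.
#' @param seed Integer seed.
#' @return An annotated [signal_recording()] of
#'   `reps * classes * (trial_active_s + trial_rest_s)` seconds.
#' @export
make_semg <- function(n_channels = 4L, classes = 4L, rate = 2000,
                      trial_active_s = 3, trial_rest_s = 5, reps = 2L,
                      activation = NULL, line_hz = 50, line_amp = 0.1,
                      noise_sd = 0.02, seed = 1L) {
  stopifnot(n_channels >= 1L, classes >= 1L, rate > 0,
            trial_active_s > 0, trial_rest_s > 0, reps >= 1L)
  if (is.null(activation)) activation <- default_activation(classes, n_channels)
  activation <- as.matrix(activation)
  stopifnot(nrow(activation) == classes, ncol(activation) == n_channels,
            all(activation >= 0))
  movement_names <- c("dorsiflexion", "plantarflexion",
                      "knee_flexion", "knee_extension")
  class_names <- if (classes <= length(movement_names)) {
    movement_names[seq_len(classes)]
  } else {
    paste0("class", seq_len(classes))
  }
  n_act <- round(trial_active_s * rate)
  n_rest <- round(trial_rest_s * rate)
  n_trial <- n_act + n_rest
  n <- reps * classes * n_trial
  # smoothed rectangular burst: raised-cosine on/off ramps
  ramp <- round(0.25 * rate)
  ramp <- min(ramp, n_act %/% 2L)
  env <- rep(1, n_act)
  if (ramp > 0L) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[seq_len(ramp)] <- up
    env[n_act - ramp + seq_len(ramp)] <- rev(up)
  }
  withr::with_seed(seed, {
    data <- matrix(stats::rnorm(n_channels * n, sd = noise_sd),
                   n_channels, n)
    ann <- rep("rest", n)
    offset <- 0L
    for (r in seq_len(reps)) {
      for (cl in seq_len(classes)) {
        span <- offset + seq_len(n_act)
        for (ch in seq_len(n_channels)) {
          data[ch, span] <- data[ch, span] +
            activation[cl, ch] * env * stats::rnorm(n_act)
        }
        ann[span] <- class_names[cl]
        offset <- offset + n_trial
      }
    }
    if (line_amp > 0) {
      t <- (seq_len(n) - 1L) / rate
      for (ch in seq_len(n_channels)) {
        phase <- 2 * pi * (ch - 1L) / n_channels
        data[ch, ] <- data[ch, ] + line_amp * sin(2 * pi * line_hz * t + phase)
      }
    }
    signal_recording(data, rate,
                     channel_names = c("TA", "Gas", "Sol", "RF",
                                       paste0("ch", seq_len(max(0L, n_channels - 4L)) + 4L))[seq_len(n_channels)],
                     annotations = ann)
  })
}
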