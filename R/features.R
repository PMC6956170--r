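#' Time-domain feature set specification
#'
#' Selects which classical surface-EMG time-domain features to extract
#' per window and per channel, with the thresholds used by the counting
#' features. Available features:
#' \describe{
#'   \item{MAV}{mean absolute value, `mean(|w|)`}
#'   \item{RMS}{root mean square, `sqrt(mean(w^2))`}
#'   \item{WL}{waveform length, `sum(|diff(w)|)`}
#'   \item{ZC}{zero crossings: sign changes whose jump exceeds
#'     `zc_threshold`}
#'   \item{SSC}{slope-sign changes whose turn product exceeds
#'     `ssc_threshold`}
#'   \item{VAR}{unbiased variance}
#'   \item{IEMG}{integrated EMG, `sum(|w|)`}
#'   \item{LOG}{log detector, `exp(mean(log(|w| + 1e-12)))`}
#' }
#'
#' @param names Ordered subset of the feature names above.
#' @param zc_threshold,ssc_threshold Nonnegative thresholds; `NULL`
#'   (default) adapts each to 1% of the window's RMS.
#' @param code Optional integer tag naming a preset (see
#'   [feature_code_set()]).
#' @return An object of class `feature_set_spec`.
#' @export
feature_set_spec <- function(names = c("MAV", "RMS", "WL", "ZC", "SSC"),
                             zc_threshold = NULL, ssc_threshold = NULL,
                             code = NULL) {
  all_names <- c("MAV", "RMS", "WL", "ZC", "SSC", "VAR", "IEMG", "LOG")
  names <- match.arg(names, all_names, several.ok = TRUE)
  if (length(names) == 0L) stop("`names` must be nonempty", call. = FALSE)
  for (thr in list(zc_threshold, ssc_threshold)) {
    if (!is.null(thr) && (!is.finite(thr) || thr < 0)) {
      stop("thresholds must be nonnegative", call. = FALSE)
    }
  }
  structure(list(names = names, zc_threshold = zc_threshold,
                 ssc_threshold = ssc_threshold, code = code),
            class = "feature_set_spec")
}

#' Feature presets by integer code
#'
#' Maps the benchmark configuration codes to concrete feature sets. The
#' mapping is provisional configuration, not a standard:
#' 11 = \{MAV, WL, ZC\}, 13 = \{MAV, RMS, WL, ZC\},
#' 14 = \{MAV, RMS, WL, ZC, SSC\}.
#'
#' @param code Integer preset code (11, 13 or 14).
#' @return A [feature_set_spec()] tagged with the code.
#' @export
feature_code_set <- function(code) {
  sets <- list(`11` = c("MAV", "WL", "ZC"),
               `13` = c("MAV", "RMS", "WL", "ZC"),
               `14` = c("MAV", "RMS", "WL", "ZC", "SSC"))
  key <- as.character(as.integer(code))
  if (!key %in% names(sets)) {
    stop(sprintf("unknown feature code %s; known codes: %s", key,
                 paste(names(sets), collapse = ", ")), call. = FALSE)
  }
  feature_set_spec(sets[[key]], code = as.integer(code))
}

#' Evaluate a single time-domain feature
#'
#' @param name Feature name (see [feature_set_spec()]).
#' @param w Nonempty numeric window (one channel).
#' @param spec A [feature_set_spec()] supplying thresholds.
#' @return The scalar feature value.
#' @export
feature_value <- function(name, w, spec = feature_set_spec()) {
  w <- as.numeric(w)
  if (length(w) == 0L) stop("empty window", call. = FALSE)
  rms <- sqrt(mean(w^2))
  zc_thr <- if (is.null(spec$zc_threshold)) 0.01 * rms else spec$zc_threshold
  ssc_thr <- if (is.null(spec$ssc_threshold)) 0.01 * rms else spec$ssc_threshold
  switch(name,
    MAV = mean(abs(w)),
    RMS = rms,
    WL = sum(abs(diff(w))),
    ZC = {
      if (length(w) < 2L) 0 else {
        a <- w[-length(w)]; b <- w[-1L]
        sum(a * b < 0 & abs(b - a) > zc_thr)
      }
    },
    SSC = {
      if (length(w) < 3L) 0 else {
        m <- w[2:(length(w) - 1L)]
        sum((m - w[1:(length(w) - 2L)]) * (m - w[3:length(w)]) > ssc_thr)
      }
    },
    VAR = if (length(w) < 2L) 0 else stats::var(w),
    IEMG = sum(abs(w)),
    LOG = exp(mean(log(abs(w) + 1e-12))),
    stop(sprintf("unknown feature '%s'", name), call. = FALSE)
  )
}

#' Extract features from segmented windows
#'
#' Turns an nwin x channels x size window tensor (from
#' [segment_windows()]) into the tabular [labeled_dataset()] consumed by
#' the classifiers. The feature vector is the channel-major concatenation
#' over channels and feature names, so `d = channels * |names|`; column
#' order is deterministic.
#'
#' @param windows Window tensor, nwin x channels x size.
#' @param labels Window labels (length nwin).
#' @param spec A [feature_set_spec()].
#' @param channel_names Optional channel names for the feature columns.
#' @return A [labeled_dataset()] with named columns `"<channel>_<feature>"`.
#' @export
extract_features <- function(windows, labels, spec = feature_set_spec(),
                             channel_names = NULL) {
  stopifnot(inherits(spec, "feature_set_spec"))
  dims <- dim(windows)
  if (length(dims) != 3L) stop("`windows` must be a 3-d array", call. = FALSE)
  nwin <- dims[1L]; nch <- dims[2L]
  if (nwin == 0L) stop("no windows to extract features from", call. = FALSE)
  if (length(labels) != nwin) {
    stop("one label per window is required", call. = FALSE)
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  nf <- length(spec$names)
  X <- matrix(0, nwin, nch * nf)
  colnames(X) <- as.vector(t(outer(channel_names, spec$names, paste, sep = "_")))
  for (w in seq_len(nwin)) {
    col <- 1L
    for (ch in seq_len(nch)) {
      seg <- windows[w, ch, ]
      for (f in spec$names) {
        X[w, col] <- feature_value(f, seg, spec)
        col <- col + 1L
      }
    }
  }
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  labeled_dataset(X, labels)
}
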