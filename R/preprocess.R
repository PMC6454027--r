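# Epoch-level cleaning chain: baseline removal, peak-to-peak trial
# rejection, zero-phase low-pass smoothing, PCA-based eyeblink removal.

#' Subtract the pre-stimulus baseline mean from every trial
#'
#' For each trial and channel, the mean over the pre-stimulus interval
#' `[t_start_ms, 0)` is subtracted from the whole trace, so the
#' post-correction pre-stimulus mean is zero.
#'
#' @param epochs An `epoch_set` whose window includes pre-stimulus samples.
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  pre <- which(epochs$time_ms < 0)
  if (!length(pre)) stopf("epoch window has no pre-stimulus samples")
  for (s in seq_along(epochs$subjects)) {
    arr <- epochs$subjects[[s]]
    base <- apply(arr[, , , pre, drop = FALSE], c(1, 2, 3), mean)
    epochs$subjects[[s]] <- arr - as.vector(base) # recycles over time axis
  }
  epochs
}

#' Flag trials whose peak-to-peak amplitude exceeds a threshold
#'
#' A trial is flagged invalid iff its maximum over channels of the
#' (max - min over time) range strictly exceeds `ptp_threshold`; data are
#' left untouched and downstream stages skip flagged trials. Rejection
#' uses the samples as given (typically raw or baseline-corrected; the
#' peak-to-peak range is unaffected by baseline subtraction).
#'
#' @param epochs An `epoch_set`.
#' @param ptp_threshold Peak-to-peak rejection threshold, same units as the
#'   samples (default 6000, i.e. 6,000 fT for femtotesla data).
#' @return The `epoch_set` with updated `valid` flags and a `rejection`
#'   element (per-subject kept/flagged counts).
#' @export
reject_bad_trials <- function(epochs, ptp_threshold = 6000) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.numeric(ptp_threshold) || ptp_threshold <= 0) {
    stopf("ptp_threshold must be > 0")
  }
  report <- vector("list", length(epochs$subjects))
  for (s in seq_along(epochs$subjects)) {
    arr <- epochs$subjects[[s]]
    rng <- apply(arr, c(1, 2, 3), function(v) max(v) - min(v))
    ptp <- apply(rng, c(1, 2), max)
    bad <- ptp > ptp_threshold
    epochs$valid[[s]] <- epochs$valid[[s]] & !bad
    report[[s]] <- list(kept = sum(!bad), flagged = sum(bad))
    if (all(bad)) warnf("subject %d: all trials flagged as bad", s)
  }
  epochs$rejection <- report
  epochs
}

#' Zero-phase low-pass filter all trials
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (`signal::filtfilt`), i.e. with zero phase shift, so the smoothing does
#' not bias latencies. The sampling rate is implied by `step_ms`.
#'
#' @param epochs An `epoch_set`.
#' @param cutoff_hz Cutoff frequency in Hz (default 30); must be below the
#'   Nyquist frequency.
#' @return The filtered `epoch_set`.
#' @export
lowpass_filter <- function(epochs, cutoff_hz = 30) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- 1000 / epochs$step_ms
  if (cutoff_hz >= fs / 2) {
    stopf("cutoff %g Hz is not below the Nyquist frequency %g Hz", cutoff_hz, fs / 2)
  }
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  for (s in seq_along(epochs$subjects)) {
    arr <- epochs$subjects[[s]]
    d <- dim(arr)
    flat <- matrix(aperm(arr, c(4, 1, 2, 3)), nrow = d[4])
    flat <- apply(flat, 2, function(v) signal::filtfilt(bf, v))
    epochs$subjects[[s]] <- aperm(
      array(flat, dim = c(d[4], d[1], d[2], d[3])), c(2, 3, 4, 1)
    )
  }
  epochs
}

#' Detect and remove eyeblink artifacts by PCA projection
#'
#' Blink events are detected where the z-score of the mean frontal-channel
#' signal (standardized per subject over all trials and samples) exceeds
#' `z_threshold` in absolute value. The first principal component of the
#' pooled blink-segment data (channels x blink samples) is then projected
#' out of every channel of each trial containing a blink. Trials without
#' detected blinks are returned numerically unchanged.
#'
#' @param epochs An `epoch_set`.
#' @param frontal_channels Character vector of frontal channel labels
#'   (default: the set designated in the epoch set).
#' @param z_threshold Detection threshold on the frontal z-score (default 4).
#' @return The cleaned `epoch_set`, with a `blink_report` element giving
#'   the number of blink-contaminated trials per subject.
#' @export
remove_eyeblinks <- function(epochs, frontal_channels = epochs$frontal_channels,
                             z_threshold = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!length(frontal_channels)) stopf("frontal channel subset is empty")
  idx <- match(frontal_channels, epochs$channel_labels)
  if (anyNA(idx)) {
    stopf(
      "frontal channels not found in channel labels: %s",
      paste(frontal_channels[is.na(idx)], collapse = ", ")
    )
  }
  report <- integer(length(epochs$subjects))
  for (s in seq_along(epochs$subjects)) {
    arr <- epochs$subjects[[s]]
    d <- dim(arr)
    front <- apply(arr[, , idx, , drop = FALSE], c(1, 2, 4), mean)
    mu <- mean(front)
    sdv <- stats::sd(front)
    if (sdv == 0) next
    z <- (front - mu) / sdv
    hit <- abs(z) > z_threshold # condition x trial x time
    if (!any(hit)) next
    # pool blink-segment data across contaminated trials
    segs <- list()
    trial_hit <- apply(hit, c(1, 2), any)
    for (cc in seq_len(d[1])) {
      for (tr in seq_len(d[2])) {
        if (!trial_hit[cc, tr]) next
        tsel <- which(hit[cc, tr, ])
        segs[[length(segs) + 1L]] <- arr[cc, tr, , tsel, drop = TRUE]
      }
    }
    seg <- do.call(cbind, lapply(segs, function(m) matrix(m, nrow = d[3])))
    u <- svd(seg, nu = 1, nv = 0)$u[, 1]
    proj <- diag(d[3]) - tcrossprod(u)
    for (cc in seq_len(d[1])) {
      for (tr in seq_len(d[2])) {
        if (!trial_hit[cc, tr]) next
        arr[cc, tr, , ] <- proj %*% arr[cc, tr, , ]
      }
    }
    epochs$subjects[[s]] <- arr
    report[s] <- sum(trial_hit)
  }
  epochs$blink_report <- report
  epochs
}

#' Run the full epoch preprocessing chain
#'
#' Baseline correction, peak-to-peak trial rejection, zero-phase low-pass
#' smoothing and eyeblink removal, in that order.
#'
#' @param epochs An `epoch_set`.
#' @param ptp_threshold,cutoff_hz,z_threshold Stage parameters; see the
#'   individual stage functions.
#' @return The preprocessed `epoch_set`.
#' @export
preprocess_epochs <- function(epochs, ptp_threshold = 6000, cutoff_hz = 30,
                              z_threshold = 4) {
  epochs <- baseline_correct(epochs)
  epochs <- reject_bad_trials(epochs, ptp_threshold)
  epochs <- lowpass_filter(epochs, cutoff_hz)
  remove_eyeblinks(epochs, z_threshold = z_threshold)
}
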