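#' Band-pass filter specification
#'
#' Zero-phase Butterworth band-pass. The defaults follow standard sERP
#' practice: 0.1--25 Hz for the EEG channels and 1--10 Hz for the ocular
#' channel Fp1, both second order and applied forward--backward so the
#' net phase response is zero (and the magnitude response is squared).
#'
#' @param low_cut,high_cut Band edges, Hz.
#' @param order Butterworth design order.
#' @param zero_phase Apply forward-backward (`filtfilt`)? Single-pass
#'   filtering is kept only for diagnostic use.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut, high_cut, order = 2L, zero_phase = TRUE) {
  if (!(low_cut > 0 && high_cut > low_cut))
    stop("need 0 < low_cut < high_cut")
  structure(list(order = as.integer(order), low_cut = low_cut,
                 high_cut = high_cut, zero_phase = zero_phase),
            class = "filter_spec")
}

apply_filter <- function(x, spec, sample_rate) {
  if (spec$high_cut >= sample_rate / 2)
    stop(sprintf("high_cut (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 spec$high_cut, sample_rate / 2))
  bf <- signal::butter(spec$order,
                       c(spec$low_cut, spec$high_cut) / (sample_rate / 2),
                       type = "pass")
  if (spec$zero_phase) signal::filtfilt(bf$b, bf$a, x)
  else as.numeric(signal::filter(bf$b, bf$a, x))
}

#' Band-pass filter a recording
#'
#' Filters the continuous recording channel-wise: the five EEG channels
#' with `eeg_spec`, Fp1 with `fp1_spec`. Filtering is applied to the whole
#' recording (not per epoch) so that epoch boundaries carry no filter edge
#' transients.
#'
#' @param recording A `serp_recording`.
#' @param eeg_spec,fp1_spec [filter_spec()]s for the EEG channels and Fp1.
#' @return The recording with filtered data.
#' @export
bandpass_filter <- function(recording,
                            eeg_spec = filter_spec(0.1, 25),
                            fp1_spec = filter_spec(1, 10)) {
  stopifnot(inherits(recording, "serp_recording"))
  for (ch in EEG_CHANNELS)
    recording$data[, ch] <- apply_filter(recording$data[, ch], eeg_spec,
                                         recording$sample_rate)
  recording$data[, "Fp1"] <- apply_filter(recording$data[, "Fp1"], fp1_spec,
                                          recording$sample_rate)
  recording$filtered <- TRUE
  recording
}

#' Segment a recording into stimulus-locked epochs
#'
#' Cuts one 650 ms epoch per event: 100 ms prestimulus baseline plus 550 ms
#' poststimulus. Events whose window does not fit inside the recording are
#' skipped and counted.
#'
#' @param recording A (filtered) `serp_recording`.
#' @param events Event table; defaults to the recording's own events.
#' @return An object of class `serp_epochs`: `data` is a samples x channels
#'   x epochs array (780 x 6 x n at 1200 Hz), `events` the retained rows,
#'   `n_skipped` the number of out-of-bounds events.
#' @export
segment_epochs <- function(recording, events = recording$events) {
  stopifnot(inherits(recording, "serp_recording"))
  fs <- recording$sample_rate
  n_pre <- round(0.1 * fs)
  n_post <- round(0.55 * fs)
  n_len <- n_pre + n_post
  if (is.null(events) || nrow(events) == 0) {
    return(structure(list(
      data = array(0, dim = c(n_len, length(CHANNELS), 0)),
      events = events, sample_rate = fs, n_pre = n_pre, n_skipped = 0L
    ), class = "serp_epochs"))
  }
  s0 <- round(events$onset * fs)  # 0-based onset sample
  ok <- s0 - n_pre >= 0 & s0 + n_post <= nrow(recording$data)
  keep <- which(ok)
  arr <- array(0, dim = c(n_len, length(CHANNELS), length(keep)),
               dimnames = list(NULL, CHANNELS, NULL))
  for (j in seq_along(keep)) {
    i <- keep[j]
    arr[, , j] <- recording$data[(s0[i] - n_pre + 1):(s0[i] + n_post), ]
  }
  structure(list(data = arr, events = events[keep, , drop = FALSE],
                 sample_rate = fs, n_pre = n_pre,
                 n_skipped = sum(!ok)),
            class = "serp_epochs")
}

#' Baseline-correct epochs
#'
#' Per channel and epoch, subtracts the mean of the 100 ms prestimulus
#' segment from the poststimulus interval. The baseline segment itself is
#' left untouched.
#'
#' @param epochs A `serp_epochs`.
#' @return The corrected `serp_epochs`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "serp_epochs"))
  n_pre <- epochs$n_pre
  if (n_pre < 1) stop("epochs carry no baseline samples")
  nE <- dim(epochs$data)[3]
  if (nE == 0) return(epochs)
  n_len <- dim(epochs$data)[1]
  bm <- apply(epochs$data[seq_len(n_pre), , , drop = FALSE], c(2, 3), mean)
  epochs$data[(n_pre + 1):n_len, , ] <-
    epochs$data[(n_pre + 1):n_len, , , drop = FALSE] -
    rep(bm, each = n_len - n_pre)
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Reject epochs containing artifacts
#'
#' An epoch is kept iff the absolute amplitude stays within
#' `eeg_threshold` on every EEG channel and within `fp1_threshold` on Fp1,
#' over the full 650 ms window.
#'
#' @param epochs Baseline-corrected `serp_epochs`.
#' @param eeg_threshold,fp1_threshold Rejection thresholds, microvolts.
#' @return The kept `serp_epochs`, with the rejection count in
#'   `$n_rejected`.
#' @export
reject_artifacts <- function(epochs, eeg_threshold = 50, fp1_threshold = 80) {
  stopifnot(inherits(epochs, "serp_epochs"))
  nE <- dim(epochs$data)[3]
  if (nE == 0) {
    epochs$n_rejected <- 0L
    return(epochs)
  }
  peak <- apply(abs(epochs$data), c(2, 3), max)  # channels x epochs
  keep <- apply(peak[EEG_CHANNELS, , drop = FALSE] <= eeg_threshold, 2, all) &
    peak["Fp1", ] <= fp1_threshold
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$events <- epochs$events[keep, , drop = FALSE]
  epochs$n_rejected <- sum(!keep)
  epochs
}

#' Extract classification trials from clean epochs
#'
#' Cuts the 50--550 ms poststimulus interval (600 samples at 1200 Hz),
#' drops the ocular channel, and labels each trial with its cluster
#' (attended location crossed with stimulated location: ADSD, ADSV, AVSD,
#' AVSV).
#'
#' @param epochs Artifact-free `serp_epochs`.
#' @return An object of class `serp_trials`: `data` is a 600 x 5 x trials
#'   array, `events` the matching event rows, `cluster` a factor.
#' @export
extract_trials <- function(epochs) {
  stopifnot(inherits(epochs, "serp_epochs"))
  fs <- epochs$sample_rate
  n_pre <- epochs$n_pre
  i0 <- n_pre + round(0.05 * fs) + 1
  i1 <- n_pre + round(0.55 * fs)
  dat <- epochs$data[i0:i1, EEG_CHANNELS, , drop = FALSE]
  cl <- factor(paste0("A", epochs$events$attended, "S", epochs$events$location),
               levels = CLUSTERS)
  structure(list(data = dat, events = epochs$events, cluster = cl,
                 sample_rate = fs),
            class = "serp_trials")
}

#' Full preprocessing chain
#'
#' Filter, epoch, baseline-correct, reject and extract in the fixed order
#' of the processing pipeline.
#'
#' @inheritParams bandpass_filter
#' @inheritParams reject_artifacts
#' @param filter Set `FALSE` to skip filtering (for already-filtered or
#'   noise-free input).
#' @return A `serp_trials` object; the numbers of skipped and rejected
#'   epochs are attached as attributes `n_skipped` and `n_rejected`.
#' @export
preprocess_recording <- function(recording,
                                 eeg_spec = filter_spec(0.1, 25),
                                 fp1_spec = filter_spec(1, 10),
                                 eeg_threshold = 50, fp1_threshold = 80,
                                 filter = TRUE) {
  if (filter) recording <- bandpass_filter(recording, eeg_spec, fp1_spec)
  ep <- segment_epochs(recording)
  ep <- baseline_correct(ep)
  ep <- reject_artifacts(ep, eeg_threshold, fp1_threshold)
  tr <- extract_trials(ep)
  attr(tr, "n_skipped") <- ep$n_skipped
  attr(tr, "n_rejected") <- ep$n_rejected
  tr
}

#' @export
print.serp_trials <- function(x, ...) {
  cat(sprintf("sERP trials: %d x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[3], dim(x$data)[2], dim(x$data)[1], x$sample_rate))
  print(table(x$cluster))
  invisible(x)
}
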