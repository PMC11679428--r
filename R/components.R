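#' Default sERP component templates
#'
#' The synthetic sERP is a superposition of Gaussian-windowed deflections,
#' one per classical somatosensory component. Exogenous components (N20,
#' P50, N70) are driven by the stimulus itself and carry no attention
#' effect (`attention_gain` fixed at 1); endogenous components (P100, N140,
#' P300) are multiplied by `attention_gain` when the stimulated location is
#' the attended one, which is the physiological effect the decoder must
#' recover. Channel weights concentrate the response on the contralateral
#' and central electrodes (C3, CP3, Cz); amplitudes are in microvolts,
#' latencies and widths in milliseconds (width is the Gaussian SD).
#'
#' @param attention_gain Multiplier applied to endogenous components when
#'   stimulated = attended.
#' @return A data frame of class `serp_components` with one row per
#'   component: `name`, `latency`, `width`, `amplitude`, `attention_gain`
#'   and one weight column per channel (`w_C3` ... `w_Fp1`).
#' @export
serp_components <- function(attention_gain = 1.5) {
  exo_w <- c(1.0, 0.8, 0.4, 0.7, 0.5, 0.05)
  endo_w <- c(1.0, 0.9, 0.35, 0.9, 0.45, 0.1)
  comps <- data.frame(
    name = c("N20", "P50", "N70", "P100", "N140", "P300"),
    latency = c(20, 50, 70, 100, 140, 300),
    width = c(5, 8, 10, 18, 22, 60),
    amplitude = c(-2, 3, -3, 4, -6, 8),
    attention_gain = c(1, 1, 1, rep(attention_gain, 3)),
    stringsAsFactors = FALSE
  )
  w <- rbind(exo_w, exo_w, exo_w, endo_w, endo_w, endo_w)
  colnames(w) <- paste0("w_", CHANNELS)
  out <- cbind(comps, as.data.frame(w))
  rownames(out) <- NULL
  class(out) <- c("serp_components", "data.frame")
  out
}

validate_components <- function(components) {
  need <- c("name", "latency", "width", "amplitude", "attention_gain",
            paste0("w_", CHANNELS))
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("components missing columns: ", paste(miss, collapse = ", "))
  if (any(components$width <= 0)) stop("component widths must be > 0")
  exo <- components$name %in% c("N20", "P50", "N70")
  if (any(components$attention_gain[exo] != 1))
    stop("exogenous components (N20, P50, N70) must have attention_gain = 1")
  invisible(components)
}

#' Render one sERP waveform
#'
#' Evaluates the component superposition for one channel over the 0--550 ms
#' poststimulus window. Near each component latency the waveform value is
#' approximately `amplitude * channel_weight * gain`, with `gain =
#' attention_gain` when the stimulated location is attended and 1 otherwise.
#'
#' @param components Component table, see [serp_components()].
#' @param stimulated,attended Stimulated and attended locations ("D"/"V").
#' @param channel Channel label (one of C3, Cz, C4, CP3, P3, Fp1).
#' @param sample_rate Sampling rate in Hz.
#' @return Numeric vector of `0.55 * sample_rate` amplitude values (microvolts).
#' @export
render_serp <- function(components = serp_components(), stimulated = "D",
                        attended = "D", channel = "C3", sample_rate = 1200) {
  validate_components(components)
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (!channel %in% CHANNELS)
    stop(sprintf("unknown channel '%s' (expected one of %s)",
                 channel, paste(CHANNELS, collapse = ", ")))
  n <- round(0.55 * sample_rate)
  t_ms <- (seq_len(n) - 1) / sample_rate * 1000
  w <- components[[paste0("w_", channel)]]
  gain <- ifelse(identical(stimulated, attended), 1, 0) *
    (components$attention_gain - 1) + 1
  y <- numeric(n)
  for (i in seq_len(nrow(components))) {
    y <- y + components$amplitude[i] * w[i] * gain[i] *
      exp(-0.5 * ((t_ms - components$latency[i]) / components$width[i])^2)
  }
  y
}

#' Background noise and artifact specification
#'
#' Parameters of the additive noise model used by
#' [synthesize_recording()]: spectrally shaped background EEG (a `1/f^alpha`
#' component mixed with a white floor), eye blinks injected at Fp1 and
#' propagated to the scalp channels, and occasional gross movement bursts
#' on the EEG channels. Default artifact rates are set so that roughly 2%
#' of epochs are rejected per session, matching the rejection statistics
#' the protocol is designed around; the default 12 uV background SD leaves
#' the single-trial attention effect (a few microvolts at best) well below
#' the noise floor.
#'
#' @param background_sd Standard deviation of the background noise, uV.
#' @param spectral_exponent Exponent alpha of the `1/f^alpha` amplitude
#'   shaping; 0 gives white noise.
#' @param white_fraction Fraction of background variance contributed by the
#'   white floor.
#' @param blink_rate Eye blinks per minute.
#' @param blink_amplitude_fp1 Peak blink amplitude at Fp1, uV.
#' @param blink_propagation Named vector: fraction of the Fp1 blink
#'   amplitude reaching each EEG channel.
#' @param gross_artifact_rate Gross movement bursts per minute.
#' @param gross_artifact_amplitude Burst peak amplitude, uV (half-sine,
#'   200 ms, applied to all EEG channels).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(background_sd = 12, spectral_exponent = 1,
                       white_fraction = 0.2,
                       blink_rate = 1.2, blink_amplitude_fp1 = 150,
                       blink_propagation = c(C3 = 0.12, Cz = 0.15, C4 = 0.12,
                                             CP3 = 0.08, P3 = 0.06),
                       gross_artifact_rate = 0.3,
                       gross_artifact_amplitude = 120) {
  vals <- c(background_sd, blink_rate, blink_amplitude_fp1,
            gross_artifact_rate, gross_artifact_amplitude, white_fraction)
  if (any(vals < 0)) stop("noise rates and amplitudes must be >= 0")
  if (white_fraction > 1) stop("white_fraction must be in [0, 1]")
  structure(list(
    background_sd = background_sd,
    spectral_exponent = spectral_exponent,
    white_fraction = white_fraction,
    blink_rate = blink_rate,
    blink_amplitude_fp1 = blink_amplitude_fp1,
    blink_propagation = blink_propagation,
    gross_artifact_rate = gross_artifact_rate,
    gross_artifact_amplitude = gross_artifact_amplitude
  ), class = "noise_spec")
}
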