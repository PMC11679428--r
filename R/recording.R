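# Spectrally shaped background noise, one channel. Amplitude shaping is
# (max(f, 0.5 Hz))^(-alpha/2) for the pink part, mixed with a white floor,
# then rescaled so the realized SD equals background_sd exactly.
shaped_noise <- function(n, sample_rate, sd, alpha, white_fraction) {
  if (sd <= 0) return(numeric(n))
  pink <- if (white_fraction < 1) {
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * sample_rate / n  # symmetric frequency map
    amp <- pmax(f, 0.5)^(-alpha / 2)
    amp[1] <- 0                            # no DC
    x <- Re(fft(fft(rnorm(n)) * amp, inverse = TRUE)) / n
    x / max(sd(x), 1e-12)
  } else numeric(n)
  white <- if (white_fraction > 0) rnorm(n) else numeric(n)
  x <- sqrt(1 - white_fraction) * pink + sqrt(white_fraction) * white
  if (all(x == 0)) return(x)
  x * sd / sd(x)
}

#' Synthesize a multi-channel EEG recording with embedded sERPs
#'
#' Builds a continuous six-channel recording: the rendered sERP template of
#' every protocol event is added to every channel at the event onset,
#' spectrally shaped background noise is added per channel, eye blinks are
#' injected at Poisson-random times at Fp1 (propagated to the EEG channels)
#' and gross movement bursts at the EEG channels. Fully deterministic given
#' the seed; the generating specifications are retained in the `truth`
#' field for parameter-recovery tests.
#'
#' @param protocol Event table from [generate_protocol()].
#' @param components Component table, see [serp_components()].
#' @param noise A [noise_spec()].
#' @param sample_rate Sampling rate, Hz. The default 1200 Hz makes the
#'   500 ms trial exactly 600 samples.
#' @param seed RNG seed.
#' @return An object of class `serp_recording`: list with `data` (samples x
#'   channels matrix, microvolts, columns named C3, Cz, C4, CP3, P3, Fp1),
#'   `sample_rate`, `channels`, `events`, `truth`.
#' @export
synthesize_recording <- function(protocol, components = serp_components(),
                                 noise = noise_spec(), sample_rate = 1200,
                                 seed = 1L) {
  if (!is.data.frame(protocol) || nrow(protocol) == 0)
    stop("protocol must be a non-empty event table")
  validate_components(components)
  stopifnot(inherits(noise, "noise_spec"))
  n_post <- round(0.55 * sample_rate)
  n <- ceiling((max(protocol$onset) + 0.55 + 0.2) * sample_rate)
  dat <- matrix(0, n, length(CHANNELS), dimnames = list(NULL, CHANNELS))

  # two template variants per channel: stimulated location attended or not
  tmpl <- list(
    att = vapply(CHANNELS, function(ch)
      render_serp(components, "D", "D", ch, sample_rate), numeric(n_post)),
    unatt = vapply(CHANNELS, function(ch)
      render_serp(components, "D", "V", ch, sample_rate), numeric(n_post))
  )
  s0 <- round(protocol$onset * sample_rate)
  is_att <- protocol$location == protocol$attended
  for (i in seq_len(nrow(protocol))) {
    rows <- (s0[i] + 1):(s0[i] + n_post)
    dat[rows, ] <- dat[rows, ] +
      (if (is_att[i]) tmpl$att else tmpl$unatt)
  }

  local_seed(seed, {
    for (ch in seq_along(CHANNELS))
      dat[, ch] <- dat[, ch] + shaped_noise(n, sample_rate,
                                            noise$background_sd,
                                            noise$spectral_exponent,
                                            noise$white_fraction)
    dur_min <- n / sample_rate / 60
    # eye blinks: ~300 ms Hann-shaped positive deflection at Fp1
    n_blink <- rpois(1, noise$blink_rate * dur_min)
    if (n_blink > 0 && noise$blink_amplitude_fp1 > 0) {
      bl <- round(0.3 * sample_rate)
      shape <- noise$blink_amplitude_fp1 * (0.5 - 0.5 * cos(2 * pi * seq_len(bl) / (bl + 1)))
      starts <- sort(sample.int(n - bl, n_blink))
      prop <- noise$blink_propagation[EEG_CHANNELS]
      prop[is.na(prop)] <- 0
      for (st in starts) {
        rows <- st:(st + bl - 1)
        dat[rows, "Fp1"] <- dat[rows, "Fp1"] + shape
        for (ch in EEG_CHANNELS)
          dat[rows, ch] <- dat[rows, ch] + prop[[ch]] * shape
      }
    }
    # gross movement bursts: 200 ms half-sine on all EEG channels
    n_gross <- rpois(1, noise$gross_artifact_rate * dur_min)
    if (n_gross > 0 && noise$gross_artifact_amplitude > 0) {
      gl <- round(0.2 * sample_rate)
      half_sine <- sin(pi * seq_len(gl) / (gl + 1))
      starts <- sort(sample.int(n - gl, n_gross))
      signs <- sample(c(-1, 1), n_gross, replace = TRUE)
      for (k in seq_along(starts)) {
        rows <- starts[k]:(starts[k] + gl - 1)
        burst <- signs[k] * noise$gross_artifact_amplitude * half_sine
        for (ch in EEG_CHANNELS) dat[rows, ch] <- dat[rows, ch] + burst
      }
    }
  })

  structure(list(
    data = dat,
    sample_rate = sample_rate,
    channels = CHANNELS,
    events = protocol,
    truth = list(components = components, noise = noise, seed = seed)
  ), class = "serp_recording")
}

#' Simulate one synthetic subject
#'
#' Convenience wrapper: draws a protocol and synthesizes the matching
#' recording, with child seeds derived from one subject seed.
#'
#' @param seed Subject-level seed.
#' @param spec A [protocol_spec()].
#' @param components,noise Generator settings, see [serp_components()] and
#'   [noise_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @return A `serp_recording`.
#' @export
simulate_subject <- function(seed = 1L, spec = protocol_spec(),
                             components = serp_components(),
                             noise = noise_spec(), sample_rate = 1200) {
  protocol <- generate_protocol(spec, seed = child_seed(seed, 1L))
  synthesize_recording(protocol, components, noise, sample_rate,
                       seed = child_seed(seed, 2L))
}

#' @export
print.serp_recording <- function(x, ...) {
  cat(sprintf("Synthetic EEG recording: %d samples x %d channels @ %g Hz (%.1f min)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate / 60))
  cat(sprintf("events: %d; channels: %s\n", nrow(x$events),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' @param x A `serp_recording`.
#' @param t_start,t_end Plotted time window, seconds.
#' @param ... Unused.
#' @rdname synthesize_recording
#' @export
plot.serp_recording <- function(x, t_start = 0, t_end = 10, ...) {
  i0 <- max(1, round(t_start * x$sample_rate))
  i1 <- min(nrow(x$data), round(t_end * x$sample_rate))
  idx <- i0:i1
  tt <- idx / x$sample_rate
  offs <- (seq_along(x$channels) - 1) * 100
  graphics::matplot(tt, sweep(x$data[idx, ], 2, offs, "+"), type = "l",
                    lty = 1, col = seq_along(x$channels),
                    xlab = "time (s)", ylab = "amplitude + offset (uV)",
                    main = "synthetic recording")
  ev <- x$events$onset[x$events$onset >= tt[1] & x$events$onset <= tt[length(tt)]]
  graphics::abline(v = ev, col = "grey80", lty = 3)
  graphics::legend("topright", legend = x$channels, col = seq_along(x$channels),
                   lty = 1, cex = 0.7, bg = "white")
  invisible(x)
}
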