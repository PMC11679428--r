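#' Average trials within clusters
#'
#' Within each cluster, trials in chronological order are partitioned into
#' consecutive non-overlapping groups of `navg`; each group's per-channel
#' mean over the 600 trial samples is decimated by 8 (every 8th sample,
#' starting at the first) to 75 samples per channel, the nominal 150 Hz
#' feature grid. Leftover trials (`n %% navg`) are discarded.
#'
#' @param trials A `serp_trials`.
#' @param navg Number of trials per average, 2--10.
#' @return An object of class `serp_averages`: per cluster a 75 x 5 x
#'   groups array plus the member trial indices.
#' @export
average_groups <- function(trials, navg) {
  stopifnot(inherits(trials, "serp_trials"))
  if (navg < 2 || navg > 10 || navg != round(navg))
    stop("navg must be an integer in 2..10")
  navg <- as.integer(navg)
  dec <- seq(1, dim(trials$data)[1], by = 8L)
  ord <- order(trials$events$onset)
  out <- list()
  members <- list()
  for (cl in CLUSTERS) {
    idx <- ord[trials$cluster[ord] == cl]
    n_g <- length(idx) %/% navg
    if (n_g == 0) {
      warning(sprintf("cluster %s has fewer than navg = %d trials", cl, navg))
      out[[cl]] <- array(0, dim = c(length(dec), length(EEG_CHANNELS), 0))
      members[[cl]] <- list()
      next
    }
    arr <- array(0, dim = c(length(dec), length(EEG_CHANNELS), n_g),
                 dimnames = list(NULL, EEG_CHANNELS, NULL))
    mem <- vector("list", n_g)
    for (g in seq_len(n_g)) {
      gi <- idx[((g - 1L) * navg + 1L):(g * navg)]
      m <- apply(trials$data[, , gi, drop = FALSE], c(1, 2), mean)
      arr[, , g] <- m[dec, ]
      mem[[g]] <- gi
    }
    out[[cl]] <- arr
    members[[cl]] <- mem
  }
  structure(list(data = out, members = members, navg = navg),
            class = "serp_averages")
}

#' Concatenate the channels of one averaged sERP
#'
#' Channels are appended in the fixed order C3, Cz, C4, CP3, P3, giving a
#' 375-sample vector (5 channels x 75 samples).
#'
#' @param avg A 75 x 5 matrix (one averaged sERP).
#' @return Numeric vector of length 375.
#' @export
concatenate_channels <- function(avg) {
  if (!is.matrix(avg) || ncol(avg) != length(EEG_CHANNELS))
    stop("avg must be a samples x 5 matrix")
  as.numeric(avg)  # column-major: C3 block first, then Cz, C4, CP3, P3
}

#' Assemble two-class input vectors
#'
#' For class AD, the i-th averaged sERP of cluster ADSD (D-location
#' stimulation) is concatenated with the i-th of ADSV (V-location); for
#' class AV, AVSD with AVSV. The D half always comes first, so each vector
#' holds 750 amplitudes and the class label reflects only the attended
#' location, never the stimulated one. The vector count per class is the
#' minimum of the two cluster counts.
#'
#' @param averages A `serp_averages`.
#' @return An object of class `serp_features`: `x` (n x 750 matrix), `y`
#'   (factor AD/AV), `navg`, and `provenance` (source group indices).
#' @export
build_input_vectors <- function(averages) {
  stopifnot(inherits(averages, "serp_averages"))
  halves <- list(AD = c("ADSD", "ADSV"), AV = c("AVSD", "AVSV"))
  xs <- list()
  ys <- character(0)
  prov <- list()
  for (lab in names(halves)) {
    d_cl <- halves[[lab]][1]
    v_cl <- halves[[lab]][2]
    n <- min(dim(averages$data[[d_cl]])[3], dim(averages$data[[v_cl]])[3])
    if (n == 0) {
      warning(sprintf("no input vectors for class %s (an input cluster is empty)", lab))
      next
    }
    for (i in seq_len(n)) {
      xs[[length(xs) + 1L]] <-
        c(concatenate_channels(averages$data[[d_cl]][, , i]),
          concatenate_channels(averages$data[[v_cl]][, , i]))
      ys <- c(ys, lab)
      prov[[length(prov) + 1L]] <- data.frame(label = lab, index = i,
                                              d_cluster = d_cl, v_cluster = v_cl)
    }
  }
  x <- if (length(xs)) do.call(rbind, xs) else matrix(0, 0, 750)
  structure(list(x = x, y = factor(ys, levels = c("AD", "AV")),
                 navg = averages$navg,
                 provenance = if (length(prov)) do.call(rbind, prov) else NULL),
            class = "serp_features")
}

#' Trials to feature vectors in one step
#'
#' @inheritParams average_groups
#' @return A `serp_features`, see [build_input_vectors()].
#' @export
build_features <- function(trials, navg) {
  build_input_vectors(average_groups(trials, navg))
}

#' Decode feature positions into (location, channel, latency)
#'
#' Inverse of the feature-vector layout: positions 1--375 come from
#' D-location stimulation, 376--750 from V; within each half the channels
#' follow the concatenation order C3, Cz, C4, CP3, P3 in blocks of 75
#' samples; within a channel, sample `j` (1-based) sits at
#' `50 + (j - 1) * 1000/150` ms poststimulus.
#'
#' @param position Integer vector of feature positions in 1..750.
#' @return Data frame with `position`, `stimulated`, `channel`, `time_ms`.
#' @examples
#' feature_index(c(1, 376, 750))
#' @export
feature_index <- function(position) {
  position <- as.integer(position)
  if (any(position < 1 | position > 750))
    stop("feature positions must lie in 1..750")
  within <- (position - 1L) %% 375L
  data.frame(
    position = position,
    stimulated = ifelse(position <= 375L, "D", "V"),
    channel = EEG_CHANNELS[within %/% 75L + 1L],
    time_ms = 50 + (within %% 75L) * (1000 / 150),
    stringsAsFactors = FALSE
  )
}

#' @export
print.serp_features <- function(x, ...) {
  cat(sprintf("sERP feature set: %d vectors x %d features (navg = %d)\n",
              nrow(x$x), ncol(x$x), x$navg))
  print(table(x$y))
  invisible(x)
}
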