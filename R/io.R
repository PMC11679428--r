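#' Write / read a recording as delimited text
#'
#' Interchange format for synthetic (or any compatible) recordings: a
#' tab-separated table with one row per sample and one column per channel,
#' preceded by a `# sample_rate_hz:` header line, plus a sidecar event
#' table (`onset`, `location`, `attended`, `block`, `subblock`).
#'
#' @param recording A `serp_recording`.
#' @param path Destination of the sample table.
#' @param events_path Destination of the event sidecar; default replaces
#'   the file extension with `_events.tsv`.
#' @return `write_recording()` returns the paths invisibly;
#'   `read_recording()` returns a `serp_recording` (without generator
#'   truth).
#' @export
write_recording <- function(recording, path,
                            events_path = default_events_path(path)) {
  stopifnot(inherits(recording, "serp_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %g", recording$sample_rate), con)
  write.table(round(recording$data, 4), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ev <- as.data.frame(recording$events)
  write.table(ev, events_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(recording = path, events = events_path))
}

default_events_path <- function(path) {
  sub("\\.[^.]*$", "", path) |> paste0("_events.tsv")
}

#' @param path Path of the sample table written by [write_recording()].
#' @param events_path Path of the event sidecar.
#' @rdname write_recording
#' @export
read_recording <- function(path, events_path = default_events_path(path)) {
  first <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*sample_rate_hz:\\s*", "", first))
  if (!is.finite(fs)) stop("missing '# sample_rate_hz:' header in ", path)
  dat <- as.matrix(read.table(path, header = TRUE, sep = "\t", skip = 1))
  if (!identical(colnames(dat), CHANNELS))
    stop("recording must have channel columns ", paste(CHANNELS, collapse = ", "))
  ev <- read.table(events_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  structure(list(data = dat, sample_rate = fs, channels = CHANNELS,
                 events = ev, truth = NULL),
            class = "serp_recording")
}

#' Write / read extracted trials as delimited text
#'
#' One row per (trial, channel): `trial`, `cluster`, `onset`, `channel`,
#' then the 600 amplitude columns.
#'
#' @param trials A `serp_trials`.
#' @param path Destination file.
#' @return `write_trials()` the path, invisibly; `read_trials()` a
#'   `serp_trials`.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "serp_trials"))
  d <- dim(trials$data)
  nT <- d[3]
  amp <- matrix(aperm(trials$data, c(2, 3, 1)), nrow = d[2] * nT, ncol = d[1])
  colnames(amp) <- paste0("s", seq_len(d[1]))
  meta <- data.frame(
    trial = rep(seq_len(nT), each = d[2]),
    cluster = rep(as.character(trials$cluster), each = d[2]),
    onset = rep(trials$events$onset, each = d[2]),
    channel = rep(EEG_CHANNELS, nT),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %g", trials$sample_rate), con)
  write.table(cbind(meta, round(amp, 4)), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  first <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*sample_rate_hz:\\s*", "", first))
  tab <- read.table(path, header = TRUE, sep = "\t", skip = 1,
                    stringsAsFactors = FALSE)
  amp_cols <- grep("^s\\d+$", names(tab))
  n_s <- length(amp_cols)
  trials_id <- unique(tab$trial)
  nT <- length(trials_id)
  dat <- array(0, dim = c(n_s, length(EEG_CHANNELS), nT),
               dimnames = list(NULL, EEG_CHANNELS, NULL))
  for (j in seq_len(nT)) {
    block <- tab[tab$trial == trials_id[j], ]
    dat[, , j] <- t(as.matrix(block[match(EEG_CHANNELS, block$channel), amp_cols]))
  }
  meta <- tab[!duplicated(tab$trial), c("trial", "cluster", "onset")]
  structure(list(
    data = dat,
    events = data.frame(onset = meta$onset),
    cluster = factor(meta$cluster, levels = CLUSTERS),
    sample_rate = fs
  ), class = "serp_trials")
}
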