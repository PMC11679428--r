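#' Information transfer rate
#'
#' One BCI decision requires `2 * navg` stimuli (navg at each location) at
#' one stimulus per `interval` seconds, so the decision time is
#' `T = 2 * navg * interval` and the decision rate `60 / T` per minute.
#' Two bit conventions are provided:
#' \describe{
#'   \item{selection_rate}{bits per decision = `log2(n_targets)`,
#'     independent of accuracy. This is the convention behind the headline
#'     ITR figures 20 bpm (navg = 2) down to 4 bpm (navg = 10) at a 0.75 s
#'     interval.}
#'   \item{accuracy_adjusted}{the Wolpaw bit rate
#'     `B = log2 N + P log2 P + (1 - P) log2((1 - P)/(N - 1))`, which
#'     discounts wrong decisions; equal to the selection rate only at
#'     P = 1.}
#' }
#' The two conventions disagree whenever P < 1; both are exposed rather
#' than silently reconciled.
#'
#' @param navg Number of averaged responses per location (vectorized).
#' @param accuracy Decision accuracy P in `[0, 1]` (used by the
#'   accuracy-adjusted convention; vectorized).
#' @param n_targets Number of selectable targets (2: attend D or attend V).
#' @param interval Inter-stimulus interval, seconds.
#' @param convention Bit-rate convention, see above.
#' @return ITR in bits per minute.
#' @examples
#' compute_itr(2)                     # 20 bpm
#' compute_itr(10)                    # 4 bpm
#' compute_itr(6)                     # 6.67 bpm
#' compute_itr(10, accuracy = 0.9, convention = "accuracy_adjusted")
#' @export
compute_itr <- function(navg, accuracy = 1, n_targets = 2, interval = 0.75,
                        convention = c("selection_rate", "accuracy_adjusted")) {
  convention <- match.arg(convention)
  if (n_targets < 2) stop("n_targets must be >= 2")
  if (any(navg < 1) || interval <= 0) stop("navg >= 1 and interval > 0 required")
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracy must lie in [0, 1]")
  decisions_per_min <- 60 / (2 * navg * interval)
  bits <- if (convention == "selection_rate") {
    log2(n_targets)
  } else {
    p <- accuracy
    xlogx <- function(z) ifelse(z > 0, z * log2(z), 0)
    b <- log2(n_targets) + xlogx(p) +
      ifelse(p < 1, (1 - p) * log2(pmax(1 - p, .Machine$double.xmin) /
                                     (n_targets - 1)), 0)
    low <- p < 1 / n_targets
    if (any(low)) {
      warning("accuracy below chance (1/N): bit rate clamped at 0")
      b[low] <- 0
    }
    pmax(b, 0)
  }
  bits * decisions_per_min
}

#' Tabulate accuracies in the study's reporting layout
#'
#' One row per (classifier, navg) with subjects as columns, the across-
#' subject mean and sample standard deviation (MV, STD), and a
#' per-classifier grand mean over all its cells.
#'
#' @param results A `serp_eval_matrix` (or plain list of `serp_eval`
#'   objects carrying `subject` fields).
#' @param percent Report accuracies in percent?
#' @return A data frame; missing cells are `NA`.
#' @export
accuracy_table <- function(results, percent = TRUE) {
  subs <- sort(unique(vapply(results, function(r) r$subject %||% "S1", character(1))))
  clfs <- unique(vapply(results, function(r) r$classifier, character(1)))
  navgs <- sort(unique(vapply(results, function(r) r$navg, integer(1))))
  mult <- if (percent) 100 else 1
  rows <- list()
  for (clf in clfs) {
    cl_vals <- c()
    for (nv in navgs) {
      acc <- vapply(subs, function(s) {
        hit <- Filter(function(r) identical(r$classifier, clf) &&
                        identical(r$navg, nv) &&
                        identical(r$subject %||% "S1", s), results)
        if (length(hit)) hit[[1]]$mean_accuracy * mult else NA_real_
      }, numeric(1))
      cl_vals <- c(cl_vals, acc)
      row <- as.list(acc)
      names(row) <- subs
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = clf, navg = nv, row,
        MV = mean(acc, na.rm = TRUE),
        STD = sd(acc[!is.na(acc)]),
        classifier_MV = NA_real_, classifier_STD = NA_real_,
        check.names = FALSE
      )
    }
    # grand mean over all the classifier's cells, shown on its last row
    rows[[length(rows)]]$classifier_MV <- mean(cl_vals, na.rm = TRUE)
    rows[[length(rows)]]$classifier_STD <- sd(cl_vals[!is.na(cl_vals)])
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Paired significance of accuracies across Navg settings
#'
#' For every pair of Navg values, a two-sided paired Wilcoxon signed-rank
#' test across subjects, significant at `alpha` (no multiple-comparison
#' correction; raw p-values are retained).
#'
#' @param acc Matrix of accuracies, subjects in rows, one column per Navg
#'   value (column names give the Navg values).
#' @param alpha Significance level.
#' @param classifier Optional label stored with the result.
#' @param min_subjects Refuse below this many subjects (a paired rank test
#'   on fewer has essentially no power).
#' @return An object of class `serp_signif`: symmetric `p` and
#'   `significant` matrices (diagonal: p = 1, not significant).
#' @export
compare_navg <- function(acc, alpha = 0.05, classifier = NULL,
                         min_subjects = 6L) {
  acc <- as.matrix(acc)
  if (nrow(acc) < min_subjects)
    stop(sprintf("need at least %d subjects for the paired test (got %d)",
                 min_subjects, nrow(acc)))
  if (any(is.na(acc))) stop("the same subjects must be present at every navg")
  k <- ncol(acc)
  nm <- colnames(acc) %||% as.character(seq_len(k))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- acc[, i] - acc[, j]
      pv <- if (all(d == 0)) 1
            else suppressWarnings(wilcox.test(acc[, i], acc[, j],
                                              paired = TRUE)$p.value)
      p[i, j] <- p[j, i] <- pv
    }
  }
  sig <- p < alpha
  diag(sig) <- FALSE
  structure(list(p = p, significant = sig, alpha = alpha,
                 classifier = classifier, n_subjects = nrow(acc)),
            class = "serp_signif")
}

#' @export
print.serp_signif <- function(x, ...) {
  cat(sprintf("Paired Wilcoxon across %d subjects (alpha = %g)%s\n",
              x$n_subjects, x$alpha,
              if (!is.null(x$classifier)) paste0(" - ", x$classifier) else ""))
  m <- ifelse(x$significant, "*", ".")
  diag(m) <- " "
  print(as.data.frame(m))
  invisible(x)
}

#' Pick the accuracy/speed-optimal Navg
#'
#' Scans Navg downward from the largest tested value and returns the first
#' setting whose accuracy differs significantly from the Navg = 10
#' reference: the fastest setting reachable before a significant accuracy
#' drop is established. If no comparison is significant, the smallest Navg
#' is returned with `flagged = TRUE` (maximal speed-up available).
#'
#' @param signif A `serp_signif` built over navg 2..10.
#' @param accuracies Named numeric vector of mean accuracies per navg
#'   (names matching the `signif` columns).
#' @param interval Inter-stimulus interval for the ITR, seconds.
#' @return List: `navg`, `accuracy`, `itr` (selection-rate convention),
#'   `flagged`.
#' @export
select_optimal_navg <- function(signif, accuracies, interval = 0.75) {
  stopifnot(inherits(signif, "serp_signif"))
  navgs <- as.integer(colnames(signif$p))
  ref <- as.character(max(navgs))
  for (nv in sort(navgs[navgs < max(navgs)], decreasing = TRUE)) {
    if (signif$significant[as.character(nv), ref]) {
      return(list(navg = nv, accuracy = unname(accuracies[as.character(nv)]),
                  itr = compute_itr(nv, interval = interval), flagged = FALSE))
    }
  }
  nv <- min(navgs)
  list(navg = nv, accuracy = unname(accuracies[as.character(nv)]),
       itr = compute_itr(nv, interval = interval), flagged = TRUE)
}

#' Feature-selection maps
#'
#' Reshapes per-position selection counts into (stimulated location x
#' channel) by latency maps, one per classifier, plus a consensus map
#' counting how many classifiers selected each feature at least once.
#'
#' @param freqs Named list (per classifier) of per-position counts, as
#'   produced by [selection_frequency()].
#' @param n_features Feature-space size.
#' @return An object of class `serp_feature_maps`: `maps` (list of 10 x 75
#'   matrices, rows D-C3 ... V-P3), `consensus`, `time_ms`.
#' @export
feature_maps <- function(freqs, n_features = 750L) {
  idx <- feature_index(seq_len(n_features))
  row_key <- paste(idx$stimulated, idx$channel, sep = "-")
  row_levels <- c(paste("D", EEG_CHANNELS, sep = "-"),
                  paste("V", EEG_CHANNELS, sep = "-"))
  times <- sort(unique(idx$time_ms))
  to_map <- function(counts) {
    m <- matrix(0, length(row_levels), length(times),
                dimnames = list(row_levels, sprintf("%.0f", times)))
    m[cbind(match(row_key, row_levels), match(idx$time_ms, times))] <- counts
    m
  }
  maps <- lapply(freqs, to_map)
  consensus <- to_map(Reduce(`+`, lapply(freqs, function(f) as.integer(f > 0))))
  structure(list(maps = maps, consensus = consensus, time_ms = times),
            class = "serp_feature_maps")
}

#' @param x A `serp_feature_maps`.
#' @param which `"consensus"` or a classifier name present in the maps.
#' @param ... Unused.
#' @rdname feature_maps
#' @export
plot.serp_feature_maps <- function(x, which = "consensus", ...) {
  m <- if (identical(which, "consensus")) x$consensus else x$maps[[which]]
  if (is.null(m)) stop("no map for '", which, "'")
  graphics::image(x$time_ms, seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  xlab = "latency (ms)", ylab = "", axes = FALSE,
                  main = sprintf("feature selection map: %s", which))
  graphics::axis(1)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' ITR trade-off curve
#'
#' @param navg Vector of Navg settings.
#' @param accuracy Optional accuracies matching `navg` (for the
#'   accuracy-adjusted column).
#' @param interval Inter-stimulus interval, seconds.
#' @return Data frame with `navg`, `itr_selection_rate` and (when
#'   accuracies are given) `itr_accuracy_adjusted`.
#' @export
itr_curve <- function(navg = 2:10, accuracy = NULL, interval = 0.75) {
  out <- data.frame(navg = navg,
                    itr_selection_rate = compute_itr(navg, interval = interval))
  if (!is.null(accuracy))
    out$itr_accuracy_adjusted <-
      compute_itr(navg, accuracy, interval = interval,
                  convention = "accuracy_adjusted")
  out
}
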