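# Shared builders for the test suite. Everything is generated in code;
# no fixture files.

# A recording object wrapped around an explicit data matrix.
manual_recording <- function(data, sample_rate = 1200, events = NULL) {
  colnames(data) <- c("C3", "Cz", "C4", "CP3", "P3", "Fp1")
  structure(list(data = data, sample_rate = sample_rate,
                 channels = colnames(data), events = events, truth = NULL),
            class = "serp_recording")
}

# Epochs with constant per-channel values (one epoch).
constant_epoch <- function(value = 0, n_pre = 120, n_post = 660,
                           sample_rate = 1200) {
  arr <- array(value, dim = c(n_pre + n_post, 6, 1),
               dimnames = list(NULL, c("C3", "Cz", "C4", "CP3", "P3", "Fp1"), NULL))
  structure(list(data = arr,
                 events = data.frame(onset = 1, location = "D", attended = "D",
                                     block = 1, subblock = 1),
                 sample_rate = sample_rate, n_pre = n_pre, n_skipped = 0L),
            class = "serp_epochs")
}

# Trials with fully controlled content: fill_fun(channel_index, trial_index)
# returns a 600-sample waveform. Clusters cycle in chronological order.
manual_trials <- function(n_per_cluster, fill_fun = function(ch, i) rep(0, 600),
                          sample_rate = 1200) {
  clusters <- rep(c("ADSD", "ADSV", "AVSD", "AVSV"), times = n_per_cluster)
  nT <- length(clusters)
  dat <- array(0, dim = c(600, 5, nT),
               dimnames = list(NULL, c("C3", "Cz", "C4", "CP3", "P3"), NULL))
  for (i in seq_len(nT))
    for (ch in 1:5) dat[, ch, i] <- fill_fun(ch, i)
  att <- substr(clusters, 2, 2)
  loc <- substr(clusters, 4, 4)
  structure(list(
    data = dat,
    events = data.frame(onset = seq_len(nT) * 0.75, location = loc,
                        attended = att, block = 1, subblock = 1),
    cluster = factor(clusters, levels = c("ADSD", "ADSV", "AVSD", "AVSV")),
    sample_rate = sample_rate
  ), class = "serp_trials")
}

# Two-class Gaussian toy data; separation in units of the noise SD on the
# first `d_informative` features.
toy_data <- function(n_per_class = 50, p = 10, separation = 6,
                     d_informative = p, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  y <- rep(c(0, 1), each = n_per_class)
  shift <- c(rep(separation, d_informative), rep(0, p - d_informative))
  x[y == 1, ] <- x[y == 1, ] + matrix(shift, n_per_class, p, byrow = TRUE)
  list(x = x, y = factor(ifelse(y == 1, "AV", "AD"), levels = c("AD", "AV")))
}

# Inner-fold accuracy of a glmnet ridge-logistic fit at the SFS-time
# default strength (the independent scorer for the selection oracle; a
# zero column is appended because glmnet requires >= 2 columns and a
# zero column cannot change a ridge fit).
eval_glmnet <- function(xtr, ytr, xva, yva) {
  g <- glmnet::glmnet(cbind(xtr, 0), ytr, family = "binomial", alpha = 0,
                      lambda = 0.1, standardize = FALSE, thresh = 1e-12)
  eta <- predict(g, cbind(xva, 0))
  mean(as.integer(eta > 0) == yva)
}

# Literal transcription of the greedy forward-selection loop, scored by an
# arbitrary fit/predict routine. Used as the independent oracle for the
# selection engine.
oracle_sfs <- function(x, y01, splits, eval_fun, max_features) {
  selected <- integer(0)
  trace <- numeric(0)
  best <- 0
  p <- ncol(x)
  while (length(selected) < max_features) {
    cand <- setdiff(seq_len(p), selected)
    accs <- vapply(cand, function(f) {
      fold_acc <- vapply(splits, function(va) {
        tr <- setdiff(seq_len(nrow(x)), va)
        cols <- c(selected, f)
        eval_fun(x[tr, cols, drop = FALSE], y01[tr],
                 x[va, cols, drop = FALSE], y01[va])
      }, numeric(1))
      mean(fold_acc)
    }, numeric(1))
    i <- which.max(accs)
    if (accs[i] > best) {
      selected <- c(selected, cand[i])
      trace <- c(trace, accs[i])
      best <- accs[i]
    } else break
  }
  list(selected = selected, trace = trace)
}
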