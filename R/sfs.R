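#' Feature-selection configuration
#'
#' @param max_features Cap on the selected-set size (the study's setting
#'   is 40).
#' @param inner_folds Number of inner cross-validation folds used to score
#'   candidate features (and, later, the hyperparameter grid).
#' @param seed Seed for fold construction and any seeded classifier fits.
#' @param outer_folds Number of outer folds used by [nested_evaluate()].
#' @return An object of class `sfs_config`.
#' @export
sfs_config <- function(max_features = 40L, inner_folds = 5L, seed = 1L,
                       outer_folds = 5L) {
  if (max_features < 1) stop("max_features must be >= 1")
  if (inner_folds < 2) stop("inner_folds must be >= 2")
  structure(list(max_features = as.integer(max_features),
                 inner_folds = as.integer(inner_folds),
                 outer_folds = as.integer(outer_folds),
                 seed = as.integer(seed)),
            class = "sfs_config")
}

#' Stratified k-fold partition
#'
#' Splits row indices into `k` folds with near-equal class composition.
#' Deterministic given the seed.
#'
#' @param y Factor (or coercible) of class labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return List of `k` integer vectors (the held-out rows of each fold).
#' @export
make_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  if (min(table(y)) < k)
    stop(sprintf("cannot stratify: a class has fewer than k = %d members", k))
  local_seed(seed, {
    folds <- vector("list", k)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      grp <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[grp == f])
    }
    lapply(folds, sort)
  })
}

# Precompute per-inner-fold train/validation matrices (standardized with
# training-fold statistics when the classifier is scale-sensitive).
# Matrices keep all feature columns; column subsetting happens per
# candidate.
prepare_fold_data <- function(x, y01, splits, scale) {
  lapply(splits, function(va) {
    tr <- setdiff(seq_len(nrow(x)), va)
    xtr <- x[tr, , drop = FALSE]
    xva <- x[va, , drop = FALSE]
    if (scale) {
      st <- standardizer(xtr)
      xtr <- apply_standardizer(xtr, st)
      xva <- apply_standardizer(xva, st)
    }
    list(Xtr = xtr, ytr = as.integer(y01[tr]),
         Xva = xva, yva = as.integer(y01[va]))
  })
}

# Mean inner-CV accuracy of one parameter setting on a fixed feature set.
eval_params_cv <- function(fold_data, name, params, cols, seed) {
  accs <- vapply(seq_along(fold_data), function(i) {
    fd <- fold_data[[i]]
    if (length(unique(fd$ytr)) < 2)
      stop("degenerate single-class training fold")
    m <- fit_classifier(name, params, fd$Xtr[, cols, drop = FALSE], fd$ytr,
                        seed = child_seed(seed, i))
    mean(predict_classifier(m, fd$Xva[, cols, drop = FALSE]) == fd$yva)
  }, numeric(1))
  mean(accs)
}

#' Sequential forward selection with inner cross-validation
#'
#' Greedy wrapper selection: starting from the empty set, every candidate
#' feature is scored by the mean inner-CV accuracy of the classifier
#' (using its SFS-time default parameters) trained on the current set plus
#' that candidate; the best candidate (ties resolve to the lowest feature
#' index) is added only if it strictly improves on the incumbent accuracy
#' (the empty set scores 0), otherwise selection stops. The same inner
#' splits are reused for every candidate and every iteration.
#'
#' @param x Feature matrix (rows = exemplars).
#' @param y Two-level factor of class labels.
#' @param classifier Classifier name or [classifier_spec()].
#' @param config An [sfs_config()].
#' @param inner_splits Optional list of held-out index vectors (a partition
#'   of the rows of `x`); built by [make_folds()] when omitted.
#' @param params SFS-time classifier parameters; defaults to the spec's
#'   `sfs_defaults`.
#' @return An object of class `serp_sfs`: `selected` (ordered feature
#'   positions), `accuracy_trace` (inner-CV accuracy after each addition),
#'   `stopped_early`, `classifier`.
#' @export
sequential_forward_select <- function(x, y, classifier = "svm",
                                      config = sfs_config(),
                                      inner_splits = NULL, params = NULL) {
  spec <- if (inherits(classifier, "classifier_spec")) classifier
          else classifier_spec(classifier)
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) stop("y must have exactly two classes")
  y01 <- as.integer(y == levels(y)[2])
  params <- params %||% spec$sfs_defaults
  if (is.null(inner_splits))
    inner_splits <- make_folds(y, config$inner_folds, config$seed)
  fold_data <- prepare_fold_data(x, y01, inner_splits, needs_scaling(spec$name))

  p <- ncol(x)
  max_k <- min(config$max_features, p)
  selected <- integer(0)
  trace <- numeric(0)
  best <- 0
  fast <- spec$name %in% c("lr", "svm", "knn")
  sweep_params <- if (spec$name == "svm" && !identical(params$kernel, "rbf")) {
    c(params[setdiff(names(params), "gamma")], list(gamma = 0))
  } else params

  while (length(selected) < max_k) {
    cand <- setdiff(seq_len(p), selected)
    accs <- if (fast) {
      as.numeric(cpp_sfs_sweep(fold_data, selected - 1L, cand - 1L,
                               spec$name, sweep_params))
    } else {
      vapply(cand, function(j)
        eval_params_cv(fold_data, spec$name, params, c(selected, j),
                       config$seed),
        numeric(1))
    }
    i_best <- which.max(accs)  # ties: lowest candidate index
    if (accs[i_best] > best) {
      selected <- c(selected, cand[i_best])
      trace <- c(trace, accs[i_best])
      best <- accs[i_best]
    } else break
  }
  structure(list(selected = selected, accuracy_trace = trace,
                 stopped_early = length(selected) < max_k,
                 classifier = spec$name, params = params,
                 inner_folds = length(inner_splits)),
            class = "serp_sfs")
}

#' @export
print.serp_sfs <- function(x, ...) {
  cat(sprintf("SFS (%s): %d features selected%s; final inner-CV accuracy %.3f\n",
              x$classifier, length(x$selected),
              if (x$stopped_early) " (stopped: no strict improvement)" else "",
              if (length(x$accuracy_trace)) max(x$accuracy_trace) else NA))
  invisible(x)
}

#' @param x A `serp_sfs`.
#' @param ... Passed to [graphics::plot()].
#' @rdname sequential_forward_select
#' @export
plot.serp_sfs <- function(x, ...) {
  graphics::plot(seq_along(x$accuracy_trace), x$accuracy_trace, type = "b",
                 xlab = "features added", ylab = "inner-CV accuracy",
                 main = sprintf("SFS trace (%s)", x$classifier), ...)
  invisible(x)
}

#' Selection frequency per feature position
#'
#' Counts, for every feature position, how many selection results contain
#' it. With 10 subjects and 9 values of Navg the maximum attainable count
#' is 90.
#'
#' @param results A named list of `serp_sfs` objects (or bare integer
#'   vectors of selected positions), one per (subject, navg) key. Duplicate
#'   keys are an error.
#' @param n_features Length of the feature space (750 for the standard
#'   layout).
#' @return Integer vector of per-position counts.
#' @export
selection_frequency <- function(results, n_features = 750L) {
  if (!is.null(names(results)) && anyDuplicated(names(results)))
    stop("duplicate result keys: ",
         paste(unique(names(results)[duplicated(names(results))]), collapse = ", "))
  counts <- integer(n_features)
  for (r in results) {
    sel <- if (inherits(r, "serp_sfs")) r$selected else as.integer(r)
    counts[unique(sel)] <- counts[unique(sel)] + 1L
  }
  counts
}
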