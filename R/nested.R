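#' Grid search over classifier hyperparameters
#'
#' Scores every row of the classifier's grid by mean inner-CV accuracy on
#' the given feature subset, reusing the inner splits that drove feature
#' selection. Ties resolve to the earliest grid row (the documented
#' enumeration order of [classifier_spec()]).
#'
#' @param x,y Training feature matrix and two-level factor labels.
#' @param classifier Classifier name or [classifier_spec()].
#' @param selected Integer vector of selected feature positions (non-empty).
#' @param inner_splits List of held-out index vectors (partition of the
#'   training rows).
#' @param seed Seed for seeded fits (RF, ANN).
#' @return List with `params` (best setting, as a list), `accuracy`, and
#'   `grid_accuracy` (per-row scores).
#' @export
grid_search <- function(x, y, classifier, selected, inner_splits, seed = 1L) {
  spec <- if (inherits(classifier, "classifier_spec")) classifier
          else classifier_spec(classifier)
  if (length(selected) == 0) stop("selected feature set must be non-empty")
  x <- as.matrix(x)[, selected, drop = FALSE]
  y <- as.factor(y)
  y01 <- as.integer(y == levels(y)[2])
  fold_data <- prepare_fold_data(x, y01, inner_splits, needs_scaling(spec$name))
  cols <- seq_along(selected)
  accs <- vapply(seq_len(nrow(spec$grid)), function(r) {
    params <- as.list(spec$grid[r, , drop = FALSE])
    eval_params_cv(fold_data, spec$name, params, cols, seed)
  }, numeric(1))
  best <- which.max(accs)
  list(params = as.list(spec$grid[best, , drop = FALSE]),
       accuracy = accs[best], grid_accuracy = accs)
}

#' Nested cross-validated evaluation of one classifier
#'
#' The full performance-estimation procedure: 5 stratified outer folds; on
#' each outer training set, inner splits are built once and reused first by
#' sequential forward selection (SFS-time default parameters), then by the
#' hyperparameter grid search on the selected features; the final model is
#' fit on all training rows and scored on the untouched test fold. The
#' reported accuracy is the mean over outer folds. Fully deterministic
#' given `seed`.
#'
#' @param x Feature matrix.
#' @param y Two-level factor of class labels (each class needs at least as
#'   many members as there are outer folds).
#' @param classifier Classifier name or [classifier_spec()].
#' @param config An [sfs_config()]; `config$seed` is overridden by `seed`
#'   when given.
#' @param seed Run seed.
#' @param navg Bookkeeping tag: the trial-averaging setting this dataset
#'   was built with (stored in the result).
#' @return An object of class `serp_eval` with per-fold accuracies,
#'   selected feature sets, tuned parameters, SFS traces, `mean_accuracy`,
#'   `classifier`, `navg` and `seed`.
#' @export
nested_evaluate <- function(x, y, classifier = "svm", config = sfs_config(),
                            seed = config$seed, navg = NA_integer_) {
  spec <- if (inherits(classifier, "classifier_spec")) classifier
          else classifier_spec(classifier)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  if (min(table(y)) < config$outer_folds)
    stop(sprintf("class with fewer than %d members: cannot stratify the outer folds",
                 config$outer_folds))
  outer <- make_folds(y, config$outer_folds, seed)
  per_fold <- numeric(length(outer))
  selected_per_fold <- vector("list", length(outer))
  tuned_per_fold <- vector("list", length(outer))
  traces <- vector("list", length(outer))

  for (f in seq_along(outer)) {
    test <- outer[[f]]
    train <- setdiff(seq_len(nrow(x)), test)
    xtr <- x[train, , drop = FALSE]
    ytr <- y[train]
    fold_seed <- child_seed(seed, f)
    inner <- make_folds(ytr, config$inner_folds, fold_seed)
    fcfg <- config
    fcfg$seed <- fold_seed
    sel <- sequential_forward_select(xtr, ytr, spec, fcfg, inner_splits = inner)
    gs <- grid_search(xtr, ytr, spec, sel$selected, inner, seed = fold_seed)

    cols <- sel$selected
    xtr_s <- xtr[, cols, drop = FALSE]
    xte_s <- x[test, cols, drop = FALSE]
    if (needs_scaling(spec$name)) {
      st <- standardizer(xtr_s)
      xtr_s <- apply_standardizer(xtr_s, st)
      xte_s <- apply_standardizer(xte_s, st)
    }
    y01tr <- as.integer(ytr == levels(y)[2])
    model <- fit_classifier(spec$name, gs$params, xtr_s, y01tr,
                            seed = child_seed(fold_seed, 99L))
    pred <- predict_classifier(model, xte_s)
    per_fold[f] <- mean(pred == as.integer(y[test] == levels(y)[2]))
    selected_per_fold[[f]] <- sel$selected
    tuned_per_fold[[f]] <- gs$params
    traces[[f]] <- sel$accuracy_trace
  }

  structure(list(classifier = spec$name, navg = navg,
                 per_fold_accuracy = per_fold,
                 mean_accuracy = mean(per_fold),
                 selected_per_fold = selected_per_fold,
                 tuned_params_per_fold = tuned_per_fold,
                 sfs_traces = traces,
                 config = config, seed = seed),
            class = "serp_eval")
}

#' @export
print.serp_eval <- function(x, ...) {
  cat(sprintf("Nested CV evaluation: %s%s\n", x$classifier,
              if (!is.na(x$navg)) sprintf(" (navg = %d)", x$navg) else ""))
  cat(sprintf("  mean accuracy %.4f (folds: %s)\n", x$mean_accuracy,
              paste(sprintf("%.3f", x$per_fold_accuracy), collapse = " ")))
  cat(sprintf("  features/fold: %s\n",
              paste(lengths(x$selected_per_fold), collapse = " ")))
  invisible(x)
}

#' @export
summary.serp_eval <- function(object, ...) {
  sel <- sort(table(unlist(object$selected_per_fold)), decreasing = TRUE)
  top <- as.integer(names(sel))[seq_len(min(10, length(sel)))]
  out <- list(classifier = object$classifier, navg = object$navg,
              mean_accuracy = object$mean_accuracy,
              sd_accuracy = sd(object$per_fold_accuracy),
              per_fold_accuracy = object$per_fold_accuracy,
              top_features = cbind(feature_index(top),
                                   times_selected = as.integer(sel[as.character(top)])),
              tuned = object$tuned_params_per_fold)
  class(out) <- "summary.serp_eval"
  out
}

#' @export
print.summary.serp_eval <- function(x, ...) {
  cat(sprintf("%s (navg = %s): accuracy %.4f +/- %.4f\n", x$classifier,
              x$navg, x$mean_accuracy, x$sd_accuracy))
  cat("most-selected features across outer folds:\n")
  print(x$top_features, row.names = FALSE)
  invisible(x)
}

#' Evaluate a grid of (subject, classifier, navg) cells
#'
#' Runs [nested_evaluate()] for every combination, optionally caching each
#' cell on disk so interrupted runs resume without recomputation.
#'
#' @param datasets Named list (one element per subject) of named lists
#'   (one per navg value, names = the navg) of `serp_features` objects or
#'   bare `list(x, y)` pairs.
#' @param classifiers Character vector of classifier names.
#' @param config An [sfs_config()].
#' @param seed Base seed; each cell derives its own child seed.
#' @param cache_dir Optional directory for per-cell RDS caching.
#' @param verbose Print progress lines?
#' @return A list of `serp_eval` objects keyed `subject.classifier.navg`,
#'   with class `serp_eval_matrix`.
#' @export
run_matrix <- function(datasets, classifiers = c("lr", "knn", "svm", "rf", "ann"),
                       config = sfs_config(), seed = 1L, cache_dir = NULL,
                       verbose = interactive()) {
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  results <- list()
  cell_id <- 0L
  for (subj in names(datasets)) {
    for (nv in names(datasets[[subj]])) {
      ds <- datasets[[subj]][[nv]]
      if (is.null(ds) || is.null(ds$x) || nrow(ds$x) == 0) {
        warning(sprintf("missing dataset for subject %s, navg %s: skipped", subj, nv))
        next
      }
      for (clf in classifiers) {
        cell_id <- cell_id + 1L
        key <- paste(subj, clf, nv, sep = ".")
        fingerprint <- sprintf("%s_seed%d_k%d_f%dx%d.rds", key, seed,
                               config$max_features, config$outer_folds,
                               config$inner_folds)
        cache_file <- if (!is.null(cache_dir)) file.path(cache_dir, fingerprint)
        if (!is.null(cache_file) && file.exists(cache_file)) {
          results[[key]] <- readRDS(cache_file)
          next
        }
        if (verbose) message(sprintf("[%s] evaluating...", key))
        res <- nested_evaluate(ds$x, ds$y, clf, config,
                               seed = child_seed(seed, cell_id),
                               navg = as.integer(nv))
        res$subject <- subj
        results[[key]] <- res
        if (!is.null(cache_file)) saveRDS(res, cache_file)
      }
    }
  }
  class(results) <- "serp_eval_matrix"
  results
}
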