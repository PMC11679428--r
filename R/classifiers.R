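#' Classifier specification: SFS-time defaults and tuning grid
#'
#' The five classifier families evaluated by the pipeline, each with the
#' fixed parameters it uses while driving feature selection and the grid
#' searched afterwards:
#' \describe{
#'   \item{lr}{Penalized logistic regression. SFS: L2, strength 0.1.
#'     Grid: penalty L1/L2 x strength \{0.001, 0.01, 0.1, 1\}. The
#'     "strength" is the penalty weight lambda on the mean log-loss scale
#'     (larger = stronger shrinkage); see [lr_strength_is_lambda].}
#'   \item{knn}{K-nearest neighbours, Euclidean metric. SFS: K = 10.
#'     Grid: K = 5..20.}
#'   \item{svm}{Hinge-loss SVM. SFS: linear kernel, C = 1 (middle of the
#'     grid). Grid: linear x C \{0.1, 1, 10, 100\}, then RBF x gamma
#'     \{0.001, 0.01, 0.1, 1\} x the same C values (gamma applies to the
#'     RBF kernel only).}
#'   \item{rf}{Random forest. SFS: 30 trees, depth 5, Gini. Grid: trees
#'     \{20, 25, 30, 35, 40\} x depth 5..10 x criterion \{gini, entropy\}.
#'     `rf_trees_step = 1` enumerates every tree count 20..40.}
#'   \item{ann}{Single-hidden-layer perceptron (32 rectified-linear units,
#'     Adam, 200-epoch budget, patience-20 early stopping). SFS: batch 8,
#'     learning rate 1e-3. Grid: batch \{4, 8, 16\} x learning rate
#'     \{1e-4, 1e-3, 1e-2, 1e-1\}.}
#' }
#' Grid rows are enumerated in the documented order above; grid-search ties
#' resolve to the earliest row.
#'
#' @param name One of "lr", "knn", "svm", "rf", "ann".
#' @param rf_trees_step Step for the RF tree-count grid (default 5).
#' @return An object of class `classifier_spec` with elements `name`,
#'   `sfs_defaults` and `grid` (a data frame, one row per setting).
#' @export
classifier_spec <- function(name = c("lr", "knn", "svm", "rf", "ann"),
                            rf_trees_step = 5L) {
  name <- match.arg(name)
  spec <- switch(name,
    lr = list(
      sfs_defaults = list(penalty = "l2", strength = 0.1),
      grid = expand.grid(penalty = c("l1", "l2"),
                         strength = c(0.001, 0.01, 0.1, 1),
                         stringsAsFactors = FALSE)
    ),
    knn = list(
      sfs_defaults = list(k = 10L),
      grid = data.frame(k = 5:20)
    ),
    svm = list(
      sfs_defaults = list(kernel = "linear", C = 1, gamma = NA_real_),
      grid = rbind(
        expand.grid(kernel = "linear", gamma = NA_real_, C = c(0.1, 1, 10, 100),
                    stringsAsFactors = FALSE),
        expand.grid(kernel = "rbf", gamma = c(0.001, 0.01, 0.1, 1),
                    C = c(0.1, 1, 10, 100), stringsAsFactors = FALSE)
      )
    ),
    rf = list(
      sfs_defaults = list(n_trees = 30L, max_depth = 5L, criterion = "gini"),
      grid = expand.grid(n_trees = seq(20L, 40L, by = as.integer(rf_trees_step)),
                         max_depth = 5:10,
                         criterion = c("gini", "entropy"),
                         stringsAsFactors = FALSE)
    ),
    ann = list(
      sfs_defaults = list(batch = 8L, learning_rate = 1e-3),
      grid = expand.grid(batch = c(4L, 8L, 16L),
                         learning_rate = c(1e-4, 1e-3, 1e-2, 1e-1))
    )
  )
  structure(c(list(name = name), spec), class = "classifier_spec")
}

#' Interpretation of the logistic-regression "regularization strength"
#'
#' The LR grid values \{0.001, 0.01, 0.1, 1\} are interpreted as the
#' penalty weight lambda in `mean log-loss + lambda * P(beta)` (larger =
#' stronger shrinkage), not as its inverse. This single constant isolates
#' that reading.
#' @export
lr_strength_is_lambda <- TRUE

# Classifiers whose metric/margin is scale-sensitive; features are
# standardized with training-fold statistics before these.
needs_scaling <- function(name) name %in% c("knn", "svm", "ann")

standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(x, st) {
  scale(x, center = st$center, scale = st$scale)[, , drop = FALSE]
}

# Fit one classifier with explicit parameters on 0/1 labels.
fit_classifier <- function(name, params, x, y01, seed = 1L) {
  x <- as.matrix(x)
  model <- switch(name,
    lr = cpp_lr_fit(x, y01, params$strength, identical(params$penalty, "l1")),
    knn = list(x = x, y = as.integer(y01), k = as.integer(params$k)),
    svm = cpp_svm_fit(x, y01, params$C, params$kernel,
                      if (identical(params$kernel, "rbf")) params$gamma else 0),
    rf = cpp_rf_fit(x, as.integer(y01), as.integer(params$n_trees),
                    as.integer(params$max_depth), params$criterion,
                    as.integer(seed)),
    ann = cpp_mlp_fit(x, y01, hidden = 32L, batch = as.integer(params$batch),
                      lr = params$learning_rate, max_epochs = 200L,
                      patience = 20L, val_frac = 0.15, seed = as.integer(seed)),
    stop("unknown classifier: ", name)
  )
  list(name = name, params = params, fit = model)
}

# Predict 0/1 labels.
predict_classifier <- function(model, x) {
  x <- as.matrix(x)
  switch(model$name,
    lr = as.integer(cpp_lr_decision(model$fit, x) > 0),
    knn = as.integer(cpp_knn_predict(model$fit$x, model$fit$y, x, model$fit$k)),
    svm = as.integer(cpp_svm_decision(model$fit, x) > 0),
    rf = as.integer(cpp_rf_predict(model$fit, x)),
    ann = as.integer(cpp_mlp_predict_prob(model$fit, x) > 0.5)
  )
}
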