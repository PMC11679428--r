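test_that("stratified folds partition the rows with balanced classes", {
  y <- factor(rep(c("AD", "AV"), times = c(40, 60)))
  folds <- make_folds(y, 5, seed = 1)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), seq_along(y))
  for (f in folds) {
    expect_equal(sum(y[f] == "AD"), 8)
    expect_equal(sum(y[f] == "AV"), 12)
  }
  expect_identical(folds, make_folds(y, 5, seed = 1))
  expect_error(make_folds(factor(c("a", "a", "b")), 5), "fewer than")
})

test_that("grid search returns the argmax setting with documented tie order", {
  d <- toy_data(30, p = 6, separation = 2, seed = 71)
  splits <- make_folds(d$y, 5, seed = 1)

  # one-setting grid returns that setting
  spec1 <- classifier_spec("knn")
  spec1$grid <- data.frame(k = 7L)
  gs1 <- grid_search(d$x, d$y, spec1, selected = 1:3, inner_splits = splits)
  expect_equal(gs1$params$k, 7L)

  # concentric classes: RBF must beat the linear kernel
  set.seed(72)
  n <- 100
  xc <- matrix(rnorm(n * 2), n)
  yc <- factor(ifelse(sqrt(rowSums(xc^2)) > 1.2, "AV", "AD"))
  splits_c <- make_folds(yc, 5, seed = 2)
  gs2 <- grid_search(xc, yc, classifier_spec("svm"), selected = 1:2,
                     inner_splits = splits_c)
  expect_equal(gs2$params$kernel, "rbf")
  # direct fits confirm the gap the grid search saw
  y01 <- as.integer(yc == "AV")
  xs <- scale(xc)
  lin <- serpbci:::cpp_svm_fit(xs, y01, 1, "linear", 0)
  rbf <- serpbci:::cpp_svm_fit(xs, y01, 1, "rbf", 0.1)
  expect_lt(mean((serpbci:::cpp_svm_decision(lin, xs) > 0) == y01), 0.7)
  expect_gt(mean((serpbci:::cpp_svm_decision(rbf, xs) > 0) == y01), 0.9)

  # KNN on tight prototype clusters, n = 20: K = 5 stays local while
  # K = 15 swallows the whole training fold and degenerates to a majority
  # vote, so the small K must win the grid search
  set.seed(73)
  protos_ad <- rbind(c(0, 0), c(3, 3), c(6, 0))
  protos_av <- rbind(c(20, 20), c(23, 23), c(26, 20))
  xp <- rbind(protos_ad[rep(1:3, length.out = 10), ],
              protos_av[rep(1:3, length.out = 10), ]) +
    matrix(rnorm(40, sd = 0.2), 20)
  yp <- factor(rep(c("AD", "AV"), each = 10))
  splits_p <- make_folds(yp, 4, seed = 3)
  spec_k <- classifier_spec("knn")
  spec_k$grid <- data.frame(k = c(5L, 15L))
  gs3 <- grid_search(xp, yp, spec_k, selected = 1:2, inner_splits = splits_p)
  expect_equal(gs3$params$k, 5L)
  expect_gt(gs3$grid_accuracy[1], gs3$grid_accuracy[2])

  expect_error(grid_search(d$x, d$y, "knn", integer(0), splits), "non-empty")
})

test_that("nested evaluation is perfect on separable data for the exact classifiers", {
  d <- toy_data(20, p = 10, separation = 6, seed = 81)
  for (clf in c("lr", "svm", "knn", "rf")) {
    res <- nested_evaluate(d$x, d$y, clf, sfs_config(max_features = 3), seed = 4)
    expect_equal(res$mean_accuracy, 1.0)
    expect_length(res$per_fold_accuracy, 5)
  }
})

test_that("nested evaluation is deterministic and validates its inputs", {
  d <- toy_data(15, p = 8, separation = 1, seed = 82)
  a <- nested_evaluate(d$x, d$y, "svm", sfs_config(max_features = 3), seed = 11)
  b <- nested_evaluate(d$x, d$y, "svm", sfs_config(max_features = 3), seed = 11)
  expect_identical(a, b)
  c <- nested_evaluate(d$x, d$y, "svm", sfs_config(max_features = 3), seed = 12)
  expect_false(identical(a$per_fold_accuracy, c$per_fold_accuracy) &&
                 identical(a$selected_per_fold, c$selected_per_fold))

  tiny <- toy_data(4, p = 5, seed = 83)  # 4 per class < 5 outer folds
  expect_error(nested_evaluate(tiny$x, tiny$y, "lr"), "stratify")
  expect_error(nested_evaluate(d$x, factor(rep("AD", 30)), "lr"), "two classes")
})

test_that("permuted labels give chance-level nested-CV accuracy", {
  set.seed(84)
  accs <- vapply(1:10, function(s) {
    x <- matrix(rnorm(200 * 8), 200)
    y <- factor(sample(rep(c("AD", "AV"), each = 100)))
    nested_evaluate(x, y, "lr", sfs_config(max_features = 3),
                    seed = s)$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("outer-test rows are never read during selection or tuning", {
  d <- toy_data(25, p = 12, separation = 1.5, seed = 85)
  cfg <- sfs_config(max_features = 4)
  base <- nested_evaluate(d$x, d$y, "svm", cfg, seed = 21)
  folds <- make_folds(d$y, cfg$outer_folds, 21)  # reproduce the outer split
  for (f in c(1, 3)) {
    x2 <- d$x
    x2[folds[[f]], ] <- x2[folds[[f]], ] + 100  # corrupt the held-out rows
    mod <- nested_evaluate(x2, d$y, "svm", cfg, seed = 21)
    expect_identical(mod$selected_per_fold[[f]], base$selected_per_fold[[f]])
    expect_identical(mod$tuned_params_per_fold[[f]], base$tuned_params_per_fold[[f]])
    expect_identical(mod$sfs_traces[[f]], base$sfs_traces[[f]])
  }
})

test_that("accuracy grows with the synthetic attention effect", {
  # three effect sizes x five seeds, rank ordering of mean accuracies
  gains <- c(1.0, 1.5, 2.5)
  mean_acc <- vapply(gains, function(g) {
    accs <- vapply(1:5, function(s) {
      spec <- protocol_spec(n_blocks = 2, subblocks_per_block = 3)
      rec <- simulate_subject(seed = 900 + s, spec = spec,
                              components = serp_components(attention_gain = g),
                              noise = noise_spec(blink_rate = 0,
                                                 gross_artifact_rate = 0))
      tr <- preprocess_recording(rec)
      fx <- build_features(tr, 8)
      nested_evaluate(fx$x, fx$y, "lr", sfs_config(max_features = 3),
                      seed = s)$mean_accuracy
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_lt(abs(mean_acc[1] - 0.5), 0.15)  # gain 1: no attention information
  expect_gt(mean_acc[2], mean_acc[1])
  expect_gt(mean_acc[3], mean_acc[2])
})

test_that("run_matrix covers the cell grid and reuses its cache", {
  d1 <- toy_data(15, p = 6, separation = 3, seed = 86)
  d2 <- toy_data(15, p = 6, separation = 3, seed = 87)
  datasets <- list(S1 = list(`2` = d1, `4` = d1), S2 = list(`2` = d2, `4` = d2))
  cache <- file.path(tempdir(), "serpbci-cache-test")
  unlink(cache, recursive = TRUE)
  res <- run_matrix(datasets, classifiers = c("lr", "svm"),
                    config = sfs_config(max_features = 2), seed = 5,
                    cache_dir = cache, verbose = FALSE)
  expect_length(res, 2 * 2 * 2)
  expect_named(res, c("S1.lr.2", "S1.svm.2", "S1.lr.4", "S1.svm.4",
                      "S2.lr.2", "S2.svm.2", "S2.lr.4", "S2.svm.4"),
               ignore.order = TRUE)
  res2 <- run_matrix(datasets, classifiers = c("lr", "svm"),
                     config = sfs_config(max_features = 2), seed = 5,
                     cache_dir = cache, verbose = FALSE)
  expect_equal(res[order(names(res))], res2[order(names(res2))],
               ignore_attr = TRUE)
  expect_warning(
    run_matrix(list(S1 = list(`2` = NULL)), classifiers = "lr",
               config = sfs_config(max_features = 2), verbose = FALSE),
    "missing dataset")
  unlink(cache, recursive = TRUE)
})
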