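# The classifier kernels are cross-checked against independent
# implementations: glmnet (penalized logistic), e1071 (SVM), class::knn
# (KNN) and randomForest (forest accuracy parity).

test_that("penalized logistic regression matches glmnet coefficients", {
  set.seed(3)
  n <- 150
  x <- matrix(rnorm(n * 6), n)
  y <- as.numeric(x[, 1] - 0.8 * x[, 3] + rnorm(n) * 0.8 > 0)
  for (cfg in list(list(l1 = FALSE, lam = 0.1), list(l1 = FALSE, lam = 0.001),
                   list(l1 = TRUE, lam = 0.01), list(l1 = TRUE, lam = 0.1))) {
    mine <- serpbci:::cpp_lr_fit(x, y, cfg$lam, cfg$l1)
    ref <- glmnet::glmnet(x, y, family = "binomial",
                          alpha = as.numeric(cfg$l1), lambda = cfg$lam,
                          standardize = FALSE, thresh = 1e-12)
    expect_equal(mine, c(ref$a0, as.numeric(ref$beta)), tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("linear SVM agrees with e1071 on well-separated data", {
  d <- toy_data(40, p = 5, separation = 4, seed = 11)
  x <- scale(d$x)
  y01 <- as.integer(d$y == "AV")
  mine <- serpbci:::cpp_svm_fit(x, y01, 1, "linear", 0)
  pred_mine <- as.integer(serpbci:::cpp_svm_decision(mine, x) > 0)
  ref <- e1071::svm(x, factor(y01), kernel = "linear", cost = 1, scale = FALSE)
  pred_ref <- as.integer(as.character(predict(ref, x)))
  expect_gte(mean(pred_mine == pred_ref), 0.975)
  expect_equal(mean(pred_mine == y01), 1)
})

test_that("RBF SVM separates concentric classes where the linear kernel cannot", {
  set.seed(21)
  n <- 120
  x <- matrix(rnorm(n * 2), n)
  y01 <- as.integer(sqrt(rowSums(x^2)) > 1.2)
  lin <- serpbci:::cpp_svm_fit(x, y01, 10, "linear", 0)
  rbf <- serpbci:::cpp_svm_fit(x, y01, 10, "rbf", 0.5)
  acc_lin <- mean((serpbci:::cpp_svm_decision(lin, x) > 0) == (y01 == 1))
  acc_rbf <- mean((serpbci:::cpp_svm_decision(rbf, x) > 0) == (y01 == 1))
  expect_lt(acc_lin, 0.75)
  expect_gt(acc_rbf, 0.95)
  ref <- e1071::svm(x, factor(y01), kernel = "radial", gamma = 0.5, cost = 10,
                    scale = FALSE)
  acc_ref <- mean(predict(ref, x) == factor(y01))
  expect_gt(acc_ref, 0.95)  # same conclusion from the independent fit
})

test_that("KNN predictions match class::knn exactly away from distance boundaries", {
  # class::knn pulls in any neighbour within a small relative tolerance of
  # the kth distance (and then breaks the enlarged vote at random), so the
  # exact comparison excludes test points whose kth/(k+1)th neighbour
  # distances nearly coincide.
  set.seed(31)
  xtr <- matrix(rnorm(80 * 4), 80)
  ytr <- as.integer(runif(80) > 0.5)
  xte <- matrix(rnorm(40 * 4), 40)
  for (k in c(5, 9, 15)) {  # odd k: no vote ties in a binary problem
    clean <- vapply(seq_len(nrow(xte)), function(i) {
      d <- sort(sqrt(colSums((t(xtr) - xte[i, ])^2)))
      d[k + 1] / d[k] > 1.001
    }, logical(1))
    expect_gt(sum(clean), 30)
    mine <- serpbci:::cpp_knn_predict(xtr, ytr, xte, k)
    ref <- as.integer(as.character(class::knn(xtr, xte, factor(ytr), k = k)))
    expect_identical(as.integer(mine)[clean], ref[clean])
  }
})

test_that("random forest matches randomForest accuracy on an easy problem and is seed-stable", {
  d <- toy_data(60, p = 8, separation = 3, seed = 41)
  y01 <- as.integer(d$y == "AV")
  xte <- toy_data(60, p = 8, separation = 3, seed = 42)
  yte <- as.integer(xte$y == "AV")
  mine <- serpbci:::cpp_rf_fit(d$x, y01, 30L, 5L, "gini", 7L)
  acc_mine <- mean(serpbci:::cpp_rf_predict(mine, xte$x) == yte)
  ref <- randomForest::randomForest(d$x, factor(y01), ntree = 30)
  acc_ref <- mean(as.integer(as.character(predict(ref, xte$x))) == yte)
  expect_gt(acc_mine, 0.9)
  expect_gt(acc_ref, 0.9)
  expect_lt(abs(acc_mine - acc_ref), 0.1)
  # entropy criterion also learns; identical seeds give identical forests
  ent <- serpbci:::cpp_rf_fit(d$x, y01, 30L, 5L, "entropy", 7L)
  expect_gt(mean(serpbci:::cpp_rf_predict(ent, xte$x) == yte), 0.9)
  again <- serpbci:::cpp_rf_fit(d$x, y01, 30L, 5L, "gini", 7L)
  expect_identical(serpbci:::cpp_rf_predict(again, xte$x),
                   serpbci:::cpp_rf_predict(mine, xte$x))
})

test_that("the perceptron's training loss decreases and fits separable data", {
  d <- toy_data(50, p = 6, separation = 5, seed = 51)
  x <- scale(d$x)
  y01 <- as.numeric(d$y == "AV")
  m <- serpbci:::cpp_mlp_fit(x, y01, 32L, 8L, 1e-3, 200L, 20L, 0.15, 9L)
  loss <- m$train_loss
  expect_gt(length(loss), 5)
  expect_lt(loss[length(loss)], loss[1])
  expect_gt(mean((serpbci:::cpp_mlp_predict_prob(m, x) > 0.5) == (y01 == 1)), 0.95)
  # seeded initialization: bit-identical refit
  m2 <- serpbci:::cpp_mlp_fit(x, y01, 32L, 8L, 1e-3, 200L, 20L, 0.15, 9L)
  expect_identical(m$W1, m2$W1)
})

test_that("classifier specs carry the documented hyperparameter grids", {
  lr <- classifier_spec("lr")
  expect_setequal(unique(lr$grid$penalty), c("l1", "l2"))
  expect_setequal(unique(lr$grid$strength), c(0.001, 0.01, 0.1, 1))
  expect_equal(nrow(lr$grid), 8)
  expect_equal(lr$sfs_defaults, list(penalty = "l2", strength = 0.1))

  knn <- classifier_spec("knn")
  expect_equal(knn$grid$k, 5:20)
  expect_equal(knn$sfs_defaults$k, 10L)

  svm <- classifier_spec("svm")
  expect_equal(nrow(svm$grid), 20)  # 4 linear + 16 rbf
  expect_true(all(is.na(svm$grid$gamma[svm$grid$kernel == "linear"])))
  expect_setequal(unique(svm$grid$C), c(0.1, 1, 10, 100))
  expect_setequal(unique(svm$grid$gamma[svm$grid$kernel == "rbf"]),
                  c(0.001, 0.01, 0.1, 1))
  expect_equal(svm$sfs_defaults$kernel, "linear")
  expect_equal(svm$sfs_defaults$C, 1)

  rf <- classifier_spec("rf")
  expect_equal(nrow(rf$grid), 60)
  expect_setequal(unique(rf$grid$n_trees), c(20, 25, 30, 35, 40))
  expect_equal(sort(unique(rf$grid$max_depth)), 5:10)
  expect_setequal(unique(rf$grid$criterion), c("gini", "entropy"))
  rf_full <- classifier_spec("rf", rf_trees_step = 1)
  expect_setequal(unique(rf_full$grid$n_trees), 20:40)
  expect_equal(rf$sfs_defaults, list(n_trees = 30L, max_depth = 5L,
                                     criterion = "gini"))

  ann <- classifier_spec("ann")
  expect_setequal(unique(ann$grid$batch), c(4, 8, 16))
  expect_setequal(unique(ann$grid$learning_rate), 10^(-4:-1))
  expect_equal(ann$sfs_defaults, list(batch = 8L, learning_rate = 1e-3))
})
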