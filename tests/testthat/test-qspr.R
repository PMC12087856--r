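test_that("Cohen's kappa reproduces hand-computed confusion matrices", {
  expect_equal(cohen_kappa(diag(c(10, 10))), 1)
  expect_equal(cohen_kappa(matrix(5, 2, 2)), 0)
  expect_equal(cohen_kappa(rbind(c(20, 5), c(10, 15))), 0.4)
  expect_error(cohen_kappa(matrix(1, 2, 3)), "square")
})

test_that("kappa matches the observed/expected-agreement form on random matrices", {
  set.seed(14)
  for (i in 1:300) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, sample(1:20, 1)), k, k)
    if (sum(cm) == 0) cm[1, 1] <- 1
    expect_lt(abs(cohen_kappa(cm) - brute_kappa(cm)), 1e-12)
  }
})

test_that("accuracy and kappa are invariant under class relabeling", {
  set.seed(15)
  cm <- matrix(rpois(25, 6), 5, 5)
  perm <- sample(5)
  cmp <- cm[perm, perm]
  expect_equal(cohen_kappa(cm), cohen_kappa(cmp))
  expect_equal(sum(diag(cm)) / sum(cm), sum(diag(cmp)) / sum(cmp))
})

test_that("confusion matrices carry true rows, predicted columns", {
  truth <- c("Surface", "Surface", "SC", "Dermis")
  pred <- c("Surface", "SC", "SC", "Distant")
  cm <- confusion_matrix(truth, pred)
  expect_equal(cm["Surface", "Surface"], 1)
  expect_equal(cm["Surface", "SC"], 1)
  expect_equal(cm["Dermis", "Distant"], 1)
  expect_equal(sum(cm), 4)
  expect_warning(confusion_matrix(truth, c("Surface", "SC", "SC", "Weird")),
                 "Weird")
})

test_that("VIP scores satisfy the normalization identity and hand cases", {
  # J = 1: identity
  expect_equal(unname(vip_scores(matrix(1, 1, 3), c(2, 1, 1))), 1)
  # J = 4, one component, equal weights: symmetry gives all 1
  expect_equal(unname(vip_scores(matrix(0.5, 4, 1), 3)), rep(1, 4))
  # J = 3, two components, unequal SSY: direct formula evaluation
  W <- cbind(c(0.8, 0.6, 0), c(0, 0.6, 0.8))
  ssy <- c(3, 1)
  v <- vip_scores(W, ssy)
  expect_equal(unname(v),
               sqrt(3 * (W^2 %*% ssy) / sum(ssy))[, 1])
  # sum(VIP^2) = J on random valid inputs
  set.seed(16)
  for (i in 1:50) {
    J <- sample(2:12, 1); F_ <- sample(1:5, 1)
    W <- matrix(rnorm(J * F_), J, F_)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    v <- vip_scores(W, runif(F_, 0.1, 5))
    expect_equal(sum(v^2), J, tolerance = 1e-9)
  }
  expect_error(vip_scores(matrix(1, 2, 1), 0), "zero total")
})

test_that("PLS-DA fits, predicts factors, and exposes VIP per feature", {
  fx <- fixture_noiseless()
  X <- fx$fm$values; y <- fx$fm$depth
  m <- pls_da_fit(X, y, ncomp = 4)
  p <- pls_da_vip(m)
  expect_length(p, ncol(X))
  expect_equal(sum(p^2), ncol(X), tolerance = 1e-9)
  expect_true(all(names(p) == colnames(X)))
})

test_that("training is deterministic given spec, seed and data", {
  fx <- fixture_noiseless()
  X <- fx$fm$values; y <- fx$fm$depth
  for (fam in c("random_forest", "decision_tree", "ksvm")) {
    m1 <- train_classifier(classifier_spec(fam, seed = 3), X[1:200, ],
                           y[1:200])
    m2 <- train_classifier(classifier_spec(fam, seed = 3), X[1:200, ],
                           y[1:200])
    expect_identical(predict(m1, X[201:300, ]), predict(m2, X[201:300, ]),
                     info = fam)
  }
})

test_that("separable training data are interpolated", {
  fx <- fixture_noiseless()
  X <- fx$fm$values; y <- fx$fm$depth
  m <- train_classifier(classifier_spec("random_forest", seed = 1), X, y)
  expect_equal(evaluate(m, X, y)$accuracy, 100)

  # 2-point, 2-class toy: a decision tree splits perfectly
  Xt <- rbind(c(0, 0), c(1, 1)); colnames(Xt) <- c("f1", "f2")
  yt <- factor(c("Surface", "Dermis"), levels = depth_levels())
  mt <- train_classifier(classifier_spec("decision_tree", seed = 1,
                                         cp = 0.001, minsplit = 1), Xt, yt)
  expect_equal(as.character(predict(mt, Xt)), as.character(yt))

  expect_error(train_classifier(classifier_spec("knn"), Xt,
                                factor(c("SC", "SC"))), "single class")
})

test_that("evaluation reports percent accuracy, kappa and the confusion matrix", {
  fx <- fixture_noiseless()
  X <- fx$fm$values; y <- fx$fm$depth
  m <- train_classifier(classifier_spec("decision_tree", seed = 1), X, y)
  ev <- evaluate(m, X, y)
  expect_equal(ev$accuracy, 100 * sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(ev$kappa, cohen_kappa(ev$confusion))
  expect_error(evaluate(m, X[0, ], y[0]), "empty")
})

test_that("the selection grid has the published table shape and is reproducible", {
  fx <- fixture_default()
  X <- fx$fmc$values; y <- fx$fmc$depth
  g <- selection_grid(X, y, splitters = c("random", "kennard_stone"),
                      classifiers = c("decision_tree", "random_forest"),
                      seed = 5)
  expect_equal(dim(g$accuracy), c(3, 3))
  expect_equal(rownames(g$accuracy)[3], "Average")
  expect_equal(colnames(g$accuracy)[3], "Average")
  expect_equal(g$accuracy["decision_tree", "Average"],
               mean(g$accuracy["decision_tree", 1:2]))
  expect_true(all(g$accuracy >= 0 & g$accuracy <= 100))
  expect_length(g$confusions, 4)

  g2 <- selection_grid(X, y, splitters = c("random", "kennard_stone"),
                       classifiers = c("decision_tree", "random_forest"),
                       seed = 5)
  expect_identical(g$accuracy, g2$accuracy)
})

test_that("permutation importance recovers the planted dominance structure", {
  fx <- fixture_noiseless()
  X <- fx$fm$values; y <- fx$fm$depth
  tr <- 1:220; va <- 221:300
  m <- train_classifier(classifier_spec("random_forest", seed = 1),
                        X[tr, ], y[tr])
  imp <- permutation_importance(m, X[va, ], y[va],
                                groups = fx$fm$encoding_map,
                                n_repeats = 5, seed = 1)
  expect_equal(imp$feature[1], "hf_diameter")
  expect_equal(imp$importance[1], 100)
  # a descriptor absent from the rule and uncorrelated with it stays low
  expect_lt(imp$importance[imp$feature == "contact_time"], 15)
  expect_true(all(depth_levels() %in% names(imp)))
})

test_that("destroying the labels zeroes all importances", {
  fx <- fixture_noiseless()
  X <- fx$fm$values; y <- fx$fm$depth
  m <- train_classifier(classifier_spec("random_forest", seed = 1),
                        X[1:220, ], y[1:220])
  set.seed(99)
  y_shuffled <- sample(y[221:300])
  imp <- permutation_importance(m, X[221:300, ], y_shuffled,
                                groups = fx$fm$encoding_map,
                                n_repeats = 5, seed = 2)
  expect_lt(max(imp$raw), 5) # accuracy drops are pure noise
})
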