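# QSPR classifiers and evaluation. Five families: decision tree (rpart),
# random forest (randomForest, 500 trees, vote ties broken toward the
# shallower layer), k-nearest neighbours (class::knn), PLS-DA (own NIPALS
# implementation, see pls_vip.R) and kernel SVM (kernlab::ksvm, RBF kernel
# with median-heuristic width). When validation data are supplied each
# family runs a small documented grid search (mtry, k, C, cp, ncomp) picked
# by validation accuracy. Evaluation reports exact-class accuracy and
# Cohen's kappa computed from the confusion matrix.

#' Classifier specification
#'
#' @param family One of "decision_tree", "random_forest", "knn", "pls_da",
#'   "ksvm".
#' @param seed Integer seed for stochastic learners.
#' @param ... Family hyperparameters: `trees` (random forest, default 500)
#'   and `mtry`, `k` (knn, default 5), `ncomp` (pls_da, up to 10), `C`
#'   (ksvm, default 1), `cp`/`minsplit` (decision tree). Hyperparameters
#'   left NULL are tuned by a small grid search on validation data when
#'   `train_classifier` receives it, otherwise they fall back to the
#'   stated defaults.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(family = c("decision_tree", "random_forest",
                                       "knn", "pls_da", "ksvm"),
                            seed = 1, ...) {
  family <- match.arg(family)
  hp <- list(...)
  defaults <- switch(family,
    decision_tree = list(cp = NULL, minsplit = 5),
    random_forest = list(trees = 500, mtry = NULL),
    knn = list(k = NULL),
    pls_da = list(ncomp = NULL),
    ksvm = list(C = NULL))
  for (nm in names(defaults))
    if (is.null(hp[[nm]])) hp[[nm]] <- defaults[[nm]]
  if (family == "random_forest" && hp$trees < 1)
    stop("classifier_spec: trees must be >= 1")
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)), class = "classifier_spec")
}

#' Train a QSPR classifier
#'
#' @param spec A `classifier_spec`.
#' @param X_train Numeric feature matrix (standardized, complete).
#' @param y_train Factor of depth classes (>= 2 classes present).
#' @param X_valid,y_valid Optional validation data used only for
#'   hyperparameter tuning (PLS-DA component count).
#' @return A `qspr_model` with `predict` and `print` methods.
#' @export
train_classifier <- function(spec, X_train, y_train,
                             X_valid = NULL, y_valid = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  X_train <- as.matrix(X_train)
  y_train <- factor(y_train, levels = depth_levels())
  y_train <- droplevels(y_train)
  if (nlevels(y_train) < 2)
    stop("train_classifier: training data contain a single class")
  hp <- spec$hyperparameters
  p <- ncol(X_train)
  has_valid <- !is.null(X_valid) && !is.null(y_valid)
  # pick the candidate with the best validation accuracy (first on ties);
  # without validation data fall back to the first candidate
  tune <- function(candidates, fit_fun, pred_fun) {
    if (length(candidates) == 1L || !has_valid) return(candidates[1])
    yv <- factor(y_valid, levels = levels(y_train))
    accs <- vapply(candidates, function(v) {
      set.seed(spec$seed)
      mean(pred_fun(fit_fun(v)) == yv, na.rm = TRUE)
    }, numeric(1))
    candidates[which.max(accs)]
  }
  Xv <- if (has_valid) as.matrix(X_valid) else NULL
  set.seed(spec$seed)
  fit <- switch(spec$family,
    decision_tree = {
      df <- data.frame(.y = y_train, X_train, check.names = TRUE)
      dfv <- if (has_valid) data.frame(Xv, check.names = TRUE) else NULL
      fit1 <- function(cp)
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = cp,
                                                    minsplit = hp$minsplit))
      cp <- if (is.null(hp$cp))
        tune(c(0.001, 0.01, 1e-4), fit1,
             function(m) stats::predict(m, newdata = dfv, type = "class"))
      else hp$cp
      hp$cp <- cp
      set.seed(spec$seed)
      fit1(cp)
    },
    random_forest = {
      fit1 <- function(mtry) randomForest::randomForest(
        x = X_train, y = y_train, ntree = hp$trees, mtry = mtry)
      mtry <- if (is.null(hp$mtry))
        tune(unique(pmax(1L, c(floor(sqrt(p)), floor(p / 4), floor(p / 2)))),
             fit1, function(m) stats::predict(m, newdata = Xv))
      else hp$mtry
      hp$mtry <- mtry
      set.seed(spec$seed)
      fit1(mtry)
    },
    knn = {
      k <- if (is.null(hp$k))
        tune(c(5L, 1L, 3L, 9L, 15L), function(k) k,
             function(k) class::knn(X_train, Xv, y_train, k = k))
      else hp$k
      hp$k <- k
      list(X = X_train, y = y_train, k = k)
    },
    pls_da = {
      cap <- min(10L, p, nrow(X_train) - 1L)
      ncomp <- if (is.null(hp$ncomp))
        tune(c(cap, seq_len(cap)), function(f) f,
             function(f) pls_da_predict(pls_da_fit(X_train, y_train,
                                                   ncomp = f), Xv))
      else hp$ncomp
      hp$ncomp <- ncomp
      pls_da_fit(X_train, y_train, ncomp = ncomp)
    },
    ksvm = {
      fit1 <- function(C) kernlab::ksvm(x = X_train, y = y_train,
                                        kernel = "rbfdot",
                                        kpar = "automatic", C = C,
                                        scaled = FALSE)
      C <- if (is.null(hp$C))
        tune(c(1, 10, 100), fit1, function(m) kernlab::predict(m, Xv))
      else hp$C
      hp$C <- C
      set.seed(spec$seed)
      fit1(C)
    })
  spec$hyperparameters <- hp
  structure(list(spec = spec, fit = fit, classes = levels(y_train),
                 feature_names = colnames(X_train)),
            class = "qspr_model")
}

#' @export
predict.qspr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  fam <- object$spec$family
  out <- switch(fam,
    decision_tree = {
      df <- data.frame(X, check.names = TRUE)
      as.character(stats::predict(object$fit, newdata = df, type = "class"))
    },
    random_forest = {
      votes <- stats::predict(object$fit, newdata = X, type = "vote",
                              norm.votes = FALSE)
      # ties broken toward the shallower layer: first max in depth order
      ord <- order(match(colnames(votes), depth_levels()))
      votes <- votes[, ord, drop = FALSE]
      colnames(votes)[apply(votes, 1, which.max)]
    },
    knn = {
      set.seed(object$spec$seed)
      as.character(class::knn(object$fit$X, X, object$fit$y,
                              k = object$fit$k))
    },
    pls_da = as.character(pls_da_predict(object$fit, X)),
    ksvm = as.character(kernlab::predict(object$fit, X)))
  factor(out, levels = depth_levels())
}

#' @export
print.qspr_model <- function(x, ...) {
  cat("QSPR classifier:", x$spec$family, "|",
      length(x$classes), "classes |",
      length(x$feature_names), "features\n")
  invisible(x)
}

#' Confusion matrix of true vs predicted classes
#'
#' Rows are true classes, columns predicted classes, over the union of the
#' five depth levels. Predictions outside the model's class set fall in
#' their own column and count as errors (with a warning).
#'
#' @param truth,pred Factors or characters of depth classes.
#' @return A `confusion_matrix` (integer matrix).
#' @export
confusion_matrix <- function(truth, pred) {
  levs <- depth_levels()
  extra <- setdiff(unique(as.character(pred)), c(levs, NA))
  if (length(extra)) {
    warning("confusion_matrix: prediction level(s) outside class set: ",
            paste(extra, collapse = ", "))
    levs <- c(levs, extra)
  }
  t_f <- factor(as.character(truth), levels = levs)
  p_f <- factor(as.character(pred), levels = levs)
  m <- table(truth = t_f, predicted = p_f)
  structure(unclass(m), class = c("confusion_matrix", "matrix"))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: with N the total count, m_ii the diagonal,
#' G_i the row (true-class) totals and C_i the column (predicted-class)
#' totals, kappa = (N * sum(m_ii) - sum(G_i * C_i)) / (N^2 - sum(G_i * C_i)).
#'
#' @param cm Square count matrix (rows true, columns predicted).
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("cohen_kappa: matrix must be square")
  N <- sum(cm)
  if (N == 0) stop("cohen_kappa: empty confusion matrix")
  gc <- sum(rowSums(cm) * colSums(cm))
  denom <- N^2 - gc
  if (denom == 0) return(1) # all mass in one (true, predicted) pair
  (N * sum(diag(cm)) - gc) / denom
}

#' Evaluate a classifier on labelled data
#'
#' @param model A `qspr_model`.
#' @param X Feature matrix.
#' @param y True depth classes.
#' @return List with `accuracy` (percent), `kappa`, `confusion`.
#' @export
evaluate <- function(model, X, y) {
  if (length(y) == 0L) stop("evaluate: empty evaluation set")
  pred <- stats::predict(model, X)
  cm <- confusion_matrix(y, pred)
  list(accuracy = 100 * sum(diag(cm)) / sum(cm),
       kappa = cohen_kappa(cm), confusion = cm)
}

#' Splitter-by-classifier selection grid
#'
#' Runs every splitting method against every classifier family and reports
#' hold-out accuracy in a grid with row and column averages, mirroring a
#' model-selection table. k-NN is implemented but excluded from the
#' headline grid by default. The per-cell hold-out confusion matrices are
#' retained.
#'
#' @param X Standardized, complete feature matrix (all records).
#' @param y Factor of depth classes.
#' @param splitters Splitting methods (columns).
#' @param classifiers Classifier families (rows).
#' @param seed Integer seed.
#' @param holdout_fraction,train_frac Passed to `rational_split`.
#' @return A `selection_grid`: list with `accuracy` (matrix with Average
#'   row/column), `kappa`, `confusions`, `splits`, `seed`.
#' @export
selection_grid <- function(X, y,
                           splitters = c("random", "kennard_stone",
                                         "kmeans", "som"),
                           classifiers = c("pls_da", "decision_tree",
                                           "ksvm", "random_forest"),
                           seed = 1, holdout_fraction = 0.2,
                           train_frac = 0.75) {
  X <- as.matrix(X)
  y <- factor(y, levels = depth_levels())
  acc <- matrix(NA_real_, nrow = length(classifiers),
                ncol = length(splitters),
                dimnames = list(classifiers, splitters))
  kap <- acc
  confusions <- list()
  splits <- list()
  for (sp in splitters) {
    spl <- rational_split(X, method = sp, holdout_fraction = holdout_fraction,
                          train_frac = train_frac, seed = seed)
    splits[[sp]] <- spl
    for (cf in classifiers) {
      model <- train_classifier(classifier_spec(cf, seed = seed),
                                X[spl$train_ids, , drop = FALSE],
                                y[spl$train_ids],
                                X[spl$validation_ids, , drop = FALSE],
                                y[spl$validation_ids])
      ev <- evaluate(model, X[spl$holdout_ids, , drop = FALSE],
                     y[spl$holdout_ids])
      acc[cf, sp] <- ev$accuracy
      kap[cf, sp] <- ev$kappa
      confusions[[paste(cf, sp, sep = ".")]] <- ev$confusion
    }
  }
  acc_full <- cbind(acc, Average = rowMeans(acc))
  acc_full <- rbind(acc_full, Average = colMeans(acc_full))
  structure(list(accuracy = acc_full, kappa = kap, confusions = confusions,
                 splits = splits, seed = seed), class = "selection_grid")
}

#' @export
print.selection_grid <- function(x, digits = 1, ...) {
  cat("Hold-out accuracy [%] by classifier (rows) and splitter (columns):\n")
  print(round(x$accuracy, digits))
  invisible(x)
}
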