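# Grouped permutation importance. Importance of a descriptor is the mean
# drop in accuracy when all encoded columns belonging to that descriptor
# (e.g. a one-hot group, or hydrophobicity value + scale indicator) are
# jointly row-permuted. Scores are rescaled so the top descriptor of the
# overall model maps to 100, matching a bounded comparative importance
# axis; per-layer importance uses one-vs-rest accuracy of the same
# multiclass predictions.

#' Grouped permutation importance
#'
#' @param model A `qspr_model`.
#' @param X_val Feature matrix of the evaluation set.
#' @param y_val True depth classes of the evaluation set.
#' @param groups Named list mapping descriptor name -> encoded column names
#'   (e.g. the `encoding_map` of a `feature_matrix`). Defaults to one group
#'   per column.
#' @param n_repeats Permutations per group (default 10).
#' @param seed Integer seed.
#' @param per_layer If TRUE also compute one-vs-rest importance per depth
#'   class.
#' @return An `importance_table`: data.frame with `feature`, `raw` (mean
#'   accuracy drop, percentage points), `importance` (0-100 rescaled),
#'   optionally one column per layer; attribute `"baseline_accuracy"`.
#' @export
permutation_importance <- function(model, X_val, y_val, groups = NULL,
                                   n_repeats = 10, seed = 1,
                                   per_layer = TRUE) {
  X_val <- as.matrix(X_val)
  y_val <- factor(y_val, levels = depth_levels())
  if (is.null(groups))
    groups <- stats::setNames(as.list(colnames(X_val)), colnames(X_val))
  groups <- lapply(groups, intersect, colnames(X_val))
  groups <- groups[lengths(groups) > 0]

  acc <- function(pred, truth) 100 * mean(pred == truth, na.rm = TRUE)
  ovr <- function(pred, truth, layer)
    100 * mean((pred == layer) == (truth == layer), na.rm = TRUE)

  base_pred <- stats::predict(model, X_val)
  base_acc <- acc(base_pred, y_val)
  base_ovr <- vapply(depth_levels(), function(l) ovr(base_pred, y_val, l),
                     numeric(1))

  n <- nrow(X_val)
  set.seed(seed)
  drops <- matrix(0, nrow = length(groups), ncol = n_repeats,
                  dimnames = list(names(groups), NULL))
  layer_drops <- array(0, dim = c(length(groups), length(depth_levels()),
                                  n_repeats),
                       dimnames = list(names(groups), depth_levels(), NULL))
  for (r in seq_len(n_repeats)) {
    perm <- sample(n)
    for (g in names(groups)) {
      cols <- groups[[g]]
      if (all(apply(X_val[, cols, drop = FALSE], 2,
                    function(v) length(unique(v)) == 1L))) next # constant
      Xp <- X_val
      Xp[, cols] <- X_val[perm, cols, drop = FALSE]
      pred <- stats::predict(model, Xp)
      drops[g, r] <- base_acc - acc(pred, y_val)
      if (per_layer)
        layer_drops[g, , r] <- base_ovr -
          vapply(depth_levels(), function(l) ovr(pred, y_val, l), numeric(1))
    }
  }
  raw <- rowMeans(drops)
  top <- max(raw, 0)
  scale <- if (top > 0) 100 / top else 0
  out <- data.frame(feature = names(groups), raw = raw,
                    importance = pmax(raw, 0) * scale,
                    row.names = NULL)
  if (per_layer) {
    lm_ <- apply(layer_drops, c(1, 2), mean)
    lm_ <- pmax(lm_, 0) * scale
    out <- cbind(out, as.data.frame(lm_))
  }
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "baseline_accuracy") <- base_acc
  class(out) <- c("importance_table", "data.frame")
  out
}

#' @export
print.importance_table <- function(x, n = 10, ...) {
  cat("Permutation importance (0-100; baseline accuracy ",
      round(attr(x, "baseline_accuracy"), 1), "%):\n", sep = "")
  print.data.frame(utils::head(
    data.frame(feature = x$feature, importance = round(x$importance, 1)), n))
  invisible(x)
}
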