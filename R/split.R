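# Hold-out partitioning and rational division. The hold-out cut is always
# random; the modeling set is divided into training and validation either
# randomly or by one of three rational, distance-based methods
# (Kennard-Stone, k-means with elbow selection, Kohonen self-organizing
# map), all applied to the standardized, imputed feature matrix with
# one-hot categoricals included. The default inner ratio is 75:25, giving
# 60:20:20 overall.

#' Random hold-out split
#'
#' @param ids Vector of record ids.
#' @param fraction Hold-out fraction in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return List with `modeling_ids` and `holdout_ids`;
#'   `length(holdout_ids) == round(fraction * length(ids))`.
#' @export
holdout_split <- function(ids, fraction = 0.2, seed = 1) {
  if (length(ids) < 5) stop("holdout_split: need at least 5 records")
  if (fraction <= 0 || fraction >= 1)
    stop("holdout_split: fraction must lie in (0, 1)")
  set.seed(seed)
  n_hold <- round(fraction * length(ids))
  hold <- sort(sample(seq_along(ids), n_hold))
  list(modeling_ids = ids[-hold], holdout_ids = ids[hold])
}

#' Kennard-Stone sequential selection
#'
#' Selects `n_select` rows covering feature space: the first two selections
#' are a maximal-Euclidean-distance pair; each subsequent selection
#' maximizes its minimum distance to the already-selected set. Ties are
#' broken toward the lowest row index, making the selection deterministic.
#'
#' @param X Numeric matrix (standardized features, no missing values).
#' @param n_select Number of rows to select (2..nrow(X)).
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X)) stop("kennard_stone: missing values present")
  if (n_select < 2 || n_select > n)
    stop("kennard_stone: n_select must lie in [2, nrow(X)]")
  D <- as.matrix(stats::dist(X))
  # maximal pair, lowest-index tie break (row-major scan of upper triangle)
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1)) {
    j <- which.max(D[i, (i + 1):n]) + i
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  selected <- best
  if (n_select > 2) {
    mind <- pmin(D[, best[1]], D[, best[2]])
    mind[selected] <- -Inf
    for (k in 3:n_select) {
      nxt <- which.max(mind) # which.max takes the first (lowest index) tie
      selected <- c(selected, nxt)
      mind <- pmin(mind, D[, nxt])
      mind[nxt] <- -Inf
    }
  }
  as.integer(unname(selected))
}

split_assignment <- function(holdout_ids, train_ids, validation_ids, method,
                             seed, parameters = list()) {
  structure(list(holdout_ids = holdout_ids, train_ids = train_ids,
                 validation_ids = validation_ids, method = method,
                 seed = seed, parameters = parameters),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("Split (", x$method, "): train ", length(x$train_ids),
      " / validation ", length(x$validation_ids),
      " / hold-out ", length(x$holdout_ids), "\n", sep = "")
  invisible(x)
}

# proportional per-group training draw; every non-empty group contributes
# at least one training point
stratified_train_draw <- function(groups, ids, train_frac) {
  train <- integer(0)
  for (g in unique(groups)) {
    members <- ids[groups == g]
    n_tr <- max(1L, round(train_frac * length(members)))
    n_tr <- min(n_tr, length(members))
    train <- c(train, members[sample.int(length(members))[seq_len(n_tr)]])
  }
  sort(train)
}

#' Train/validation split of the modeling set by a chosen method
#'
#' Applies the hold-out cut (always random) and then divides the modeling
#' set by `method`: "random" sampling, "kennard_stone" (training = the
#' Kennard-Stone selection), "kmeans" (k chosen from `k_range` by the elbow
#' method -- largest second difference of within-cluster sum of squares --
#' then proportional per-cluster training draws), or "som" (hexagonal
#' Kohonen map, learning rate decaying over [0.05, 0.01], proportional
#' draws per occupied unit).
#'
#' @param X Standardized, complete feature matrix (all records).
#' @param method Splitting method.
#' @param holdout_fraction Random hold-out fraction (default 0.2).
#' @param train_frac Training fraction within the modeling set (default
#'   0.75, i.e. 60:20:20 overall).
#' @param k_range Candidate cluster counts for "kmeans".
#' @param grid_dim SOM grid side length; default `ceiling(sqrt(5 *
#'   sqrt(n)))` per side.
#' @param seed Integer seed.
#' @return A `split_assignment`.
#' @export
rational_split <- function(X, method = c("random", "kennard_stone",
                                         "kmeans", "som"),
                           holdout_fraction = 0.2, train_frac = 0.75,
                           k_range = 2:20, grid_dim = NULL, seed = 1) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (anyNA(X)) stop("rational_split: missing values present (impute first)")
  ids <- seq_len(nrow(X))
  hs <- holdout_split(ids, holdout_fraction, seed)
  mod_ids <- hs$modeling_ids
  Xm <- X[mod_ids, , drop = FALSE]
  n_train <- max(2L, round(train_frac * length(mod_ids)))
  set.seed(seed + 1L)
  params <- list(train_frac = train_frac)

  train_local <- switch(method,
    random = sort(sample(seq_along(mod_ids), n_train)),
    kennard_stone = sort(kennard_stone(Xm, n_train)),
    kmeans = {
      km <- kmeans_elbow(Xm, k_range, seed = seed + 1L)
      params$k <- km$k
      stratified_train_draw(km$cluster, seq_along(mod_ids), train_frac)
    },
    som = {
      sm <- som_map(Xm, grid_dim = grid_dim, seed = seed + 1L)
      params$grid_dim <- sm$grid_dim
      stratified_train_draw(sm$unit, seq_along(mod_ids), train_frac)
    })

  split_assignment(holdout_ids = hs$holdout_ids,
                   train_ids = mod_ids[train_local],
                   validation_ids = mod_ids[-train_local],
                   method = method, seed = seed, parameters = params)
}

#' k-means with elbow selection of k
#'
#' Scans `k_range`, records the within-cluster sum of squares curve, and
#' picks the k with the largest second difference (the elbow). Degenerate
#' inputs (all rows identical) force k = 1 with a warning.
#'
#' @param X Numeric matrix.
#' @param k_range Candidate k values.
#' @param seed Integer seed.
#' @return List with `k`, `cluster` (assignments), `wss` (curve).
#' @export
kmeans_elbow <- function(X, k_range = 2:20, seed = 1) {
  X <- as.matrix(X)
  if (nrow(X) < max(k_range))
    k_range <- k_range[k_range <= nrow(unique(X))]
  if (nrow(unique(X)) == 1L) {
    warning("kmeans_elbow: all rows identical; k forced to 1")
    return(list(k = 1L, cluster = rep(1L, nrow(X)), wss = 0))
  }
  set.seed(seed)
  fits <- lapply(k_range, function(k)
    suppressWarnings(stats::kmeans(X, centers = k, nstart = 5,
                                   iter.max = 50)))
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  if (length(k_range) >= 3) {
    d2 <- diff(diff(wss)) # second difference; elbow = largest curvature
    k_idx <- which.max(d2) + 1L
  } else k_idx <- 1L
  list(k = k_range[k_idx], cluster = fits[[k_idx]]$cluster, wss = wss)
}

#' Fit a hexagonal self-organizing map and assign best-matching units
#'
#' Online Kohonen SOM (class::SOM) on a hexagonal grid with the learning
#' rate decaying over [0.05, 0.01]. Returns the best-matching unit of each
#' row and a quantization-error trace over training epochs.
#'
#' @param X Numeric matrix.
#' @param grid_dim Grid side length; default `ceiling(sqrt(5 * sqrt(n)))`.
#' @param rlen Training presentations (default 100 * n).
#' @param seed Integer seed.
#' @return List with `unit` (BMU per row), `grid_dim`, `codes`,
#'   `qe_trace` (quantization error after each third of training).
#' @export
som_map <- function(X, grid_dim = NULL, rlen = NULL, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(grid_dim)) grid_dim <- max(2L, ceiling(sqrt(5 * sqrt(n))))
  if (n < grid_dim) stop("som_map: fewer records than grid side")
  if (is.null(rlen)) rlen <- 100L * n
  grid <- class::somgrid(xdim = grid_dim, ydim = grid_dim,
                         topo = "hexagonal")
  qe <- function(codes) {
    d <- outer(rowSums(X^2), rowSums(codes^2), "+") - 2 * X %*% t(codes)
    mean(sqrt(pmax(apply(d, 1, min), 0)))
  }
  set.seed(seed)
  stages <- 3L
  init <- X[sample(n, grid_dim^2, replace = n < grid_dim^2), , drop = FALSE]
  codes <- init
  qe_trace <- numeric(stages)
  alphas <- seq(0.05, 0.01, length.out = rlen)
  radii <- seq(4, 1, length.out = rlen)
  per <- rlen %/% stages
  for (s in seq_len(stages)) {
    idx <- ((s - 1) * per + 1):(if (s == stages) rlen else s * per)
    fit <- class::SOM(X, grid, rlen = length(idx), alpha = alphas[idx],
                      radii = radii[idx], init = codes)
    codes <- fit$codes
    qe_trace[s] <- qe(codes)
  }
  d <- outer(rowSums(X^2), rowSums(codes^2), "+") - 2 * X %*% t(codes)
  list(unit = apply(d, 1, which.min), grid_dim = grid_dim, codes = codes,
       qe_trace = qe_trace)
}
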