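# Applicability domain: PCA to a few components, then the convex hull of
# the training scores. Membership is a facet test (all half-space
# inequalities satisfied), which vectorises over large in-silico
# populations. The 3-D hull is built by an incremental beneath-beyond
# algorithm (quickhull family); 2-D uses the monotone-chain hull from
# grDevices::chull; 1-D reduces to the score range.

# ---- convex hull facets ----------------------------------------------------

# incremental 3-D convex hull; returns list(normals = F x 3, offsets = F)
# with outward normals: interior satisfies normals %*% x <= offsets.
hull3d_facets <- function(P, eps = NULL) {
  P <- unique(as.matrix(P))
  n <- nrow(P)
  if (is.null(eps)) {
    diam <- max(apply(P, 2, function(v) diff(range(v))), 1)
    eps <- 1e-12 * diam
  }
  # initial simplex: extreme pair, farthest from line, farthest from plane
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (i1 == i2) { i1 <- which.min(P[, 2]); i2 <- which.max(P[, 2]) }
  a <- P[i1, ]; b <- P[i2, ]
  ab <- b - a
  d_line <- vapply(seq_len(n), function(i) {
    v <- P[i, ] - a
    sqrt(max(sum(v^2) - (sum(v * ab))^2 / sum(ab^2), 0))
  }, numeric(1))
  i3 <- which.max(d_line)
  nrm0 <- pracma_cross(P[i3, ] - a, ab)
  d_plane <- abs((P %*% nrm0) - sum(nrm0 * a))
  i4 <- which.max(d_plane)
  if (d_plane[i4] <= eps)
    stop("hull3d_facets: points are coplanar (rank < 3)")
  verts <- c(i1, i2, i3, i4)
  centroid <- colMeans(P[verts, ])

  make_face <- function(i, j, k) {
    nrm <- pracma_cross(P[j, ] - P[i, ], P[k, ] - P[i, ])
    nn <- sqrt(sum(nrm^2))
    if (nn < eps) return(NULL)
    nrm <- nrm / nn
    off <- sum(nrm * P[i, ])
    if (sum(nrm * centroid) > off) { nrm <- -nrm; off <- -off }
    list(v = c(i, j, k), n = nrm, o = off)
  }
  faces <- list(make_face(i1, i2, i3), make_face(i1, i2, i4),
                make_face(i1, i3, i4), make_face(i2, i3, i4))
  faces <- Filter(Negate(is.null), faces)

  for (p in setdiff(seq_len(n), verts)) {
    vis <- vapply(faces, function(f) sum(f$n * P[p, ]) > f$o + eps,
                  logical(1))
    if (!any(vis)) next
    # horizon = edges appearing exactly once among visible faces
    edge_key <- function(i, j) paste(min(i, j), max(i, j))
    tab <- new.env(parent = emptyenv())
    for (f in faces[vis]) {
      v <- f$v
      for (e in list(c(v[1], v[2]), c(v[1], v[3]), c(v[2], v[3]))) {
        k <- edge_key(e[1], e[2])
        assign(k, c(if (exists(k, tab)) get(k, tab) else integer(0), e),
               envir = tab)
      }
    }
    horizon <- list()
    for (k in ls(tab)) {
      v <- get(k, tab)
      if (length(v) == 2L) horizon[[length(horizon) + 1L]] <- v
    }
    faces <- faces[!vis]
    centroid <- colMeans(rbind(P[unique(unlist(lapply(faces, `[[`, "v"))), ,
                                 drop = FALSE], P[p, , drop = FALSE]))
    for (e in horizon) {
      f <- make_face(e[1], e[2], p)
      if (!is.null(f)) faces[[length(faces) + 1L]] <- f
    }
  }
  list(normals = do.call(rbind, lapply(faces, `[[`, "n")),
       offsets = vapply(faces, `[[`, numeric(1), "o"),
       vertices = sort(unique(unlist(lapply(faces, `[[`, "v")))))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

hull2d_facets <- function(P) {
  P <- unique(as.matrix(P))
  h <- grDevices::chull(P[, 1], P[, 2]) # counter-clockwise vertex order
  k <- length(h)
  centroid <- colMeans(P[h, , drop = FALSE])
  normals <- matrix(0, k, 2); offsets <- numeric(k)
  for (i in seq_len(k)) {
    a <- P[h[i], ]; b <- P[h[if (i == k) 1 else i + 1], ]
    e <- b - a
    nrm <- c(e[2], -e[1]); nrm <- nrm / sqrt(sum(nrm^2))
    off <- sum(nrm * a)
    if (sum(nrm * centroid) > off) { nrm <- -nrm; off <- -off }
    normals[i, ] <- nrm; offsets[i] <- off
  }
  list(normals = normals, offsets = offsets, vertices = sort(h))
}

# ---- applicability domain --------------------------------------------------

#' Fit a convex-hull applicability domain in PC space
#'
#' Reduces the training matrix to `d` principal components (default 3) and
#' takes the convex hull of the scores as the applicability domain: the
#' smallest convex set containing all training points. A rank-deficient
#' training matrix reduces `d` with a warning.
#'
#' @param X_train Standardized, complete training feature matrix.
#' @param d Number of principal components for the hull (1-3).
#' @return An `applicability_domain` with the PCA basis and hull facets.
#' @export
fit_applicability_domain <- function(X_train, d = 3) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < d + 2)
    stop("fit_applicability_domain: need more than d + 1 training points")
  pca <- stats::prcomp(X_train, center = TRUE, scale. = FALSE)
  tol_sv <- max(pca$sdev) * 1e-8
  rank <- sum(pca$sdev > tol_sv)
  if (rank < d) {
    warning("fit_applicability_domain: rank-deficient training matrix; ",
            "reducing d from ", d, " to ", rank)
    d <- rank
  }
  if (d < 1) stop("fit_applicability_domain: degenerate training matrix")
  S <- pca$x[, seq_len(d), drop = FALSE]
  hull <- if (d == 1) {
    list(normals = matrix(c(1, -1), 2, 1),
         offsets = c(max(S[, 1]), -min(S[, 1])), vertices = NULL)
  } else if (d == 2) hull2d_facets(S) else hull3d_facets(S)
  diam <- max(apply(S, 2, function(v) diff(range(v))), 1)
  structure(list(rotation = pca$rotation[, seq_len(d), drop = FALSE],
                 center = pca$center, d = d, hull = hull,
                 tol = 1e-9 * diam, n_train = nrow(X_train)),
            class = "applicability_domain")
}

#' Test points for applicability-domain membership
#'
#' @param ad An `applicability_domain`.
#' @param X Feature matrix of query points (same columns as the training
#'   matrix).
#' @return Logical vector: TRUE where the point lies inside or on the hull.
#' @export
ad_contains <- function(ad, X) {
  stopifnot(inherits(ad, "applicability_domain"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  S <- sweep(X, 2, ad$center) %*% ad$rotation
  slack <- S %*% t(ad$hull$normals) # n x F
  apply(sweep(slack, 2, ad$hull$offsets + ad$tol, "<="), 1, all)
}

#' @export
print.applicability_domain <- function(x, ...) {
  cat("Convex-hull applicability domain: d =", x$d, "PCs,",
      nrow(x$hull$normals), "facets,", x$n_train, "training points\n")
  invisible(x)
}
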