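# PLS-DA via NIPALS PLS2 on one-hot class indicators, and variable
# importance in projection (VIP). The PLS fit keeps the x-weights and the
# per-component explained sum of squares of Y that the VIP formula needs.
# Prediction is the argmax of the continuous indicator outputs.

# NIPALS PLS2. X assumed column-centered-ish (standardized upstream);
# centering is still applied internally for robustness.
nipals_pls2 <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  xmeans <- colMeans(X); ymeans <- colMeans(Y)
  E <- sweep(X, 2, xmeans); F_ <- sweep(Y, 2, ymeans)
  n <- nrow(E); J <- ncol(E); q <- ncol(F_)
  ncomp <- min(ncomp, J, n - 1L)
  W <- matrix(0, J, ncomp); P <- matrix(0, J, ncomp)
  Q <- matrix(0, q, ncomp); Tm <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  for (f in seq_len(ncomp)) {
    u <- F_[, which.max(colSums(F_^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u); wn <- sqrt(sum(w^2))
      if (wn < tol) break
      w <- w / wn
      tt <- E %*% w
      qv <- crossprod(F_, tt) / drop(crossprod(tt))
      u <- F_ %*% qv / drop(crossprod(qv))
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    if (sqrt(sum(w^2)) < tol) { ncomp <- f - 1L; break }
    tt2 <- drop(crossprod(tt))
    p <- crossprod(E, tt) / tt2
    W[, f] <- w; P[, f] <- p; Q[, f] <- qv; Tm[, f] <- tt
    # explained sum of squares of Y by component f
    ssy[f] <- tt2 * sum(qv^2)
    E <- E - tcrossprod(tt, p)
    F_ <- F_ - tcrossprod(tt, qv)
  }
  if (ncomp < 1) stop("nipals_pls2: no usable components")
  keep <- seq_len(ncomp)
  list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
       Q = Q[, keep, drop = FALSE], scores = Tm[, keep, drop = FALSE],
       ssy = ssy[keep], xmeans = xmeans, ymeans = ymeans, ncomp = ncomp)
}

# regression coefficients B such that Yhat = 1 ymeans' + Xc B
pls_coefficients <- function(fit) {
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  R %*% t(fit$Q)
}

#' Fit a PLS-DA classifier
#'
#' One-hot encodes the classes, fits NIPALS PLS2 with `ncomp` latent
#' components, and predicts by argmax of the continuous outputs.
#'
#' @param X Numeric feature matrix.
#' @param y Factor of classes.
#' @param ncomp Number of latent components.
#' @return A `pls_da` fit.
#' @export
pls_da_fit <- function(X, y, ncomp = 2) {
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("pls_da_fit: need at least 2 classes")
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  fit <- nipals_pls2(X, Y, ncomp)
  structure(list(pls = fit, B = pls_coefficients(fit), classes = levels(y)),
            class = "pls_da")
}

pls_da_predict <- function(object, X) {
  X <- as.matrix(X)
  Yhat <- sweep(sweep(X, 2, object$pls$xmeans) %*% object$B, 2,
                object$pls$ymeans, "+")
  factor(object$classes[apply(Yhat, 1, which.max)], levels = object$classes)
}

#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt(J * sum_f(w_jf^2 * SSY_f) / sum_f SSY_f), with w_jf the
#' normalised x-weight of variable j on component f, SSY_f the explained
#' sum of squares of Y of component f, and J the number of x variables.
#' The scores satisfy the algebraic identity sum_j VIP_j^2 = J.
#'
#' @param W J x F matrix of x-weights (columns unit-normalised).
#' @param ssy Length-F vector of per-component explained sums of squares.
#' @return Length-J vector of VIP scores.
#' @export
vip_scores <- function(W, ssy) {
  W <- as.matrix(W)
  if (length(ssy) != ncol(W))
    stop("vip_scores: length(ssy) must equal ncol(W)")
  if (any(ssy < 0)) stop("vip_scores: SSY components must be >= 0")
  tot <- sum(ssy)
  if (tot <= 0) stop("vip_scores: zero total explained sum of squares")
  cn <- colSums(W^2)
  if (any(abs(cn - 1) > 1e-6))
    W <- sweep(W, 2, sqrt(cn), "/")
  J <- nrow(W)
  v <- sqrt(J * drop(W^2 %*% ssy) / tot)
  stats::setNames(v, rownames(W))
}

#' VIP scores of a fitted PLS-DA model
#'
#' @param object A `pls_da` fit.
#' @return Named vector of per-feature VIP scores.
#' @export
pls_da_vip <- function(object) {
  stopifnot(inherits(object, "pls_da"))
  W <- object$pls$W
  rownames(W) <- names(object$pls$xmeans)
  vip_scores(W, object$pls$ssy)
}
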