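#' Fit a multi-trait partial least squares model (kernel algorithm)
#'
#' Extracts latent components by singular value decomposition of the
#' cross-product matrix \eqn{S = E^T F}, with deflation between components:
#' per component, the x-weight `w` and y-weight `q` are the leading left and
#' right singular vectors of `S` (equivalently the leading eigenvectors of
#' \eqn{S S^T} and \eqn{S^T S}); scores \eqn{t = E w} and \eqn{u = F q} are
#' normalized to unit length; loadings \eqn{p = E^T t}, \eqn{q_y = F^T t};
#' and both blocks are deflated by the rank-one fits \eqn{t p^T} and
#' \eqn{t q_y^T}. After extraction the transformed weights
#' \eqn{R = W (P^T W)^{-1}}, the inner regression coefficients
#' \eqn{b = (T^T T)^{-1} T^T Y} with \eqn{T = X R}, and the coefficients on
#' the original (centered/scaled) predictors \eqn{B = R b} are recovered.
#'
#' Extraction stops early when the deflated predictor block is numerically
#' zero (Frobenius norm below `1e-12` times that of the centered `x`); the
#' achieved component count is recorded in the returned model.
#'
#' @param x predictor matrix, n x p.
#' @param y response matrix, n x n_T (or a vector for one trait).
#' @param n_components number of latent components to extract; must not
#'   exceed `min(n - 1, p)`.
#' @param center center the columns of both blocks (default TRUE; the fitted
#'   means are stored and reapplied at prediction).
#' @param scale scale columns to unit variance (default FALSE). Zero-variance
#'   y columns error under scaling; zero-variance x columns get scale 1 and
#'   stay zero after centering.
#' @return An object of class `mtpls` holding `W`, `P`, `Q`, `T`, `U`, `R`,
#'   `b`, `B`, the centering/scaling constants and the achieved
#'   `n_components`.
#' @seealso [predict.mtpls()], [fit_stpls()]
#' @export
fit_mtpls <- function(x, y, n_components, center = TRUE, scale = FALSE) {
  x <- as.matrix(x) + 0
  y <- as.matrix(y) + 0
  stop_if_not_matrix(x, "x"); stop_if_not_matrix(y, "y")
  n <- nrow(x); p <- ncol(x); nT <- ncol(y)
  if (nrow(y) != n) stop("x and y row counts differ", call. = FALSE)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("x and y must be complete", call. = FALSE)
  a_max <- min(n - 1L, p)
  if (n_components < 1 || n_components > a_max) {
    stop(sprintf("n_components must lie in 1..min(n-1, p) = %d", a_max),
         call. = FALSE)
  }

  x_means <- if (center) colMeans(x) else rep(0, p)
  y_means <- if (center) colMeans(y) else rep(0, nT)
  E <- sweep(x, 2, x_means)
  Fm <- sweep(y, 2, y_means)
  if (scale) {
    x_scales <- apply(E, 2, stats::sd)
    x_scales[x_scales == 0] <- 1
    y_scales <- apply(Fm, 2, stats::sd)
    if (any(y_scales == 0)) {
      stop("zero-variance response column with scaling enabled", call. = FALSE)
    }
    E <- sweep(E, 2, x_scales, "/")
    Fm <- sweep(Fm, 2, y_scales, "/")
  } else {
    x_scales <- rep(1, p); y_scales <- rep(1, nT)
  }
  Xc <- E; Yc <- Fm
  norm0 <- frobenius(E)

  a <- as.integer(n_components)
  W <- matrix(0, p, a); P <- matrix(0, p, a); Q <- matrix(0, nT, a)
  Tm <- matrix(0, n, a); U <- matrix(0, n, a)
  achieved <- 0L
  for (k in seq_len(a)) {
    S <- crossprod(E, Fm)
    if (frobenius(S) < 1e-14 * max(1, norm0)) break
    sv <- svd(S, nu = 1, nv = 1)
    w <- sv$u[, 1]; q <- sv$v[, 1]
    i <- which.max(abs(w))
    if (w[i] < 0) { w <- -w; q <- -q }   # joint sign fix keeps S = sigma w q^T
    tvec <- E %*% w
    tn <- frobenius(tvec)
    if (tn < 1e-14 * max(1, norm0)) break
    tvec <- tvec / tn
    uvec <- Fm %*% q
    un <- frobenius(uvec)
    if (un > 0) uvec <- uvec / un
    pvec <- crossprod(E, tvec)
    qvec <- crossprod(Fm, tvec)
    E <- E - tvec %*% t(pvec)
    Fm <- Fm - tvec %*% t(qvec)
    W[, k] <- w; P[, k] <- pvec; Q[, k] <- qvec
    Tm[, k] <- tvec; U[, k] <- uvec
    achieved <- k
    if (frobenius(E) < 1e-12 * norm0) break
  }
  if (achieved == 0L) stop("no component could be extracted (x'y is zero)",
                           call. = FALSE)
  if (achieved < a) {
    idx <- seq_len(achieved)
    W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
    Q <- Q[, idx, drop = FALSE]; Tm <- Tm[, idx, drop = FALSE]
    U <- U[, idx, drop = FALSE]
  }

  PW <- crossprod(P, W)
  # W %*% PW^{-1} via a least-squares solve; PW is unit-upper-triangular in
  # exact arithmetic, so this is well conditioned
  R <- t(qr.solve(t(PW), t(W), tol = 1e-12))
  Tfit <- Xc %*% R
  b <- solve(crossprod(Tfit), crossprod(Tfit, Yc))
  B <- R %*% b

  dn <- list(colnames(x), NULL)
  dimnames(W) <- dn; dimnames(P) <- dn; dimnames(R) <- dn
  dimnames(B) <- list(colnames(x), colnames(y))
  rownames(Q) <- colnames(y)
  structure(list(
    n_components = achieved,
    x_means = x_means, y_means = y_means,
    x_scales = x_scales, y_scales = y_scales,
    center = center, scale = scale,
    W = W, P = P, Q = Q, T = Tfit, U = U, R = R, b = b, B = B,
    trait_names = colnames(y)
  ), class = "mtpls")
}

#' Fit a single-trait PLS model
#'
#' The one-column special case of [fit_mtpls()].
#'
#' @inheritParams fit_mtpls
#' @param y_single response vector (one trait).
#' @return An `mtpls` object with `n_T = 1`.
#' @export
fit_stpls <- function(x, y_single, n_components, center = TRUE, scale = FALSE) {
  fit_mtpls(x, matrix(as.numeric(y_single), ncol = 1), n_components,
            center = center, scale = scale)
}

#' Predict from a fitted PLS model
#'
#' New predictors are centered (and scaled, if the model was fitted with
#' scaling) with the training constants, then either multiplied directly by
#' the coefficient matrix \eqn{B} (`method = "coefficients"`) or projected to
#' scores \eqn{T_{new} = X_{new} R} and multiplied by the inner coefficients
#' `b` (`method = "scores"`); the two routes are algebraically identical. The
#' y-centering (and scaling) is then undone.
#'
#' @param object fitted `mtpls` model.
#' @param x_new matrix of new predictors, m x p (same columns as training x).
#' @param n_components use only the first `n_components` components (defaults
#'   to all fitted); valid because the score columns are orthonormal, so the
#'   truncated model equals a refit at that component count.
#' @param method computation route, see above.
#' @param ... unused.
#' @return m x n_T matrix of predictions on the original response scale.
#' @export
predict.mtpls <- function(object, x_new, n_components = object$n_components,
                          method = c("coefficients", "scores"), ...) {
  method <- match.arg(method)
  x_new <- as.matrix(x_new) + 0
  if (ncol(x_new) != length(object$x_means)) {
    stop("x_new has ", ncol(x_new), " columns; model expects ",
         length(object$x_means), call. = FALSE)
  }
  a <- as.integer(n_components)
  if (a < 1 || a > object$n_components) {
    stop("n_components must lie in 1..", object$n_components, call. = FALSE)
  }
  Xc <- sweep(x_new, 2, object$x_means)
  if (object$scale) Xc <- sweep(Xc, 2, object$x_scales, "/")
  ba <- object$b[seq_len(a), , drop = FALSE]
  Yc <- if (method == "coefficients") {
    Xc %*% (object$R[, seq_len(a), drop = FALSE] %*% ba)
  } else {
    (Xc %*% object$R[, seq_len(a), drop = FALSE]) %*% ba
  }
  if (object$scale) Yc <- sweep(Yc, 2, object$y_scales, "*")
  out <- sweep(Yc, 2, object$y_means, "+")
  colnames(out) <- object$trait_names
  out
}

#' @export
print.mtpls <- function(x, ...) {
  cat(sprintf("Multi-trait PLS model: %d component(s), %d predictors, %d trait(s)\n",
              x$n_components, nrow(x$B), ncol(x$B)))
  cat(sprintf("  centered: %s, scaled: %s\n", x$center, x$scale))
  invisible(x)
}

#' Save/load a fitted PLS model
#'
#' Serializes the full model state (arrays plus metadata) to a single file;
#' a round-trip reproduces predictions bit-for-bit.
#'
#' @param model fitted `mtpls` object.
#' @param path file path.
#' @return `read_pls_model` returns the model; `write_pls_model` returns
#'   `path` invisibly.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "mtpls"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mtpls"))
  model
}
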