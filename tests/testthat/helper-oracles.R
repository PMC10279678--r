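# Independent reference implementations and fixture builders used across the
# suite. The NIPALS reference deliberately uses a power-iteration inner loop
# (not an SVD) so it exercises a different numerical route than the package.

# Classical NIPALS PLS2 with the same normalization convention as the package:
# scores t are unit-norm, both blocks are deflated with t. Returns W, P, Q and
# the coefficient matrix B on the centered/scaled state.
nipals_reference <- function(x, y, a, center = TRUE, scale = FALSE,
                             max_iter = 1000, tol = 1e-13) {
  E <- as.matrix(x) + 0
  Fm <- as.matrix(y) + 0
  xm <- if (center) colMeans(E) else rep(0, ncol(E))
  ym <- if (center) colMeans(Fm) else rep(0, ncol(Fm))
  E <- sweep(E, 2, xm); Fm <- sweep(Fm, 2, ym)
  if (scale) {
    xs <- apply(E, 2, sd); xs[xs == 0] <- 1
    ys <- apply(Fm, 2, sd)
    E <- sweep(E, 2, xs, "/"); Fm <- sweep(Fm, 2, ys, "/")
  }
  Xc <- E; Yc <- Fm
  p <- ncol(E); nT <- ncol(Fm)
  W <- matrix(0, p, a); P <- matrix(0, p, a); Q <- matrix(0, nT, a)
  Tm <- matrix(0, nrow(E), a)
  for (k in seq_len(a)) {
    u <- Fm[, which.max(apply(Fm, 2, var))]
    t_old <- rep(Inf, nrow(E))
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)
      w <- w / sqrt(sum(w^2))
      tvec <- E %*% w
      q <- crossprod(Fm, tvec)
      q <- q / sqrt(sum(q^2))
      u <- Fm %*% q
      if (sqrt(sum((tvec - t_old)^2)) < tol * sqrt(sum(tvec^2))) break
      t_old <- tvec
    }
    i <- which.max(abs(w))
    if (w[i] < 0) { w <- -w; q <- -q }
    tvec <- E %*% w
    tvec <- tvec / sqrt(sum(tvec^2))
    pv <- crossprod(E, tvec)
    qv <- crossprod(Fm, tvec)
    E <- E - tvec %*% t(pv)
    Fm <- Fm - tvec %*% t(qv)
    W[, k] <- w; P[, k] <- pv; Q[, k] <- qv; Tm[, k] <- tvec
  }
  R <- W %*% solve(crossprod(P, W))
  Tfit <- Xc %*% R
  b <- solve(crossprod(Tfit), crossprod(Tfit, Yc))
  list(W = W, P = P, Q = Q, T = Tfit, R = R, b = b, B = R %*% b)
}

# max relative discrepancy between two matrices, allowing per-column sign flips
max_reldiff_signfree <- function(a, b) {
  stopifnot(dim(a) == dim(b))
  d <- vapply(seq_len(ncol(a)), function(j) {
    min(max(abs(a[, j] - b[, j])), max(abs(a[, j] + b[, j])))
  }, numeric(1))
  max(d) / max(abs(b), 1e-300)
}

# strip dimnames and kernel attributes, keeping only the numbers
bare <- function(m) {
  m <- as.matrix(m) + 0
  attributes(m) <- list(dim = dim(m))
  m
}

rand_geno <- function(n_lines, n_markers, seed = 1) {
  set.seed(seed)
  M <- matrix(rbinom(n_lines * n_markers, 2, runif(n_markers, 0.1, 0.5)[
    rep(seq_len(n_markers), each = n_lines)]), n_lines, n_markers)
  dimnames(M) <- list(sprintf("L%03d", seq_len(n_lines)),
                      sprintf("M%04d", seq_len(n_markers)))
  M
}

# small long-format phenotype table over a full line x env grid
grid_pheno <- function(line_ids, env_ids, values) {
  data.frame(line = rep(line_ids, length(env_ids)),
             env = rep(env_ids, each = length(line_ids)),
             values, stringsAsFactors = FALSE)
}
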