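#' Genomic relationship matrix of lines
#'
#' Computes the line-by-line kinship \eqn{K_L = M M^T / r} from a raw dosage
#' matrix `M` (lines x markers, coded 0/1/2), where `r` is the number of
#' markers. Dosages are not centered by default, following the raw-coding
#' convention; `center = TRUE` switches on allele-frequency centering
#' (subtracting each marker's mean dosage) for the conventional VanRaden-style
#' numerator.
#'
#' @param geno numeric dosage matrix with unique rownames (line IDs); no
#'   missing entries allowed.
#' @param center logical; subtract column means before the cross-product.
#' @return Symmetric PSD matrix (lines x lines) with line-ID dimnames and
#'   attribute `kind = "line"`.
#' @export
line_kinship <- function(geno, center = FALSE) {
  M <- as.matrix(geno) + 0
  stop_if_not_matrix(M, "geno")
  if (anyNA(M)) stop("geno contains missing dosages", call. = FALSE)
  if (nrow(M) < 2) stop("need at least 2 lines", call. = FALSE)
  if (is.null(rownames(M)) || anyDuplicated(rownames(M))) {
    stop("geno must carry unique line IDs as rownames", call. = FALSE)
  }
  if (center) M <- scale(M, center = TRUE, scale = FALSE)
  K <- tcrossprod(M) / ncol(M)
  dimnames(K) <- list(rownames(geno), rownames(geno))
  attr(K, "kind") <- "line"
  K
}

#' Environment relationship matrix
#'
#' With no environmental covariates the environment kernel is the identity:
#' environments are modelled only through their incidence (dummy) positions.
#'
#' @param env_ids unique environment identifiers.
#' @return Identity matrix of order `length(env_ids)` with env-ID dimnames and
#'   attribute `kind = "environment"`.
#' @export
env_kinship <- function(env_ids) {
  env_ids <- as.character(env_ids)
  if (length(env_ids) < 1 || anyDuplicated(env_ids)) {
    stop("env_ids must be nonempty and unique", call. = FALSE)
  }
  K <- diag(length(env_ids))
  dimnames(K) <- list(env_ids, env_ids)
  attr(K, "kind") <- "environment"
  K
}

#' Genotype-by-environment relationship matrix
#'
#' Kronecker product \eqn{K_{LE} = K_E \otimes K_L} on the full environment x
#' line grid. Labels are environment-major (`env:line`; the line index varies
#' fastest), matching the column order of the interaction incidence matrix
#' built by [incidence_matrices()].
#'
#' @param ke environment kernel from [env_kinship()].
#' @param kl line kernel from [line_kinship()].
#' @return Symmetric matrix of order `I*J` with `env:line` dimnames and
#'   attribute `kind = "interaction"`.
#' @export
interaction_kinship <- function(ke, kl) {
  if (!identical(attr(ke, "kind"), "environment")) {
    stop("ke must be an environment kernel", call. = FALSE)
  }
  if (!identical(attr(kl, "kind"), "line")) {
    stop("kl must be a line kernel", call. = FALSE)
  }
  K <- kronecker(ke, kl)
  labs <- paste(rep(rownames(ke), each = nrow(kl)), rep(rownames(kl), nrow(ke)),
                sep = ":")
  dimnames(K) <- list(labs, labs)
  attr(K, "kind") <- "interaction"
  K
}

# Symmetric PSD square root of a plain symmetric matrix via eigendecomposition.
# Eigenvalues below tol * lambda_max are clipped to zero; an eigenvalue below
# -tol * lambda_max signals a genuinely non-PSD input. Eigenvector signs are
# fixed (largest-magnitude entry positive) so the factor is deterministic
# across BLAS implementations.
sym_sqrt_matrix <- function(K, tol = 1e-10) {
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- ee$values
  lmax <- max(lam, 0)
  if (any(lam < -tol * max(lmax, 1))) {
    stop(sprintf("matrix is not positive semidefinite (min eigenvalue %.3e)",
                 min(lam)), call. = FALSE)
  }
  lam[lam < tol * lmax] <- 0
  V <- ee$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  L <- V %*% (t(V) * sqrt(lam))
  (L + t(L)) / 2
}

#' Symmetric square root of a relationship kernel
#'
#' Eigendecomposition-based symmetric square root \eqn{L} with
#' \eqn{L L^T = K}. A symmetric (not Cholesky) factor is used because the
#' interaction kernel is rank-deficient by construction, so triangular
#' factorization would fail. Eigenvalues below `tol * lambda_max` are clipped
#' to zero; more negative eigenvalues raise an error.
#'
#' @param kernel symmetric PSD matrix (e.g. from [line_kinship()] or
#'   [interaction_kinship()]).
#' @param tol relative eigenvalue clipping threshold.
#' @return Symmetric matrix `L` with the kernel's dimnames and `kind`
#'   attribute, plus `sqrt = TRUE`.
#' @export
psd_sqrt <- function(kernel, tol = 1e-10) {
  L <- sym_sqrt_matrix(as.matrix(kernel) + 0, tol = tol)
  dimnames(L) <- dimnames(kernel)
  attr(L, "kind") <- attr(kernel, "kind")
  attr(L, "sqrt") <- TRUE
  L
}

#' Read/write labelled kernels as TSV
#'
#' Kernels are stored as square tab-separated matrices whose first row and
#' first column carry the IDs.
#'
#' @param kernel labelled symmetric matrix.
#' @param path file path.
#' @param kind kernel kind to attach on read ("line", "environment",
#'   "interaction"), or NULL to leave unset.
#' @return `read_kernel` returns the labelled matrix; `write_kernel` returns
#'   `path` invisibly.
#' @export
write_kernel <- function(kernel, path) {
  df <- data.frame(id = rownames(kernel), as.data.frame(unclass(kernel)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path, kind = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  storage.mode(K) <- "double"
  if (!is.null(kind)) attr(K, "kind") <- kind
  K
}
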