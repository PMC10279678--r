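#' Incidence matrices for environments, lines and their combinations
#'
#' Builds the 0/1 design matrices used as the raw blocks of the PLS input:
#' `X_E` (records x environments), `X_g` (records x lines) and `X_gE`
#' (records x environment.line combinations). `X_gE` keeps one column per
#' (environment, line) cell of the full grid — environment-major, line index
#' varying fastest — including unobserved combinations, so its column space
#' aligns with the interaction kernel built by [interaction_kinship()].
#'
#' @param records data.frame with character columns `line` and `env`, one row
#'   per observed record; duplicate (line, env) pairs are rejected.
#' @param line_ids ordered registry of line IDs (must cover the records).
#' @param env_ids ordered registry of environment IDs (must cover the records).
#' @return An object of class `design_set`: list with `X_E`, `X_g`, `X_gE`,
#'   the registries, the records, and `column_blocks` (filled once
#'   [assemble_input()] has run).
#' @export
incidence_matrices <- function(records, line_ids, env_ids) {
  line_ids <- as.character(line_ids); env_ids <- as.character(env_ids)
  stopifnot(!anyDuplicated(line_ids), !anyDuplicated(env_ids))
  li <- match(records$line, line_ids)
  ei <- match(records$env, env_ids)
  if (anyNA(li)) stop("records contain line IDs absent from the registry: ",
                      paste(unique(records$line[is.na(li)]), collapse = ", "),
                      call. = FALSE)
  if (anyNA(ei)) stop("records contain env IDs absent from the registry: ",
                      paste(unique(records$env[is.na(ei)]), collapse = ", "),
                      call. = FALSE)
  if (anyDuplicated(cbind(li, ei))) {
    d <- which(duplicated(cbind(li, ei)))[1]
    stop(sprintf("duplicate (line, env) record: (%s, %s)",
                 records$line[d], records$env[d]), call. = FALSE)
  }
  n <- nrow(records); J <- length(line_ids); I <- length(env_ids)
  X_E <- matrix(0, n, I, dimnames = list(NULL, env_ids))
  X_g <- matrix(0, n, J, dimnames = list(NULL, line_ids))
  combo_ids <- paste(rep(env_ids, each = J), rep(line_ids, I), sep = ":")
  X_gE <- matrix(0, n, I * J, dimnames = list(NULL, combo_ids))
  X_E[cbind(seq_len(n), ei)] <- 1
  X_g[cbind(seq_len(n), li)] <- 1
  X_gE[cbind(seq_len(n), (ei - 1L) * J + li)] <- 1
  structure(list(X_E = X_E, X_g = X_g, X_gE = X_gE,
                 line_ids = line_ids, env_ids = env_ids,
                 records = records[, c("line", "env"), drop = FALSE],
                 X_input = NULL, column_blocks = NULL),
            class = "design_set")
}

#' Assemble the kernel-augmented PLS input matrix
#'
#' Post-multiplies the line and interaction incidence blocks by the symmetric
#' square-root factors of their relationship kernels and concatenates
#' \deqn{X = [X_E,\; X_g L_g,\; X_{gE} L_{gE}].}
#' The environment block is left untouched because the environment kernel is
#' the identity. The label order of the factors must match the incidence
#' column order exactly (environment-major for the interaction block).
#'
#' @param designs a `design_set` from [incidence_matrices()].
#' @param lg J x J square-root factor of the line kernel ([psd_sqrt()]).
#' @param lge (I*J) x (I*J) square-root factor of the interaction kernel.
#' @return The `design_set` with `X_input` set and `column_blocks` recording
#'   the column index ranges of the three blocks.
#' @export
assemble_input <- function(designs, lg, lge) {
  stopifnot(inherits(designs, "design_set"))
  if (!identical(colnames(designs$X_g), rownames(lg))) {
    stop("line factor rows do not match X_g columns (label-order mismatch)",
         call. = FALSE)
  }
  if (!identical(colnames(designs$X_gE), rownames(lge))) {
    stop("interaction factor rows do not match X_gE columns ",
         "(label-order mismatch)", call. = FALSE)
  }
  I <- length(designs$env_ids); J <- length(designs$line_ids)
  X <- cbind(designs$X_E, designs$X_g %*% lg, designs$X_gE %*% lge)
  designs$X_input <- X
  designs$column_blocks <- list(env = seq_len(I),
                                line = I + seq_len(J),
                                interaction = I + J + seq_len(I * J))
  designs
}
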