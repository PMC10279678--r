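#' Pearson correlation between observed and predicted values
#'
#' Pairs with a missing value in either vector are dropped. The correlation
#' is undefined (returned as `NA`) when fewer than 3 complete pairs remain or
#' either vector has zero variance; an undefined cell propagates as missing
#' rather than silently becoming zero.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return Correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @export
pearson <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 3) return(NA_real_)
  if (stats::sd(o) == 0 || stats::sd(p) == 0) return(NA_real_)
  stats::cor(o, p)
}

#' Normalized root mean squared error
#'
#' \eqn{NRMSE = RMSE / \bar{y}} with
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum_i (y_i - \hat{y}_i)^2}}; the
#' normalization by the mean of the observed values makes the metric
#' comparable across traits on different scales. A near-zero observed mean
#' (\eqn{|\bar y| < 10^{-8} \, sd(y)}) leaves the metric undefined and raises
#' an error.
#'
#' @inheritParams pearson
#' @return Nonnegative scalar (for positive-mean traits).
#' @export
nrmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  if (length(o) < 1) stop("no complete observation pairs", call. = FALSE)
  ybar <- mean(o)
  s <- if (length(o) > 1) stats::sd(o) else abs(ybar)
  if (abs(ybar) < 1e-8 * max(s, 1e-300)) {
    stop("observed mean is numerically zero; NRMSE undefined", call. = FALSE)
  }
  sqrt(mean((o - p)^2)) / ybar
}

#' Tune the number of PLS components by inner cross-validation
#'
#' Splits the training records into `k_inner` seeded folds; for every
#' candidate component count the model is fitted on the inner-training part
#' and scored on the validation part by NRMSE, averaged across traits and
#' folds. The candidate minimizing the mean inner NRMSE wins; ties go to the
#' smallest count. Internally one model per fold is fitted at the largest
#' feasible candidate and truncated for the smaller ones, which is exact
#' because the score columns are orthonormal.
#'
#' @param x_train,y_train training predictors and responses.
#' @param grid candidate component counts; entries infeasible for the
#'   smallest inner training split are dropped with a warning.
#' @param k_inner number of inner folds (default 5).
#' @param seed seed for the inner fold assignment.
#' @param center,scale passed to [fit_mtpls()].
#' @return The selected component count, with attribute `inner_nrmse` (named
#'   mean NRMSE per candidate).
#' @export
tune_components <- function(x_train, y_train, grid, k_inner = 5, seed = 1,
                            center = TRUE, scale = FALSE) {
  x_train <- as.matrix(x_train) + 0
  y_train <- as.matrix(y_train) + 0
  n <- nrow(x_train)
  if (length(grid) < 1) stop("component grid is empty", call. = FALSE)
  grid <- sort(unique(as.integer(grid)))
  folds <- fold_assignment(n, k_inner, seed)
  min_train <- n - max(tabulate(folds, k_inner))
  feas_max <- min(min_train - 1L, ncol(x_train))
  feasible <- grid[grid >= 1 & grid <= feas_max]
  if (length(feasible) < length(grid)) {
    warning(sprintf("dropping %d infeasible grid entries (> %d)",
                    length(grid) - length(feasible), feas_max), call. = FALSE)
  }
  if (length(feasible) == 0) stop("no feasible component count in grid",
                                  call. = FALSE)
  a_hi <- max(feasible)
  scores <- matrix(NA_real_, k_inner, length(feasible))
  for (f in seq_len(k_inner)) {
    tr <- folds != f
    fit <- fit_mtpls(x_train[tr, , drop = FALSE], y_train[tr, , drop = FALSE],
                     n_components = a_hi, center = center, scale = scale)
    xv <- x_train[!tr, , drop = FALSE]
    yv <- y_train[!tr, , drop = FALSE]
    for (j in seq_along(feasible)) {
      a <- min(feasible[j], fit$n_components)   # early-stopped fits cap a
      pred <- predict(fit, xv, n_components = a)
      per_trait <- vapply(seq_len(ncol(yv)), function(t) {
        tryCatch(nrmse(yv[, t], pred[, t]), error = function(e) NA_real_)
      }, numeric(1))
      scores[f, j] <- mean(per_trait, na.rm = TRUE)
    }
  }
  mean_scores <- colMeans(scores, na.rm = TRUE)
  best <- feasible[which.min(mean_scores)]   # which.min takes the first = smallest a
  structure(best, inner_nrmse = stats::setNames(mean_scores, feasible))
}

# Build the kernel-augmented input matrix for a phenotype table: registries,
# kernels, square roots and incidence blocks. Returns the design_set with
# X_input set. Kernels depend only on the genotypes and registries, never on
# which records end up in training, so they are computed once per run.
build_input_matrix <- function(geno, pheno, kinship_center = FALSE) {
  line_ids <- rownames(geno)
  miss <- setdiff(unique(pheno$line), line_ids)
  if (length(miss) > 0) {
    stop("phenotype lines without genotypes: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  env_ids <- unique(pheno$env)   # first-appearance order
  K_L <- line_kinship(geno, center = kinship_center)
  L_g <- psd_sqrt(K_L)
  K_E <- env_kinship(env_ids)
  K_LE <- interaction_kinship(K_E, K_L)
  L_gE <- psd_sqrt(K_LE)
  ds <- incidence_matrices(pheno[, c("line", "env")], line_ids, env_ids)
  assemble_input(ds, L_g, L_gE)
}

#' Recompute accuracy cells from record-level predictions
#'
#' For multi-fold schemes (5FCV) each per-environment and global cell is the
#' mean over the folds in which it is defined, with SE = sd/sqrt(#folds); for
#' LOEO the per-environment cells are single values (no SE) and only the
#' Across aggregation carries an SE over environments. The tables stored in a
#' `cv_result` are exactly this function applied to its `predictions`, so
#' every summary cell is reproducible from the record-level output.
#'
#' @param predictions data.frame with columns `line`, `env`, `trait`, `fold`,
#'   `observed`, `predicted`.
#' @param scheme `"5FCV"` or `"LOEO"`.
#' @param env_ids,trait_names registries fixing row order.
#' @return list with data.frames `per_env` and `global`.
#' @export
cv_metrics <- function(predictions, scheme, env_ids, trait_names) {
  fold_ids <- unique(predictions$fold)
  cell <- function(df) {
    c(rho = pearson(df$observed, df$predicted),
      nrmse = tryCatch(nrmse(df$observed, df$predicted),
                       error = function(e) NA_real_))
  }
  agg <- function(vals) {
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) return(c(NA_real_, NA_real_))
    c(mean(vals), if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else NA_real_)
  }
  per_env <- do.call(rbind, lapply(trait_names, function(tr) {
    do.call(rbind, lapply(env_ids, function(e) {
      sub <- predictions[predictions$env == e & predictions$trait == tr, ]
      if (scheme == "LOEO") {
        m <- cell(sub)
        data.frame(env = e, trait = tr, rho = m[["rho"]], rho_se = NA_real_,
                   nrmse = m[["nrmse"]], nrmse_se = NA_real_)
      } else {
        m <- vapply(fold_ids, function(f) cell(sub[sub$fold == f, , drop = FALSE]),
                    numeric(2))
        r <- agg(m["rho", ]); nr <- agg(m["nrmse", ])
        data.frame(env = e, trait = tr, rho = r[1], rho_se = r[2],
                   nrmse = nr[1], nrmse_se = nr[2])
      }
    }))
  }))
  global <- do.call(rbind, lapply(trait_names, function(tr) {
    sub <- predictions[predictions$trait == tr, ]
    if (scheme == "LOEO") {
      pe <- per_env[per_env$trait == tr, ]
      r <- agg(pe$rho); nr <- agg(pe$nrmse)
    } else {
      m <- vapply(fold_ids, function(f) cell(sub[sub$fold == f, , drop = FALSE]),
                  numeric(2))
      r <- agg(m["rho", ]); nr <- agg(m["nrmse", ])
    }
    data.frame(trait = tr, rho = r[1], rho_se = r[2], nrmse = nr[1],
               nrmse_se = nr[2])
  }))
  rownames(per_env) <- NULL; rownames(global) <- NULL
  list(per_env = per_env, global = global)
}

# Shared engine behind run_5fcv and run_loeo. `fold_of` maps record rows of
# `pheno` to outer fold labels; tuning and refitting happen inside each outer
# training set only.
run_cv_engine <- function(geno, pheno, model_type, grid, seed, scheme,
                          fold_of, center, scale, kinship_center) {
  model_type <- match.arg(model_type, c("MT", "ST"))
  trait_names <- setdiff(names(pheno), c("line", "env"))
  stopifnot(length(trait_names) >= 1)
  ds <- build_input_matrix(geno, pheno, kinship_center = kinship_center)
  X <- ds$X_input
  fold_labels <- unique(fold_of)
  default_grid <- function(n_train) seq_len(min(30L, n_train - 2L, ncol(X)))

  trait_sets <- if (model_type == "MT") list(all = trait_names) else
    stats::setNames(as.list(trait_names), trait_names)

  preds <- list(); chosen <- list()
  for (set_name in names(trait_sets)) {
    traits <- trait_sets[[set_name]]
    Yall <- as.matrix(pheno[, traits, drop = FALSE])
    usable <- stats::complete.cases(Yall)
    for (f in fold_labels) {
      test <- usable & (fold_of == f)
      train <- usable & (fold_of != f)
      if (!any(test) || sum(train) < 10) next
      g <- if (is.null(grid)) default_grid(sum(train)) else grid
      # named substream: depends on scheme and fold only, so ST and MT runs
      # (and runs with extra traits) share identical inner splits
      inner_seed <- substream_seed(seed, paste("inner", scheme, f))
      a_star <- tune_components(X[train, , drop = FALSE],
                                Yall[train, , drop = FALSE],
                                grid = g, k_inner = 5, seed = inner_seed,
                                center = center, scale = scale)
      fit <- fit_mtpls(X[train, , drop = FALSE], Yall[train, , drop = FALSE],
                       n_components = as.integer(a_star),
                       center = center, scale = scale)
      yhat <- predict(fit, X[test, , drop = FALSE])
      idx <- which(test)
      for (t in seq_along(traits)) {
        preds[[length(preds) + 1L]] <- data.frame(
          line = pheno$line[idx], env = pheno$env[idx], trait = traits[t],
          fold = f, observed = Yall[idx, t], predicted = yhat[, t],
          stringsAsFactors = FALSE)
      }
      chosen[[length(chosen) + 1L]] <- data.frame(
        fold = f, trait_set = set_name, n_components = as.integer(a_star),
        stringsAsFactors = FALSE)
    }
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  metrics <- cv_metrics(predictions, scheme, ds$env_ids, trait_names)
  structure(list(
    scheme = scheme, model_type = model_type,
    per_env = metrics$per_env, global = metrics$global,
    chosen_components = do.call(rbind, chosen),
    predictions = predictions,
    env_ids = ds$env_ids, trait_names = trait_names, seed = seed
  ), class = "cv_result")
}

#' Random five-fold cross-validation (tested lines in tested environments)
#'
#' Partitions the observed line-by-environment records into five seeded folds
#' of near-equal size — records, not lines, rotate, so a line may appear in
#' training and testing in different environments. Within each outer training
#' set the number of components is tuned by [tune_components()] (inner
#' five-fold, NRMSE objective), the model is refitted at the selected count,
#' and the outer test fold is predicted. Per-environment and global
#' correlation/NRMSE cells are fold-wise means with SE = sd/sqrt(5); an
#' environment absent (or degenerate) in some fold's test set is simply
#' excluded from that cell's mean.
#'
#' For `model_type = "MT"` records missing any trait are dropped
#' (complete-case); for `"ST"` each trait keeps its own observed records and
#' gets its own tuning and fit.
#'
#' @param geno dosage matrix (lines x markers) with line-ID rownames.
#' @param pheno long-format data.frame: `line`, `env`, one column per trait.
#' @param model_type `"MT"` (joint fit of all traits) or `"ST"` (one fit per
#'   trait).
#' @param grid candidate component counts; default `1..min(30, n_train-2, p)`.
#' @param seed master seed; fold assignment and inner splits derive from it
#'   through named substreams.
#' @param center,scale PLS preprocessing flags.
#' @param kinship_center allele-frequency centering for [line_kinship()].
#' @param n_folds number of outer folds (default 5).
#' @return A `cv_result`: per-environment and global accuracy tables, chosen
#'   component counts per fold, and record-level predictions.
#' @export
run_5fcv <- function(geno, pheno, model_type = c("MT", "ST"), grid = NULL,
                     seed = 1, center = TRUE, scale = FALSE,
                     kinship_center = FALSE, n_folds = 5) {
  model_type <- match.arg(model_type)
  folds <- fold_assignment(nrow(pheno), n_folds,
                           substream_seed(seed, "outer_5fcv"))
  run_cv_engine(geno, pheno, model_type, grid, seed, scheme = "5FCV",
                fold_of = folds, center = center, scale = scale,
                kinship_center = kinship_center)
}

#' Leave-one-environment-out cross-validation (untested environments)
#'
#' Each environment in turn is held out entirely; the model is trained on the
#' remaining environments' records (the held-out environment's incidence
#' columns exist but are all-zero in training rows), with the component count
#' tuned by an inner five-fold split of the training records. Per-environment
#' cells are single values (no SE); the Across row is the mean over the I
#' per-environment values with SE = sd/sqrt(I).
#'
#' @inheritParams run_5fcv
#' @return A `cv_result` with `fold` equal to the held-out environment ID.
#' @export
run_loeo <- function(geno, pheno, model_type = c("MT", "ST"), grid = NULL,
                     seed = 1, center = TRUE, scale = FALSE,
                     kinship_center = FALSE) {
  model_type <- match.arg(model_type)
  env_ids <- unique(pheno$env)
  if (length(env_ids) < 2) stop("LOEO needs at least 2 environments", call. = FALSE)
  run_cv_engine(geno, pheno, model_type, grid, seed, scheme = "LOEO",
                fold_of = pheno$env, center = center, scale = scale,
                kinship_center = kinship_center)
}

#' Summarize a cross-validation result as an accuracy table
#'
#' One row per environment plus an `Across` row, with columns rho/SE and
#' NRMSE/SE per trait — the standard accuracy-table layout of
#' multi-environment genomic-prediction studies. LOEO per-environment SE
#' cells are `NA` (single values).
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return data.frame with columns `env`, `trait`, `rho`, `rho_se`, `nrmse`,
#'   `nrmse_se`.
#' @export
summary.cv_result <- function(object, ...) {
  across <- data.frame(env = "Across", object$global, stringsAsFactors = FALSE)
  out <- rbind(object$per_env, across[, names(object$per_env)])
  rownames(out) <- NULL
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation, %s-PLS (%d traits, %d environments)\n",
              x$scheme, x$model_type, length(x$trait_names), length(x$env_ids)))
  print(summary(x), digits = 4)
  invisible(x)
}

#' Side-by-side ST/MT accuracy report
#'
#' Joins single-trait and multi-trait results for one scheme into a wide
#' table mirroring the published layout (rho/SE/NRMSE/SE for ST and MT side
#' by side), with an explicit `best` flag column marking the model with the
#' larger correlation in each row instead of bold type.
#'
#' @param st,mt `cv_result` objects for the same scheme and data (either may
#'   be NULL).
#' @return Wide data.frame with one row per (environment, trait) plus Across
#'   rows.
#' @export
cv_report <- function(st = NULL, mt = NULL) {
  stopifnot(!is.null(st) || !is.null(mt))
  pull <- function(res, tag) {
    if (is.null(res)) return(NULL)
    s <- summary(res)
    names(s)[3:6] <- paste0(names(s)[3:6], "_", tag)
    s
  }
  a <- pull(st, "st"); b <- pull(mt, "mt")
  out <- if (is.null(a)) b else if (is.null(b)) a else
    merge(a, b, by = c("env", "trait"), sort = FALSE)
  if (!is.null(a) && !is.null(b)) {
    out$best <- ifelse(is.na(out$rho_st) | is.na(out$rho_mt), NA_character_,
                       ifelse(out$rho_mt >= out$rho_st, "MT", "ST"))
  }
  out
}
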