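test_that("pearson matches affine expectations and the explicit-sum oracle", {
  o <- c(1, 2, 3, 5, 8)
  expect_equal(pearson(o, 2 * o + 1), 1)
  expect_equal(pearson(o, -o), -1)
  set.seed(4)
  a <- rnorm(50); b <- a + rnorm(50)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2)) * sqrt(sum((b - mean(b))^2))
  expect_equal(pearson(a, b), num / den, tolerance = 1e-12)
  # undefined cells propagate as NA, never as zero
  expect_true(is.na(pearson(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(pearson(c(1, 2), c(1, 2))))
})

test_that("nrmse matches the hand computation and the loop oracle", {
  expect_equal(nrmse(c(2, 4), c(3, 3)), 1 / 3)
  o <- c(5, 7, 9); expect_equal(nrmse(o, o), 0)
  set.seed(6)
  a <- rnorm(40, mean = 10); b <- a + rnorm(40)
  expect_equal(nrmse(a, b), sqrt(sum((a - b)^2) / 40) / mean(a),
               tolerance = 1e-12)
  expect_error(nrmse(c(-1, 1, -1, 1), c(0, 0, 0, 0)), "zero")
})

test_that("tuning returns the exhaustive-grid argmin with smallest-a tie-break", {
  set.seed(17)
  x <- matrix(rnorm(60 * 15), 60, 15)
  y <- 10 + x[, 1:3] %*% matrix(rnorm(6), 3, 2) + matrix(rnorm(120, sd = .5), 60, 2)
  grid <- 1:6
  a_star <- tune_components(x, y, grid, k_inner = 5, seed = 9)

  # exhaustive recomputation: refit from scratch at every candidate
  folds <- plsmet:::fold_assignment(60, 5, 9)   # same seeded split as tune_components
  means <- sapply(grid, function(a) {
    mean(sapply(1:5, function(f) {
      tr <- folds != f
      fit <- fit_mtpls(x[tr, ], y[tr, , drop = FALSE], a)
      pred <- predict(fit, x[!tr, ])
      mean(sapply(1:2, function(t) nrmse(y[!tr, t], pred[, t])))
    }))
  })
  expect_equal(as.integer(a_star), grid[which.min(means)])
  expect_equal(unname(attr(a_star, "inner_nrmse")), means, tolerance = 1e-10)
})

test_that("tuning finds the minimal component count on a noise-free low-rank signal", {
  set.seed(23)
  lat <- matrix(rnorm(50 * 2), 50, 2)        # two latent drivers
  x <- lat %*% matrix(rnorm(2 * 10), 2, 10)  # rank-2 predictor block
  y <- sweep(x %*% matrix(rnorm(20), 10, 2), 2, c(20, 30), "+")  # noise-free
  a_star <- tune_components(x, y, grid = 1:5, seed = 3)
  inner <- attr(a_star, "inner_nrmse")
  expect_lt(inner[[as.character(a_star)]], 1e-6)
  smaller <- inner[as.integer(names(inner)) < as.integer(a_star)]
  expect_true(all(smaller > 1e-6))
  expect_identical(as.integer(tune_components(x, y, grid = 3, seed = 3)), 3L)
})

test_that("infeasible grid entries are dropped, an empty feasible grid errors", {
  x <- matrix(rnorm(15 * 4), 15, 4)
  y <- matrix(rnorm(15), ncol = 1)
  expect_warning(a <- tune_components(x, y, grid = c(2, 50), seed = 1),
                 "infeasible")
  expect_lte(as.integer(a), 4L)
  expect_error(suppressWarnings(tune_components(x, y, grid = 50, seed = 1)),
               "feasible")
})

make_cv_fixture <- function(n_lines = 40, n_markers = 80, n_envs = 3,
                            h2 = 0.85, seed = 1, ...) {
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers, n_envs = n_envs,
                    trait_heritabilities = h2, seed = seed, ...)
  g <- simulate_genotypes(cfg)
  list(geno = g, pheno = simulate_phenotypes(g, cfg)$pheno)
}

test_that("5FCV partitions records into balanced disjoint folds covering everything", {
  fx <- make_cv_fixture(seed = 2)
  res <- run_5fcv(fx$geno, fx$pheno, "MT", grid = 1:4, seed = 11)
  key <- paste(res$predictions$line, res$predictions$env)
  expect_identical(sort(unique(key)), sort(paste(fx$pheno$line, fx$pheno$env)))
  expect_true(all(table(key) == 1))   # each record in exactly one test fold
  sizes <- table(res$predictions$fold)
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("cross-validation results are deterministic and recomputable from predictions", {
  fx <- make_cv_fixture(seed = 3)
  r1 <- run_5fcv(fx$geno, fx$pheno, "MT", grid = 1:4, seed = 7)
  r2 <- run_5fcv(fx$geno, fx$pheno, "MT", grid = 1:4, seed = 7)
  expect_identical(r1$per_env, r2$per_env)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$chosen_components, r2$chosen_components)

  # metric round-trip from stored record-level predictions
  m <- cv_metrics(r1$predictions, "5FCV", r1$env_ids, r1$trait_names)
  expect_equal(m$per_env, r1$per_env, tolerance = 1e-12)
  expect_equal(m$global, r1$global, tolerance = 1e-12)
})

test_that("LOEO holds each environment out exactly once and omits per-env SEs", {
  fx <- make_cv_fixture(seed = 4)
  res <- run_loeo(fx$geno, fx$pheno, "ST", grid = 1:4, seed = 5)
  for (e in res$env_ids) {
    sub <- res$predictions[res$predictions$env == e, ]
    expect_true(all(sub$fold == e))   # an env is predicted only as its own fold
  }
  expect_true(all(is.na(res$per_env$rho_se)))
  expect_true(all(is.na(res$per_env$nrmse_se)))
  expect_false(anyNA(res$global$rho_se))
  # Across = mean over per-environment values with SE = sd/sqrt(I)
  pe <- res$per_env[res$per_env$trait == "trait1", ]
  expect_equal(res$global$rho[1], mean(pe$rho), tolerance = 1e-12)
  expect_equal(res$global$rho_se[1], sd(pe$rho) / sqrt(nrow(pe)), tolerance = 1e-12)
})

test_that("single-trait tables survive the summary and report round-trip", {
  fx <- make_cv_fixture(seed = 6)
  st <- run_5fcv(fx$geno, fx$pheno, "ST", grid = 1:4, seed = 2)
  mt <- run_5fcv(fx$geno, fx$pheno, "MT", grid = 1:4, seed = 2)
  s <- summary(st)
  expect_identical(s$env, c(st$env_ids, "Across"))
  rep_tab <- cv_report(st = st, mt = mt)
  expect_true(all(c("rho_st", "rho_mt", "best") %in% names(rep_tab)))
  expect_identical(nrow(rep_tab), nrow(s))
  i <- which(rep_tab$env == "Across")[1]
  expect_identical(rep_tab$best[i],
                   if (rep_tab$rho_mt[i] >= rep_tab$rho_st[i]) "MT" else "ST")
})

test_that("missing trait cells are handled complete-case (MT) and per-trait (ST)", {
  cfg <- sim_config(n_lines = 40, n_markers = 60, n_envs = 3,
                    trait_heritabilities = c(0.9, 0.9), missing_rate = 0.1,
                    seed = 12)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)$pheno
  mt <- run_5fcv(g, ph, "MT", grid = 1:4, seed = 3)
  st <- run_5fcv(g, ph, "ST", grid = 1:4, seed = 3)
  n_complete <- sum(complete.cases(ph[, c("trait1", "trait2")]))
  expect_identical(nrow(mt$predictions), 2L * n_complete)
  expect_identical(nrow(st$predictions),
                   sum(!is.na(ph$trait1)) + sum(!is.na(ph$trait2)))
})
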