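#' Simulation configuration for synthetic multi-environment trial data
#'
#' Bundles and validates every knob of the synthetic potato-breeding data
#' generator. Defaults emulate a Scandinavian potato genomic-selection trial:
#' roughly 253 genotyped breeding clones scored on 2503 biallelic SNPs in six
#' environments (three locations by two years), with three correlated tuber
#' traits of heritabilities 0.93, 0.84 and 0.78.
#'
#' Heritability here is the within-environment ratio
#' \eqn{h^2 = Var(g) / (Var(g) + Var(ge) + Var(\epsilon))}, so the
#' environment-specific share of genetic variance is bounded:
#' `gxe_variance_ratio` must not exceed `1 / max(trait_heritabilities) - 1`.
#'
#' @param n_lines number of genotyped lines (breeding clones/cultivars).
#' @param n_markers number of biallelic SNP markers.
#' @param maf_range length-2 numeric, minor-allele-frequency range in (0, 0.5];
#'   each marker's allele frequency is drawn uniformly from this interval.
#' @param n_envs number of environments (location-year combinations).
#' @param env_effect_sd standard deviation of environment main effects, in
#'   trait units (genetic standard deviations, since Var(g) is normalized to 1).
#' @param trait_heritabilities vector of within-environment heritabilities in
#'   (0, 1]; its length sets the number of traits.
#' @param genetic_correlation either a single exchangeable correlation or a
#'   full trait-by-trait correlation matrix (symmetric, unit diagonal, PSD).
#' @param gxe_variance_ratio share of genetic variance that is
#'   environment-specific (Var(ge)/Var(g)); nonnegative.
#' @param missing_rate fraction in [0, 1) of trait records blanked completely
#'   at random.
#' @param trait_means grand mean per trait (kept away from zero so NRMSE is
#'   well defined); defaults to 20, 25, 30, ...
#' @param seed integer master seed; all draws derive from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 40, n_markers = 100, n_envs = 3,
#'                   trait_heritabilities = c(0.9, 0.5), seed = 1)
sim_config <- function(n_lines = 253, n_markers = 2503,
                       maf_range = c(0.05, 0.5),
                       n_envs = 6, env_effect_sd = 1,
                       trait_heritabilities = c(0.93, 0.84, 0.78),
                       genetic_correlation = 0.5,
                       gxe_variance_ratio = 0.05,
                       missing_rate = 0,
                       trait_means = NULL,
                       seed = 1L) {
  stopifnot(n_lines >= 2, n_markers >= 1, n_envs >= 1)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 0.5]", call. = FALSE)
  }
  if (any(trait_heritabilities <= 0) || any(trait_heritabilities > 1)) {
    stop("trait_heritabilities must lie in (0, 1]", call. = FALSE)
  }
  if (gxe_variance_ratio < 0) stop("gxe_variance_ratio must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  n_traits <- length(trait_heritabilities)
  G <- genetic_correlation
  if (is.matrix(G)) {
    if (nrow(G) != n_traits || ncol(G) != n_traits) {
      stop("genetic_correlation matrix must be n_traits x n_traits", call. = FALSE)
    }
  } else {
    stopifnot(length(G) == 1, G >= -1, G <= 1)
    G <- matrix(G, n_traits, n_traits)
    diag(G) <- 1
  }
  if (max(abs(G - t(G))) > 1e-12 || max(abs(diag(G) - 1)) > 1e-12) {
    stop("genetic_correlation must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("genetic_correlation must be positive semidefinite", call. = FALSE)
  }
  # residual variance 1/h - 1 - ratio must be nonnegative for every trait
  bad <- 1 / trait_heritabilities - 1 - gxe_variance_ratio < -1e-12
  if (any(bad)) {
    stop(sprintf(
      "gxe_variance_ratio = %g is incompatible with heritability %g; ",
      gxe_variance_ratio, max(trait_heritabilities[bad])),
      "within-environment h^2 requires gxe_variance_ratio <= 1/h^2 - 1",
      call. = FALSE)
  }
  if (is.null(trait_means)) trait_means <- 20 + 5 * (seq_len(n_traits) - 1)
  stopifnot(length(trait_means) == n_traits)
  structure(list(
    n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
    maf_range = as.numeric(maf_range), n_envs = as.integer(n_envs),
    env_effect_sd = env_effect_sd,
    trait_heritabilities = trait_heritabilities,
    genetic_correlation = G,
    gxe_variance_ratio = gxe_variance_ratio,
    missing_rate = missing_rate,
    trait_means = trait_means,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a SNP dosage matrix
#'
#' Draws one allele frequency per marker uniformly from `config$maf_range`,
#' then diploid dosages (0/1/2) binomially and independently across lines.
#' Markers are unlinked (no LD) by design.
#'
#' @param config a [sim_config()] object.
#' @return Integer matrix of dosages, lines x markers, with line IDs `L001...`
#'   as rownames and marker IDs `M00001...` as colnames.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_lines; r <- config$n_markers
  with_seed(substream_seed(config$seed, "genotypes"), {
    p <- stats::runif(r, config$maf_range[1], config$maf_range[2])
    M <- matrix(stats::rbinom(J * r, size = 2, prob = rep(p, each = J)), J, r)
  })
  dimnames(M) <- list(
    sprintf("L%03d", seq_len(J)),
    sprintf("M%05d", seq_len(r))
  )
  storage.mode(M) <- "integer"
  M
}

#' Simulate multi-environment multi-trait phenotypes
#'
#' Generates one record per line x environment under the additive model
#' \deqn{y_{jit} = \mu_t + E_{it} + g_{jt} + ge_{jit} + \epsilon_{jit}.}
#' Marker effects are i.i.d. Gaussian per trait and correlated across traits
#' through a symmetric square-root factor of `genetic_correlation`; the
#' additive values `g = M_c alpha` (centered dosages) are rescaled so each
#' trait's realized genetic variance is exactly 1. The genotype-by-environment
#' deviations `ge` are drawn per environment and rescaled so their realized
#' variance is exactly `gxe_variance_ratio`; the residual variance is set so
#' the realized within-environment heritability equals
#' `trait_heritabilities[t]` (variances enforced empirically so recovery tests
#' have exact targets).
#'
#' @param geno dosage matrix from [simulate_genotypes()].
#' @param config the same [sim_config()] used for the genotypes.
#' @return A list with elements
#'   \item{pheno}{long-format data.frame: `line`, `env`, one column per trait
#'     (`trait1`, ...); environment-major record order.}
#'   \item{true}{list of the generating signals: `additive_values` (lines x
#'     traits), `gxe_values` ((env x line) rows, environment-major, x traits),
#'     `env_means` (envs x traits), `trait_means`.}
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  stop_if_not_matrix(geno + 0, "geno")
  J <- config$n_lines; I <- config$n_envs
  nT <- length(config$trait_heritabilities)
  if (nrow(geno) != J) stop("geno has ", nrow(geno), " lines but config says ", J,
                            call. = FALSE)
  line_ids <- rownames(geno)
  env_ids <- sprintf("E%d", seq_len(I))
  trait_names <- sprintf("trait%d", seq_len(nT))

  Gsqrt <- sym_sqrt_matrix(config$genetic_correlation, tol = 1e-10)

  g <- with_seed(substream_seed(config$seed, "marker_effects"), {
    alpha <- matrix(stats::rnorm(config$n_markers * nT), config$n_markers, nT) %*% Gsqrt
    Mc <- scale(geno, center = TRUE, scale = FALSE)
    gv <- Mc %*% alpha
    gv <- scale(gv, center = TRUE, scale = FALSE)
    # enforce unit genetic variance per trait (empirical, exact)
    sds <- apply(gv, 2, stats::sd)
    if (any(sds == 0)) stop("degenerate genetic values (zero variance)", call. = FALSE)
    sweep(gv, 2, sds, "/")
  })
  dimnames(g) <- list(line_ids, trait_names)

  env_means <- with_seed(substream_seed(config$seed, "env_effects"), {
    if (config$env_effect_sd > 0) {
      matrix(stats::rnorm(I * nT, sd = config$env_effect_sd), I, nT)
    } else matrix(0, I, nT)
  })
  dimnames(env_means) <- list(env_ids, trait_names)

  ratio <- config$gxe_variance_ratio
  ge <- with_seed(substream_seed(config$seed, "gxe"), {
    if (ratio > 0) {
      out <- matrix(0, I * J, nT)
      for (t in seq_len(nT)) {
        m <- matrix(stats::rnorm(J * I), J, I)
        m <- scale(m, center = TRUE, scale = FALSE)   # mean 0 within each env
        m <- m * sqrt(ratio / mean(apply(m, 2, stats::var)))
        out[, t] <- as.vector(m)                       # environment-major
      }
      out
    } else matrix(0, I * J, nT)
  })
  dimnames(ge) <- list(paste(rep(env_ids, each = J), rep(line_ids, I), sep = ":"),
                       trait_names)

  eps <- with_seed(substream_seed(config$seed, "noise"), {
    out <- matrix(0, I * J, nT)
    for (t in seq_len(nT)) {
      v_eps <- 1 / config$trait_heritabilities[t] - 1 - ratio
      if (v_eps > 1e-12) {
        e <- stats::rnorm(I * J)
        e <- e - mean(e)
        out[, t] <- e * sqrt(v_eps) / stats::sd(e)
      }
    }
    out
  })

  rec_line <- rep(line_ids, I)
  rec_env <- rep(env_ids, each = J)
  Y <- matrix(config$trait_means, I * J, nT, byrow = TRUE) +
    env_means[rec_env, , drop = FALSE] +
    g[rec_line, , drop = FALSE] + ge + eps
  colnames(Y) <- trait_names

  if (config$missing_rate > 0) {
    miss <- with_seed(substream_seed(config$seed, "missing"),
                      matrix(stats::runif(I * J * nT) < config$missing_rate, I * J, nT))
    Y[miss] <- NA_real_
  }

  pheno <- data.frame(line = rec_line, env = rec_env, Y,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(pheno = pheno,
       true = list(additive_values = g, gxe_values = ge, env_means = env_means,
                   trait_means = stats::setNames(config$trait_means, trait_names)))
}
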