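#' Read a genotype dosage matrix
#'
#' TSV layout: header row of marker IDs, first column of line IDs, integer
#' dosages in \{0,1,2\}. VCF input (biallelic SNPs) is converted to
#' alternate-allele dosage per genotype call; non-biallelic sites are skipped
#' with a warning. Lines carrying any missing genotype are dropped with a
#' logged count, so downstream kinship code never sees missing dosages.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @return Integer dosage matrix with line-ID rownames and marker-ID colnames.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  M <- if (format == "vcf") read_genotypes_vcf(path) else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    m
  }
  bad_rows <- apply(M, 1, anyNA)
  if (any(bad_rows)) {
    message(sum(bad_rows), " line(s) dropped for missing genotype calls: ",
            paste(utils::head(rownames(M)[bad_rows], 5), collapse = ", "),
            if (sum(bad_rows) > 5) ", ..." else "")
    M <- M[!bad_rows, , drop = FALSE]
  }
  if (!all(M %in% c(0, 1, 2))) {
    stop("dosages outside {0, 1, 2} in ", path, call. = FALSE)
  }
  if (anyDuplicated(rownames(M))) stop("duplicate line IDs in ", path, call. = FALSE)
  storage.mode(M) <- "integer"
  M
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (!all(bi)) {
    warning(sum(!bi), " non-biallelic site(s) skipped", call. = FALSE)
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles in calls like 0/1, 1|1; any missing allele -> NA
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == "." | al == "")) return(NA_real_)
    sum(al == "1")
  })
  ids <- vcfR::getID(v)
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids)) {
    ids <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))
  }
  rownames(dos) <- ids
  t(dos)   # lines x markers
}

#' Write a genotype dosage matrix as TSV
#'
#' @param geno dosage matrix with line-ID rownames and marker-ID colnames.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(line = rownames(geno), as.data.frame(unclass(geno)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' CSV with columns `line`, `env` and one column per trait. Duplicate
#' (line, env) rows are rejected; when a genotype matrix is supplied, records
#' for ungenotyped lines raise an error listing the offenders.
#'
#' @param path file path.
#' @param geno optional dosage matrix for line-ID validation.
#' @param traits optional character vector selecting a subset of trait
#'   columns.
#' @return data.frame with `line`, `env` (character) and numeric trait
#'   columns.
#' @export
read_phenotypes <- function(path, geno = NULL, traits = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("line", "env") %in% names(df))) {
    stop("phenotype file must have 'line' and 'env' columns", call. = FALSE)
  }
  df$line <- as.character(df$line); df$env <- as.character(df$env)
  dup <- duplicated(df[, c("line", "env")])
  if (any(dup)) {
    d <- which(dup)[1]
    stop(sprintf("duplicate (line, env) record: (%s, %s)", df$line[d], df$env[d]),
         call. = FALSE)
  }
  trait_cols <- setdiff(names(df), c("line", "env"))
  if (!is.null(traits)) {
    missing_tr <- setdiff(traits, trait_cols)
    if (length(missing_tr)) stop("unknown trait column(s): ",
                                 paste(missing_tr, collapse = ", "), call. = FALSE)
    trait_cols <- traits
  }
  if (length(trait_cols) < 1) stop("no trait columns found", call. = FALSE)
  for (tc in trait_cols) df[[tc]] <- as.numeric(df[[tc]])
  if (!is.null(geno)) {
    unknown <- setdiff(unique(df$line), rownames(geno))
    if (length(unknown) > 0) {
      stop("phenotype lines without genotypes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  df[, c("line", "env", trait_cols)]
}

#' Write a phenotype table as CSV
#'
#' @param pheno long-format phenotype data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run configuration for the prediction pipeline
#'
#' Validated bundle of every pipeline option; defaults mirror the analysis
#' choices (centering on, scaling off, raw-dosage kinship).
#'
#' @param genotype_path,phenotype_path input files (see [read_genotypes()],
#'   [read_phenotypes()]).
#' @param traits optional trait subset.
#' @param model_type `"ST"`, `"MT"` or `"both"`.
#' @param scheme `"5FCV"`, `"LOEO"` or `"both"`.
#' @param component_grid candidate component counts (NULL = default grid).
#' @param center,scale,kinship_center flags as in [run_5fcv()].
#' @param seed master seed.
#' @param output_dir directory for result artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(genotype_path, phenotype_path, traits = NULL,
                       model_type = c("both", "ST", "MT"),
                       scheme = c("both", "5FCV", "LOEO"),
                       component_grid = NULL, center = TRUE, scale = FALSE,
                       kinship_center = FALSE, seed = 1,
                       output_dir = "plsmet_results") {
  structure(list(
    genotype_path = genotype_path, phenotype_path = phenotype_path,
    traits = traits, model_type = match.arg(model_type),
    scheme = match.arg(scheme), component_grid = component_grid,
    center = center, scale = scale, kinship_center = kinship_center,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "run_config")
}

#' Run the full prediction pipeline and write result artifacts
#'
#' Reads genotypes and phenotypes, runs the requested cross-validation
#' scheme(s) for the requested model type(s), and writes per-run artifacts to
#' `config$output_dir`: record-level predictions
#' (`predictions_<scheme>_<model>.csv`), accuracy summaries
#' (`summary_<scheme>.csv`, ST and MT side by side), chosen component counts
#' (`components.csv`) and a machine-readable `manifest.json` carrying the
#' configuration, its hash and the package version. Identical configurations
#' reproduce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a named list of `cv_result` objects keyed
#'   `<scheme>_<model>`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$genotype_path)) {
    stop("genotype file not found: ", config$genotype_path, call. = FALSE)
  }
  if (!file.exists(config$phenotype_path)) {
    stop("phenotype file not found: ", config$phenotype_path, call. = FALSE)
  }
  geno <- read_genotypes(config$genotype_path)
  pheno <- read_phenotypes(config$phenotype_path, geno = geno,
                           traits = config$traits)
  schemes <- if (config$scheme == "both") c("5FCV", "LOEO") else config$scheme
  models <- if (config$model_type == "both") c("ST", "MT") else config$model_type
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  for (sc in schemes) {
    for (mt in models) {
      message("Running ", sc, " / ", mt, "-PLS ...")
      res <- if (sc == "5FCV") {
        run_5fcv(geno, pheno, model_type = mt, grid = config$component_grid,
                 seed = config$seed, center = config$center,
                 scale = config$scale, kinship_center = config$kinship_center)
      } else {
        run_loeo(geno, pheno, model_type = mt, grid = config$component_grid,
                 seed = config$seed, center = config$center,
                 scale = config$scale, kinship_center = config$kinship_center)
      }
      results[[paste0(sc, "_", mt)]] <- res
      utils::write.csv(res$predictions,
                       file.path(config$output_dir,
                                 sprintf("predictions_%s_%s.csv", sc, mt)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  for (sc in schemes) {
    rep_tab <- cv_report(st = results[[paste0(sc, "_ST")]],
                         mt = results[[paste0(sc, "_MT")]])
    utils::write.csv(format(rep_tab, digits = 6),
                     file.path(config$output_dir, sprintf("summary_%s.csv", sc)),
                     row.names = FALSE, quote = FALSE)
  }
  comp <- do.call(rbind, lapply(names(results), function(k) {
    data.frame(run = k, results[[k]]$chosen_components,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(comp, file.path(config$output_dir, "components.csv"),
                   row.names = FALSE, quote = FALSE)

  cfg_plain <- unclass(config)
  manifest <- list(
    config = cfg_plain,
    config_hash = fnv1a_hash(paste(deparse(cfg_plain), collapse = "")),
    package = "plsmet",
    version = as.character(utils::packageVersion("plsmet")),
    n_lines = nrow(geno), n_markers = ncol(geno),
    n_records = nrow(pheno)
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(results)
}

#' Write simulated fixtures to disk
#'
#' Convenience wrapper: simulates genotypes and phenotypes from a
#' [sim_config()] and writes the genotype TSV, phenotype CSV and the
#' true-signal CSV sidecars (additive values, G-by-E deviations, environment
#' means) to a directory.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of file paths written.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- simulate_genotypes(config)
  sim <- simulate_phenotypes(geno, config)
  paths <- list(
    genotypes = file.path(dir, "genotypes.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    true_additive = file.path(dir, "true_additive.csv"),
    true_gxe = file.path(dir, "true_gxe.csv"),
    true_env_means = file.path(dir, "true_env_means.csv")
  )
  write_genotypes(geno, paths$genotypes)
  write_phenotypes(sim$pheno, paths$phenotypes)
  utils::write.csv(data.frame(line = rownames(sim$true$additive_values),
                              sim$true$additive_values, check.names = FALSE),
                   paths$true_additive, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(cell = rownames(sim$true$gxe_values),
                              sim$true$gxe_values, check.names = FALSE),
                   paths$true_gxe, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(env = rownames(sim$true$env_means),
                              sim$true$env_means, check.names = FALSE),
                   paths$true_env_means, row.names = FALSE, quote = FALSE)
  invisible(paths)
}
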