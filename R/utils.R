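# Internal helpers shared across modules.

frobenius <- function(x) sqrt(sum(x^2))

#' @noRd
#' Deterministic sub-stream seed derived from a master seed and a stream name.
#' Keeps fold assignment stable when unrelated draws (e.g. extra traits) are
#' added, and stays below 2^31 so it is always a valid R integer seed.
substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' @noRd
#' Run `expr` under a local RNG state seeded with `seed`, restoring the
#' caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @noRd
#' Assign n items to k folds of sizes differing by at most one, in a random
#' seeded order.
fold_assignment <- function(n, k, seed) {
  stopifnot(n >= k, k >= 2)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# FNV-1a hash of a character string, reported as hex; used to fingerprint run
# configurations in output manifests.
fnv1a_hash <- function(x) {
  h <- 2166136261
  for (code in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stop_if_not_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
}
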