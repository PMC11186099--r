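#' Derive child seeds from a master seed
#'
#' All stochastic entry points in the package take an explicit integer seed;
#' operations that need several independent RNG streams derive them from the
#' master seed with this helper so that a single seed reproduces a whole run.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @param salt optional string mixed into the stream so different call sites
#'   with the same master seed get unrelated children.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n, salt = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  off <- if (nzchar(salt)) sum(utf8ToInt(salt)) %% 10000L else 0L
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer((abs(seed) + off) %% (.Machine$integer.max - 1)))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr under a local seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

# Column-wise L2 normalization; zero columns left at zero.
l2_normalize_cols <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2, nrm, "/")
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}
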