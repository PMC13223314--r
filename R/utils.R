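#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd var predict approx fft
#' @importFrom utils head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib csaemg, .registration = TRUE
NULL

# Deterministic substream seeds: one global seed fans out to named streams so
# independent stages (synthesis, init, training, folds) are reproducible in
# isolation. Kept below 2^31 - 1.
substream_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 131 + ch) %% 2147483629
  }
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bit-exact digest of a parameter group, for freeze-contract checks.
param_digest <- function(params) {
  vapply(params, function(p) {
    v <- as.numeric(p)
    sum(v * seq_along(v)) + sum(v^2)
  }, numeric(1))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
  invisible(x)
}
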