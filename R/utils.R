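## Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Scalar fraction check; f may be 0 or 1.
#' @noRd
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1], got %s",
                 name, deparse(substitute(x, env = parent.frame()))),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Geometric mean
#'
#' Geometric mean of strictly positive values, the natural location summary
#' for ratio-scale quantities such as RT-qPCR fold-changes under
#' multiplicative noise.
#'
#' @param x numeric vector of positive values.
#' @return a single positive number.
#' @export
geometric_mean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric_mean() requires finite positive values", call. = FALSE)
  }
  exp(mean(log(x)))
}

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream (the global .Random.seed is restored on exit).
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Derive a per-table stream seed from a root seed so that adding one table
## does not shift the draws of another. Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(root, tag) {
  stopifnot(is.numeric(root), length(root) == 1L)
  offs <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(root) * 7919 + offs) %% 2147483647)
}

## Small FNV-1a-style hash of a deparsed R object, for report provenance.
#' @noRd
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
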