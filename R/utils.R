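# Internal helpers shared across modules.

#' Evaluate an expression with a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so library calls do not perturb user-level streams.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a child seed for a named random stream
#'
#' Hashes a root seed together with one or more stream labels into a new
#' 32-bit seed, keeping independent randomness streams (trials, channel
#' noise, augmentation draws, experiment stages) reproducible without
#' sharing RNG state. FNV-1a style string hash; avoids an external digest
#' dependency.
#'
#' @param seed Root seed.
#' @param ... Stream labels (coerced to character).
#' @return An integer seed.
#' @export
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- as.integer(charToRaw(key))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2147483629
  }
  as.integer(h)
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) return(v * 0)
  v / n
}

# Pearson r that returns NA (not an error/NaN warning) for degenerate inputs.
safe_cor <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
  stats::cor(a, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
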