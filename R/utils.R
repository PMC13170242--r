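#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded helpers do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Derive a child seed from a master seed and a key
#'
#' Deterministic integer hash (multiplicative, mod 2^31 - 1) so that cohorts,
#' folds, and augmentation draws are reproducible from one master seed while
#' remaining mutually independent.
#'
#' @param master_seed Integer master seed.
#' @param key Character or integer distinguishing the consumer.
#' @return An integer in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(master_seed, key) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  bytes <- utf8ToInt(paste0(as.character(key), collapse = ""))
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 2) + 1)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}
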