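#' @keywords internal
"_PACKAGE"

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be TRUE or FALSE", name)
  x
}

check_count <- function(x, name, min = 1L) {
  check_scalar(x, name)
  if (x != round(x) || x < min)
    stopf("'%s' must be an integer >= %d (got %s)", name, min, format(x))
  as.integer(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never disturb the
#' caller's RNG stream.
#' @param seed integer seed; `NULL` leaves the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation, kept below 2^31 so it is a valid R seed.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + (as.double(p) %% 2147483647) + 1) %% 2147483629
  as.integer(h)
}
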