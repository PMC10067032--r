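# Internal helpers: seed management, argument checks.

ARM_LEVELS <- c("algorithm", "clinician")
PROFESSION_LEVELS <- c("doctor", "nurse", "other")

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random-number stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed for a named component, so that one master seed drives
# independent, individually reproducible streams (allocation, covariates,
# responses, dropout). Kept below 2^31 - 1.
derive_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 1000003
  as.integer((as.numeric(seed) %% 2147483647 + h * 2011) %% 2147483647)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  low_ok <- if (strict_lower) x > lower else x >= lower
  up_ok <- if (strict_upper) x < upper else x <= upper
  if (!low_ok || !up_ok) {
    stop(sprintf("`%s` = %g is outside its allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}
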