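#' @keywords internal
"_PACKAGE"

## Vacuum permittivity [F/m]
EPS0 <- 8.8541878128e-12

#' Stop with a classed validation error
#' @noRd
stop_validation <- function(msg, class = "kneebis_validation_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Stop with a classed domain error (inputs outside the physical domain)
#' @noRd
stop_domain <- function(msg) {
  stop_validation(msg, class = c("kneebis_domain_error", "kneebis_validation_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(sprintf("'%s' must be a finite numeric scalar", name))
  if (strict_lower && x <= lower)
    stop_validation(sprintf("'%s' must be > %g (got %g)", name, lower, x))
  if (!strict_lower && x < lower)
    stop_validation(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  if (x > upper)
    stop_validation(sprintf("'%s' must be <= %g (got %g)", name, upper, x))
  invisible(x)
}

#' Evaluate a function with a locally-scoped RNG seed
#'
#' Saves and restores `.Random.seed` so package functions never leak global
#' random state.
#' @noRd
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
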