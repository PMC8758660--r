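## The seven dielectric degrees of freedom of the personalization, with the
## tissue-table slot each one occupies and its fitting transform. Delta_eps,
## tau and sigma_dc are fitted in log space (they span many decades); the
## broadening exponents alpha in a bounded logit space.
ALPHA_LO <- 1e-4
ALPHA_HI <- 0.95

personalization_parameter_info <- function() {
  data.frame(
    name = c("WetSkin.delta_eps3", "WetSkin.delta_eps4", "Fat.alpha4",
             "Fat.sigma_dc", "MuscleParallel.alpha3", "MuscleParallel.tau4",
             "MuscleParallel.sigma_dc"),
    tissue = c("Wet Skin", "Wet Skin", "Fat", "Fat", "Muscle (Parallel)",
               "Muscle (Parallel)", "Muscle (Parallel)"),
    field = c("delta_eps", "delta_eps", "alpha", "sigma_dc", "alpha", "tau",
              "sigma_dc"),
    index = c(3L, 4L, 4L, NA, 3L, 4L, NA),
    transform = c("log", "log", "logit", "log", "logit", "log", "log"),
    stringsAsFactors = FALSE)
}

#' The seven personalization parameters
#'
#' Extracts (or constructs) the named seven-scalar parameter set driving the
#' model customization: the wet-skin increments of dispersions 3 and 4, the
#' fat broadening exponent of dispersion 4 and static conductivity, and the
#' parallel-muscle broadening exponent of dispersion 3, relaxation time of
#' dispersion 4 and static conductivity.
#'
#' @param tissues Tissue table to read the values from.
#' @return Named numeric vector of length 7 with class
#'   `"personalization_parameters"`.
#' @export
default_parameters <- function(tissues = default_tissue_table()) {
  validate_tissue_table(tissues)
  info <- personalization_parameter_info()
  v <- vapply(seq_len(nrow(info)), function(k) {
    p <- tissues[[info$tissue[k]]]
    switch(info$field[k],
           sigma_dc = p$sigma_dc,
           delta_eps = p$dispersions[[info$index[k]]]$delta_eps,
           tau = p$dispersions[[info$index[k]]]$tau,
           alpha = p$dispersions[[info$index[k]]]$alpha)
  }, numeric(1))
  names(v) <- info$name
  structure(v, class = "personalization_parameters")
}

validate_parameters <- function(theta) {
  info <- personalization_parameter_info()
  if (length(theta) != 7L)
    stop_validation("exactly seven personalization parameters are required")
  if (is.null(names(theta))) names(theta) <- info$name
  if (!setequal(names(theta), info$name))
    stop_validation(paste0("parameter names must be: ",
                           paste(info$name, collapse = ", ")))
  theta <- theta[info$name]
  bad <- (info$transform == "log" & theta <= 0) |
    (info$transform == "logit" & (theta < 0 | theta >= 1))
  if (any(bad))
    stop_validation(paste0("parameter(s) out of bounds: ",
                           paste(info$name[bad], collapse = ", ")))
  structure(theta, class = "personalization_parameters")
}

#' Substitute the seven parameters into a tissue table
#'
#' @param tissues Base tissue table.
#' @param theta Named seven-parameter vector (see [default_parameters()]).
#' @return A modified tissue table.
#' @export
apply_parameters <- function(tissues, theta) {
  validate_tissue_table(tissues)
  theta <- validate_parameters(theta)
  info <- personalization_parameter_info()
  for (k in seq_len(nrow(info))) {
    p <- tissues[[info$tissue[k]]]
    val <- as.numeric(theta[[info$name[k]]])
    if (info$field[k] == "sigma_dc") p$sigma_dc <- val
    else p$dispersions[[info$index[k]]][[info$field[k]]] <- val
    tissues[[info$tissue[k]]] <- p
  }
  tissues
}

## Transformed (unbounded) fitting space.
to_transformed <- function(theta) {
  info <- personalization_parameter_info()
  t <- numeric(7)
  for (k in 1:7) {
    v <- theta[[k]]
    t[k] <- if (info$transform[k] == "log") log(v)
    else {
      p <- (min(max(v, ALPHA_LO), ALPHA_HI - 1e-12) - ALPHA_LO) /
        (ALPHA_HI - ALPHA_LO)
      p <- min(max(p, 1e-12), 1 - 1e-12)
      log(p / (1 - p))
    }
  }
  names(t) <- info$name
  t
}

from_transformed <- function(t) {
  info <- personalization_parameter_info()
  v <- numeric(7)
  for (k in 1:7) {
    v[k] <- if (info$transform[k] == "log") exp(t[[k]])
    else ALPHA_LO + (ALPHA_HI - ALPHA_LO) * stats::plogis(t[[k]])
  }
  names(v) <- info$name
  structure(v, class = "personalization_parameters")
}

#' @export
print.personalization_parameters <- function(x, ...) {
  cat("Personalization parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}
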