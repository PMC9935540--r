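#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the scores of a functional space
#'
#' @param x a `functional_space` from [ordinate()].
#' @param ... unused.
#' @return the scores tibble (one row per simulation).
#' @method tidy functional_space
#' @export
tidy.functional_space <- function(x, ...) x$scores

#' One-row summary of a functional space
#'
#' @param x a `functional_space`.
#' @param ... unused.
#' @return tibble with `n_simulations`, `n_intervals_kept`,
#'   `var_pc1`, `var_pc2` (proportions of variance).
#' @method glance functional_space
#' @export
glance.functional_space <- function(x, ...) {
  ev <- x$explained_variance
  tibble::tibble(n_simulations = nrow(x$scores),
                 n_intervals_kept = length(x$kept_columns),
                 var_pc1 = ev[1L],
                 var_pc2 = if (length(ev) >= 2L) ev[2L] else NA_real_)
}

#' Tidy the signed sides of a functional triangle
#'
#' @param x a `functional_triangle`.
#' @param ... unused.
#' @return the sides tibble with a `specimen_id` column prepended.
#' @method tidy functional_triangle
#' @export
tidy.functional_triangle <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(specimen_id = as.character(x$specimen_id)),
                   x$sides)
}

#' One-row summary of a functional triangle
#'
#' @param x a `functional_triangle`.
#' @param ... unused.
#' @return one row of [triangle_report()].
#' @method glance functional_triangle
#' @export
glance.functional_triangle <- function(x, ...) triangle_report(list(x))

#' @method tidy regression_result
#' @export
tidy.regression_result <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$x_label),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance regression_result
#' @export
glance.regression_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value, n = x$n)
}
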