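#' Tidy a cross-mapping background model
#'
#' @param x A `subgenome_background` from [estimate_background()].
#' @param ... Unused.
#' @return `tidy()` returns one row per estimated term (the background rate
#'   `beta` and its implied minor-side Relative Coverage `2 * beta`);
#'   `glance()` returns a one-row summary of the fit.
#' @export
tidy.subgenome_background <- function(x, ...) {
  tibble(
    term = c("beta", "minor_relative_coverage"),
    estimate = c(x$beta, 2 * x$beta)
  )
}

#' @rdname tidy.subgenome_background
#' @export
glance.subgenome_background <- function(x, ...) {
  tibble(
    beta = x$beta,
    iterations = x$iterations,
    converged = x$converged,
    n_pure_windows = x$n_pure_windows,
    from_fallback = x$from_fallback
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
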