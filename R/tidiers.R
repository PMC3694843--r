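# broom-style tidiers for fitted objects.

#' Tidy an elasticity fit
#'
#' @param x An `elasticity_fit` (or `elasticity_params`) object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy elasticity_fit
#' @export
tidy.elasticity_fit <- function(x, ...) {
  tibble(term = c("G_max", "E_m"), estimate = c(x$G_max, x$E_m))
}

#' @method tidy elasticity_params
#' @export
tidy.elasticity_params <- tidy.elasticity_fit

#' One-row summary of an elasticity fit
#'
#' @param x An `elasticity_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `G_max`, `E_m`, `rss`, `n_points`.
#' @method glance elasticity_fit
#' @export
glance.elasticity_fit <- function(x, ...) {
  tibble(G_max = x$G_max, E_m = x$E_m,
         rss = x$rss %||% NA_real_,
         n_points = x$n_points %||% NA_integer_)
}
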