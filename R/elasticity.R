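# Hyperbolic expression-growth elasticity model and its inversion.
#
# Growth rate of a cell expressing a protein variant at relative expression
# strength E with per-molecule function F follows a binding-curve elasticity:
#   G(E, F) = G_max * (E * F) / (E_m + E * F)
# where E_m is the net function giving half-maximal growth. Selection
# coefficients are defined against the wild-type sequence (F = 1) in the same
# construct: s = G(E, F) / G(E, 1) - 1.

#' Elasticity parameters
#'
#' Container for the two parameters of the hyperbolic elasticity function
#' relating net protein function (expression strength E times per-molecule
#' function F) to growth rate.
#'
#' @param G_max Maximal growth rate at saturating net function (per hour).
#' @param E_m Relative net function giving half-maximal growth
#'   (dimensionless, endogenous expression = 1).
#'
#' @return An object of class `elasticity_params`.
#' @examples
#' elasticity_params(G_max = 0.45, E_m = 0.014)
#' @export
elasticity_params <- function(G_max, E_m) {
  if (!is.numeric(G_max) || length(G_max) != 1 || !is.finite(G_max) || G_max <= 0)
    abort("`G_max` must be a single positive number.")
  if (!is.numeric(E_m) || length(E_m) != 1 || !is.finite(E_m) || E_m <= 0)
    abort("`E_m` must be a single positive number.")
  structure(list(G_max = G_max, E_m = E_m), class = "elasticity_params")
}

#' @export
print.elasticity_params <- function(x, ...) {
  cat("<elasticity_params>  G_max =", format(x$G_max),
      "per hr,  E_m =", format(x$E_m), "\n")
  invisible(x)
}

#' Default elasticity parameters for the Hsp90 system
#'
#' The fitted maximal growth rate (0.45 per hour) and half-maximal net
#' function (E_m = 0.014) for plasmid-rescued Hsp90 shutoff yeast.
#'
#' @return An `elasticity_params` object.
#' @export
hsp90_elasticity <- function() elasticity_params(G_max = 0.45, E_m = 0.014)

#' Growth rate from the elasticity function
#'
#' Evaluates `G = G_max * E * F / (E_m + E * F)`.
#'
#' @param E Relative expression strength (>= 0, endogenous = 1). Vectorized.
#' @param F Per-molecule function relative to wild type (>= 0). Vectorized.
#' @param params An [elasticity_params()] object.
#'
#' @return Growth rate(s) in per hour; 0 when `E * F` is 0 and always below
#'   `G_max`.
#' @examples
#' growth_rate(1, 1, hsp90_elasticity())
#' @export
growth_rate <- function(E, F, params) {
  stopifnot(inherits(params, "elasticity_params"))
  if (any(E < 0, na.rm = TRUE) || any(F < 0, na.rm = TRUE))
    abort("`E` and `F` must be non-negative.")
  net <- E * F
  params$G_max * net / (params$E_m + net)
}

#' Effective selection coefficient implied by a functional defect
#'
#' The selection coefficient of a variant with per-molecule function `F`
#' expressed at strength `E`, relative to the wild-type sequence (F = 1) in
#' the same construct: `s = G(E, F) / G(E, 1) - 1`.
#'
#' @inheritParams growth_rate
#' @return Selection coefficient(s): 0 for F = 1, -1 for F = 0, monotone
#'   increasing in F.
#' @examples
#' selection_from_function(1, 0.21, hsp90_elasticity())
#' @export
selection_from_function <- function(E, F, params) {
  stopifnot(inherits(params, "elasticity_params"))
  if (any(E <= 0, na.rm = TRUE))
    abort("`E` must be positive: fitness is undefined without expression.")
  if (any(F < 0, na.rm = TRUE)) abort("`F` must be non-negative.")
  # ratio form: W = F * (E_m + E) / (E_m + E * F); G_max cancels
  E_m <- params$E_m
  F * (E_m + E) / (E_m + E * F) - 1
}

#' Invert a selection coefficient to per-molecule function
#'
#' Solves the elasticity model for F given an observed selection coefficient:
#' with `g = (1 + s) * E / (E_m + E)`, `F = E_m * g / (E * (1 - g))`.
#' This is the exact inverse of [selection_from_function()].
#'
#' @param s Effective selection coefficient(s).
#' @param E Relative expression strength (> 0).
#' @param params An [elasticity_params()] object.
#'
#' @return Per-molecule function F. `s <= -1` returns `-Inf` as a
#'   lower-bound marker (function at or below the null detection floor);
#'   `g >= 1` (fitness at or above the model ceiling) returns `Inf` as an
#'   upper-unbounded marker.
#' @examples
#' invert_function(-0.05, 1, hsp90_elasticity())
#' @export
invert_function <- function(s, E, params) {
  stopifnot(inherits(params, "elasticity_params"))
  if (any(E <= 0, na.rm = TRUE)) abort("`E` must be positive.")
  E_m <- params$E_m
  g <- (1 + s) * E / (E_m + E)
  out <- E_m * g / (E * (1 - g))
  out[s <= -1] <- -Inf
  out[g >= 1] <- Inf
  out
}

#' Fit growth rate from an OD time course
#'
#' Ordinary least-squares slope of `ln(od600 * cumulative_dilution)` against
#' time. Cultures kept in log phase by periodic dilution are handled through
#' the cumulative dilution factor.
#'
#' @param curve Data frame with columns `time_hr`, `od600` and (optionally)
#'   `cumulative_dilution` (defaults to 1, i.e. no dilution).
#'
#' @return A one-row tibble with `growth_rate` (per hour), `intercept`,
#'   `r_squared`, and `n_points`.
#' @examples
#' fit_growth_rate(data.frame(time_hr = 0:5, od600 = 0.1 * 2^(0:5)))
#' @export
fit_growth_rate <- function(curve) {
  curve <- as_tibble(curve)
  if (!all(c("time_hr", "od600") %in% names(curve)))
    abort("`curve` needs columns `time_hr` and `od600`.")
  if (!"cumulative_dilution" %in% names(curve)) curve$cumulative_dilution <- 1
  if (nrow(curve) < 3)
    abort("Need at least 3 OD readings to fit a growth rate.")
  if (any(curve$od600 <= 0) || any(curve$cumulative_dilution < 1))
    abort("`od600` must be positive and `cumulative_dilution` >= 1.")
  if (is.unsorted(curve$time_hr, strictly = TRUE))
    abort("`time_hr` must be strictly increasing.")
  fit <- lm(log(od600 * cumulative_dilution) ~ time_hr, data = curve)
  # summary.lm warns on noise-free data; the R^2 itself is well defined
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(
    growth_rate = unname(coef(fit)[2]),
    intercept   = unname(coef(fit)[1]),
    r_squared   = r2,
    n_points    = nrow(curve)
  )
}

#' Fit the elasticity function to (expression, growth-rate) points
#'
#' Nonlinear least squares fit of the wild-type elasticity curve
#' `G = G_max * E / (E_m + E)` (F = 1) to measured growth rates across an
#' expression ladder. Uses bounded Levenberg-Marquardt with `G_max`
#' initialized at the maximum observed growth rate and `E_m` at the
#' expression value whose growth is nearest half of that maximum.
#'
#' @param points Data frame with columns `E` (relative expression) and
#'   `growth_rate` (per hour).
#' @param max_iter Iteration cap for the optimizer.
#'
#' @return An object of class `elasticity_fit`: an [elasticity_params()]
#'   carrying, in addition, `rss`, `n_points`, and the `data` fitted.
#'   Supports [tidy()], [glance()] and [autoplot_elasticity()].
#' @export
fit_elasticity <- function(points, max_iter = 500) {
  points <- as_tibble(points)
  if (!all(c("E", "growth_rate") %in% names(points)))
    abort("`points` needs columns `E` and `growth_rate`.")
  pts <- dplyr::distinct(points, .data$E, .keep_all = TRUE)
  if (nrow(pts) < 3)
    abort("Need at least 3 distinct expression strengths to fit elasticity.")
  g_max0 <- max(points$growth_rate)
  e_m0 <- points$E[which.min(abs(points$growth_rate - g_max0 / 2))]
  e_m0 <- max(e_m0, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      growth_rate ~ G_max * E / (E_m + E),
      data = points,
      start = list(G_max = g_max0, E_m = e_m0),
      lower = c(G_max = 1e-12, E_m = 1e-12),
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ptol = 1e-10, ftol = 1e-15
      )
    ),
    error = function(e) {
      abort(paste0(
        "Elasticity fit did not converge (last start: G_max = ",
        format(g_max0), ", E_m = ", format(e_m0), "): ", conditionMessage(e)
      ))
    }
  )
  est <- coef(fit)
  out <- elasticity_params(G_max = unname(est["G_max"]), E_m = unname(est["E_m"]))
  out$rss <- sum(stats::resid(fit)^2)
  out$n_points <- nrow(points)
  out$data <- points
  class(out) <- c("elasticity_fit", "elasticity_params")
  out
}

#' @export
print.elasticity_fit <- function(x, ...) {
  cat("<elasticity_fit>  G_max =", format(x$G_max),
      "per hr,  E_m =", format(x$E_m),
      " (rss =", format(x$rss, digits = 3),
      ", n =", x$n_points, ")\n")
  invisible(x)
}

#' Informative per-molecule function range for a construct
#'
#' The window of per-molecule function over which fitness measurements in a
#' given construct are informative: below the lower edge variants are
#' null-like (depleting too fast to monitor precisely); above the upper edge
#' growth is within `wt_margin` of the construct's own wild type, where
#' growth and function decouple. The upper edge is reported as unbounded
#' (`Inf`) when it exceeds `cap`, i.e. when essentially the whole range above
#' the lower edge is informative.
#'
#' @param construct A one-row data frame (or list) with at least `name`, `E`
#'   and `s_cut` (the null-like selection-coefficient cutoff, <= 0); see
#'   [hsp90_constructs()].
#' @param params An [elasticity_params()] object.
#' @param wt_margin Growth-defect fraction below the construct's wild type at
#'   which coupling is considered lost (default 0.05).
#' @param cap Upper-edge value at and above which the range is reported
#'   unbounded (default 0.8).
#'
#' @return A one-row tibble: `construct`, `E`, `lower`, `upper` (`Inf` when
#'   unbounded), `unbounded`.
#' @examples
#' gpd <- hsp90_constructs()[1, ]
#' function_range(gpd, hsp90_elasticity())
#' @export
function_range <- function(construct, params, wt_margin = 0.05, cap = 0.8) {
  construct <- as.list(as_tibble(construct)[1, ])
  stopifnot(!is.null(construct$E), !is.null(construct$s_cut))
  if (construct$s_cut >= -wt_margin)
    abort(paste0("Empty informative range for ", construct$name,
                 ": null cutoff ", construct$s_cut,
                 " is not below -wt_margin = ", -wt_margin, "."))
  lower <- invert_function(construct$s_cut, construct$E, params)
  upper <- invert_function(-wt_margin, construct$E, params)
  unbounded <- is.infinite(upper) || upper >= cap
  con_name <- construct$name %||% NA_character_
  con_E <- construct$E
  tibble(
    construct = con_name,
    E = con_E,
    lower = lower,
    upper = if (unbounded) Inf else upper,
    unbounded = unbounded
  )
}

#' Informative function ranges for a table of constructs
#'
#' @param constructs Data frame of constructs (see [hsp90_constructs()]).
#' @inheritParams function_range
#' @return A tibble with one row per construct, ordered as given.
#' @export
function_range_table <- function(constructs, params, wt_margin = 0.05,
                                 cap = 0.8) {
  constructs <- as_tibble(constructs)
  purrr::map_dfr(seq_len(nrow(constructs)), function(i) {
    function_range(constructs[i, ], params, wt_margin = wt_margin, cap = cap)
  })
}

#' Functional defect hidden below a given growth defect
#'
#' How much per-molecule function can be lost before growth slows by
#' `growth_defect` relative to wild type at expression strength `E`. The
#' returned `F_star` solves `selection_from_function(E, F) = -growth_defect`;
#' `percent_hidden = (1 - F_star) * 100`.
#'
#' @param params An [elasticity_params()] object.
#' @param E Relative expression strength (default endogenous, 1).
#' @param growth_defect Fractional growth defect considered measurable
#'   (default 0.05).
#'
#' @return A one-row tibble with `F_star` and `percent_hidden`.
#' @examples
#' hidden_defect_threshold(hsp90_elasticity())
#' @export
hidden_defect_threshold <- function(params, E = 1, growth_defect = 0.05) {
  if (growth_defect <= 0 || growth_defect >= 1)
    abort("`growth_defect` must be in (0, 1).")
  f_star <- invert_function(-growth_defect, E, params)
  tibble(F_star = f_star, percent_hidden = (1 - f_star) * 100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
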