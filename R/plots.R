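# ggplot2 figures for the main result types.

#' Plot the elasticity curve with its data
#'
#' Fitted hyperbolic growth-versus-expression curve on a log expression
#' axis, with the fitted (E, growth-rate) points when available.
#'
#' @param object An `elasticity_fit` or `elasticity_params` object.
#' @param E_range Expression range for the curve (default 1e-3 to 1).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot elasticity_fit
#' @export
autoplot.elasticity_fit <- function(object, E_range = c(1e-3, 1), ...) {
  grid <- tibble(E = exp(seq(log(E_range[1]), log(E_range[2]),
                             length.out = 200)))
  grid$G <- growth_rate(grid$E, 1, object)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$E, y = .data$G)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative expression strength E",
                  y = "growth rate (per hr)",
                  title = sprintf("Elasticity: G_max = %.3g/hr, E_m = %.3g",
                                  object$G_max, object$E_m)) +
    ggplot2::theme_minimal()
  if (!is.null(object$data))
    p <- p + ggplot2::geom_point(data = object$data,
                                 ggplot2::aes(y = .data$growth_rate),
                                 size = 2)
  p
}

#' @method autoplot elasticity_params
#' @export
autoplot.elasticity_params <- autoplot.elasticity_fit

#' Histogram of a distribution of fitness (or function) effects
#'
#' @param values Selection coefficients (or function values).
#' @param binwidth Bin width (default 0.05).
#' @param xlab Axis label.
#' @return A ggplot.
#' @export
plot_dfe <- function(values, binwidth = 0.05,
                     xlab = "effective selection coefficient s") {
  ggplot2::ggplot(tibble(v = values[is.finite(values)]),
                  ggplot2::aes(x = .data$v)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::labs(x = xlab, y = "substitutions") +
    ggplot2::theme_minimal()
}

#' Epistasis scatter: reduced versus endogenous expression strength
#'
#' @param epi Output of [epistasis()] (optionally several constructs
#'   row-bound with a `construct` column).
#' @return A ggplot.
#' @export
plot_epistasis <- function(epi) {
  p <- ggplot2::ggplot(epi, ggplot2::aes(x = .data$s_endog,
                                         y = .data$s_reduced)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1.3) +
    ggplot2::labs(x = "s at endogenous expression",
                  y = "s at reduced expression") +
    ggplot2::theme_minimal()
  if ("construct" %in% names(epi))
    p <- p + ggplot2::facet_wrap(~construct)
  p
}

#' Competition trajectories on the log-ratio scale
#'
#' @param trajectories Output of [simulate_competition()].
#' @param sample_every Plot every n-th integration step (default 10).
#' @return A ggplot of `ln(N/N_WT)` against time per variant.
#' @export
plot_trajectories <- function(trajectories, sample_every = 10) {
  wt <- trajectories |>
    filter(.data$variant == "WT") |>
    select("time_hr", wt_abundance = "abundance")
  d <- trajectories |>
    inner_join(wt, by = "time_hr") |>
    mutate(log_ratio = log(.data$abundance / .data$wt_abundance)) |>
    group_by(.data$variant) |>
    filter(row_number() %% sample_every == 1) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_hr, y = .data$log_ratio,
                                  colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hours", y = "ln(N / N_WT)", colour = NULL) +
    ggplot2::theme_minimal()
}
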