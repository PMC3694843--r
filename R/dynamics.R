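# Numerical-integration competition models under constant (CE) or linearly
# increasing (LIE) expression. Stepwise integration of dN/dt = G(E(t), F) * N
# with dt = 0.1 h by default; expression rises multiplicatively as
# E(t) = E_0 * (1 + tau * t). The default step is geometric
# (N <- N * exp(G dt), i.e. Euler on ln N), exact under constant expression;
# a plain forward-Euler step is available for comparison.

#' Dynamics configuration
#'
#' @param model `"CE"` (constant expression) or `"LIE"` (linearly increasing
#'   expression).
#' @param E_0 Expression strength at the start of the modeled window.
#' @param tau Fractional expression increase rate (per hour); ignored by CE.
#' @param params [elasticity_params()].
#' @param dt Euler step (hours, default 0.1).
#' @param horizon Simulated duration (hours, default 36).
#' @return A list of class `dynamics_config`.
#' @examples
#' dynamics_config("LIE", E_0 = 0.016, tau = 0.11, params = hsp90_elasticity())
#' @export
dynamics_config <- function(model = c("CE", "LIE"), E_0, tau = 0,
                            params = hsp90_elasticity(), dt = 0.1,
                            horizon = 36) {
  model <- match.arg(model)
  if (E_0 <= 0) abort("`E_0` must be positive.")
  if (is.na(tau) || tau < 0) abort("`tau` must be >= 0.")
  if (dt <= 0 || horizon < dt)
    abort("Need `dt` > 0 and `horizon` >= `dt`.")
  structure(list(model = model, E_0 = E_0, tau = tau, params = params,
                 dt = dt, horizon = horizon),
            class = "dynamics_config")
}

#' Expression strength at time t
#'
#' CE: `E(t) = E_0`. LIE: `E(t) = E_0 * (1 + tau * t)` — the fold increase
#' relative to the window start grows linearly in time.
#'
#' @param t Hours since the start of the modeled window (>= 0, vectorized).
#' @param config A [dynamics_config()].
#' @return Expression strength(s).
#' @export
expression_at <- function(t, config) {
  stopifnot(inherits(config, "dynamics_config"))
  if (any(t < 0)) abort("`t` must be non-negative.")
  if (config$model == "CE") rep(config$E_0, length(t))
  else config$E_0 * (1 + config$tau * t)
}

#' Simulate a bulk competition by numerical integration
#'
#' Forward-Euler integration of `dN_v/dt = G(E(t), F_v) * N_v` for a set of
#' variants with per-molecule functions `F_list` plus the wild type
#' (F = 1). Abundances are absolute (no normalization during growth);
#' frequencies are obtained by normalizing at each sampled time.
#'
#' The default `"log"` step advances `ln N` by `G(E(t)) * dt` per step
#' (geometric update), which is exact when expression is constant within the
#' step and in particular reproduces the closed-form exponential under the
#' CE model; `"linear"` is plain forward Euler on N and carries a
#' growth-discretization bias of order `(G dt)^2` per step.
#'
#' @param F_list Named (or unnamed) numeric vector of per-molecule functions
#'   (all >= 0). A wild-type entry `WT` with F = 1 is appended if absent.
#' @param config A [dynamics_config()].
#' @param N0 Initial abundances, recycled (default 1).
#' @param step `"log"` (default) or `"linear"` update per time step.
#' @return Tibble: `time_hr`, `variant`, `F`, `abundance`, `frequency`.
#' @export
simulate_competition <- function(F_list, config, N0 = 1,
                                 step = c("log", "linear")) {
  stopifnot(inherits(config, "dynamics_config"))
  step <- match.arg(step)
  if (any(F_list < 0)) abort("All `F_list` entries must be >= 0.")
  if (is.null(names(F_list)))
    names(F_list) <- paste0("F=", format(F_list))
  if (!"WT" %in% names(F_list)) F_list <- c(F_list, WT = 1)
  nv <- length(F_list)
  N0 <- rep_len(N0, nv)
  steps <- floor(config$horizon / config$dt + 1e-9)
  times <- seq(0, by = config$dt, length.out = steps + 1)
  N <- matrix(NA_real_, nrow = steps + 1, ncol = nv,
              dimnames = list(NULL, names(F_list)))
  N[1, ] <- N0
  for (k in seq_len(steps)) {
    E_t <- expression_at(times[k], config)
    G <- growth_rate(E_t, F_list, config$params)
    N[k + 1, ] <- if (step == "log") N[k, ] * exp(G * config$dt)
                  else N[k, ] * (1 + G * config$dt)
  }
  freq <- N / rowSums(N)
  tibble(
    time_hr = rep(times, times = nv),
    variant = rep(names(F_list), each = steps + 1),
    F = rep(unname(F_list), each = steps + 1),
    abundance = as.vector(N),
    frequency = as.vector(freq)
  )
}

#' Slopes of log abundance ratios to wild type
#'
#' Least-squares slope of `ln(N_v / N_wt)` against time over a fitting
#' window, per variant — the quantity the sequencing-based selection
#' estimates measure.
#'
#' @param trajectories Output of [simulate_competition()] (must contain a
#'   `WT` variant).
#' @param fit_window Length-2 numeric, hours; default the full range.
#' @return Tibble: `variant`, `F`, `slope` (per hour).
#' @export
trajectory_slope <- function(trajectories, fit_window = NULL) {
  if (!"WT" %in% trajectories$variant)
    abort("Trajectories must include the `WT` variant.")
  if (is.null(fit_window)) fit_window <- range(trajectories$time_hr)
  wt <- trajectories |>
    filter(.data$variant == "WT") |>
    select("time_hr", wt_abundance = "abundance")
  d <- trajectories |>
    inner_join(wt, by = "time_hr") |>
    filter(.data$time_hr >= fit_window[1], .data$time_hr <= fit_window[2])
  if (length(unique(d$time_hr)) < 3)
    abort("Need at least 3 sampled times in the fitting window.")
  d |>
    group_by(.data$variant) |>
    summarise(
      F = .data$F[1],
      slope = {
        y <- log(.data$abundance / .data$wt_abundance)
        x <- .data$time_hr
        sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      },
      .groups = "drop"
    )
}

#' Compare CE and LIE slope estimates
#'
#' Runs both the constant-expression and increasing-expression models over
#' the same variants and window and reports the per-variant slope ratio —
#' the size of the bias incurred by assuming constant expression.
#'
#' @param F_list Per-molecule functions to compete (see
#'   [simulate_competition()]).
#' @param config A [dynamics_config()]; its `model` field is overridden.
#' @param fit_window Passed to [trajectory_slope()].
#' @return Tibble: `variant`, `F`, `slope_ce`, `slope_lie`,
#'   `ratio_ce_lie`.
#' @export
compare_ce_lie <- function(F_list, config, fit_window = NULL) {
  cfg_ce <- config; cfg_ce$model <- "CE"
  cfg_lie <- config; cfg_lie$model <- "LIE"
  s_ce <- trajectory_slope(simulate_competition(F_list, cfg_ce), fit_window) |>
    rename(slope_ce = "slope")
  s_lie <- trajectory_slope(simulate_competition(F_list, cfg_lie), fit_window) |>
    rename(slope_lie = "slope")
  inner_join(s_ce, s_lie, by = c("variant", "F")) |>
    mutate(ratio_ce_lie = .data$slope_ce / .data$slope_lie)
}

#' Predict growth-rate increase under rising expression
#'
#' Growth rate predicted at `t_to` from the growth state at `t_from`, the
#' elasticity function, and the observed linear expression increase:
#' `G_pred = G(E_0 * (1 + tau * (t_to - t_from)), F = 1)`.
#'
#' @param construct One-row construct record carrying `E_0` and `tau` (or a
#'   [dynamics_config()]).
#' @param params [elasticity_params()]; ignored when `construct` is a
#'   `dynamics_config` (which carries its own).
#' @param t_from,t_to Hours bracketing the prediction window.
#' @return A one-row tibble: `E_from`, `E_to`, `G_from`, `G_pred`.
#' @export
predict_growth_increase <- function(construct, params = hsp90_elasticity(),
                                    t_from, t_to) {
  if (inherits(construct, "dynamics_config")) {
    E_0 <- construct$E_0; tau <- construct$tau; params <- construct$params
  } else {
    construct <- as_tibble(construct)[1, ]
    E_0 <- construct$E_0; tau <- construct$tau
  }
  if (is.null(tau) || is.na(tau))
    abort("Construct has no expression-increase rate `tau`.")
  if (is.null(E_0) || is.na(E_0)) abort("Construct has no `E_0`.")
  E_to <- E_0 * (1 + tau * (t_to - t_from))
  tibble(
    E_from = E_0, E_to = E_to,
    G_from = growth_rate(E_0, 1, params),
    G_pred = growth_rate(E_to, 1, params)
  )
}
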