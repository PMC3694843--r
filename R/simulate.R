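# Synthetic-data generators: mutant libraries with known true function,
# bulk-competition count tables with multinomial sequencing noise, growth
# curves with dilution bookkeeping, and expression time courses. Every
# generator is a pure function of (configuration, seed).

#' Draw true per-molecule function for a mutant library
#'
#' Assigns a true per-molecule function `F_true` to every library variant.
#' Draws are made per amino-acid state, so synonymous codons share their
#' value; stop codons are fixed at 0 and wild-type-encoding codons
#' (including synonymous wild type) at 1.
#'
#' Presets:
#' * `"bimodal"` — non-WT substitutions are near-functional
#'   (`F ~ 1 - |N(0, 0.03)|`) with probability `p_null` complement, else
#'   near-null (`F ~ |N(0, 0.02)|`): the shape expected when stability
#'   effects dominate.
#' * `"intermediate"` — `F ~ Uniform(0.1, 0.9)`: a single peak of partial
#'   defects, the shape expected for a rate-limiting functional site.
#' * `"uniform"` — `F ~ Uniform(0, 1)`.
#' * `"planted"` — `F` increases linearly with BLOSUM62 similarity to the
#'   wild-type residue, clipped to `[0, 1]` (for similarity-recovery tests).
#'
#' @param library Library tibble from [build_library()].
#' @param preset One of `"bimodal"`, `"intermediate"`, `"uniform"`,
#'   `"planted"`.
#' @param seed Integer seed; draws are deterministic given (preset, seed).
#' @param p_null Probability of the near-null mode under `"bimodal"`
#'   (default 0.4).
#' @return The library tibble with an `F_true` column.
#' @export
sample_true_function <- function(library, preset = c("bimodal", "intermediate",
                                                     "uniform", "planted"),
                                 seed = 1, p_null = 0.4) {
  preset <- tryCatch(match.arg(preset),
                     error = function(e) abort(paste0("Unknown preset: '",
                                                      preset[1], "'.")))
  wt_aa <- library$aa[library$is_wt_codon]
  names(wt_aa) <- as.character(library$position[library$is_wt_codon])
  states <- dplyr::distinct(library, .data$position, .data$aa)
  n <- nrow(states)
  withr_seed(seed, {
    f <- switch(preset,
      bimodal = {
        null_mode <- runif(n) < p_null
        ifelse(null_mode, abs(rnorm(n, 0, 0.02)),
               pmax(0, 1 - abs(rnorm(n, 0, 0.03))))
      },
      intermediate = runif(n, 0.1, 0.9),
      uniform = runif(n, 0, 1),
      planted = {
        sc <- blosum62_safe(wt_aa[as.character(states$position)], states$aa)
        pmin(1, pmax(0, 0.5 + sc / 8 + rnorm(n, 0, 0.05)))
      }
    )
    states$F_true <- f
  })
  states$F_true[states$aa == "*"] <- 0
  states$F_true[states$aa == wt_aa[as.character(states$position)]] <- 1
  left_join(library, states, by = c("position", "aa"))
}

# BLOSUM62 that maps stops to the matrix minimum instead of erroring.
blosum62_safe <- function(aa1, aa2) {
  out <- rep(min(blosum62_matrix), length(aa2))
  ok <- aa2 %in% rownames(blosum62_matrix) & aa1 %in% rownames(blosum62_matrix)
  out[ok] <- blosum62(aa1[ok], aa2[ok])
  out
}

# Evaluate code under a local RNG state seeded with `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate a bulk-competition count table
#'
#' Generates the sequencing count table for one construct: variant
#' frequencies grow exponentially at the elasticity-model rate
#' `G(E, F_true)` (or by stepwise integration under a time-varying
#' expression model when `dynamics` is given), and reads at each timepoint
#' are drawn multinomially across variants at the stated depth. Time is
#' measured from the first sampled timepoint, where initial frequencies
#' apply.
#'
#' @param truth Library tibble with `F_true` (from
#'   [sample_true_function()]).
#' @param construct One-row construct record with `E` and `timepoints` (see
#'   [hsp90_constructs()]).
#' @param params [elasticity_params()].
#' @param depth Reads per timepoint (recycled across timepoints). `Inf`
#'   disables sampling: expected counts (scaled to 1e9 total) are returned,
#'   so log-ratio slopes are exact.
#' @param seed Integer seed for the multinomial draws.
#' @param wt_fraction Initial frequency mass on the wild-type reference
#'   (default 0.1); the remainder is spread uniformly over the 576 variants.
#' @param dynamics Optional [dynamics_config()] for time-varying expression;
#'   its `E_0` overrides the construct's `E`.
#' @return A count table tibble (identity columns, `wt` flag, `t<hh>` count
#'   columns) with attributes `construct`, `depth`, `seed`.
#' @export
simulate_bulk_competition <- function(truth, construct, params,
                                      depth = 5e5, seed = 1,
                                      wt_fraction = 0.1, dynamics = NULL) {
  construct <- as_tibble(construct)[1, ]
  timepoints <- construct$timepoints[[1]]
  stopifnot(length(timepoints) >= 3, all(depth > 0))
  if (!"F_true" %in% names(truth))
    abort("`truth` must carry `F_true` (see sample_true_function()).")
  nv <- nrow(truth)
  f0 <- c(rep((1 - wt_fraction) / nv, nv), wt_fraction)
  if (any(f0 <= 0)) abort("Initial frequencies must all be positive.")
  F_all <- c(truth$F_true, 1)
  t_rel <- timepoints - timepoints[1]

  if (is.null(dynamics)) {
    G <- growth_rate(construct$E, F_all, params)
    logN <- outer(G, t_rel) + log(f0)   # variants x timepoints
  } else {
    cfg <- dynamics
    cfg$horizon <- max(t_rel)
    traj_t <- seq(0, max(t_rel), by = cfg$dt)
    logN <- matrix(log(f0), nrow = length(F_all), ncol = length(t_rel))
    cum <- log(f0)
    ti <- 1L
    for (k in seq_along(traj_t)) {
      hit <- which(abs(t_rel - traj_t[k]) < cfg$dt / 2)
      if (length(hit)) logN[, hit] <- cum
      if (k < length(traj_t)) {
        G_k <- growth_rate(expression_at(traj_t[k], cfg), F_all, cfg$params)
        cum <- cum + G_k * cfg$dt
      }
    }
  }
  freq <- apply(logN, 2, function(l) { w <- exp(l - max(l)); w / sum(w) })

  depth <- rep_len(depth, length(t_rel))
  counts <- withr_seed(seed, {
    vapply(seq_along(t_rel), function(j) {
      if (is.infinite(depth[j])) freq[, j] * 1e9
      else as.numeric(rmultinom(1, size = depth[j], prob = freq[, j]))
    }, numeric(length(F_all)))
  })
  colnames(counts) <- paste0("t", timepoints)

  out <- bind_rows(
    truth[, c("variant_id", "position", "codon", "aa",
              "is_wt_codon", "is_synonymous_wt", "is_stop")],
    tibble(variant_id = "WT", position = NA_integer_, codon = NA_character_,
           aa = NA_character_, is_wt_codon = NA, is_synonymous_wt = NA,
           is_stop = FALSE)
  )
  out$wt <- as.integer(out$variant_id == "WT")
  out <- bind_cols(out, as_tibble(counts))
  attr(out, "construct") <- construct$name
  attr(out, "depth") <- depth
  attr(out, "seed") <- seed
  out
}

#' Simulate log-phase growth curves across an expression ladder
#'
#' OD time courses at the elasticity-model growth rate for each expression
#' strength, with multiplicative lognormal measurement noise and periodic
#' dilution keeping OD within (0.1, 0.8); the cumulative dilution factor is
#' recorded as a real assay would.
#'
#' @param E_grid Expression strengths to simulate.
#' @param params [elasticity_params()].
#' @param noise_sd Standard deviation of the multiplicative (log scale)
#'   OD noise (default 0, noise-free).
#' @param seed Integer seed.
#' @param times Reading times in hours (default every 2 h to 24 h).
#' @param od_start Starting OD (default 0.1).
#' @return Tibble: `E`, `time_hr`, `od600`, `cumulative_dilution`.
#' @export
simulate_growth_curves <- function(E_grid, params, noise_sd = 0, seed = 1,
                                   times = seq(0, 24, by = 2),
                                   od_start = 0.1) {
  stopifnot(length(E_grid) >= 1)
  withr_seed(seed, {
    purrr::map_dfr(E_grid, function(E) {
      g <- growth_rate(E, 1, params)
      od_true <- od_start
      cum_dil <- 1
      rows <- vector("list", length(times))
      for (i in seq_along(times)) {
        if (i > 1) {
          od_true <- od_true * exp(g * (times[i] - times[i - 1]))
          while (od_true > 0.8) {       # 4x dilution back into log window
            od_true <- od_true / 4
            cum_dil <- cum_dil * 4
          }
        }
        od_obs <- od_true * exp(rnorm(1, 0, noise_sd))
        rows[[i]] <- tibble(E = E, time_hr = times[i], od600 = od_obs,
                            cumulative_dilution = cum_dil)
      }
      bind_rows(rows)
    })
  })
}

#' Simulate a GFP-fusion expression time course
#'
#' Mean expression rising linearly in fold change,
#' `E(t) = E_0 * (1 + tau * (t - t0))`, with multiplicative noise — the
#' sparse flow-cytometry design used to estimate the expression increase
#' rate.
#'
#' @param E_0 Expression at the first timepoint.
#' @param tau Fractional increase rate (per hour).
#' @param times Measurement times (hours), first = reference t0.
#' @param noise_sd Multiplicative (log scale) noise SD (default 0).
#' @param seed Integer seed.
#' @return Tibble: `time_hr`, `expression`, `fold_change` (observed,
#'   relative to the first timepoint).
#' @export
simulate_gfp_timecourse <- function(E_0, tau, times = c(19, 36, 48),
                                    noise_sd = 0, seed = 1) {
  if (is.unsorted(times, strictly = TRUE))
    abort("`times` must be strictly increasing.")
  withr_seed(seed, {
    mean_e <- E_0 * (1 + tau * (times - times[1]))
    obs <- mean_e * exp(rnorm(length(times), 0, noise_sd))
    tibble(time_hr = times, expression = obs, fold_change = obs / obs[1])
  })
}

#' Fit the expression-increase rate from a GFP time course
#'
#' Least-squares fit of observed fold change against hours since the first
#' timepoint: `fold = 1 + tau * (t - t0)` (intercept fixed at 1).
#'
#' @param timecourse Output of [simulate_gfp_timecourse()] (or any tibble
#'   with `time_hr` and `fold_change`).
#' @return Estimated `tau` (per hour).
#' @export
fit_expression_increase <- function(timecourse) {
  dt <- timecourse$time_hr - timecourse$time_hr[1]
  y <- timecourse$fold_change - 1
  sum(dt * y) / sum(dt^2)
}
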