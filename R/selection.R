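# Effective selection coefficients from variant x time sequencing counts.
#
# A count table is a tibble with one row per variant plus a wild-type
# reference row (wt = 1), identity columns (variant_id, position, codon, aa,
# wt) and one count column per sampled time, named t<hours> (e.g. t12, t16).

count_columns <- function(table) {
  grep("^t[0-9]+$", names(table), value = TRUE)
}

#' Timepoints of a count table
#'
#' @param table A count table (see [estimate_selection()]).
#' @return Numeric vector of hours, parsed from the `t<hh>` column names.
#' @export
count_timepoints <- function(table) {
  as.numeric(sub("^t", "", count_columns(table)))
}

validate_count_table <- function(table) {
  table <- as_tibble(table)
  tcols <- count_columns(table)
  if (length(tcols) < 2) abort("Count table needs at least 2 `t<hh>` columns.")
  if (is.unsorted(count_timepoints(table), strictly = TRUE))
    abort("Count-table timepoints must be strictly increasing.")
  if (!"wt" %in% names(table) || sum(table$wt == 1) != 1)
    abort("Count table must contain exactly one wild-type reference row (wt = 1).")
  cts <- as.matrix(table[tcols])
  if (any(!is.finite(cts)) || any(cts < 0))
    abort("Counts must be finite and non-negative.")
  if (table[table$wt == 1, tcols[1], drop = TRUE] <= 0)
    abort("Wild-type reference count at the first timepoint must be positive.")
  table
}

# Row-wise least squares of y (matrix, rows = variants) on x; identical to
# per-row lm(y ~ x) but vectorized.
row_ls_fit <- function(Y, x) {
  xc <- x - mean(x)
  ybar <- rowMeans(Y)
  slope <- as.vector((Y %*% xc) / sum(xc^2))
  fitted <- outer(slope, xc) + ybar
  resid <- Y - fitted
  list(slope = slope,
       intercept = ybar - slope * mean(x),
       mean_abs_resid = rowMeans(abs(resid)))
}

#' Per-variant log count-ratio series against the wild-type reference
#'
#' Computes `ln((c_v + pc) / (c_wt + pc))` for every variant at every
#' timepoint, the quantity whose slope over time measures the growth-rate
#' difference from wild type.
#'
#' @param table A count table.
#' @param pseudocount Added to both numerator and denominator counts so the
#'   log is finite at zero counts (default 0.5).
#'
#' @return A long tibble: `variant_id`, `time_hr`, `log_ratio`.
#' @export
log_ratio_series <- function(table, pseudocount = 0.5) {
  table <- validate_count_table(table)
  tcols <- count_columns(table)
  wt_row <- as.numeric(table[table$wt == 1, tcols])
  if (all(wt_row == 0)) abort("Wild-type reference counts are all zero.")
  vt <- table[table$wt != 1, ]
  Y <- log(sweep(as.matrix(vt[tcols]) + pseudocount, 2,
                 wt_row + pseudocount, "/"))
  tibble(
    variant_id = rep(vt$variant_id, times = length(tcols)),
    time_hr = rep(count_timepoints(table), each = nrow(vt)),
    log_ratio = as.vector(Y)
  )
}

#' Estimate effective selection coefficients from a count table
#'
#' Fits, for each variant, a least-squares line to `ln(mutant/WT)` counts
#' against time; the slope (per hour) divided by the wild-type monoculture
#' growth rate `G_wt` gives the effective selection coefficient
#' `s = W - 1`, the per-wild-type-generation growth (dis)advantage. A
#' non-growing variant competing against wild type growing at `G_wt` has
#' slope `-G_wt`, hence s = -1; a variant tracking wild type has s = 0.
#'
#' @param table A count table (one construct).
#' @param G_wt Wild-type monoculture growth rate (per hour, > 0).
#' @param pseudocount Pseudocount for the log ratios (default 0.5).
#' @param timepoints Which timepoints (hours) to fit; default all in the
#'   table. At least 3 required.
#'
#' @return A tibble with one row per variant: identity columns plus `slope`
#'   (per hour), `s`, `residual_per_timepoint` (mean absolute fit residual
#'   divided by the number of fitted timepoints), `initial_ratio`
#'   (raw mutant/WT count ratio at the first timepoint),
#'   `n_timepoints_used`, and `klass` (`"NUMERIC"` at this stage).
#' @export
estimate_selection <- function(table, G_wt, pseudocount = 0.5,
                               timepoints = NULL) {
  table <- validate_count_table(table)
  if (!is.numeric(G_wt) || length(G_wt) != 1 || G_wt <= 0)
    abort("`G_wt` must be a single positive growth rate (per hour).")
  tcols <- count_columns(table)
  tp_all <- count_timepoints(table)
  if (is.null(timepoints)) timepoints <- tp_all
  use <- tp_all %in% timepoints
  if (sum(use) < 3) abort("Need at least 3 timepoints to fit selection.")
  tcols_use <- tcols[use]
  tp_use <- tp_all[use]

  wt_row <- as.numeric(table[table$wt == 1, tcols_use])
  vt <- table[table$wt != 1, ]
  Y <- log(sweep(as.matrix(vt[tcols_use]) + pseudocount, 2,
                 wt_row + pseudocount, "/"))
  fit <- row_ls_fit(Y, tp_use)
  id_cols <- intersect(c("variant_id", "position", "codon", "aa",
                         "is_wt_codon", "is_synonymous_wt", "is_stop"),
                       names(vt))
  out <- vt[id_cols]
  out$slope <- fit$slope
  out$s <- fit$slope / G_wt
  out$residual_per_timepoint <- fit$mean_abs_resid / length(tp_use)
  out$initial_ratio <- as.numeric(vt[[tcols[1]]]) /
    as.numeric(table[table$wt == 1, tcols[1]])
  out$n_timepoints_used <- length(tp_use)
  out$klass <- "NUMERIC"
  as_tibble(out)
}

#' Null-like cutoff from stop-codon selection coefficients
#'
#' Variants whose selection coefficient falls within two standard deviations
#' of the stop-codon mean deplete too fast for precise estimation and are
#' binned as null-like. The cutoff is `mean(s_stop) + 2 * sd(s_stop)`.
#'
#' @param stop_s Numeric vector of stop-codon selection coefficients (or a
#'   selection-estimate tibble, from which stop rows are taken).
#' @return The cutoff (a single number).
#' @export
null_like_cutoff <- function(stop_s) {
  if (is.data.frame(stop_s)) {
    if (!"is_stop" %in% names(stop_s))
      abort("Selection table lacks an `is_stop` column.")
    stop_s <- stop_s$s[stop_s$is_stop]
  }
  stop_s <- stop_s[is.finite(stop_s)]
  if (length(stop_s) < 2)
    abort("Need at least 2 stop-codon estimates to set a null-like cutoff.")
  mean(stop_s) + 2 * sd(stop_s)
}

#' Refit null-like variants on the first three selection timepoints
#'
#' Stop codons and all variants at or below the null-like cutoff deplete to
#' noise levels quickly, so their slopes are refit using only the first
#' three sampled timepoints; their class becomes `"NULL_LIKE"`. Variants
#' above the cutoff are returned untouched.
#'
#' @param estimates Selection-estimate tibble from [estimate_selection()].
#' @param table The count table the estimates came from.
#' @param cutoff Null-like cutoff (e.g. from [null_like_cutoff()]).
#' @param G_wt Wild-type growth rate used for normalization.
#' @param pseudocount Pseudocount for the log ratios.
#' @return The estimates tibble with null-like rows refit and reclassed.
#' @export
refit_null_like <- function(estimates, table, cutoff, G_wt,
                            pseudocount = 0.5) {
  table <- validate_count_table(table)
  flag <- estimates$s <= cutoff | isTRUE_vec(estimates$is_stop)
  if (!any(flag)) return(estimates)
  tcols <- count_columns(table)
  if (length(tcols) < 3) abort("Need at least 3 timepoints for the null refit.")
  first3 <- count_timepoints(table)[1:3]
  sub <- table[table$wt == 1 | table$variant_id %in% estimates$variant_id[flag], ]
  refit <- estimate_selection(sub, G_wt, pseudocount = pseudocount,
                              timepoints = first3)
  idx <- match(refit$variant_id, estimates$variant_id)
  for (col in c("slope", "s", "residual_per_timepoint", "n_timepoints_used"))
    estimates[[col]][idx] <- refit[[col]]
  estimates$klass[idx] <- "NULL_LIKE"
  estimates
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Apply the fit-quality and abundance filters
#'
#' Marks as `"FILTERED"` every estimate whose mean absolute residual per
#' fitted timepoint exceeds `residual_max` (strict) or whose initial
#' mutant/WT count ratio is below `min_initial_ratio` (strict).
#'
#' @param estimates Selection-estimate tibble.
#' @param residual_max Residual-per-timepoint ceiling (default 0.25).
#' @param min_initial_ratio Initial mutant/WT abundance floor (default 0.004).
#' @return The tibble with `klass` updated.
#' @export
apply_filters <- function(estimates, residual_max = 0.25,
                          min_initial_ratio = 0.004) {
  fire <- estimates$residual_per_timepoint > residual_max |
    estimates$initial_ratio < min_initial_ratio
  estimates$klass[fire] <- "FILTERED"
  estimates
}

#' Full per-construct selection-coefficient pass
#'
#' Convenience wrapper chaining [estimate_selection()], the stop-codon
#' [null_like_cutoff()], [refit_null_like()] and [apply_filters()] — the
#' complete single pass from a count table to classified selection
#' coefficients for one construct.
#'
#' @inheritParams estimate_selection
#' @inheritParams apply_filters
#' @param cutoff Null-like cutoff; by default computed from this table's
#'   stop codons. Supply the construct's configured value to override.
#' @return Classified selection-estimate tibble; the applied cutoff is
#'   stored in attribute `"null_cutoff"`.
#' @export
fit_selection <- function(table, G_wt, pseudocount = 0.5, cutoff = NULL,
                          residual_max = 0.25, min_initial_ratio = 0.004) {
  est <- estimate_selection(table, G_wt, pseudocount = pseudocount)
  if (is.null(cutoff)) cutoff <- null_like_cutoff(est)
  est <- refit_null_like(est, table, cutoff, G_wt, pseudocount = pseudocount)
  est <- apply_filters(est, residual_max = residual_max,
                       min_initial_ratio = min_initial_ratio)
  attr(est, "null_cutoff") <- cutoff
  est
}

#' Average selection coefficients over synonymous codons
#'
#' The effective selection coefficient of each amino-acid substitution is
#' the unweighted mean over its non-filtered synonymous codons. An amino
#' acid is classed `"NULL_LIKE"` when its averaged coefficient falls at or
#' below the construct's null-like cutoff; amino acids with no surviving
#' codon are reported with `s = NA` and class `"MISSING"`.
#'
#' @param estimates Classified selection-estimate tibble (codon level).
#' @param cutoff Null-like cutoff used for the amino-acid classification;
#'   defaults to the `"null_cutoff"` attribute left by [fit_selection()].
#' @return A tibble with one row per (position, aa): `s`, `n_codons`,
#'   `klass`.
#' @export
aggregate_synonyms <- function(estimates, cutoff = attr(estimates, "null_cutoff")) {
  if (is.null(cutoff)) abort("Supply the construct's null-like `cutoff`.")
  estimates |>
    group_by(.data$position, .data$aa) |>
    summarise(
      s = mean(.data$s[.data$klass != "FILTERED"]),
      n_codons = sum(.data$klass != "FILTERED"),
      .groups = "drop"
    ) |>
    mutate(klass = dplyr::case_when(
      .data$n_codons == 0 ~ "MISSING",
      .data$s <= cutoff ~ "NULL_LIKE",
      TRUE ~ "NUMERIC"
    ), s = ifelse(.data$n_codons == 0, NA_real_, .data$s))
}

#' Synonym deviations for persisting variants
#'
#' For every codon of a persisting mutation (`s > persist_threshold`), the
#' difference between that codon's selection coefficient and the mean over
#' all synonyms encoding the same amino acid — a narrow, zero-centered
#' distribution when amino-acid sequence dominates fitness.
#'
#' @param estimates Codon-level classified selection-estimate tibble.
#' @param persist_threshold Persistence gate on s (default -0.1).
#' @return Tibble of persisting, non-filtered codons with `synonym_mean` and
#'   `deviation` columns.
#' @export
synonym_deviations <- function(estimates, persist_threshold = -0.1) {
  estimates |>
    filter(.data$klass != "FILTERED", .data$s > persist_threshold) |>
    group_by(.data$position, .data$aa) |>
    mutate(synonym_mean = mean(.data$s),
           deviation = .data$s - .data$synonym_mean) |>
    ungroup()
}

#' Expression-by-mutation epistasis
#'
#' Difference in effective selection coefficient at a reduced expression
#' strength relative to endogenous strength, per amino-acid substitution.
#' Null-like entries are treated as true nulls (s = -1) on both sides, so a
#' wild-type-like mutation at endogenous strength that becomes null-like at
#' reduced strength has epistasis -1. Filtered/missing entries yield `NA`.
#'
#' @param aa_endog Amino-acid-level estimates ([aggregate_synonyms()]) at
#'   endogenous expression strength.
#' @param aa_reduced Amino-acid-level estimates at the reduced strength.
#' @return Tibble with `position`, `aa`, `s_endog`, `s_reduced`,
#'   `epistasis`.
#' @export
epistasis <- function(aa_endog, aa_reduced) {
  null_to_minus1 <- function(d) {
    s <- ifelse(d$klass == "NULL_LIKE", -1, d$s)
    s[d$klass == "MISSING"] <- NA_real_
    s
  }
  e <- aa_endog |>
    mutate(s_endog = null_to_minus1(aa_endog)) |>
    select("position", "aa", "s_endog")
  r <- aa_reduced |>
    mutate(s_reduced = null_to_minus1(aa_reduced)) |>
    select("position", "aa", "s_reduced")
  inner_join(e, r, by = c("position", "aa")) |>
    mutate(epistasis = .data$s_reduced - .data$s_endog)
}
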