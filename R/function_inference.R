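# Per-molecule function from selection coefficients across the expression
# ladder: numeric inversion where fitness is informative, bounds elsewhere,
# and the downstream summaries (cross-construct consistency, surface/core
# partition, BLOSUM62 similarity, stability-table join, DFE shares).

#' Per-construct function estimate or bound for one amino-acid substitution
#'
#' Within one construct, a non-filtered amino-acid estimate maps to exactly
#' one of: a bound `BELOW` the construct's informative lower edge (null-like
#' class), a bound `ABOVE` the upper edge (growth within `wt_margin` of the
#' construct's wild type, where fitness and function decouple), or a numeric
#' per-molecule function from [invert_function()].
#'
#' @param aa_estimates Amino-acid-level estimates ([aggregate_synonyms()])
#'   for one construct.
#' @param construct One-row construct record (with `E`, `s_cut`).
#' @param params [elasticity_params()].
#' @param wt_margin Wild-type coupling margin (default 0.05).
#' @param cap Unbounded-above cap passed to [function_range()].
#' @return Tibble: `position`, `aa`, `construct`, `kind`
#'   (`"numeric"|"above"|"below"`), `F` (numeric value or the bound edge;
#'   `NA` for missing), `s`.
#' @export
per_construct_function <- function(aa_estimates, construct, params,
                                   wt_margin = 0.05, cap = 0.8) {
  construct <- as_tibble(construct)[1, ]
  rng <- function_range(construct, params, wt_margin = wt_margin, cap = cap)
  E <- construct$E
  aa_estimates |>
    mutate(
      construct = construct$name,
      kind = dplyr::case_when(
        .data$klass == "MISSING" ~ NA_character_,
        .data$klass == "NULL_LIKE" ~ "below",
        .data$s > -wt_margin ~ "above",
        TRUE ~ "numeric"
      ),
      F = dplyr::case_when(
        is.na(.data$kind) ~ NA_real_,
        .data$kind == "below" ~ rng$lower,
        .data$kind == "above" ~ rng$upper,
        TRUE ~ invert_function(.data$s, E, params)
      )
    ) |>
    select("position", "aa", "construct", "kind", "F", "s")
}

#' Combine per-construct function estimates into a final estimate
#'
#' The final per-molecule function for each substitution is the unweighted
#' mean over constructs yielding a numeric estimate (bounds excluded), with
#' the sample standard deviation across those constructs. Substitutions with
#' only bounds are reported as the intersection of their bounds: `ABOVE`
#' the largest lower edge and/or `BELOW` the smallest upper edge. A numeric
#' combined value lying outside a reported bound, or an empty bound
#' intersection, raises the `inconsistent` flag rather than an error; values
#' above `flag_above` (beneficial-at-low-expression artifacts) raise
#' `F_gt_flag`.
#'
#' @param per_construct Row-bound output of [per_construct_function()] over
#'   several constructs.
#' @param flag_above Combined-F level above which the estimate is flagged
#'   (default 1.2).
#' @return Tibble with one row per (position, aa): `combined_F`,
#'   `sd_across_constructs`, `n_numeric`, `bound_above`, `bound_below`,
#'   `inconsistent`, `F_gt_flag`.
#' @export
combine_across_constructs <- function(per_construct, flag_above = 1.2) {
  per_construct |>
    filter(!is.na(.data$kind)) |>
    group_by(.data$position, .data$aa) |>
    summarise(
      n_numeric = sum(.data$kind == "numeric"),
      combined_F = if (n_numeric > 0)
        mean(.data$F[.data$kind == "numeric"]) else NA_real_,
      sd_across_constructs = if (n_numeric > 1)
        sd(.data$F[.data$kind == "numeric"]) else NA_real_,
      bound_above = if (any(.data$kind == "above"))
        max(.data$F[.data$kind == "above"]) else NA_real_,
      bound_below = if (any(.data$kind == "below"))
        min(.data$F[.data$kind == "below"]) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      inconsistent =
        (!is.na(.data$bound_above) & !is.na(.data$bound_below) &
           .data$bound_above > .data$bound_below) |
        (!is.na(.data$combined_F) & !is.na(.data$bound_above) &
           .data$combined_F < .data$bound_above & is.finite(.data$bound_above)) |
        (!is.na(.data$combined_F) & !is.na(.data$bound_below) &
           .data$combined_F > .data$bound_below),
      F_gt_flag = !is.na(.data$combined_F) & .data$combined_F > flag_above
    )
}

#' Cross-construct consistency of numeric function estimates
#'
#' Squared Pearson correlation between numeric per-molecule function
#' estimates of constructs adjacent in expression strength, plus the pooled
#' R-squared over all adjacent pairs. Pairs sharing fewer than `min_shared`
#' numeric substitutions are reported `NA`.
#'
#' @param per_construct Output of [per_construct_function()] over several
#'   constructs.
#' @param construct_order Construct names ordered by decreasing expression
#'   strength; default the order of first appearance.
#' @param min_shared Minimum shared numeric substitutions per pair
#'   (default 3).
#' @return A list with `pairs` (tibble: construct_a, construct_b, n_shared,
#'   r_squared) and `pooled_r_squared`.
#' @export
cross_construct_consistency <- function(per_construct,
                                        construct_order = unique(per_construct$construct),
                                        min_shared = 3) {
  num <- filter(per_construct, .data$kind == "numeric")
  pooled_a <- numeric(0)
  pooled_b <- numeric(0)
  pairs <- purrr::map_dfr(seq_len(length(construct_order) - 1), function(i) {
    a <- filter(num, .data$construct == construct_order[i])
    b <- filter(num, .data$construct == construct_order[i + 1])
    shared <- inner_join(a, b, by = c("position", "aa"),
                         suffix = c("_a", "_b"))
    r2 <- NA_real_
    if (nrow(shared) >= min_shared) {
      r2 <- cor(shared$F_a, shared$F_b)^2
      pooled_a <<- c(pooled_a, shared$F_a)
      pooled_b <<- c(pooled_b, shared$F_b)
    }
    tibble(construct_a = construct_order[i],
           construct_b = construct_order[i + 1],
           n_shared = nrow(shared), r_squared = r2)
  })
  pooled <- if (length(pooled_a) >= min_shared) cor(pooled_a, pooled_b)^2 else NA_real_
  list(pairs = pairs, pooled_r_squared = pooled)
}

#' Partition function estimates into solvent-exposed and core positions
#'
#' Positions 582, 583 and 585 orient towards solvent; 584 and 586-590
#' towards the protein core. Returns the combined-function values split by
#' partition, with bounded estimates carried at their bound edge so they
#' fall in the edge bins of a histogram.
#'
#' @param combined Output of [combine_across_constructs()].
#' @param surface_positions Integer positions in the solvent-exposed set.
#' @return Tibble: `position`, `aa`, `F_plot` (combined or bound edge),
#'   `partition` (`"surface"|"core"`), `is_bound`.
#' @export
partition_surface_core <- function(combined,
                                   surface_positions = c(582, 583, 585)) {
  combined |>
    mutate(
      F_plot = dplyr::coalesce(.data$combined_F, .data$bound_above,
                               .data$bound_below),
      is_bound = is.na(.data$combined_F),
      partition = ifelse(.data$position %in% surface_positions,
                         "surface", "core")
    ) |>
    filter(is.finite(.data$F_plot)) |>
    select("position", "aa", "F_plot", "partition", "is_bound")
}

#' BLOSUM62 similarity versus per-molecule function
#'
#' Scores every substitution's similarity to the wild-type residue at its
#' position with the canonical BLOSUM62 matrix and relates similarity to
#' combined function by Spearman rank correlation. Self-substitutions (to
#' the wild-type residue) and stops are excluded from the correlation.
#'
#' @param combined Output of [combine_across_constructs()].
#' @param wt_aa Named character vector: wild-type amino acid per position
#'   (names = positions). Default derived from [default_wt_codons()].
#' @return List with `table` (tibble: position, aa, wt_aa, blosum_score,
#'   combined_F) and `spearman_rho` over numeric, non-self substitutions.
#' @export
blosum_similarity_table <- function(combined,
                                    wt_aa = translate_codon(default_wt_codons())) {
  if (is.null(names(wt_aa))) names(wt_aa) <- names(default_wt_codons())
  tbl <- combined |>
    filter(.data$aa != "*") |>
    mutate(
      wt_aa = unname(wt_aa[as.character(.data$position)]),
      blosum_score = blosum62(.data$wt_aa, .data$aa),
      is_self = .data$aa == .data$wt_aa
    ) |>
    select("position", "aa", "wt_aa", "blosum_score", "combined_F", "is_self")
  use <- !tbl$is_self & !is.na(tbl$combined_F)
  rho <- if (sum(use) >= 3 && sd(tbl$blosum_score[use]) > 0 &&
             sd(tbl$combined_F[use]) > 0) {
    cor(tbl$blosum_score[use], tbl$combined_F[use], method = "spearman")
  } else NA_real_
  list(table = tbl, spearman_rho = rho)
}

#' Join an external stability (ddG) table to function estimates
#'
#' Inner join of a per-substitution folding-stability table (e.g. from
#' structural simulation) with the combined function estimates, reporting
#' Pearson and Spearman correlations between ddG and function. Zero-variance
#' inputs give `NA` correlations; unmatched keys are counted, not errors.
#'
#' @param ddg Tibble with columns `position`, `aa`, `ddg_kcal_mol`.
#' @param combined Output of [combine_across_constructs()].
#' @return List: `table` (joined records), `pearson_r`, `spearman_rho`,
#'   `n_dropped` (keys present in only one input).
#' @export
ddg_function_join <- function(ddg, combined) {
  ddg <- as_tibble(ddg)
  if (!all(c("position", "aa", "ddg_kcal_mol") %in% names(ddg)))
    abort("`ddg` needs columns `position`, `aa`, `ddg_kcal_mol`.")
  joined <- inner_join(ddg, select(combined, "position", "aa", "combined_F"),
                       by = c("position", "aa"))
  n_dropped <- nrow(ddg) + nrow(combined) - 2 * nrow(joined)
  use <- complete.cases(joined[, c("ddg_kcal_mol", "combined_F")])
  ok <- sum(use) >= 3 && sd(joined$ddg_kcal_mol[use]) > 0 &&
    sd(joined$combined_F[use]) > 0
  list(
    table = joined,
    pearson_r = if (ok) cor(joined$ddg_kcal_mol[use], joined$combined_F[use]) else NA_real_,
    spearman_rho = if (ok) cor(joined$ddg_kcal_mol[use], joined$combined_F[use],
                               method = "spearman") else NA_real_,
    n_dropped = n_dropped
  )
}

#' Distribution of effects with class shares
#'
#' Histogram of selection coefficients (a fitness DFE) or per-molecule
#' function values, with the shares of wild-type-like, null-like and
#' intermediate effects. For selection coefficients, wild-type-like means
#' `s > -wt_margin` and null-like follows the supplied class vector; for
#' function values, intermediate means a 10-90% defect (`F` in
#' `[0.1, 0.9]`).
#'
#' @param values Numeric vector of s or F values.
#' @param klass Optional class vector aligned with `values` (used to count
#'   `NULL_LIKE`).
#' @param type `"selection"` or `"function"`.
#' @param binwidth Histogram bin width (default 0.05).
#' @param wt_margin Wild-type-like margin on s (default 0.05).
#' @return List: `histogram` (tibble: bin midpoints and counts), `shares`
#'   (tibble: wt_like, null_like, intermediate fractions), `n`.
#' @export
dfe_histogram <- function(values, klass = NULL,
                          type = c("selection", "function"),
                          binwidth = 0.05, wt_margin = 0.05) {
  type <- match.arg(type)
  keep <- is.finite(values)
  values <- values[keep]
  if (!is.null(klass)) klass <- klass[keep]
  n <- length(values)
  lo <- floor(min(values) / binwidth) * binwidth
  breaks <- seq(lo, max(values) + binwidth, by = binwidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  if (type == "selection") {
    null_like <- if (!is.null(klass)) mean(klass == "NULL_LIKE") else
      mean(values <= -1 + wt_margin)
    wt_like <- mean(values > -wt_margin &
                      (if (!is.null(klass)) klass != "NULL_LIKE" else TRUE))
  } else {
    null_like <- mean(values < 0.1)
    wt_like <- mean(values > 0.9)
  }
  list(
    histogram = tibble(mid = h$mids, count = h$counts),
    shares = tibble(wt_like = wt_like, null_like = null_like,
                    intermediate = 1 - wt_like - null_like),
    n = n
  )
}

#' Classify a distribution of effects as bimodal or unimodal-intermediate
#'
#' A distribution whose intermediate share (neither wild-type-like nor
#' null-like) exceeds `intermediate_min` is called
#' `"unimodal-intermediate"`; otherwise `"bimodal"`. Used to ask whether
#' fitness data at a given expression strength can distinguish the
#' underlying shape of functional effects.
#'
#' @inheritParams dfe_histogram
#' @param intermediate_min Share threshold (default 1/3).
#' @return `"bimodal"` or `"unimodal-intermediate"`.
#' @export
classify_dfe_shape <- function(values, klass = NULL,
                               type = c("selection", "function"),
                               wt_margin = 0.05, intermediate_min = 1 / 3) {
  d <- dfe_histogram(values, klass = klass, type = match.arg(type),
                     wt_margin = wt_margin)
  if (d$shares$intermediate > intermediate_min) "unimodal-intermediate"
  else "bimodal"
}
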