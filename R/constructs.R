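# Default promoter/terminator construct metadata for the Hsp90 shutoff system.

#' Promoter construct metadata for the Hsp90 expression ladder
#'
#' The seven promoter/terminator constructs spanning a ~100-fold range of
#' Hsp90 expression, with the metadata the pipeline needs per construct:
#'
#' * `E` — relative expression strength used for function inference. For the
#'   three strongest constructs this is the directly measured value
#'   (Western + GFP); for the four weak constructs it is the value derived
#'   from observed growth rate through the elasticity function, which is less
#'   noisy at low expression. The directly measured value is kept in
#'   `E_measured` for reference.
#' * `G_wt` — wild-type-sequence monoculture growth rate under the construct
#'   (per hour), here the elasticity-model value at `E` with F = 1.
#' * `s_cut` — null-like selection-coefficient cutoff (mean stop-codon s
#'   plus two standard deviations) used for binning.
#' * `E_0`, `tau` — expression-dynamics parameters (start expression and
#'   fractional increase rate per hour) where characterized; `NA` otherwise.
#' * `timepoints` — list-column of bulk-competition sampling times (hours in
#'   dextrose). The three strong constructs include the 12 h point; the weak
#'   four start at 16 h.
#'
#' @param params Elasticity parameters used to derive `G_wt`
#'   (default [hsp90_elasticity()]).
#' @return A tibble with one row per construct.
#' @examples
#' hsp90_constructs()
#' @export
hsp90_constructs <- function(params = hsp90_elasticity()) {
  tbl <- tibble(
    name       = c("GPD", "TEF", "TEFdter", "CYC", "CYCdter", "ADH", "ADHdter"),
    E          = c(1, 0.32, 0.094, 0.028, 0.015, 0.014, 0.010),
    E_measured = c(1, 0.32, 0.094, 0.044, 0.019, 0.014, 0.008),
    s_cut      = c(-0.28, -0.37, -0.40, -0.35, -0.44, -0.46, -0.43),
    E_0        = c(NA, NA, NA, NA, 0.016, NA, NA),
    tau        = c(NA, NA, NA, NA, 0.11, NA, NA)
  )
  tbl$G_wt <- growth_rate(tbl$E, 1, params)
  strong <- tbl$name %in% c("GPD", "TEF", "TEFdter")
  tbl$timepoints <- ifelse(strong,
    list(c(12, 16, 20, 24, 32, 40, 48)),
    list(c(16, 20, 24, 32, 40, 48))
  )
  tbl
}

#' Look up one construct by name
#'
#' @param name Construct label, e.g. `"GPD"`.
#' @param constructs Construct table (default [hsp90_constructs()]).
#' @return A one-row tibble.
#' @export
get_construct <- function(name, constructs = hsp90_constructs()) {
  hit <- constructs[constructs$name == name, ]
  if (nrow(hit) == 0)
    abort(paste0("Unknown construct: '", name, "'. Known: ",
                 paste(constructs$name, collapse = ", "), "."))
  hit
}
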