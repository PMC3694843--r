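# End-to-end orchestration: synthetic library -> bulk competitions across
# the construct ladder -> selection coefficients -> function estimates ->
# epistasis -> report summaries.

#' Run the full analysis pipeline on synthetic competitions
#'
#' Generates (or accepts) a mutant library with known true function,
#' simulates one bulk competition per construct, estimates classified
#' selection coefficients, averages synonyms, inverts fitness to
#' per-molecule function per construct, combines across the ladder, and
#' computes expression-by-mutation epistasis of every reduced-expression
#' construct against the endogenous-strength reference.
#'
#' @param config Pipeline configuration (see [default_config()]).
#' @param constructs Construct metadata table (default
#'   [hsp90_constructs()]).
#' @param truth Optional pre-built truth library (from
#'   [sample_true_function()]); generated from `config$synthetic` when
#'   `NULL`.
#' @param outdir Optional directory; when given, all result tables are
#'   written as TSV (with version/hash/seed headers) alongside a
#'   `elasticity.json` parameter record.
#'
#' @return A list of class `dms_pipeline_result`:
#' `truth`, `selection` (codon level, per construct), `aa_selection`,
#' `per_construct_F`, `combined_F`, `epistasis`, `ranges`, `report`
#' (DFE shares per construct, function-distribution shares, null cutoffs),
#' `config`, `params`.
#' @export
run_pipeline <- function(config = default_config(),
                         constructs = hsp90_constructs(),
                         truth = NULL, outdir = NULL) {
  constructs <- as_tibble(constructs)
  if (nrow(constructs) == 0) abort("Empty construct list.")
  needed <- c("name", "E", "s_cut", "G_wt", "timepoints")
  miss <- setdiff(needed, names(constructs))
  if (length(miss) > 0)
    abort(paste0("Construct metadata lacks: ", paste(miss, collapse = ", ")))
  params <- elasticity_params(config$elasticity$G_max, config$elasticity$E_m)
  est_cfg <- config$estimation

  if (is.null(truth)) {
    truth <- sample_true_function(build_library(),
                                  preset = config$synthetic$preset,
                                  seed = config$synthetic$seed)
  }

  per_construct <- purrr::map(seq_len(nrow(constructs)), function(i) {
    con <- constructs[i, ]
    counts <- simulate_bulk_competition(
      truth, con, params,
      depth = config$synthetic$depth,
      seed = config$synthetic$seed + i,
      wt_fraction = config$synthetic$wt_fraction
    )
    sel <- fit_selection(counts, G_wt = con$G_wt,
                         pseudocount = est_cfg$pseudocount,
                         residual_max = est_cfg$residual_max,
                         min_initial_ratio = est_cfg$min_initial_ratio)
    aa <- aggregate_synonyms(sel)
    fn <- per_construct_function(aa, con, params,
                                 wt_margin = est_cfg$wt_margin,
                                 cap = est_cfg$cap)
    list(construct = con$name, counts = counts, selection = sel,
         aa = aa, fn = fn, cutoff = attr(sel, "null_cutoff"))
  })
  names(per_construct) <- constructs$name

  selection <- purrr::map_dfr(per_construct, function(x)
    mutate(x$selection, construct = x$construct))
  aa_selection <- purrr::map_dfr(per_construct, function(x)
    mutate(x$aa, construct = x$construct))
  per_construct_F <- purrr::map_dfr(per_construct, "fn")
  combined <- combine_across_constructs(per_construct_F)

  endog <- per_construct[[1]]$aa
  epi <- purrr::map_dfr(per_construct[-1], function(x)
    mutate(epistasis(endog, x$aa), construct = x$construct))

  ranges <- function_range_table(constructs, params,
                                 wt_margin = est_cfg$wt_margin,
                                 cap = est_cfg$cap)

  dfe_shares <- purrr::map_dfr(per_construct, function(x) {
    d <- dfe_histogram(x$aa$s, klass = x$aa$klass, type = "selection",
                       wt_margin = est_cfg$wt_margin)
    mutate(d$shares, construct = x$construct, null_cutoff = x$cutoff)
  })
  fdist <- dfe_histogram(combined$combined_F[!is.na(combined$combined_F)],
                         type = "function")
  report <- list(dfe_shares = dfe_shares,
                 function_shares = fdist$shares,
                 function_histogram = fdist$histogram,
                 consistency = cross_construct_consistency(per_construct_F))

  out <- structure(list(
    truth = truth, selection = selection, aa_selection = aa_selection,
    per_construct_F = per_construct_F, combined_F = combined,
    epistasis = epi, ranges = ranges, report = report,
    config = config, params = params
  ), class = "dms_pipeline_result")

  if (!is.null(outdir)) write_pipeline_result(out, outdir)
  out
}

#' @export
print.dms_pipeline_result <- function(x, ...) {
  cat("<dms_pipeline_result>\n",
      " constructs:", paste(unique(x$selection$construct), collapse = ", "), "\n",
      " codon estimates:", nrow(x$selection), "\n",
      " aa substitutions combined:", nrow(x$combined_F), "\n",
      " preset:", x$config$synthetic$preset,
      " seed:", x$config$synthetic$seed, "\n")
  invisible(x)
}

#' Write all pipeline result tables to a directory
#'
#' TSVs mirror the structure of per-codon selection, per-amino-acid
#' selection, per-construct and combined function estimates, epistasis and
#' the informative-range table; `elasticity.json` records the fitted/used
#' parameters. Every file carries version, config-hash and seed headers.
#'
#' @param result A `dms_pipeline_result`.
#' @param outdir Directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- output_header(c(
    paste0("# config_hash: ", config_hash(result$config)),
    paste0("# seed: ", result$config$synthetic$seed)
  ))
  dump <- function(tbl, name) {
    path <- file.path(outdir, name)
    writeLines(hdr, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  }
  dump(result$selection, "selection_codon.tsv")
  dump(result$aa_selection, "selection_aa.tsv")
  dump(result$per_construct_F, "function_per_construct.tsv")
  dump(result$combined_F, "function_combined.tsv")
  dump(result$epistasis, "epistasis.tsv")
  dump(result$ranges, "function_ranges.tsv")
  dump(result$report$dfe_shares, "report_dfe_shares.tsv")
  jsonlite::write_json(
    list(G_max = result$params$G_max, E_m = result$params$E_m,
         rss = result$params$rss, n_points = result$params$n_points),
    file.path(outdir, "elasticity.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  invisible(outdir)
}
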