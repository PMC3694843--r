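# TSV count-table dialect and YAML configuration I/O. Every file written
# carries header comment lines with the tool version, a config hash, and the
# seeds used, so outputs are traceable.

id_cols_out <- c("variant_id", "position", "codon", "aa",
                 "is_wt_codon", "is_synonymous_wt", "is_stop", "wt")

output_header <- function(extra = character()) {
  c(paste0("# elastidms ", as.character(utils::packageVersion("elastidms"))),
    extra)
}

#' Write a count table to TSV
#'
#' Columns: `variant_id` (`POS.CODON`), `position`, `codon`, `aa`, flag
#' columns, `wt`, then one `t<hh>` count column per timepoint. Header
#' comment lines record the tool version, construct, sequencing depth and
#' seed.
#'
#' @param table Count table (see [simulate_bulk_competition()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  meta <- c(
    if (!is.null(attr(table, "construct")))
      paste0("# construct: ", attr(table, "construct")),
    if (!is.null(attr(table, "depth")))
      paste0("# depth: ", paste(attr(table, "depth"), collapse = ",")),
    if (!is.null(attr(table, "seed")))
      paste0("# seed: ", attr(table, "seed"))
  )
  writeLines(output_header(meta), path)
  readr::write_tsv(table, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a count table from TSV
#'
#' Validates structure on read: the `t<hh>` columns must hold non-negative
#' finite counts and exactly one wild-type reference row (`wt = 1`) must be
#' present. Header comments (`# construct: ...`, `# seed: ...`) are restored
#' as attributes.
#'
#' @param path File written by [write_count_table()] (or matching dialect).
#' @return A validated count-table tibble.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  head_lines <- readLines(path, n = 20)
  meta <- grep("^#", head_lines, value = TRUE)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  tcols <- grep("^t[0-9]+$", names(tbl), value = TRUE)
  for (col in tcols) {
    bad <- which(!is.finite(tbl[[col]]) | tbl[[col]] < 0)
    if (length(bad) > 0)
      abort(paste0("Malformed count in column ", col, ", data row ", bad[1],
                   ": counts must be non-negative numbers."))
  }
  if (!"wt" %in% names(tbl) || sum(tbl$wt == 1, na.rm = TRUE) != 1) {
    cons <- sub("^# construct: ", "", grep("^# construct:", meta, value = TRUE))
    abort(paste0("Count table ", path, " lacks a unique wild-type row",
                 if (length(cons)) paste0(" (construct ", cons, ")"), "."))
  }
  grab <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1]) else NULL
  }
  if (!is.null(grab("construct"))) attr(tbl, "construct") <- grab("construct")
  if (!is.null(grab("seed"))) attr(tbl, "seed") <- as.integer(grab("seed"))
  tbl
}

#' Default pipeline configuration
#'
#' All thresholds at their standard values: pseudocount 0.5 on count
#' ratios; residual-per-timepoint ceiling 0.25; initial-abundance floor
#' 0.004; wild-type coupling margin 0.05; persistence gate -0.1;
#' unbounded-range cap 0.8; elasticity G_max = 0.45/hr, E_m = 0.014;
#' synthetic preset `"bimodal"` at depth 5e5 with 10% initial wild-type
#' mass; dynamics dt = 0.1 h.
#'
#' @param preset Synthetic truth preset (see [sample_true_function()]).
#' @param seed Base integer seed for the synthetic stages.
#' @return Nested configuration list of class `pipeline_config`.
#' @export
default_config <- function(preset = "bimodal", seed = 1) {
  structure(list(
    elasticity = list(G_max = 0.45, E_m = 0.014),
    estimation = list(pseudocount = 0.5, residual_max = 0.25,
                      min_initial_ratio = 0.004, wt_margin = 0.05,
                      persist_threshold = -0.1, cap = 0.8),
    synthetic = list(preset = preset, seed = seed, depth = 5e5,
                     wt_fraction = 0.1),
    dynamics = list(dt = 0.1, horizon = 36)
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' Configurations round-trip losslessly through serialization.
#'
#' @param config A `pipeline_config` list.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

config_hash <- function(config) rlang::hash(unclass(config))
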