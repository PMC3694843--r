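# Shared fixtures: canonical parameters, a small hand-built count table, and
# a memoized default pipeline run so several test files can share one
# simulation.

params_std <- hsp90_elasticity()   # G_max = 0.45/hr, E_m = 0.014
constructs_std <- hsp90_constructs()

# Count table with exact exponential counts (no sampling noise): wild type
# doubles each hour, each variant grows at 2^(w * t) for a given relative
# rate w, so ln(mut/wt) slopes are exactly (w - 1) * ln 2.
exact_count_table <- function(w = c(a = 1, b = 0, c = 0.5),
                              times = 0:4, n0 = 1000) {
  counts <- matrix(vapply(times, function(t) n0 * 2^(w * t),
                          numeric(length(w))),
                   nrow = length(w))
  tbl <- tibble::tibble(
    variant_id = names(w),
    position = 582L, codon = "AAA", aa = "K",
    is_stop = FALSE, wt = 0L
  )
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(
    `colnames<-`(counts, paste0("t", times))
  ))
  wt_row <- tibble::tibble(variant_id = "WT", position = NA_integer_,
                           codon = NA_character_, aa = NA_character_,
                           is_stop = FALSE, wt = 1L)
  for (t in times) wt_row[[paste0("t", t)]] <- n0 * 2^t
  dplyr::bind_rows(tbl, wt_row)
}

# One default-conditions pipeline run per preset, computed once per session.
pipeline_cache <- new.env(parent = emptyenv())
cached_pipeline <- function(preset = "intermediate", seed = 7) {
  key <- paste(preset, seed, sep = "_")
  if (is.null(pipeline_cache[[key]])) {
    pipeline_cache[[key]] <- run_pipeline(
      default_config(preset = preset, seed = seed)
    )
  }
  pipeline_cache[[key]]
}

truth_std <- function(preset = "bimodal", seed = 1) {
  key <- paste0("truth_", preset, "_", seed)
  if (is.null(pipeline_cache[[key]]))
    pipeline_cache[[key]] <- sample_true_function(build_library(),
                                                  preset = preset, seed = seed)
  pipeline_cache[[key]]
}
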