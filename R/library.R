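# Codon-level mutant library over the scanned region (positions 582-590).

#' Default wild-type codons for the scanned region
#'
#' Residues named in the literature for this region are fixed (583 = Phe,
#' 585 = Trp, 586 = Ser, 587 = Ala, 590 = Glu); the remaining wild-type
#' codon identities are placeholders — arbitrary but fixed — and can be
#' overridden wherever a `wt_codons` argument is accepted.
#'
#' @return Named character vector of 9 codons, names = positions 582-590.
#' @export
default_wt_codons <- function() {
  c(`582` = "ATT",  # Ile (placeholder)
    `583` = "TTT",  # Phe
    `584` = "CTG",  # Leu (placeholder)
    `585` = "TGG",  # Trp
    `586` = "TCT",  # Ser
    `587` = "GCT",  # Ala
    `588` = "AAA",  # Lys (placeholder)
    `589` = "GAT",  # Asp (placeholder)
    `590` = "GAA")  # Glu
}

#' Translate DNA codons to amino acids
#'
#' Standard genetic code; stop codons translate to `"*"`.
#'
#' @param codons Character vector of 3-letter codons over A/C/G/T.
#' @return Character vector of one-letter amino acids.
#' @export
translate_codon <- function(codons) {
  codons <- toupper(codons)
  bad <- !codons %in% names(Biostrings::GENETIC_CODE)
  if (any(bad))
    abort(paste0("Invalid codon(s): ", paste(unique(codons[bad]), collapse = ", ")))
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Enumerate the single-codon substitution library
#'
#' All 64 codons at each of the 9 scanned positions — 576 engineered
#' variants — plus flags identifying the wild-type codon and synonymous
#' wild-type codons at each position.
#'
#' @param wt_codons Named character vector of wild-type codons, names =
#'   positions (default [default_wt_codons()]).
#'
#' @return A tibble with columns `variant_id` (`"<pos>.<codon>"`),
#'   `position`, `codon`, `aa` (one-letter, `"*"` for stop), `is_wt_codon`,
#'   `is_synonymous_wt`, `is_stop`.
#' @examples
#' nrow(build_library())  # 576
#' @export
build_library <- function(wt_codons = default_wt_codons()) {
  if (length(wt_codons) != 9 || is.null(names(wt_codons)))
    abort("`wt_codons` must be a named vector of 9 codons.")
  wt_codons <- toupper(wt_codons)
  wt_aa <- translate_codon(wt_codons)  # validates letters
  if (any(wt_aa == "*")) abort("Wild-type codons cannot be stops.")
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(b3 = bases, b2 = bases, b1 = bases), 1,
                      function(r) paste0(r[["b1"]], r[["b2"]], r[["b3"]]))
  positions <- as.integer(names(wt_codons))
  lib <- tidyr::expand_grid(position = positions, codon = sort(all_codons))
  lib$aa <- translate_codon(lib$codon)
  lib$is_wt_codon <- lib$codon == wt_codons[as.character(lib$position)]
  wt_aa_at <- setNames(wt_aa, names(wt_codons))
  lib$is_synonymous_wt <- !lib$is_wt_codon &
    lib$aa == wt_aa_at[as.character(lib$position)]
  lib$is_stop <- lib$aa == "*"
  lib$variant_id <- paste0(lib$position, ".", lib$codon)
  lib[, c("variant_id", "position", "codon", "aa",
          "is_wt_codon", "is_synonymous_wt", "is_stop")]
}
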