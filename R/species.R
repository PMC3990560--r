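#' Normalize species labels
#'
#' Field inventories spell the same species inconsistently; to a computer
#' `"Cedrela  Odorata"` and `"cedrela odorata"` are two species, inflating
#' richness. This applies the mechanical part of label cleaning only: trim
#' surrounding whitespace, collapse internal whitespace runs to single
#' spaces, and case-fold to lower case. No fuzzy matching or taxonomic
#' synonym resolution is attempted, so genuinely different spellings (e.g.
#' `"Cedrella"` vs `"Cedrela"`) remain distinct labels by design.
#'
#' @param x Character vector of raw species labels.
#' @return Character vector of canonical labels. Idempotent:
#'   `normalize_species_label(normalize_species_label(x))` equals
#'   `normalize_species_label(x)`.
#' @examples
#' normalize_species_label("  Cedrela  odorata ")  # "cedrela odorata"
#' @export
normalize_species_label <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  out <- tolower(trimws(gsub("\\s+", " ", x)))
  if (any(!nzchar(out) | is.na(out))) {
    bad <- which(!nzchar(out) | is.na(out))
    abort(sprintf("species label empty after normalization at position(s): %s",
                  paste(utils::head(bad, 10), collapse = ", ")),
          class = "standcompare_validation_error")
  }
  out
}
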