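#' Normalize a free-text key field
#'
#' Applies the normalization used to build matching keys: Unicode NFKC
#' (so the micro sign U+00B5 and Greek mu U+03BC coincide), lower-casing,
#' collapsing of internal whitespace, and stripping of leading/trailing
#' punctuation. Greek letters are preserved.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_key_field("  Beta-Galactosidase ")
normalize_key_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- stringi::stri_trans_nfkc(x)
  x <- stringr::str_to_lower(x)
  x <- stringr::str_squish(x)
  # strip leading/trailing punctuation but keep interior hyphens etc.
  x <- stringr::str_replace_all(x, "^[\\p{P}\\p{S}]+|[\\p{P}\\p{S}]+$", "")
  stringr::str_squish(x)
}

#' Normalize a mutation descriptor
#'
#' Single-letter amino-acid substitution codes are upper-cased and
#' de-spaced ("a 123 g" becomes "A123G"); anything that does not look like a
#' point-substitution code is passed through with whitespace squished.
#'
#' @param x character vector of mutation descriptors (may be empty strings).
#' @return character vector.
#' @export
normalize_mutation <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- stringi::stri_trans_nfkc(x)
  x <- stringr::str_squish(x)
  compact <- stringr::str_replace_all(x, "\\s+", "")
  is_point <- stringr::str_detect(compact, "^[A-Za-z]\\d+[A-Za-z]$")
  x[is_point] <- stringr::str_to_upper(compact[is_point])
  x
}

#' Build the matching key of a measurement
#'
#' The key that identifies one kinetic measurement across datasets:
#' normalized enzyme name, mutation, substrate name and organism.
#' Construction is idempotent — normalizing an already-normalized key is a
#' no-op.
#'
#' @param m a measurement table (one or more rows) or any data frame with
#'   columns `enzyme_name`, `mutation`, `substrate_name`, `organism`.
#' @return a tibble with columns `enzyme_name_norm`, `mutation_norm`,
#'   `substrate_norm`, `organism_norm`, one row per input row.
#' @export
entry_key <- function(m) {
  tibble::tibble(
    enzyme_name_norm = normalize_key_field(m$enzyme_name),
    mutation_norm    = normalize_mutation(m$mutation),
    substrate_norm   = normalize_key_field(m$substrate_name),
    organism_norm    = normalize_key_field(m$organism)
  )
}
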