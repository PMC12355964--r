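# Post-extraction curation: duplicate and empty-row removal, document-level
# hallucination and repetition flags, row-level scientific-notation marking,
# and the exclusion policy. Flag categories may overlap; tallies are kept
# independently and the conservation ledger accounts for every input row.

#' QC configuration
#'
#' @param hallucination_min_found_fraction a document is flagged as possibly
#'   hallucinated when the fraction of its extracted kinetic value strings
#'   locatable verbatim in the document text falls strictly below this
#'   threshold (default 0.5).
#' @param repetition_min_unique_fraction a document is flagged as repetitive
#'   when the fraction of distinct kinetic value strings among all its
#'   kinetic value strings falls strictly below this threshold (default 0.3).
#' @param exclude_flagged drop rows carrying any of the hallucinated /
#'   repetitive / scientific-notation flags (default `TRUE`).
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(hallucination_min_found_fraction = 0.5,
                      repetition_min_unique_fraction = 0.3,
                      exclude_flagged = TRUE) {
  stopifnot(hallucination_min_found_fraction >= 0,
            hallucination_min_found_fraction <= 1,
            repetition_min_unique_fraction >= 0,
            repetition_min_unique_fraction <= 1)
  structure(list(
    hallucination_min_found_fraction = hallucination_min_found_fraction,
    repetition_min_unique_fraction = repetition_min_unique_fraction,
    exclude_flagged = exclude_flagged
  ), class = "qc_config")
}

doc_value_strings <- function(entries) {
  vals <- c(entries[["kcat_printed"]], entries[["km_printed"]])
  if (is.null(vals)) return(character())
  vals[nzchar(vals)]
}

#' Flag a document as possibly hallucinated
#'
#' Computes the fraction of extracted kinetic value strings that can be
#' located verbatim in the document text ([find_value_in_text()]); the
#' document is flagged iff that fraction is strictly below the configured
#' threshold. A document with no extracted numeric values is never flagged.
#'
#' @param doc a `document_record`.
#' @param extractions measurement rows belonging to `doc`.
#' @param cfg a [qc_config()].
#' @return `list(flagged = logical, found_fraction = numeric)`.
#' @export
flag_hallucination <- function(doc, extractions, cfg = qc_config()) {
  vals <- doc_value_strings(extractions)
  if (!length(vals)) {
    warning("document ", doc$doc_id, " has no extracted numeric values",
            call. = FALSE)
    return(list(flagged = FALSE, found_fraction = NA_real_))
  }
  found <- vapply(vals, find_value_in_text, logical(1), doc = doc)
  frac <- mean(found)
  list(flagged = frac < cfg$hallucination_min_found_fraction,
       found_fraction = frac)
}

#' Flag a document as repetitive
#'
#' @param extractions measurement rows for one document.
#' @param cfg a [qc_config()].
#' @return `list(flagged = logical, unique_fraction = numeric)`.
#' @export
flag_repetition <- function(extractions, cfg = qc_config()) {
  vals <- doc_value_strings(extractions)
  if (!length(vals)) {
    return(list(flagged = FALSE, unique_fraction = NA_real_))
  }
  frac <- length(unique(vals)) / length(vals)
  list(flagged = frac < cfg$repetition_min_unique_fraction,
       unique_fraction = frac)
}

#' Curate extracted measurements
#'
#' Pipeline order: (1) drop exact duplicate rows (all serialized fields
#' equal); (2) when the same `doc_id` exists in both pdf_text and xml form,
#' keep the xml rows; (3) drop empty rows; (4) set document-level
#' hallucination and repetition flags; (5) set row-level
#' scientific-notation flags; (6) when `exclude_flagged`, remove rows with
#' any of the three flags. Every removal is tallied without double-counting,
#' so `n_input = n_kept + n_duplicates + n_format_dupes + n_empty +
#' n_excluded_flagged`.
#'
#' @param entries a measurement tibble (canonicalized).
#' @param docs a list of `document_record`s covering the entries' doc_ids
#'   (named or not); may be `NULL`, in which case the hallucination check is
#'   skipped.
#' @param cfg a [qc_config()].
#' @return `list(entries = kept tibble, report = qc_report)`.
#' @export
curate <- function(entries, docs = NULL, cfg = qc_config()) {
  entries <- as_measurement_table(entries)
  n_input <- nrow(entries)
  doc_index <- list()
  for (d in docs) doc_index[[d$doc_id]] <- d

  # (1) exact duplicates on the serialized record
  ser <- vapply(seq_len(nrow(entries)), function(i) {
    as.character(measurement_to_json(entries[i, ]))
  }, character(1))
  dup <- duplicated(ser)
  n_duplicates <- sum(dup)
  entries <- entries[!dup, , drop = FALSE]

  # (2) pdf+xml duplication of the same document: keep xml
  fmt <- dplyr::distinct(entries, .data$doc_id, .data$source_format)
  both <- fmt |>
    dplyr::count(.data$doc_id) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::pull(.data$doc_id)
  drop_fmt <- entries$doc_id %in% both & entries$source_format == "pdf_text"
  n_format_dupes <- sum(drop_fmt)
  entries <- entries[!drop_fmt, , drop = FALSE]

  # (3) empty rows
  empty <- !nzchar(entries$enzyme_name) & !nzchar(entries$substrate_name) &
    is.na(entries$kcat_value) & is.na(entries$km_value)
  n_empty <- sum(empty)
  entries$flag_empty_row <- entries$flag_empty_row | empty
  entries <- entries[!empty, , drop = FALSE]

  # (4) per-document hallucination / repetition flags
  per_doc <- list()
  for (id in unique(entries$doc_id)) {
    sel <- entries$doc_id == id
    rows <- entries[sel, , drop = FALSE]
    rep_res <- flag_repetition(rows, cfg)
    if (!is.null(doc_index[[id]])) {
      hal_res <- suppressWarnings(flag_hallucination(doc_index[[id]], rows, cfg))
    } else {
      hal_res <- list(flagged = FALSE, found_fraction = NA_real_)
    }
    entries$flag_hallucinated[sel] <- entries$flag_hallucinated[sel] | hal_res$flagged
    entries$flag_repetitive[sel] <- entries$flag_repetitive[sel] | rep_res$flagged
    per_doc[[length(per_doc) + 1L]] <- tibble::tibble(
      doc_id = id,
      found_fraction = hal_res$found_fraction,
      unique_fraction = rep_res$unique_fraction,
      hallucinated = hal_res$flagged,
      repetitive = rep_res$flagged
    )
  }
  per_doc <- if (length(per_doc)) dplyr::bind_rows(per_doc) else
    tibble::tibble(doc_id = character(), found_fraction = double(),
                   unique_fraction = double(), hallucinated = logical(),
                   repetitive = logical())

  # (5) row-level scientific-notation flags
  entries$flag_scientific_notation <- entries$flag_scientific_notation |
    entries$kcat_sci_notation | entries$km_sci_notation

  n_hallucinated_rows <- sum(entries$flag_hallucinated)
  n_repetitive_rows <- sum(entries$flag_repetitive)
  n_sci_notation_rows <- sum(entries$flag_scientific_notation)

  # (6) exclusion policy
  flagged_any <- entries$flag_hallucinated | entries$flag_repetitive |
    entries$flag_scientific_notation
  n_excluded <- if (cfg$exclude_flagged) sum(flagged_any) else 0L
  if (cfg$exclude_flagged) entries <- entries[!flagged_any, , drop = FALSE]

  report <- structure(list(
    n_input = n_input,
    n_duplicates = n_duplicates,
    n_format_dupes = n_format_dupes,
    n_empty = n_empty,
    n_hallucinated_rows = n_hallucinated_rows,
    n_repetitive_rows = n_repetitive_rows,
    n_sci_notation_rows = n_sci_notation_rows,
    n_excluded_flagged = n_excluded,
    n_kept = nrow(entries),
    per_doc = per_doc
  ), class = "qc_report")
  list(entries = entries, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  cat(sprintf("  input rows        %d\n", x$n_input))
  cat(sprintf("  duplicates        %d\n", x$n_duplicates))
  cat(sprintf("  pdf/xml dupes     %d\n", x$n_format_dupes))
  cat(sprintf("  empty rows        %d\n", x$n_empty))
  cat(sprintf("  hallucinated rows %d\n", x$n_hallucinated_rows))
  cat(sprintf("  repetitive rows   %d\n", x$n_repetitive_rows))
  cat(sprintf("  sci-notation rows %d\n", x$n_sci_notation_rows))
  cat(sprintf("  excluded flagged  %d\n", x$n_excluded_flagged))
  cat(sprintf("  kept              %d\n", x$n_kept))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
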