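# Compilation of curated, resolved entries into the final database files
# (CSV + Parquet) plus the corpus-level summary statistics: entry counts,
# confidence-tier counts, the EC first-digit histogram, temperature/pH
# means and log10 value ranges.

#' Summary statistics for a measurement table
#'
#' @param entries a measurement tibble.
#' @return a list of class `summary_stats`.
#' @export
summary_stats <- function(entries) {
  entries <- as_measurement_table(entries)
  tiers <- entries$confidence[entries$confidence %in%
                                c("high", "medium", "low", "unmapped")]
  conf_counts <- vapply(c("high", "medium", "low", "unmapped"),
                        function(t) sum(tiers == t), integer(1))
  first_digit <- stringr::str_match(entries$ec, "^([1-7])\\.")[, 2]
  first_digit <- first_digit[!is.na(first_digit)]
  ec_hist <- vapply(as.character(1:7), function(d) sum(first_digit == d),
                    integer(1))
  rng <- function(x) {
    x <- x[!is.na(x) & x > 0]
    if (!length(x)) c(NA_real_, NA_real_) else range(log10(x))
  }
  structure(list(
    n_entries = nrow(entries),
    n_kcat = sum(!is.na(entries$kcat_canonical)),
    n_km = sum(!is.na(entries$km_canonical)),
    confidence_counts = as.list(conf_counts),
    ec_first_digit_hist = as.list(ec_hist),
    n_ec_classified = sum(ec_hist),
    temp_mean = if (any(!is.na(entries$temperature_C)))
      mean(entries$temperature_C, na.rm = TRUE) else NA_real_,
    ph_mean = if (any(!is.na(entries$ph)))
      mean(entries$ph, na.rm = TRUE) else NA_real_,
    log10_kcat_range = rng(entries$kcat_canonical),
    log10_km_range = rng(entries$km_canonical)
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Database: %d entries (%d kcat, %d Km)\n",
              x$n_entries, x$n_kcat, x$n_km))
  cat("  confidence:",
      paste(names(x$confidence_counts), unlist(x$confidence_counts),
            sep = "=", collapse = " "), "\n")
  cat(sprintf("  EC-classified: %d\n", x$n_ec_classified))
  invisible(x)
}

#' Build the database files from curated, resolved entries
#'
#' Writes `database.csv`, `database.parquet`, the sequence-mapped subset
#' `database_sequence_mapped.csv` (non-empty sequence and a confidence tier
#' other than unmapped), and `summary_stats.json`. Row order is
#' deterministic (doc_id, then row_index), so rebuilding from the same
#' entries is byte-identical.
#'
#' @param entries a measurement tibble (curated and resolved).
#' @param out_dir output directory (created if needed).
#' @return `list(files = named paths, stats = summary_stats)`.
#' @export
build_database <- function(entries, out_dir) {
  ok <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.access(out_dir, 2) == 0
  }, error = function(e) FALSE)
  if (!isTRUE(ok)) stop("output directory is not writable: ", out_dir)
  entries <- as_measurement_table(entries)
  entries <- dplyr::arrange(entries, .data$doc_id, .data$table_id,
                            .data$row_index)
  stats <- summary_stats(entries)
  files <- c(
    csv = file.path(out_dir, "database.csv"),
    parquet = file.path(out_dir, "database.parquet"),
    mapped = file.path(out_dir, "database_sequence_mapped.csv"),
    stats = file.path(out_dir, "summary_stats.json")
  )
  readr::write_csv(entries, files[["csv"]])
  arrow::write_parquet(entries, files[["parquet"]])
  mapped <- entries[nzchar(entries$sequence) &
                      entries$confidence %in% c("high", "medium", "low"), ]
  readr::write_csv(mapped, files[["mapped"]])
  jsonlite::write_json(unclass(stats), files[["stats"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  list(files = files, stats = stats)
}

#' Recompute summary statistics from a database file
#'
#' @param path a `database.csv` or `database.parquet` written by
#'   [build_database()].
#' @return a `summary_stats` identical to the one produced at build time.
#' @export
summarize_database <- function(path) {
  entries <- if (grepl("\\.parquet$", path)) {
    tibble::as_tibble(arrow::read_parquet(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  need <- names(measurement_defaults())
  missing <- setdiff(need, names(entries))
  if (length(missing)) {
    stop("database schema mismatch; missing columns: ",
         paste(missing, collapse = ", "))
  }
  # CSV round-trips empty strings as NA; restore the schema defaults
  for (nm in names(entries)) {
    if (is.character(entries[[nm]])) {
      entries[[nm]][is.na(entries[[nm]])] <- ""
    }
  }
  for (nm in c("flag_hallucinated", "flag_repetitive",
               "flag_scientific_notation", "flag_duplicate",
               "flag_empty_row", "kcat_sci_notation", "km_sci_notation",
               "kcat_glyph_ambiguous", "km_glyph_ambiguous")) {
    entries[[nm]][is.na(entries[[nm]])] <- FALSE
  }
  summary_stats(entries)
}
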