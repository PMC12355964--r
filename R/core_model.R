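# Shared domain model: one kinetic measurement per row of a tibble.
#
# A "measurement table" is a tibble with one row per enzyme-substrate-kinetics
# record. Canonical numeric values are stored alongside the printed value and
# the raw unit string so that downstream stages can audit the conversion.

measurement_col_types <- function() {
  list(
    enzyme_name = character(), organism = character(), mutation = character(),
    substrate_name = character(), substrate_smiles = character(),
    kcat_value = double(), kcat_unit = character(), kcat_canonical = double(),
    kcat_printed = character(), kcat_sci_notation = logical(),
    kcat_glyph_ambiguous = logical(),
    km_value = double(), km_unit = character(), km_canonical = double(),
    km_printed = character(), km_sci_notation = logical(),
    km_glyph_ambiguous = logical(),
    ph = double(), temperature_C = double(),
    uniprot = character(), ncbi = character(), pdb = character(),
    ec = character(), sequence = character(), confidence = character(),
    flag_hallucinated = logical(), flag_repetitive = logical(),
    flag_scientific_notation = logical(), flag_duplicate = logical(),
    flag_empty_row = logical(),
    doc_id = character(), source_format = character(),
    table_id = character(), row_index = integer()
  )
}

empty_measurement_table <- function() {
  tibble::as_tibble(measurement_col_types())
}

measurement_defaults <- function() {
  list(
    enzyme_name = "", organism = "", mutation = "",
    substrate_name = "", substrate_smiles = "",
    kcat_value = NA_real_, kcat_unit = "", kcat_canonical = NA_real_,
    kcat_printed = "", kcat_sci_notation = FALSE, kcat_glyph_ambiguous = FALSE,
    km_value = NA_real_, km_unit = "", km_canonical = NA_real_,
    km_printed = "", km_sci_notation = FALSE, km_glyph_ambiguous = FALSE,
    ph = NA_real_, temperature_C = NA_real_,
    uniprot = "", ncbi = "", pdb = "", ec = "", sequence = "",
    confidence = "",
    flag_hallucinated = FALSE, flag_repetitive = FALSE,
    flag_scientific_notation = FALSE, flag_duplicate = FALSE,
    flag_empty_row = FALSE,
    doc_id = "", source_format = "markdown_fixture", table_id = "",
    row_index = 0L
  )
}

#' Construct a kinetic measurement record
#'
#' Returns a one-row measurement tibble with every known column present;
#' unspecified fields take the documented defaults (empty strings for text,
#' `NA` for numbers, `FALSE` for quality flags).
#'
#' @param ... named fields; see the package vignette for the schema.
#' @return a one-row tibble.
#' @export
#' @examples
#' kinetic_measurement(enzyme_name = "urease", kcat_canonical = 3.1,
#'                     doc_id = "10.1000/x1")
kinetic_measurement <- function(...) {
  fields <- list(...)
  defs <- measurement_defaults()
  unknown <- setdiff(names(fields), names(defs))
  if (length(unknown)) {
    stop("unknown measurement field(s): ", paste(unknown, collapse = ", "))
  }
  defs[names(fields)] <- fields
  defs$row_index <- as.integer(defs$row_index)
  tibble::as_tibble(defs)
}

#' Coerce a data frame to the full measurement schema
#'
#' Missing columns are added with their default values; column order is
#' normalized. Existing columns are kept as-is.
#'
#' @param df a data frame with a subset of measurement columns.
#' @return a measurement tibble.
#' @export
as_measurement_table <- function(df) {
  defs <- measurement_defaults()
  df <- tibble::as_tibble(df)
  for (nm in names(defs)) {
    if (!nm %in% names(df)) df[[nm]] <- defs[[nm]]
  }
  df$row_index <- as.integer(df$row_index)
  df[names(defs)]
}

#' Validate a measurement record against the domain invariants
#'
#' Pure check, never raises and never mutates: returns one row per violated
#' rule. `severity` is `"error"` for hard invariants (positivity of canonical
#' kinetic values, pH within 0-14, temperature within -20 to 150, non-empty
#' provenance) and `"warning"` for values outside the span observed in
#' curated corpora (assay temperatures 0-100 degrees C).
#'
#' @param m a one-row measurement tibble (or a list with the same fields).
#' @return a tibble with columns `field`, `rule`, `severity`, `message`;
#'   zero rows when every invariant holds.
#' @export
validate_measurement <- function(m) {
  m <- as_measurement_table(tibble::as_tibble(as.list(m)))
  v <- list()
  add <- function(field, rule, severity, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(
      field = field, rule = rule, severity = severity, message = message
    )
  }
  if (!nzchar(m$doc_id)) {
    add("doc_id", "nonempty", "error", "provenance doc_id must be non-empty")
  }
  if (is.na(m$row_index) || m$row_index < 0L) {
    add("row_index", "nonnegative", "error", "row_index must be >= 0")
  }
  empty <- !nzchar(m$enzyme_name) && !nzchar(m$substrate_name) &&
    is.na(m$kcat_canonical) && is.na(m$kcat_value) &&
    is.na(m$km_canonical) && is.na(m$km_value)
  if (empty) {
    add("record", "empty_row", "error",
        "record lacks enzyme, substrate and kinetic values (empty row)")
  }
  if (!is.na(m$kcat_canonical) && m$kcat_canonical <= 0) {
    add("kcat_canonical", "positive", "error",
        "canonical kcat must be strictly positive")
  }
  if (!is.na(m$km_canonical) && m$km_canonical <= 0) {
    add("km_canonical", "positive", "error",
        "canonical Km must be strictly positive")
  }
  if (!is.na(m$ph) && (m$ph < 0 || m$ph > 14)) {
    add("ph", "range_0_14", "error", "pH outside [0, 14]")
  }
  if (!is.na(m$temperature_C)) {
    if (m$temperature_C < -20 || m$temperature_C > 150) {
      add("temperature_C", "range_-20_150", "error",
          "temperature outside [-20, 150] degrees C")
    } else if (m$temperature_C < 0 || m$temperature_C > 100) {
      add("temperature_C", "observed_span_0_100", "warning",
          "temperature outside the 0-100 degrees C span observed in curated corpora")
    }
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(field = character(), rule = character(),
                   severity = character(), message = character())
}

# ---- JSON Lines serialization -------------------------------------------

jsonl_field_order <- c(
  "enzyme_name", "organism", "mutation", "substrate_name", "substrate_smiles",
  "kcat_value", "kcat_unit", "km_value", "km_unit", "ph", "temperature_C",
  "uniprot", "ncbi", "pdb", "ec", "sequence", "confidence", "flags",
  "doc_id", "source_format", "table_id", "row_index"
)

measurement_to_json <- function(row) {
  rec <- list(
    enzyme_name = row$enzyme_name, organism = row$organism,
    mutation = row$mutation, substrate_name = row$substrate_name,
    substrate_smiles = row$substrate_smiles,
    kcat_value = row$kcat_value, kcat_unit = row$kcat_unit,
    km_value = row$km_value, km_unit = row$km_unit,
    ph = row$ph, temperature_C = row$temperature_C,
    uniprot = row$uniprot, ncbi = row$ncbi, pdb = row$pdb, ec = row$ec,
    sequence = row$sequence, confidence = row$confidence,
    flags = list(
      hallucinated = row$flag_hallucinated,
      repetitive = row$flag_repetitive,
      scientific_notation = row$flag_scientific_notation,
      duplicate = row$flag_duplicate,
      empty_row = row$flag_empty_row
    ),
    doc_id = row$doc_id, source_format = row$source_format,
    table_id = row$table_id, row_index = row$row_index
  )
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null")
}

#' Write measurements as JSON Lines
#'
#' One UTF-8 JSON object per line, flat schema with a nested `flags` object.
#'
#' @param entries a measurement tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements_jsonl <- function(entries, path) {
  entries <- as_measurement_table(entries)
  lines <- vapply(seq_len(nrow(entries)), function(i) {
    as.character(measurement_to_json(entries[i, ]))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read measurements from JSON Lines
#'
#' Canonical kinetic values are recomputed from the printed value and raw
#' unit string, so a round trip preserves them.
#'
#' @param path input file path.
#' @return a measurement tibble.
#' @export
read_measurements_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_measurement_table())
  rows <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    flags <- rec$flags
    rec$flags <- NULL
    null2 <- function(x, d) if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.na(x) && is.character(d))) d else x
    args <- measurement_defaults()
    for (nm in names(rec)) {
      if (nm %in% names(args)) args[[nm]] <- null2(rec[[nm]], args[[nm]])
    }
    args$flag_hallucinated <- isTRUE(flags$hallucinated)
    args$flag_repetitive <- isTRUE(flags$repetitive)
    args$flag_scientific_notation <- isTRUE(flags$scientific_notation)
    args$flag_duplicate <- isTRUE(flags$duplicate)
    args$flag_empty_row <- isTRUE(flags$empty_row)
    do.call(kinetic_measurement, args)
  })
  out <- dplyr::bind_rows(rows)
  # recompute canonical values from printed value + raw unit
  recanon <- function(value, unit, kind) {
    mapply(function(v, u) {
      if (is.na(v)) return(NA_real_)
      if (!nzchar(u)) return(NA_real_)
      q <- try(parse_quantity(paste(format(v, scientific = FALSE, trim = TRUE), u), kind),
               silent = TRUE)
      if (inherits(q, "try-error")) NA_real_ else q$canonical_value
    }, value, unit)
  }
  out$kcat_canonical <- recanon(out$kcat_value, out$kcat_unit, "rate")
  out$km_canonical <- recanon(out$km_value, out$km_unit, "concentration")
  out
}
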