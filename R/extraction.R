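# Extraction backend contract and the deterministic reference backend.
#
# The reference backend plays the role an instruction-tuned language model
# plays in a production pipeline: it reads a document's tables and emits one
# raw extraction per row carrying at least one kinetic value. It is a pure
# function of (document, lexicon), which keeps every downstream stage
# testable offline.

raw_extraction_defaults <- function() {
  list(
    enzyme_name = "", organism = "", mutation = "",
    substrate_name = "", substrate_smiles = "",
    kcat_value = "", kcat_unit = "", km_value = "", km_unit = "",
    ph = "", temperature_C = "",
    uniprot = "", ncbi = "", pdb = "", ec = "",
    doc_id = "", source_format = "markdown_fixture",
    table_id = "", row_index = 0L, backend_name = "reference"
  )
}

#' Default header-synonym lexicon
#'
#' Maps column-header spellings (lower-cased, unit annotations stripped) to
#' the roles the extractor understands. Kinetics roles win ties by lexicon
#' order.
#'
#' @return a named list role -> character vector of synonyms.
#' @export
default_lexicon <- function() {
  list(
    kcat = c("kcat", "k_cat", "k cat", "turnover number", "kcat value"),
    km = c("km", "k_m", "k m", "michaelis constant",
           "michaelis-menten constant", "km value"),
    enzyme = c("enzyme", "enzyme name", "protein"),
    organism = c("organism", "species", "source organism", "source"),
    mutation = c("mutation", "mutant", "variant"),
    substrate = c("substrate", "substrate name", "compound"),
    ph = c("ph"),
    temperature = c("temperature", "temp", "t"),
    uniprot = c("uniprot", "uniprot id", "uniprot accession"),
    ncbi = c("ncbi", "ncbi accession", "genbank"),
    pdb = c("pdb", "pdb id"),
    ec = c("ec", "ec number")
  )
}

# Split a header cell into (role text, unit annotation). The unit may sit in
# a trailing parenthetical "kcat (s^-1)" or after the last comma "kcat, s^-1".
split_header_unit <- function(header) {
  h <- stringr::str_trim(header)
  m <- stringr::str_match(h, "^(.*?)\\s*\\(([^()]*)\\)\\s*$")
  if (!is.na(m[1, 1])) return(list(base = m[1, 2], unit = stringr::str_trim(m[1, 3])))
  m <- stringr::str_match(h, "^(.*),\\s*([^,]*)$")
  if (!is.na(m[1, 1])) {
    cand <- stringr::str_trim(m[1, 3])
    if (parse_unit_token(cand)$base_unit != "unknown") {
      return(list(base = m[1, 2], unit = cand))
    }
  }
  list(base = h, unit = "")
}

# Resolve each header cell to a role (or NA). Longest-synonym match,
# case-insensitive, over NFKC-normalized text; ties resolved by lexicon order.
resolve_column_roles <- function(header, lexicon = default_lexicon()) {
  roles <- rep(NA_character_, length(header))
  units <- character(length(header))
  for (i in seq_along(header)) {
    sp <- split_header_unit(header[i])
    units[i] <- sp$unit
    base <- normalize_key_field(sp$base)
    best_role <- NA_character_
    best_len <- -1L
    for (role in names(lexicon)) {
      for (syn in lexicon[[role]]) {
        if (base == syn && nchar(syn) > best_len) {
          best_role <- role
          best_len <- nchar(syn)
        }
      }
    }
    roles[i] <- best_role
  }
  list(roles = roles, units = units)
}

# Split a data cell "3.1 min^-1" into value string and embedded unit string.
split_cell_value_unit <- function(cell) {
  cell <- stringr::str_trim(cell)
  if (!nzchar(cell)) return(list(value = "", unit = ""))
  tok <- parse_numeric_token(cell)
  if (is.null(tok)) return(list(value = cell, unit = ""))
  # the unit suffix length is preserved by text normalization (all character
  # maps are 1:1), so split the original cell at that length to keep both
  # the printed value and the unit exactly as they appear in the document
  if (nzchar(tok$rest)) {
    cut <- nchar(cell) - nchar(tok$rest)
    value_str <- stringr::str_trim(stringr::str_sub(cell, 1L, cut))
    unit_str <- stringr::str_sub(cell, cut + 1L, nchar(cell))
  } else {
    value_str <- cell
    unit_str <- ""
  }
  if (!nzchar(value_str)) value_str <- cell
  list(value = value_str, unit = unit_str)
}

doc_level_metadata <- function(doc) {
  lines <- c(doc$narrative_pre, doc$narrative_post)
  grab <- function(label) {
    hit <- stringr::str_match(lines, paste0("^", label, ":\\s*(.+)$"))[, 2]
    hit <- hit[!is.na(hit)]
    if (length(hit)) stringr::str_trim(hit[1]) else ""
  }
  list(enzyme = grab("Enzyme"), organism = grab("Organism"),
       mutation = grab("Mutation"))
}

#' Extract raw kinetic records from a document's tables
#'
#' Deterministic reference extractor: one raw record per table row that
#' carries at least one kinetic value. Units are taken from the cell when
#' embedded there, otherwise inherited from the column header. When a table
#' lacks enzyme/organism columns, document-level `Enzyme:` / `Organism:`
#' statements in the narrative are attached to every row.
#'
#' @param doc a `document_record`.
#' @param lexicon a role -> synonyms map, see [default_lexicon()].
#' @return a tibble of raw extractions (string-valued fields, units
#'   unparsed), zero rows when no table has a recognizable kinetic column.
#' @export
reference_extract <- function(doc, lexicon = default_lexicon()) {
  out <- list()
  meta <- doc_level_metadata(doc)
  for (tbl in doc$tables) {
    res <- resolve_column_roles(tbl$header, lexicon)
    roles <- res$roles
    if (!any(roles %in% c("kcat", "km"), na.rm = TRUE)) next
    col_of <- function(role) {
      ix <- which(roles == role)
      if (length(ix)) ix[1] else NA_integer_
    }
    for (r in seq_along(tbl$rows)) {
      row <- tbl$rows[[r]]
      rec <- raw_extraction_defaults()
      get_cell <- function(role) {
        ix <- col_of(role)
        if (is.na(ix)) "" else stringr::str_trim(row[ix])
      }
      for (fld in c("kcat", "km")) {
        cell <- get_cell(fld)
        if (!nzchar(cell)) next
        sp <- split_cell_value_unit(cell)
        unit <- if (nzchar(sp$unit)) sp$unit else res$units[col_of(fld)]
        rec[[paste0(fld, "_value")]] <- sp$value
        rec[[paste0(fld, "_unit")]] <- unit
      }
      if (!nzchar(rec$kcat_value) && !nzchar(rec$km_value)) next
      rec$enzyme_name <- if (!is.na(col_of("enzyme"))) get_cell("enzyme") else meta$enzyme
      rec$organism <- if (!is.na(col_of("organism"))) get_cell("organism") else meta$organism
      rec$mutation <- if (!is.na(col_of("mutation"))) get_cell("mutation") else meta$mutation
      rec$substrate_name <- get_cell("substrate")
      rec$ph <- get_cell("ph")
      rec$temperature_C <- get_cell("temperature")
      for (idf in c("uniprot", "ncbi", "pdb", "ec")) rec[[idf]] <- get_cell(idf)
      rec$doc_id <- doc$doc_id
      rec$source_format <- doc$source_format
      rec$table_id <- tbl$table_id
      rec$row_index <- r - 1L
      out[[length(out) + 1L]] <- tibble::as_tibble(rec)
    }
  }
  if (!length(out)) {
    return(tibble::as_tibble(lapply(raw_extraction_defaults(), function(x) x[0])))
  }
  dplyr::bind_rows(out)
}

#' Validate one raw-extraction JSON record against the documented schema
#'
#' Never raises: returns the coerced record plus a character vector of
#' violations (empty when the record is well-formed). Unknown keys are
#' reported; provenance (`doc_id`) is required; numeric-string fields must
#' contain a parseable number when non-empty.
#'
#' @param json_record a named list (e.g. from `jsonlite::fromJSON`).
#' @return `list(record = <one-row tibble or NULL>, violations = character())`.
#' @export
schema_validate <- function(json_record) {
  defs <- raw_extraction_defaults()
  v <- character()
  unknown <- setdiff(names(json_record), c(names(defs), "flags"))
  if (length(unknown)) {
    v <- c(v, paste0("unknown key: ", unknown))
  }
  rec <- defs
  for (nm in intersect(names(json_record), names(defs))) {
    val <- json_record[[nm]]
    if (nm == "row_index") {
      if (!is.numeric(val) || length(val) != 1L || is.na(val) || val < 0) {
        v <- c(v, "row_index must be a non-negative integer")
      } else rec$row_index <- as.integer(val)
    } else {
      if (is.numeric(val)) val <- format(val, scientific = FALSE, trim = TRUE)
      if (!is.character(val) || length(val) != 1L) {
        v <- c(v, paste0(nm, " must be a scalar string"))
      } else rec[[nm]] <- val
    }
  }
  if (!nzchar(rec$doc_id)) v <- c(v, "provenance.doc_id required")
  for (nm in c("kcat_value", "km_value", "ph", "temperature_C")) {
    if (nzchar(rec[[nm]]) && is.null(parse_numeric_token(rec[[nm]]))) {
      v <- c(v, paste0(nm, " is not numeric: ", sQuote(rec[[nm]])))
    }
  }
  list(record = if (length(v)) NULL else tibble::as_tibble(rec),
       violations = v)
}

#' Canonicalize raw extractions into measurement records
#'
#' Parses the kinetic value/unit strings with the unit engine, filling
#' canonical values, scientific-notation and glyph-ambiguity flags.
#'
#' @param raw a raw-extraction tibble from [reference_extract()].
#' @return a measurement tibble.
#' @export
canonicalize_extractions <- function(raw) {
  if (!nrow(raw)) return(empty_measurement_table())
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    x <- raw[i, ]
    m <- measurement_defaults()
    for (nm in c("enzyme_name", "organism", "substrate_name",
                 "substrate_smiles", "uniprot", "ncbi", "pdb", "ec",
                 "doc_id", "source_format", "table_id")) {
      m[[nm]] <- x[[nm]]
    }
    m$mutation <- normalize_mutation(x$mutation)
    m$row_index <- x$row_index
    num_or_na <- function(s) {
      tok <- parse_numeric_token(s)
      if (is.null(tok)) NA_real_ else tok$value
    }
    if (nzchar(x$ph)) m$ph <- num_or_na(x$ph)
    if (nzchar(x$temperature_C)) m$temperature_C <- num_or_na(x$temperature_C)
    for (fld in c("kcat", "km")) {
      vs <- x[[paste0(fld, "_value")]]
      us <- x[[paste0(fld, "_unit")]]
      if (!nzchar(vs)) next
      kind <- if (fld == "kcat") "rate" else "concentration"
      q <- tryCatch(parse_quantity(paste(vs, us), kind), error = function(e) NULL)
      if (is.null(q)) next
      m[[paste0(fld, "_value")]] <- q$value
      m[[paste0(fld, "_unit")]] <- us
      m[[paste0(fld, "_canonical")]] <- q$canonical_value
      m[[paste0(fld, "_printed")]] <- vs
      m[[paste0(fld, "_sci_notation")]] <- q$sci_notation
      m[[paste0(fld, "_glyph_ambiguous")]] <- q$glyph_ambiguous
    }
    tibble::as_tibble(m)
  })
  dplyr::bind_rows(rows)
}
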