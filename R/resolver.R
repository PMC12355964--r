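# Offline resolution of enzyme names to sequences and substrate names to
# SMILES, plus the metadata-count confidence tiers. Lookups are pluggable:
# the fixture-backed tables used here share their contract with live
# UniProt/PubChem clients, which are deliberately out of scope.

#' Confidence-tier configuration
#'
#' Tiering counts how many of five metadata fields (enzyme name, organism,
#' UniProt, NCBI, PDB identifiers) are present: at least `high_min` gives
#' "high", exactly `medium_eq` gives "medium", exactly `low_eq` gives "low",
#' zero gives "unmapped".
#'
#' @param high_min,medium_eq,low_eq tier boundaries (defaults 3, 2, 1).
#' @return a list of class `resolution_config`.
#' @export
resolution_config <- function(high_min = 3L, medium_eq = 2L, low_eq = 1L) {
  stopifnot(high_min > medium_eq, medium_eq > low_eq, low_eq >= 1L)
  structure(list(
    metadata_fields = c("enzyme_name", "organism", "uniprot", "ncbi", "pdb"),
    high_min = high_min, medium_eq = medium_eq, low_eq = low_eq
  ), class = "resolution_config")
}

#' Assign confidence tiers by metadata-field count
#'
#' @param entries a measurement tibble (or any data frame with the five
#'   metadata columns).
#' @param cfg a [resolution_config()].
#' @return a character vector of tiers (`"high"`, `"medium"`, `"low"`,
#'   `"unmapped"`), one per row.
#' @export
score_confidence <- function(entries, cfg = resolution_config()) {
  counts <- Reduce(`+`, lapply(cfg$metadata_fields, function(f) {
    x <- as.character(entries[[f]])
    as.integer(!is.na(x) & nzchar(x))
  }))
  dplyr::case_when(
    counts >= cfg$high_min ~ "high",
    counts == cfg$medium_eq ~ "medium",
    counts == cfg$low_eq ~ "low",
    .default = "unmapped"
  )
}

#' Sequence lookup backed by a fixture table
#'
#' @param x a TSV path or a data frame with columns `kind`, `id`, `name`,
#'   `organism`, `sequence`; row order defines the ranking of
#'   name-plus-organism hits.
#' @return a list of class `sequence_lookup` with functions
#'   `by_identifier(kind, id)` and `by_name_organism(name, organism)`.
#' @export
sequence_lookup <- function(x) {
  tab <- if (is.character(x)) {
    readr::read_tsv(x, show_col_types = FALSE,
                    col_types = readr::cols(.default = "c"))
  } else {
    tibble::as_tibble(x)
  }
  stopifnot(all(c("kind", "id", "name", "organism", "sequence") %in% names(tab)))
  tab$name_norm <- normalize_key_field(tab$name)
  tab$organism_norm <- normalize_key_field(tab$organism)
  structure(list(
    table = tab,
    by_identifier = function(kind, id) {
      hit <- tab[tab$kind == kind & tab$id == id, ]
      if (nrow(hit)) hit$sequence[1] else NA_character_
    },
    by_name_organism = function(name, organism) {
      tab[tab$name_norm == normalize_key_field(name) &
            tab$organism_norm == normalize_key_field(organism), ]
    }
  ), class = "sequence_lookup")
}

#' Resolve a measurement to a protein sequence
#'
#' Identifier-first precedence: UniProt, then NCBI, then PDB; the first
#' identifier that resolves wins. With no resolvable identifier, a combined
#' name-plus-organism search is performed and the top-ranked hit selected.
#' Lookup misses never raise.
#'
#' @param m a one-row measurement tibble.
#' @param lookup a [sequence_lookup()].
#' @return `list(sequence = string or NA, method = tag)` where the tag is
#'   `"identifier:uniprot"`, `"identifier:ncbi"`, `"identifier:pdb"`,
#'   `"name_search"` or `"unresolved"`.
#' @export
resolve_sequence <- function(m, lookup) {
  for (kind in c("uniprot", "ncbi", "pdb")) {
    id <- as.character(m[[kind]])
    if (!is.na(id) && nzchar(id)) {
      seq <- lookup$by_identifier(kind, id)
      if (!is.na(seq)) {
        return(list(sequence = seq, method = paste0("identifier:", kind)))
      }
    }
  }
  nm <- as.character(m$enzyme_name)
  org <- as.character(m$organism)
  if (nzchar(nm) && nzchar(org)) {
    hits <- lookup$by_name_organism(nm, org)
    if (nrow(hits)) {
      return(list(sequence = hits$sequence[1], method = "name_search"))
    }
  }
  list(sequence = NA_character_, method = "unresolved")
}

#' Compound lookup backed by fixture tables
#'
#' @param compounds a TSV path or data frame with columns `name`, `rank`,
#'   `smiles`.
#' @param abbreviations optional TSV path or data frame with columns
#'   `abbrev`, `full_name`.
#' @return a list of class `compound_lookup` with `by_name(name)` and
#'   `expand_abbreviation(abbrev)`.
#' @export
compound_lookup <- function(compounds, abbreviations = NULL) {
  ctab <- if (is.character(compounds)) {
    readr::read_tsv(compounds, show_col_types = FALSE,
                    col_types = readr::cols(name = "c", rank = "i", smiles = "c"))
  } else {
    tibble::as_tibble(compounds)
  }
  ctab$name_norm <- normalize_key_field(ctab$name)
  atab <- if (is.null(abbreviations)) {
    tibble::tibble(abbrev = character(), full_name = character())
  } else if (is.character(abbreviations)) {
    readr::read_tsv(abbreviations, show_col_types = FALSE,
                    col_types = readr::cols(.default = "c"))
  } else {
    tibble::as_tibble(abbreviations)
  }
  atab$abbrev_norm <- normalize_key_field(atab$abbrev)
  structure(list(
    table = ctab,
    by_name = function(name) {
      hits <- ctab[ctab$name_norm == normalize_key_field(name), ]
      hits[order(hits$rank), ]
    },
    expand_abbreviation = function(abbrev) {
      hit <- atab[atab$abbrev_norm == normalize_key_field(abbrev), ]
      if (nrow(hit)) hit$full_name[1] else NA_character_
    }
  ), class = "compound_lookup")
}

#' Resolve a substrate name to a SMILES string
#'
#' Abbreviations are expanded first when the abbreviation table knows them;
#' the query then returns the top-ranked SMILES. Generic polymeric names on
#' the stop-list (DNA, RNA, protein, starch by default) are refused with
#' reason `"generic_substrate"` since they lack a defined structure.
#'
#' @param name substrate name (non-empty).
#' @param lookup a [compound_lookup()].
#' @param stoplist lower-case generic names to refuse.
#' @return `list(smiles = string or NA, resolved_name = string,
#'   reason = "" or "generic_substrate" or "not_found")`.
#' @export
resolve_substrate <- function(name, lookup,
                              stoplist = c("dna", "rna", "protein", "starch")) {
  stopifnot(nzchar(name))
  norm <- normalize_key_field(name)
  if (norm %in% stoplist) {
    return(list(smiles = NA_character_, resolved_name = name,
                reason = "generic_substrate"))
  }
  full <- lookup$expand_abbreviation(name)
  query <- if (!is.na(full)) full else name
  hits <- lookup$by_name(query)
  if (nrow(hits)) {
    list(smiles = hits$smiles[1], resolved_name = query, reason = "")
  } else {
    list(smiles = NA_character_, resolved_name = query, reason = "not_found")
  }
}

#' Resolve all entries: confidence tiers, sequences and SMILES
#'
#' Convenience wrapper applying [score_confidence()], [resolve_sequence()]
#' and [resolve_substrate()] over a measurement table.
#'
#' @param entries a measurement tibble.
#' @param seq_lookup a [sequence_lookup()], or `NULL` to skip sequences.
#' @param cmpd_lookup a [compound_lookup()], or `NULL` to skip SMILES.
#' @param cfg a [resolution_config()].
#' @return the entries with `confidence`, `sequence` and `substrate_smiles`
#'   filled in.
#' @export
resolve_entries <- function(entries, seq_lookup = NULL, cmpd_lookup = NULL,
                            cfg = resolution_config()) {
  entries <- as_measurement_table(entries)
  entries$confidence <- score_confidence(entries, cfg)
  if (!is.null(seq_lookup)) {
    for (i in seq_len(nrow(entries))) {
      res <- resolve_sequence(entries[i, ], seq_lookup)
      if (!is.na(res$sequence)) entries$sequence[i] <- res$sequence
    }
  }
  if (!is.null(cmpd_lookup)) {
    for (i in seq_len(nrow(entries))) {
      nm <- entries$substrate_name[i]
      if (!nzchar(nm) || nzchar(entries$substrate_smiles[i])) next
      res <- resolve_substrate(nm, cmpd_lookup)
      if (!is.na(res$smiles)) entries$substrate_smiles[i] <- res$smiles
    }
  }
  entries
}
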