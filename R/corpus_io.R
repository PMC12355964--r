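# Document fixtures: plain text with embedded pipe-delimited Markdown tables,
# or a minimal XML dialect (<doc><p>...</p><table><tr><td>...). Documents
# expose both a single searchable text string and structured tables.

#' Construct a parsed table
#'
#' @param table_id identifier within the document.
#' @param header character vector of column names (non-empty).
#' @param rows list of character vectors, each of length `length(header)`.
#' @return a list of class `markdown_table`.
#' @export
markdown_table <- function(table_id, header, rows) {
  stopifnot(length(header) >= 1L)
  rows <- lapply(rows, as.character)
  bad <- vapply(rows, length, integer(1)) != length(header)
  if (any(bad)) stop("rows must have exactly ", length(header), " cells")
  structure(list(table_id = table_id, header = as.character(header),
                 rows = rows), class = "markdown_table")
}

#' Render a table in pipe-delimited Markdown
#'
#' @param tbl a `markdown_table`.
#' @return a single string (lines joined with newlines).
#' @export
render_markdown_table <- function(tbl) {
  line <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")
  sep <- paste0("|", paste(rep(" --- ", length(tbl$header)), collapse = "|"), "|")
  paste(c(line(tbl$header), sep,
          vapply(tbl$rows, line, character(1))), collapse = "\n")
}

#' Construct a document record
#'
#' `narrative_pre` / `narrative_post` keep the free text surrounding the
#' tables so the full text can be re-rendered after table edits.
#'
#' @param doc_id document identifier (DOI or PubMed ID).
#' @param source_format one of `"pdf_text"`, `"xml"`, `"markdown_fixture"`.
#' @param full_text the complete searchable text.
#' @param tables list of `markdown_table`s.
#' @param narrative_pre,narrative_post character vectors of text lines.
#' @return a list of class `document_record`.
#' @export
document_record <- function(doc_id, source_format, full_text, tables,
                            narrative_pre = character(),
                            narrative_post = character()) {
  stopifnot(nzchar(doc_id))
  structure(list(doc_id = doc_id, source_format = source_format,
                 full_text = full_text, tables = tables,
                 narrative_pre = narrative_pre,
                 narrative_post = narrative_post),
            class = "document_record")
}

#' Re-render a document's full text from its narrative and tables
#'
#' @param doc a `document_record`.
#' @return the document with `full_text` rebuilt.
#' @export
render_document <- function(doc) {
  parts <- c(doc$narrative_pre,
             vapply(doc$tables, render_markdown_table, character(1)),
             doc$narrative_post)
  doc$full_text <- paste(parts, collapse = "\n")
  doc
}

is_pipe_row <- function(line) grepl("^\\s*\\|.*\\|\\s*$", line)
is_separator_row <- function(line) {
  grepl("^\\s*\\|[\\s:|-]*\\|\\s*$", line, perl = TRUE) &&
    grepl("-", line, fixed = TRUE)
}

split_pipe_row <- function(line) {
  line <- stringr::str_trim(line)
  line <- stringr::str_replace(line, "^\\|", "")
  line <- stringr::str_replace(line, "\\|$", "")
  stringr::str_trim(stringr::str_split(line, stringr::fixed("|"))[[1]])
}

parse_markdown_tables <- function(lines) {
  tables <- list()
  n <- length(lines)
  i <- 1L
  in_table <- FALSE
  block <- integer()
  blocks <- list()
  for (i in seq_len(n)) {
    if (is_pipe_row(lines[i])) {
      block <- c(block, i)
      in_table <- TRUE
    } else if (in_table) {
      blocks[[length(blocks) + 1L]] <- block
      block <- integer()
      in_table <- FALSE
    }
  }
  if (in_table) blocks[[length(blocks) + 1L]] <- block
  out <- list()
  for (b in blocks) {
    rows_txt <- lines[b]
    if (length(rows_txt) < 2L || !is_separator_row(rows_txt[2])) next
    header <- split_pipe_row(rows_txt[1])
    data_rows <- lapply(rows_txt[-(1:2)], split_pipe_row)
    width <- length(header)
    data_rows <- lapply(data_rows, function(r) {
      if (length(r) < width) {
        warning("ragged table row padded to header width", call. = FALSE)
        r <- c(r, rep("", width - length(r)))
      } else if (length(r) > width) {
        warning("ragged table row truncated to header width", call. = FALSE)
        r <- r[seq_len(width)]
      }
      r
    })
    out[[length(out) + 1L]] <-
      markdown_table(paste0("T", length(out) + 1L), header, data_rows)
  }
  out
}

read_document_markdown <- function(lines, doc_id, source_format) {
  tables <- parse_markdown_tables(lines)
  pipe <- vapply(lines, is_pipe_row, logical(1))
  # narrative = everything up to the first table line / after the last
  first <- if (any(pipe)) which(pipe)[1] else length(lines) + 1L
  last <- if (any(pipe)) max(which(pipe)) else 0L
  document_record(
    doc_id = doc_id, source_format = source_format,
    full_text = paste(lines, collapse = "\n"), tables = tables,
    narrative_pre = if (first > 1L) lines[seq_len(first - 1L)] else character(),
    narrative_post = if (last < length(lines)) lines[seq(last + 1L, length(lines))] else character()
  )
}

read_document_xml <- function(text, doc_id) {
  x <- tryCatch(xml2::read_xml(text),
                error = function(e) stop("malformed XML for ", doc_id, ": ",
                                         conditionMessage(e), call. = FALSE))
  paras <- xml2::xml_text(xml2::xml_find_all(x, ".//p"))
  tbl_nodes <- xml2::xml_find_all(x, ".//table")
  tables <- list()
  for (k in seq_along(tbl_nodes)) {
    trs <- xml2::xml_find_all(tbl_nodes[[k]], ".//tr")
    cells <- lapply(trs, function(tr) {
      xml2::xml_text(xml2::xml_find_all(tr, ".//td | .//th"))
    })
    if (!length(cells)) next
    header <- cells[[1]]
    width <- length(header)
    data_rows <- lapply(cells[-1], function(r) {
      if (length(r) < width) {
        warning("ragged table row padded to header width", call. = FALSE)
        r <- c(r, rep("", width - length(r)))
      }
      r[seq_len(width)]
    })
    tables[[length(tables) + 1L]] <-
      markdown_table(paste0("T", length(tables)), header, data_rows)
  }
  # re-number from T1
  for (k in seq_along(tables)) tables[[k]]$table_id <- paste0("T", k)
  doc <- document_record(doc_id = doc_id, source_format = "xml",
                         full_text = "", tables = tables,
                         narrative_pre = paras)
  render_document(doc)
}

#' Read a fixture document
#'
#' Markdown fixtures are plain UTF-8 text whose tables are pipe rows with a
#' dash separator under the header; the XML dialect is
#' `<doc><p>...</p><table><tr><td>...</td></tr></table></doc>`. The format is
#' taken from `source_format` or sniffed from the leading character.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param doc_id document identifier.
#' @param source_format `"markdown_fixture"`, `"pdf_text"` or `"xml"`;
#'   `NULL` to sniff.
#' @param text optional in-memory document text (overrides `path`).
#' @return a `document_record`.
#' @export
read_document <- function(path = NULL, doc_id, source_format = NULL,
                          text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("cannot read document file: ", path)
    text <- readLines(path, encoding = "UTF-8", warn = FALSE)
  }
  joined <- paste(text, collapse = "\n")
  if (is.null(source_format)) {
    source_format <- if (grepl("^\\s*<", joined)) "xml" else "markdown_fixture"
  }
  if (source_format == "xml") {
    read_document_xml(joined, doc_id)
  } else {
    lines <- strsplit(joined, "\n", fixed = TRUE)[[1]]
    read_document_markdown(lines, doc_id, source_format)
  }
}

#' Load a corpus from a directory manifest
#'
#' @param manifest_path CSV with columns `doc_id`, `path`, `source_format`;
#'   relative paths are resolved against the manifest's directory.
#' @return a list of `document_record`s.
#' @export
read_corpus_manifest <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_document(p, doc_id = man$doc_id[i],
                  source_format = man$source_format[i])
  })
}

#' Is a numeric value present verbatim in a document's text?
#'
#' Word-boundary semantics for numbers: the match may not be immediately
#' preceded or followed by a digit or decimal point, so `"4.2"` does not
#' match inside `"14.25"`. Thousands-separator commas are normalized on both
#' sides; trailing zeros are neither added nor removed.
#'
#' @param value_text the number exactly as extracted, as a string.
#' @param doc a `document_record` (or any list with `full_text`).
#' @return `TRUE` or `FALSE`.
#' @export
find_value_in_text <- function(value_text, doc) {
  strip <- function(x) gsub("(?<=\\d),(?=\\d)", "", x, perl = TRUE)
  needle <- strip(stringr::str_trim(value_text))
  if (!nzchar(needle)) return(FALSE)
  hay <- strip(doc$full_text)
  pat <- paste0("(?<![0-9.])", stringr::str_escape(needle), "(?![0-9.])")
  stringr::str_detect(hay, stringr::regex(pat))
}
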