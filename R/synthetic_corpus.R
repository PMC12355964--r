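# Synthetic corpus with known ground truth and controlled corruptions.
#
# Each document carries narrative filler plus one pipe-delimited kinetics
# table. Two channels exist per document: the rendered text (what regex
# verification searches) and the structured table (what the extractor
# reads). Printed-text corruptions (glyph_swap, rate_unit_swap,
# sci_notation) alter both channels consistently; extraction-channel
# corruptions (hallucinate_value, repeat_value) alter only the table,
# emulating a generative extractor whose output is not grounded in the
# text. The corruption log suffices to undo every corruption.

#' Synthetic corpus specification
#'
#' Defaults mirror the value ranges observed in large literature-derived
#' kinetics corpora: log10(kcat / s^-1) truncated to \[-5.8, 5.3\] and
#' log10(Km / M) truncated to \[-5.5, 4.5\], approximately Gaussian; assay
#' pH averaging 7.2 on 2-12 and temperatures averaging 25.9 on 0-100
#' degrees C.
#'
#' @param n_docs number of documents.
#' @param rows_per_doc integer range `c(min, max)` of table rows.
#' @param log10_kcat_dist,log10_km_dist lists `(mean, sd, min, max)` of the
#'   truncated normal log10 value distributions (kcat in s^-1, Km in M).
#' @param kcat_units,km_units named probability weights over unit dialects.
#' @param corruption_rates named rates in \[0,1\] for `glyph_swap`,
#'   `rate_unit_swap`, `sci_notation` (per row) and `hallucinate_value`,
#'   `repeat_value` (per document).
#' @param typo_rate per-document probability of a single-character typo in
#'   the printed enzyme and organism names (truth keeps the clean name),
#'   exercising the 90% similarity pathway.
#' @param units_in_cells_prob probability that a document embeds units in
#'   table cells rather than the header.
#' @param doc_metadata_prob probability that a document states enzyme and
#'   organism in the narrative instead of table columns.
#' @param mutation_prob per-row probability of a point-mutation descriptor.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return a list of class `corpus_spec`.
#' @export
corpus_spec <- function(
    n_docs = 10L,
    rows_per_doc = c(3L, 8L),
    log10_kcat_dist = list(mean = 0.8, sd = 1.5, min = -5.8, max = 5.3),
    log10_km_dist = list(mean = -4.2, sd = 1.2, min = -5.5, max = 4.5),
    kcat_units = c("s^-1" = 0.4, "s−1" = 0.2, "min^-1" = 0.3, "1/s" = 0.1),
    km_units = c("μM" = 0.3, "mM" = 0.3, "uM" = 0.1, "µM" = 0.1,
                 "mmol/L" = 0.1, "μmol/L" = 0.1),
    corruption_rates = c(glyph_swap = 0, rate_unit_swap = 0,
                         hallucinate_value = 0, repeat_value = 0,
                         sci_notation = 0),
    typo_rate = 0,
    units_in_cells_prob = 0.5,
    doc_metadata_prob = 0.3,
    mutation_prob = 0.3,
    seed = 1L) {
  all_rates <- c(glyph_swap = 0, rate_unit_swap = 0, hallucinate_value = 0,
                 repeat_value = 0, sci_notation = 0)
  all_rates[names(corruption_rates)] <- corruption_rates
  stopifnot(all(all_rates >= 0), all(all_rates <= 1),
            n_docs >= 1L, rows_per_doc[1] >= 1L,
            rows_per_doc[2] >= rows_per_doc[1],
            log10_kcat_dist$min < log10_kcat_dist$max,
            log10_km_dist$min < log10_km_dist$max)
  structure(list(
    n_docs = as.integer(n_docs), rows_per_doc = as.integer(rows_per_doc),
    log10_kcat_dist = log10_kcat_dist, log10_km_dist = log10_km_dist,
    kcat_units = kcat_units, km_units = km_units,
    corruption_rates = all_rates, typo_rate = typo_rate,
    units_in_cells_prob = units_in_cells_prob,
    doc_metadata_prob = doc_metadata_prob,
    mutation_prob = mutation_prob, seed = as.integer(seed)
  ), class = "corpus_spec")
}

rtrunc_norm <- function(n, dist) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, dist$mean, dist$sd)
      if (x >= dist$min && x <= dist$max) break
    }
    out[i] <- x
  }
  out
}

format_plain <- function(x) {
  format(signif(x, 4), scientific = FALSE, trim = TRUE)
}

sample_weighted <- function(weights) {
  names(weights)[sample.int(length(weights), 1, prob = weights)]
}

# size-safe scalar sampling (sample() treats a length-1 vector as 1:n)
sample1 <- function(x) x[sample.int(length(x), 1L)]

inject_typo <- function(name) {
  chars <- strsplit(name, "")[[1]]
  i <- sample(seq_along(chars), 1)
  chars[i] <- sample(letters[letters != tolower(chars[i])], 1)
  paste(chars, collapse = "")
}

glyph_swap_unit <- function(unit) {
  swaps <- c("μM" = "mM", "µM" = "mM", "uM" = "mM",
             "mM" = "μM",
             "μmol/L" = "mmol/L", "mmol/L" = "μmol/L")
  out <- unname(swaps[unit])
  if (is.na(out)) unit else out
}

rate_swap_unit <- function(unit) {
  swaps <- c("s^-1" = "min^-1", "min^-1" = "s^-1",
             "s−1" = "min−1", "min−1" = "s−1",
             "1/s" = "1/min", "1/min" = "1/s")
  out <- unname(swaps[unit])
  if (is.na(out)) unit else out
}

to_sci_string <- function(value_str) {
  v <- as.numeric(value_str)
  k <- floor(log10(abs(v)))
  mant <- signif(v / 10^k, 3)
  sprintf("%s × 10^%d", format(mant, scientific = FALSE, trim = TRUE), k)
}

table_cell <- function(value_str, unit, in_cells) {
  if (in_cells) paste(value_str, unit) else value_str
}

# build one clean document's row data (no corruption)
build_doc_content <- function(d, spec) {
  doc_id <- sprintf("SYN-%04d", d)
  n_rows <- sample1(seq(spec$rows_per_doc[1], spec$rows_per_doc[2]))
  enzyme <- sample(synthetic_enzymes, 1)
  organism <- sample(synthetic_organisms, 1)
  substrates <- sample(synthetic_substrates, n_rows)
  mutation <- ifelse(
    runif(n_rows) < spec$mutation_prob,
    paste0(sample(LETTERS[1:20], n_rows, TRUE),
           sample(20:400, n_rows, TRUE),
           sample(LETTERS[1:20], n_rows, TRUE)),
    ""
  )
  kcat_unit <- sample_weighted(spec$kcat_units)
  km_unit <- sample_weighted(spec$km_units)
  log_kcat <- rtrunc_norm(n_rows, spec$log10_kcat_dist)
  log_km <- rtrunc_norm(n_rows, spec$log10_km_dist)
  kcat_factor <- canonical_or_na(
    structure(list(value = 1, prefix = parse_unit_token(kcat_unit)$prefix,
                   base_unit = parse_unit_token(kcat_unit)$base_unit),
              class = "quantity"), "rate")
  km_factor <- canonical_or_na(
    structure(list(value = 1, prefix = parse_unit_token(km_unit)$prefix,
                   base_unit = parse_unit_token(km_unit)$base_unit),
              class = "quantity"), "concentration")
  kcat_printed <- format_plain(10^log_kcat / kcat_factor)
  km_printed <- format_plain(10^log_km / km_factor)
  ph <- format_plain(round(pmin(pmax(rnorm(n_rows, 7.2, 1.2), 2), 12), 1))
  temp <- format_plain(round(pmin(pmax(rnorm(n_rows, 25.9, 8), 0), 100), 1))
  printed_enzyme <- enzyme
  printed_organism <- organism
  if (runif(1) < spec$typo_rate) printed_enzyme <- inject_typo(enzyme)
  if (runif(1) < spec$typo_rate) printed_organism <- inject_typo(organism)
  list(
    doc_id = doc_id, n_rows = n_rows,
    enzyme = enzyme, organism = organism,
    printed_enzyme = printed_enzyme, printed_organism = printed_organism,
    substrates = substrates, mutation = mutation,
    kcat_unit = kcat_unit, km_unit = km_unit,
    kcat_printed = kcat_printed, km_printed = km_printed,
    ph = ph, temp = temp,
    units_in_cells = runif(1) < spec$units_in_cells_prob,
    doc_metadata = runif(1) < spec$doc_metadata_prob,
    filler = sample(synthetic_filler_sentences, 2)
  )
}

render_doc_from_content <- function(ct, table_rows_override = NULL) {
  in_cells <- ct$units_in_cells
  kcat_hdr <- if (in_cells) "kcat" else sprintf("kcat (%s)", ct$kcat_unit)
  km_hdr <- if (in_cells) "Km" else sprintf("Km (%s)", ct$km_unit)
  header <- c("Substrate", "Mutation", kcat_hdr, km_hdr, "pH",
              "Temperature (°C)")
  if (!ct$doc_metadata) header <- c("Enzyme", "Organism", header)
  rows <- lapply(seq_len(ct$n_rows), function(r) {
    cells <- c(ct$substrates[r], ct$mutation[r],
               table_cell(ct$kcat_printed[r], ct$kcat_unit, in_cells),
               table_cell(ct$km_printed[r], ct$km_unit, in_cells),
               ct$ph[r], ct$temp[r])
    if (!ct$doc_metadata) {
      cells <- c(ct$printed_enzyme, ct$printed_organism, cells)
    }
    cells
  })
  if (!is.null(table_rows_override)) rows <- table_rows_override
  tbl <- markdown_table("T1", header, rows)
  pre <- c(
    sprintf("Kinetic characterization of %s from %s.",
            ct$printed_enzyme, ct$printed_organism),
    if (ct$doc_metadata) c(sprintf("Enzyme: %s", ct$printed_enzyme),
                           sprintf("Organism: %s", ct$printed_organism)),
    ct$filler[1]
  )
  post <- ct$filler[2]
  render_document(document_record(
    doc_id = ct$doc_id, source_format = "markdown_fixture", full_text = "",
    tables = list(tbl), narrative_pre = pre, narrative_post = post
  ))
}

truth_from_content <- function(ct) {
  rows <- lapply(seq_len(ct$n_rows), function(r) {
    kq <- parse_quantity(paste(ct$kcat_printed[r], ct$kcat_unit), "rate")
    mq <- parse_quantity(paste(ct$km_printed[r], ct$km_unit), "concentration")
    kinetic_measurement(
      enzyme_name = ct$enzyme, organism = ct$organism,
      mutation = ct$mutation[r], substrate_name = ct$substrates[r],
      kcat_value = kq$value, kcat_unit = ct$kcat_unit,
      kcat_canonical = kq$canonical_value, kcat_printed = ct$kcat_printed[r],
      km_value = mq$value, km_unit = ct$km_unit,
      km_canonical = mq$canonical_value, km_printed = ct$km_printed[r],
      ph = as.numeric(ct$ph[r]), temperature_C = as.numeric(ct$temp[r]),
      doc_id = ct$doc_id, source_format = "markdown_fixture",
      table_id = "T1", row_index = r - 1L
    )
  })
  dplyr::bind_rows(rows)
}

empty_corruption_log <- function() {
  tibble::tibble(
    doc_id = character(), row_index = integer(), kind = character(),
    field = character(), channel = character(),
    original_value = character(), corrupted_value = character(),
    original_unit = character(), corrupted_unit = character()
  )
}

# locate the cell column for a field in the rendered table
field_column <- function(ct, field) {
  base <- switch(field, kcat = 3L, km = 4L)
  if (ct$doc_metadata) base else base + 2L
}

#' Generate a synthetic corpus with ground truth and a corruption log
#'
#' @param spec a [corpus_spec()].
#' @return a list of class `synthetic_corpus` with elements `docs` (list of
#'   `document_record`s), `truth` (measurement tibble of clean canonical
#'   values), `log` (corruption log tibble) and the `spec`.
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  contents <- with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_docs), build_doc_content, spec = spec)
  })
  # corruption decisions come from a separate RNG stream so the underlying
  # content is identical across corruption settings
  corr <- with_local_seed(spec$seed + 777L, {
    lapply(contents, function(ct) {
      n <- ct$n_rows
      rates <- spec$corruption_rates
      list(
        glyph_swap = runif(n) < rates[["glyph_swap"]],
        rate_unit_swap = runif(n) < rates[["rate_unit_swap"]],
        sci_notation = runif(n) < rates[["sci_notation"]],
        hallucinate = runif(1) < rates[["hallucinate_value"]],
        repeat_value = runif(1) < rates[["repeat_value"]],
        hallu_mult = runif(n, 1.7, 8.3)
      )
    })
  })
  docs <- vector("list", spec$n_docs)
  truths <- vector("list", spec$n_docs)
  logs <- list()
  for (d in seq_len(spec$n_docs)) {
    ct <- contents[[d]]
    cr <- corr[[d]]
    truths[[d]] <- truth_from_content(ct)

    # ---- text-channel corruptions (document and table both change) ----
    ct_txt <- ct
    for (r in seq_len(ct$n_rows)) {
      if (cr$sci_notation[r]) {
        new_val <- to_sci_string(ct$kcat_printed[r])
        logs[[length(logs) + 1L]] <- tibble::tibble(
          doc_id = ct$doc_id, row_index = r - 1L, kind = "sci_notation",
          field = "kcat", channel = "text",
          original_value = table_cell(ct$kcat_printed[r], ct$kcat_unit,
                                      ct$units_in_cells),
          corrupted_value = table_cell(new_val, ct$kcat_unit,
                                       ct$units_in_cells),
          original_unit = ct$kcat_unit, corrupted_unit = ct$kcat_unit
        )
        ct_txt$kcat_printed[r] <- new_val
      }
    }
    swap_rows_kcat <- which(cr$rate_unit_swap)
    swap_rows_km <- which(cr$glyph_swap)
    docs[[d]] <- render_doc_from_content(ct_txt)
    # per-row unit swaps override the cell (units become cell-embedded for
    # the affected row even in header-unit documents)
    tbl <- docs[[d]]$tables[[1]]
    for (r in swap_rows_kcat) {
      bad_unit <- rate_swap_unit(ct$kcat_unit)
      col <- field_column(ct, "kcat")
      old_cell <- tbl$rows[[r]][col]
      tbl$rows[[r]][col] <- paste(ct_txt$kcat_printed[r], bad_unit)
      logs[[length(logs) + 1L]] <- tibble::tibble(
        doc_id = ct$doc_id, row_index = r - 1L, kind = "rate_unit_swap",
        field = "kcat", channel = "text",
        original_value = old_cell, corrupted_value = tbl$rows[[r]][col],
        original_unit = ct$kcat_unit, corrupted_unit = bad_unit
      )
    }
    for (r in swap_rows_km) {
      bad_unit <- glyph_swap_unit(ct$km_unit)
      col <- field_column(ct, "km")
      old_cell <- tbl$rows[[r]][col]
      tbl$rows[[r]][col] <- paste(ct_txt$km_printed[r], bad_unit)
      logs[[length(logs) + 1L]] <- tibble::tibble(
        doc_id = ct$doc_id, row_index = r - 1L, kind = "glyph_swap",
        field = "km", channel = "text",
        original_value = old_cell, corrupted_value = tbl$rows[[r]][col],
        original_unit = ct$km_unit, corrupted_unit = bad_unit
      )
    }
    docs[[d]]$tables[[1]] <- tbl
    docs[[d]] <- render_document(docs[[d]])

    # ---- extraction-channel corruptions (table only; text unchanged) ----
    tbl <- docs[[d]]$tables[[1]]
    if (cr$hallucinate) {
      for (r in seq_len(ct$n_rows)) {
        for (field in c("kcat", "km")) {
          col <- field_column(ct, field)
          old_cell <- tbl$rows[[r]][col]
          unit <- if (field == "kcat") ct$kcat_unit else ct$km_unit
          v <- as.numeric(ct[[paste0(field, "_printed")]][r])
          new_val <- format_plain(v * cr$hallu_mult[r])
          attempts <- 0L
          while (find_value_in_text(new_val, docs[[d]]) && attempts < 20L) {
            attempts <- attempts + 1L
            new_val <- format_plain(v * cr$hallu_mult[r] * (1 + attempts / 10))
          }
          tbl$rows[[r]][col] <- table_cell(new_val, unit, ct$units_in_cells)
          logs[[length(logs) + 1L]] <- tibble::tibble(
            doc_id = ct$doc_id, row_index = r - 1L, kind = "hallucinate_value",
            field = field, channel = "extraction",
            original_value = old_cell, corrupted_value = tbl$rows[[r]][col],
            original_unit = unit, corrupted_unit = unit
          )
        }
      }
    }
    if (cr$repeat_value) {
      rep_val <- ct_txt$kcat_printed[1]
      for (r in seq_len(ct$n_rows)) {
        for (field in c("kcat", "km")) {
          col <- field_column(ct, field)
          old_cell <- tbl$rows[[r]][col]
          unit <- if (field == "kcat") ct$kcat_unit else ct$km_unit
          new_cell <- table_cell(rep_val, unit, ct$units_in_cells)
          if (identical(old_cell, new_cell)) next
          tbl$rows[[r]][col] <- new_cell
          logs[[length(logs) + 1L]] <- tibble::tibble(
            doc_id = ct$doc_id, row_index = r - 1L, kind = "repeat_value",
            field = field, channel = "extraction",
            original_value = old_cell, corrupted_value = new_cell,
            original_unit = unit, corrupted_unit = unit
          )
        }
      }
    }
    docs[[d]]$tables[[1]] <- tbl
  }
  structure(list(
    docs = docs,
    truth = dplyr::bind_rows(truths),
    log = if (length(logs)) dplyr::bind_rows(logs) else empty_corruption_log(),
    spec = spec
  ), class = "synthetic_corpus")
}

#' Undo every corruption recorded in a corpus's log
#'
#' Restores the logged table cells (in reverse application order) and
#' re-renders each document's text, returning a corpus whose documents are
#' byte-identical to a generation of the same spec with all corruption
#' rates zero.
#'
#' @param corpus a `synthetic_corpus`.
#' @return the corpus with clean documents and an empty log.
#' @export
revert_corruptions <- function(corpus) {
  docs <- corpus$docs
  by_id <- stats::setNames(seq_along(docs),
                           vapply(docs, function(d) d$doc_id, character(1)))
  lg <- corpus$log
  for (i in rev(seq_len(nrow(lg)))) {
    d <- by_id[[lg$doc_id[i]]]
    tbl <- docs[[d]]$tables[[1]]
    r <- lg$row_index[i] + 1L
    row <- tbl$rows[[r]]
    roles <- resolve_column_roles(tbl$header)$roles
    col <- which(roles == lg$field[i])[1]
    if (is.na(col) || !identical(row[col], lg$corrupted_value[i])) next
    row[col] <- lg$original_value[i]
    tbl$rows[[r]] <- row
    docs[[d]]$tables[[1]] <- tbl
  }
  docs <- lapply(docs, render_document)
  corpus$docs <- docs
  corpus$log <- empty_corruption_log()
  corpus
}

#' Emit the corpus ground truth in the benchmark CSV schema
#'
#' One row per (entry, parameter): columns `enzyme`, `mutation`,
#' `substrate`, `organism`, `smiles`, `value`, `unit`, `parameter`.
#'
#' @param corpus a `synthetic_corpus`.
#' @param path optional CSV output path.
#' @return the ground-truth tibble (written to `path` when given).
#' @export
emit_ground_truth <- function(corpus, path = NULL) {
  tr <- corpus$truth
  out <- list()
  for (param in c("kcat", "km")) {
    val <- tr[[paste0(param, "_printed")]]
    unit <- tr[[paste0(param, "_unit")]]
    keep <- nzchar(val)
    if (!any(keep)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      enzyme = tr$enzyme_name[keep], mutation = tr$mutation[keep],
      substrate = tr$substrate_name[keep], organism = tr$organism[keep],
      smiles = tr$substrate_smiles[keep], value = val[keep],
      unit = unit[keep], parameter = param,
      doc_id = tr$doc_id[keep], row_index = tr$row_index[keep]
    )
  }
  gt <- dplyr::bind_rows(out)
  gt <- dplyr::arrange(gt, .data$doc_id, .data$row_index, .data$parameter)
  if (!is.null(path)) readr::write_csv(gt, path)
  gt
}

#' Write a corpus to disk as Markdown documents plus CSV sidecars
#'
#' Produces a directory of `.md` documents, a `manifest.csv`
#' (doc_id, path, source_format), `truth.csv` (benchmark schema) and
#' `corruption_log.csv`.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list()
  for (doc in corpus$docs) {
    fname <- paste0(doc$doc_id, ".md")
    writeLines(doc$full_text, file.path(dir, fname), useBytes = TRUE)
    man[[length(man) + 1L]] <- tibble::tibble(
      doc_id = doc$doc_id, path = fname, source_format = doc$source_format
    )
  }
  readr::write_csv(dplyr::bind_rows(man), file.path(dir, "manifest.csv"))
  emit_ground_truth(corpus, file.path(dir, "truth.csv"))
  readr::write_csv(corpus$log, file.path(dir, "corruption_log.csv"))
  invisible(dir)
}

#' Extract every document of a corpus with the reference backend
#'
#' @param corpus a `synthetic_corpus`.
#' @param lexicon see [reference_extract()].
#' @return a measurement tibble (canonicalized).
#' @export
extract_corpus <- function(corpus, lexicon = default_lexicon()) {
  raw <- dplyr::bind_rows(lapply(corpus$docs, reference_extract,
                                 lexicon = lexicon))
  canonicalize_extractions(raw)
}
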