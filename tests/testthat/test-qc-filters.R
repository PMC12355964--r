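mk_doc <- function(doc_id, values) {
  lines <- c("Measured rates:",
             "| Substrate | kcat (s^-1) |",
             "| --- | --- |",
             paste0("| s", seq_along(values), " | ", values, " |"))
  read_document(text = lines, doc_id = doc_id)
}

mk_rows <- function(doc_id, printed, source_format = "markdown_fixture") {
  dplyr::bind_rows(lapply(seq_along(printed), function(i) {
    kinetic_measurement(
      enzyme_name = "enz", substrate_name = paste0("s", i),
      kcat_value = as.numeric(printed[i]), kcat_unit = "s^-1",
      kcat_canonical = as.numeric(printed[i]), kcat_printed = printed[i],
      doc_id = doc_id, source_format = source_format, table_id = "T1",
      row_index = i - 1L
    )
  }))
}

test_that("hallucination flagging uses a strict found-fraction threshold", {
  vals <- as.character(1:10 + 0.5)
  doc <- mk_doc("H1", vals)

  all_found <- mk_rows("H1", vals)
  expect_false(flag_hallucination(doc, all_found)$flagged)

  none_found <- mk_rows("H1", as.character(100:109 + 0.77))
  res <- flag_hallucination(doc, none_found)
  expect_true(res$flagged)
  expect_equal(res$found_fraction, 0)

  # 4 of 10 found -> flagged; 5 of 10 -> not (strict <)
  four <- mk_rows("H1", c(vals[1:4], as.character(900:905 + 0.33)))
  expect_true(flag_hallucination(doc, four)$flagged)
  five <- mk_rows("H1", c(vals[1:5], as.character(900:904 + 0.33)))
  expect_false(flag_hallucination(doc, five)$flagged)
})

test_that("repetition flagging uses a strict unique-fraction threshold", {
  expect_true(flag_repetition(mk_rows("R1", rep("3.2", 10)))$flagged)
  expect_false(flag_repetition(mk_rows("R1", as.character(1:10)))$flagged)
  # 3 distinct among 10 at threshold 0.3 -> not flagged (strict <)
  expect_false(flag_repetition(
    mk_rows("R1", c(rep("1.1", 4), rep("2.2", 3), rep("3.3", 3))))$flagged)
  expect_false(flag_repetition(mk_rows("R1", character(0)))$flagged)
})

test_that("curation removes duplicates, format dupes and empty rows", {
  rows <- mk_rows("D1", c("1.5", "2.5"))
  dup <- dplyr::bind_rows(rows, rows[1, ])
  pdf <- mk_rows("D1", c("1.5", "2.5"), source_format = "pdf_text")
  empty <- kinetic_measurement(doc_id = "D1", ph = 7)
  empty$flag_empty_row <- FALSE
  all_rows <- dplyr::bind_rows(dup, pdf, empty)
  res <- curate(all_rows, docs = list(mk_doc("D1", c("1.5", "2.5"))))
  expect_equal(res$report$n_input, 6L)
  expect_equal(res$report$n_duplicates, 1L)
  expect_equal(res$report$n_format_dupes, 2L)  # pdf rows yield to the text form
  expect_equal(res$report$n_empty, 1L)
})

test_that("pdf rows are dropped when the same doc exists as xml", {
  md <- mk_rows("X1", c("1.5", "2.5"), source_format = "xml")
  pdf <- mk_rows("X1", c("1.5", "2.5"), source_format = "pdf_text")
  res <- curate(dplyr::bind_rows(md, pdf), docs = NULL)
  expect_equal(res$report$n_format_dupes, 2L)
  expect_true(all(res$entries$source_format == "xml"))
})

test_that("curation ledger conserves rows and is idempotent", {
  sp <- corpus_spec(n_docs = 20, rows_per_doc = c(4, 8),
                    corruption_rates = c(hallucinate_value = 0.3,
                                         sci_notation = 0.15,
                                         repeat_value = 0.2),
                    seed = 91)
  co <- generate_corpus(sp)
  pred <- extract_corpus(co)
  res <- curate(pred, co$docs)
  r <- res$report
  expect_equal(r$n_input,
               r$n_kept + r$n_duplicates + r$n_format_dupes + r$n_empty +
                 r$n_excluded_flagged)
  # second pass removes nothing
  res2 <- curate(res$entries, co$docs)
  expect_equal(res2$report$n_kept, nrow(res$entries))
  expect_equal(nrow(res2$entries), nrow(res$entries))
  expect_equal(res2$report$n_excluded_flagged, 0L)
})

test_that("flags may overlap and are tallied independently", {
  # one document: repeated value printed once in the text, so rows are
  # repetitive but found; plus a sci-notation row
  doc <- mk_doc("O1", c("7.77", "8.88"))
  rows <- mk_rows("O1", rep("7.77", 6))
  rows$kcat_sci_notation[1] <- TRUE
  res <- curate(rows, docs = list(doc), qc_config(exclude_flagged = FALSE))
  expect_equal(res$report$n_repetitive_rows, 6L)
  expect_equal(res$report$n_sci_notation_rows, 1L)
  expect_true(res$entries$flag_repetitive[1] &&
                res$entries$flag_scientific_notation[1])
  expect_equal(res$report$n_kept, 6L)
})

test_that("qc report serializes to JSON", {
  rows <- mk_rows("J1", c("1.5", "2.5"))
  res <- curate(rows, docs = list(mk_doc("J1", c("1.5", "2.5"))))
  path <- withr::local_tempfile(fileext = ".json")
  write_qc_report(res$report, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$n_kept, 2L)
})
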