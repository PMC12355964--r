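test_that("generation is deterministic and respects the truncation bounds", {
  sp <- corpus_spec(n_docs = 6, seed = 21)
  a <- generate_corpus(sp)
  b <- generate_corpus(sp)
  expect_identical(a$docs, b$docs)
  expect_identical(a$truth, b$truth)
  lk <- log10(a$truth$kcat_canonical)
  lm <- log10(a$truth$km_canonical)
  # printed values are rounded to 4 significant digits, so allow the
  # rounding slack at the borders
  expect_true(all(lk >= -5.81 & lk <= 5.31))
  expect_true(all(lm >= -5.51 & lm <= 4.51))
})

test_that("a clean corpus round-trips through extraction exactly", {
  sp <- corpus_spec(n_docs = 8, seed = 5)
  co <- generate_corpus(sp)
  pred <- extract_corpus(co)
  expect_equal(nrow(pred), nrow(co$truth))
  ord <- order(pred$doc_id, pred$row_index)
  tord <- order(co$truth$doc_id, co$truth$row_index)
  for (col in c("enzyme_name", "organism", "mutation", "substrate_name",
                "kcat_canonical", "km_canonical", "ph", "temperature_C")) {
    expect_equal(pred[[col]][ord], co$truth[[col]][tord], info = col)
  }
  # reflexivity: every uncorrupted value is findable in its own document
  by_id <- setNames(co$docs, vapply(co$docs, `[[`, "", "doc_id"))
  found <- mapply(function(v, id) find_value_in_text(v, by_id[[id]]),
                  c(co$truth$kcat_printed, co$truth$km_printed),
                  c(co$truth$doc_id, co$truth$doc_id))
  expect_true(all(found))
})

test_that("ground-truth emission counts one row per entry and parameter", {
  sp <- corpus_spec(n_docs = 1, rows_per_doc = c(3, 3), seed = 8)
  co <- generate_corpus(sp)
  gt <- emit_ground_truth(co)
  expect_equal(nrow(gt), 6L)
  expect_equal(sum(gt$parameter == "kcat"), 3L)
  # round trip through the CSV reader
  path <- withr::local_tempfile(fileext = ".csv")
  emit_ground_truth(co, path)
  back <- read_ground_truth(path)
  expect_equal(nrow(back), 6L)
  km <- back[back$parameter == "km", ]
  expect_equal(sort(km$value_canonical),
               sort(co$truth$km_canonical))
})

test_that("glyph swaps shift every Km by exactly 1000x", {
  sp <- corpus_spec(n_docs = 6, corruption_rates = c(glyph_swap = 1),
                    seed = 13)
  co <- generate_corpus(sp)
  pred <- extract_corpus(co)
  ord <- order(pred$doc_id, pred$row_index)
  tord <- order(co$truth$doc_id, co$truth$row_index)
  ratio <- pred$km_canonical[ord] / co$truth$km_canonical[tord]
  expect_true(all(abs(abs(log10(ratio)) - 3) < 1e-9))
  # kcat untouched
  expect_equal(pred$kcat_canonical[ord], co$truth$kcat_canonical[tord])
})

test_that("rate-unit swaps shift kcat by exactly a factor of 60", {
  sp <- corpus_spec(n_docs = 6, corruption_rates = c(rate_unit_swap = 1),
                    seed = 14)
  co <- generate_corpus(sp)
  pred <- extract_corpus(co)
  ord <- order(pred$doc_id, pred$row_index)
  tord <- order(co$truth$doc_id, co$truth$row_index)
  ratio <- pred$kcat_canonical[ord] / co$truth$kcat_canonical[tord]
  expect_true(all(abs(abs(log10(ratio)) - log10(60)) < 1e-9))
})

test_that("hallucinated corpora disagree with their text, repeated ones repeat", {
  sp <- corpus_spec(n_docs = 4, corruption_rates = c(hallucinate_value = 1),
                    seed = 15)
  co <- generate_corpus(sp)
  pred <- extract_corpus(co)
  by_id <- setNames(co$docs, vapply(co$docs, `[[`, "", "doc_id"))
  found <- mapply(function(v, id) find_value_in_text(v, by_id[[id]]),
                  pred$kcat_printed, pred$doc_id)
  expect_false(any(found))

  sp2 <- corpus_spec(n_docs = 4, corruption_rates = c(repeat_value = 1),
                     seed = 16)
  co2 <- generate_corpus(sp2)
  pred2 <- extract_corpus(co2)
  per_doc <- split(c(pred2$kcat_printed, pred2$km_printed),
                   c(pred2$doc_id, pred2$doc_id))
  expect_true(all(vapply(per_doc, function(v) length(unique(v)) == 1L,
                         logical(1))))
})

test_that("corruption counts follow the configured binomial rates", {
  sp <- corpus_spec(n_docs = 170, rows_per_doc = c(5, 7),
                    corruption_rates = c(sci_notation = 0.1,
                                         glyph_swap = 0.2),
                    seed = 17)
  co <- generate_corpus(sp)
  n <- nrow(co$truth)
  expect_gte(n, 1000L)
  for (kind in c("sci_notation", "glyph_swap")) {
    p <- sp$corruption_rates[[kind]]
    got <- sum(co$log$kind == kind)
    expect_lt(abs(got - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9,
              label = kind)
  }
})

test_that("the corruption log undoes every corruption", {
  sp <- corpus_spec(n_docs = 8,
                    corruption_rates = c(glyph_swap = 0.4,
                                         rate_unit_swap = 0.4,
                                         sci_notation = 0.3,
                                         hallucinate_value = 0.5,
                                         repeat_value = 0.4),
                    seed = 18)
  co <- generate_corpus(sp)
  expect_gt(nrow(co$log), 0L)
  clean <- revert_corruptions(co)
  sp0 <- sp; sp0$corruption_rates[] <- 0
  co0 <- generate_corpus(sp0)
  expect_identical(clean$docs, co0$docs)
})

test_that("a corpus writes to disk and reloads through the manifest", {
  dir <- withr::local_tempdir()
  sp <- corpus_spec(n_docs = 3, seed = 19)
  co <- generate_corpus(sp)
  write_corpus(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  docs <- read_corpus_manifest(file.path(dir, "manifest.csv"))
  expect_length(docs, 3L)
  pred <- canonicalize_extractions(
    dplyr::bind_rows(lapply(docs, reference_extract)))
  gt <- read_ground_truth(file.path(dir, "truth.csv"))
  rep_ <- benchmark_extractions(pred, gt)
  expect_equal(rep_$accuracy, 1)
})

test_that("typo injection keeps entries matchable at the 90% threshold", {
  sp <- corpus_spec(n_docs = 10, typo_rate = 1, seed = 20)
  co <- generate_corpus(sp)
  pred <- extract_corpus(co)
  gt <- emit_ground_truth(co)
  path <- withr::local_tempfile(fileext = ".csv")
  emit_ground_truth(co, path)
  rep_ <- benchmark_extractions(pred, read_ground_truth(path))
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$unresolved, 0L)
})
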