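test_that("name similarity matches the DP edit-distance oracle", {
  expect_equal(name_similarity("glucose", "glucose"), 1)
  expect_equal(name_similarity(normalize_key_field("Glucose "),
                               normalize_key_field("glucose")), 1)
  expect_equal(name_similarity("lactase", "lactate"), 6 / 7)
  expect_equal(name_similarity("", ""), 1)
  set.seed(42)
  pool <- c("hexokinase", "hexokinse", "beta-galactosidase", "lysozyme",
            "lysozymes", "urease", "ureases b", "pyruvate kinase")
  for (i in 1:25) {
    a <- sample(pool, 1); b <- sample(pool, 1)
    d <- dp_edit_distance(a, b)
    expect_equal(name_similarity(a, b), 1 - d / max(nchar(a), nchar(b)))
    expect_equal(name_similarity(a, b), name_similarity(b, a))
  }
})

test_that("crossed similarities resolve to the max-sum assignment", {
  pred <- make_entries(c("hexokinase a", "hexokinase ab"), "glucose",
                       kcat = c(1, 2))
  truth <- make_truth(c("hexokinase ab", "hexokinase aa"), "glucose",
                      values = c(2, 1))
  al <- align_entries(pred, truth)
  # p1 is closer to t2, p2 to t1; total similarity maximized crosswise
  total <- sum(al$pairs$score)
  pk <- entry_key(pred); tk <- entry_key(truth)
  score <- outer(seq_len(2), seq_len(2), Vectorize(function(i, j) {
    s <- (name_similarity(pk$enzyme_name_norm[i], tk$enzyme_name_norm[j]) +
            1) / 2
    if (s >= 0.9) s else NA_real_
  }))
  expect_equal(total, brute_force_assignment(score), tolerance = 1e-12)
})

test_that("below-threshold similarity leaves entries unmatched", {
  pred <- make_entries("aaaaaaaaaa", "glucose", kcat = 1)
  truth <- make_truth("aabbaaaaaa", "glucose", values = 1)  # sim 0.8
  al <- align_entries(pred, truth)
  expect_equal(nrow(al$pairs), 0L)
  expect_equal(al$unmatched_pred, 1L)
  expect_equal(al$unmatched_truth, 1L)
})

test_that("mutation strings and substrates gate admissibility", {
  pred <- make_entries("hexokinase", "glucose", kcat = 1, mutations = "A123G")
  truth <- make_truth("hexokinase", "glucose", values = 1, mutations = "")
  expect_equal(nrow(align_entries(pred, truth)$pairs), 0L)

  # SMILES identity substitutes for an exact substrate name match
  pred2 <- make_entries("hexokinase", "alpha-D-glucose", kcat = 1)
  pred2$substrate_smiles <- "OC1OC(CO)C(O)C(O)C1O"
  truth2 <- make_truth("hexokinase", "glucose", values = 1)
  truth2$substrate_smiles <- "OC1OC(CO)C(O)C(O)C1O"
  expect_equal(nrow(align_entries(pred2, truth2)$pairs), 1L)
})

test_that("assignment optimality equals brute force on random instances", {
  set.seed(2024)
  for (trial in 1:60) {
    np <- sample(2:6, 1); nt <- sample(2:6, 1)
    score <- matrix(NA_real_, np, nt)
    adm <- matrix(runif(np * nt) < 0.5, np, nt)
    score[adm] <- runif(sum(adm), 0.9, 1)
    edges <- which(adm, arr.ind = TRUE)
    if (!nrow(edges)) next
    etab <- tibble::tibble(pred_idx = edges[, 1], truth_idx = edges[, 2],
                           score = score[adm])
    got <- sum(enzkinex:::lsa_assign(etab)$score)
    expect_equal(got, brute_force_assignment(score), tolerance = 1e-9,
                 info = paste("trial", trial))
  }
})

test_that("classification separates TP, FN, FP and the off-by tallies", {
  pred <- make_entries(rep("hexokinase", 4),
                       c("glucose", "maltose", "fructose", "xylose"),
                       kcat = c(1.0, NA, 300, 5.2))
  truth <- make_truth(rep("hexokinase", 4),
                      c("glucose", "maltose", "fructose", "xylose"),
                      values = c(1.0, 2.0, 0.3, 5.0))
  rep_ <- benchmark_extractions(pred, truth)
  expect_equal(rep_$TP, 1L)       # glucose exact
  expect_equal(rep_$FN, 1L)       # maltose value missing
  expect_equal(rep_$FP, 2L)       # fructose off 1000x, xylose off 4%
  expect_equal(rep_$off_by_1000, 1L)
  expect_equal(rep_$off_by_10, 0L)
  expect_equal(rep_$unresolved, 0L)
})

test_that("value tolerance absorbs printed rounding at 1%", {
  pred <- make_entries("hexokinase", "glucose", kcat = 1.009)
  truth <- make_truth("hexokinase", "glucose", values = 1.0)
  expect_equal(benchmark_extractions(pred, truth)$TP, 1L)
  pred2 <- make_entries("hexokinase", "glucose", kcat = 1.02)
  expect_equal(benchmark_extractions(pred2, truth)$TP, 0L)
})

test_that("off-by factors are detected in both directions", {
  for (ratio in c(10, 0.1, 100, 0.01, 1000, 0.001)) {
    pred <- make_entries("hexokinase", "glucose", kcat = 2 * ratio)
    truth <- make_truth("hexokinase", "glucose", values = 2)
    rep_ <- benchmark_extractions(pred, truth)
    k <- round(abs(log10(ratio)))
    expect_equal(rep_[[paste0("off_by_", 10^k)]], 1L, info = ratio)
  }
})

test_that("unmatched truth is unresolved, unmatched pred is FP", {
  pred <- make_entries(c("hexokinase", "zzzzzzzz"), c("glucose", "qqq"),
                       kcat = c(1, 9))
  truth <- make_truth(c("hexokinase", "aldolase"), c("glucose", "f16bp"),
                      values = c(1, 4))
  rep_ <- benchmark_extractions(pred, truth)
  expect_equal(rep_$TP, 1L)
  expect_equal(rep_$FP, 1L)         # the stray prediction
  expect_equal(rep_$unresolved, 1L) # the unmatched truth entry
})

test_that("metrics reproduce the defining formulas and guard degeneracy", {
  m <- metrics(301, 59, 17)
  expect_equal(m$accuracy, 301 / 377)
  expect_equal(m$precision, 301 / 360)
  expect_equal(metrics(0, 0, 0), list(accuracy = 0, precision = 0))
  expect_equal(metrics(10, 0, 0), list(accuracy = 1, precision = 1))
  expect_error(metrics(-1, 0, 0))
})

test_that("accuracy never exceeds precision on random counts", {
  set.seed(7)
  for (i in 1:200) {
    tp <- sample(0:500, 1); fp <- sample(0:500, 1); fn <- sample(0:500, 1)
    m <- metrics(tp, fp, fn)
    expect_lte(m$accuracy, m$precision + 1e-15)
  }
})

test_that("self-benchmark of any entry list is perfect", {
  sp <- corpus_spec(n_docs = 6, seed = 3, typo_rate = 0.5,
                    mutation_prob = 0.5)
  co <- generate_corpus(sp)
  pred <- extract_corpus(co)
  truth <- tibble::tibble(
    enzyme_name = pred$enzyme_name, mutation = pred$mutation,
    substrate_name = pred$substrate_name, organism = pred$organism,
    substrate_smiles = pred$substrate_smiles,
    parameter = "kcat", value_canonical = pred$kcat_canonical
  )
  rep_ <- benchmark_extractions(pred, truth)
  expect_equal(rep_$FP, 0L)
  expect_equal(rep_$FN, 0L)
  expect_equal(rep_$unresolved, 0L)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$precision, 1)
})

test_that("classification conserves every truth entry and stray prediction", {
  set.seed(11)
  for (trial in 1:10) {
    sp <- corpus_spec(n_docs = 4, seed = trial,
                      corruption_rates = c(glyph_swap = 0.3,
                                           hallucinate_value = 0.3))
    co <- generate_corpus(sp)
    pred <- extract_corpus(co)
    gt <- emit_ground_truth(co)
    gt_km <- gt[gt$parameter == "km", ]
    truth <- tibble::tibble(
      enzyme_name = gt_km$enzyme, mutation = gt_km$mutation,
      substrate_name = gt_km$substrate, organism = gt_km$organism,
      substrate_smiles = gt_km$smiles, parameter = "km",
      value_canonical = mapply(function(v, u)
        parse_quantity(paste(v, u), "concentration")$canonical_value,
        gt_km$value, gt_km$unit)
    )
    al <- align_entries(pred, truth)
    rep_ <- classify(al, pred$km_canonical, truth$value_canonical)
    n_classified <- rep_$TP + rep_$FP + rep_$FN + rep_$unresolved
    # every truth row is a pair or unresolved; every stray pred an FP
    expect_equal(nrow(al$pairs) + length(al$unmatched_truth), nrow(truth))
    expect_equal(n_classified,
                 nrow(al$pairs) + length(al$unmatched_pred) +
                   length(al$unmatched_truth))
  }
})

test_that("ground-truth CSVs load with canonical values", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    enzyme = "hexokinase", mutation = NA, substrate = "glucose",
    organism = "yeast", smiles = NA, value = "120", unit = "min^-1",
    parameter = "kcat"
  ), path)
  gt <- read_ground_truth(path)
  expect_equal(gt$value_canonical, 2)
  expect_equal(gt$mutation, "")
  expect_error(read_ground_truth(withr::local_tempfile(fileext = ".csv")))
})
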