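seq_fixture <- function() {
  sequence_lookup(tibble::tibble(
    kind = c("uniprot", "ncbi", "pdb", "name", "name"),
    id = c("P00698", "NP_000001", "1AKI", "", ""),
    name = c("lysozyme c", "lysozyme c", "lysozyme c",
             "hexokinase", "hexokinase"),
    organism = c("gallus gallus", "gallus gallus", "gallus gallus",
                 "saccharomyces cerevisiae", "saccharomyces cerevisiae"),
    sequence = c("SEQ_UNIPROT", "SEQ_NCBI", "SEQ_PDB", "SEQ_HXK_TOP",
                 "SEQ_HXK_SECOND")
  ))
}

cmpd_fixture <- function() {
  compound_lookup(
    tibble::tibble(
      name = c("adenosine triphosphate", "adenosine triphosphate", "glucose"),
      rank = c(2L, 1L, 1L),
      smiles = c("ATP_SMILES_ALT", "ATP_SMILES_TOP", "GLC_SMILES")
    ),
    tibble::tibble(abbrev = "ATP", full_name = "adenosine triphosphate")
  )
}

test_that("confidence tiers follow the metadata-field count", {
  rows <- dplyr::bind_rows(
    kinetic_measurement(enzyme_name = "e", organism = "o", uniprot = "U1",
                        doc_id = "D"),
    kinetic_measurement(enzyme_name = "e", organism = "o", doc_id = "D"),
    kinetic_measurement(enzyme_name = "e", doc_id = "D"),
    kinetic_measurement(substrate_name = "s", doc_id = "D"),
    kinetic_measurement(enzyme_name = "e", organism = "o", uniprot = "U",
                        ncbi = "N", pdb = "P", doc_id = "D")
  )
  expect_equal(score_confidence(rows),
               c("high", "medium", "low", "unmapped", "high"))
})

test_that("tier assignment is monotone in field count", {
  fields <- c("enzyme_name", "organism", "uniprot", "ncbi", "pdb")
  rank <- c(unmapped = 0, low = 1, medium = 2, high = 3)
  last <- -1
  for (k in 0:5) {
    m <- kinetic_measurement(doc_id = "D")
    for (f in utils::head(fields, k)) m[[f]] <- "x"
    tier <- score_confidence(m)
    expect_gte(rank[[tier]], last)
    last <- rank[[tier]]
  }
})

test_that("sequence resolution honors identifier precedence over all presence patterns", {
  lk <- seq_fixture()
  # brute-force oracle over all 2^5 presence patterns of the five fields
  fields <- c("uniprot", "ncbi", "pdb", "name_org")
  for (mask in 0:15) {
    has <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0)
    m <- kinetic_measurement(doc_id = "D")
    if (has[1]) m$uniprot <- "P00698"
    if (has[2]) m$ncbi <- "NP_000001"
    if (has[3]) m$pdb <- "1AKI"
    if (has[4]) { m$enzyme_name <- "Lysozyme C"; m$organism <- "Gallus gallus" }
    res <- resolve_sequence(m, lk)
    expected <- if (has[1]) c("SEQ_UNIPROT", "identifier:uniprot")
      else if (has[2]) c("SEQ_NCBI", "identifier:ncbi")
      else if (has[3]) c("SEQ_PDB", "identifier:pdb")
      else if (has[4]) c("SEQ_UNIPROT", "name_search")
      else c(NA_character_, "unresolved")
    # name search hits the first fixture row for lysozyme c
    expect_equal(res$method, expected[2], info = paste("mask", mask))
    expect_equal(res$sequence, expected[1], info = paste("mask", mask))
  }
})

test_that("unresolvable identifiers fall through without raising", {
  lk <- seq_fixture()
  m <- kinetic_measurement(uniprot = "NOPE", ncbi = "NP_000001", doc_id = "D")
  res <- resolve_sequence(m, lk)
  expect_equal(res$method, "identifier:ncbi")
  m2 <- kinetic_measurement(uniprot = "NOPE", doc_id = "D")
  expect_equal(resolve_sequence(m2, lk)$method, "unresolved")
})

test_that("name search returns the top-ranked (first) fixture hit", {
  lk <- seq_fixture()
  m <- kinetic_measurement(enzyme_name = "hexokinase",
                           organism = "Saccharomyces cerevisiae",
                           doc_id = "D")
  res <- resolve_sequence(m, lk)
  expect_equal(res$sequence, "SEQ_HXK_TOP")
})

test_that("substrate resolution expands abbreviations and ranks hits", {
  lk <- cmpd_fixture()
  res <- resolve_substrate("ATP", lk)
  expect_equal(res$smiles, "ATP_SMILES_TOP")
  expect_equal(res$resolved_name, "adenosine triphosphate")
  expect_equal(resolve_substrate("glucose", lk)$smiles, "GLC_SMILES")
  expect_equal(resolve_substrate("unobtainium", lk)$reason, "not_found")
})

test_that("generic polymeric substrates are refused", {
  lk <- cmpd_fixture()
  for (nm in c("DNA", "RNA", "protein", "starch")) {
    res <- resolve_substrate(nm, lk)
    expect_true(is.na(res$smiles))
    expect_equal(res$reason, "generic_substrate")
  }
})

test_that("fixture TSVs load through the documented schema", {
  dir <- withr::local_tempdir()
  seqs <- file.path(dir, "seqs.tsv")
  readr::write_tsv(tibble::tibble(
    kind = "uniprot", id = "P1", name = "urease",
    organism = "canavalia ensiformis", sequence = "MKLV"
  ), seqs)
  lk <- sequence_lookup(seqs)
  expect_equal(lk$by_identifier("uniprot", "P1"), "MKLV")
  cmp <- file.path(dir, "cmp.tsv")
  readr::write_tsv(tibble::tibble(name = "urea", rank = 1L, smiles = "NC(N)=O"),
                   cmp)
  expect_equal(compound_lookup(cmp)$by_name("Urea")$smiles, "NC(N)=O")
})

test_that("resolve_entries fills tiers, sequences and SMILES", {
  entries <- dplyr::bind_rows(
    kinetic_measurement(enzyme_name = "Lysozyme C", organism = "Gallus gallus",
                        substrate_name = "glucose", doc_id = "D1"),
    kinetic_measurement(enzyme_name = "nobody", organism = "nowhere",
                        substrate_name = "DNA", doc_id = "D2")
  )
  out <- resolve_entries(entries, seq_fixture(), cmpd_fixture())
  expect_equal(out$confidence, c("medium", "medium"))
  expect_equal(out$sequence[1], "SEQ_UNIPROT")
  expect_equal(out$substrate_smiles[1], "GLC_SMILES")
  expect_equal(out$sequence[2], "")
  expect_equal(out$substrate_smiles[2], "")
})
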