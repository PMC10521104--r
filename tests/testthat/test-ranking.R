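test_that("target summaries reproduce a mixed-evidence target row", {
  # a target supported by 10 DrugBank hits and 11 active / 7 inactive
  # ChEMBL ligands (no PDB evidence): active - inactive difference of 4
  db_keys <- paste0("KD", 1:10)
  act_keys <- paste0("KA", 1:11)
  inact_keys <- paste0("KI", 1:7)
  hits <- dplyr::bind_rows(
    tibble::tibble(corpus = "drugbank", reference_id = paste0("DB", 1:10),
                   canonical_key = db_keys),
    tibble::tibble(corpus = "chembl",
                   reference_id = paste0("CH", 1:18),
                   canonical_key = c(act_keys, inact_keys)))
  labels <- tibble::tibble(
    canonical_key = c(act_keys, inact_keys), target_id = "P35968",
    label = c(rep("active", 11), rep("inactive", 7)),
    n_supporting_rows = 1L)
  annotations <- dplyr::bind_rows(
    tibble::tibble(corpus = "drugbank", record_id = paste0("DB", 1:10),
                   target_id = "P35968",
                   target_name = "Vascular endothelial growth factor receptor 2",
                   organism = "Homo sapiens"),
    tibble::tibble(corpus = "chembl", record_id = NA_character_,
                   target_id = "P35968",
                   target_name = "Vascular endothelial growth factor receptor 2",
                   organism = "Homo sapiens"))
  summ <- summarize_targets(hits, labels, annotations)
  expect_equal(nrow(summ), 1)
  expect_equal(summ$pdb_count, 0L)
  expect_equal(summ$db_count, 10L)
  expect_equal(summ$chembl_active, 11L)
  expect_equal(summ$chembl_inactive, 7L)
  expect_equal(summ$active_minus_inactive, 4L)
  expect_equal(summ$n_corpora, 2L)
})

test_that("summaries count distinct molecules, handle unknowns and empties", {
  hits <- tibble::tibble(
    corpus = c("drugbank", "drugbank", "pdb"),
    reference_id = c("DB1", "DB2", "HET"),
    canonical_key = c("K1", "K1", "K2"))  # same molecule under two DB ids
  annotations <- tibble::tibble(
    corpus = "drugbank", record_id = c("DB1", "DB2"), target_id = "T1",
    target_name = "t", organism = "o")
  labels <- tibble::tibble(canonical_key = character(),
                           target_id = character(), label = character(),
                           n_supporting_rows = integer())
  summ <- suppressMessages(summarize_targets(hits, labels, annotations))
  expect_equal(summ$db_count[summ$target_id == "T1"], 1L)
  expect_true("UNKNOWN" %in% summ$target_id)  # pdb hit lacks annotation
  expect_equal(nrow(summarize_targets(hits[0, ], labels, annotations)), 0)
})

test_that("ranking puts multi-database targets first, then potency balance", {
  summ <- tibble::tibble(
    target_id = c("B", "A", "C", "D"),
    target_name = "t", organism = "o",
    pdb_count = c(0L, 1L, 0L, 0L),
    db_count = c(0L, 2L, 0L, 0L),
    chembl_active = c(10L, 5L, 4L, 1L),
    chembl_inactive = c(0L, 1L, 0L, 0L),
    n_corpora = c(1L, 3L, 1L, 1L),
    active_minus_inactive = c(10L, 4L, 4L, 1L))
  r <- rank_targets(summ)
  expect_identical(r$target_id, c("A", "B", "C", "D"))
  expect_identical(r$rank, 1:4)
})

test_that("alphabetical tie-break makes the order total and stable", {
  base <- tibble::tibble(
    target_id = c("T2", "T1"), target_name = "t", organism = "o",
    pdb_count = 1L, db_count = 1L, chembl_active = 2L,
    chembl_inactive = 1L, n_corpora = 3L, active_minus_inactive = 1L)
  expect_identical(rank_targets(base)$target_id, c("T1", "T2"))
  # permutation-invariant
  withr::with_seed(9, {
    summ <- tibble::tibble(
      target_id = paste0("T", 1:12), target_name = "t", organism = "o",
      pdb_count = sample(0:2, 12, TRUE), db_count = sample(0:5, 12, TRUE),
      chembl_active = sample(0:8, 12, TRUE),
      chembl_inactive = sample(0:8, 12, TRUE))
    summ$n_corpora <- (summ$pdb_count > 0) + (summ$db_count > 0) +
      (summ$chembl_active + summ$chembl_inactive > 0)
    summ$active_minus_inactive <- summ$chembl_active - summ$chembl_inactive
    r1 <- rank_targets(summ)
    r2 <- rank_targets(summ[sample(12), ])
    expect_identical(r1$target_id, r2$target_id)
  })
})
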