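test_that("canonicalization merges equivalent SMILES spellings", {
  expect_equal(canonicalize("C1=CC=CC=C1"), canonicalize("c1ccccc1"))
  expect_equal(canonicalize("OCC"), canonicalize("CCO"))
  # idempotent
  k <- canonicalize("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(canonicalize(k), k)
  # stereo preserved and distinguishing
  expect_false(canonicalize("C[C@H](N)C(=O)O") ==
                 canonicalize("C[C@@H](N)C(=O)O"))
})

test_that("invalid SMILES raise a typed parse error naming the string", {
  err <- expect_error(canonicalize("C1CC"), class = "lbvs_parse_error")
  expect_match(conditionMessage(err), "C1CC", fixed = TRUE)
  expect_true(is.na(canonicalize("C1CC", strict = FALSE)))
})

test_that("canonicalization partitions shuffled spellings into one key each", {
  spellings <- list(
    c("c1ccccc1O", "Oc1ccccc1", "C1=CC=C(O)C=C1"),
    c("CCN(CC)CC", "N(CC)(CC)CC"),
    c("O=C(O)CC", "CCC(=O)O", "CCC(O)=O"))
  for (grp in spellings) {
    keys <- unique(canonicalize(grp))
    expect_length(keys, 1)
  }
  # different molecules get different keys
  all_keys <- vapply(spellings, function(g) canonicalize(g[1]), character(1))
  expect_length(unique(all_keys), length(spellings))
})

test_that("read_corpus parses dialect tables and skips junk rows", {
  d <- withr::local_tempdir()
  p <- file.path(d, "db.csv")
  readr::write_csv(tibble::tibble(
    id = c("DB1", "DB2", "DB3", "DB4"),
    smiles = c("CCO", "c1ccccc1", "NOT_A_SMILES((", "CC(=O)N"),
    type = c("small_molecule", "biologic", "small_molecule",
             "small_molecule")), p)
  recs <- suppressMessages(read_corpus(p, "drugbank"))
  expect_equal(nrow(recs), 3)
  expect_equal(attr(recs, "n_skipped"), 1L)
  expect_identical(recs$record_id, c("DB1", "DB2", "DB4"))
  expect_true(all(recs$corpus == "drugbank"))
  expect_false(anyNA(recs$canonical_key))
})

test_that("read_corpus enforces required dialect columns and missing files", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.csv")
  readr::write_csv(tibble::tibble(smiles = "CCO"), p)
  expect_error(read_corpus(p, "drugbank"), "id")
  expect_error(read_corpus(file.path(d, "absent.csv"), "pdb"), "not found")
})

test_that("smi reader preserves order and ids", {
  d <- withr::local_tempdir()
  p <- file.path(d, "mols.smi")
  writeLines(c("CCO mol_a", "c1ccccc1 mol_b"), p)
  recs <- read_corpus(p, "query")
  expect_identical(recs$record_id, c("mol_a", "mol_b"))
})

test_that("tables round-trip through csv, tsv and json", {
  tab <- tibble::tibble(query_id = c("q1", "q2"),
                        reference_id = c("r1", "r2"),
                        tc_maccs = c(0.71234567, 0.5),
                        pass_2d = c(TRUE, FALSE))
  d <- withr::local_tempdir()
  for (fmt in c("csv", "tsv", "json")) {
    p <- file.path(d, paste0("t.", fmt))
    write_table(tab, p, fmt)
    back <- read_table_file(p)
    expect_equal(back$query_id, tab$query_id)
    expect_equal(back$pass_2d, tab$pass_2d)
    expect_equal(back$tc_maccs, signif(tab$tc_maccs, 6), tolerance = 1e-9)
  }
  # empty table -> header-only file
  p <- file.path(d, "empty.csv")
  write_table(tab[0, ], p, "csv")
  expect_equal(nrow(read_table_file(p)), 0)
  expect_equal(names(read_table_file(p)), names(tab))
})

test_that("parameter snapshots are stable and order-insensitive", {
  a <- param_snapshot(list(x = 1, y = "a"))
  b <- param_snapshot(list(y = "a", x = 1))
  c <- param_snapshot(list(x = 2, y = "a"))
  expect_identical(a, b)
  expect_false(a == c)
  expect_match(a, "^[0-9a-f]{8}$")
})
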