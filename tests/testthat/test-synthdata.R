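test_that("corpus generation is deterministic under a fixed seed", {
  d1 <- file.path(tempdir(), "synth-det1")
  d2 <- file.path(tempdir(), "synth-det2")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- synthetic_config(seed = 99L, n_decoys_per_corpus = 10L,
                          n_analogs = 3L, n_biologics = 2L,
                          n_solvent_ion_records = 3L)
  suppressMessages(generate_corpora(cfg, d1))
  suppressMessages(generate_corpora(cfg, d2))
  for (f in c("drugbank.csv", "pdb.csv", "chembl.csv", "annotations.csv",
              "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("planted structure matches the declared configuration", {
  dir <- fixture_synth_dir()
  man <- fixture_manifest()
  cfg <- synthetic_config(seed = 1L)

  db <- suppressMessages(read_corpus(file.path(dir, "drugbank.csv"),
                                     "drugbank"))
  kept <- filter_drugbank(db)
  expect_equal(nrow(db) - nrow(kept), cfg$n_biologics)
  expect_setequal(setdiff(db$record_id, kept$record_id),
                  unlist(man$contaminants$drugbank_biologics))

  pdb <- suppressMessages(read_corpus(file.path(dir, "pdb.csv"), "pdb"))
  kept_pdb <- suppressMessages(filter_pdb_ligands(pdb))
  expect_true(all(!unlist(man$contaminants$pdb_solvent_ions) %in%
                    kept_pdb$het_code))

  rows <- read_activities(file.path(dir, "chembl.csv"))
  expect_true(any(rows$assay_format != "Single Protein"))
  expect_true(any(rows$relation != "="))
  expect_true(any(tolower(rows$units) == "um"))
  v <- convert_to_nM(rows$value, rows$units)
  expect_true(any(v <= 1000, na.rm = TRUE) && any(v > 1000, na.rm = TRUE))
  planted <- rows[rows$target_id == man$planted_target_id, ]
  expect_equal(length(unique(planted$molecule_id)), cfg$n_analogs)
})

test_that("planted analogs pass the five 2D thresholds against the scaffold", {
  man <- fixture_manifest()
  scaffold <- tibble::tibble(id = "scaffold",
                             smiles = "O=C1Nc2ccccc2C1CC3=NNC(=O)C3")
  analogs <- tibble::tibble(
    id = vapply(man$analogs, `[[`, character(1), "chembl_id"),
    smiles = vapply(man$analogs, `[[`, character(1), "smiles"))
  s2 <- screen_2d(scaffold, analogs)
  expect_gte(mean(s2$pass_2d), 0.8)
})

test_that("activity values respect the declared ranges", {
  dir <- fixture_synth_dir()
  man <- fixture_manifest()
  rows <- read_activities(file.path(dir, "chembl.csv"))
  v <- convert_to_nM(rows$value, rows$units)
  expect_true(all(v[!is.na(v)] >= 1 & v[!is.na(v)] <= 1e5 * 1.01))
  planted_ids <- vapply(man$analogs, `[[`, character(1), "chembl_id")
  pv <- v[rows$molecule_id %in% planted_ids]
  # analog values are drawn from [10, 800] nM plus rare planted conflicts
  expect_gte(mean(pv >= 10 & pv <= 800), 0.75)
})
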