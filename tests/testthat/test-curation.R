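mk_records <- function(smiles, type = NA, het = NA, corpus = "drugbank") {
  tibble::tibble(record_id = paste0("m", seq_along(smiles)), corpus = corpus,
                 smiles = smiles,
                 canonical_key = canonicalize(smiles, strict = FALSE),
                 name = NA_character_, molecule_type = type, het_code = het,
                 coords = list(NULL))
}

test_that("drugbank filter keeps only small molecules", {
  recs <- mk_records(c("CCO", "CC(N)C(=O)O", "c1ccccc1"),
                     type = c("small_molecule", "biologic", "small_molecule"))
  out <- filter_drugbank(recs)
  expect_equal(nrow(out), 2)
  expect_true(all(out$molecule_type == "small_molecule"))
  expect_warning(filter_drugbank(recs[2, ]), "no small molecules")
  expect_equal(nrow(suppressWarnings(filter_drugbank(recs[0, ]))), 0)
  # idempotent
  expect_identical(filter_drugbank(out), out)
})

test_that("pdb filter removes solvents, ions and charged carbon-free species", {
  recs <- mk_records(
    c("O", "[Na+]", "CC(=O)Nc1ccc(O)cc1", "[O-]S(=O)(=O)[O-]",
      "O=C1Nc2ccccc2C1"),
    het = c("HOH", "NA", "TYL", "XXX", "OXI"), corpus = "pdb")
  cfg <- curation_config()
  out <- filter_pdb_ligands(recs, cfg)
  # HOH stoplisted; NA monoatomic ion; XXX (sulfate) charged without carbon
  expect_identical(out$het_code, c("TYL", "OXI"))
  expect_identical(filter_pdb_ligands(out, cfg)$het_code, out$het_code)
})

test_that("chembl filter applies format, type, relation and unit rules", {
  rows <- tibble::tibble(
    molecule_id = paste0("C", 1:6), smiles = "CCO",
    target_id = "T1", target_name = "t", organism = "o",
    assay_format = c("Single Protein", "Protein Complex", "Single Protein",
                     "Single Protein", "Single Protein", "Single Protein"),
    activity_type = c("IC50", "IC50", "Inhibition", "Ki", "Kd", "EC50"),
    value = c(500, 500, 500, 0.5, 100, 200),
    units = c("nM", "nM", "nM", "uM", "furlongs", "nM"),
    relation = c("=", "=", "=", "=", "=", ">"))
  out <- filter_chembl(rows)
  expect_identical(out$molecule_id, c("C1", "C4"))
  expect_equal(out$value_nM, c(500, 500))  # 0.5 uM -> 500 nM
  log <- attr(out, "drop_log")
  expect_setequal(log$reason[log$molecule_id == "C2"], "assay_format")
  expect_setequal(log$reason[log$molecule_id == "C3"], "activity_type")
  expect_setequal(log$reason[log$molecule_id == "C5"], "units")
  expect_setequal(log$reason[log$molecule_id == "C6"], "relation")
})

test_that("activity labeling is inclusive at the 1000 nM boundary and monotone", {
  expect_equal(label_activity(500), "active")
  expect_equal(label_activity(5000), "inactive")
  expect_equal(label_activity(1000), "active")
  expect_error(label_activity(-1), "negative")
  # monotone: lowering a value never flips active -> inactive
  v <- sort(exp(runif(50, log(1), log(1e5))))
  lab <- label_activity(v)
  expect_false(any(lab == "inactive" & dplyr::lead(lab, default = "inactive")
                   == "active"))
})

test_that("duplicate resolution is strict majority with tie dropping", {
  expect_equal(resolve_duplicates(c("active", "active", "inactive")),
               list(label = "active", n_supporting_rows = 3L))
  expect_equal(resolve_duplicates("inactive"),
               list(label = "inactive", n_supporting_rows = 1L))
  expect_null(resolve_duplicates(c("active", "inactive")))
})

test_that("duplicate resolution matches a frequency-count oracle", {
  withr::with_seed(11, {
    for (i in 1:50) {
      labs <- sample(c("active", "inactive"), sample(1:9, 1), replace = TRUE)
      got <- resolve_duplicates(labs)
      na <- sum(labs == "active"); ni <- sum(labs == "inactive")
      if (na == ni) {
        expect_null(got)
      } else {
        expect_equal(got$label, if (na > ni) "active" else "inactive")
        expect_equal(got$n_supporting_rows, length(labs))
      }
    }
  })
})

test_that("label_ligands aggregates per (molecule, target) and drops ties", {
  rows <- tibble::tibble(
    molecule_id = c("A", "A", "A", "B", "B", "C"),
    smiles = c("CCO", "OCC", "CCO", "c1ccccc1", "c1ccccc1", "CC(=O)N"),
    target_id = c("T1", "T1", "T1", "T1", "T1", "T2"),
    target_name = "t", organism = "o", assay_format = "Single Protein",
    activity_type = "IC50",
    value = c(100, 200, 5000, 400, 8000, 900), units = "nM", relation = "=")
  out <- suppressMessages(label_ligands(filter_chembl(rows)))
  # A: 2 active vs 1 inactive -> active; B: tie -> dropped; C: active
  expect_equal(nrow(out), 2)
  a <- out[out$canonical_key == canonicalize("CCO"), ]
  expect_equal(a$label, "active")
  expect_equal(a$n_supporting_rows, 3L)
  expect_equal(attr(out, "n_ties_dropped"), 1L)
})
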