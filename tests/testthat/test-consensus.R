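mk2d <- function(q, r, pass) tibble::tibble(
  query_id = q, reference_id = r, tc_maccs = 0.8, tc_ecfp4 = 0.4,
  tc_ecfp6 = 0.5, tc_fcfp4 = 0.4, tc_fcfp6 = 0.5, pass_2d = pass)

mk3d <- function(q, r, tc) tibble::tibble(
  query_id = q, reference_id = r, shape_tanimoto = tc / 2,
  color_tanimoto = tc / 2, tanimoto_combo = tc, pass_3d = tc >= 1.2)

test_that("merge_screens is the conjunction of both passes", {
  t2 <- mk2d(c("q1", "q1", "q2"), c("r1", "r2", "r1"), c(TRUE, TRUE, FALSE))
  t3 <- mk3d(c("q1", "q1"), c("r1", "r2"), c(1.3, 1.0))
  m <- suppressMessages(merge_screens(t2, t3))
  key <- paste(m$query_id, m$reference_id)
  expect_true(m$pass_consensus[key == "q1 r1"])   # 2D pass, TC 1.3
  expect_false(m$pass_consensus[key == "q1 r2"])  # TC 1.0
  expect_false(m$pass_consensus[key == "q2 r1"])  # absent from 3D
  expect_error(merge_screens(rbind(t2, t2[1, ]), t3), "duplicate")
})

test_that("merge_screens equals explicit boolean conjunction on random tables", {
  withr::with_seed(21, {
    for (i in 1:10) {
      qs <- paste0("q", 1:4); rs <- paste0("r", 1:5)
      grid <- expand.grid(q = qs, r = rs, stringsAsFactors = FALSE)
      pick2 <- grid[sample(nrow(grid), 15), ]
      pick3 <- grid[sample(nrow(grid), 15), ]
      t2 <- mk2d(pick2$q, pick2$r, runif(15) < 0.5)
      t3 <- mk3d(pick3$q, pick3$r, runif(15, 0.5, 2))
      m <- suppressMessages(merge_screens(t2, t3))
      k2 <- paste(t2$query_id, t2$reference_id)
      k3 <- paste(t3$query_id, t3$reference_id)
      for (j in seq_len(nrow(m))) {
        k <- paste(m$query_id[j], m$reference_id[j])
        want <- (k %in% k2 && t2$pass_2d[match(k, k2)]) &&
          (k %in% k3 && t3$pass_3d[match(k, k3)])
        expect_identical(m$pass_consensus[j], want)
      }
    }
  })
})

test_that("cross-corpus join groups one molecule under its database aliases", {
  key_sem <- canonicalize("Cc1cc(C)c(/C=C2\\C(=O)Nc3ccccc32)[nH]1")
  tabs <- list(
    drugbank = dplyr::mutate(mk2d("q1", "DB06436", TRUE), tanimoto_combo = 1.4,
                             pass_consensus = TRUE, canonical_key = key_sem),
    pdb = dplyr::mutate(mk2d("q1", "X2M", TRUE), tanimoto_combo = 1.5,
                        pass_consensus = TRUE, canonical_key = key_sem),
    chembl = dplyr::mutate(mk2d("q1", "CHEMBL276711", TRUE),
                           tanimoto_combo = 1.3, pass_consensus = TRUE,
                           canonical_key = key_sem))
  joined <- join_across_corpora(tabs)
  expect_equal(nrow(joined), 3)
  expect_equal(length(unique(joined$canonical_key)), 1)
  hits <- cross_corpus_hits(joined, min_corpora = 3)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$n_corpora, 3L)
  expect_equal(hits$best_tanimoto_combo, 1.5)
})

test_that("stereoisomers stay in separate groups and empty inputs join empty", {
  k1 <- canonicalize("C[C@H](N)C(=O)O")
  k2 <- canonicalize("C[C@@H](N)C(=O)O")
  tabs <- list(
    drugbank = dplyr::mutate(mk2d(c("q", "q"), c("d1", "d2"), TRUE),
                             tanimoto_combo = 1.3, pass_consensus = TRUE,
                             canonical_key = c(k1, k2)))
  joined <- join_across_corpora(tabs)
  expect_equal(nrow(joined), 2)
  expect_equal(nrow(cross_corpus_hits(joined, min_corpora = 1)), 2)
  expect_equal(nrow(join_across_corpora(list(drugbank = NULL))), 0)
  expect_equal(nrow(cross_corpus_hits(join_across_corpora(list(a = NULL)))), 0)
})

test_that("join partitions references: one group per canonical key", {
  withr::with_seed(31, {
    keys <- canonicalize(fixture_decoys(8)$smiles)
    tab <- dplyr::mutate(
      mk2d(rep("q", 20), paste0("r", 1:20), TRUE),
      tanimoto_combo = runif(20, 0.5, 2),
      pass_consensus = runif(20) < 0.7,
      canonical_key = sample(keys, 20, replace = TRUE))
    joined <- join_across_corpora(list(chembl = tab))
    expect_lte(nrow(joined), length(unique(tab$canonical_key)))
    # every reference id appears in exactly one group
    ref_lists <- strsplit(joined$reference_ids, ";")
    expect_equal(sort(unique(unlist(ref_lists))), sort(unique(tab$reference_id)))
    expect_false(anyDuplicated(unlist(ref_lists)) > 0)
  })
})
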