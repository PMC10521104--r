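test_that("tanimoto matches a naive per-bit oracle on random bitsets", {
  withr::with_seed(3, {
    for (i in 1:40) {
      nb <- 64L
      xa <- sort(sample(0:(nb - 1), sample(0:20, 1)))
      xb <- sort(sample(0:(nb - 1), sample(0:20, 1)))
      a <- make_fp(xa, nb); b <- make_fp(xb, nb)
      expect_equal(tanimoto(a, b), naive_tanimoto(as_dense(a), as_dense(b)))
      expect_equal(tanimoto(a, b), tanimoto(b, a))
    }
  })
})

test_that("tanimoto edge cases and conventions", {
  a <- make_fp(c(1, 2, 3)); b <- make_fp(c(2, 3, 4))
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(make_fp(1:3), make_fp(5:7)), 0)
  e <- make_fp(integer(0))
  expect_equal(tanimoto(e, e), 1)
  expect_equal(tanimoto(e, e, both_empty = 0), 0)
  expect_error(tanimoto(a, make_fp(1, nbits = 128L)), "mismatch")
})

test_that("fingerprints are deterministic across SMILES spellings", {
  for (kind in c("maccs", "ecfp4", "ecfp6", "fcfp4", "fcfp6")) {
    f1 <- fingerprint("c1ccccc1CCO", kind)
    f2 <- fingerprint("OCCc1ccccc1", kind)
    expect_identical(unclass(f1), unclass(f2))
  }
  expect_gt(length(fingerprint("c1ccccc1", "ecfp4")), 0)
  expect_equal(attr(fingerprint("CCO", "maccs"), "nbits"), 166L)
})

test_that("circular fingerprint radii match environment-class counts", {
  # linear decane: degree-aware invariants mean the radius-r environment
  # of atom i is determined by min(d_i, r+1), with d_i the distance to
  # the nearer chain end; distinct identifiers at level r therefore
  # number |unique(min(d, r+1))|, summed over levels 0..R
  decane <- "CCCCCCCCCC"
  d <- pmin(0:9, 9:0)
  env_classes <- function(R) sum(vapply(0:R, function(r)
    length(unique(pmin(d, r + 1))), numeric(1)))
  e4 <- fingerprint(decane, "ecfp4")
  e6 <- fingerprint(decane, "ecfp6")
  expect_equal(length(e4), env_classes(2))
  expect_equal(length(e6), env_classes(3))
  expect_true(all(unclass(e4) %in% unclass(e6)))
  expect_gt(length(e6), length(e4))
})

test_that("functional-class fingerprints differ from element-based ones", {
  # phenol vs aniline: donor/acceptor/aromatic roles coincide for the
  # heteroatom, so FCFP similarity exceeds ECFP similarity
  tc_e <- tanimoto(fingerprint("c1ccccc1O", "ecfp4"),
                   fingerprint("c1ccccc1N", "ecfp4"))
  tc_f <- tanimoto(fingerprint("c1ccccc1O", "fcfp4"),
                   fingerprint("c1ccccc1N", "fcfp4"))
  expect_gt(tc_f, tc_e)
})

test_that("screen_2d flags pairs by the five-threshold conjunction", {
  q <- tibble::tibble(id = "q", smiles = "CC(=O)Nc1ccc(O)cc1")
  refs <- tibble::tibble(
    id = c("same", "close", "far"),
    smiles = c("CC(=O)Nc1ccc(O)cc1", "CC(=O)Nc1ccc(OC)cc1", "CCCCCC"))
  out <- screen_2d(q, refs)
  expect_equal(nrow(out), 3)
  expect_true(out$pass_2d[out$reference_id == "same"])
  expect_false(out$pass_2d[out$reference_id == "far"])
  expect_true(all(out$tc_maccs[out$reference_id == "same"] == 1))
  # thresholds equal to the observed values still pass (>= semantics)
  cl <- out[out$reference_id == "close", ]
  th <- threshold_config(cl$tc_maccs, cl$tc_ecfp4, cl$tc_ecfp6,
                         cl$tc_fcfp4, cl$tc_fcfp6)
  out2 <- screen_2d(q, refs, th)
  expect_true(out2$pass_2d[out2$reference_id == "close"])
})

test_that("raising any threshold never grows the 2D hit set", {
  q <- enumerate_states(oxindole_state_space())[c(7, 9), ]
  refs <- fixture_decoys(10)
  base <- screen_2d(q, refs, threshold_config(0.1, 0.05, 0.05, 0.05, 0.05))
  tight <- screen_2d(q, refs, threshold_config(0.3, 0.1, 0.1, 0.1, 0.1))
  key <- function(x) paste(x$query_id, x$reference_id)[x$pass_2d]
  expect_true(all(key(tight) %in% key(base)))
})
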