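test_that("pairwise overlap volume follows the closed form for simple cases", {
  pa <- shape_params()
  A <- matrix(0, 1, 3, dimnames = list("C", NULL))
  # two coincident carbon Gaussians: p^2 (pi / 2 alpha)^{3/2}
  alpha <- pi * (3 * pa$p / (4 * pi * 1.7^3))^(2 / 3)
  expect_equal(pairwise_overlap_volume(A, A, pa),
               pa$p^2 * (pi / (2 * alpha))^1.5, tolerance = 1e-12)
  # distant atoms decay to nothing
  B <- matrix(c(50, 0, 0), 1, 3, dimnames = list("C", NULL))
  expect_lt(pairwise_overlap_volume(A, B, pa), 1e-10)
  # symmetry
  C2 <- matrix(c(0, 0, 0, 1.4, 0, 0), 2, 3, byrow = TRUE,
               dimnames = list(c("C", "O"), NULL))
  expect_equal(pairwise_overlap_volume(A, C2, pa),
               pairwise_overlap_volume(C2, A, pa))
})

test_that("analytic overlap matches grid integration on small systems", {
  pa <- shape_params()
  withr::with_seed(7, {
    for (i in 1:5) {
      nA <- sample(1:3, 1); nB <- sample(1:3, 1)
      A <- matrix(runif(nA * 3, -1, 1), nA, 3)
      B <- matrix(runif(nB * 3, -1, 1), nB, 3)
      rownames(A) <- sample(c("C", "N", "O"), nA, replace = TRUE)
      rownames(B) <- sample(c("C", "N", "O"), nB, replace = TRUE)
      v_an <- pairwise_overlap_volume(A, B, pa)
      v_gr <- grid_overlap_volume(A, B, pa, spacing = 0.25, pad = 4)
      expect_lt(abs(v_an - v_gr) / v_an, 0.01)
    }
  })
})

test_that("self-overlay is perfect and rigid-motion invariant", {
  smi <- "CC(=O)Nc1ccc(O)cc1"
  q <- overlay_mol(smi)
  ov <- optimize_overlay(q, q)
  expect_gte(ov$shape_tanimoto, 0.99)
  expect_gte(ov$tanimoto_combo, 1.98)
  expect_equal(ov$tanimoto_combo, ov$shape_tanimoto + ov$color_tanimoto)
  expect_equal(det(ov$rotation), 1, tolerance = 1e-8)
  # rotated + translated copy scores the same
  R <- lbvs:::rotation_from_axisangle(c(0.4, -1.0, 2.2))
  xyz2 <- sweep(q$xyz %*% t(R), 2, c(5, -3, 2), "+")
  ov2 <- optimize_overlay(overlay_mol(smi, xyz = xyz2), q)
  expect_equal(ov2$tanimoto_combo, ov$tanimoto_combo, tolerance = 0.01)
})

test_that("dissimilar shapes score low and degenerate queries still run", {
  m1 <- suppressMessages(optimize_overlay(overlay_mol("C"),
                                          overlay_mol("c1ccccc1")))
  expect_lt(m1$shape_tanimoto, 0.5)
  expect_gte(m1$n_starts_evaluated, 4)
})

test_that("conformer generation respects caps, dedup and determinism", {
  expect_equal(length(generate_conformers("c1ccccc1", n_max = 5)), 1)
  hex <- generate_conformers("CCCCCC", n_max = 5, seed = 1)
  expect_gte(length(hex), 1)
  expect_lte(length(hex), 5)
  hex2 <- generate_conformers("CCCCCC", n_max = 5, seed = 1)
  expect_identical(hex, hex2)
  # dedup: all returned conformers mutually distinct at the RMSD radius
  if (length(hex) > 1) {
    for (i in 1:(length(hex) - 1)) for (j in (i + 1):length(hex))
      expect_gte(lbvs:::kabsch_rmsd(hex[[i]], hex[[j]]), 0.5)
  }
})

test_that("screen_3d max-over-conformers equals a brute-force double loop", {
  mols <- tibble::tibble(
    id = c("a", "b"),
    smiles = c("CC(=O)Nc1ccccc1", "CC(=O)Nc1ccc(C)cc1"))
  qs <- mols[1, ]; rs <- mols[2, ]
  got <- screen_3d(qs, rs, n_conf_query = 3, n_conf_ref = 3, seed = 2)
  # brute force: same ensembles, explicit double loop over optimizations
  pa <- shape_params()
  qc <- generate_conformers(qs$smiles, 3, seed = 2)
  rc <- generate_conformers(rs$smiles, 3, seed = 2)
  qm <- lapply(qc, function(x) overlay_mol(qs$smiles, xyz = x, params = pa))
  rm_ <- lapply(rc, function(x) overlay_mol(rs$smiles, xyz = x, params = pa))
  best <- -Inf
  for (a in qm) for (b in rm_) {
    best <- max(best, optimize_overlay(a, b, pa)$tanimoto_combo)
  }
  expect_equal(got$tanimoto_combo, best, tolerance = 1e-8)
  expect_equal(got$pass_3d, best >= 1.2)
})

test_that("crystal mode uses supplied coordinates and skips records without", {
  smi <- "CC(=O)Nc1ccc(O)cc1"
  xyz <- lbvs:::embed_3d(smi, seed = 3)[[1]]
  refs <- tibble::tibble(id = c("r1", "r2"), smiles = smi,
                         coords = list(xyz, NULL))
  qs <- tibble::tibble(id = "q", smiles = smi)
  out <- suppressMessages(
    screen_3d(qs, refs, n_conf_query = 2, direction = "ref_crystal_vs_query_confs",
              seed = 3))
  expect_equal(out$reference_id, "r1")
  expect_gte(out$tanimoto_combo, 1.9)  # identical molecule, own geometry
})
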