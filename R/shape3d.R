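# Gaussian-overlap shape and pharmacophore-colour similarity: a
# first-order (atom-pairwise) Gaussian volume model with rigid-body
# overlay optimization, scored as ShapeTanimoto + ColorTanimoto
# (TanimotoCombo, 0..2).

# Bondi van der Waals radii (Angstrom)
.bondi_radii <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
                  F = 1.47, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
                  Br = 1.85, I = 1.98)

.color_types <- c("donor", "acceptor", "cation", "anion", "hydrophobe", "ring")

#' Gaussian shape model parameters
#'
#' The density of each heavy atom is a single Gaussian of amplitude `p`
#' whose exponent is chosen so that the Gaussian integrates to the hard
#' sphere volume of the atom's van der Waals radius:
#' `alpha = pi * (3 p / (4 pi r^3))^(2/3)`. Colour features (donor,
#' acceptor, cation, anion, hydrophobe, aromatic-ring centroid) are unit
#' weight Gaussians of fixed radius; only features of the same type
#' interact.
#'
#' @param p Gaussian amplitude (default `2 * sqrt(2)`, the value at which
#'   two identical overlapping spheres reproduce the hard-sphere volume).
#' @param radii named per-element van der Waals radii in Angstrom
#'   (Bondi set).
#' @param radius_uniform if `TRUE` all heavy atoms use the carbon radius.
#' @param color_radius Gaussian radius of colour features in Angstrom.
#' @return list of class `lbvs_shape_params`.
#' @export
shape_params <- function(p = 2 * sqrt(2), radii = .bondi_radii,
                         radius_uniform = FALSE, color_radius = 1.0) {
  stopifnot(p > 0, all(radii > 0), color_radius > 0)
  structure(list(p = p, radii = radii, radius_uniform = radius_uniform,
                 color_radius = color_radius),
            class = "lbvs_shape_params")
}

#' Conformer generation policy
#'
#' Maximum conformer counts by role: up to 5 conformers for the query
#' states, up to 50 per ChEMBL reference, up to 600 per DrugBank
#' reference (broader sampling of the likely bioactive conformation), and
#' up to 50 query conformers when screening against crystallographic PDB
#' ligands. Conformers closer than `rmsd_dedup` Angstrom heavy-atom RMSD
#' are deduplicated.
#'
#' @param n_query_default,n_ref_chembl,n_ref_drugbank,n_query_vs_pdb
#'   positive integers.
#' @param seed integer seed fixed per run.
#' @param rmsd_dedup RMSD deduplication radius in Angstrom.
#' @return list of class `lbvs_conformer_policy`.
#' @export
conformer_policy <- function(n_query_default = 5L, n_ref_chembl = 50L,
                             n_ref_drugbank = 600L, n_query_vs_pdb = 50L,
                             seed = 1L, rmsd_dedup = 0.5) {
  counts <- c(n_query_default, n_ref_chembl, n_ref_drugbank, n_query_vs_pdb)
  stopifnot(all(counts >= 1), rmsd_dedup > 0)
  structure(list(n_query_default = as.integer(n_query_default),
                 n_ref_chembl = as.integer(n_ref_chembl),
                 n_ref_drugbank = as.integer(n_ref_drugbank),
                 n_query_vs_pdb = as.integer(n_query_vs_pdb),
                 seed = as.integer(seed), rmsd_dedup = rmsd_dedup),
            class = "lbvs_conformer_policy")
}

.alpha_for <- function(r, p) pi * (3 * p / (4 * pi * r^3))^(2 / 3)

.atom_alphas <- function(elem, params) {
  r <- if (params$radius_uniform) rep(params$radii[["C"]], length(elem))
  else {
    ri <- params$radii[elem]
    ri[is.na(ri)] <- params$radii[["C"]]
    ri
  }
  unname(.alpha_for(r, params$p))
}

#' First-order Gaussian overlap volume between two conformers
#'
#' `sum_{i in A, j in B} p^2 (pi/(a_i+a_j))^(3/2)
#'  exp(-a_i a_j / (a_i + a_j) d_ij^2)` over heavy-atom pairs: the
#' integral of the product of the two summed atomic Gaussian densities.
#' Symmetric and strictly positive.
#'
#' @param A,B numeric matrices (n x 3) of heavy-atom coordinates in
#'   Angstrom with element-symbol rownames.
#' @param params [shape_params()].
#' @return overlap volume in cubic Angstrom.
#' @export
pairwise_overlap_volume <- function(A, B, params = shape_params()) {
  aA <- .atom_alphas(rownames(A), params)
  aB <- .atom_alphas(rownames(B), params)
  .overlap_terms(A, B, aA, aB, params$p)
}

.overlap_terms <- function(A, B, aA, aB, p) {
  S <- outer(aA, aB, "+")
  P <- outer(aA, aB, "*")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sum(p^2 * (pi / S)^1.5 * exp(-(P / S) * d2))
}

#' Grid-integration oracle for the Gaussian overlap volume
#'
#' Numerically integrates the product of the two summed Gaussian
#' densities on a regular 3D grid. Slow; used to validate
#' [pairwise_overlap_volume()] on small systems.
#'
#' @param A,B coordinate matrices as in [pairwise_overlap_volume()].
#' @param params [shape_params()].
#' @param spacing grid spacing in Angstrom.
#' @param pad grid padding beyond the atom bounding box in Angstrom.
#' @return overlap volume in cubic Angstrom.
#' @export
grid_overlap_volume <- function(A, B, params = shape_params(),
                                spacing = 0.2, pad = 4.5) {
  aA <- .atom_alphas(rownames(A), params)
  aB <- .atom_alphas(rownames(B), params)
  all_xyz <- rbind(A, B)
  lo <- apply(all_xyz, 2, min) - pad
  hi <- apply(all_xyz, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  total <- 0
  # slab over z to bound memory
  pts_xy <- as.matrix(expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE))
  dens <- function(pts, M, al) {
    d2 <- outer(rowSums(pts^2), rowSums(M^2), "+") - 2 * tcrossprod(pts, M)
    d2[d2 < 0] <- 0
    as.vector(exp(-sweep(d2, 2, al, "*")) %*% rep(params$p, nrow(M)))
  }
  for (z in gz) {
    pts <- cbind(pts_xy, z)
    total <- total + sum(dens(pts, A, aA) * dens(pts, B, aB))
  }
  total * spacing^3
}

#' Extract colour features of a conformer
#'
#' Pharmacophore feature points derived from rule-based atom typing on
#' the molecular graph: hydrogen-bond donors (N/O bearing H), acceptors
#' (N/O with a free lone pair), cations/anions (formal charges),
#' hydrophobes (carbons with no heteroatom neighbour, plus heavy
#' halogens) and aromatic-ring centroids.
#'
#' @param mol parsed molecule (internal graph) or SMILES string.
#' @param xyz heavy-atom coordinate matrix aligned with the graph's atom
#'   order.
#' @return data.frame with `type`, `x`, `y`, `z`.
#' @export
color_features <- function(mol, xyz) {
  if (is.character(mol)) mol <- parse_mol(mol)
  roles <- .atom_roles(mol)
  feat <- list()
  add <- function(type, m) {
    if (nrow(m) > 0)
      feat[[length(feat) + 1]] <<- data.frame(
        type = type, x = m[, 1], y = m[, 2], z = m[, 3])
  }
  add("donor", xyz[roles$donor, , drop = FALSE])
  add("acceptor", xyz[roles$acceptor, , drop = FALSE])
  add("cation", xyz[roles$cation, , drop = FALSE])
  add("anion", xyz[roles$anion, , drop = FALSE])
  add("hydrophobe", xyz[roles$hydrophobe, , drop = FALSE])
  for (ring in mol$arom_rings) {
    ctr <- colMeans(xyz[ring, , drop = FALSE])
    feat[[length(feat) + 1]] <- data.frame(
      type = "ring", x = ctr[1], y = ctr[2], z = ctr[3])
  }
  if (length(feat) == 0)
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      z = numeric()))
  do.call(rbind, feat)
}

#' Build an overlay-ready conformer object
#'
#' Bundles heavy-atom coordinates, per-atom Gaussian exponents, colour
#' features and self-overlap volumes for use with [optimize_overlay()].
#'
#' @param smiles molecule SMILES (source of the graph/features).
#' @param xyz optional heavy-atom coordinates aligned to the SMILES parse
#'   order; when `NULL` a 3D structure is built.
#' @param params [shape_params()].
#' @return list of class `lbvs_overlay_mol`.
#' @export
overlay_mol <- function(smiles, xyz = NULL, params = shape_params()) {
  mol <- parse_mol(smiles)
  if (is.null(xyz)) {
    xyz <- embed_3d(smiles)[[1]]
    if (is.null(xyz)) rlang::abort(paste0("3D embedding failed: ", smiles))
  }
  if (nrow(xyz) != nrow(mol$atoms))
    rlang::abort("overlay_mol: coordinates do not match the heavy-atom count")
  .overlay_obj(mol, xyz, params)
}

.overlay_obj <- function(mol, xyz, params) {
  xyz <- as.matrix(xyz)
  elem <- mol$atoms$elem
  rownames(xyz) <- elem
  alphas <- .atom_alphas(elem, params)
  feat <- color_features(mol, xyz)
  fxyz <- as.matrix(feat[, c("x", "y", "z"), drop = FALSE])
  falpha <- rep(.alpha_for(params$color_radius, params$p), nrow(feat))
  self_shape <- .overlap_terms(xyz, xyz, alphas, alphas, params$p)
  self_color <- if (nrow(feat) > 0)
    .color_overlap(fxyz, feat$type, fxyz, feat$type, falpha, params$p) else 0
  structure(list(xyz = xyz, elem = elem, alphas = alphas,
                 feat_xyz = fxyz, feat_type = feat$type,
                 feat_alpha = falpha, self_shape = self_shape,
                 self_color = self_color, params = params),
            class = "lbvs_overlay_mol")
}

# colour overlap: same-type feature pairs only
.color_overlap <- function(FA, tA, FB, tB, fal, p) {
  if (nrow(FA) == 0 || nrow(FB) == 0) return(0)
  total <- 0
  a <- fal[1]
  for (tp in unique(tA)) {
    ia <- tA == tp
    ib <- tB == tp
    if (!any(ib)) next
    total <- total + .overlap_terms(FA[ia, , drop = FALSE],
                                    FB[ib, , drop = FALSE],
                                    rep(a, sum(ia)), rep(a, sum(ib)), p)
  }
  total
}

# principal axes of a point cloud as a proper rotation matrix (columns)
.principal_axes <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / nrow(Xc)
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  list(axes = V, centroid = colMeans(X), evals = e$values)
}

.axis_flips <- list(diag(c(1, 1, 1)), diag(c(1, -1, -1)),
                    diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))

#' Optimize the rigid-body overlay of two conformers
#'
#' Starts from centroid-aligned poses in the reference inertial frame over
#' the four proper axis-flip combinations (plus deterministic extra
#' rotation starts when the query is degenerate, e.g. collinear), then
#' locally maximizes the combined shape + colour overlap over rotation
#' and translation with a derivative-free simplex. ShapeTanimoto is
#' `O_AB / (O_AA + O_BB - O_AB)` at the optimum; ColorTanimoto is the
#' analogous ratio over matching feature types (1 when neither molecule
#' has any feature).
#'
#' @param query,ref `lbvs_overlay_mol` objects (see [overlay_mol()]).
#' @param params [shape_params()] (must match the objects).
#' @param maxit simplex iteration cap per start.
#' @param reltol simplex relative convergence tolerance.
#' @return list of class `lbvs_overlay_result`: `rotation` (3 x 3),
#'   `translation`, `shape_tanimoto`, `color_tanimoto`, `tanimoto_combo`,
#'   `n_starts_evaluated`.
#' @export
optimize_overlay <- function(query, ref, params = shape_params(),
                             maxit = 300L, reltol = 1e-4) {
  stopifnot(inherits(query, "lbvs_overlay_mol"),
            inherits(ref, "lbvs_overlay_mol"))
  pq <- .principal_axes(query$xyz)
  pr <- .principal_axes(ref$xyz)
  degenerate <- pq$evals[2] < 1e-8 * max(pq$evals[1], 1e-12)
  starts <- lapply(.axis_flips, function(Fm) pr$axes %*% Fm %*% t(pq$axes))
  if (degenerate) {
    extra <- list(c(pi / 2, 0, 0), c(0, pi / 2, 0), c(0, 0, pi / 2))
    starts <- c(starts, lapply(extra, function(w)
      pr$axes %*% rotation_from_axisangle(w) %*% t(pq$axes)))
    rlang::inform("optimize_overlay: degenerate query, extra starts added")
  }

  p <- params$p
  # combined objective: shape atoms and colour features stacked into one
  # point set with precomputed kernel matrices (zero weight off the
  # shape-shape and matching-type colour blocks)
  nq <- nrow(query$xyz)
  nr <- nrow(ref$xyz)
  Xq <- rbind(query$xyz, query$feat_xyz)
  Xr <- rbind(ref$xyz, ref$feat_xyz)
  aq <- c(query$alphas, query$feat_alpha)
  ar <- c(ref$alphas, ref$feat_alpha)
  S <- outer(aq, ar, "+")
  G <- outer(aq, ar, "*") / S
  K <- p^2 * (pi / S)^1.5
  # mask: atom-atom block and same-type feature block only
  mask <- matrix(0, nrow(Xq), nrow(Xr))
  mask[seq_len(nq), seq_len(nr)] <- 1
  if (length(query$feat_type) > 0 && length(ref$feat_type) > 0)
    mask[nq + seq_along(query$feat_type), nr + seq_along(ref$feat_type)] <-
      outer(query$feat_type, ref$feat_type, "==") * 1
  K <- K * mask
  rr2 <- rowSums(Xr^2)
  obj <- function(theta, R0) {
    R <- rotation_from_axisangle(theta[1:3]) %*% R0
    Q <- Xq %*% t(R)
    Q[, 1] <- Q[, 1] + theta[4]
    Q[, 2] <- Q[, 2] + theta[5]
    Q[, 3] <- Q[, 3] + theta[6]
    d2 <- outer(rowSums(Q^2), rr2, "+") - 2 * tcrossprod(Q, Xr)
    -sum(K * exp(-G * d2))
  }

  best <- NULL
  for (R0 in starts) {
    # centroid superposition under this start rotation
    t0 <- pr$centroid - as.vector(R0 %*% pq$centroid)
    th0 <- c(0, 0, 0, t0)
    f0 <- obj(th0, R0)
    opt <- tryCatch(
      stats::optim(th0, obj, R0 = R0, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) list(par = th0, value = f0))
    cand <- if (opt$value < f0) list(par = opt$par, value = opt$value, R0 = R0)
    else list(par = th0, value = f0, R0 = R0)
    if (is.null(best) || cand$value < best$value) best <- cand
  }

  R <- rotation_from_axisangle(best$par[1:3]) %*% best$R0
  t_vec <- best$par[4:6]
  Q <- sweep(query$xyz %*% t(R), 2, t_vec, "+")
  o_ab <- .overlap_terms(Q, ref$xyz, query$alphas, ref$alphas, p)
  st <- o_ab / (query$self_shape + ref$self_shape - o_ab)
  nq <- nrow(query$feat_xyz)
  nr <- nrow(ref$feat_xyz)
  if (nq == 0 && nr == 0) {
    ct <- 1
  } else if (nq == 0 || nr == 0) {
    ct <- 0
  } else {
    QF <- sweep(query$feat_xyz %*% t(R), 2, t_vec, "+")
    c_ab <- .color_overlap(QF, query$feat_type, ref$feat_xyz, ref$feat_type,
                           ref$feat_alpha, p)
    ct <- c_ab / (query$self_color + ref$self_color - c_ab)
  }
  st <- min(max(st, 0), 1)
  ct <- min(max(ct, 0), 1)
  structure(list(rotation = R, translation = t_vec,
                 shape_tanimoto = st, color_tanimoto = ct,
                 tanimoto_combo = st + ct,
                 n_starts_evaluated = length(starts)),
            class = "lbvs_overlay_result")
}

# rotatable bonds: acyclic single bonds between heavy atoms that each
# carry at least one further heavy neighbour
.rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0) return(b[0, ])
  deg <- mol$atoms$degree
  keep <- b$order == 1 & !b$aromatic & deg[b$a1] >= 2 & deg[b$a2] >= 2
  ring_bond <- mol$atoms$in_ring[b$a1] & mol$atoms$in_ring[b$a2] &
    .same_ring_bond(mol, b)
  b[keep & !ring_bond, , drop = FALSE]
}

# a bond is in a ring if removing it leaves its endpoints connected
.same_ring_bond <- function(mol, b) {
  vapply(seq_len(nrow(b)), function(i) {
    .connected_without(mol, b$a1[i], b$a2[i])
  }, logical(1))
}

.connected_without <- function(mol, a1, a2) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    x <- mol$bonds$a1[i]; y <- mol$bonds$a2[i]
    if ((x == a1 && y == a2) || (x == a2 && y == a1)) next
    adj[[x]] <- c(adj[[x]], y)
    adj[[y]] <- c(adj[[y]], x)
  }
  seen <- rep(FALSE, n)
  frontier <- a1
  seen[a1] <- TRUE
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!seen[nxt]]
    if (a2 %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

# atoms on the a2 side of the (a1, a2) bond
.branch_atoms <- function(mol, a1, a2) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    x <- mol$bonds$a1[i]; y <- mol$bonds$a2[i]
    if ((x == a1 && y == a2) || (x == a2 && y == a1)) next
    adj[[x]] <- c(adj[[x]], y)
    adj[[y]] <- c(adj[[y]], x)
  }
  seen <- rep(FALSE, n)
  seen[a2] <- TRUE
  frontier <- a2
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

# minimum distance between atom pairs separated by more than two bonds
.min_nonbonded_dist <- function(xyz, topo_far) {
  if (length(topo_far) == 0) return(Inf)
  d <- as.matrix(stats::dist(xyz))
  min(d[topo_far])
}

#' Generate conformers of a molecule
#'
#' Builds a deterministic base geometry with the OpenBabel structure
#' builder, then enumerates staggered torsion settings (0, +120, -120
#' degrees from the base dihedral) over the rotatable bonds. When the
#' torsion grid exceeds the requested count a seeded deterministic subset
#' is drawn. Candidates with steric clashes (non-bonded heavy atoms
#' closer than 1.6 Angstrom) are rejected and survivors are deduplicated
#' at `rmsd_dedup` Angstrom heavy-atom RMSD.
#'
#' @param smiles molecule SMILES.
#' @param n_max maximum number of conformers.
#' @param seed integer seed (subset selection).
#' @param rmsd_dedup deduplication radius in Angstrom.
#' @param base optional precomputed base geometry (heavy-atom matrix from
#'   a batched embedding); embedded on the fly when `NULL`.
#' @return list of heavy-atom coordinate matrices (possibly empty when 3D
#'   embedding fails, with a log message).
#' @export
generate_conformers <- function(smiles, n_max = 5L, seed = 1L,
                                rmsd_dedup = 0.5, base = NULL) {
  stopifnot(n_max >= 1)
  if (is.null(base)) base <- embed_3d(smiles, seed)[[1]]
  if (is.null(base)) {
    rlang::inform(paste0("generate_conformers: embedding failed, skipped: ",
                         smiles))
    return(list())
  }
  mol <- parse_mol(smiles)
  rot <- .rotatable_bonds(mol)
  n_atoms <- nrow(base)

  # atom pairs more than two bonds apart, for the clash filter
  topo_far <- matrix(integer(0), ncol = 2)
  if (n_atoms >= 4) {
    bd <- .bond_distance_matrix(mol)
    topo_far <- which(upper.tri(bd) & bd > 2, arr.ind = TRUE)
  }
  min_clash <- function(xyz) {
    if (nrow(topo_far) == 0) return(Inf)
    min(sqrt(rowSums((xyz[topo_far[, 1], , drop = FALSE] -
                        xyz[topo_far[, 2], , drop = FALSE])^2)))
  }

  k <- nrow(rot)
  if (k == 0) return(list(base))
  angles <- c(0, 2 * pi / 3, -2 * pi / 3)
  n_combo <- 3^k
  cap <- min(n_combo, max(4L * n_max, 64L))
  combo_idx <- if (n_combo <= cap) seq_len(n_combo) else {
    withr::with_seed(seed, c(1L, sample(2:n_combo, cap - 1L)))
  }
  branches <- lapply(seq_len(k), function(i)
    .branch_atoms(mol, rot$a1[i], rot$a2[i]))

  confs <- list()
  for (ci in combo_idx) {
    digits <- (ci - 1) %/% 3^(seq_len(k) - 1) %% 3 + 1
    xyz <- base
    for (i in seq_len(k)) {
      ang <- angles[digits[i]]
      if (ang == 0) next
      a1 <- rot$a1[i]; a2 <- rot$a2[i]
      axis <- xyz[a2, ] - xyz[a1, ]
      axis <- axis / sqrt(sum(axis^2))
      R <- rotation_from_axisangle(axis * ang)
      idx <- branches[[i]]
      xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, xyz[a1, ]) %*%
                            t(R), 2, xyz[a1, ], "+")
    }
    if (min_clash(xyz) < 1.6) next
    dup <- FALSE
    for (cc in confs) {
      if (kabsch_rmsd(cc, xyz) < rmsd_dedup) { dup <- TRUE; break }
    }
    if (!dup) confs[[length(confs) + 1]] <- xyz
    if (length(confs) >= n_max) break
  }
  if (length(confs) == 0) confs <- list(base)
  confs
}

# heavy-atom bond-count distance matrix (BFS per atom)
.bond_distance_matrix <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    x <- mol$bonds$a1[i]; y <- mol$bonds$a2[i]
    adj[[x]] <- c(adj[[x]], y)
    adj[[y]] <- c(adj[[y]], x)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] > d]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

#' 3D shape screen over conformer ensembles
#'
#' For every (query, reference) molecule pair the score is the maximum
#' TanimotoCombo over all conformer pairs; `pass_3d` requires the score
#' to be at or above `tc_min` (default 1.2). In
#' `ref_crystal_vs_query_confs` mode, references contribute only their
#' supplied (crystallographic) conformer and references without
#' coordinates are skipped with a log.
#'
#' @param queries,references data frames with an id column and `smiles`;
#'   references may carry a `coords` list-column for crystal mode.
#' @param n_conf_query,n_conf_ref conformer caps per molecule.
#' @param direction `"query_confs_vs_ref_confs"` (default) or
#'   `"ref_crystal_vs_query_confs"`.
#' @param tc_min TanimotoCombo pass threshold.
#' @param params [shape_params()].
#' @param seed integer seed for conformer subset selection.
#' @param rmsd_dedup conformer deduplication radius (Angstrom).
#' @param pairs optional tibble (`query_id`, `reference_id`) restricting
#'   which pairs are scored (e.g. the 2D hit list); `NULL` scores all.
#' @param score_cache optional environment; molecule-pair scores are
#'   memoized there by canonical structure keys and conformer settings,
#'   so repeated screens of the same molecules (e.g. across corpora)
#'   reuse earlier results.
#' @return tibble `query_id`, `reference_id`, `shape_tanimoto`,
#'   `color_tanimoto`, `tanimoto_combo`, `pass_3d`.
#' @export
screen_3d <- function(queries, references, n_conf_query = 5L,
                      n_conf_ref = 50L,
                      direction = c("query_confs_vs_ref_confs",
                                    "ref_crystal_vs_query_confs"),
                      tc_min = 1.2, params = shape_params(), seed = 1L,
                      rmsd_dedup = 0.5, pairs = NULL, score_cache = NULL) {
  direction <- match.arg(direction)
  q <- .id_smiles(queries)
  r <- .id_smiles(references)
  crystal <- direction == "ref_crystal_vs_query_confs"
  if (crystal) {
    if (!"coords" %in% names(references))
      rlang::abort("crystal mode requires a 'coords' column on references")
    r$coords <- references$coords
  }
  if (is.null(pairs)) {
    pairs <- expand.grid(query_id = q$id, reference_id = r$id,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  pairs <- tibble::as_tibble(pairs)[, c("query_id", "reference_id")]
  empty <- tibble::tibble(query_id = character(), reference_id = character(),
                          shape_tanimoto = numeric(),
                          color_tanimoto = numeric(),
                          tanimoto_combo = numeric(), pass_3d = logical())
  if (nrow(pairs) == 0) return(empty)

  # one batched embedding call for every molecule that needs a built
  # geometry, then conformer ensembles cached per molecule id
  need_q <- unique(pairs$query_id)
  need_r <- if (crystal) character(0) else unique(pairs$reference_id)
  embed_ids <- c(paste0("q:", need_q, recycle0 = TRUE),
                 paste0("r:", need_r, recycle0 = TRUE))
  embed_smi <- c(q$smiles[match(need_q, q$id)],
                 r$smiles[match(need_r, r$id)])
  bases <- if (length(embed_smi) > 0)
    stats::setNames(embed_3d(embed_smi, seed), embed_ids) else list()

  q_cache <- new.env(parent = emptyenv())
  r_cache <- new.env(parent = emptyenv())
  get_ens <- function(cache, role, id, smiles, n_conf,
                      crystal_coords = NULL) {
    key <- as.character(id)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ens <- if (!is.null(crystal_coords)) {
      mol <- parse_mol(smiles)
      if (nrow(crystal_coords) != nrow(mol$atoms)) list()
      else list(.overlay_obj(mol, crystal_coords, params))
    } else {
      confs <- generate_conformers(smiles, n_conf, seed, rmsd_dedup,
                                   base = bases[[paste0(role, ":", id)]])
      mol <- parse_mol(smiles)
      lapply(confs, function(x) .overlay_obj(mol, x, params))
    }
    cache[[key]] <- ens
    ens
  }

  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    qi <- match(pairs$query_id[i], q$id)
    ri <- match(pairs$reference_id[i], r$id)
    if (is.na(qi) || is.na(ri)) next
    ckey <- NULL
    if (!is.null(score_cache)) {
      ckey <- paste(canonicalize(q$smiles[qi]), canonicalize(r$smiles[ri]),
                    direction, n_conf_query, n_conf_ref, seed, sep = "|")
      hit <- score_cache[[ckey]]
      if (!is.null(hit)) {
        res[[i]] <- tibble::tibble(
          query_id = pairs$query_id[i],
          reference_id = pairs$reference_id[i],
          shape_tanimoto = hit$st, color_tanimoto = hit$ct,
          tanimoto_combo = hit$tc, pass_3d = hit$tc >= tc_min)
        next
      }
    }
    q_ens <- get_ens(q_cache, "q", q$id[qi], q$smiles[qi], n_conf_query)
    r_ens <- if (crystal) {
      cc <- r$coords[[ri]]
      if (is.null(cc)) {
        rlang::inform(paste0("screen_3d: reference without coordinates ",
                             "skipped: ", r$id[ri]))
        list()
      } else get_ens(r_cache, "r", r$id[ri], r$smiles[ri], 1L,
                     crystal_coords = as.matrix(cc))
    } else {
      get_ens(r_cache, "r", r$id[ri], r$smiles[ri], n_conf_ref)
    }
    if (length(q_ens) == 0 || length(r_ens) == 0) next
    best <- list(st = 0, ct = 0, tc = -Inf)
    for (qc in q_ens) for (rc in r_ens) {
      ov <- optimize_overlay(qc, rc, params)
      if (ov$tanimoto_combo > best$tc)
        best <- list(st = ov$shape_tanimoto, ct = ov$color_tanimoto,
                     tc = ov$tanimoto_combo)
    }
    if (!is.null(score_cache)) score_cache[[ckey]] <- best
    res[[i]] <- tibble::tibble(
      query_id = pairs$query_id[i], reference_id = pairs$reference_id[i],
      shape_tanimoto = best$st, color_tanimoto = best$ct,
      tanimoto_combo = best$tc, pass_3d = best$tc >= tc_min)
  }
  out <- dplyr::bind_rows(res[!vapply(res, is.null, logical(1))])
  if (nrow(out) == 0)
    out <- tibble::tibble(query_id = character(), reference_id = character(),
                          shape_tanimoto = numeric(),
                          color_tanimoto = numeric(),
                          tanimoto_combo = numeric(), pass_3d = logical())
  out[order(out$query_id, out$reference_id), , drop = FALSE]
}
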