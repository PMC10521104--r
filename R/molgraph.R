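# Internal molecular-graph model built on ChemmineR's SDF perception.
# Atoms are kept in SMILES parse order (heavy atoms only), which is the
# same order OpenBabel uses when writing 3D SDF blocks for the same
# canonical SMILES -- graph attributes and 3D coordinates therefore align
# by index.

# usual organic-subset valences; S and P pick the smallest allowed valence
# that accommodates the explicit bond-order sum
.default_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)
.hypervalent <- list(S = c(2, 4, 6), P = c(3, 5))

# old-style SDF charge codes: 1..3 -> +3..+1, 5..7 -> -1..-3
.sdf_charge <- function(code) {
  ifelse(code >= 1 & code <= 3, 4 - code,
         ifelse(code >= 5 & code <= 7, -(code - 4), 0))
}

# parse a SMILES into atoms/bonds with aromaticity, ring membership,
# implicit hydrogen counts and formal charges
parse_mol <- function(smiles) {
  can <- canonicalize(smiles)
  single <- .single_atom_graph(can)
  if (!is.null(single)) return(single)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(can, "m"))[[1]])
  out <- graph_from_sdf(sdf)
  out$canonical <- can
  out
}

# single heavy atoms (water, methane, monoatomic ions) cannot round-trip
# through the SDF machinery; build their one-atom graph directly
.single_atom_graph <- function(can) {
  m <- regmatches(can, regexec(
    "^(?:([A-IK-Za-ik-z][a-z]?)|\\[([A-IK-Za-ik-z][a-z]?)(H\\d*)?(\\+{1,3}|-{1,3}|[+-]\\d+)?\\])$",
    can))[[1]]
  if (length(m) == 0) return(NULL)
  elem <- if (nzchar(m[2])) m[2] else m[3]
  elem <- paste0(toupper(substr(elem, 1, 1)), substring(elem, 2))
  charge <- 0L
  if (nzchar(m[5])) {
    cs <- m[5]
    charge <- if (grepl("^[+-]\\d+$", cs)) {
      as.integer(cs)
    } else {
      nchar(cs) * (if (startsWith(cs, "+")) 1L else -1L)
    }
  }
  nH <- if (nzchar(m[4])) {
    d <- sub("^H", "", m[4])
    if (nzchar(d)) as.integer(d) else 1L
  } else if (nzchar(m[2])) {
    v <- .default_valence[elem]
    if (is.na(v)) 0L else as.integer(v)
  } else 0L
  list(
    atoms = data.frame(elem = elem, charge = charge, nH = nH,
                       degree = 0L, aromatic = FALSE, in_ring = FALSE,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = integer(), a2 = integer(), order = integer(),
                       aromatic = logical()),
    arom_rings = list(),
    coords = matrix(0, 1, 3, dimnames = list(elem, c("x", "y", "z"))),
    canonical = can)
}

# same perception applied to an already-parsed SDF object (hydrogens, if
# present, are dropped; atom indices refer to heavy atoms in block order)
graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- .sdf_charge(as.numeric(charge_code))

  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    data.frame(a1 = integer(), a2 = integer(), order = integer(),
               aromatic = logical())
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]), aromatic = FALSE)
  }

  in_ring <- rep(FALSE, n)
  aromatic <- rep(FALSE, n)
  arom_ring_raw <- list()
  if (nrow(bonds) > 0) {
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 7, type = "all",
                                        arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical()))
    ring_idx <- lapply(rg$RINGS, function(r) as.integer(sub("^.*_", "", r)))
    for (k in seq_along(ring_idx)) {
      idx <- ring_idx[[k]]
      in_ring[idx] <- TRUE
      # only monocycle-sized rings can be aromatic under this perception
      if (isTRUE(rg$AROMATIC[[k]]) && length(idx) <= 6) {
        aromatic[idx] <- TRUE
        arom_ring_raw <- c(arom_ring_raw, list(idx))
        on <- bonds$a1 %in% idx & bonds$a2 %in% idx
        bonds$aromatic[on] <- TRUE
      }
    }
  }

  bond_sum <- rep(0, n)
  degree <- rep(0L, n)
  if (nrow(bonds) > 0) {
    for (i in seq_len(nrow(bonds))) {
      o <- bonds$order[i]
      bond_sum[bonds$a1[i]] <- bond_sum[bonds$a1[i]] + o
      bond_sum[bonds$a2[i]] <- bond_sum[bonds$a2[i]] + o
      degree[bonds$a1[i]] <- degree[bonds$a1[i]] + 1L
      degree[bonds$a2[i]] <- degree[bonds$a2[i]] + 1L
    }
  }

  # implicit hydrogens from standard valences (explicit H bonds are already
  # inside bond_sum, so they are not double counted)
  nH <- vapply(seq_len(n), function(i) {
    e <- elem[i]
    if (e %in% names(.hypervalent)) {
      vals <- .hypervalent[[e]]
      v <- vals[vals >= bond_sum[i]]
      v <- if (length(v) == 0) max(vals) else v[1]
    } else {
      v <- .default_valence[e]
      if (is.na(v)) return(0L)  # metals/ions: no implicit hydrogens
    }
    max(0L, as.integer(v + charge[i] - bond_sum[i]))
  }, integer(1))
  # monoatomic anions (e.g. chloride) carry no hydrogens
  nH[degree == 0 & charge < 0] <- 0L

  # add explicit hydrogens to the H count, then drop them from the graph
  is_h <- elem == "H"
  if (any(is_h) && nrow(bonds) > 0) {
    for (i in seq_len(nrow(bonds))) {
      if (is_h[bonds$a2[i]] && !is_h[bonds$a1[i]])
        nH[bonds$a1[i]] <- nH[bonds$a1[i]] + 1L
      if (is_h[bonds$a1[i]] && !is_h[bonds$a2[i]])
        nH[bonds$a2[i]] <- nH[bonds$a2[i]] + 1L
    }
  }
  idx_map <- cumsum(!is_h)
  heavy_bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
  heavy_bonds$a1 <- idx_map[heavy_bonds$a1]
  heavy_bonds$a2 <- idx_map[heavy_bonds$a2]
  rownames(heavy_bonds) <- NULL
  hdeg <- rep(0L, sum(!is_h))
  if (nrow(heavy_bonds) > 0) {
    t1 <- table(heavy_bonds$a1)
    t2 <- table(heavy_bonds$a2)
    hdeg[as.integer(names(t1))] <- hdeg[as.integer(names(t1))] + as.integer(t1)
    hdeg[as.integer(names(t2))] <- hdeg[as.integer(names(t2))] + as.integer(t2)
  }

  coords <- ab[!is_h, 1:3, drop = FALSE]
  rownames(coords) <- elem[!is_h]
  colnames(coords) <- c("x", "y", "z")

  list(
    atoms = data.frame(elem = elem[!is_h], charge = charge[!is_h],
                       nH = nH[!is_h], degree = hdeg,
                       aromatic = aromatic[!is_h],
                       in_ring = in_ring[!is_h], stringsAsFactors = FALSE),
    bonds = heavy_bonds,
    arom_rings = lapply(arom_ring_raw, function(idx) unname(idx_map[idx])),
    coords = coords)
}

# neighbor list: for atom i, data.frame(nbr, order) where aromatic bonds
# carry the order code 4 so fingerprints do not depend on kekulization
mol_neighbors <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- data.frame(nbr = integer(), order = integer())
  b <- mol$bonds
  if (nrow(b) > 0) {
    ord <- ifelse(b$aromatic, 4L, b$order)
    for (i in seq_len(nrow(b))) {
      nb[[b$a1[i]]] <- rbind(nb[[b$a1[i]]],
                             data.frame(nbr = b$a2[i], order = ord[i]))
      nb[[b$a2[i]]] <- rbind(nb[[b$a2[i]]],
                             data.frame(nbr = b$a1[i], order = ord[i]))
    }
  }
  nb
}

# deterministic integer hash of an integer vector (mod 2^31-1)
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (as.numeric(x) %% 2147483647)) %% 2147483647
  as.integer(h)
}

# heavy-atom 3D coordinates for a batch of SMILES via ETKDG
# distance-geometry embedding with force-field relaxation (seeded and
# fully deterministic). Molecules are embedded from their canonical
# SMILES, so coordinates align with the parse_mol atom order. Returns a
# list (one per input) of x/y/z matrices with element-symbol rownames;
# NULL where embedding failed.
embed_3d <- function(smiles, seed = 1L) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  can <- canonicalize(smiles)
  ids <- sprintf("m%06d", seq_along(can))
  tmp_in <- tempfile(fileext = ".smi")
  tmp_out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  writeLines(paste(can, ids), tmp_in)
  script <- system.file("python", "embed3d.py", package = "lbvs")
  status <- suppressWarnings(system2("python",
    c(shQuote(script), shQuote(tmp_in), shQuote(tmp_out),
      as.integer(seed)),
    stdout = FALSE, stderr = FALSE))
  out <- stats::setNames(vector("list", length(can)), ids)
  if (!file.exists(tmp_out) || file.size(tmp_out) == 0) return(unname(out))
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp_out))
  ok <- ChemmineR::validSDF(sdfs)
  sdfs <- sdfs[ok]
  got <- unname(ChemmineR::sdfid(sdfs))
  for (i in seq_along(sdfs)) {
    ab <- ChemmineR::atomblock(sdfs[[i]])
    elem <- sub("_.*$", "", rownames(ab))
    keep <- elem != "H"
    m <- ab[keep, 1:3, drop = FALSE]
    rownames(m) <- elem[keep]
    colnames(m) <- c("x", "y", "z")
    out[[got[i]]] <- m
  }
  unname(out)
}

# Kabsch: optimal rotation of B onto A (both centered), returns RMSD
kabsch_rmsd <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  Ac <- scale(A, scale = FALSE)
  Bc <- scale(B, scale = FALSE)
  s <- svd(crossprod(Bc, Ac))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Br <- Bc %*% R
  sqrt(mean(rowSums((Ac - Br)^2)))
}

# proper rotation matrix from an axis-angle vector
rotation_from_axisangle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
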