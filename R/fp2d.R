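# element -> atomic number for fingerprint invariants
.atomic_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53)

.fp_kinds <- c("maccs", "ecfp4", "ecfp6", "fcfp4", "fcfp6")

#' 2D Tanimoto threshold configuration
#'
#' Per-fingerprint Tanimoto cutoffs used by the 2D screen; a reference
#' passes only if all five coefficients are at or above their threshold.
#' Defaults: MACCS 0.7, ECFP4 0.3, ECFP6 0.4, FCFP4 0.3, FCFP6 0.4.
#'
#' @param tc_maccs,tc_ecfp4,tc_ecfp6,tc_fcfp4,tc_fcfp6 numbers in \[0, 1\].
#' @return named numeric vector of class `lbvs_thresholds`.
#' @export
threshold_config <- function(tc_maccs = 0.7, tc_ecfp4 = 0.3, tc_ecfp6 = 0.4,
                             tc_fcfp4 = 0.3, tc_fcfp6 = 0.4) {
  th <- c(maccs = tc_maccs, ecfp4 = tc_ecfp4, ecfp6 = tc_ecfp6,
          fcfp4 = tc_fcfp4, fcfp6 = tc_fcfp6)
  stopifnot(all(th >= 0 & th <= 1))
  structure(th, class = "lbvs_thresholds")
}

# pharmacophoric atom roles shared by the FCFP invariants and the 3D
# colour features
.atom_roles <- function(mol) {
  a <- mol$atoms
  donor <- a$elem %in% c("N", "O") & a$nH > 0
  acceptor <- (a$elem == "O" & a$charge <= 0) |
    (a$elem == "N" & a$charge <= 0 & !(a$aromatic & a$nH > 0))
  cation <- a$charge > 0
  anion <- a$charge < 0
  halogen <- a$elem %in% c("F", "Cl", "Br", "I")
  hydrophobe <- (a$elem == "C" & !a$aromatic) | a$elem %in% c("Cl", "Br", "I")
  if (nrow(mol$bonds) > 0) {
    # aliphatic carbons bonded to a heteroatom are not hydrophobic
    het <- which(!(a$elem %in% c("C", "H")))
    touched <- unique(c(mol$bonds$a1[mol$bonds$a2 %in% het],
                        mol$bonds$a2[mol$bonds$a1 %in% het]))
    hydrophobe[touched] <- hydrophobe[touched] & a$elem[touched] != "C"
  }
  data.frame(donor = donor, acceptor = acceptor, cation = cation,
             anion = anion, aromatic = a$aromatic, halogen = halogen,
             hydrophobe = hydrophobe)
}

# hashed circular (Morgan) fingerprint; radius 2 for the diameter-4
# variants, 3 for diameter-6. functional = TRUE swaps the element-based
# initial invariants for pharmacophoric-role invariants (FCFP).
.morgan_bits <- function(mol, radius, nbits, functional = FALSE) {
  a <- mol$atoms
  n <- nrow(a)
  if (n == 0) rlang::abort("fingerprint: structure has no heavy atoms")
  nb <- mol_neighbors(mol)
  inv <- if (functional) {
    r <- .atom_roles(mol)
    vapply(seq_len(n), function(i) {
      hash_ints(c(91L, as.integer(unlist(r[i, ]))))
    }, integer(1))
  } else {
    vapply(seq_len(n), function(i) {
      z <- .atomic_number[a$elem[i]]
      if (is.na(z)) z <- 0
      hash_ints(c(17L, as.integer(z), a$degree[i], a$nH[i],
                  a$charge[i] + 8L, as.integer(a$in_ring[i]),
                  as.integer(a$aromatic[i])))
    }, integer(1))
  }
  ids <- inv
  for (it in seq_len(radius)) {
    inv_new <- vapply(seq_len(n), function(i) {
      nbi <- nb[[i]]
      if (nrow(nbi) == 0) return(hash_ints(c(it, inv[i])))
      pairs <- cbind(nbi$order, inv[nbi$nbr])
      ord <- order(pairs[, 1], pairs[, 2])
      hash_ints(c(it, inv[i], as.integer(t(pairs[ord, , drop = FALSE]))))
    }, integer(1))
    ids <- c(ids, inv_new)
    inv <- inv_new
  }
  sort(unique(as.integer(unique(ids) %% nbits)))
}

.new_fp <- function(bits, nbits, kind) {
  structure(as.integer(bits), nbits = as.integer(nbits), kind = kind,
            class = "lbvs_fp")
}

# MACCS key fingerprints for a batch of SMILES via OpenBabel's 166
# SMARTS-pattern key set
.maccs_batch <- function(smiles) {
  can <- canonicalize(smiles)
  sdf <- ChemmineR::smiles2sdf(stats::setNames(can, paste0("m", seq_along(can))))
  fp <- ChemmineR::fingerprintOB(sdf, "MACCS")
  m <- fp@fpma
  lapply(seq_len(nrow(m)), function(i) {
    on <- which(m[i, ] != 0) - 1L
    .new_fp(on[on < 166L], 166L, "maccs")
  })
}

#' Compute one fingerprint of a molecule
#'
#' Five fingerprint types are supported: `maccs` (166 substructure keys),
#' `ecfp4`/`ecfp6` (hashed circular fingerprints of diameter 4/6 bonds,
#' i.e. radius 2/3) and `fcfp4`/`fcfp6` (the same topology with
#' pharmacophoric functional-class atom invariants). Fingerprints are
#' computed on the canonicalized structure, so any SMILES spelling of the
#' same molecule yields an identical bitset.
#'
#' @param smiles single SMILES string.
#' @param kind one of `"maccs"`, `"ecfp4"`, `"ecfp6"`, `"fcfp4"`, `"fcfp6"`.
#' @param nbits hashed fingerprint length for the circular types
#'   (default 2048; MACCS is fixed at 166).
#' @return object of class `lbvs_fp`: sorted 0-based on-bit positions with
#'   `nbits` and `kind` attributes.
#' @export
fingerprint <- function(smiles, kind = .fp_kinds, nbits = 2048L) {
  kind <- match.arg(kind)
  if (kind == "maccs") return(.maccs_batch(smiles)[[1]])
  mol <- parse_mol(smiles)
  radius <- if (kind %in% c("ecfp4", "fcfp4")) 2L else 3L
  functional <- kind %in% c("fcfp4", "fcfp6")
  .new_fp(.morgan_bits(mol, radius, nbits, functional), nbits, kind)
}

#' Compute all five fingerprints for a vector of molecules
#'
#' @param smiles character vector.
#' @param nbits hashed circular fingerprint length.
#' @return list (one element per molecule) of named lists of `lbvs_fp`
#'   (`maccs`, `ecfp4`, `ecfp6`, `fcfp4`, `fcfp6`).
#' @export
fingerprint_set <- function(smiles, nbits = 2048L) {
  stopifnot(length(smiles) > 0)
  maccs <- .maccs_batch(smiles)
  mols <- lapply(smiles, parse_mol)
  lapply(seq_along(smiles), function(i) {
    list(
      maccs = maccs[[i]],
      ecfp4 = .new_fp(.morgan_bits(mols[[i]], 2L, nbits, FALSE), nbits, "ecfp4"),
      ecfp6 = .new_fp(.morgan_bits(mols[[i]], 3L, nbits, FALSE), nbits, "ecfp6"),
      fcfp4 = .new_fp(.morgan_bits(mols[[i]], 2L, nbits, TRUE), nbits, "fcfp4"),
      fcfp6 = .new_fp(.morgan_bits(mols[[i]], 3L, nbits, TRUE), nbits, "fcfp6"))
  })
}

#' Tanimoto coefficient between two bitsets
#'
#' `|A \& B| / (|A| + |B| - |A \& B|)`. When both bitsets are empty the
#' molecules are indistinguishable to that fingerprint and the
#' coefficient is defined as `both_empty` (default 1).
#'
#' @param a,b `lbvs_fp` objects of equal length.
#' @param both_empty value returned when neither bitset has any bit set.
#' @return number in \[0, 1\].
#' @export
tanimoto <- function(a, b, both_empty = 1) {
  stopifnot(inherits(a, "lbvs_fp"), inherits(b, "lbvs_fp"))
  if (attr(a, "nbits") != attr(b, "nbits"))
    rlang::abort("tanimoto: bitset length mismatch")
  na <- length(a)
  nb <- length(b)
  if (na == 0 && nb == 0) return(both_empty)
  i <- length(intersect(unclass(a), unclass(b)))
  i / (na + nb - i)
}

#' 2D fingerprint similarity screen
#'
#' Computes all five Tanimoto coefficients for every (query, reference)
#' pair and flags the pairs whose coefficients are at or above every
#' threshold (`pass_2d`). The full table is returned; the hit view is
#' `dplyr::filter(result, pass_2d)`.
#'
#' @param queries,references data frames with an id column (`item_id`,
#'   `record_id` or `id`) and a `smiles` column.
#' @param thresholds [threshold_config()].
#' @param nbits hashed circular fingerprint length.
#' @return tibble with `query_id`, `reference_id`, `tc_maccs`, `tc_ecfp4`,
#'   `tc_ecfp6`, `tc_fcfp4`, `tc_fcfp6`, `pass_2d`.
#' @export
screen_2d <- function(queries, references, thresholds = threshold_config(),
                      nbits = 2048L) {
  q <- .id_smiles(queries)
  r <- .id_smiles(references)
  stopifnot(nrow(q) > 0, nrow(r) > 0)
  fq <- fingerprint_set(q$smiles, nbits)
  fr <- fingerprint_set(r$smiles, nbits)
  grid <- expand.grid(qi = seq_len(nrow(q)), ri = seq_len(nrow(r)),
                      KEEP.OUT.ATTRS = FALSE)
  tc <- matrix(NA_real_, nrow(grid), length(.fp_kinds),
               dimnames = list(NULL, paste0("tc_", .fp_kinds)))
  for (k in seq_along(.fp_kinds)) {
    kind <- .fp_kinds[k]
    tc[, k] <- vapply(seq_len(nrow(grid)), function(j) {
      tanimoto(fq[[grid$qi[j]]][[kind]], fr[[grid$ri[j]]][[kind]])
    }, numeric(1))
  }
  pass <- rep(TRUE, nrow(grid))
  for (k in seq_along(.fp_kinds))
    pass <- pass & tc[, k] >= unname(thresholds[.fp_kinds[k]])
  out <- tibble::tibble(query_id = q$id[grid$qi],
                        reference_id = r$id[grid$ri])
  out <- dplyr::bind_cols(out, tibble::as_tibble(tc))
  out$pass_2d <- pass
  out[order(out$query_id, out$reference_id), , drop = FALSE]
}

# accept item_id / record_id / id as the identifier column
.id_smiles <- function(df) {
  idcol <- intersect(c("item_id", "record_id", "id"), names(df))[1]
  if (is.na(idcol) || !"smiles" %in% names(df))
    rlang::abort("expected an id column (item_id/record_id/id) and 'smiles'")
  tibble::tibble(id = as.character(df[[idcol]]), smiles = df$smiles)
}
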