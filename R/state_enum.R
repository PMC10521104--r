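#' Define a tautomer/stereoisomer state space
#'
#' A state space is a SMILES template with named `{placeholder}` slots,
#' together with the alternative fragments each slot can take: tautomer
#' sites (proton position / bond order variants) and stereocenters
#' (`@`/`@@` configurations). The enumerated library is the Cartesian
#' product over all slots.
#'
#' @param base SMILES template containing one `{name}` placeholder per
#'   site and stereocenter.
#' @param sites named list; each element is a named character vector
#'   mapping state labels to SMILES fragments.
#' @param stereocenters named list like `sites`, one element per
#'   stereocenter, mapping configuration labels to fragments.
#' @param aliases optional data frame with one column per slot plus an
#'   `alias` column, used to attach external item names (e.g. the
#'   oxindole_1..oxindole_20 labels) to enumerated states.
#' @return list of class `lbvs_state_space`.
#' @export
state_space <- function(base, sites, stereocenters = list(), aliases = NULL) {
  stopifnot(is.character(base), length(base) == 1)
  all_slots <- c(sites, stereocenters)
  if (length(all_slots) == 0) rlang::abort("state_space: no sites defined")
  if (is.null(names(all_slots)) || any(!nzchar(names(all_slots))))
    rlang::abort("state_space: every site needs a name")
  for (nm in names(all_slots)) {
    if (length(all_slots[[nm]]) < 1)
      rlang::abort(paste0("state_space: site '", nm, "' has no states"))
    if (!grepl(paste0("{", nm, "}"), base, fixed = TRUE))
      rlang::abort(paste0("state_space: placeholder {", nm,
                          "} missing from base template"))
  }
  structure(list(base = base, sites = sites,
                 stereocenters = stereocenters, aliases = aliases),
            class = "lbvs_state_space")
}

#' Read a state space from YAML
#'
#' Expected YAML layout: a `base` template string, a `sites` map of
#' name -> (label -> fragment), an optional `stereocenters` map with the
#' same shape, and an optional `aliases` list of records each giving one
#' label per slot plus `alias`.
#'
#' @param path YAML file.
#' @return `lbvs_state_space`.
#' @export
read_state_space <- function(path) {
  y <- yaml::read_yaml(path)
  to_named <- function(x) vapply(x, as.character, character(1))
  sites <- lapply(y$sites, to_named)
  stereo <- lapply(y$stereocenters %||% list(), to_named)
  aliases <- if (!is.null(y$aliases)) {
    dplyr::bind_rows(lapply(y$aliases, tibble::as_tibble))
  } else NULL
  state_space(y$base, sites, stereo, aliases)
}

#' Enumerate all states of a state space
#'
#' Produces the full Cartesian product of site states and stereocenter
#' configurations in a deterministic order: the first site varies
#' slowest, stereocenters vary fastest ("site-major, stereo-minor").
#' Item ids are `item_1`, `item_2`, ... in enumeration order; if the
#' state space defines aliases, an `alias` column is attached. Every
#' enumerated SMILES must canonicalize and all canonical keys must be
#' distinct, otherwise an error names the offending site/state.
#'
#' @param space [state_space()].
#' @return tibble with `item_id`, `smiles`, `canonical_key`, one label
#'   column per slot, and optionally `alias`.
#' @export
enumerate_states <- function(space) {
  stopifnot(inherits(space, "lbvs_state_space"))
  slots <- c(space$sites, space$stereocenters)
  labels <- lapply(slots, names)
  # expand.grid varies the FIRST factor fastest; feed reversed slots so the
  # first site is the slowest index, then restore column order
  grid <- expand.grid(rev(labels), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  names(grid) <- names(slots)

  smiles <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    s <- space$base
    for (nm in names(slots)) {
      lab <- grid[[nm]][r]
      s <- sub(paste0("{", nm, "}"), slots[[nm]][[lab]], s, fixed = TRUE)
    }
    smiles[r] <- s
  }
  keys <- canonicalize(smiles, strict = FALSE)
  if (anyNA(keys)) {
    r <- which(is.na(keys))[1]
    rlang::abort(paste0(
      "enumerate_states: invalid structure for state (",
      paste(names(slots), unlist(grid[r, ]), sep = "=", collapse = ", "),
      "): ", smiles[r]))
  }
  if (anyDuplicated(keys)) {
    r <- which(duplicated(keys))[1]
    rlang::abort(paste0(
      "enumerate_states: state (",
      paste(names(slots), unlist(grid[r, ]), sep = "=", collapse = ", "),
      ") duplicates an earlier canonical structure"))
  }
  out <- tibble::tibble(item_id = paste0("item_", seq_len(nrow(grid))),
                        smiles = smiles, canonical_key = keys)
  out <- dplyr::bind_cols(out, tibble::as_tibble(grid))
  if (!is.null(space$aliases)) {
    out <- dplyr::left_join(out, space$aliases, by = names(slots))
  }
  out
}

#' Order enumerated states by an external stability ranking
#'
#' Accepts an externally computed energy map (e.g. quantum-mechanical
#' single-point energies, kcal/mol) and returns the items in ascending
#' energy order. Without energies the input order is preserved. A partial
#' energy map is an error: silently ranking a subset would misrepresent
#' the library.
#'
#' @param items tibble from [enumerate_states()].
#' @param energies optional named numeric vector, `item_id` (or alias)
#'   -> energy.
#' @return `items`, reordered; with energies an `energy` column is added.
#' @export
rank_states <- function(items, energies = NULL) {
  if (is.null(energies)) return(items)
  key <- if ("alias" %in% names(items) &&
               all(names(energies) %in% items$alias))
    items$alias else items$item_id
  missing_ids <- setdiff(key, names(energies))
  if (length(missing_ids) > 0)
    rlang::abort(paste0("rank_states: no energy for item(s): ",
                        paste(missing_ids, collapse = ", ")))
  items$energy <- unname(energies[key])
  items[order(items$energy), , drop = FALSE]
}

#' The query scaffold state-space fixture shipped with the package
#'
#' A 3-(pyrazolylmethyl)oxindole scaffold whose indolinone ring can adopt
#' the lactam (oxindole) or lactim (2-hydroxy-3H-indole) form, whose
#' pyrazolone ring adopts five tautomeric states, and whose C3 center is
#' enumerated in both configurations: 5 x 2 x 2 = 20 states.
#'
#' @return `lbvs_state_space`.
#' @export
oxindole_state_space <- function() {
  read_state_space(system.file("extdata", "oxindole_states.yaml",
                               package = "lbvs"))
}
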