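#' Default PDB component stoplist
#'
#' HET codes of common crystallization adjuvants, buffer components,
#' solvents and ions that are removed from PDB-dialect ligand corpora.
#' Shipped as a plain-text file under `extdata/pdb_stoplist.txt` and
#' fully configurable through [curation_config()].
#'
#' @return character vector of HET codes.
#' @export
pdb_default_stoplist <- function() {
  path <- system.file("extdata", "pdb_stoplist.txt", package = "lbvs")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Curation configuration
#'
#' Bundles the corpus filter constants: the activity threshold separating
#' actives from inactives (1000 nM, boundary inclusive), the retained
#' assay format ("Single Protein"), the retained activity types (Ki, IC50,
#' Kd, EC50, Potency), the PDB contaminant stoplist, and the heavy-atom
#' cutoff below which a structure is treated as a monoatomic ion.
#'
#' @param activity_threshold_nM positive number; values `<=` threshold are
#'   labeled active.
#' @param allowed_assay_format assay format string retained from
#'   ChEMBL-dialect rows.
#' @param allowed_activity_types character vector of retained activity
#'   types.
#' @param pdb_stoplist character vector of HET codes to remove.
#' @param max_inorganic_heavy_atoms records with this many heavy atoms or
#'   fewer are removed from PDB-dialect corpora (monoatomic ions).
#' @return list of class `lbvs_curation_config`.
#' @export
curation_config <- function(activity_threshold_nM = 1000,
                            allowed_assay_format = "Single Protein",
                            allowed_activity_types =
                              c("Ki", "IC50", "Kd", "EC50", "Potency"),
                            pdb_stoplist = pdb_default_stoplist(),
                            max_inorganic_heavy_atoms = 1L) {
  stopifnot(activity_threshold_nM > 0, length(pdb_stoplist) > 0)
  structure(list(
    activity_threshold_nM = activity_threshold_nM,
    allowed_assay_format = allowed_assay_format,
    allowed_activity_types = allowed_activity_types,
    pdb_stoplist = toupper(pdb_stoplist),
    max_inorganic_heavy_atoms = as.integer(max_inorganic_heavy_atoms)),
    class = "lbvs_curation_config")
}

#' Filter a DrugBank-dialect corpus to small molecules
#'
#' @param records molecule-record tibble from [read_corpus()].
#' @return subset of `records` with `molecule_type == "small_molecule"`.
#' @export
filter_drugbank <- function(records) {
  out <- records[!is.na(records$molecule_type) &
                   records$molecule_type == "small_molecule", , drop = FALSE]
  if (nrow(out) == 0) rlang::warn("filter_drugbank: no small molecules retained")
  out
}

#' Filter a PDB-dialect corpus of ligands
#'
#' Removes crystallization adjuvants and solvents (HET code on the
#' stoplist), monoatomic ions (heavy-atom count at or below the
#' configured cutoff), and charged species without a carbon atom
#' (inorganic ions that escaped the code-based rules). Records lacking
#' both a HET code and a parsable structure are skipped with a log.
#'
#' @param records molecule-record tibble from [read_corpus()].
#' @param config [curation_config()].
#' @return filtered tibble; attribute `n_removed` counts removals.
#' @export
filter_pdb_ligands <- function(records, config = curation_config()) {
  keep <- logical(nrow(records))
  n_skipped <- 0L
  for (i in seq_len(nrow(records))) {
    het <- records$het_code[i]
    if (!is.na(het) && toupper(het) %in% config$pdb_stoplist) next
    mol <- tryCatch(parse_mol(records$smiles[i]), error = function(e) NULL)
    if (is.null(mol)) {
      if (is.na(het)) { n_skipped <- n_skipped + 1L; next }
      # het code present but structure unparsable: conservatively keep
      keep[i] <- TRUE
      next
    }
    n_heavy <- sum(mol$atoms$elem != "H")
    if (n_heavy <= config$max_inorganic_heavy_atoms) next
    net_charge <- sum(mol$atoms$charge)
    has_carbon <- any(mol$atoms$elem == "C")
    if (net_charge != 0 && !has_carbon) next
    keep[i] <- TRUE
  }
  out <- records[keep, , drop = FALSE]
  if (n_skipped > 0)
    rlang::inform(paste0("filter_pdb_ligands: skipped ", n_skipped,
                         " record(s) lacking het code and structure"))
  attr(out, "n_removed") <- as.integer(nrow(records) - nrow(out) - n_skipped)
  out
}

# unit -> nM multiplier; NA for unconvertible units
.unit_to_nM <- c("nm" = 1, "um" = 1e3, "µm" = 1e3, "mm" = 1e6,
                 "pm" = 1e-3, "fm" = 1e-6, "m" = 1e9)

#' Convert an activity value to nanomolar
#'
#' @param value numeric vector.
#' @param units character vector of concentration units (nM, uM, mM, pM,
#'   fM, M; case-insensitive).
#' @return numeric vector in nM; `NA` where the unit is unconvertible.
#' @export
convert_to_nM <- function(value, units) {
  mult <- .unit_to_nM[tolower(trimws(units))]
  as.numeric(value) * unname(mult)
}

#' Filter ChEMBL-dialect activity rows
#'
#' Retains rows measured in the allowed assay format, with an allowed
#' activity type, an exact ("=") relation, and a unit convertible to nM.
#' A `value_nM` column with the normalized value is added. Dropped rows
#' are tallied by reason in the `drop_log` attribute (a tibble of
#' `molecule_id`, `reason`).
#'
#' @param rows activity tibble from [read_activities()].
#' @param config [curation_config()].
#' @return filtered tibble with `value_nM`.
#' @export
filter_chembl <- function(rows, config = curation_config()) {
  value_nM <- convert_to_nM(rows$value, rows$units)
  reason <- rep(NA_character_, nrow(rows))
  reason[is.na(reason) &
           !(rows$assay_format %in% config$allowed_assay_format)] <-
    "assay_format"
  reason[is.na(reason) &
           !(rows$activity_type %in% config$allowed_activity_types)] <-
    "activity_type"
  reason[is.na(reason) & !(rows$relation %in% "=")] <- "relation"
  reason[is.na(reason) & is.na(value_nM)] <- "units"
  keep <- is.na(reason)
  out <- rows[keep, , drop = FALSE]
  out$value_nM <- value_nM[keep]
  attr(out, "drop_log") <- tibble::tibble(
    molecule_id = rows$molecule_id[!keep], reason = reason[!keep])
  out
}

#' Label an activity value as active or inactive
#'
#' Active if and only if the value in nM is at or below the configured
#' threshold (1000 nM by default; boundary inclusive).
#'
#' @param value_nM non-negative numeric vector.
#' @param config [curation_config()].
#' @return character vector, `"active"`/`"inactive"`.
#' @export
label_activity <- function(value_nM, config = curation_config()) {
  if (any(value_nM < 0, na.rm = TRUE))
    rlang::abort("label_activity: negative activity value")
  ifelse(value_nM <= config$activity_threshold_nM, "active", "inactive")
}

#' Resolve duplicate activity labels for one ligand-target pair
#'
#' The strict-majority label wins; an exact tie drops the pair (ambiguous
#' evidence should not seed repurposing claims).
#'
#' @param labels character vector of `"active"`/`"inactive"` labels.
#' @return list with `label` and `n_supporting_rows`, or `NULL` when tied.
#' @export
resolve_duplicates <- function(labels) {
  stopifnot(length(labels) > 0)
  n_act <- sum(labels == "active")
  n_inact <- sum(labels == "inactive")
  if (n_act == n_inact) return(NULL)
  list(label = if (n_act > n_inact) "active" else "inactive",
       n_supporting_rows = length(labels))
}

#' Reduce filtered activity rows to per-ligand-per-target labels
#'
#' Applies [label_activity()] to every retained row, groups rows by
#' (canonical structure key, target), and resolves duplicates by strict
#' majority; tied pairs are dropped and logged.
#'
#' @param rows output of [filter_chembl()] (must carry `value_nM`).
#' @param config [curation_config()].
#' @return tibble with `canonical_key`, `target_id`, `label`,
#'   `n_supporting_rows`; attribute `n_ties_dropped`.
#' @export
label_ligands <- function(rows, config = curation_config()) {
  if (nrow(rows) == 0)
    return(tibble::tibble(canonical_key = character(),
                          target_id = character(), label = character(),
                          n_supporting_rows = integer()))
  rows$canonical_key <- canonicalize(rows$smiles, strict = FALSE)
  rows <- rows[!is.na(rows$canonical_key), , drop = FALSE]
  rows$label <- label_activity(rows$value_nM, config)
  grouped <- split(rows$label,
                   paste(rows$canonical_key, rows$target_id, sep = "\r"))
  res <- lapply(grouped, resolve_duplicates)
  keys <- names(grouped)[!vapply(res, is.null, logical(1))]
  n_ties <- sum(vapply(res, is.null, logical(1)))
  res <- res[!vapply(res, is.null, logical(1))]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- tibble::tibble(
    canonical_key = vapply(parts, `[`, character(1), 1),
    target_id = vapply(parts, `[`, character(1), 2),
    label = unname(vapply(res, `[[`, character(1), "label")),
    n_supporting_rows = unname(vapply(res, `[[`, integer(1),
                                      "n_supporting_rows")))
  out <- out[order(out$canonical_key, out$target_id), , drop = FALSE]
  if (n_ties > 0)
    rlang::inform(paste0("label_ligands: dropped ", n_ties,
                         " tied ligand-target pair(s)"))
  attr(out, "n_ties_dropped") <- as.integer(n_ties)
  out
}
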