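# Synthetic corpus generator: emulates the statistical structure of
# DrugBank / PDB / ChEMBL extracts (biologic entries, solvent and ion
# contaminants, non-single-protein assays, duplicate activity rows with
# conflicts, values straddling the 1000 nM threshold) and plants
# close analogs of the query scaffold on one designated target so the
# full pipeline has a recoverable ground truth.

# contaminant HET codes and structures for the mock PDB corpus
.solvent_ion_map <- c(
  HOH = "O", GOL = "OCC(O)CO", EDO = "OCCO", DMS = "CS(C)=O",
  ACT = "CC(=O)[O-]", FMT = "C(=O)[O-]", SO4 = "[O-]S(=O)(=O)[O-]",
  PO4 = "[O-]P(=O)([O-])[O-]", NO3 = "[N+](=O)([O-])[O-]",
  CL = "[Cl-]", "NA" = "[Na+]", K = "[K+]", MG = "[Mg+2]",
  CA = "[Ca+2]", ZN = "[Zn+2]")

# small peptides standing in for DrugBank biologic entries
.biologic_smiles <- c(
  "CC(N)C(=O)NCC(=O)O",
  "NCC(=O)NC(CO)C(=O)O",
  "CC(N)C(=O)NC(CC(C)C)C(=O)O",
  "NC(CC(=O)O)C(=O)NCC(=O)O",
  "NC(Cc1ccccc1)C(=O)NCC(=O)O",
  "CC(N)C(=O)NC(C)C(=O)NCC(=O)O",
  "NC(CO)C(=O)NC(CO)C(=O)O",
  "NCC(=O)NC(Cc1ccccc1)C(=O)O")

# single-substituent analog templates of the query scaffold: one
# aromatic H or the lactam N-H swapped for F / Cl / methyl / methoxy
.analog_templates <- c(
  "O=C1Nc2ccc({X})cc2C1CC3=NNC(=O)C3",
  "O=C1Nc2cc({X})ccc2C1CC3=NNC(=O)C3",
  "O=C1N({X})c2ccccc2C1CC3=NNC(=O)C3")
.analog_subs <- c("F", "Cl", "C", "OC")

#' Synthetic corpus configuration
#'
#' All randomness derives from `seed`; a fixed seed reproduces the
#' corpora byte for byte. Decoy activity values are log-uniform over
#' `activity_range_nM` (straddling the 1000 nM activity threshold);
#' planted analogs receive values from `analog_range_nM` (well inside
#' the active range) on `planted_target_id`.
#'
#' @param seed integer.
#' @param n_decoys_per_corpus decoy molecules drawn per corpus from the
#'   shipped 200-molecule drug-like vocabulary.
#' @param n_analogs number of planted scaffold analogs (max 12).
#' @param planted_target_id,planted_target_name,planted_target_organism
#'   identity of the designated target.
#' @param n_biologics biologic (non-small-molecule) DrugBank entries.
#' @param n_solvent_ion_records solvent/ion contaminant records in the
#'   PDB corpus.
#' @param duplicate_rate fraction of ChEMBL decoy rows duplicated.
#' @param conflict_rate fraction of duplicates whose label conflicts.
#' @param activity_range_nM decoy value range (log-uniform), nM.
#' @param analog_range_nM planted analog value range (log-uniform), nM.
#' @param n_decoy_targets number of decoy protein targets.
#' @param n_chembl_rows_per_analog replicate measurements per analog.
#' @return list of class `lbvs_synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_decoys_per_corpus = 60L,
                             n_analogs = 8L,
                             planted_target_id = "P35968",
                             planted_target_name =
                               "Vascular endothelial growth factor receptor 2",
                             planted_target_organism = "Homo sapiens",
                             n_biologics = 6L, n_solvent_ion_records = 8L,
                             duplicate_rate = 0.2, conflict_rate = 0.1,
                             activity_range_nM = c(1, 1e5),
                             analog_range_nM = c(10, 800),
                             n_decoy_targets = 12L,
                             n_chembl_rows_per_analog = 3L) {
  stopifnot(n_analogs >= 1, n_analogs <= 12,
            duplicate_rate >= 0, duplicate_rate <= 1,
            conflict_rate >= 0, conflict_rate <= 1,
            n_chembl_rows_per_analog >= 1)
  structure(as.list(environment()), class = "lbvs_synthetic_config")
}

#' The shipped drug-like decoy vocabulary
#'
#' @return tibble with `id`, `smiles` (200 molecules).
#' @export
decoy_vocabulary <- function() {
  path <- system.file("extdata", "decoy_library.smi", package = "lbvs")
  v <- .read_smi(path)
  tibble::tibble(id = v$record_id, smiles = v$smiles)
}

# enumerated analog SMILES in deterministic template-major order
.analog_smiles <- function(n) {
  grid <- expand.grid(sub = .analog_subs, tpl = .analog_templates,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  smi <- vapply(seq_len(nrow(grid)), function(i)
    sub("{X}", grid$sub[i], grid$tpl[i], fixed = TRUE), character(1))
  smi[seq_len(n)]
}

#' Generate the three synthetic corpora with planted ground truth
#'
#' Writes `drugbank.csv`, `pdb.csv` (with per-record SDF conformers for
#' the planted analogs), `chembl.csv`, `annotations.csv` and
#' `manifest.json` into `dir`. The DrugBank file mixes small molecules
#' and biologics; the PDB file mixes organic HET groups with stoplist
#' solvents/ions; the ChEMBL file mixes Single-Protein and other assay
#' formats, all retained activity types plus others, qualified
#' relations, mixed units, and duplicate rows with label conflicts.
#' Analogs of the query scaffold are concentrated on the planted target
#' with active-range values; the manifest records every planted fact.
#'
#' @param config [synthetic_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with the file paths and the manifest.
#' @export
generate_corpora <- function(config = synthetic_config(), dir) {
  stopifnot(inherits(config, "lbvs_synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed, .generate_corpora_impl(config, dir))
}

.generate_corpora_impl <- function(config, dir) {
  vocab <- decoy_vocabulary()
  analog_smi <- .analog_smiles(config$n_analogs)
  analog_key <- canonicalize(analog_smi)
  n_a <- length(analog_smi)

  # corpus membership: all analogs in ChEMBL, ~3/4 in DrugBank,
  # ~1/2 in PDB, so some span all three corpora
  in_db <- seq_len(n_a) <= ceiling(0.75 * n_a)
  in_pdb <- seq_len(n_a) <= ceiling(0.5 * n_a)
  db_ids <- sprintf("DB%05d", 9000 + seq_len(n_a))
  het_ids <- sprintf("AX%01d", seq_len(n_a))
  chembl_ids <- sprintf("CHEMBL%d", 800000 + seq_len(n_a))

  decoy_targets <- tibble::tibble(
    target_id = sprintf("Q%05d", seq_len(config$n_decoy_targets)),
    target_name = sprintf("Decoy protein kinase %d",
                          seq_len(config$n_decoy_targets)),
    organism = "Homo sapiens")

  # ---- DrugBank corpus -------------------------------------------------
  db_decoy <- vocab[sample.int(nrow(vocab), config$n_decoys_per_corpus), ]
  bio_idx <- seq_len(config$n_biologics)
  bio_smi <- rep(.biologic_smiles,
                 length.out = config$n_biologics)
  drugbank <- dplyr::bind_rows(
    tibble::tibble(id = db_ids[in_db], smiles = analog_smi[in_db],
                   type = "small_molecule",
                   name = paste0("analog-", which(in_db))),
    tibble::tibble(id = paste0("DB", sprintf("%05d", 1000 + seq_len(nrow(db_decoy)))),
                   smiles = db_decoy$smiles, type = "small_molecule",
                   name = db_decoy$id),
    tibble::tibble(id = sprintf("DB%05d", 5000 + bio_idx), smiles = bio_smi,
                   type = "biologic", name = paste0("biologic-", bio_idx)))
  readr::write_csv(drugbank, file.path(dir, "drugbank.csv"))

  # ---- PDB corpus ------------------------------------------------------
  pdb_decoy <- vocab[sample.int(nrow(vocab), config$n_decoys_per_corpus), ]
  pdb_decoy_het <- sprintf("D%02d", seq_len(nrow(pdb_decoy)))
  si <- .solvent_ion_map[sample(seq_along(.solvent_ion_map),
                                config$n_solvent_ion_records,
                                replace = config$n_solvent_ion_records >
                                  length(.solvent_ion_map))]
  # crystal-like conformers for the planted analogs
  sdf_dir <- file.path(dir, "pdb_confs")
  dir.create(sdf_dir, showWarnings = FALSE)
  analog_pdb_smi <- analog_smi[in_pdb]
  analog_pdb_het <- het_ids[in_pdb]
  sdf_paths <- rep(NA_character_, length(analog_pdb_smi))
  if (length(analog_pdb_smi) > 0) {
    coords <- embed_3d(analog_pdb_smi, config$seed)
    for (i in seq_along(coords)) {
      if (is.null(coords[[i]])) next
      p <- file.path(sdf_dir, paste0(analog_pdb_het[i], ".sdf"))
      .write_sdf_conformer(analog_pdb_het[i], analog_pdb_smi[i],
                           coords[[i]], p)
      sdf_paths[i] <- file.path("pdb_confs", paste0(analog_pdb_het[i], ".sdf"))
    }
  }
  pdb <- dplyr::bind_rows(
    tibble::tibble(het_code = analog_pdb_het, smiles = analog_pdb_smi,
                   sdf_path = sdf_paths,
                   name = paste0("analog-", which(in_pdb))),
    tibble::tibble(het_code = pdb_decoy_het, smiles = pdb_decoy$smiles,
                   sdf_path = NA_character_, name = pdb_decoy$id),
    tibble::tibble(het_code = names(si), smiles = unname(si),
                   sdf_path = NA_character_, name = names(si)))
  readr::write_csv(pdb, file.path(dir, "pdb.csv"))

  # ---- ChEMBL corpus ---------------------------------------------------
  act_types <- c("Ki", "IC50", "Kd", "EC50", "Potency")
  rows <- list()
  # planted analog rows: replicated active measurements on the target,
  # with occasional conflicting inactive duplicates (minority)
  for (i in seq_len(n_a)) {
    nrep <- config$n_chembl_rows_per_analog
    vals <- exp(stats::runif(nrep, log(config$analog_range_nM[1]),
                             log(config$analog_range_nM[2])))
    rows[[length(rows) + 1]] <- tibble::tibble(
      molecule_id = chembl_ids[i], smiles = analog_smi[i],
      target_id = config$planted_target_id,
      target_name = config$planted_target_name,
      organism = config$planted_target_organism,
      assay_format = "Single Protein",
      activity_type = sample(act_types, nrep, replace = TRUE),
      value = round(vals, 2), units = "nM", relation = "=")
    if (stats::runif(1) < config$conflict_rate) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        molecule_id = chembl_ids[i], smiles = analog_smi[i],
        target_id = config$planted_target_id,
        target_name = config$planted_target_name,
        organism = config$planted_target_organism,
        assay_format = "Single Protein",
        activity_type = sample(act_types, 1),
        value = round(exp(stats::runif(1, log(2000), log(50000))), 2),
        units = "nM", relation = "=")
    }
  }
  # decoy rows: mixed formats, types, relations and units
  ch_decoy <- vocab[sample.int(nrow(vocab), config$n_decoys_per_corpus), ]
  ch_decoy_ids <- sprintf("CHEMBL%d", 100000 + seq_len(nrow(ch_decoy)))
  for (i in seq_len(nrow(ch_decoy))) {
    n_rows <- sample(1:3, 1)
    tgt <- decoy_targets[sample.int(nrow(decoy_targets), 1), ]
    fmt <- sample(c("Single Protein", "Protein Complex", "Cell-based"),
                  n_rows, replace = TRUE, prob = c(0.7, 0.15, 0.15))
    typ <- sample(c(act_types, "Inhibition"), n_rows, replace = TRUE,
                  prob = c(rep(0.18, 5), 0.1))
    rel <- sample(c("=", ">", "<"), n_rows, replace = TRUE,
                  prob = c(0.8, 0.1, 0.1))
    use_uM <- stats::runif(n_rows) < 0.25
    vals <- exp(stats::runif(n_rows, log(config$activity_range_nM[1]),
                             log(config$activity_range_nM[2])))
    rows[[length(rows) + 1]] <- tibble::tibble(
      molecule_id = ch_decoy_ids[i], smiles = ch_decoy$smiles[i],
      target_id = tgt$target_id, target_name = tgt$target_name,
      organism = tgt$organism, assay_format = fmt, activity_type = typ,
      value = round(ifelse(use_uM, vals / 1000, vals), 4),
      units = ifelse(use_uM, "uM", "nM"), relation = rel)
    if (stats::runif(1) < config$duplicate_rate) {
      conflict <- stats::runif(1) < config$conflict_rate
      v <- vals[1]
      v2 <- if (conflict) {
        if (v <= 1000) exp(stats::runif(1, log(2000), log(50000)))
        else exp(stats::runif(1, log(10), log(800)))
      } else v * exp(stats::runif(1, -0.2, 0.2))
      rows[[length(rows) + 1]] <- tibble::tibble(
        molecule_id = ch_decoy_ids[i], smiles = ch_decoy$smiles[i],
        target_id = tgt$target_id, target_name = tgt$target_name,
        organism = tgt$organism, assay_format = fmt[1],
        activity_type = typ[1], value = round(v2, 4), units = "nM",
        relation = "=")
    }
  }
  chembl <- dplyr::bind_rows(rows)
  readr::write_csv(chembl, file.path(dir, "chembl.csv"))

  # ---- target annotations ---------------------------------------------
  db_decoy_tgt <- decoy_targets[
    1 + (seq_len(nrow(db_decoy)) - 1) %% nrow(decoy_targets), ]
  pdb_decoy_tgt <- decoy_targets[
    1 + (seq_len(nrow(pdb_decoy)) - 1) %% nrow(decoy_targets), ]
  annotations <- dplyr::bind_rows(
    tibble::tibble(corpus = "drugbank", record_id = db_ids[in_db],
                   target_id = config$planted_target_id,
                   target_name = config$planted_target_name,
                   organism = config$planted_target_organism),
    tibble::tibble(corpus = "drugbank",
                   record_id = drugbank$id[drugbank$type == "small_molecule"][
                     -seq_len(sum(in_db))],
                   target_id = db_decoy_tgt$target_id,
                   target_name = db_decoy_tgt$target_name,
                   organism = db_decoy_tgt$organism),
    tibble::tibble(corpus = "pdb", record_id = analog_pdb_het,
                   target_id = config$planted_target_id,
                   target_name = config$planted_target_name,
                   organism = config$planted_target_organism),
    tibble::tibble(corpus = "pdb", record_id = pdb_decoy_het,
                   target_id = pdb_decoy_tgt$target_id,
                   target_name = pdb_decoy_tgt$target_name,
                   organism = pdb_decoy_tgt$organism),
    tibble::tibble(corpus = "chembl", record_id = NA_character_,
                   target_id = c(config$planted_target_id,
                                 decoy_targets$target_id),
                   target_name = c(config$planted_target_name,
                                   decoy_targets$target_name),
                   organism = c(config$planted_target_organism,
                                decoy_targets$organism)))
  readr::write_csv(annotations, file.path(dir, "annotations.csv"))

  # ---- manifest --------------------------------------------------------
  # expected per-target ChEMBL counts after majority-vote resolution,
  # recomputed here by direct frequency counting on the emitted rows
  retained <- chembl[chembl$assay_format == "Single Protein" &
                       chembl$activity_type %in% act_types &
                       chembl$relation == "=", , drop = FALSE]
  v_nM <- retained$value * ifelse(tolower(retained$units) == "um", 1000, 1)
  lab <- ifelse(v_nM <= 1000, "active", "inactive")
  key <- canonicalize(retained$smiles)
  planted <- retained$target_id == config$planted_target_id
  tab <- table(key[planted], lab[planted])
  act_keys <- rownames(tab)[
    (if ("active" %in% colnames(tab)) tab[, "active"] else 0) >
      (if ("inactive" %in% colnames(tab)) tab[, "inactive"] else 0)]
  inact_keys <- rownames(tab)[
    (if ("inactive" %in% colnames(tab)) tab[, "inactive"] else 0) >
      (if ("active" %in% colnames(tab)) tab[, "active"] else 0)]

  manifest <- list(
    seed = config$seed,
    planted_target_id = config$planted_target_id,
    analogs = lapply(seq_len(n_a), function(i) list(
      smiles = analog_smi[i], canonical_key = analog_key[i],
      chembl_id = chembl_ids[i],
      drugbank_id = if (in_db[i]) db_ids[i] else NA,
      pdb_het = if (in_pdb[i]) het_ids[i] else NA)),
    expected_counts = list(
      db_count = sum(in_db), pdb_count = sum(in_pdb),
      chembl_active = length(intersect(act_keys, analog_key)),
      chembl_inactive = length(intersect(inact_keys, analog_key))),
    contaminants = list(
      drugbank_biologics = drugbank$id[drugbank$type == "biologic"],
      pdb_solvent_ions = names(si)),
    decoy_ids = list(
      drugbank = drugbank$name[drugbank$type == "small_molecule"][
        -seq_len(sum(in_db))],
      pdb = pdb_decoy$id, chembl = ch_decoy$id))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    paths = list(drugbank = file.path(dir, "drugbank.csv"),
                 pdb = file.path(dir, "pdb.csv"),
                 chembl = file.path(dir, "chembl.csv"),
                 annotations = file.path(dir, "annotations.csv"),
                 manifest = file.path(dir, "manifest.json")),
    manifest = manifest))
}

# minimal V2000 writer for a single heavy-atom conformer; bonds are taken
# from the parsed graph so downstream readers re-perceive the molecule
.write_sdf_conformer <- function(id, smiles, xyz, path) {
  mol <- parse_mol(smiles)
  n <- nrow(xyz)
  nb <- nrow(mol$bonds)
  lines <- c(id, "  lbvs  3D", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              xyz[i, 1], xyz[i, 2], xyz[i, 3],
                              mol$atoms$elem[i]))
  }
  for (i in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1[i],
                              mol$bonds$a2[i], mol$bonds$order[i]))
  }
  lines <- c(lines, "M  END", "$$$$")
  writeLines(lines, path)
}

#' Evaluate pipeline output against the planted ground truth
#'
#' Reads a pipeline run directory produced from a synthetic corpus set
#' and reports how well the planted signal was recovered: the rank of
#' the planted target in the final target table, precision/recall of the
#' consensus reference hits against the planted analogs, and the
#' fraction of planted contaminants (solvents, ions, biologics) absent
#' from every hit list. The run seed must match the manifest seed.
#'
#' @param run_dir pipeline output directory from [run_pipeline()].
#' @param manifest manifest list or path to `manifest.json`.
#' @return list with `planted_target_rank`, `precision`, `recall`,
#'   `contaminant_filter_score`, `counts_match`.
#' @export
ground_truth_eval <- function(run_dir, manifest) {
  if (is.character(manifest)) manifest <- jsonlite::fromJSON(manifest,
                                                             simplifyVector = FALSE)
  snap <- jsonlite::fromJSON(file.path(run_dir, "params_snapshot.json"),
                             simplifyVector = TRUE)
  if (!identical(as.integer(snap$seed), as.integer(manifest$seed)))
    rlang::abort("ground_truth_eval: run seed does not match manifest seed")

  ranking <- read_table_file(file.path(run_dir, "target_ranking.csv"))
  planted <- manifest$planted_target_id
  planted_rank <- if (planted %in% ranking$target_id)
    ranking$rank[ranking$target_id == planted] else NA_integer_

  hits <- read_table_file(file.path(run_dir, "consensus_hits.csv"))
  hit_keys <- unique(hits$canonical_key)
  analog_keys <- vapply(manifest$analogs, function(a) a$canonical_key,
                        character(1))
  tp <- length(intersect(hit_keys, analog_keys))
  precision <- if (length(hit_keys) == 0) NA_real_ else tp / length(hit_keys)
  recall <- tp / length(analog_keys)

  contaminant_ids <- c(unlist(manifest$contaminants$drugbank_biologics),
                       unlist(manifest$contaminants$pdb_solvent_ions))
  present <- contaminant_ids %in% hits$reference_id
  contaminant_score <- 1 - mean(present)

  exp_counts <- manifest$expected_counts
  row <- ranking[ranking$target_id == planted, , drop = FALSE]
  counts_match <- nrow(row) == 1 &&
    row$db_count == exp_counts$db_count &&
    row$pdb_count == exp_counts$pdb_count &&
    row$chembl_active == exp_counts$chembl_active &&
    row$chembl_inactive == exp_counts$chembl_inactive

  list(planted_target_rank = planted_rank, precision = precision,
       recall = recall, contaminant_filter_score = contaminant_score,
       counts_match = counts_match)
}
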