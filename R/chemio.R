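#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   distinct left_join bind_rows n across all_of row_number desc
NULL

.corpus_levels <- c("drugbank", "pdb", "chembl", "query")

#' Canonicalize SMILES strings
#'
#' Converts SMILES to canonical isomeric SMILES (stereo descriptors
#' preserved, no tautomer normalization), so that any two spellings of the
#' same molecular graph and stereochemistry map to the same key. Used as
#' the structure key for joining ligands across corpora.
#'
#' @param smiles character vector of SMILES strings.
#' @param strict if `TRUE` (default) an unparsable SMILES raises an error of
#'   class `lbvs_parse_error` naming the offending string; if `FALSE` it
#'   yields `NA`.
#' @return character vector of canonical isomeric SMILES keys.
#' @examples
#' canonicalize(c("C1=CC=CC=C1", "c1ccccc1"))  # same key twice
#' @export
canonicalize <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  out <- vapply(smiles, .ob_canonical_one, character(1), USE.NAMES = FALSE)
  if (strict && anyNA(out)) {
    bad <- smiles[is.na(out)][1]
    abort(paste0("invalid SMILES: '", bad, "'"), class = "lbvs_parse_error")
  }
  out
}

# single-string canonicalization through OpenBabel; NA on parse failure
.ob_canonical_one <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NA_character_)
  res <- suppressWarnings(tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste(s, "m")),
    error = function(e) ""))
  res <- sub("[\t ].*$", "", sub("\n$", "", res))
  if (!nzchar(res)) NA_character_ else res
}

#' Read a ligand corpus file
#'
#' Parses one of the supported corpus dialects into a molecule-record
#' table. Unparsable entries are skipped and counted (see attribute
#' `n_skipped`), not fatal; input order is preserved.
#'
#' Supported formats by extension: `.smi` (SMILES whitespace id), `.sdf`
#' (V2000), `.csv`/`.tsv` with dialect-specific columns:
#' \describe{
#'   \item{drugbank}{`id, smiles, type` (+ optional `name`); `type` is
#'     `small_molecule`, `biologic` or `unknown`.}
#'   \item{pdb}{`het_code, smiles` (+ optional `sdf_path`, `name`); if
#'     `sdf_path` points to an SDF file its first conformer's coordinates
#'     (Angstrom) are attached in the `coords` list-column.}
#'   \item{chembl}{`molecule_id, smiles, target_id, target_name, organism,
#'     assay_format, activity_type, value, units, relation`; distinct
#'     molecules are returned (use [read_activities()] for the activity
#'     rows).}
#' }
#'
#' @param path file path.
#' @param dialect one of `"drugbank"`, `"pdb"`, `"chembl"`, `"query"`.
#' @return a tibble of molecule records with columns `record_id`, `corpus`,
#'   `smiles`, `canonical_key`, `name`, `molecule_type`, `het_code` and a
#'   `coords` list-column (NULL when no 3D information is present), plus
#'   attribute `n_skipped`.
#' @export
read_corpus <- function(path, dialect = c("drugbank", "pdb", "chembl", "query")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("corpus file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    smi = .read_smi(path),
    sdf = .read_sdf_corpus(path),
    csv = ,
    tsv = .read_dialect_table(path, dialect, ext),
    abort(paste0("unsupported corpus format: .", ext)))
  .finalize_records(raw, dialect, path)
}

.read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  tibble(
    record_id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                       character(1)),
    smiles = vapply(parts, `[`, character(1), 1),
    name = NA_character_, molecule_type = NA_character_,
    het_code = NA_character_, coords = list(NULL))
}

.read_sdf_corpus <- function(path) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sdfs)
  n_bad <- sum(!valid)
  sdfs <- sdfs[valid]
  if (length(sdfs) == 0) {
    out <- tibble(record_id = character(), smiles = character(),
                  name = character(), molecule_type = character(),
                  het_code = character(), coords = list())
    attr(out, "n_skipped_pre") <- n_bad
    return(out)
  }
  ids <- unname(ChemmineR::sdfid(sdfs))
  smi <- vapply(seq_along(sdfs), function(i) {
    s <- suppressWarnings(tryCatch(
      as.character(ChemmineR::sdf2smiles(sdfs[i])),
      error = function(e) NA_character_))
    if (length(s) == 0) NA_character_ else s[1]
  }, character(1))
  coords <- lapply(seq_along(sdfs), function(i) {
    ab <- ChemmineR::atomblock(sdfs[[i]])
    elem <- sub("_.*$", "", rownames(ab))
    keep <- elem != "H"
    m <- ab[keep, 1:3, drop = FALSE]
    rownames(m) <- elem[keep]
    colnames(m) <- c("x", "y", "z")
    m
  })
  out <- tibble(record_id = ids, smiles = smi, name = ids,
                molecule_type = NA_character_, het_code = NA_character_,
                coords = coords)
  attr(out, "n_skipped_pre") <- n_bad
  out
}

.read_dialect_table <- function(path, dialect, ext) {
  reader <- if (ext == "csv") readr::read_csv else readr::read_tsv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  req <- switch(dialect,
    drugbank = c("id", "smiles", "type"),
    pdb = c("het_code", "smiles"),
    chembl = c("molecule_id", "smiles"),
    query = c("id", "smiles"))
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    abort(paste0("corpus file ", path, " lacks required ", dialect,
                 " column(s): ", paste(missing_cols, collapse = ", ")))
  switch(dialect,
    drugbank = tibble(
      record_id = as.character(df$id), smiles = as.character(df$smiles),
      name = as.character(if ("name" %in% names(df)) df$name else df$id),
      molecule_type = as.character(df$type),
      het_code = NA_character_, coords = list(NULL)),
    pdb = {
      coords <- if ("sdf_path" %in% names(df)) {
        lapply(df$sdf_path, function(p) {
          if (is.na(p) || !nzchar(p)) return(NULL)
          # relative SDF paths resolve against the corpus file location
          if (!file.exists(p))
            p <- file.path(dirname(path), p)
          if (!file.exists(p)) return(NULL)
          rec <- .read_sdf_corpus(p)
          if (nrow(rec) == 0) NULL else rec$coords[[1]]
        })
      } else rep(list(NULL), nrow(df))
      tibble(
        record_id = as.character(df$het_code), smiles = as.character(df$smiles),
        name = as.character(if ("name" %in% names(df)) df$name else df$het_code),
        molecule_type = NA_character_,
        het_code = as.character(df$het_code), coords = coords)
    },
    chembl = df %>%
      distinct(.data$molecule_id, .keep_all = TRUE) %>%
      with(tibble(
        record_id = as.character(molecule_id), smiles = as.character(smiles),
        name = as.character(molecule_id), molecule_type = NA_character_,
        het_code = NA_character_, coords = list(NULL))),
    query = tibble(
      record_id = as.character(df$id), smiles = as.character(df$smiles),
      name = as.character(if ("name" %in% names(df)) df$name else df$id),
      molecule_type = NA_character_, het_code = NA_character_,
      coords = list(NULL)))
}

.finalize_records <- function(raw, dialect, path) {
  n_pre <- attr(raw, "n_skipped_pre") %||% 0L
  keys <- canonicalize(raw$smiles, strict = FALSE)
  bad <- is.na(keys) | is.na(raw$record_id) | !nzchar(raw$record_id %||% "")
  n_skipped <- sum(bad) + n_pre
  out <- raw[!bad, , drop = FALSE]
  out$canonical_key <- keys[!bad]
  out$corpus <- dialect
  out <- out[, c("record_id", "corpus", "smiles", "canonical_key", "name",
                 "molecule_type", "het_code", "coords")]
  if (n_skipped > 0)
    inform(paste0("read_corpus(", dialect, "): skipped ", n_skipped,
                  " unparsable record(s) in ", path))
  if (nrow(out) == 0)
    abort(paste0("no parsable ", dialect, " records in ", path))
  attr(out, "n_skipped") <- as.integer(n_skipped)
  out
}

#' Read ChEMBL-dialect activity rows
#'
#' @param path CSV/TSV file with columns `molecule_id, smiles, target_id,
#'   target_name, organism, assay_format, activity_type, value, units,
#'   relation`.
#' @return tibble of activity rows (one per measurement).
#' @export
read_activities <- function(path) {
  if (!file.exists(path)) abort(paste0("activity file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  reader <- if (ext == "tsv") readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  req <- c("molecule_id", "smiles", "target_id", "assay_format",
           "activity_type", "value", "units", "relation")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    abort(paste0("activity file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  if (!"target_name" %in% names(df)) df$target_name <- df$target_id
  if (!"organism" %in% names(df)) df$organism <- NA_character_
  as_tibble(df) %>%
    mutate(value = as.numeric(.data$value))
}

#' Write a result table to disk
#'
#' Serializes similarity/summary tables so that they round-trip losslessly
#' through [read_table_file()]. Floating-point columns are written at six
#' significant digits.
#'
#' @param x data frame.
#' @param path output path.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], signif, digits = 6)
  ok <- tryCatch({
    switch(format,
      csv = utils::write.csv(x, path, row.names = FALSE, quote = TRUE),
      tsv = utils::write.table(x, path, row.names = FALSE, quote = TRUE,
                               sep = "\t"),
      json = jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                                  na = "null", auto_unbox = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(paste0("cannot write table to ", path))
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path file path; format inferred from extension.
#' @return tibble.
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) abort(paste0("table file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  out <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    json = as_tibble(jsonlite::fromJSON(path)),
    abort(paste0("unsupported table format: .", ext)))
  as_tibble(out)
}

#' Load a pipeline parameter file
#'
#' Reads a YAML or JSON configuration and attaches a `snapshot` attribute:
#' a short content hash recorded into every output table so results can be
#' traced back to the exact parameter set they were computed under.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return named list of parameters with attribute `snapshot`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    abort(paste0("unsupported config format: .", ext)))
  attr(cfg, "snapshot") <- param_snapshot(cfg)
  cfg
}

#' Parameter snapshot hash
#'
#' Deterministic 32-bit FNV-1a hash over the serialized parameter list,
#' rendered as 8 hex digits. Identical parameters always give the same
#' snapshot id.
#'
#' @param params named list.
#' @return length-1 character hash.
#' @export
param_snapshot <- function(params) {
  s <- paste(deparse(params[order(names(params))]), collapse = "")
  .fnv1a_hex(utf8ToInt(s))
}

# 32-bit FNV-1a in double arithmetic (exact below 2^53); the xor only ever
# touches the low byte because input bytes are < 256
.fnv1a_hex <- function(bytes) {
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
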