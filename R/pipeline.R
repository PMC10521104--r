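#' Assemble a pipeline configuration
#'
#' @param corpora named list of corpus file paths (`drugbank`, `pdb`,
#'   `chembl`; any subset).
#' @param annotations path to the target annotation CSV.
#' @param state_space path to the query state-space YAML (default: the
#'   shipped oxindole fixture).
#' @param thresholds [threshold_config()].
#' @param policy [conformer_policy()].
#' @param params [shape_params()].
#' @param tc_min TanimotoCombo consensus threshold.
#' @param nbits hashed fingerprint length.
#' @param min_corpora corpora required for a cross-corpus hit.
#' @param seed integer seed for the run.
#' @param skip_3d if `TRUE` the 3D stage is skipped and the consensus
#'   reduces to the 2D pass.
#' @return list of class `lbvs_pipeline_config`.
#' @export
pipeline_config <- function(corpora, annotations,
                            state_space = system.file(
                              "extdata", "oxindole_states.yaml",
                              package = "lbvs"),
                            thresholds = threshold_config(),
                            policy = conformer_policy(),
                            params = shape_params(),
                            tc_min = 1.2, nbits = 2048L, min_corpora = 3L,
                            seed = 1L, skip_3d = FALSE) {
  stopifnot(is.list(corpora), length(corpora) > 0, !is.null(names(corpora)))
  structure(list(corpora = corpora, annotations = annotations,
                 state_space = state_space, thresholds = thresholds,
                 policy = policy, params = params, tc_min = tc_min,
                 nbits = as.integer(nbits), min_corpora = as.integer(min_corpora),
                 seed = as.integer(seed), skip_3d = isTRUE(skip_3d)),
            class = "lbvs_pipeline_config")
}

#' Run the full repurposing pipeline
#'
#' Orchestrates curate, enumerate, 2D screen, 3D screen, consensus
#' merge, cross-corpus join and target ranking as one reproducible run.
#' Every intermediate table is written to `outdir`; rerunning with the
#' same inputs and seed reproduces the ranking byte for byte. A fatal
#' stage error aborts with the stage name; outputs of completed stages
#' are retained.
#'
#' @param config [pipeline_config()], or a path to a YAML/JSON file with
#'   the same fields.
#' @param outdir output directory (created).
#' @return invisibly, a list with the final ranking, the cross-corpus
#'   hits and the output paths.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- .config_from_file(config)
  stopifnot(inherits(config, "lbvs_pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) cat(paste0(..., "\n"), file = log_path, append = TRUE)
  unlink(log_path)

  stage <- function(name, expr) {
    logf("stage ", name, ": start")
    res <- tryCatch(expr, error = function(e) {
      logf("stage ", name, ": FAILED: ", conditionMessage(e))
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
    logf("stage ", name, ": done")
    res
  }

  cfg_list <- list(
    corpora = config$corpora, annotations = config$annotations,
    state_space = config$state_space,
    thresholds = as.list(unclass(config$thresholds)),
    policy = unclass(config$policy), tc_min = config$tc_min,
    nbits = config$nbits, min_corpora = config$min_corpora,
    seed = config$seed, skip_3d = config$skip_3d,
    shape_p = config$params$p, color_radius = config$params$color_radius)
  snapshot <- param_snapshot(cfg_list)
  jsonlite::write_json(c(cfg_list, list(snapshot = snapshot)),
                       file.path(outdir, "params_snapshot.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # ---- curate ----------------------------------------------------------
  curated <- stage("curate", {
    ccfg <- curation_config()
    out <- list()
    for (corp in names(config$corpora)) {
      recs <- read_corpus(config$corpora[[corp]], corp)
      out[[corp]] <- switch(corp,
        drugbank = filter_drugbank(recs),
        pdb = filter_pdb_ligands(recs, ccfg),
        chembl = recs,
        recs)
      write_table(out[[corp]][, setdiff(names(out[[corp]]), "coords")],
                  file.path(outdir, paste0("curated_", corp, ".csv")))
    }
    out
  })

  labels <- stage("labels", {
    if (!"chembl" %in% names(config$corpora)) {
      tibble::tibble(canonical_key = character(), target_id = character(),
                     label = character(), n_supporting_rows = integer())
    } else {
      rows <- read_activities(config$corpora$chembl)
      kept <- filter_chembl(rows, curation_config())
      lab <- label_ligands(kept, curation_config())
      write_table(lab, file.path(outdir, "chembl_labels.csv"))
      lab
    }
  })

  states <- stage("enumerate", {
    sp <- read_state_space(config$state_space)
    st <- enumerate_states(sp)
    write_table(st, file.path(outdir, "query_states.csv"))
    st
  })

  annotations <- stage("annotations", {
    read_table_file(config$annotations)
  })

  # ---- 2D and 3D screens per corpus -----------------------------------
  score_cache <- new.env(parent = emptyenv())
  merged <- list()
  for (corp in names(curated)) {
    refs <- curated[[corp]]
    t2d <- stage(paste0("fp2d_", corp), {
      t <- screen_2d(states, refs, config$thresholds, config$nbits)
      write_table(t, file.path(outdir, paste0("similarity2d_", corp, ".csv")))
      t
    })
    pass_pairs <- t2d[t2d$pass_2d, c("query_id", "reference_id")]
    if (config$skip_3d) {
      m <- t2d
      m$shape_tanimoto <- NA_real_
      m$color_tanimoto <- NA_real_
      m$tanimoto_combo <- NA_real_
      m$pass_consensus <- m$pass_2d
    } else {
      t3d <- stage(paste0("shape3d_", corp), {
        pol <- config$policy
        has_coords <- "coords" %in% names(refs) &&
          any(!vapply(refs$coords, is.null, logical(1)))
        direction <- if (corp == "pdb" && has_coords)
          "ref_crystal_vs_query_confs" else "query_confs_vs_ref_confs"
        n_q <- if (direction == "ref_crystal_vs_query_confs")
          pol$n_query_vs_pdb else pol$n_query_default
        n_r <- switch(corp, drugbank = pol$n_ref_drugbank,
                      chembl = pol$n_ref_chembl, pol$n_ref_chembl)
        t <- screen_3d(states, refs, n_conf_query = n_q, n_conf_ref = n_r,
                       direction = direction, tc_min = config$tc_min,
                       params = config$params, seed = pol$seed,
                       rmsd_dedup = pol$rmsd_dedup, pairs = pass_pairs,
                       score_cache = score_cache)
        write_table(t, file.path(outdir, paste0("similarity3d_", corp, ".csv")))
        t
      })
      m <- stage(paste0("consensus_", corp), merge_screens(t2d, t3d))
    }
    key_map <- stats::setNames(refs$canonical_key, refs$record_id)
    m$canonical_key <- unname(key_map[m$reference_id])
    write_table(m, file.path(outdir, paste0("consensus_", corp, ".csv")))
    merged[[corp]] <- m
  }

  # ---- cross-corpus join and hit report -------------------------------
  joined <- stage("join", join_across_corpora(merged))
  write_table(joined, file.path(outdir, "joined_references.csv"))
  xhits <- stage("cross_corpus",
                 cross_corpus_hits(joined, config$min_corpora))
  write_table(xhits, file.path(outdir, "cross_corpus_hits.csv"))
  jsonlite::write_json(xhits, file.path(outdir, "cross_corpus_hits.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  # ---- target ranking --------------------------------------------------
  hits_long <- dplyr::bind_rows(lapply(names(merged), function(corp) {
    m <- merged[[corp]][merged[[corp]]$pass_consensus, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    tibble::tibble(corpus = corp, reference_id = m$reference_id,
                   canonical_key = m$canonical_key)
  }))
  if (is.null(hits_long)) hits_long <- tibble::tibble(
    corpus = character(), reference_id = character(),
    canonical_key = character())
  hits_long <- dplyr::distinct(hits_long)
  write_table(hits_long, file.path(outdir, "consensus_hits.csv"))

  ranking <- stage("rank", {
    summ <- summarize_targets(hits_long, labels, annotations)
    if (nrow(summ) == 0) {
      tibble::tibble(target_id = character(), target_name = character(),
                     organism = character(), pdb_count = integer(),
                     db_count = integer(), chembl_active = integer(),
                     chembl_inactive = integer(), n_corpora = integer(),
                     active_minus_inactive = integer(), rank = integer())
    } else rank_targets(summ)
  })
  write_table(ranking, file.path(outdir, "target_ranking.csv"))
  logf("pipeline complete; snapshot ", snapshot)

  invisible(list(ranking = ranking, cross_corpus_hits = xhits,
                 outdir = outdir, snapshot = snapshot))
}

#' Pipeline configuration for a synthetic corpus directory
#'
#' Convenience wrapper binding a [generate_corpora()] output directory to
#' a [pipeline_config()] at the package's demonstration scale: conformer
#' caps of 3 per query state, 8 per ChEMBL/DrugBank reference and 6 query
#' conformers against crystallographic PDB ligands. Screening thresholds
#' are the standard defaults ([threshold_config()], TC >= 1.2).
#'
#' @param dir directory holding `drugbank.csv`, `pdb.csv`, `chembl.csv`
#'   and `annotations.csv`.
#' @param seed run seed (also used for conformer generation).
#' @param ... passed on to [pipeline_config()].
#' @return `lbvs_pipeline_config`.
#' @export
synthetic_pipeline_config <- function(dir, seed = 1L, ...) {
  pipeline_config(
    corpora = list(drugbank = file.path(dir, "drugbank.csv"),
                   pdb = file.path(dir, "pdb.csv"),
                   chembl = file.path(dir, "chembl.csv")),
    annotations = file.path(dir, "annotations.csv"),
    policy = conformer_policy(n_query_default = 3L, n_ref_chembl = 8L,
                              n_ref_drugbank = 8L, n_query_vs_pdb = 6L,
                              seed = as.integer(seed)),
    seed = as.integer(seed), ...)
}

.config_from_file <- function(path) {
  y <- load_config(path)
  pipeline_config(
    corpora = y$corpora,
    annotations = y$annotations,
    state_space = y$state_space %||% system.file(
      "extdata", "oxindole_states.yaml", package = "lbvs"),
    thresholds = do.call(threshold_config, y$thresholds %||% list()),
    policy = do.call(conformer_policy, y$policy %||% list()),
    params = do.call(shape_params, y$params %||% list()),
    tc_min = y$tc_min %||% 1.2,
    nbits = y$nbits %||% 2048L,
    min_corpora = y$min_corpora %||% 3L,
    seed = y$seed %||% 1L,
    skip_3d = isTRUE(y$skip_3d))
}
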