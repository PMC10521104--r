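#' Summarize consensus hits per candidate target
#'
#' Builds one row per protein target counting the distinct similar
#' molecules (by canonical structure key) found in each corpus, with
#' ChEMBL molecules split into actives and inactives by their resolved
#' labels. ChEMBL hits without a label are dropped with a log; hits
#' whose reference lacks a target annotation are tallied under
#' `"UNKNOWN"`.
#'
#' @param consensus_hits tibble of consensus-passing hit rows across
#'   corpora with columns `corpus`, `reference_id`, `canonical_key`.
#' @param labels labeled-ligand tibble from [label_ligands()]
#'   (`canonical_key`, `target_id`, `label`).
#' @param annotations target metadata for the non-ChEMBL corpora: tibble
#'   with `corpus`, `record_id`, `target_id`, `target_name`, `organism`.
#' @return tibble with `target_id` (accession), `target_name`, `organism`,
#'   `pdb_count`, `db_count`, `chembl_active`, `chembl_inactive`,
#'   `n_corpora`, `active_minus_inactive`.
#' @export
summarize_targets <- function(consensus_hits, labels, annotations) {
  empty <- tibble::tibble(
    target_id = character(), target_name = character(),
    organism = character(), pdb_count = integer(), db_count = integer(),
    chembl_active = integer(), chembl_inactive = integer(),
    n_corpora = integer(), active_minus_inactive = integer())
  if (nrow(consensus_hits) == 0) return(empty)

  hits <- tibble::as_tibble(consensus_hits)
  per_target <- list()

  # DrugBank / PDB hits map to targets through the annotation table
  for (corp in c("drugbank", "pdb")) {
    h <- hits[hits$corpus == corp, , drop = FALSE]
    if (nrow(h) == 0) next
    ann <- annotations[annotations$corpus == corp, , drop = FALSE]
    h <- dplyr::left_join(h, ann[, c("record_id", "target_id",
                                     "target_name", "organism")],
                          by = c("reference_id" = "record_id"))
    unk <- is.na(h$target_id)
    if (any(unk)) {
      rlang::inform(paste0("summarize_targets: ", sum(unk), " ", corp,
                           " hit(s) without target annotation -> UNKNOWN"))
      h$target_id[unk] <- "UNKNOWN"
      h$target_name[unk] <- "UNKNOWN"
    }
    per_target[[corp]] <- h %>%
      dplyr::group_by(.data$target_id, .data$target_name, .data$organism) %>%
      dplyr::summarise(n = dplyr::n_distinct(.data$canonical_key),
                       .groups = "drop") %>%
      dplyr::mutate(corpus = corp, label = NA_character_)
  }

  # ChEMBL hits carry activity labels per (molecule, target)
  h <- hits[hits$corpus == "chembl", , drop = FALSE]
  if (nrow(h) > 0) {
    h <- dplyr::inner_join(h["canonical_key"] %>% dplyr::distinct(),
                           labels, by = "canonical_key")
    n_unlabeled <- dplyr::n_distinct(
      setdiff(hits$canonical_key[hits$corpus == "chembl"], h$canonical_key))
    if (n_unlabeled > 0)
      rlang::inform(paste0("summarize_targets: ", n_unlabeled,
                           " chembl hit(s) without activity label dropped"))
    if (nrow(h) > 0) {
      ann <- annotations[annotations$corpus == "chembl", , drop = FALSE]
      h <- dplyr::left_join(
        h, dplyr::distinct(ann[, c("target_id", "target_name", "organism")]),
        by = "target_id")
      per_target[["chembl"]] <- h %>%
        dplyr::group_by(.data$target_id, .data$target_name, .data$organism,
                        .data$label) %>%
        dplyr::summarise(n = dplyr::n_distinct(.data$canonical_key),
                         .groups = "drop") %>%
        dplyr::mutate(corpus = "chembl")
    }
  }

  long <- dplyr::bind_rows(per_target)
  if (nrow(long) == 0) return(empty)
  long$target_name[is.na(long$target_name)] <- long$target_id[is.na(long$target_name)]
  long$organism[is.na(long$organism)] <- "unknown"

  out <- long %>%
    dplyr::group_by(.data$target_id) %>%
    dplyr::summarise(
      target_name = .data$target_name[1],
      organism = .data$organism[1],
      pdb_count = sum(.data$n[.data$corpus == "pdb"]),
      db_count = sum(.data$n[.data$corpus == "drugbank"]),
      chembl_active = sum(.data$n[.data$corpus == "chembl" &
                                    .data$label == "active"], na.rm = TRUE),
      chembl_inactive = sum(.data$n[.data$corpus == "chembl" &
                                      .data$label == "inactive"],
                            na.rm = TRUE),
      .groups = "drop") %>%
    dplyr::mutate(
      dplyr::across(dplyr::all_of(c("pdb_count", "db_count", "chembl_active",
                                    "chembl_inactive")), as.integer),
      n_corpora = (.data$pdb_count > 0) + (.data$db_count > 0) +
        (.data$chembl_active + .data$chembl_inactive > 0),
      active_minus_inactive = .data$chembl_active - .data$chembl_inactive)
  out[order(out$target_id), , drop = FALSE]
}

#' Rank candidate targets for repurposing
#'
#' Orders target summaries by descending lexicographic key: number of
#' corpora contributing hits (multi-database evidence first), the
#' active-minus-inactive difference (more potent-inhibitor support
#' first), total ligand count, then ChEMBL active count; remaining ties
#' break alphabetically by accession, making the order total and stable.
#'
#' @param summaries tibble from [summarize_targets()].
#' @return `summaries` with a `rank` column, in rank order.
#' @export
rank_targets <- function(summaries) {
  stopifnot(nrow(summaries) > 0)
  total <- summaries$pdb_count + summaries$db_count +
    summaries$chembl_active + summaries$chembl_inactive
  ord <- order(-summaries$n_corpora, -summaries$active_minus_inactive,
               -total, -summaries$chembl_active, summaries$target_id)
  out <- summaries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
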