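#' Merge the 2D and 3D screens of one corpus
#'
#' Joins the two similarity tables on (query, reference) and sets
#' `pass_consensus = pass_2d AND pass_3d`. A pair present in only one
#' table fails the consensus (and is logged); duplicate keys inside
#' either table indicate an upstream bug and are fatal.
#'
#' @param table_2d output of [screen_2d()].
#' @param table_3d output of [screen_3d()].
#' @return tibble with all 2D columns, the 3D scores and
#'   `pass_consensus`.
#' @export
merge_screens <- function(table_2d, table_3d) {
  k2 <- paste(table_2d$query_id, table_2d$reference_id)
  k3 <- paste(table_3d$query_id, table_3d$reference_id)
  if (anyDuplicated(k2) || anyDuplicated(k3))
    rlang::abort("merge_screens: duplicate (query, reference) keys")
  out <- dplyr::full_join(table_2d, table_3d,
                          by = c("query_id", "reference_id"))
  n_partial <- sum(is.na(out$pass_2d)) + sum(is.na(out$pass_3d))
  if (n_partial > 0)
    rlang::inform(paste0("merge_screens: ", n_partial,
                         " pair(s) present in only one screen fail consensus"))
  out$pass_consensus <- !is.na(out$pass_2d) & out$pass_2d &
    !is.na(out$pass_3d) & out$pass_3d
  out[order(out$query_id, out$reference_id), , drop = FALSE]
}

#' Join hit lists across corpora by canonical structure key
#'
#' Groups reference molecules from several per-corpus similarity tables
#' by their canonical isomeric SMILES key, listing each group's
#' per-corpus native identifiers and best scores. This is how one
#' physical molecule catalogued under different identifiers (a DrugBank
#' accession, a PDB HET code, a ChEMBL id) is recognized as a single
#' entity.
#'
#' @param hitlists named list, corpus name -> merged similarity table
#'   (from [merge_screens()]) that carries a `canonical_key` column for
#'   its references.
#' @return tibble with one row per (canonical_key, corpus):
#'   `canonical_key`, `corpus`, `reference_ids` (collapsed `;`),
#'   `best_tanimoto_combo`, `n_pairs`, `any_consensus`.
#' @export
join_across_corpora <- function(hitlists) {
  stopifnot(is.list(hitlists), !is.null(names(hitlists)))
  rows <- lapply(names(hitlists), function(corpus) {
    tab <- hitlists[[corpus]]
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    if (!"canonical_key" %in% names(tab))
      rlang::abort("join_across_corpora: tables need a canonical_key column")
    tab %>%
      dplyr::group_by(.data$canonical_key) %>%
      dplyr::summarise(
        corpus = corpus,
        reference_ids = paste(sort(unique(.data$reference_id)),
                              collapse = ";"),
        best_tanimoto_combo = if (all(is.na(.data$tanimoto_combo)))
          NA_real_ else max(.data$tanimoto_combo, na.rm = TRUE),
        n_pairs = dplyr::n(),
        any_consensus = any(.data$pass_consensus),
        .groups = "drop")
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    return(tibble::tibble(canonical_key = character(), corpus = character(),
                          reference_ids = character(),
                          best_tanimoto_combo = numeric(),
                          n_pairs = integer(), any_consensus = logical()))
  out[order(out$canonical_key, out$corpus), , drop = FALSE]
}

#' Cross-corpus consensus hits
#'
#' Returns the structure groups whose consensus-passing entries span at
#' least `min_corpora` corpora, ordered by best TanimotoCombo
#' (descending). With the default of 3 this surfaces molecules
#' independently catalogued in all three databases -- the strongest
#' repurposing candidates.
#'
#' @param joined output of [join_across_corpora()].
#' @param min_corpora minimum number of corpora with a consensus pass.
#' @return tibble with `canonical_key`, `n_corpora`, `corpora`
#'   (collapsed `;`), `best_tanimoto_combo`, per-corpus id strings.
#' @export
cross_corpus_hits <- function(joined, min_corpora = 3L) {
  if (nrow(joined) == 0)
    return(tibble::tibble(canonical_key = character(), n_corpora = integer(),
                          corpora = character(),
                          best_tanimoto_combo = numeric()))
  hits <- joined[joined$any_consensus, , drop = FALSE]
  out <- hits %>%
    dplyr::group_by(.data$canonical_key) %>%
    dplyr::summarise(
      n_corpora = dplyr::n_distinct(.data$corpus),
      corpora = paste(sort(unique(.data$corpus)), collapse = ";"),
      ids = paste(paste0(.data$corpus, ":", .data$reference_ids),
                  collapse = ";"),
      best_tanimoto_combo = if (all(is.na(.data$best_tanimoto_combo)))
        NA_real_ else max(.data$best_tanimoto_combo, na.rm = TRUE),
      .groups = "drop") %>%
    dplyr::filter(.data$n_corpora >= min_corpora) %>%
    dplyr::arrange(dplyr::desc(.data$best_tanimoto_combo),
                   .data$canonical_key)
  out
}
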