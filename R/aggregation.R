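#' Vote-aggregation parameters
#'
#' @param vote_threshold minimum positive votes for a relation to be
#'   predicted true (default 4 of 5).
#' @param judgments_per_task trusted judgments expected per task (default 5).
#' @return an `aggregation_config` list.
#' @export
aggregation_config <- function(vote_threshold = 4L, judgments_per_task = 5L) {
  stopifnot(vote_threshold >= 0, judgments_per_task >= 1)
  structure(list(vote_threshold = as.integer(vote_threshold),
                 judgments_per_task = as.integer(judgments_per_task)),
            class = "aggregation_config")
}

#' Tally trusted judgments into per-relation vote counts
#'
#' Only `yes_cid` counts as a positive vote; `no_relation` and
#' `chained_induction` are both negative.  Votes are first tallied per task;
#' for a sentence-scoped relation — which may have several tasks, one per
#' co-occurring sentence — the task with the most positive votes represents
#' the relation (the relation is taken to hold for the abstract if at least
#' one sentence supports it).
#'
#' @param judgments judgment tibble (`task_id`, `worker_id`, `choice`,
#'   `trusted`).
#' @param tasks the task tibble the judgments answer.
#' @param judgments_per_task trusted judgments required per task; a task
#'   with any other count raises an error naming it.
#' @return tally tibble: `doc_id`, `chemical_id`, `disease_id`, `scope`,
#'   `positive_votes`, `per_sentence_votes` (list column of
#'   `sentence_index` / `positive_votes` tibbles; empty for abstract scope).
#' @export
tally_votes <- function(judgments, tasks, judgments_per_task = 5L) {
  trusted <- judgments[judgments$trusted, ]
  n_by_task <- table(factor(trusted$task_id, levels = tasks$task_id))
  bad <- names(n_by_task)[n_by_task != judgments_per_task]
  if (length(bad)) {
    stop(sprintf("task %s has %d trusted judgments, expected %d",
                 bad[1], n_by_task[[bad[1]]], judgments_per_task))
  }
  pos_by_task <- tapply(trusted$choice == "yes_cid",
                        factor(trusted$task_id, levels = tasks$task_id), sum)
  per_task <- mutate(tasks, positive_votes = as.integer(pos_by_task[.data$task_id]))
  per_task |>
    group_by(.data$doc_id, .data$chemical_id, .data$disease_id, .data$scope) |>
    summarise(per_sentence_votes = {
      si <- .data$sentence_index
      pv <- .data$positive_votes
      list(tibble(sentence_index = si[!is.na(si)],
                  positive_votes = pv[!is.na(si)]))
    },
    positive_votes = max(.data$positive_votes),
    .groups = "drop") |>
    select("doc_id", "chemical_id", "disease_id", "scope",
           "positive_votes", "per_sentence_votes") |>
    arrange(.data$doc_id, .data$chemical_id, .data$disease_id)
}

#' Decide the final predicted relation set
#'
#' Relations with at least `vote_threshold` positive votes (sentence or
#' abstract scope) are united with the auto-accepted pattern relations;
#' duplicates collapse (set semantics).
#'
#' @param tallies tally tibble from [tally_votes()].
#' @param pattern_relations triples auto-accepted by the CID pattern.
#' @param config an [aggregation_config()].
#' @return tibble of predicted triples (`doc_id`, `chemical_id`,
#'   `disease_id`).
#' @export
decide_relations <- function(tallies, pattern_relations = empty_triples(),
                             config = aggregation_config()) {
  voted <- tallies[tallies$positive_votes >= config$vote_threshold,
                   c("doc_id", "chemical_id", "disease_id")]
  out <- distinct(bind_rows(
    voted, pattern_relations[, c("doc_id", "chemical_id", "disease_id")]))
  arrange(out, .data$doc_id, .data$chemical_id, .data$disease_id)
}

#' Export vote tallies as TSV
#'
#' @param tallies tally tibble from [tally_votes()].
#' @param path output path.
#' @return the flat tibble written, invisibly.
#' @export
export_tallies <- function(tallies, path) {
  flat <- tallies |>
    mutate(per_sentence_votes = map_chr(.data$per_sentence_votes, function(d) {
      paste(sprintf("%d=%d", d$sentence_index, d$positive_votes),
            collapse = ",")
    }))
  readr::write_tsv(flat, path)
  invisible(flat)
}
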