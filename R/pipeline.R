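#' Run the end-to-end crowd CID extraction workflow
#'
#' Executes the full chain on a parsed corpus: acronym resolution ->
#' MeSH filtering -> candidate pair generation -> lexical pattern
#' auto-accept and sentence/abstract routing -> task building -> simulated
#' crowd judgments -> threshold-vote aggregation -> evaluation against the
#' corpus gold relations (micro P/R/F, maximum theoretical recall, ROC/AUC
#' over vote thresholds).  Deterministic given the simulator seed.
#'
#' @param corpus a [cid_corpus()] whose `relations` table is the gold
#'   standard.
#' @param workers a [worker_pool()].
#' @param sim a [sim_config()].
#' @param pattern a [pattern_config()].
#' @param acronym an [acronym_rule_config()], or `NULL` to skip acronym
#'   resolution.
#' @param aggregation an [aggregation_config()].
#' @param oracle optional truth oracle; defaults to [oracle_from_gold()].
#' @param thresholds vote thresholds for the ROC sweep.
#' @param outdir optional directory; when given, every intermediate artifact
#'   (candidates, tasks, judgments, worker ledger, tallies, predictions as
#'   CID lines, evaluation summary) is written there deterministically.
#' @return list with elements `annotations` (post-processed), `candidates`,
#'   `sentences`, `pattern_relations`, `tasks`, `judgments`, `ledger`,
#'   `tallies`, `predictions`, `prf`, `max_recall`, `roc`, `auc`.
#' @export
run_cid_pipeline <- function(corpus, workers, sim = sim_config(),
                             pattern = pattern_config(),
                             acronym = acronym_rule_config(),
                             aggregation = aggregation_config(),
                             oracle = NULL, thresholds = 6:0,
                             outdir = NULL) {
  sim$judgments_per_task <- aggregation$judgments_per_task
  resolved <- if (is.null(acronym)) corpus else resolve_acronyms(corpus, acronym)
  ann <- exclude_non_mesh(resolved$annotations)
  routed <- route_candidates(resolved, pattern, annotations = ann)
  candidates <- routed$candidates
  pattern_relations <- candidates[candidates$scope == "pattern",
                                  c("doc_id", "chemical_id", "disease_id")]
  crowd_cand <- candidates[candidates$scope != "pattern", ]
  tasks <- build_tasks(crowd_cand, resolved, annotations = ann,
                       sentences = routed$sentences)
  if (is.null(oracle)) oracle <- oracle_from_gold(tasks, corpus$relations)
  simres <- simulate_judgments(tasks, oracle, workers, sim)
  tallies <- tally_votes(simres$judgments, tasks, sim$judgments_per_task)
  predictions <- decide_relations(tallies, pattern_relations, aggregation)
  prf <- relation_prf(predictions, corpus$relations)
  mr <- max_recall(candidates, corpus$relations)
  roc <- NULL; auc <- NA_real_
  ok_roc <- nrow(corpus$relations) > 0 &&
    nrow(candidates) > sum(triple_key(candidates) %in%
                             triple_key(corpus$relations))
  if (ok_roc) {
    roc <- roc_points(tallies, candidates, corpus$relations, thresholds,
                      pattern_votes = sim$judgments_per_task)
    auc <- roc_auc(roc)
  }
  out <- list(annotations = ann, candidates = candidates,
              sentences = routed$sentences,
              pattern_relations = pattern_relations, tasks = tasks,
              judgments = simres$judgments, ledger = simres$ledger,
              tallies = tallies, predictions = predictions, prf = prf,
              max_recall = mr, roc = roc, auc = auc)
  if (!is.null(outdir)) write_pipeline_outputs(out, resolved, outdir)
  out
}

write_pipeline_outputs <- function(res, corpus, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  export_candidates(res$candidates, p("candidates.tsv"))
  export_tasks(res$tasks, corpus, p("tasks.csv"))
  readr::write_csv(res$judgments, p("judgments.csv"))
  readr::write_csv(res$ledger, p("worker_ledger.csv"))
  export_tallies(res$tallies, p("tallies.tsv"))
  readr::write_tsv(res$predictions, p("predictions.tsv"))
  write_cid_lines(res$predictions, p("predictions.pubtator"))
  if (!is.null(res$roc)) readr::write_tsv(res$roc, p("roc_points.tsv"))
  summary_lines <- c(
    sprintf("documents\t%d", nrow(corpus$documents)),
    sprintf("candidates_pattern\t%d", sum(res$candidates$scope == "pattern")),
    sprintf("candidates_sentence\t%d", sum(res$candidates$scope == "sentence")),
    sprintf("candidates_abstract\t%d", sum(res$candidates$scope == "abstract")),
    sprintf("tasks\t%d", nrow(res$tasks)),
    sprintf("workers_removed\t%d", sum(res$ledger$removed, na.rm = TRUE)),
    sprintf("predictions\t%d", nrow(res$predictions)),
    sprintf("precision\t%.6f", res$prf$precision),
    sprintf("recall\t%.6f", res$prf$recall),
    sprintf("f1\t%.6f", res$prf$f1),
    sprintf("max_recall\t%.6f", res$max_recall),
    sprintf("auc\t%.6f", res$auc))
  writeLines(summary_lines, p("summary.tsv"))
  invisible(res)
}
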