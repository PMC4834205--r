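#' Build a pool of simulated workers
#'
#' @param n number of workers.
#' @param accuracy probability (recycled over workers) that a worker answers
#'   any item — quiz question, hidden test question or real task — correctly.
#' @param id_prefix prefix for generated worker IDs.
#' @return tibble `worker_id`, `accuracy`.
#' @export
worker_pool <- function(n, accuracy, id_prefix = "w") {
  stopifnot(n >= 1, all(accuracy >= 0), all(accuracy <= 1))
  tibble(worker_id = sprintf("%s%04d", id_prefix, seq_len(n)),
         accuracy = rep_len(accuracy, n))
}

#' Crowd-simulation parameters
#'
#' Defaults mirror the quality gates of a managed crowd platform: a
#' six-question admission quiz, hidden test questions at a 10% rate, and
#' removal (with judgment invalidation) once a worker's running test
#' accuracy drops below 70%.
#'
#' @param judgments_per_task trusted judgments required per task (default 5).
#' @param quiz_size admission quiz length (default 6).
#' @param quiz_pass_min_correct minimum correct quiz answers to be admitted
#'   (default 5, i.e. 70% of six rounded up).
#' @param accuracy_floor minimum running test-question accuracy (default
#'   0.70).
#' @param test_question_rate probability a hidden test question precedes a
#'   task in the stream (default 0.10).
#' @param min_test_answers test answers required before the floor can
#'   trigger removal (default 4).
#' @param rng_seed integer seed; the simulation is fully deterministic given
#'   the seed and inputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(judgments_per_task = 5L, quiz_size = 6L,
                       quiz_pass_min_correct = 5L, accuracy_floor = 0.70,
                       test_question_rate = 0.10, min_test_answers = 4L,
                       rng_seed = 1L) {
  stopifnot(quiz_pass_min_correct <= quiz_size,
            accuracy_floor > 0, accuracy_floor <= 1,
            test_question_rate >= 0, test_question_rate < 1,
            judgments_per_task >= 1)
  structure(list(judgments_per_task = as.integer(judgments_per_task),
                 quiz_size = as.integer(quiz_size),
                 quiz_pass_min_correct = as.integer(quiz_pass_min_correct),
                 accuracy_floor = accuracy_floor,
                 test_question_rate = test_question_rate,
                 min_test_answers = as.integer(min_test_answers),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Truth oracle derived from gold relations
#'
#' A task's correct choice is `yes_cid` iff its (document, chemical,
#' disease) triple is in the gold standard, else `no_relation` — a
#' perfectly informed crowd.
#'
#' @param tasks task tibble from [build_tasks()].
#' @param gold gold relation tibble.
#' @return named character vector, task_id -> correct choice.
#' @export
oracle_from_gold <- function(tasks, gold) {
  in_gold <- triple_key(tasks) %in% triple_key(gold)
  setNames(ifelse(in_gold, "yes_cid", "no_relation"), tasks$task_id)
}

#' Simulate a quality-gated crowd answering the task stream
#'
#' Workers are processed in pool order.  Each first sits the admission quiz
#' (each question answered correctly with probability equal to their
#' accuracy); failures contribute nothing.  An admitted worker then streams
#' through tasks still needing judgments (at most one judgment per worker
#' per task), with hidden test questions interleaved at
#' `test_question_rate`.  After each test answer — once at least
#' `min_test_answers` have accumulated — a worker whose running test
#' accuracy is below `accuracy_floor` is removed: all their judgments are
#' marked untrusted and the affected tasks return to the queue for
#' replacement workers.  The simulation ends when every task holds exactly
#' `judgments_per_task` trusted judgments; if the pool runs out first an
#' error reports the number of unfilled tasks.  A wrong answer is drawn
#' uniformly from the task's other choices.
#'
#' @param tasks task tibble from [build_tasks()].
#' @param oracle named vector task_id -> correct choice (see
#'   [oracle_from_gold()]), or a function of a task row returning a choice.
#' @param workers tibble from [worker_pool()].
#' @param config a [sim_config()].
#' @return list with `judgments` (tibble `task_id`, `worker_id`, `choice`,
#'   `trusted`) and `ledger` (per-worker tibble `worker_id`, `accuracy`,
#'   `quiz_passed`, `removed`, `n_judgments`, `n_test`, `n_test_correct`).
#' @export
simulate_judgments <- function(tasks, oracle, workers,
                               config = sim_config()) {
  correct_choice <- if (is.function(oracle)) {
    map_chr(seq_len(nrow(tasks)), function(i) oracle(tasks[i, ]))
  } else {
    unname(oracle[tasks$task_id])
  }
  if (anyNA(correct_choice) && nrow(tasks)) {
    stop("oracle undefined for some tasks")
  }
  choice_sets <- map(tasks$scope, choices_for_scope)
  ok <- unlist(map2(correct_choice, choice_sets, `%in%`))
  bad <- which(!ok)
  if (length(bad)) {
    stop("oracle choice not in task's choice set for task ",
         tasks$task_id[bad[1]])
  }
  withr::with_seed(config$rng_seed, {
    n_tasks <- nrow(tasks)
    need <- rep(config$judgments_per_task, n_tasks)
    j_task <- integer(0); j_worker <- character(0)
    j_choice <- character(0); j_trusted <- logical(0)
    ledger <- vector("list", nrow(workers))
    for (w in seq_len(nrow(workers))) {
      if (!any(need > 0L)) {
        ledger[[w]] <- worker_ledger_row(workers[w, ], NA, FALSE, 0L, 0L, 0L)
        next
      }
      acc <- workers$accuracy[w]
      quiz_correct <- rbinom(1L, config$quiz_size, acc)
      passed <- quiz_correct >= config$quiz_pass_min_correct
      if (!passed) {
        ledger[[w]] <- worker_ledger_row(workers[w, ], FALSE, FALSE, 0L, 0L, 0L)
        next
      }
      avail <- which(need > 0L)
      my_task <- integer(length(avail)); my_choice <- character(length(avail))
      n_mine <- 0L
      test_n <- 0L; test_c <- 0L; removed <- FALSE
      for (ti in avail) {
        if (config$test_question_rate > 0 &&
            runif(1L) < config$test_question_rate) {
          ok <- runif(1L) < acc
          test_n <- test_n + 1L
          test_c <- test_c + as.integer(ok)
          if (test_n >= config$min_test_answers &&
              test_c / test_n < config$accuracy_floor) {
            removed <- TRUE
            break
          }
        }
        ch <- if (runif(1L) < acc) {
          correct_choice[ti]
        } else {
          others <- setdiff(choice_sets[[ti]], correct_choice[ti])
          others[sample.int(length(others), 1L)]
        }
        n_mine <- n_mine + 1L
        my_task[n_mine] <- ti
        my_choice[n_mine] <- ch
        need[ti] <- need[ti] - 1L
      }
      my_task <- my_task[seq_len(n_mine)]
      my_choice <- my_choice[seq_len(n_mine)]
      if (removed) need[my_task] <- need[my_task] + 1L
      j_task <- c(j_task, my_task)
      j_worker <- c(j_worker, rep(workers$worker_id[w], n_mine))
      j_choice <- c(j_choice, my_choice)
      j_trusted <- c(j_trusted, rep(!removed, n_mine))
      ledger[[w]] <- worker_ledger_row(workers[w, ], TRUE, removed, n_mine,
                                       test_n, test_c)
    }
    if (any(need > 0L)) {
      stop(sprintf(
        "worker pool exhausted: %d task(s) still lack trusted judgments",
        sum(need > 0L)))
    }
    list(judgments = tibble(task_id = tasks$task_id[j_task],
                            worker_id = j_worker, choice = j_choice,
                            trusted = j_trusted),
         ledger = bind_rows(ledger))
  })
}

worker_ledger_row <- function(worker, quiz_passed, removed, n_judgments,
                              n_test, n_test_correct) {
  tibble(worker_id = worker$worker_id, accuracy = worker$accuracy,
         quiz_passed = quiz_passed, removed = removed,
         n_judgments = as.integer(n_judgments), n_test = as.integer(n_test),
         n_test_correct = as.integer(n_test_correct))
}
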