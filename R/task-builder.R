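sentence_choices <- c("yes_cid", "no_relation", "chained_induction")
abstract_choices <- c("yes_cid", "no_relation")

choices_for_scope <- function(scope) {
  if (scope == "sentence") sentence_choices else abstract_choices
}

#' Materialize routed candidates as crowd judgment tasks
#'
#' Sentence-scoped pairs yield one task per co-occurring sentence; abstract
#' pairs yield one task showing the whole combined text.  Every mention of
#' the pair's chemical and disease inside the task's unit is highlighted.
#' Sentence tasks carry three choices — `yes_cid`, `no_relation`, and
#' `chained_induction` for "chemical-induced intermediate causes disease"
#' chains (counted as negative at aggregation time) — abstract tasks carry
#' two.
#'
#' @param candidates routed candidates with scope `sentence` or `abstract`
#'   (see [route_candidates()]); `pattern` rows are rejected.
#' @param corpus the [cid_corpus()] the candidates came from.
#' @param annotations annotation table used for highlighting (default the
#'   corpus annotations; pass the MeSH-filtered table used for routing).
#' @param sentences sentence spans (recomputed when `NULL`).
#' @return a task tibble: `task_id`, `doc_id`, `chemical_id`, `disease_id`,
#'   `scope`, `sentence_index` (`NA` for abstract tasks), `unit_start`,
#'   `unit_end`, `choices` (codes joined by `|`), `highlights` (list column
#'   of unit-relative 0-based spans with class), `is_test_question`,
#'   `expected_choice`.
#' @export
build_tasks <- function(candidates, corpus,
                        annotations = corpus$annotations, sentences = NULL) {
  if (any(candidates$scope == "pattern")) {
    stop("pattern-scoped candidates are auto-accepted, not shown to a crowd")
  }
  docs <- corpus$documents
  rows <- list()
  for (k in seq_len(nrow(candidates))) {
    cd <- candidates[k, ]
    d <- docs[docs$doc_id == cd$doc_id, ]
    if (!nrow(d)) stop("candidate references unknown document ", cd$doc_id)
    ann <- annotations[annotations$doc_id == cd$doc_id, ]
    units <- if (cd$scope == "sentence") {
      sents <- if (is.null(sentences)) {
        split_sentences(d$title, d$abstract, d$doc_id)
      } else {
        sentences[sentences$doc_id == cd$doc_id, ]
      }
      idx <- cd$sentence_indices[[1]]
      lapply(idx, function(i) {
        s <- sents[sents$index == i, ]
        list(index = i, start = s$start, end = s$end)
      })
    } else {
      list(list(index = NA_integer_, start = 0L, end = nchar(d$text)))
    }
    for (u in units) {
      hl <- pair_highlights(ann, cd$chemical_id, cd$disease_id,
                            u$start, u$end)
      if (!any(hl$class == "chemical") || !any(hl$class == "disease")) {
        stop(sprintf(
          "task for %s (%s, %s): pair has no highlightable mention in unit [%d,%d)",
          cd$doc_id, cd$chemical_id, cd$disease_id, u$start, u$end))
      }
      rows[[length(rows) + 1L]] <- tibble(
        task_id = paste(cd$doc_id, cd$chemical_id, cd$disease_id, cd$scope,
                        ifelse(is.na(u$index), "A", u$index), sep = ":"),
        doc_id = cd$doc_id, chemical_id = cd$chemical_id,
        disease_id = cd$disease_id, scope = cd$scope,
        sentence_index = as.integer(u$index),
        unit_start = as.integer(u$start), unit_end = as.integer(u$end),
        choices = paste(choices_for_scope(cd$scope), collapse = "|"),
        highlights = list(hl),
        is_test_question = FALSE, expected_choice = NA_character_)
    }
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(
    task_id = character(), doc_id = character(), chemical_id = character(),
    disease_id = character(), scope = character(),
    sentence_index = integer(), unit_start = integer(), unit_end = integer(),
    choices = character(), highlights = list(),
    is_test_question = logical(), expected_choice = character())
  arrange(out, .data$doc_id, .data$chemical_id, .data$disease_id,
          .data$sentence_index)
}

# unit-relative highlight spans for both concepts of a pair
pair_highlights <- function(ann, chemical_id, disease_id, unit_start,
                            unit_end) {
  sel <- (ann$concept_class == "chemical" &
            map_lgl(ann$concept_ids, function(v) chemical_id %in% v)) |
    (ann$concept_class == "disease" &
       map_lgl(ann$concept_ids, function(v) disease_id %in% v))
  sel <- sel & ann$start >= unit_start & ann$start < unit_end
  hl <- ann[sel, ]
  tibble(start = hl$start - unit_start,
         end = pmin(hl$end, unit_end) - unit_start,
         class = hl$concept_class) |>
    distinct() |>
    arrange(.data$start, .data$end)
}

#' Render highlighted task text
#'
#' Wraps each span in a class-labelled tag (`<chemical>...</chemical>`,
#' `<disease>...</disease>`).  [strip_highlight()] inverts the markup
#' exactly.
#'
#' @param unit_text the task's unit text.
#' @param highlights tibble of unit-relative 0-based spans (`start`, `end`,
#'   `class`), non-overlapping.
#' @return the markup string; overlapping spans raise an error.
#' @export
render_highlight <- function(unit_text, highlights) {
  if (!nrow(highlights)) return(unit_text)
  hl <- arrange(highlights, .data$start, .data$end)
  if (any(hl$start[-1] < hl$end[-nrow(hl)])) {
    stop("overlapping highlight spans")
  }
  if (any(hl$start < 0L) || any(hl$end > nchar(unit_text))) {
    stop("highlight span outside unit text")
  }
  pieces <- character(0)
  pos <- 0L
  for (i in seq_len(nrow(hl))) {
    pieces <- c(pieces,
                slice_text(unit_text, pos, hl$start[i]),
                paste0("<", hl$class[i], ">",
                       slice_text(unit_text, hl$start[i], hl$end[i]),
                       "</", hl$class[i], ">"))
    pos <- hl$end[i]
  }
  paste0(paste(pieces, collapse = ""),
         slice_text(unit_text, pos, nchar(unit_text)))
}

#' @rdname render_highlight
#' @param markup a string produced by `render_highlight()`.
#' @export
strip_highlight <- function(markup) {
  gsub("</?(chemical|disease)>", "", markup)
}

#' Export and re-import crowd tasks as CSV
#'
#' One row per task in deterministic order, including the rendered unit
#' markup.  `import_tasks()` recovers task IDs, spans, choices and
#' highlights exactly.
#'
#' @param tasks task tibble from [build_tasks()].
#' @param corpus the corpus the tasks refer to (for unit text).
#' @param path CSV path.
#' @return `export_tasks()` the flat tibble written, invisibly;
#'   `import_tasks()` the task tibble (without rendered text).
#' @export
export_tasks <- function(tasks, corpus, path) {
  text_of <- setNames(corpus$documents$text, corpus$documents$doc_id)
  unit_text <- map_chr(seq_len(nrow(tasks)), function(i) {
    slice_text(text_of[[tasks$doc_id[i]]], tasks$unit_start[i],
               tasks$unit_end[i])
  })
  rendered <- map_chr(seq_len(nrow(tasks)), function(i) {
    render_highlight(unit_text[i], tasks$highlights[[i]])
  })
  flat <- tasks |>
    mutate(unit_markup = if (nrow(tasks)) rendered else character(),
           highlights = map_chr(.data$highlights, serialize_highlights))
  readr::write_csv(flat, path, na = "")
  invisible(flat)
}

serialize_highlights <- function(hl) {
  paste(sprintf("%d:%d:%s", hl$start, hl$end, hl$class), collapse = ";")
}

deserialize_highlights <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(tibble(start = integer(), end = integer(), class = character()))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble(start = as.integer(map_chr(parts, 1)),
         end = as.integer(map_chr(parts, 2)),
         class = map_chr(parts, 3))
}

#' @rdname export_tasks
#' @export
import_tasks <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            sentence_index = readr::col_integer(),
                            unit_start = readr::col_integer(),
                            unit_end = readr::col_integer(),
                            is_test_question = readr::col_logical(),
                            expected_choice = readr::col_character(),
                            .default = readr::col_character()))
  flat$highlights <- map(flat$highlights, deserialize_highlights)
  flat$unit_markup <- NULL
  as_tibble(flat)
}

#' Crowd task pricing
#'
#' @param pay_per_judgment pay per single judgment, USD.
#' @param min_seconds_per_judgment enforced minimum seconds per judgment.
#' @param judgments_per_task judgments gathered per relation (default 5).
#' @return a `task_pricing` list.
#' @export
task_pricing <- function(pay_per_judgment, min_seconds_per_judgment,
                         judgments_per_task = 5L) {
  stopifnot(pay_per_judgment > 0, min_seconds_per_judgment > 0,
            judgments_per_task > 0)
  structure(list(pay_per_judgment = pay_per_judgment,
                 min_seconds_per_judgment = min_seconds_per_judgment,
                 judgments_per_task = as.integer(judgments_per_task)),
            class = "task_pricing")
}

#' Maximum theoretical hourly pay for a task configuration
#'
#' A worker answering back-to-back at the enforced minimum time earns
#' `3600 * pay_per_judgment / min_seconds_per_judgment` USD per hour: $24/h
#' at 2 cents / 3 s (sentence tasks), $14.40/h at 4 cents / 10 s (abstract
#' tasks).
#'
#' @param pricing a [task_pricing()].
#' @return USD per hour.
#' @export
max_hourly_pay <- function(pricing) {
  3600 * pricing$pay_per_judgment / pricing$min_seconds_per_judgment
}
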