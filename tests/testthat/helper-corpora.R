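# Small hand-built corpora used across test files.

# one document: a pattern hit, a sentence co-occurrence and an
# abstract-only pair, with gold covering the first two
toy_block <- function() {
  paste0(
    "101|t|Cisplatin toxicity in rats.\n",
    "101|a|We observed cisplatin-induced nephrotoxicity in all animals. ",
    "Anemia was frequent under cisplatin. ",
    "Hearing loss appeared later.\n",
    "101\t0\t9\tCisplatin\tChemical\tD002945\n",
    "101\t40\t49\tcisplatin\tChemical\tD002945\n",
    "101\t58\t72\tnephrotoxicity\tDisease\tD007674\n",
    "101\t89\t95\tAnemia\tDisease\tD000740\n",
    "101\t115\t124\tcisplatin\tChemical\tD002945\n",
    "101\t126\t138\tHearing loss\tDisease\tD034381\n",
    "101\tCID\tD002945\tD007674\n",
    "101\tCID\tD002945\tD000740\n")
}

toy_corpus <- function() parse_pubtator(toy_block())

# triples helper
triples <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  tibble::tibble(doc_id = m[, 1], chemical_id = m[, 2], disease_id = m[, 3])
}

# annotation tibble row
ann_row <- function(doc_id, start, end, surface, class, ids) {
  tibble::tibble(doc_id = doc_id, start = as.integer(start),
                 end = as.integer(end), surface = surface,
                 concept_class = class, concept_ids = list(ids))
}

# a corpus from explicit pieces without going through PubTator text
mk_corpus <- function(title, abstract, ann, rel = NULL, doc_id = "d1") {
  docs <- tibble::tibble(doc_id = doc_id, title = title, abstract = abstract,
                         text = paste(title, abstract))
  cid_corpus(documents = docs, annotations = ann, relations = rel)
}

# task tibble for direct simulator tests (bypasses text/units)
bare_tasks <- function(n, scope = "abstract") {
  tibble::tibble(
    task_id = sprintf("t%05d", seq_len(n)),
    doc_id = "d1", chemical_id = "D900001", disease_id = "D910001",
    scope = scope, sentence_index = NA_integer_,
    unit_start = 0L, unit_end = 1L,
    choices = ifelse(scope == "sentence",
                     "yes_cid|no_relation|chained_induction",
                     "yes_cid|no_relation"),
    highlights = replicate(n, tibble::tibble(start = integer(),
                                             end = integer(),
                                             class = character()),
                           simplify = FALSE),
    is_test_question = FALSE, expected_choice = NA_character_)
}

# deterministic judgments for a set of tasks: n_yes positive votes each
mk_judgments <- function(task_ids, n_yes, per_task = 5L,
                         negative = "no_relation") {
  out <- lapply(seq_along(task_ids), function(i) {
    ch <- c(rep("yes_cid", n_yes[i]), rep(negative, per_task - n_yes[i]))
    tibble::tibble(task_id = task_ids[i],
                   worker_id = sprintf("w%02d", seq_len(per_task)),
                   choice = ch, trusted = TRUE)
  })
  dplyr::bind_rows(out)
}
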