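#' Synthetic-corpus generator parameters
#'
#' The generator emulates concept-annotated title+abstract documents with
#' planted chemical-induced disease relations, controlling how each true
#' relation is expressed in the surface text: via the lexical
#' "-induced" pattern (`p_pattern`), via plain same-sentence co-occurrence
#' (`p_sentence_cooccur`), or split across sentences so the pair only
#' co-occurs at abstract level (`p_abstract_only`).  Chemicals may be
#' introduced long-form with a parenthetical acronym and then mentioned by
#' the unmapped acronym (`p_acronym`); disease mentions may be emitted with
#' the unmapped sentinel `"-1"` (`p_unmapped`), which makes their relation
#' unindexable.  Each document additionally carries `n_distractor_pairs`
#' co-occurring chemical-disease pairs that are *not* relations.  Concept
#' IDs live in a reserved `D9...` namespace so they can never collide with
#' real MeSH descriptors.
#'
#' @param n_documents number of documents (default 100).
#' @param n_chemical_ids,n_disease_ids synthetic vocabulary sizes.
#' @param p_pattern,p_sentence_cooccur,p_abstract_only branch probabilities
#'   for true relations; must sum to 1.
#' @param p_unmapped probability a relation's disease mention is emitted
#'   unmapped.
#' @param p_acronym probability a relation's chemical is introduced with a
#'   parenthetical acronym and then mentioned by it.
#' @param n_distractor_pairs co-occurring non-relation pairs per document.
#' @param relations_per_doc integer vector sampled from for the number of
#'   true relations per document.
#' @param rng_seed integer seed.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(n_documents = 100L, n_chemical_ids = 40L,
                           n_disease_ids = 40L, p_pattern = 0.10,
                           p_sentence_cooccur = 0.55,
                           p_abstract_only = 0.35, p_unmapped = 0.10,
                           p_acronym = 0.15, n_distractor_pairs = 2L,
                           relations_per_doc = 1:3, rng_seed = 20160416L) {
  probs <- c(p_pattern, p_sentence_cooccur, p_abstract_only)
  stopifnot(n_documents >= 1, n_chemical_ids >= 1, n_disease_ids >= 1,
            all(probs >= 0), all(probs <= 1),
            abs(sum(probs) - 1) < 1e-8,
            p_unmapped >= 0, p_unmapped <= 1,
            p_acronym >= 0, p_acronym <= 1,
            n_distractor_pairs >= 0, all(relations_per_doc >= 0))
  need <- max(relations_per_doc) + n_distractor_pairs
  if (n_chemical_ids < need || n_disease_ids < need) {
    stop("vocabulary too small: need at least ", need,
         " chemical and disease IDs per document")
  }
  structure(list(n_documents = as.integer(n_documents),
                 n_chemical_ids = as.integer(n_chemical_ids),
                 n_disease_ids = as.integer(n_disease_ids),
                 p_pattern = p_pattern,
                 p_sentence_cooccur = p_sentence_cooccur,
                 p_abstract_only = p_abstract_only,
                 p_unmapped = p_unmapped, p_acronym = p_acronym,
                 n_distractor_pairs = as.integer(n_distractor_pairs),
                 relations_per_doc = as.integer(relations_per_doc),
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_config")
}

# incremental builder for one document's combined text + annotations
new_doc_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$pieces <- character(0)
  env$len <- 0L
  env$ann <- list()
  env
}

db_text <- function(b, s) {
  b$pieces[[length(b$pieces) + 1L]] <- s
  b$len <- b$len + nchar(s)
  invisible(b)
}

db_mention <- function(b, surface, class, ids) {
  b$ann[[length(b$ann) + 1L]] <- tibble(
    start = b$len, end = b$len + nchar(surface), surface = surface,
    concept_class = class, concept_ids = list(ids))
  db_text(b, surface)
}

db_finish <- function(b, doc_id) {
  ann <- if (length(b$ann)) bind_rows(b$ann) else empty_annotations()[, -1]
  list(text = paste(b$pieces, collapse = ""),
       annotations = if (nrow(ann)) mutate(ann, doc_id = doc_id,
                                           .before = 1) else
         empty_annotations())
}

#' Generate a synthetic annotated corpus with planted ground truth
#'
#' Builds `config$n_documents` title+abstract documents carrying
#' span-valid chemical/disease annotations, gold CID relations, acronym
#' definitions, unmapped mentions and co-occurring distractor pairs, all
#' deterministically from `config$rng_seed`.  The truth metadata records,
#' for every gold relation, which surface branch expresses it
#' (pattern / sentence / abstract), whether its chemical was mentioned via
#' an acronym, whether its disease mention was emitted unmapped, and hence
#' whether the relation is indexable by candidate generation.
#'
#' @param config a [fixture_config()].
#' @return list with `corpus` (a [cid_corpus()] whose relations table is the
#'   gold standard), `gold` (the same triples), `truth` (per-relation
#'   metadata tibble), and `distractors` (planted non-relation pairs).
#' @export
generate_corpus <- function(config = fixture_config()) {
  withr::with_seed(config$rng_seed, {
    chem_ids <- sprintf("D91%04d", seq_len(config$n_chemical_ids))
    chem_names <- sprintf("toxamine-%03d", seq_len(config$n_chemical_ids))
    chem_acrs <- sprintf("TXA%03d", seq_len(config$n_chemical_ids))
    dis_ids <- sprintf("D92%04d", seq_len(config$n_disease_ids))
    dis_names <- sprintf("cardiopathy type %03d",
                         seq_len(config$n_disease_ids))
    docs <- list(); anns <- list(); golds <- list()
    truths <- list(); distractors <- list()
    for (i in seq_len(config$n_documents)) {
      doc_id <- sprintf("90%06d", i)
      k <- if (length(config$relations_per_doc) == 1L) {
        config$relations_per_doc
      } else {
        sample(config$relations_per_doc, 1L)
      }
      nd <- config$n_distractor_pairs
      ch <- sample.int(config$n_chemical_ids, k + nd)
      di <- sample.int(config$n_disease_ids, k + nd)
      branch <- sample(c("pattern", "sentence", "abstract"), k,
                       replace = TRUE,
                       prob = c(config$p_pattern, config$p_sentence_cooccur,
                                config$p_abstract_only))
      acro <- runif(k) < config$p_acronym
      unmapped <- runif(k) < config$p_unmapped
      b <- new_doc_builder()
      # title: first relation chemical (long form, mapped), no disease
      title_chem <- if (k >= 1L) ch[1] else ch[length(ch)]
      db_text(b, "Observations on ")
      db_mention(b, chem_names[title_chem], "chemical", chem_ids[title_chem])
      db_text(b, " exposure in a clinical cohort.")
      title_len <- b$len
      db_text(b, " ")
      first_abs <- TRUE
      add_sentence <- function(build) {
        if (!first_abs) db_text(b, " ")
        first_abs <<- FALSE
        build()
      }
      for (r in seq_len(k)) {
        chem_surface <- chem_names[ch[r]]
        chem_id_out <- chem_ids[ch[r]]
        if (acro[r]) {
          add_sentence(function() {
            db_text(b, "The compound ")
            db_mention(b, chem_names[ch[r]], "chemical", chem_ids[ch[r]])
            db_text(b, " (")
            db_mention(b, chem_acrs[ch[r]], "chemical", "-1")
            db_text(b, ") was administered daily.")
          })
          chem_surface <- chem_acrs[ch[r]]
          chem_id_out <- "-1"
        }
        dis_id_out <- if (unmapped[r]) "-1" else dis_ids[di[r]]
        if (branch[r] == "pattern") {
          add_sentence(function() {
            db_text(b, "Notably, ")
            db_mention(b, chem_surface, "chemical", chem_id_out)
            db_text(b, "-induced ")
            db_mention(b, dis_names[di[r]], "disease", dis_id_out)
            db_text(b, " was observed in the treated group.")
          })
        } else if (branch[r] == "sentence") {
          add_sentence(function() {
            db_text(b, "Treatment with ")
            db_mention(b, chem_surface, "chemical", chem_id_out)
            db_text(b, " was frequently followed by ")
            db_mention(b, dis_names[di[r]], "disease", dis_id_out)
            db_text(b, " in our patients.")
          })
        } else {
          add_sentence(function() {
            db_text(b, "We examined the effects of ")
            db_mention(b, chem_surface, "chemical", chem_id_out)
            db_text(b, " in a controlled cohort.")
          })
          add_sentence(function() {
            db_text(b, "Several subjects subsequently developed ")
            db_mention(b, dis_names[di[r]], "disease", dis_id_out)
            db_text(b, " during follow-up.")
          })
        }
      }
      for (j in seq_len(nd)) {
        cj <- ch[k + j]; dj <- di[k + j]
        add_sentence(function() {
          db_text(b, "Both ")
          db_mention(b, chem_names[cj], "chemical", chem_ids[cj])
          db_text(b, " and ")
          db_mention(b, dis_names[dj], "disease", dis_ids[dj])
          db_text(b, " were monitored throughout the study period.")
        })
        distractors[[length(distractors) + 1L]] <- tibble(
          doc_id = doc_id, chemical_id = chem_ids[cj],
          disease_id = dis_ids[dj])
      }
      built <- db_finish(b, doc_id)
      title <- substr(built$text, 1L, title_len)
      abstract <- substr(built$text, title_len + 2L, nchar(built$text))
      docs[[i]] <- tibble(doc_id = doc_id, title = title,
                          abstract = abstract, text = built$text)
      anns[[i]] <- built$annotations
      if (k >= 1L) {
        golds[[length(golds) + 1L]] <- tibble(
          doc_id = doc_id, chemical_id = chem_ids[ch[seq_len(k)]],
          disease_id = dis_ids[di[seq_len(k)]])
        truths[[length(truths) + 1L]] <- tibble(
          doc_id = doc_id, chemical_id = chem_ids[ch[seq_len(k)]],
          disease_id = dis_ids[di[seq_len(k)]], branch = branch,
          chem_acronym = acro, dis_unmapped = unmapped,
          indexable = !unmapped)
      }
    }
    corpus <- cid_corpus(documents = bind_rows(docs),
                         annotations = bind_rows(anns),
                         relations = if (length(golds)) bind_rows(golds)
                         else NULL)
    list(corpus = corpus, gold = corpus$relations,
         truth = if (length(truths)) bind_rows(truths) else
           mutate(empty_triples(), branch = character(),
                  chem_acronym = logical(), dis_unmapped = logical(),
                  indexable = logical()),
         distractors = if (length(distractors)) bind_rows(distractors)
         else empty_triples(),
         config = config)
  })
}
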