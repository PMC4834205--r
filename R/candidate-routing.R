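#' Lexical CID-pattern parameters
#'
#' The auto-accept pattern: a chemical mention followed, within at most
#' `max_gap` characters, by a disease mention, with the trigger substring
#' (default `"induce"`, matching "induced", "induces", ...) somewhere in the
#' gap text — as in "cisplatin-induced nephrotoxicity".
#'
#' @param max_gap maximum characters between chemical end and disease start
#'   (default 15).
#' @param trigger literal trigger substring (default `"induce"`).
#' @param case_insensitive match the trigger case-insensitively (default
#'   `TRUE`).
#' @return a `pattern_config` list.
#' @export
pattern_config <- function(max_gap = 15L, trigger = "induce",
                           case_insensitive = TRUE) {
  stopifnot(is.numeric(max_gap), max_gap >= 0,
            is.character(trigger), nzchar(trigger))
  structure(list(max_gap = as.integer(max_gap), trigger = trigger,
                 case_insensitive = isTRUE(case_insensitive)),
            class = "pattern_config")
}

# MeSH IDs carried by annotations of one class in one document
doc_class_ids <- function(ann, cls) {
  v <- unlist(ann$concept_ids[ann$concept_class == cls], use.names = FALSE)
  sort(unique(v[is_mesh_id(v)]))
}

#' Generate all chemical x disease candidate pairs per document
#'
#' Every distinct chemical MeSH ID in a document is paired with every
#' distinct disease MeSH ID in the same document; composite-ID annotations
#' contribute each component ID.  Annotations should first be filtered with
#' [exclude_non_mesh()] (non-MeSH IDs are ignored here regardless).
#'
#' @param annotations annotation tibble covering one or more documents.
#' @return tibble with columns `doc_id`, `chemical_id`, `disease_id`; empty
#'   when a document lacks chemicals or diseases.
#' @export
generate_candidate_pairs <- function(annotations) {
  if (!nrow(annotations)) return(empty_triples())
  out <- lapply(split(annotations, annotations$doc_id), function(ann) {
    chems <- doc_class_ids(ann, "chemical")
    dis <- doc_class_ids(ann, "disease")
    if (!length(chems) || !length(dis)) return(NULL)
    tibble(doc_id = ann$doc_id[1],
           chemical_id = rep(chems, each = length(dis)),
           disease_id = rep(dis, times = length(chems)))
  })
  out <- bind_rows(out)
  if (!nrow(out)) return(empty_triples())
  arrange(out, .data$doc_id, .data$chemical_id, .data$disease_id)
}

#' Test one pair against the CID auto-accept pattern
#'
#' `TRUE` iff some chemical mention carrying `chemical_id` ends at most
#' `config$max_gap` characters before the start of a disease mention
#' carrying `disease_id`, and the text strictly between them contains the
#' trigger substring.
#'
#' @param text the document's combined text.
#' @param annotations the document's annotations.
#' @param chemical_id,disease_id the pair's MeSH IDs.
#' @param config a [pattern_config()].
#' @return logical scalar.
#' @export
match_cid_pattern <- function(text, annotations, chemical_id, disease_id,
                              config = pattern_config()) {
  has_id <- function(v, id) id %in% v
  chem <- annotations[annotations$concept_class == "chemical" &
                        map_lgl(annotations$concept_ids, has_id, chemical_id), ]
  dis <- annotations[annotations$concept_class == "disease" &
                       map_lgl(annotations$concept_ids, has_id, disease_id), ]
  if (!nrow(chem) || !nrow(dis)) return(FALSE)
  for (a in seq_len(nrow(chem))) {
    gap <- dis$start - chem$end[a]
    hit <- which(gap >= 0L & gap <= config$max_gap)
    for (b in hit) {
      between <- slice_text(text, chem$end[a], dis$start[b])
      if (grepl(escape_regex(config$trigger), between,
                ignore.case = config$case_insensitive)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

default_abbreviations <- c(
  "e\\.g\\.", "i\\.e\\.", "vs\\.", "cf\\.", "ca\\.", "etc\\.", "et al\\.",
  "Dr\\.", "Mr\\.", "Mrs\\.", "Ms\\.", "Prof\\.", "Fig\\.", "Figs\\.",
  "No\\.", "approx\\.", "[A-Za-z]\\.")

#' Split a document into sentence spans
#'
#' Deterministic rule-based splitting: a run of `.`, `!` or `?` followed by
#' whitespace and an uppercase letter or digit ends a sentence, unless the
#' preceding token is on a fixed abbreviation list (which includes
#' single-letter tokens, so "e.g." and initials do not split).  The title is
#' always its own first sentence unit; abstract sentences follow.  Spans are
#' 0-based, end-exclusive offsets into the combined text, ordered and
#' non-overlapping; only inter-sentence whitespace falls outside them.
#'
#' @param title,abstract the document's two text fields.
#' @param doc_id optional document ID recorded in the output.
#' @return tibble with columns `doc_id`, `index` (1-based ordinal), `start`,
#'   `end`.
#' @export
split_sentences <- function(title, abstract, doc_id = NA_character_) {
  spans <- list(tibble(start = 0L, end = nchar(title)))
  if (nzchar(abstract)) {
    off <- nchar(title) + 1L
    ab <- split_plain_sentences(abstract)
    spans[[2]] <- tibble(start = ab$start + off, end = ab$end + off)
  }
  out <- bind_rows(spans)
  tibble(doc_id = doc_id, index = seq_len(nrow(out)),
         start = out$start, end = out$end)
}

# 0-based sentence spans within a single text block
split_plain_sentences <- function(text) {
  n <- nchar(text)
  if (n == 0L) return(tibble(start = integer(), end = integer()))
  m <- gregexpr("[.!?]+[ \t\r\n]+(?=[A-Z0-9])", text, perl = TRUE)[[1]]
  starts <- 0L
  ends <- integer()
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      p <- m[k]                       # 1-based index of first terminator char
      piece <- substr(text, p, p + lens[k] - 1L)
      n_term <- attr(regexpr("^[.!?]+", piece), "match.length")
      prefix <- substr(text, max(1L, p - 12L), p + n_term - 1L)
      abbrev <- paste0("(^|[ \t(])(", paste(default_abbreviations,
                                            collapse = "|"), ")$")
      if (grepl(abbrev, prefix)) next
      ends <- c(ends, p + n_term - 1L)          # end as 0-based exclusive
      starts <- c(starts, p + lens[k] - 1L)     # next start, 0-based
    }
  }
  ends <- c(ends, n)
  tibble(start = starts, end = ends)
}

# sentence index containing a 0-based offset, NA if in inter-sentence gap
sentence_of_offset <- function(sentences, offset) {
  hit <- which(sentences$start <= offset & offset < sentences$end)
  if (length(hit)) sentences$index[hit[1]] else NA_integer_
}

#' Assign each candidate pair a routing scope
#'
#' Candidates are divided into three mutually exclusive, exhaustive classes:
#' `pattern` (matched the lexical auto-accept pattern; never routed to the
#' crowd), `sentence` (both concepts are mentioned in at least one common
#' sentence; all such sentence indices are recorded), and `abstract`
#' (everything else).  A mention belongs to the sentence containing its
#' start offset.
#'
#' @param text combined document text.
#' @param annotations the document's annotations (MeSH-filtered).
#' @param pairs tibble of candidate pairs for this document (from
#'   [generate_candidate_pairs()]).
#' @param sentences sentence spans from [split_sentences()].
#' @param config a [pattern_config()].
#' @return tibble `doc_id`, `chemical_id`, `disease_id`, `scope`,
#'   `sentence_indices` (list column; empty unless scope is `sentence`).
#' @export
classify_scope <- function(text, annotations, pairs, sentences,
                           config = pattern_config()) {
  if (!nrow(pairs)) {
    return(mutate(empty_triples(), scope = character(),
                  sentence_indices = list()))
  }
  ann <- annotations
  ann_sent <- map_int(ann$start, function(s) sentence_of_offset(sentences, s))
  scope <- character(nrow(pairs))
  sidx <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    chem_id <- pairs$chemical_id[k]
    dis_id <- pairs$disease_id[k]
    if (match_cid_pattern(text, ann, chem_id, dis_id, config)) {
      scope[k] <- "pattern"
      sidx[[k]] <- integer()
      next
    }
    chem_s <- ann_sent[ann$concept_class == "chemical" &
                         map_lgl(ann$concept_ids, function(v) chem_id %in% v)]
    dis_s <- ann_sent[ann$concept_class == "disease" &
                        map_lgl(ann$concept_ids, function(v) dis_id %in% v)]
    co <- sort(intersect(chem_s[!is.na(chem_s)], dis_s[!is.na(dis_s)]))
    if (length(co)) {
      scope[k] <- "sentence"
      sidx[[k]] <- as.integer(co)
    } else {
      scope[k] <- "abstract"
      sidx[[k]] <- integer()
    }
  }
  mutate(pairs, scope = scope, sentence_indices = sidx)
}

#' Route all candidate pairs of a corpus
#'
#' Convenience wrapper running [generate_candidate_pairs()],
#' [split_sentences()] and [classify_scope()] over every document.
#'
#' @param corpus a [cid_corpus()].
#' @param config a [pattern_config()].
#' @param annotations annotations to use (default the corpus annotations;
#'   pass a MeSH-filtered or acronym-resolved table to route on that).
#' @return list with elements `candidates` (routed candidate tibble) and
#'   `sentences` (all documents' sentence spans).
#' @export
route_candidates <- function(corpus, config = pattern_config(),
                             annotations = corpus$annotations) {
  docs <- corpus$documents
  sent_all <- vector("list", nrow(docs))
  cand_all <- vector("list", nrow(docs))
  pairs <- generate_candidate_pairs(annotations)
  for (i in seq_len(nrow(docs))) {
    d <- docs[i, ]
    sents <- split_sentences(d$title, d$abstract, d$doc_id)
    sent_all[[i]] <- sents
    p <- pairs[pairs$doc_id == d$doc_id, ]
    if (!nrow(p)) next
    ann <- annotations[annotations$doc_id == d$doc_id, ]
    cand_all[[i]] <- classify_scope(d$text, ann, p, sents, config)
  }
  candidates <- bind_rows(cand_all)
  if (!nrow(candidates)) {
    candidates <- mutate(empty_triples(), scope = character(),
                         sentence_indices = list())
  }
  list(candidates = candidates, sentences = bind_rows(sent_all))
}

#' Export routed candidates as TSV
#'
#' One row per candidate with `sentence_indices` serialized as a
#' comma-separated list.
#'
#' @param candidates routed candidate tibble.
#' @param path output file path.
#' @return the written tibble, invisibly.
#' @export
export_candidates <- function(candidates, path) {
  flat <- mutate(candidates,
                 sentence_indices = map_chr(.data$sentence_indices,
                                            paste, collapse = ","))
  readr::write_tsv(flat, path)
  invisible(flat)
}
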