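#' Acronym-resolution rule parameters
#'
#' Controls which unmapped mentions qualify as acronyms for
#' [resolve_acronyms()].
#'
#' @param max_acronym_length maximum surface length, in characters, for a
#'   mention to be treated as an acronym (default 10).
#' @param require_uppercase when `TRUE` (default) the surface must contain at
#'   least one uppercase letter.
#' @return an `acronym_rule_config` list.
#' @export
acronym_rule_config <- function(max_acronym_length = 10L,
                                require_uppercase = TRUE) {
  stopifnot(is.numeric(max_acronym_length), max_acronym_length >= 1,
            is.logical(require_uppercase))
  structure(list(max_acronym_length = as.integer(max_acronym_length),
                 require_uppercase = isTRUE(require_uppercase)),
            class = "acronym_rule_config")
}

#' Resolve unmapped acronym annotations within each document
#'
#' Named-entity tools sometimes locate an acronym mention (e.g. "BPA") but
#' fail to attach a concept ID, emitting the sentinel `"-1"`.  This pass
#' copies IDs onto such mentions from mapped annotations in the same
#' document using two rules:
#'
#' 1. *Same-surface propagation*: an unmapped mention whose surface exactly
#'    equals a mapped same-class mention's surface inherits its IDs.
#' 2. *Parenthetical definition*: if the acronym appears wrapped in
#'    parentheses within 2 characters after the end of a mapped same-class
#'    mention (the long form, as in "bisphenol A (BPA)"), every unmapped
#'    mention of that acronym in the document inherits the long form's IDs.
#'
#' A candidate acronym must satisfy `config`: at most
#' `max_acronym_length` characters, no whitespace, and (by default) at least
#' one uppercase letter.  When several mapped mentions could resolve the same
#' acronym with different IDs, the nearest mention preceding the acronym (by
#' start offset) wins; a message reports the conflict.  Spans, surfaces and
#' classes are never changed, the number of annotations is preserved, and
#' the operation is idempotent.  Unresolvable mentions keep `"-1"`.
#'
#' @param corpus a [cid_corpus()].
#' @param config an [acronym_rule_config()].
#' @return the corpus with updated annotation ID lists.
#' @export
resolve_acronyms <- function(corpus, config = acronym_rule_config()) {
  ann <- corpus$annotations
  if (!nrow(ann)) return(corpus)
  out <- ann
  for (doc in unique(ann$doc_id)) {
    idx <- which(ann$doc_id == doc)
    text <- corpus$documents$text[corpus$documents$doc_id == doc]
    out$concept_ids[idx] <- resolve_doc_acronyms(text, ann[idx, ], config)
  }
  corpus$annotations <- out
  corpus
}

resolve_doc_acronyms <- function(text, ann, config) {
  ids <- ann$concept_ids
  unmapped <- map_lgl(ids, function(v) all(v == "-1"))
  if (!any(unmapped)) return(ids)
  acr_ok <- nchar(ann$surface) <= config$max_acronym_length &
    !grepl("\\s", ann$surface) &
    (!config$require_uppercase | grepl("[A-Z]", ann$surface))
  for (i in which(unmapped & acr_ok)) {
    surf <- ann$surface[i]
    same_class <- ann$concept_class == ann$concept_class[i]
    mapped <- !unmapped & same_class
    by_surface <- mapped & ann$surface == surf
    by_paren <- mapped & map_lgl(seq_len(nrow(ann)), function(j) {
      mapped[j] && has_parenthetical_after(text, ann$end[j], surf)
    })
    cand <- which(by_surface | by_paren)
    if (!length(cand)) next
    resolver_ids <- ids[cand]
    if (length(unique(map_chr(resolver_ids, paste, collapse = "|"))) > 1L) {
      message(sprintf(
        "acronym '%s': conflicting resolvers; using nearest preceding mention",
        surf))
    }
    preceding <- cand[ann$start[cand] <= ann$start[i]]
    pick <- if (length(preceding)) {
      preceding[which.max(ann$start[preceding])]
    } else {
      cand[which.min(ann$start[cand])]
    }
    ids[[i]] <- ids[[pick]]
  }
  ids
}

# Is "(surf)" found starting at most 2 characters after 0-based offset end0?
has_parenthetical_after <- function(text, end0, surf) {
  window <- substr(text, end0 + 1L,
                   min(nchar(text), end0 + 2L + nchar(surf) + 2L))
  m <- regexpr(paste0("\\(", escape_regex(surf), "\\)"), window)[1]
  m != -1L && (m - 1L) <= 2L
}

#' Drop annotations without a MeSH identifier
#'
#' Mentions whose ID list holds only the unmapped sentinel `"-1"` or
#' foreign-ontology identifiers (e.g. `CHEBI:16236`) cannot take part in
#' MeSH-keyed relation extraction and are removed.  Annotations carrying at
#' least one MeSH ID (`C`/`D` + digits) are kept, composite lists included.
#'
#' @param annotations an annotation tibble (see [cid_corpus()]).
#' @return the surviving rows.
#' @export
exclude_non_mesh <- function(annotations) {
  if (!nrow(annotations)) return(annotations)
  keep <- map_lgl(annotations$concept_ids, function(v) any(is_mesh_id(v)))
  annotations[keep, ]
}
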