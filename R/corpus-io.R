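#' Corpus container for annotated abstracts
#'
#' A `cid_corpus` bundles the three tables read from a PubTator file:
#' documents (title + abstract), concept annotations (character spans with
#' one or more concept IDs), and gold CID relations.  Annotation offsets are
#' 0-based, end-exclusive character offsets into the combined text
#' `title + " " + abstract`.
#'
#' @param documents tibble with columns `doc_id`, `title`, `abstract`,
#'   `text` (the combined text).
#' @param annotations tibble with columns `doc_id`, `start`, `end`,
#'   `surface`, `concept_class` (`"chemical"` or `"disease"`) and
#'   `concept_ids` (list column of character vectors; `"-1"` marks an
#'   unmapped mention, IDs containing `":"` come from foreign ontologies).
#' @param relations tibble with columns `doc_id`, `chemical_id`,
#'   `disease_id` (normalized MeSH IDs).
#' @return an object of class `cid_corpus`.
#' @export
cid_corpus <- function(documents = NULL, annotations = NULL, relations = NULL) {
  if (is.null(documents)) {
    documents <- tibble(doc_id = character(), title = character(),
                        abstract = character(), text = character())
  }
  if (is.null(annotations)) annotations <- empty_annotations()
  if (is.null(relations)) relations <- empty_triples()
  corpus <- structure(list(documents = as_tibble(documents),
                           annotations = as_tibble(annotations),
                           relations = as_tibble(relations)),
                      class = "cid_corpus")
  validate_corpus(corpus)
  corpus
}

empty_annotations <- function() {
  tibble(doc_id = character(), start = integer(), end = integer(),
         surface = character(), concept_class = character(),
         concept_ids = list())
}

#' @export
print.cid_corpus <- function(x, ...) {
  cat(sprintf("<cid_corpus> %d documents, %d annotations, %d gold relations\n",
              nrow(x$documents), nrow(x$annotations), nrow(x$relations)))
  invisible(x)
}

validate_corpus <- function(corpus) {
  docs <- corpus$documents
  if (anyDuplicated(docs$doc_id)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", "))
  }
  if (any(!nzchar(docs$doc_id))) stop("empty doc_id in corpus")
  bad <- which(nchar(docs$text) !=
                 nchar(docs$title) + 1L + nchar(docs$abstract))
  if (length(bad)) {
    stop("combined text length mismatch for document ", docs$doc_id[bad[1]])
  }
  ann <- corpus$annotations
  if (nrow(ann)) {
    text_of <- setNames(docs$text, docs$doc_id)
    unknown <- setdiff(ann$doc_id, docs$doc_id)
    if (length(unknown)) {
      stop("annotation references unknown document ", unknown[1])
    }
    txt <- text_of[ann$doc_id]
    bad <- which(ann$start < 0L | ann$start >= ann$end | ann$end > nchar(txt))
    if (length(bad)) {
      i <- bad[1]
      stop(sprintf("annotation span out of bounds in document %s at [%d,%d)",
                   ann$doc_id[i], ann$start[i], ann$end[i]))
    }
    got <- slice_text(txt, ann$start, ann$end)
    bad <- which(got != ann$surface)
    if (length(bad)) {
      i <- bad[1]
      stop(sprintf(
        "span/text mismatch in document %s at [%d,%d): text is '%s' but annotation says '%s'",
        ann$doc_id[i], ann$start[i], ann$end[i], got[i], ann$surface[i]))
    }
    if (any(lengths(ann$concept_ids) == 0L)) {
      stop("annotation with empty concept ID list (use \"-1\" for unmapped)")
    }
    if (!all(ann$concept_class %in% c("chemical", "disease"))) {
      stop("concept_class must be 'chemical' or 'disease'")
    }
  }
  rel <- corpus$relations
  if (nrow(rel)) {
    unknown <- setdiff(rel$doc_id, docs$doc_id)
    if (length(unknown)) stop("relation references unknown document ", unknown[1])
  }
  invisible(corpus)
}

#' Parse a PubTator-format corpus
#'
#' Reads the plain-text dialect distributed for the BioCreative V CDR task:
#' blank-line-separated document blocks, each holding a `id|t|title` line, a
#' `id|a|abstract` line, tab-separated annotation lines
#' (`id  start  end  text  type  conceptID`) and `id  CID  chem  disease`
#' relation lines.  Offsets index the concatenation `title + " " + abstract`
#' (0-based, end-exclusive, counted in characters).  A leading `MESH:` prefix
#' on concept IDs is stripped; the unmapped sentinel `"-1"`, foreign-ontology
#' IDs (e.g. `CHEBI:16236`) and composite IDs joined by `|` are kept
#' verbatim (composites are stored as multi-element ID lists).
#'
#' @param x a file path, a single string containing the whole stream, or a
#'   character vector of lines.
#' @return a [cid_corpus()].  Malformed lines, span/text mismatches and
#'   duplicate document IDs raise errors naming the offending line or
#'   document.
#' @export
parse_pubtator <- function(x) {
  lines <- pubtator_lines(x)
  docs <- list(); anns <- list(); rels <- list()
  cur <- NULL
  flush_doc <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$title) || is.null(cur$abstract)) {
      stop("document ", cur$doc_id, " lacks a title or abstract line")
    }
    docs[[length(docs) + 1L]] <<- tibble(
      doc_id = cur$doc_id, title = cur$title, abstract = cur$abstract,
      text = paste(cur$title, cur$abstract))
    if (length(cur$ann)) anns[[length(anns) + 1L]] <<- bind_rows(cur$ann)
    if (length(cur$rel)) rels[[length(rels) + 1L]] <<- bind_rows(cur$rel)
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) { flush_doc(); next }
    m <- regmatches(line, regexec("^([^|\t]+)\\|([ta])\\|(.*)$", line))[[1]]
    if (length(m) == 4L) {
      id <- m[2]; kind <- m[3]; body <- m[4]
      if (kind == "t") {
        flush_doc()
        cur <- list(doc_id = id, title = body, abstract = NULL,
                    ann = list(), rel = list())
      } else {
        if (is.null(cur) || cur$doc_id != id) {
          stop("line ", i, ": abstract line for '", id,
               "' outside its document block")
        }
        if (!is.null(cur$abstract)) stop("line ", i, ": duplicate abstract line")
        cur$abstract <- body
      }
      next
    }
    if (grepl("\t", line, fixed = TRUE)) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (is.null(cur)) stop("line ", i, ": annotation outside a document block")
      if (length(f) >= 2L && f[2] == "CID") {
        if (length(f) < 4L) stop("line ", i, ": malformed relation line")
        if (f[1] != cur$doc_id) stop("line ", i, ": relation doc_id mismatch")
        cur$rel[[length(cur$rel) + 1L]] <- tibble(
          doc_id = f[1],
          chemical_id = normalize_concept_id(f[3]),
          disease_id = normalize_concept_id(f[4]))
        next
      }
      if (length(f) < 6L) stop("line ", i, ": malformed annotation line")
      if (f[1] != cur$doc_id) stop("line ", i, ": annotation doc_id mismatch")
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end)) {
        stop("line ", i, ": non-numeric annotation offsets")
      }
      cls <- tolower(f[5])
      if (!cls %in% c("chemical", "disease")) {
        stop("line ", i, ": unknown annotation type '", f[5], "'")
      }
      ids <- normalize_concept_id(strsplit(f[6], "|", fixed = TRUE)[[1]])
      if (!length(ids)) ids <- "-1"
      cur$ann[[length(cur$ann) + 1L]] <- tibble(
        doc_id = f[1], start = start, end = end, surface = f[4],
        concept_class = cls, concept_ids = list(ids))
      next
    }
    stop("line ", i, ": malformed line: ", substr(line, 1, 60))
  }
  flush_doc()
  cid_corpus(documents = if (length(docs)) bind_rows(docs) else NULL,
             annotations = if (length(anns)) bind_rows(anns) else NULL,
             relations = if (length(rels)) bind_rows(rels) else NULL)
}

pubtator_lines <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
      nzchar(x) && file.exists(x)) {
    return(readLines(x, encoding = "UTF-8", warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE))
}

#' Serialize a corpus to PubTator text
#'
#' Inverse of [parse_pubtator()]: `parse_pubtator(write_pubtator(corpus))`
#' reproduces the corpus exactly (annotation and relation order preserved,
#' composite ID lists re-joined with `|`).
#'
#' @param corpus a [cid_corpus()].
#' @param path optional file path; when given the text is also written there.
#' @return the serialized text, invisibly when `path` is given.
#' @export
write_pubtator <- function(corpus, path = NULL) {
  validate_corpus(corpus)
  blocks <- character(nrow(corpus$documents))
  for (i in seq_len(nrow(corpus$documents))) {
    d <- corpus$documents[i, ]
    ann <- corpus$annotations[corpus$annotations$doc_id == d$doc_id, ]
    rel <- corpus$relations[corpus$relations$doc_id == d$doc_id, ]
    lines <- c(paste0(d$doc_id, "|t|", d$title),
               paste0(d$doc_id, "|a|", d$abstract))
    if (nrow(ann)) {
      cls <- ifelse(ann$concept_class == "chemical", "Chemical", "Disease")
      ids <- map_chr(ann$concept_ids, paste, collapse = "|")
      lines <- c(lines, paste(ann$doc_id, ann$start, ann$end, ann$surface,
                              cls, ids, sep = "\t"))
    }
    if (nrow(rel)) {
      lines <- c(lines, paste(rel$doc_id, "CID", rel$chemical_id,
                              rel$disease_id, sep = "\t"))
    }
    blocks[i] <- paste(lines, collapse = "\n")
  }
  out <- if (length(blocks)) paste0(paste(blocks, collapse = "\n\n"), "\n") else ""
  if (!is.null(path)) {
    writeLines(out, path, sep = "", useBytes = FALSE)
    return(invisible(out))
  }
  out
}

#' Write predictions as PubTator CID lines
#'
#' @param triples tibble with `doc_id`, `chemical_id`, `disease_id`.
#' @param path optional output file.
#' @return the lines, invisibly when `path` is given.
#' @export
write_cid_lines <- function(triples, path = NULL) {
  lines <- paste(triples$doc_id, "CID", triples$chemical_id,
                 triples$disease_id, sep = "\t")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
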