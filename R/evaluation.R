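#' Micro-averaged precision/recall/F from confusion counts
#'
#' Precision is `tp/(tp+fp)`, recall `tp/(tp+fn)`, and F the balanced
#' harmonic mean of the two.  An empty denominator yields 0 with a warning
#' (this only arises on degenerate inputs such as an empty prediction set).
#'
#' @param tp,fp,fn non-negative counts of true positives, false positives
#'   and false negatives.
#' @return a `prf_result` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
prf_from_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) {
    tp / (tp + fp)
  } else {
    warning("no predicted positives; precision defined as 0")
    0
  }
  recall <- if (tp + fn > 0) {
    tp / (tp + fn)
  } else {
    warning("no actual positives; recall defined as 0")
    0
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f_measure(precision, recall)),
            class = "prf_result")
}

#' @export
print.prf_result <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F = %.4f  (tp %d, fp %d, fn %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Balanced harmonic mean of precision and recall
#'
#' @param precision,recall fractions in \[0, 1\].
#' @return `2PR/(P+R)`, or 0 when both are 0.
#' @export
f_measure <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Score predicted relations against gold
#'
#' Relations are (document, chemical MeSH ID, disease MeSH ID) triples; all
#' documents are pooled into one set before counting (micro-average).
#' Duplicate triples collapse before scoring.
#'
#' @param predicted,gold triple tibbles (`doc_id`, `chemical_id`,
#'   `disease_id`).
#' @return a [prf_from_counts()] result.
#' @export
relation_prf <- function(predicted, gold) {
  p <- unique(triple_key(predicted))
  g <- unique(triple_key(gold))
  prf_from_counts(tp = sum(p %in% g), fp = sum(!p %in% g),
                  fn = sum(!g %in% p))
}

# canonical key for exact annotation matching: doc, span, sorted ID set
ann_mention_keys <- function(ann) {
  ids <- map_chr(ann$concept_ids, function(v) {
    paste(sort(unique(v)), collapse = "|")
  })
  paste(ann$doc_id, ann$start, ann$end, ids, sep = "\r")
}

#' Exact annotation match
#'
#' Two annotations match iff they are in the same document and their start
#' offset, end offset and concept ID sets are all exactly equal.
#'
#' @param a,b single-row annotation tibbles.
#' @return logical scalar.
#' @export
annotation_match <- function(a, b) {
  a$doc_id == b$doc_id && a$start == b$start && a$end == b$end &&
    setequal(a$concept_ids[[1]], b$concept_ids[[1]])
}

#' Score NER output against gold annotations
#'
#' `mention` level compares (document, start, end, ID set) exactly;
#' `concept_doc` level compares unique (document, concept ID) pairs, the
#' unit used for the disease-NER evaluation of the CDR task.
#'
#' @param predicted,gold annotation tibbles.
#' @param level `"mention"` or `"concept_doc"`.
#' @return a [prf_from_counts()] result.
#' @export
ner_prf <- function(predicted, gold, level = c("mention", "concept_doc")) {
  level <- match.arg(level)
  keys <- function(ann) {
    if (level == "mention") {
      unique(ann_mention_keys(ann))
    } else {
      unique(paste(rep(ann$doc_id, lengths(ann$concept_ids)),
                   unlist(ann$concept_ids), sep = "\r"))
    }
  }
  p <- keys(predicted)
  g <- keys(gold)
  prf_from_counts(tp = sum(p %in% g), fp = sum(!p %in% g),
                  fn = sum(!g %in% p))
}

#' Restrict evaluation to relations free of NER errors
#'
#' Keeps a relation — on both the predicted and the gold side — only if, in
#' its document, both its chemical ID and its disease ID are carried by at
#' least one predicted annotation that exactly matches a gold annotation
#' (position and ID set).  This removes unindexable gold relations (NER
#' false negatives) and predictions built on wrong annotations (NER false
#' positives), isolating judgment quality from recognition quality.  The
#' filter returns subsets of its inputs and is idempotent.
#'
#' @param pred_relations,gold_relations triple tibbles.
#' @param pred_annotations,gold_annotations annotation tibbles.
#' @return list with elements `predicted` and `gold`.
#' @export
ner_error_filter <- function(pred_relations, gold_relations,
                             pred_annotations, gold_annotations) {
  matched <- pred_annotations[ann_mention_keys(pred_annotations) %in%
                                ann_mention_keys(gold_annotations), ]
  verified <- unique(paste(rep(matched$doc_id, lengths(matched$concept_ids)),
                           unlist(matched$concept_ids), sep = "\r"))
  keep <- function(rel) {
    ok <- paste(rel$doc_id, rel$chemical_id, sep = "\r") %in% verified &
      paste(rel$doc_id, rel$disease_id, sep = "\r") %in% verified
    rel[ok, ]
  }
  list(predicted = keep(pred_relations), gold = keep(gold_relations))
}

#' Maximum theoretical recall of the candidate-generation step
#'
#' The fraction of gold triples whose (chemical, disease) pair appears among
#' the candidate pairs generated for that document.  Gold relations using a
#' concept ID never produced by NER in their abstract are unindexable and
#' bound recall from above no matter how the crowd votes.
#'
#' @param candidates candidate tibble (`doc_id`, `chemical_id`,
#'   `disease_id`).
#' @param gold gold triple tibble.
#' @return fraction in \[0, 1\] (`NaN` when gold is empty).
#' @export
max_recall <- function(candidates, gold) {
  mean(unique(triple_key(gold)) %in% triple_key(candidates))
}

#' ROC points over vote thresholds, and the area under the curve
#'
#' The instance universe is the set of judged candidates plus any
#' unindexable gold relations, which are injected with zero positive votes
#' (as if unanimously voted false).  Pattern-accepted candidates carry
#' `pattern_votes` votes (default: the full judgment count).  Positives are
#' the gold triples.  At threshold `t` an instance is predicted positive
#' iff its votes are at least `t`; the true- and false-positive rates are
#' computed per threshold.  `roc_auc()` applies the trapezoidal rule over
#' points sorted by FPR, anchored at (0,0) and (1,1).
#'
#' @param tallies tally tibble from [tally_votes()].
#' @param candidates routed candidate tibble (all scopes); every
#'   sentence-/abstract-scoped candidate must have a tally, otherwise an
#'   error is raised.
#' @param gold gold triple tibble.
#' @param thresholds integer vote thresholds, default `6:0`.
#' @param pattern_votes votes assigned to pattern-accepted candidates
#'   (default 5).
#' @return `roc_points()` a tibble `threshold`, `tpr`, `fpr`; `roc_auc()` a
#'   fraction in \[0, 1\].
#' @export
roc_points <- function(tallies, candidates, gold, thresholds = 6:0,
                       pattern_votes = 5L) {
  ck <- triple_key(candidates)
  tk <- triple_key(tallies)
  votes <- tallies$positive_votes[match(ck, tk)]
  votes[candidates$scope == "pattern"] <- pattern_votes
  if (anyNA(votes)) {
    miss <- candidates[which(is.na(votes))[1], ]
    stop(sprintf("candidate (%s, %s, %s) has no vote tally",
                 miss$doc_id, miss$chemical_id, miss$disease_id))
  }
  gk <- unique(triple_key(gold))
  extra <- setdiff(gk, ck)             # unindexable gold: zero votes
  key <- c(ck, extra)
  votes <- c(votes, rep(0L, length(extra)))
  label <- key %in% gk
  pos <- sum(label)
  neg <- sum(!label)
  if (pos == 0L || neg == 0L) {
    stop("ROC needs at least one positive and one negative instance")
  }
  tibble(threshold = as.integer(thresholds),
         tpr = vapply(thresholds, function(t) sum(votes >= t & label) / pos,
                      numeric(1)),
         fpr = vapply(thresholds, function(t) sum(votes >= t & !label) / neg,
                      numeric(1)))
}

#' @rdname roc_points
#' @param points tibble with `fpr` and `tpr` columns.
#' @export
roc_auc <- function(points) {
  fpr <- c(0, points$fpr, 1)
  tpr <- c(0, points$tpr, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]
  tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Partition gold relations by which systems predicted them
#'
#' Computes the Venn partition of the gold standard over any number of
#' prediction sets: for every subset of systems, the number of gold triples
#' predicted by exactly those systems, plus the gold triples predicted by
#' none.
#'
#' @param systems named list of triple tibbles, one per system.
#' @param gold gold triple tibble.
#' @return tibble `region` (system names joined by `+`, or `"none"`) and
#'   `count`, covering all 2^k regions.
#' @export
overlap_partition <- function(systems, gold) {
  stopifnot(length(systems) >= 1, !is.null(names(systems)),
            all(nzchar(names(systems))))
  gk <- unique(triple_key(gold))
  member <- vapply(systems, function(s) gk %in% unique(triple_key(s)),
                   logical(length(gk)))
  member <- matrix(member, nrow = length(gk),
                   dimnames = list(NULL, names(systems)))
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(systems)))
  names(combos) <- names(systems)
  region <- apply(combos, 1, function(sel) {
    if (!any(sel)) "none" else paste(names(systems)[sel], collapse = "+")
  })
  count <- apply(combos, 1, function(sel) {
    sum(apply(member, 1, function(m) all(m == sel)))
  })
  arrange(tibble(region = region, count = as.integer(count)),
          dplyr::desc(.data$count), .data$region)
}

#' Percentage share of a total
#'
#' @param count numerator, between 0 and `total`.
#' @param total positive denominator.
#' @return `100 * count / total` (unrounded; callers format to two decimals
#'   for reporting).
#' @export
share_of_total <- function(count, total) {
  if (total <= 0) stop("total must be positive")
  stopifnot(count >= 0, count <= total)
  100 * count / total
}
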