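test_that("micro P/R/F from counts matches hand computation", {
  r <- prf_from_counts(576, 635, 490)
  expect_equal(r$precision, 576 / 1211)
  expect_equal(r$recall, 576 / 1066)
  expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0, 0.7), 0)
  expect_warning(p0 <- prf_from_counts(0, 0, 3), "precision")
  expect_equal(p0$precision, 0)
})

test_that("relation_prf agrees with brute-force membership counting", {
  pred <- triples("d1", "c1", "x1",
                  "d1", "c2", "x1",
                  "d2", "c1", "x2",
                  "d2", "c1", "x2")   # duplicate collapses
  gold <- triples("d1", "c1", "x1",
                  "d2", "c9", "x2")
  r <- relation_prf(pred, gold)
  expect_equal(c(r$tp, r$fp, r$fn), c(1, 2, 1))
  # identity and disjoint cases
  same <- relation_prf(gold, gold)
  expect_equal(c(same$precision, same$recall, same$f1), c(1, 1, 1))
  disj <- relation_prf(triples("d9", "c9", "x9"), gold)
  expect_equal(c(disj$tp, disj$precision, disj$recall), c(0, 0, 0))
  # property: random small sets vs element-by-element counting
  withr::with_seed(99, {
    for (i in 1:20) {
      u <- triples(sample(c("a", "b"), 30, TRUE),
                   sample(paste0("c", 1:4), 30, TRUE),
                   sample(paste0("x", 1:4), 30, TRUE))
      p <- dplyr::distinct(u[sample(30, 12), ])
      g <- dplyr::distinct(u[sample(30, 12), ])
      key <- function(d) paste(d$doc_id, d$chemical_id, d$disease_id)
      r <- relation_prf(p, g)
      expect_equal(r$tp, sum(vapply(key(p), function(k) k %in% key(g),
                                    logical(1))))
      expect_equal(r$fn, sum(!vapply(key(g), function(k) k %in% key(p),
                                     logical(1))))
    }
  })
})

test_that("exact annotation matching requires identical span and ID set", {
  a <- ann_row("d1", 10, 15, "aspir", "chemical", "D900001")
  expect_true(annotation_match(a, a))
  b <- ann_row("d1", 10, 15, "aspir", "chemical", "D900002")
  expect_false(annotation_match(a, b))
  c_off <- ann_row("d1", 11, 15, "spir", "chemical", "D900001")
  expect_false(annotation_match(a, c_off))
})

test_that("NER scoring works at mention and document-concept level", {
  gold <- dplyr::bind_rows(
    ann_row("d1", 0, 5, "drugA", "chemical", "D900001"),
    ann_row("d1", 10, 15, "drugA", "chemical", "D900001"),
    ann_row("d2", 0, 5, "drugB", "chemical", "D900002"))
  same <- ner_prf(gold, gold, "mention")
  expect_equal(c(same$precision, same$recall, same$f1), c(1, 1, 1))
  pred <- dplyr::bind_rows(gold, ann_row("d2", 6, 8, "zz", "chemical",
                                         "D900003"))
  r <- ner_prf(pred, gold, "mention")
  expect_equal(c(r$tp, r$fp, r$fn), c(3, 1, 0))
  # two mentions of the same (doc, ID) collapse to one unit
  rc <- ner_prf(pred, gold, "concept_doc")
  expect_equal(c(rc$tp, rc$fp, rc$fn), c(2, 1, 0))
})

test_that("the NER-error filter drops relations built on mismatched annotations", {
  gold_ann <- dplyr::bind_rows(
    ann_row("d1", 0, 5, "drugA", "chemical", "D900001"),
    ann_row("d1", 10, 16, "illnes", "disease", "D910001"),
    ann_row("d2", 0, 5, "drugB", "chemical", "D900002"),
    ann_row("d2", 10, 16, "illnes", "disease", "D910002"))
  pred_ann <- gold_ann
  pred_ann$concept_ids[[4]] <- "D919999"   # wrong disease ID in d2
  gold_rel <- triples("d1", "D900001", "D910001",
                      "d2", "D900002", "D910002")
  pred_rel <- triples("d1", "D900001", "D910001",
                      "d2", "D900002", "D919999")
  f <- ner_error_filter(pred_rel, gold_rel, pred_ann, gold_ann)
  expect_equal(f$gold, gold_rel[1, ])
  expect_equal(f$predicted, pred_rel[1, ])
  # subset-ness and idempotence
  f2 <- ner_error_filter(f$predicted, f$gold, pred_ann, gold_ann)
  expect_equal(f2, f)
  # all annotations matching and all relation IDs verified: identity
  id <- ner_error_filter(gold_rel, gold_rel, gold_ann, gold_ann)
  expect_equal(id$gold, gold_rel)
  expect_equal(id$predicted, gold_rel)
})

test_that("maximum recall counts indexable gold relations", {
  cand <- triples("d1", "c1", "x1",
                  "d1", "c1", "x2",
                  "d2", "c2", "x1")
  gold <- triples("d1", "c1", "x1",
                  "d1", "c1", "x2",
                  "d2", "c2", "x1",
                  "d2", "c9", "x9")
  expect_equal(max_recall(cand, gold), 0.75)
  expect_equal(max_recall(gold, gold), 1)
})

test_that("ROC endpoints, monotonicity, bounds and reversal symmetry hold", {
  # perfectly separating votes
  tal <- tibble::tibble(doc_id = "d1",
                        chemical_id = paste0("c", 1:10),
                        disease_id = "x1",
                        scope = "abstract",
                        positive_votes = c(rep(5L, 4), rep(0L, 6)),
                        per_sentence_votes = list(NULL))
  cand <- tal[, c("doc_id", "chemical_id", "disease_id", "scope")]
  gold <- cand[1:4, c("doc_id", "chemical_id", "disease_id")]
  pts <- roc_points(tal, cand, gold)
  expect_equal(roc_auc(pts), 1)
  expect_equal(unlist(pts[pts$threshold == 0, c("tpr", "fpr")]),
               c(tpr = 1, fpr = 1))
  expect_equal(unlist(pts[pts$threshold == 6, c("tpr", "fpr")]),
               c(tpr = 0, fpr = 0))
  expect_true(all(diff(pts$tpr) >= 0) && all(diff(pts$fpr) >= 0))
  # label-independent votes give AUC near 1/2; reversal flips the curve
  withr::with_seed(7, {
    n <- 1000
    tal2 <- tibble::tibble(doc_id = "d1",
                           chemical_id = paste0("c", seq_len(2 * n)),
                           disease_id = "x1", scope = "abstract",
                           positive_votes = sample(0:5, 2 * n, TRUE),
                           per_sentence_votes = list(NULL))
    cand2 <- tal2[, c("doc_id", "chemical_id", "disease_id", "scope")]
    gold2 <- cand2[seq_len(n), c("doc_id", "chemical_id", "disease_id")]
    pts2 <- roc_points(tal2, cand2, gold2)
    auc2 <- roc_auc(pts2)
    expect_lt(abs(auc2 - 0.5), 0.05)
    rev_tal <- tal2
    rev_tal$positive_votes <- 5L - tal2$positive_votes
    # reversing scores with thresholds t is the complement curve
    rev_auc <- roc_auc(roc_points(rev_tal, cand2, gold2, thresholds = 6:0))
    expect_equal(rev_auc + auc2, 1, tolerance = 0.02)
    expect_true(auc2 >= 0 && auc2 <= 1)
  })
  # unindexable gold enters the universe with zero votes and caps the TPR
  gold3 <- dplyr::bind_rows(gold, triples("d9", "c9", "x9"))
  pts3 <- roc_points(tal, cand, gold3)
  expect_equal(max(pts3$tpr[pts3$threshold > 0]), 4 / 5)
})

test_that("overlap partition equals brute-force membership enumeration", {
  gold <- triples("d1", "c1", "x1",
                  "d1", "c2", "x1",
                  "d2", "c1", "x2",
                  "d3", "c3", "x3")
  sysA <- gold[1:3, ]
  sysB <- gold[2:3, ]
  sysC <- triples("d1", "c1", "x1", "d9", "c9", "x9")
  part <- overlap_partition(list(A = sysA, B = sysB, C = sysC), gold)
  expect_equal(sum(part$count), nrow(gold))
  get <- function(region) part$count[part$region == region]
  expect_equal(get("A+C"), 1L)       # d1 c1 x1
  expect_equal(get("A+B"), 2L)       # rows 2 and 3
  expect_equal(get("none"), 1L)      # d3 c3 x3
  # three identical systems equal to gold: everything in the core region
  all3 <- overlap_partition(list(A = gold, B = gold, C = gold), gold)
  expect_equal(all3$count[all3$region == "A+B+C"], nrow(gold))
  expect_equal(sum(all3$count[all3$region != "A+B+C"]), 0L)
  # disjoint systems: no pairwise regions
  disj <- overlap_partition(list(A = gold[1, ], B = gold[2, ]), gold)
  expect_equal(disj$count[disj$region == "A+B"], 0L)
  expect_equal(disj$count[disj$region == "none"], 2L)
})

test_that("percentage shares are exact and guard the denominator", {
  expect_equal(share_of_total(485, 1066), 100 * 485 / 1066)
  expect_equal(share_of_total(0, 10), 0)
  expect_equal(share_of_total(10, 10), 100)
  expect_error(share_of_total(1, 0), "total")
})
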