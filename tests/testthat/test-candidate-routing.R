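test_that("candidate pairs are the per-document product of distinct MeSH IDs", {
  ann <- dplyr::bind_rows(
    ann_row("d1", 0, 1, "a", "chemical", "D900001"),
    ann_row("d1", 2, 3, "b", "chemical", "D900002"),
    ann_row("d1", 4, 5, "x", "disease", "D910001"))
  pairs <- generate_candidate_pairs(ann)
  expect_equal(nrow(pairs), 2)
  expect_setequal(pairs$chemical_id, c("D900001", "D900002"))
  expect_equal(unique(pairs$disease_id), "D910001")
  # no chemicals -> empty
  expect_equal(nrow(generate_candidate_pairs(ann[3, ])), 0)
  # duplicated mentions and composite IDs still give unique pairs
  ann2 <- dplyr::bind_rows(
    ann_row("d2", 0, 1, "a", "chemical", c("D900001", "D900002")),
    ann_row("d2", 2, 3, "a", "chemical", "D900001"),
    ann_row("d2", 4, 5, "b", "chemical", "D900003"),
    ann_row("d2", 6, 7, "x", "disease", "D910001"),
    ann_row("d2", 8, 9, "y", "disease", c("D910002", "D910003")),
    ann_row("d2", 10, 11, "y", "disease", "D910004"))
  pairs2 <- generate_candidate_pairs(ann2)
  expect_equal(nrow(pairs2), 12)  # 3 chemical IDs x 4 disease IDs
  expect_equal(nrow(dplyr::distinct(pairs2)), 12)
})

test_that("the CID pattern respects the gap limit and trigger", {
  mk <- function(gap_text) {
    text <- paste0("drugA", gap_text, "illnessB here")
    ann <- dplyr::bind_rows(
      ann_row("d1", 0, 5, "drugA", "chemical", "D900001"),
      ann_row("d1", 5 + nchar(gap_text), 5 + nchar(gap_text) + 8,
              "illnessB", "disease", "D910001"))
    list(text = text, ann = ann)
  }
  gap15 <- "-induced xxxxxx"   # 15 characters, contains trigger
  stopifnot(nchar(gap15) == 15)
  m <- mk(gap15)
  expect_true(match_cid_pattern(m$text, m$ann, "D900001", "D910001"))
  gap16 <- "-induced xxxxxxx"  # 16 characters: one past the limit
  m <- mk(gap16)
  expect_false(match_cid_pattern(m$text, m$ann, "D900001", "D910001"))
  # trigger absent within the window
  m <- mk(" causes thing ")
  expect_false(match_cid_pattern(m$text, m$ann, "D900001", "D910001"))
  # trigger matching is case-insensitive by default and covers inflections
  m <- mk(" Induces the ")
  expect_true(match_cid_pattern(m$text, m$ann, "D900001", "D910001"))
  # disease before chemical never matches ("before" is directional)
  ann_rev <- dplyr::bind_rows(
    ann_row("d1", 0, 8, "illnessB", "disease", "D910001"),
    ann_row("d1", 17, 22, "drugA", "chemical", "D900001"))
  expect_false(match_cid_pattern("illnessB-induced drugA", ann_rev,
                                 "D900001", "D910001"))
})

test_that("sentence splitting keeps the title separate and respects abbreviations", {
  s <- split_sentences("A title.", "First point. Second point.")
  expect_equal(nrow(s), 3)  # title + 2 abstract sentences
  expect_equal(s$start[1], 0)
  expect_equal(s$end[1], nchar("A title."))
  s2 <- split_sentences("T.", "We used e.g. Aspirin today. It worked.")
  # "e.g." must not split even before an uppercase word
  expect_equal(nrow(s2), 3)
  s3 <- split_sentences("T.", "no terminator at all")
  expect_equal(nrow(s3), 2)
  expect_equal(s3$end[2], nchar("T. no terminator at all"))
  # spans ordered, non-overlapping, covering text minus inter-span whitespace
  corp <- toy_corpus()
  sp <- split_sentences(corp$documents$title, corp$documents$abstract)
  expect_true(all(diff(sp$start) > 0))
  expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
  gaps <- substring(corp$documents$text, sp$end[-nrow(sp)] + 1, sp$start[-1])
  expect_true(all(grepl("^\\s*$", gaps)))
})

test_that("scope classes are mutually exclusive, exhaustive and match the toy corpus", {
  corp <- toy_corpus()
  routed <- route_candidates(corp)
  cand <- routed$candidates
  expect_equal(nrow(cand), 3)
  scope_of <- setNames(cand$scope, cand$disease_id)
  # pattern wins even though the pair also co-occurs in a sentence
  expect_equal(unname(scope_of["D007674"]), "pattern")
  expect_equal(unname(scope_of["D000740"]), "sentence")
  expect_equal(unname(scope_of["D034381"]), "abstract")
  idx <- cand$sentence_indices[[which(cand$disease_id == "D000740")]]
  expect_equal(idx, 3L)
  # partition: every candidate in exactly one class
  expect_equal(sum(cand$scope == "pattern") + sum(cand$scope == "sentence") +
                 sum(cand$scope == "abstract"), nrow(cand))
})

test_that("classify_scope agrees with a brute-force mention-by-sentence scan", {
  for (seed in c(11, 12, 13)) {
    fx <- generate_corpus(fixture_config(n_documents = 5, rng_seed = seed))
    corp <- resolve_acronyms(fx$corpus)
    ann_all <- exclude_non_mesh(corp$annotations)
    routed <- route_candidates(corp, annotations = ann_all)
    cand <- routed$candidates
    for (k in seq_len(nrow(cand))) {
      cd <- cand[k, ]
      text <- corp$documents$text[corp$documents$doc_id == cd$doc_id]
      ann <- ann_all[ann_all$doc_id == cd$doc_id, ]
      sents <- routed$sentences[routed$sentences$doc_id == cd$doc_id, ]
      has <- function(v, id) id %in% v
      chem <- ann[ann$concept_class == "chemical" &
                    purrr::map_lgl(ann$concept_ids, has, cd$chemical_id), ]
      dis <- ann[ann$concept_class == "disease" &
                   purrr::map_lgl(ann$concept_ids, has, cd$disease_id), ]
      # brute force: every mention pair, every sentence
      pat <- FALSE
      co <- integer()
      for (a in seq_len(nrow(chem))) {
        for (b in seq_len(nrow(dis))) {
          gap <- dis$start[b] - chem$end[a]
          between <- substr(text, chem$end[a] + 1, dis$start[b])
          if (gap >= 0 && gap <= 15 &&
              grepl("induce", between, ignore.case = TRUE)) {
            pat <- TRUE
          }
          for (s in seq_len(nrow(sents))) {
            in_s <- function(p) sents$start[s] <= p & p < sents$end[s]
            if (in_s(chem$start[a]) && in_s(dis$start[b])) {
              co <- union(co, sents$index[s])
            }
          }
        }
      }
      expected <- if (pat) "pattern" else if (length(co)) "sentence" else "abstract"
      expect_equal(cd$scope, expected)
      if (expected == "sentence") {
        expect_equal(cd$sentence_indices[[1]], sort(co))
      }
    }
  }
})
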