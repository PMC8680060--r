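test_that("syntheticCorpusSpec validates rates and ranges", {
  spec <- syntheticCorpusSpec()
  expect_equal(spec$n_docs, 10L)
  expect_equal(spec$sentences_per_doc, c(5L, 5L))
  expect_error(syntheticCorpusSpec(mention_rate = 2.5))
  expect_error(syntheticCorpusSpec(nesting_rate = -0.1))
  expect_error(syntheticCorpusSpec(misspelling_distance = 0L))
  expect_error(syntheticCorpusSpec(sentences_per_doc = c(3L, 2L)))
})

test_that("makeDictionary is deterministic with pairwise-separated terms", {
  d1 <- makeDictionary(15, seed = 9)
  d2 <- makeDictionary(15, seed = 9)
  expect_identical(conceptEntries(d1$concepts), conceptEntries(d2$concepts))
  expect_identical(d1$abbreviations, d2$abbreviations)
  terms <- conceptEntries(d1$concepts)$term
  expect_length(terms, 15L)
  expect_false(anyDuplicated(terms) > 0)
  for (i in seq_along(terms)) {
    others <- terms[-i]
    expect_gte(min(levenshteinDistance(terms[i], others)), 3L)
  }
  # single-concept dictionary
  expect_equal(nrow(conceptEntries(makeDictionary(1, seed = 2)$concepts)), 1L)
})

test_that("abbreviations map back to dictionary terms", {
  d <- makeDictionary(20, seed = 10)
  expect_true(length(d$abbreviations) > 0)
  expect_true(all(d$abbreviations %in% conceptEntries(d$concepts)$term))
})

test_that("perturbTerm hits the exact distance and is seeded", {
  for (dst in 1:3) {
    out <- perturbTerm("prednisona", dst, seed = 21)
    expect_equal(levenshteinDistance("prednisona", out), dst)
  }
  expect_identical(perturbTerm("prednisona", 2, seed = 5),
                   perturbTerm("prednisona", 2, seed = 5))
  expect_identical(perturbTerm("prednisona", 0), "prednisona")
  expect_error(perturbTerm("ab", 2), "smaller than term length")
  # spaces in multi-token terms are preserved as separators
  out <- perturbTerm("calcio ionico", 1, seed = 3)
  expect_equal(levenshteinDistance("calcio ionico", out), 1L)
})

test_that("generateCorpus is deterministic and self-consistent", {
  dict <- makeDictionary(12, seed = 5)
  spec <- syntheticCorpusSpec(n_docs = 4, seed = 5)
  c1 <- generateCorpus(spec, dict$concepts, dict$abbreviations)
  c2 <- generateCorpus(spec, dict$concepts, dict$abbreviations)
  expect_identical(lapply(c1$docs, docText), lapply(c2$docs, docText))
  expect_identical(lapply(c1$docs, mentions), lapply(c2$docs, mentions))
  # manifest counts match the realized corpus
  expect_equal(c1$manifest$n_docs, 4L)
  expect_equal(c1$manifest$n_sentences, length(c1$sentences))
  expect_equal(c1$manifest$n_mentions,
               sum(vapply(c1$docs, function(d) nrow(mentions(d)),
                          integer(1))))
  # default spec yields n_docs * 5 sentences
  expect_equal(c1$manifest$n_sentences, 20L)
})

test_that("generated corpora pass validation with zero violations", {
  dict <- makeDictionary(15, seed = 8)
  corp <- generateCorpus(syntheticCorpusSpec(n_docs = 5, seed = 8),
                         dict$concepts, dict$abbreviations)
  v <- validateCorpus(corp$docs)
  expect_length(v$violations, 0L)
  expect_equal(sum(v$summary$nested_pairs), corp$manifest$n_nested)
})

test_that("gold tags equal the codec encoding of gold mentions", {
  dict <- makeDictionary(10, seed = 14)
  corp <- generateCorpus(syntheticCorpusSpec(n_docs = 3, seed = 14),
                         dict$concepts, dict$abbreviations)
  k <- 0L
  for (d in corp$docs) {
    txt <- docText(d); m <- mentions(d)
    sp <- splitSentences(txt)
    for (i in seq_len(nrow(sp))) {
      tk <- tokenize(txt, c(sp$start[i], sp$end[i]))
      inside <- m[m$start >= sp$start[i] & m$end <= sp$end[i], , drop = FALSE]
      k <- k + 1L
      expect_identical(corp$sentences[[k]]$tags,
                       encodeTags(tk, inside, corp$schema))
    }
  }
})

test_that("rate zero switches produce the promised corpora", {
  dict <- makeDictionary(10, seed = 3)
  # no mentions at all
  c0 <- generateCorpus(syntheticCorpusSpec(n_docs = 2, mention_rate = 0,
                                           seed = 3), dict$concepts)
  expect_equal(c0$manifest$n_mentions, 0L)
  expect_true(all(unlist(lapply(c0$sentences, `[[`, "tags")) == "O"))
  # no nesting -> no V tags
  c1 <- generateCorpus(syntheticCorpusSpec(n_docs = 3, nesting_rate = 0,
                                           misspelling_rate = 0, seed = 3),
                       dict$concepts)
  expect_equal(c1$manifest$n_nested, 0L)
  expect_false(any(grepl("^V-", unlist(lapply(c1$sentences, `[[`, "tags")))))
  # no misspelling -> every top-level surface is a dictionary term
  terms <- conceptEntries(dict$concepts)$term
  for (d in c1$docs) {
    m <- mentions(d)
    expect_true(all(tolower(m$surface) %in% terms))
  }
})

test_that("misspelled surfaces are at the exact configured distance", {
  dict <- makeDictionary(10, seed = 19)
  spec <- syntheticCorpusSpec(n_docs = 4, misspelling_rate = 1,
                              misspelling_distance = 2,
                              abbreviation_rate = 0, nesting_rate = 0,
                              seed = 19)
  corp <- generateCorpus(spec, dict$concepts, NULL)
  terms <- conceptEntries(dict$concepts)$term
  ids <- conceptEntries(dict$concepts)$concept_id
  for (d in corp$docs) {
    m <- mentions(d)
    for (i in seq_len(nrow(m))) {
      gold <- terms[match(m$concept_id[i], ids)]
      expect_equal(levenshteinDistance(tolower(m$surface[i]), gold), 2L)
    }
  }
  expect_equal(corp$manifest$n_misspelled, corp$manifest$n_mentions)
})

test_that("nesting is consistent per concept across the corpus", {
  dict <- makeDictionary(15, seed = 23)
  spec <- syntheticCorpusSpec(n_docs = 8, nesting_rate = 0.5,
                              misspelling_rate = 0, abbreviation_rate = 0,
                              seed = 23)
  corp <- generateCorpus(spec, dict$concepts, NULL)
  # for every concept: either all its occurrences carry an inner mention or
  # none does, and the inner type is always the same
  occ <- list()
  for (d in corp$docs) {
    m <- mentions(d)
    top <- m[!is.na(m$concept_id), , drop = FALSE]
    for (i in seq_len(nrow(top))) {
      inner <- m[is.na(m$concept_id) & m$start == top$start[i] &
                   m$end < top$end[i], , drop = FALSE]
      cid <- top$concept_id[i]
      occ[[cid]] <- c(occ[[cid]], if (nrow(inner)) inner$entity_type[1]
                                  else "<none>")
    }
  }
  for (cid in names(occ))
    expect_length(unique(occ[[cid]]), 1L)
})
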