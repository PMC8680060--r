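mkDict <- function(ids, terms) {
  conceptDictionary(data.frame(concept_id = ids, term = terms,
                               stringsAsFactors = FALSE))
}

test_that("levenshteinDistance matches hand-checked examples", {
  expect_equal(levenshteinDistance("durogesic", "duragesic"), 1L)
  expect_equal(levenshteinDistance("abc", "abc"), 0L)
  expect_equal(levenshteinDistance("", "abc"), 3L)
  expect_equal(levenshteinDistance("abc", ""), 3L)
  expect_equal(levenshteinDistance("kitten", "sitting"), 3L)
  expect_equal(levenshteinDistance("flaw", c("lawn", "flaws", "flaw")),
               c(2L, 1L, 0L))
})

test_that("distances are over code points, not bytes", {
  expect_equal(levenshteinDistance("ácido", "acido"), 1L)
  expect_equal(levenshteinDistance("ñ", "n"), 1L)
  expect_equal(levenshteinDistance("ñoño", "ñoño"), 0L)
})

test_that("levenshtein agrees with the adist oracle on random pairs", {
  set.seed(11)
  for (i in 1:500) {
    a <- randomString(); b <- randomString()
    expect_equal(levenshteinDistance(a, b),
                 as.integer(utils::adist(a, b)[1, 1]),
                 label = sprintf("lev('%s','%s')", a, b))
  }
})

test_that("levenshtein satisfies metric properties", {
  set.seed(12)
  for (i in 1:200) {
    a <- randomString(8); b <- randomString(8); c <- randomString(8)
    dab <- levenshteinDistance(a, b)
    expect_equal(dab, levenshteinDistance(b, a))               # symmetry
    expect_equal(levenshteinDistance(a, a), 0L)                # identity
    expect_identical(dab == 0L, a == b)
    dac <- levenshteinDistance(a, c)
    dcb <- levenshteinDistance(c, b)
    expect_lte(dab, dac + dcb)                                 # triangle
  }
})

test_that("normalizeMention stages: exact, levenshtein, fuzzy, unmatched", {
  dict <- mkDict(c("C1", "C2"), c("prednisona", "tenecteplasa"))
  r <- normalizeMention("Prednisona", dict)
  expect_equal(r$concept_id, "C1")
  expect_equal(r$stage, "exact")
  expect_equal(r$score, 0)

  r <- normalizeMention("prednisena", dict)   # distance 1
  expect_equal(r$concept_id, "C1")
  expect_equal(r$stage, "levenshtein")
  expect_equal(r$score, 1L)

  r <- normalizeMention("tenecteplosas", dict)  # distance 2, sim 11/13 = .846
  expect_equal(r$concept_id, "C2")
  expect_equal(r$stage, "fuzzy")
  expect_equal(r$score, 1 - 2 / 13, tolerance = 1e-12)

  r <- normalizeMention("xyzzy", dict)
  expect_true(is.na(r$concept_id))
  expect_equal(r$stage, "unmatched")
})

test_that("similarity 0.7 stays below the 0.80 default threshold", {
  # a 10-char term at distance 3: similarity 0.7 -> unmatched
  dict <- mkDict("C1", "abcdefghij")
  r <- normalizeMention("abcdefgxyz", dict)
  expect_equal(levenshteinDistance("abcdefgxyz", "abcdefghij"), 3L)
  expect_equal(r$stage, "unmatched")
})

test_that("exact match always wins over near matches", {
  dict <- mkDict(c("C1", "C2"), c("insulina", "insulinas"))
  r <- normalizeMention("insulina", dict)
  expect_equal(r$stage, "exact")
  expect_equal(r$concept_id, "C1")
})

test_that("abbreviations expand before lookup, including multi-token keys", {
  dict <- mkDict(c("C1", "C2"),
                 c("hemoglobina", "citoqueratina siete"))
  ab <- c("hb" = "hemoglobina", "ck 7" = "citoqueratina siete")
  expect_equal(expandAbbreviations("hb", ab), "hemoglobina")
  expect_equal(expandAbbreviations("ck 7 alta", ab),
               "citoqueratina siete alta")
  r <- normalizeMention("HB", dict, abbrevs = ab)
  expect_equal(r$concept_id, "C1")
  expect_equal(r$stage, "exact")
  r2 <- normalizeMention("ck 7", dict, abbrevs = ab)
  expect_equal(r2$concept_id, "C2")
})

test_that("ambiguous terms follow the configured policy", {
  dict <- mkDict(c("C9", "C2"), c("cortisol", "cortisol"))
  r <- normalizeMention("cortisol", dict)
  expect_equal(r$concept_id, "C2")   # lexicographically smallest id
  expect_true(r$ambiguous)
  r2 <- normalizeMention("cortisol", dict,
                         cfg = normalizerConfig(ambiguity_policy = "reject"))
  expect_true(is.na(r2$concept_id))
  expect_equal(r2$stage, "unmatched")
  expect_true(r2$ambiguous)
})

test_that("dictionary terms are case-normalized on construction", {
  dict <- mkDict("C1", "Heparina Sodica")
  expect_equal(conceptEntries(dict)$term, "heparina sodica")
  expect_equal(normalizeMention("heparina sodica", dict)$stage, "exact")
})

test_that("dictionary and abbreviation TSV readers work and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("C1\tprednisona", "C2\tinsulina"), f)
  dict <- readConceptDictionary(f)
  expect_equal(conceptIds(dict), c("C1", "C2"))
  fa <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("hb\themoglobina", "HB\totra"), fa)
  expect_error(readAbbreviationDictionary(fa), "duplicate")
})

test_that("normalizeCorpus fills concept ids and counts stages", {
  dict <- mkDict(c("C1", "C2"), c("prednisona", "insulina"))
  text <- "toma prednisona y tambien insulena"
  m <- data.frame(mention_id = c("T1", "T2"),
                  entity_type = "NORMALIZABLES",
                  start = c(5L, 26L), end = c(15L, 34L),
                  surface = c("prednisona", "insulena"),
                  concept_id = NA_character_, stringsAsFactors = FALSE)
  docs <- list(d1 = annotatedDocument("d1", text, m))
  out <- normalizeCorpus(docs, dict)
  got <- mentions(out$d1)
  expect_equal(got$concept_id, c("C1", "C2"))
  st <- attr(out, "stages")
  expect_equal(unname(st["exact"]), 1L)
  expect_equal(unname(st["levenshtein"]), 1L)
  res <- attr(out, "results")
  expect_equal(nrow(res), 2L)
  # empty corpus passes through
  empty <- normalizeCorpus(list(), dict)
  expect_length(empty, 0L)
})

test_that("conceptizeText replaces longest match first and is idempotent", {
  dict <- mkDict(c("C2", "C3"), c("calcio ionico", "calcio"))
  expect_equal(conceptizeText("calcio ionico alto", dict), "C2 alto")
  expect_equal(conceptizeText("nivel de calcio", dict), "nivel de C3")
  expect_equal(conceptizeText("sin terminos", dict), "sin terminos")
  once <- conceptizeText("calcio ionico y calcio", dict)
  expect_equal(once, "C2 y C3")
  expect_equal(conceptizeText(once, dict), once)
})
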