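test_that("tag inventory has 5 tags per type plus O, in fixed order", {
  inv <- buildTagset(pharmaconerTypes())
  expect_length(inv, 21L)
  expect_equal(inv[1:5], paste0(c("B", "M", "E", "W", "V"), "-NORMALIZABLES"))
  expect_equal(inv[21], "O")
  expect_length(buildTagset(c("A", "B", "C")), 16L)
  expect_error(buildTagset(character()), "non-empty")
  expect_error(buildTagset(c("A", "A")), "duplicate")
})

test_that("encodeTags covers W, B/M/E and O cases", {
  toks <- tokenize("toma acido acetil salicilico y calcio")
  men <- data.frame(entity_type = c("NORMALIZABLES", "PROTEINAS"),
                    start = c(5L, 31L), end = c(28L, 37L))
  tags <- encodeTags(toks, men, tagSchema())
  expect_equal(tags, c("O", "B-NORMALIZABLES", "M-NORMALIZABLES",
                       "E-NORMALIZABLES", "O", "W-PROTEINAS"))
})

test_that("nested mentions produce V on the shared token", {
  toks <- tokenize("calcio ionico corregido")
  men <- data.frame(entity_type = c("NORMALIZABLES", "NORMALIZABLES"),
                    start = c(0L, 0L), end = c(23L, 6L))
  tags <- encodeTags(toks, men, tagSchema())
  expect_equal(tags, c("V-NORMALIZABLES", "M-NORMALIZABLES",
                       "E-NORMALIZABLES"))
})

test_that("V takes the innermost covering mention's type", {
  toks <- tokenize("alfa beta gama")
  men <- data.frame(entity_type = c("PROTEINAS", "UNCLEAR"),
                    start = c(0L, 0L), end = c(14L, 4L))
  tags <- encodeTags(toks, men, tagSchema())
  expect_equal(tags[1], "V-UNCLEAR")
})

test_that("no mentions encode to all O; unknown types error", {
  toks <- tokenize("sin menciones")
  expect_equal(encodeTags(toks, NULL, tagSchema()), c("O", "O"))
  men <- data.frame(entity_type = "NOPE", start = 0L, end = 3L)
  expect_error(encodeTags(toks, men, tagSchema()), "not in schema")
})

test_that("misaligned boundaries error by default and snap on request", {
  toks <- tokenize("paracetamol oral")
  men <- data.frame(entity_type = "NORMALIZABLES", start = 0L, end = 5L)
  expect_error(encodeTags(toks, men, tagSchema()), "misaligned")
  expect_warning(tags <- encodeTags(toks, men, tagSchema(),
                                    misaligned = "snap"), "snapping")
  expect_equal(tags, c("W-NORMALIZABLES", "O"))
})

test_that("decode inverts encode on flat and nested patterns", {
  text <- "mide calcio ionico corregido y tenecteplasa pura"
  toks <- tokenize(text)
  men <- data.frame(entity_type = c("NORMALIZABLES", "NORMALIZABLES",
                                    "PROTEINAS"),
                    start = c(5L, 5L, 31L), end = c(28L, 11L, 43L))
  tags <- encodeTags(toks, men, tagSchema())
  dec <- decodeTags(toks, tags, tagSchema(), text = text)
  expect_equal(nrow(dec), 3L)
  expect_setequal(paste(dec$entity_type, dec$start, dec$end),
                  paste(men$entity_type, men$start, men$end))
  expect_equal(dec$surface[dec$start == 5L & dec$end == 28L],
               "calcio ionico corregido")
})

test_that("decoding an all-V run uses the V type for inner and outer", {
  toks <- tokenize("abc def")
  dec <- decodeTags(toks, c("V-PROTEINAS", "E-UNCLEAR"), tagSchema())
  expect_equal(nrow(dec), 2L)
  expect_setequal(dec$entity_type, c("PROTEINAS", "UNCLEAR"))
  inner <- dec[dec$end == 3L, ]
  expect_equal(inner$entity_type, "PROTEINAS")
})

test_that("repairTags fixes orphans and is idempotent", {
  sch <- tagSchema()
  expect_equal(repairTags("M-PROTEINAS", sch), "W-PROTEINAS")
  expect_equal(repairTags(c("B-PROTEINAS", "O"), sch),
               c("W-PROTEINAS", "O"))
  expect_equal(repairTags(c("O", "E-UNCLEAR"), sch), c("O", "W-UNCLEAR"))
  expect_equal(repairTags(c("B-PROTEINAS", "M-UNCLEAR"), sch),
               c("W-PROTEINAS", "W-UNCLEAR"))
  # mid-run type change closes the first run
  r <- repairTags(c("B-PROTEINAS", "M-PROTEINAS", "M-UNCLEAR",
                    "E-UNCLEAR"), sch)
  expect_true(isWellFormedTags(r, sch))
  # idempotence on random raw sequences
  set.seed(5)
  inv <- tagInventory(sch)
  for (i in 1:50) {
    raw <- sample(inv, sample(1:12, 1), replace = TRUE)
    rep1 <- repairTags(raw, sch)
    expect_identical(repairTags(rep1, sch), rep1)
    expect_true(isWellFormedTags(rep1, sch))
  }
})

test_that("well-formed gold encodings need no repair", {
  dict <- makeDictionary(8, seed = 3)
  corp <- generateCorpus(syntheticCorpusSpec(n_docs = 3, seed = 3),
                         dict$concepts, dict$abbreviations)
  for (s in corp$sentences)
    expect_true(isWellFormedTags(s$tags, corp$schema))
})

test_that("bmewovToBio maps prefixes as documented", {
  expect_equal(bmewovToBio(c("B-X", "M-X", "E-X", "W-X", "V-X", "O")),
               c("B-X", "I-X", "I-X", "B-X", "B-X", "O"))
})

test_that("toConll produces one row per token with Others for O", {
  doc <- tinyDoc()
  conll <- toConll(doc, tagSchema())
  expect_equal(unique(conll$sentence), c(1L, 2L))
  expect_true(all(c("token", "entity_type", "start", "end", "tag") %in%
                    names(conll)))
  expect_equal(conll$entity_type[conll$tag == "O"],
               rep("Others", sum(conll$tag == "O")))
  pred <- conll[conll$token == "prednisona", ]
  expect_equal(pred$tag, "W-NORMALIZABLES")
  expect_equal(pred$start, 38L)
  expect_equal(pred$end, 48L)
  # nested "calcio" shows as V on the shared token
  expect_equal(conll$tag[conll$token == "calcio"], "V-NORMALIZABLES")
})

test_that("conll lines round trip through fromConll", {
  conll <- toConll(tinyDoc(), tagSchema())
  lines <- writeConllLines(conll)
  back <- fromConll(lines)
  expect_equal(back, conll)
})

test_that("conll file i/o round trips and skips -DOCSTART-", {
  conll <- toConll(tinyDoc(), tagSchema())
  f <- withr::local_tempfile(fileext = ".conll")
  writeConll(conll, f)
  back <- readConll(f)
  expect_equal(back, conll)
  back2 <- fromConll(c("-DOCSTART- x", writeConllLines(conll)))
  expect_equal(back2, conll)
})

test_that("ragged or non-integer CoNLL rows error with the line number", {
  expect_error(fromConll(c("a\tOthers\t0\t1\tO", "bad\trow")),
               "line 2")
  expect_error(fromConll("a\tOthers\tx\ty\tO"), "non-integer")
})
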