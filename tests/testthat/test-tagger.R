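## Unit tests use a deliberately small configuration (tinyTaggerConfig) so
## the whole file runs in seconds; full-size behaviour is covered by the
## acceptance tests.

makeToySentences <- function() {
  sch <- tagSchema(c("DRUG", "PROT"))
  s1 <- list(tokens = tokenize("toma farmacil dos veces"),
             tags = c("O", "W-DRUG", "O", "O"))
  s2 <- list(tokens = tokenize("la protena alfa beta sube"),
             tags = c("O", "B-PROT", "M-PROT", "E-PROT", "O"))
  list(schema = sch, sentences = list(s1, s2))
}

test_that("taggerConfig validates its arguments", {
  cfg <- taggerConfig()
  expect_equal(cfg$word_dim, 300L)
  expect_equal(cfg$sense_dim, 128L)
  expect_equal(cfg$lstm_hidden, 100L)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$learning_rate, 0.005)
  expect_equal(cfg$epochs, 100L)
  expect_error(taggerConfig(dropout = 1), "dropout")
  expect_error(taggerConfig(learning_rate = 0))
  expect_error(taggerConfig(optimizer = "adam"))
})

test_that("initTaggerModel builds vocabularies and seeded parameters", {
  toy <- makeToySentences()
  cfg <- tinyTaggerConfig()
  m1 <- initTaggerModel(toy$sentences, toy$schema, cfg)
  m2 <- initTaggerModel(toy$sentences, toy$schema, cfg)
  expect_s4_class(m1, "TaggerModel")
  expect_identical(m1@params, m2@params)
  expect_true("farmacil" %in% m1@vocab$words)
  expect_true(all(c("<UNK>", "a") %in% m1@vocab$chars) ||
                length(m1@vocab$chars) > 1)
  # feature dimension is word + sense + 2 * char_hidden
  f <- assembleFeatures(m1, toy$sentences[[1]]$tokens)
  expect_equal(nrow(f), cfg$word_dim + cfg$sense_dim + 2L * cfg$char_hidden)
  expect_equal(ncol(f), 4L)
})

test_that("charEncode is deterministic and maps unknown chars to UNK", {
  toy <- makeToySentences()
  m <- initTaggerModel(toy$sentences, toy$schema, tinyTaggerConfig())
  v1 <- charEncode(m, "farmacil")
  expect_length(v1, 2L * m@config$char_hidden)
  expect_identical(v1, charEncode(m, "farmacil"))
  # a string of entirely unseen characters still encodes
  expect_length(charEncode(m, "ZZZ999"), 2L * m@config$char_hidden)
})

test_that("analytic gradients match numeric differentiation", {
  toy <- makeToySentences()
  cfg <- taggerConfig(char_dim = 3L, char_hidden = 4L, word_dim = 5L,
                      sense_dim = 3L, lstm_hidden = 6L, dropout = 0,
                      epochs = 1L, seed = 11L)
  model <- initTaggerModel(toy$sentences, toy$schema, cfg)
  inv <- tagInventory(toy$schema)
  tokens <- toy$sentences[[2]]$tokens
  gold <- match(toy$sentences[[2]]$tags, inv)
  lg <- clinner:::sentenceLossGrad(model, tokens, gold)
  eps <- 1e-5
  set.seed(42)
  for (nm in names(lg$grads)) {
    P <- model@params[[nm]]
    for (i in sample(length(P), min(6L, length(P)))) {
      if (!is.finite(P[i])) next
      m2 <- model
      p <- m2@params[[nm]]
      p[i] <- P[i] + eps; m2@params[[nm]] <- p
      lp <- clinner:::sentenceLossGrad(m2, tokens, gold, grad = FALSE)$loss
      p[i] <- P[i] - eps; m2@params[[nm]] <- p
      lm <- clinner:::sentenceLossGrad(m2, tokens, gold, grad = FALSE)$loss
      num <- (lp - lm) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training memorizes a single sentence and predicts its gold tags", {
  toy <- makeToySentences()
  cfg <- tinyTaggerConfig(epochs = 150L, dropout = 0.2,
                          learning_rate = 0.05)
  model <- trainTagger(toy$sentences, toy$schema, cfg)
  hist <- modelConfig(model)$loss_history
  expect_length(hist, 150L)
  expect_lt(hist[150], hist[1])
  pred <- predictTagger(model, lapply(toy$sentences, `[[`, "tokens"))
  expect_identical(pred[[1]], toy$sentences[[1]]$tags)
  expect_identical(pred[[2]], toy$sentences[[2]]$tags)
})

test_that("training is deterministic: same seed, same loss history", {
  toy <- makeToySentences()
  cfg <- tinyTaggerConfig(epochs = 5L)
  m1 <- trainTagger(toy$sentences, toy$schema, cfg)
  m2 <- trainTagger(toy$sentences, toy$schema, cfg)
  expect_identical(modelConfig(m1)$loss_history,
                   modelConfig(m2)$loss_history)
  expect_identical(m1@params, m2@params)
})

test_that("prediction is deterministic and repairs by default", {
  toy <- makeToySentences()
  model <- trainTagger(toy$sentences, toy$schema, tinyTaggerConfig(epochs = 3L))
  toks <- list(tokenize("farmacil y protena alfa"))
  p1 <- predictTagger(model, toks)
  p2 <- predictTagger(model, toks)
  expect_identical(p1, p2)
  expect_true(isWellFormedTags(p1[[1]], toy$schema))
  raw <- attr(p1, "raw")
  expect_length(raw[[1]], 4L)
  # empty input gives empty output
  expect_length(predictTagger(model, list()), 0L)
})

test_that("pre-trained embeddings are frozen and OOV resolves to zero", {
  toy <- makeToySentences()
  cfg <- tinyTaggerConfig(epochs = 2L)
  vocab <- c("toma", "farmacil", "dos")
  emb <- list(vocab = vocab,
              vectors = matrix(runif(3 * cfg$word_dim), 3, cfg$word_dim))
  m <- initTaggerModel(toy$sentences, toy$schema, cfg, word_embeddings = emb)
  expect_true("wordEmb" %in% m@frozen)
  # OOV row (first row) is all zero
  expect_equal(unname(m@params$wordEmb[1L, ]), rep(0, cfg$word_dim))
  trained <- trainTagger(toy$sentences, toy$schema, cfg,
                         word_embeddings = emb)
  expect_identical(trained@params$wordEmb, m@params$wordEmb)
})

test_that("readEmbeddings parses plain and headered files", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 3", "casa 0.1 0.2 0.3", "piso 0.4 0.5 0.6"), f)
  e <- readEmbeddings(f)
  expect_equal(e$vocab, c("casa", "piso"))
  expect_equal(dim(e$vectors), c(2L, 3L))
  expect_equal(unname(e$vectors[2, 3]), 0.6)
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("solo 1 2", f2)
  e2 <- readEmbeddings(f2)
  expect_equal(e2$vocab, "solo")
})

test_that("sense keys fall back from token|POS to token to UNK", {
  toy <- makeToySentences()
  m <- initTaggerModel(toy$sentences, toy$schema, tinyTaggerConfig())
  senses <- m@vocab$senses
  expect_true("farmacil|NOUN" %in% senses)
  ids <- clinner:::senseIds("farmacil", "VERB", senses)
  expect_equal(senses[ids], "farmacil")       # token-only fallback
  expect_equal(clinner:::senseIds("nuncavisto", "NOUN", senses), 1L)  # UNK
})

test_that("model save/load round trips exactly", {
  toy <- makeToySentences()
  model <- trainTagger(toy$sentences, toy$schema, tinyTaggerConfig(epochs = 2L))
  f <- withr::local_tempfile(fileext = ".rds")
  saveTaggerModel(model, f)
  back <- loadTaggerModel(f)
  expect_identical(back@params, model@params)
  expect_identical(back@vocab, model@vocab)
  toks <- list(tokenize("toma farmacil"))
  expect_identical(predictTagger(back, toks), predictTagger(model, toks))
})

test_that("loadTaggerModel rejects foreign objects", {
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(not = "a model"), f)
  expect_error(loadTaggerModel(f))
})

test_that("early stopping with a dev set keeps the best parameters", {
  toy <- makeToySentences()
  cfg <- tinyTaggerConfig(epochs = 30L, patience = 3L)
  model <- trainTagger(toy$sentences, toy$schema, cfg, dev = toy$sentences)
  expect_lte(modelConfig(model)$epochs_trained, 30L)
})
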