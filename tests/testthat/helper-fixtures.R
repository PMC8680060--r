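## Shared fixtures for the test suite.  Everything is built in-process and
## seeded so the suite is deterministic and needs no external data.

## A two-sentence document with one nested mention pair, offsets hand-counted.
tinyDoc <- function() {
  ##        0123456789012345678901234567890123456789012345678
  text <- "Se detecta calcio ionico alto. Recibe prednisona."
  m <- data.frame(
    mention_id = c("T1", "T2", "T3"),
    entity_type = c("NORMALIZABLES", "NORMALIZABLES", "NORMALIZABLES"),
    start = c(11L, 11L, 38L),
    end = c(24L, 17L, 48L),
    surface = c("calcio ionico", "calcio", "prednisona"),
    concept_id = c("C100", NA, "C200"),
    stringsAsFactors = FALSE)
  annotatedDocument("tiny", text, m)
}

## Random unconstrained emission/transition instances for CRF oracle tests.
randomCrfInstance <- function(L, K) {
  E <- matrix(stats::rnorm(K * L), K, L)
  Tm <- matrix(stats::rnorm((K + 2L) * (K + 2L)), K + 2L, K + 2L)
  list(E = E, Tm = Tm)
}

## Exhaustive enumeration oracles for small CRFs (K^L paths).
enumLogZ <- function(E, Tm) {
  K <- nrow(E); L <- ncol(E)
  paths <- do.call(expand.grid, rep(list(seq_len(K)), L))
  scores <- apply(paths, 1L, function(p) crfScore(E, Tm, as.integer(p)))
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

enumViterbi <- function(E, Tm) {
  K <- nrow(E); L <- ncol(E)
  paths <- do.call(expand.grid, rep(list(seq_len(K)), L))
  scores <- apply(paths, 1L, function(p) crfScore(E, Tm, as.integer(p)))
  best <- which.max(scores)
  list(path = as.integer(paths[best, ]), score = max(scores))
}

## Random letter strings (possibly empty) for Levenshtein property tests.
randomString <- function(maxLen = 12L, alphabet = letters[1:6]) {
  n <- sample.int(maxLen + 1L, 1L) - 1L
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Tiny tagger configuration so unit tests train in seconds.
tinyTaggerConfig <- function(...) {
  args <- list(char_dim = 8L, char_hidden = 8L, word_dim = 16L,
               sense_dim = 8L, lstm_hidden = 16L, dropout = 0.5,
               epochs = 60L, seed = 7L)
  override <- list(...)
  args[names(override)] <- override
  do.call(taggerConfig, args)
}

## A deterministic short-term dictionary whose terms are pairwise far apart;
## separation is asserted where the tests rely on it.
shortTermDictionary <- function() {
  terms <- c("bremalina", "cotrivasa", "dunaplexo", "ferbolina",
             "golvidasa", "lumbraceto", "muralpina", "nerbocuta",
             "pilgrosena", "rivaldexo", "sobentilo", "tavrimosa")
  conceptDictionary(data.frame(
    concept_id = sprintf("CX%03d", seq_along(terms)),
    term = terms, stringsAsFactors = FALSE))
}

## Order a mention table by id for set-wise comparison.
sortMentions <- function(m) {
  m <- m[order(m$mention_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}
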