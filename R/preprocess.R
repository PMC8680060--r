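## Deterministic, offset-preserving sentence splitting and tokenization.
##
## The rule set is intentionally small and fully specified so tokenization —
## a known error source for entity offset recognition — is reproducible
## across platforms: sentences break after [.?!] followed by whitespace when
## the preceding word is not a protected abbreviation and the next
## non-whitespace character is not lowercase; newlines are hard breaks.
## Tokens are maximal runs of letters/digits/underscore; every other
## non-whitespace character is a single-character token (hyphens optionally
## kept inside words).

#' Default protected abbreviations for the sentence splitter
#'
#' Words after which a period never ends a sentence. Shipped as a plain-text
#' config, not an attempt to reproduce any particular external splitter.
#'
#' @return character vector of lowercase abbreviations (no trailing period).
#' @export
protectedAbbreviations <- function() {
  f <- system.file("extdata", "protected_abbreviations.txt",
                   package = "clinner")
  tolower(readLines(f, encoding = "UTF-8", warn = FALSE))
}

#' Split text into sentence spans
#'
#' Returns 0-based end-exclusive character spans, ordered and non-overlapping,
#' such that every non-whitespace character lies in exactly one span.
#'
#' @param text document text.
#' @param protected lowercase abbreviation list (defaults to the packaged
#'   list); a period directly after one of these never ends a sentence.
#' @return `data.frame` with integer columns `start`, `end`.
#' @examples
#' splitSentences("A b. C d.")
#' @export
splitSentences <- function(text, protected = protectedAbbreviations()) {
  n <- nchar(text)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  chars <- strsplit(text, "", fixed = FALSE)[[1L]]
  isWs <- grepl("\\s", chars, perl = TRUE)
  boundary <- logical(n)  # boundary[i]: sentence ends at char i (1-based)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "\n") { boundary[i] <- TRUE; next }
    if (!ch %in% c(".", "!", "?")) next
    if (i < n && !isWs[i + 1L]) next
    if (ch == ".") {
      j <- i - 1L
      while (j >= 1L && grepl("[\\p{L}\\p{N}]", chars[j], perl = TRUE))
        j <- j - 1L
      word <- tolower(paste(chars[seq.int(j + 1L, length.out = i - 1L - j)],
                            collapse = ""))
      if (nzchar(word) && word %in% protected) next
    }
    k <- i + 1L
    while (k <= n && isWs[k]) k <- k + 1L
    if (k <= n && grepl("\\p{Ll}", chars[k], perl = TRUE)) next
    boundary[i] <- TRUE
  }
  ends <- which(boundary)
  if (length(ends) == 0L || max(ends) < n) ends <- c(ends, n)
  spans <- list(); s <- 1L
  for (e in ends) {
    a <- s; b <- e
    while (a <= b && isWs[a]) a <- a + 1L
    while (b >= a && isWs[b]) b <- b - 1L
    if (a <= b)
      spans[[length(spans) + 1L]] <- c(a - 1L, b)  # to 0-based end-exclusive
    s <- e + 1L
  }
  if (length(spans) == 0L)
    return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, spans)
  data.frame(start = as.integer(m[, 1L]), end = as.integer(m[, 2L]))
}

#' Tokenize a sentence span with document-level offsets
#'
#' Tokens are maximal runs of letters, digits and underscore; any other
#' non-whitespace character becomes its own single-character token. With
#' `hyphen_split = FALSE` a hyphen flanked by word characters stays inside
#' the token (so `"S-100"` is one token instead of three).
#'
#' @param text full document text.
#' @param sentence optional `c(start, end)` 0-based end-exclusive span
#'   (default: the whole text).
#' @param hyphen_split split at hyphens (default `TRUE`).
#' @return `data.frame` with columns `text`, `start`, `end` (document-level,
#'   0-based end-exclusive) and `pos` (naive part-of-speech label, see
#'   [naivePosTag()]).
#' @examples
#' tokenize("tratamiento con corticoides")
#' tokenize("S-100", hyphen_split = FALSE)
#' @export
tokenize <- function(text, sentence = NULL, hyphen_split = TRUE) {
  if (is.null(sentence)) sentence <- c(0L, nchar(text))
  s0 <- as.integer(sentence[1L]); s1 <- as.integer(sentence[2L])
  stopifnot(s0 >= 0L, s1 <= nchar(text))
  slice <- substring(text, s0 + 1L, s1)
  if (!nzchar(slice))
    return(data.frame(text = character(), start = integer(),
                      end = integer(), pos = character()))
  pat <- if (hyphen_split)
    "[\\p{L}\\p{N}_]+|[^\\p{L}\\p{N}_\\s]"
  else
    "[\\p{L}\\p{N}_]+(?:-[\\p{L}\\p{N}_]+)*|[^\\p{L}\\p{N}_\\s]"
  ml <- gregexpr(pat, slice, perl = TRUE)
  m <- ml[[1L]]
  if (m[1L] == -1L)
    return(data.frame(text = character(), start = integer(),
                      end = integer(), pos = character()))
  starts <- as.integer(m) - 1L + s0
  lens <- attr(m, "match.length")
  toks <- regmatches(slice, ml)[[1L]]
  data.frame(text = toks, start = starts, end = starts + lens,
             pos = naivePosTag(toks), stringsAsFactors = FALSE)
}

#' Naive suffix-based part-of-speech placeholder
#'
#' A deliberately simple deterministic tagger used only to build sense-lookup
#' keys (`token|POS`) when no external POS column is supplied. Not a
#' linguistic tagger.
#'
#' @param tokens character vector of token strings.
#' @return character vector of coarse labels
#'   (`NOUN`, `ADJ`, `VERB`, `NUM`, `PUNCT`).
#' @export
naivePosTag <- function(tokens) {
  out <- rep("NOUN", length(tokens))
  out[grepl("^[\\p{N}.,]+$", tokens, perl = TRUE)] <- "NUM"
  out[grepl("^[^\\p{L}\\p{N}_]+$", tokens, perl = TRUE)] <- "PUNCT"
  out[grepl("(oso|osa|ico|ica|ivo|iva|al|ar)$", tokens, perl = TRUE) &
        out == "NOUN"] <- "ADJ"
  out[grepl("(ando|endo|arse|erse|irse|aron|ieron)$", tokens, perl = TRUE)] <-
    "VERB"
  out
}

#' Read a one-term-per-line stopword file
#'
#' @param path file path, or one of the packaged lists `"es"`, `"en"`.
#' @return lowercase character vector.
#' @export
readStopwords <- function(path = "es") {
  if (path %in% c("es", "en"))
    path <- system.file("extdata", paste0("stopwords_", path, ".txt"),
                        package = "clinner")
  tolower(trimws(readLines(path, encoding = "UTF-8", warn = FALSE)))
}

#' Normalize raw corpus text for embedding training
#'
#' Lowercases, removes punctuation, collapses whitespace and drops stopword
#' tokens, in that order. Idempotent: applying it twice equals applying it
#' once.
#'
#' @param text raw text.
#' @param stopwords character vector of lowercase stopwords
#'   (default: the packaged Spanish list).
#' @return normalized single-space-separated text.
#' @examples
#' normalizeCorpusText("La Hemoglobina.", stopwords = "la")
#' @export
normalizeCorpusText <- function(text, stopwords = readStopwords("es")) {
  x <- tolower(text)
  x <- gsub("[^\\p{L}\\p{N}\\s]", " ", x, perl = TRUE)
  toks <- strsplit(trimws(x), "\\s+", perl = TRUE)[[1L]]
  toks <- toks[!(toks %in% stopwords)]
  paste(toks, collapse = " ")
}

#' Strip markup tags from text
#'
#' Minimal helper for extracting raw text from simple XML-like corpus files:
#' replaces `<...>` tags with spaces (offsets are not preserved).
#'
#' @param text markup text.
#' @return plain text.
#' @export
stripMarkupTags <- function(text) {
  trimws(gsub("\\s+", " ", gsub("<[^>]*>", " ", text)))
}
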