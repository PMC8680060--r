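## Two-stage concept normalization: case-fold and expand abbreviations, then
## (1) exact / bounded-Levenshtein full-text search over dictionary terms,
## (2) thresholded fuzzy search with normalized similarity
##     1 - d / max(|a|, |b|) for mentions the first stage misses.
## Distances are computed over Unicode code points by the package's own DP
## implementation (src/levenshtein.cpp).

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and
#' substitutions transforming `a` into `b`, counted over Unicode code
#' points. Symmetric, zero iff the strings are equal, and satisfies the
#' triangle inequality.
#'
#' @param a single string.
#' @param b a character vector; the distance is computed against each
#'   element.
#' @return integer vector of distances, same length as `b`.
#' @examples
#' levenshteinDistance("durogesic", "duragesic")  # 1
#' @export
levenshteinDistance <- function(a, b) {
  qa <- utf8ToInt(a)
  if (length(b) == 1L) return(cpp_levenshtein(qa, utf8ToInt(b)))
  cpp_levenshtein_many(qa, lapply(b, utf8ToInt))
}

#' Normalizer configuration
#'
#' @param max_edit_distance bound for the first-stage Levenshtein search
#'   (default 1).
#' @param fuzzy_threshold minimal normalized similarity
#'   `1 - d / max(|a|, |b|)` for the second stage, in (0, 1] (default 0.80).
#' @param ambiguity_policy `"first-by-id"` (default: the lexicographically
#'   smallest concept id wins, result flagged ambiguous) or `"reject"`
#'   (ambiguous matches become unmatched).
#' @return named list of class `"normalizerConfig"`.
#' @export
normalizerConfig <- function(max_edit_distance = 1L, fuzzy_threshold = 0.80,
                             ambiguity_policy = c("first-by-id", "reject")) {
  stopifnot(max_edit_distance >= 0L, fuzzy_threshold > 0,
            fuzzy_threshold <= 1)
  structure(list(max_edit_distance = as.integer(max_edit_distance),
                 fuzzy_threshold = fuzzy_threshold,
                 ambiguity_policy = match.arg(ambiguity_policy)),
            class = "normalizerConfig")
}

#' Read a TSV concept dictionary
#'
#' Format: `concept_id<TAB>term`, one row per (id, term) pair; a concept may
#' have several terms and a term may belong to several concepts.
#'
#' @param path TSV file.
#' @return a [ConceptDictionary-class].
#' @export
readConceptDictionary <- function(path) {
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          col.names = c("concept_id", "term"),
                          colClasses = "character", encoding = "UTF-8")
  conceptDictionary(df)
}

#' Read a TSV abbreviation dictionary
#'
#' Format: `abbrev<TAB>expansion`. Keys are case-normalized and must be
#' unique after lowercasing.
#'
#' @param path TSV file.
#' @return named character vector (names = lowercase abbreviations).
#' @export
readAbbreviationDictionary <- function(path) {
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          col.names = c("abbrev", "expansion"),
                          colClasses = "character", encoding = "UTF-8")
  keys <- tolower(df$abbrev)
  if (anyDuplicated(keys))
    stop("duplicate abbreviation key after case normalization: ",
         keys[duplicated(keys)][1L])
  stats::setNames(df$expansion, keys)
}

#' Expand abbreviations in a mention
#'
#' Whole-token replacement only, greedy longest-key-first and left to right;
#' keys may span several tokens (`"ck 7"`). Unknown tokens pass through
#' unchanged. The mention should be lowercased first (keys are lowercase).
#'
#' @param mention mention string.
#' @param abbrevs named character vector from
#'   [readAbbreviationDictionary()] (or any `abbrev = expansion` mapping).
#' @return expanded string.
#' @examples
#' expandAbbreviations("hb", c(hb = "hemoglobina"))
#' @export
expandAbbreviations <- function(mention, abbrevs) {
  if (length(abbrevs) == 0L || !nzchar(mention)) return(mention)
  toks <- strsplit(mention, " ", fixed = TRUE)[[1L]]
  keyToks <- strsplit(names(abbrevs), " ", fixed = TRUE)
  ord <- order(-lengths(keyToks), -nchar(names(abbrevs)))
  out <- character(); i <- 1L
  while (i <= length(toks)) {
    hit <- 0L
    for (k in ord) {
      kl <- length(keyToks[[k]])
      if (i + kl - 1L <= length(toks) &&
          identical(toks[i:(i + kl - 1L)], keyToks[[k]])) { hit <- k; break }
    }
    if (hit > 0L) {
      out <- c(out, abbrevs[[hit]])
      i <- i + length(keyToks[[hit]])
    } else {
      out <- c(out, toks[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = " ")
}

resolveCandidates <- function(ids, terms, policy) {
  uid <- sort(unique(ids))
  amb <- length(uid) > 1L
  if (amb && policy == "reject")
    return(list(id = NA_character_, term = NA_character_, ambiguous = TRUE))
  id <- uid[1L]
  list(id = id, term = terms[ids == id][1L], ambiguous = amb)
}

#' Normalize one mention against a concept dictionary
#'
#' Pipeline: lowercase, expand abbreviations, then search the dictionary —
#' exact term match first, then minimal Levenshtein distance within
#' `max_edit_distance`, then the fuzzy stage (best normalized similarity
#' `1 - d / max(|a|, |b|)` at or above `fuzzy_threshold`). An unmatched
#' mention is a result, not an error.
#'
#' @param mention mention surface string.
#' @param dict a [ConceptDictionary-class].
#' @param abbrevs optional abbreviation mapping (see
#'   [expandAbbreviations()]).
#' @param cfg a [normalizerConfig()].
#' @return list with `concept_id` (or `NA`), `stage` (`"exact"`,
#'   `"levenshtein"`, `"fuzzy"` or `"unmatched"`), `score` (distance for the
#'   first stages, similarity for fuzzy), `matched_term` and `ambiguous`.
#' @export
normalizeMention <- function(mention, dict, abbrevs = NULL,
                             cfg = normalizerConfig()) {
  entries <- conceptEntries(dict)
  q <- tolower(mention)
  if (!is.null(abbrevs)) q <- expandAbbreviations(q, abbrevs)
  unmatched <- list(concept_id = NA_character_, stage = "unmatched",
                    score = NA_real_, matched_term = NA_character_,
                    ambiguous = FALSE)
  if (nrow(entries) == 0L || !nzchar(q)) return(unmatched)
  hit <- entries$term == q
  if (any(hit)) {
    r <- resolveCandidates(entries$concept_id[hit], entries$term[hit],
                           cfg$ambiguity_policy)
    if (is.na(r$id)) { unmatched$ambiguous <- TRUE; return(unmatched) }
    return(list(concept_id = r$id, stage = "exact", score = 0,
                matched_term = r$term, ambiguous = r$ambiguous))
  }
  d <- levenshteinDistance(q, entries$term)
  dmin <- min(d)
  if (dmin <= cfg$max_edit_distance) {
    sel <- d == dmin
    r <- resolveCandidates(entries$concept_id[sel], entries$term[sel],
                           cfg$ambiguity_policy)
    if (is.na(r$id)) { unmatched$ambiguous <- TRUE; return(unmatched) }
    return(list(concept_id = r$id, stage = "levenshtein", score = dmin,
                matched_term = r$term, ambiguous = r$ambiguous))
  }
  sim <- 1 - d / pmax(nchar(q), nchar(entries$term))
  smax <- max(sim)
  if (smax >= cfg$fuzzy_threshold) {
    sel <- sim == smax
    r <- resolveCandidates(entries$concept_id[sel], entries$term[sel],
                           cfg$ambiguity_policy)
    if (is.na(r$id)) { unmatched$ambiguous <- TRUE; return(unmatched) }
    return(list(concept_id = r$id, stage = "fuzzy", score = smax,
                matched_term = r$term, ambiguous = r$ambiguous))
  }
  unmatched
}

#' Normalize every mention of a corpus
#'
#' Runs [normalizeMention()] on each mention of each document and fills the
#' `concept_id` column. Per-stage counts are attached as attribute
#' `"stages"` and a per-mention result table as attribute `"results"`.
#'
#' @param docs list of [AnnotatedDocument-class] (e.g. output of the NER
#'   step).
#' @param dict a [ConceptDictionary-class].
#' @param abbrevs optional abbreviation mapping.
#' @param cfg a [normalizerConfig()].
#' @return the documents with `concept_id` filled (NA when unmatched).
#' @export
normalizeCorpus <- function(docs, dict, abbrevs = NULL,
                            cfg = normalizerConfig()) {
  stages <- c(exact = 0L, levenshtein = 0L, fuzzy = 0L, unmatched = 0L)
  rows <- list()
  out <- lapply(docs, function(d) {
    m <- mentions(d)
    if (nrow(m) > 0L) {
      for (i in seq_len(nrow(m))) {
        r <- normalizeMention(m$surface[i], dict, abbrevs, cfg)
        m$concept_id[i] <- r$concept_id
        stages[r$stage] <<- stages[r$stage] + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          doc_id = docId(d), mention_id = m$mention_id[i],
          surface = m$surface[i], concept_id = r$concept_id,
          stage = r$stage, score = r$score, matched_term = r$matched_term,
          ambiguous = r$ambiguous, stringsAsFactors = FALSE)
      }
      mentions(d) <- m
    }
    d
  })
  attr(out, "stages") <- stages
  attr(out, "results") <- if (length(rows)) do.call(rbind, rows) else NULL
  out
}

#' Replace dictionary terms in running text by concept ids
#'
#' Non-overlapping, longest-match-first, left-to-right whole-token
#' replacement of dictionary terms by their concept id (the transform used
#' to build concept-level corpora). Input should be case-normalized.
#'
#' @param text lowercased text.
#' @param dict a [ConceptDictionary-class].
#' @return text with matched terms replaced.
#' @examples
#' d <- conceptDictionary(data.frame(concept_id = "C1", term = "corticoides"))
#' conceptizeText("corticoides orales", d)  # "C1 orales"
#' @export
conceptizeText <- function(text, dict) {
  entries <- conceptEntries(dict)
  if (nrow(entries) == 0L || !nzchar(text)) return(text)
  termToks <- strsplit(entries$term, " ", fixed = TRUE)
  ord <- order(-lengths(termToks), entries$term, entries$concept_id)
  toks <- strsplit(text, " ", fixed = TRUE)[[1L]]
  out <- character(); i <- 1L
  while (i <= length(toks)) {
    hit <- 0L
    for (k in ord) {
      kl <- length(termToks[[k]])
      if (i + kl - 1L <= length(toks) &&
          identical(toks[i:(i + kl - 1L)], termToks[[k]])) { hit <- k; break }
    }
    if (hit > 0L) {
      out <- c(out, entries$concept_id[hit])
      i <- i + length(termToks[[hit]])
    } else {
      out <- c(out, toks[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = " ")
}
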