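## Seeded generator of toy clinical-case corpora with gold annotations:
## template carrier sentences with embedded dictionary terms, a controlled
## fraction of nested mentions (single-token inner mention, the recoverable
## pattern), misspelled mentions at an exact edit distance, and abbreviated
## mentions.  Everything any pipeline stage consumes — BRAT documents,
## tokenized sentences, gold BMEWO-V tags, gold concept ids — comes out of
## one deterministic pass.

#' Synthetic corpus specification
#'
#' The defaults describe a small clinical-case corpus: 10 documents of 5
#' sentences (50 sentences), the four PharmaCoNER-style entity types, about
#' 1.5 mentions per sentence, 15% of multi-token concepts carrying a nested
#' single-token inner mention, 10% misspelled at edit distance 1, 10%
#' abbreviated.
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc inclusive `c(min, max)` sentence-count range.
#' @param entity_types entity type labels.
#' @param mention_rate expected mentions per sentence, in \[0, 2\].
#' @param nesting_rate fraction of multi-token concepts whose mentions all
#'   carry a nested single-token inner mention; the decision is made once
#'   per concept so a term is annotated consistently across the corpus.
#' @param misspelling_rate fraction of mention surfaces perturbed.
#' @param misspelling_distance exact edit distance of each perturbation.
#' @param abbreviation_rate fraction of mentions rendered as abbreviations
#'   (among concepts that have one).
#' @param seed RNG seed; identical spec and seed give an identical corpus.
#' @return named list of class `"syntheticCorpusSpec"`.
#' @export
syntheticCorpusSpec <- function(n_docs = 10L, sentences_per_doc = c(5L, 5L),
                                entity_types = pharmaconerTypes(),
                                mention_rate = 1.5, nesting_rate = 0.15,
                                misspelling_rate = 0.1,
                                misspelling_distance = 1L,
                                abbreviation_rate = 0.1, seed = 42L) {
  stopifnot(n_docs >= 1L, length(sentences_per_doc) == 2L,
            sentences_per_doc[1L] >= 1L,
            sentences_per_doc[2L] >= sentences_per_doc[1L],
            mention_rate >= 0, mention_rate <= 2,
            nesting_rate >= 0, nesting_rate <= 1,
            misspelling_rate >= 0, misspelling_rate <= 1,
            misspelling_distance >= 1L,
            abbreviation_rate >= 0, abbreviation_rate <= 1)
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 entity_types = entity_types, mention_rate = mention_rate,
                 nesting_rate = nesting_rate,
                 misspelling_rate = misspelling_rate,
                 misspelling_distance = as.integer(misspelling_distance),
                 abbreviation_rate = abbreviation_rate,
                 seed = as.integer(seed)),
            class = "syntheticCorpusSpec")
}

randomSyllableWord <- function(minSyl = 2L, maxSyl = 4L) {
  cons <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  n <- sample.int(maxSyl - minSyl + 1L, 1L) + minSyl - 1L
  word <- paste0(sample(cons, n, replace = TRUE),
                 sample(vow, n, replace = TRUE), collapse = "")
  if (runif(1) < 0.5)
    word <- paste0(word, sample(c("ina", "ol", "asa", "ato", "ida"), 1L))
  word
}

#' Generate a concept dictionary and abbreviation dictionary
#'
#' Terms are pronounceable Spanish-like words of 1-3 tokens, unique per
#' concept, rejection-sampled so all terms are pairwise at Levenshtein
#' distance at least 3 (so a distance-1 perturbation always has a unique
#' nearest term). A fraction of concepts gets an abbreviation built from
#' token initials.
#'
#' @param n_concepts number of concepts (>= 1).
#' @param seed RNG seed.
#' @param abbreviation_fraction fraction of concepts given an abbreviation.
#' @param min_separation minimal pairwise Levenshtein distance between terms.
#' @return list with `concepts` (a [ConceptDictionary-class]),
#'   `abbreviations` (named character) and `terms` (`data.frame` with
#'   `concept_id`, `term`, `abbrev`).
#' @export
makeDictionary <- function(n_concepts, seed = 1L,
                           abbreviation_fraction = 0.3,
                           min_separation = 3L) {
  stopifnot(n_concepts >= 1L)
  set.seed(seed)
  terms <- character()
  guard <- 0L
  while (length(terms) < n_concepts) {
    guard <- guard + 1L
    if (guard > 1000L * n_concepts)
      stop("could not sample ", n_concepts, " pairwise-separated terms")
    nTok <- sample.int(3L, 1L, prob = c(0.35, 0.45, 0.2))
    cand <- paste(replicate(nTok, randomSyllableWord()), collapse = " ")
    if (length(terms) == 0L ||
        min(levenshteinDistance(cand, terms)) >= min_separation)
      terms <- c(terms, cand)
  }
  ids <- sprintf("SC%05d", seq_len(n_concepts))
  abbrevs <- character(0)
  nAb <- round(abbreviation_fraction * n_concepts)
  if (nAb > 0L) {
    pick <- sort(sample.int(n_concepts, nAb))
    for (i in pick) {
      toks <- strsplit(terms[i], " ", fixed = TRUE)[[1L]]
      ab <- if (length(toks) >= 2L)
        paste(substr(toks, 1L, 1L), collapse = "") else substr(toks, 1L, 3L)
      if (ab %in% names(abbrevs) || ab %in% terms)
        ab <- paste0(ab, substr(toks[1L], 2L, 2L))
      if (ab %in% names(abbrevs) || ab %in% terms) next
      abbrevs[ab] <- terms[i]
    }
  }
  abbrevCol <- if (length(abbrevs))
    names(abbrevs)[match(terms, abbrevs)] else rep(NA_character_, n_concepts)
  df <- data.frame(concept_id = ids, term = terms, abbrev = abbrevCol,
                   stringsAsFactors = FALSE)
  list(concepts = conceptDictionary(df[, c("concept_id", "term")]),
       abbreviations = abbrevs, terms = df)
}

#' Perturb a term to an exact Levenshtein distance
#'
#' Applies random single-character edits (substitution, insertion, deletion
#' of lowercase letters; spaces are never touched) and verifies with the
#' distance oracle that the result is at exactly the requested distance,
#' retrying if edits collapse.
#'
#' @param term input string.
#' @param distance target edit distance, `0 <= distance < nchar(term)`.
#' @param seed optional seed for a reproducible standalone call (inside
#'   [generateCorpus()] the generator's RNG stream is used).
#' @return a string at exactly `distance` from `term`.
#' @export
perturbTerm <- function(term, distance, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  distance <- as.integer(distance)
  if (distance >= nchar(term))
    stop("distance ", distance, " must be smaller than term length ",
         nchar(term))
  if (distance == 0L) return(term)
  letters26 <- letters
  for (try in seq_len(200L)) {
    chars <- strsplit(term, "", fixed = TRUE)[[1L]]
    for (e in seq_len(distance)) {
      op <- sample(c("sub", "ins", "del"), 1L, prob = c(0.5, 0.3, 0.2))
      letterPos <- which(chars != " ")
      if (op == "sub") {
        p <- sample(letterPos, 1L)
        chars[p] <- sample(setdiff(letters26, chars[p]), 1L)
      } else if (op == "ins") {
        p <- sample(length(chars) + 1L, 1L)
        chars <- append(chars, sample(letters26, 1L), after = p - 1L)
      } else {
        if (length(letterPos) <= 1L) next
        chars <- chars[-sample(letterPos, 1L)]
      }
    }
    out <- paste(chars, collapse = "")
    if (out != term && levenshteinDistance(term, out) == distance)
      return(out)
  }
  stop("could not realize an exact distance-", distance,
       " perturbation of '", term, "'")
}

carrierTemplates <- function() {
  list(
    none = c("El paciente permanece estable durante el ingreso.",
             "Se decide alta hospitalaria con seguimiento ambulatorio.",
             "La exploracion fisica no muestra hallazgos relevantes."),
    one = c("Se pauta tratamiento con {X} hasta nueva revision.",
            "El paciente recibe {X} por via oral.",
            "Se detecta elevacion de {X} en la analitica de control.",
            "Niveles de {X} dentro de la normalidad.",
            "Se suspende la administracion de {X} por intolerancia."),
    two = c("Se administra {X} junto con {X} durante el ingreso.",
            "La determinacion de {X} y de {X} resulta normal.",
            "Tratamiento combinado con {X} y {X} en pauta descendente."))
}

#' Generate a synthetic annotated corpus
#'
#' Builds template carrier sentences with embedded dictionary terms and
#' returns everything downstream stages need: BRAT-style annotated
#' documents with gold concept ids, tokenized sentences with gold BMEWO-V
#' tags, the tag schema, and a manifest of realized counts. Nested inner
#' mentions follow the recoverable pattern (single first token of a
#' multi-token mention, with no concept id of their own).
#'
#' @param spec a [syntheticCorpusSpec()].
#' @param dict a [ConceptDictionary-class] (from [makeDictionary()]).
#' @param abbrevs named abbreviation vector (from [makeDictionary()]);
#'   `NULL` disables abbreviated mentions.
#' @return list with `docs` (named list of [AnnotatedDocument-class]),
#'   `sentences` (per sentence: `doc_id`, `tokens`, `tags`), `schema`,
#'   `manifest` and the `spec`.
#' @export
generateCorpus <- function(spec, dict, abbrevs = NULL) {
  stopifnot(inherits(spec, "syntheticCorpusSpec"))
  set.seed(spec$seed)
  schema <- tagSchema(spec$entity_types)
  entries <- conceptEntries(dict)
  ids <- sort(unique(entries$concept_id))
  terms <- entries$term[match(ids, entries$concept_id)]
  types <- spec$entity_types[(seq_along(ids) - 1L) %%
                               length(spec$entity_types) + 1L]
  termToAbbrev <- if (is.null(abbrevs)) character(0) else abbrevs
  ## Nesting is decided once per concept, not per occurrence, so a given
  ## term is annotated consistently across the corpus (as under real
  ## annotation guidelines); the inner mention's type is likewise a fixed
  ## function of the canonical first token.
  multiTok <- lengths(strsplit(terms, " ", fixed = TRUE)) >= 2L
  nestedConcept <- runif(length(ids)) < spec$nesting_rate & multiTok
  innerTypes <- vapply(strsplit(terms, " ", fixed = TRUE), function(tk)
    spec$entity_types[sum(utf8ToInt(tk[1L])) %% length(spec$entity_types) + 1L],
    character(1))
  tpl <- carrierTemplates()
  rate <- spec$mention_rate
  p <- if (rate <= 1) c(1 - rate, rate, 0) else c(0, 2 - rate, rate - 1)

  docs <- list(); sentences <- list()
  nNested <- nMiss <- nAbbr <- nMention <- 0L
  for (d in seq_len(spec$n_docs)) {
    doc_id <- sprintf("doc%03d", d)
    sentRange <- seq.int(spec$sentences_per_doc[1L],
                         spec$sentences_per_doc[2L])
    # sample() on a length-1 numeric would draw from 1:n
    nSent <- if (length(sentRange) == 1L) sentRange else sample(sentRange, 1L)
    text <- ""
    men <- list(); sentSpans <- list()
    for (s in seq_len(nSent)) {
      k <- sample(0:2, 1L, prob = p)
      template <- sample(tpl[[k + 1L]], 1L)
      parts <- strsplit(template, "{X}", fixed = TRUE)[[1L]]
      base <- nchar(text) + if (nzchar(text)) 1L else 0L  # joining space
      sent <- parts[1L]
      for (slot in seq_len(k)) {
        ci <- sample.int(length(ids), 1L)
        term <- terms[ci]
        surface <- term
        isAbbr <- FALSE; isMiss <- FALSE
        abKey <- if (length(termToAbbrev))
          names(termToAbbrev)[match(term, termToAbbrev)] else NA_character_
        if (!is.na(abKey) && runif(1) < spec$abbreviation_rate) {
          surface <- abKey; isAbbr <- TRUE
        } else if (runif(1) < spec$misspelling_rate &&
                   spec$misspelling_distance < nchar(term)) {
          surface <- perturbTerm(term, spec$misspelling_distance)
          isMiss <- TRUE
        }
        start <- base + nchar(sent)
        end <- start + nchar(surface)
        men[[length(men) + 1L]] <- data.frame(
          entity_type = types[ci], start = start, end = end,
          surface = surface, concept_id = ids[ci],
          stringsAsFactors = FALSE)
        nMention <- nMention + 1L
        if (isAbbr) nAbbr <- nAbbr + 1L
        if (isMiss) nMiss <- nMiss + 1L
        toks <- strsplit(surface, " ", fixed = TRUE)[[1L]]
        if (!isAbbr && length(toks) >= 2L && nestedConcept[ci]) {
          men[[length(men) + 1L]] <- data.frame(
            entity_type = innerTypes[ci], start = start,
            end = start + nchar(toks[1L]), surface = toks[1L],
            concept_id = NA_character_, stringsAsFactors = FALSE)
          nNested <- nNested + 1L; nMention <- nMention + 1L
        }
        sent <- paste0(sent, surface, parts[slot + 1L])
      }
      sentStart <- base
      text <- if (nzchar(text)) paste(text, sent) else sent
      sentSpans[[s]] <- c(sentStart, sentStart + nchar(sent))
    }
    m <- if (length(men)) do.call(rbind, men) else emptyMentions()
    if (nrow(m)) {
      m <- m[order(m$start, m$end), , drop = FALSE]
      m <- data.frame(mention_id = paste0("T", seq_len(nrow(m))), m,
                      stringsAsFactors = FALSE)
    }
    doc <- annotatedDocument(doc_id, text, m)
    docs[[doc_id]] <- doc
    for (s in seq_len(nSent)) {
      sp <- sentSpans[[s]]
      toks <- tokenize(text, sp)
      inside <- if (nrow(m))
        m[m$start >= sp[1L] & m$end <= sp[2L], , drop = FALSE] else m
      tags <- encodeTags(toks, inside, schema)
      sentences[[length(sentences) + 1L]] <-
        list(doc_id = doc_id, tokens = toks, tags = tags)
    }
  }
  manifest <- list(n_docs = spec$n_docs, n_sentences = length(sentences),
                   n_mentions = nMention, n_nested = nNested,
                   n_misspelled = nMiss, n_abbreviated = nAbbr,
                   n_concepts = length(ids))
  list(docs = docs, sentences = sentences, schema = schema,
       manifest = manifest, spec = spec)
}
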