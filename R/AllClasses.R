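#' Annotated document with (possibly nested) entity mentions
#'
#' An `AnnotatedDocument` holds one document's raw text together with a table
#' of typed entity mentions addressed by character offsets. Offsets are
#' 0-based, end-exclusive, counted in Unicode code points (the BRAT standoff
#' convention), so `surface` always equals the text slice `[start, end)`.
#' Mentions may overlap or be strictly nested; each has a unique id.
#'
#' @slot docId single character, unique within a corpus.
#' @slot text full document text.
#' @slot mentions `data.frame` with columns `mention_id`, `entity_type`,
#'   `start`, `end`, `surface`, `concept_id` (NA when unlinked).
#'
#' @seealso [parseBrat()], [writeBrat()], [validateCorpus()]
#' @export
setClass("AnnotatedDocument",
  representation(docId = "character", text = "character",
                 mentions = "data.frame"))

emptyMentions <- function() {
  data.frame(mention_id = character(), entity_type = character(),
             start = integer(), end = integer(),
             surface = character(), concept_id = character(),
             stringsAsFactors = FALSE)
}

#' @importFrom methods setValidity
setValidity("AnnotatedDocument", function(object) {
  msgs <- character()
  if (length(object@docId) != 1L || is.na(object@docId) || !nzchar(object@docId))
    msgs <- c(msgs, "docId must be a single non-empty string")
  if (length(object@text) != 1L || is.na(object@text))
    msgs <- c(msgs, "text must be a single string")
  m <- object@mentions
  need <- c("mention_id", "entity_type", "start", "end", "surface", "concept_id")
  if (!all(need %in% names(m))) {
    msgs <- c(msgs, paste("mentions must have columns",
                          paste(need, collapse = ", ")))
    return(msgs)
  }
  if (nrow(m) > 0L) {
    if (!nzchar(object@text))
      msgs <- c(msgs, "annotated document has empty text")
    if (anyDuplicated(m$mention_id))
      msgs <- c(msgs, "duplicated mention_id")
    n <- nchar(object@text)
    bad <- which(!(m$start >= 0L & m$start < m$end & m$end <= n))
    if (length(bad))
      msgs <- c(msgs, paste0("mention ", m$mention_id[bad[1L]],
                             ": offsets out of range [0, ", n, "]"))
    ok <- m$start >= 0L & m$end <= n & m$start < m$end
    if (any(ok)) {
      slice <- substring(object@text, m$start[ok] + 1L, m$end[ok])
      mism <- which(slice != m$surface[ok])
      if (length(mism))
        msgs <- c(msgs, paste0("mention ", m$mention_id[ok][mism[1L]],
                               ": surface does not match text slice"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotatedDocument
#'
#' @param docId document identifier.
#' @param text document text.
#' @param mentions mention table (see [AnnotatedDocument-class]); missing
#'   `concept_id` is filled with `NA`.
#' @return an [AnnotatedDocument-class] object.
#' @examples
#' annotatedDocument("d1", "tratamiento con corticoides",
#'   data.frame(mention_id = "T1", entity_type = "NORMALIZABLES",
#'              start = 16L, end = 27L, surface = "corticoides"))
#' @export
annotatedDocument <- function(docId, text, mentions = emptyMentions()) {
  if (nrow(mentions) > 0L) {
    if (is.null(mentions$concept_id)) mentions$concept_id <- NA_character_
    if (is.null(mentions$surface))
      mentions$surface <- substring(text, mentions$start + 1L, mentions$end)
    mentions$start <- as.integer(mentions$start)
    mentions$end <- as.integer(mentions$end)
    mentions$concept_id <- as.character(mentions$concept_id)
  } else {
    mentions <- emptyMentions()
  }
  rownames(mentions) <- NULL
  new("AnnotatedDocument", docId = as.character(docId),
      text = as.character(text), mentions = mentions)
}

#' @describeIn AnnotatedDocument-class document identifier
#' @param object,x an `AnnotatedDocument`
#' @export
setGeneric("docId", function(x) standardGeneric("docId"))
#' @rdname AnnotatedDocument-class
#' @export
setMethod("docId", "AnnotatedDocument", function(x) x@docId)

#' @describeIn AnnotatedDocument-class document text
#' @export
setGeneric("docText", function(x) standardGeneric("docText"))
#' @rdname AnnotatedDocument-class
#' @export
setMethod("docText", "AnnotatedDocument", function(x) x@text)

#' @describeIn AnnotatedDocument-class mention table
#' @export
setGeneric("mentions", function(x) standardGeneric("mentions"))
#' @rdname AnnotatedDocument-class
#' @export
setMethod("mentions", "AnnotatedDocument", function(x) x@mentions)

#' @describeIn AnnotatedDocument-class replace the mention table
#' @param value replacement mention table
#' @export
setGeneric("mentions<-", function(x, value) standardGeneric("mentions<-"))
#' @rdname AnnotatedDocument-class
#' @export
setReplaceMethod("mentions", "AnnotatedDocument", function(x, value) {
  x@mentions <- value
  validObject(x)
  x
})

setMethod("show", "AnnotatedDocument", function(object) {
  m <- object@mentions
  cat("AnnotatedDocument '", object@docId, "': ",
      nchar(object@text), " chars, ", nrow(m), " mention",
      if (nrow(m) == 1L) "" else "s", "\n", sep = "")
  if (nrow(m) > 0L) {
    shown <- head(m, 5L)
    cat(sprintf("  %s [%d,%d) %s %s\n", shown$mention_id, shown$start,
                shown$end, shown$entity_type, shown$surface), sep = "")
    if (nrow(m) > 5L) cat("  ... and", nrow(m) - 5L, "more\n")
  }
})

#' BMEWO-V tag schema
#'
#' The tag inventory for a set of entity types under the BMEWO-V scheme:
#' for each type there are five prefixed tags (B begin, M middle, E end,
#' W whole single-token mention, V token covered by two or more mentions)
#' plus the single outside tag `O`, so the inventory has `5 * T + 1` tags.
#'
#' @slot entityTypes ordered character vector of type labels.
#' @slot inventory full ordered tag inventory (types x prefixes B,M,E,W,V,
#'   then `O`).
#' @seealso [tagSchema()], [encodeTags()], [decodeTags()]
#' @export
setClass("TagSchema",
  representation(entityTypes = "character", inventory = "character"))

setValidity("TagSchema", function(object) {
  if (length(object@entityTypes) == 0L) return("entityTypes must be non-empty")
  if (anyDuplicated(object@entityTypes)) return("duplicate entity type label")
  if (length(object@inventory) != 5L * length(object@entityTypes) + 1L)
    return("inventory size must be 5 * n_types + 1")
  TRUE
})

#' @describeIn TagSchema-class entity type labels
#' @param x a `TagSchema`
#' @export
setGeneric("entityTypes", function(x) standardGeneric("entityTypes"))
#' @rdname TagSchema-class
#' @export
setMethod("entityTypes", "TagSchema", function(x) x@entityTypes)

#' @describeIn TagSchema-class full tag inventory
#' @export
setGeneric("tagInventory", function(x) standardGeneric("tagInventory"))
#' @rdname TagSchema-class
#' @export
setMethod("tagInventory", "TagSchema", function(x) x@inventory)

setMethod("show", "TagSchema", function(object) {
  cat("TagSchema:", length(object@entityTypes), "entity types,",
      length(object@inventory), "tags (BMEWO-V)\n")
  cat("  types:", paste(object@entityTypes, collapse = ", "), "\n")
})

#' Concept dictionary for normalization
#'
#' Maps concept identifiers to sets of case-normalized terms. A term may be
#' ambiguous (attached to several concepts); the ambiguity policy of
#' [normalizerConfig()] decides how such terms resolve.
#'
#' @slot entries `data.frame` with columns `concept_id`, `term` (one row per
#'   pair; terms lowercased at construction).
#' @seealso [conceptDictionary()], [normalizeMention()]
#' @export
setClass("ConceptDictionary", representation(entries = "data.frame"))

setValidity("ConceptDictionary", function(object) {
  e <- object@entries
  if (!all(c("concept_id", "term") %in% names(e)))
    return("entries must have columns concept_id, term")
  if (nrow(e) > 0L && any(!nzchar(e$term))) return("empty term in dictionary")
  TRUE
})

#' Construct a ConceptDictionary
#'
#' @param entries `data.frame` with columns `concept_id` and `term`.
#' @return a [ConceptDictionary-class]; terms are lowercased and duplicate
#'   (id, term) pairs dropped.
#' @examples
#' conceptDictionary(data.frame(concept_id = "C1", term = "corticoides"))
#' @export
conceptDictionary <- function(entries) {
  entries$concept_id <- as.character(entries$concept_id)
  entries$term <- tolower(as.character(entries$term))
  entries <- unique(entries[, c("concept_id", "term")])
  rownames(entries) <- NULL
  new("ConceptDictionary", entries = entries)
}

#' @describeIn ConceptDictionary-class the (concept_id, term) table
#' @param x a `ConceptDictionary`
#' @export
setGeneric("conceptEntries", function(x) standardGeneric("conceptEntries"))
#' @rdname ConceptDictionary-class
#' @export
setMethod("conceptEntries", "ConceptDictionary", function(x) x@entries)

#' @describeIn ConceptDictionary-class unique concept identifiers
#' @export
setGeneric("conceptIds", function(x) standardGeneric("conceptIds"))
#' @rdname ConceptDictionary-class
#' @export
setMethod("conceptIds", "ConceptDictionary",
          function(x) sort(unique(x@entries$concept_id)))

setMethod("show", "ConceptDictionary", function(object) {
  cat("ConceptDictionary:", length(unique(object@entries$concept_id)),
      "concepts,", nrow(object@entries), "terms\n")
})

#' Trained sequence-tagger model
#'
#' Container for a trained bidirectional LSTM-CRF tagger: resolved
#' configuration, tag schema, vocabularies (words, characters, sense keys)
#' and all parameter matrices (embedding tables, recurrent weights, emission
#' projection and CRF transition matrix).
#'
#' @slot config resolved [taggerConfig()] list.
#' @slot schema the [TagSchema-class] the model emits tags from.
#' @slot vocab list with character vectors `words`, `chars`, `senses`.
#' @slot params named list of numeric matrices/vectors.
#' @slot frozen names of parameters excluded from gradient updates.
#' @slot version serialization format version string.
#' @seealso [trainTagger()], [predictTagger()], [saveTaggerModel()]
#' @export
setClass("TaggerModel",
  representation(config = "list", schema = "TagSchema", vocab = "list",
                 params = "list", frozen = "character", version = "character"))

#' @describeIn TaggerModel-class resolved training configuration
#' @param x a `TaggerModel`
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname TaggerModel-class
#' @export
setMethod("modelConfig", "TaggerModel", function(x) x@config)

#' @describeIn TaggerModel-class tag schema of the model
#' @export
setGeneric("modelSchema", function(x) standardGeneric("modelSchema"))
#' @rdname TaggerModel-class
#' @export
setMethod("modelSchema", "TaggerModel", function(x) x@schema)

setMethod("show", "TaggerModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat("TaggerModel:", length(object@vocab$words), "word /",
      length(object@vocab$chars), "char /",
      length(object@vocab$senses), "sense vocab,",
      np, "parameters\n")
  cat("  tags:", length(tagInventory(object@schema)),
      " epochs trained:", object@config$epochs_trained %||% 0L, "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
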