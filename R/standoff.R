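## BRAT standoff reader/writer and corpus validation.
##
## Only entity (T) lines and normalization links (N lines, or AnnotatorNotes
## # lines that reference a T id) are interpreted; relation/event/attribute
## lines are skipped with a notice.  Offsets are 0-based end-exclusive code
## points, the convention under which an entity line's printed surface equals
## the text slice.

bratError <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- paste0(msg, " [line: ", line, "]")
  stop(errorCondition(msg, class = c("clinner_brat_error", "error")))
}

#' Parse BRAT standoff annotation lines
#'
#' Converts the lines of a `.ann` file, together with the corresponding
#' document text, into an [AnnotatedDocument-class]. Entity (`T`) lines must
#' have the form `T<id>\\t<TYPE> <start> <end>\\t<surface>`; the surface is
#' re-extracted from `text` and must match the stated surface. `N` lines (and
#' `#` AnnotatorNotes lines naming a `T` id) attach concept identifiers.
#' Relation, event and attribute lines are skipped with a notice.
#' Discontinuous fragment spans (`start end;start end`) are rejected.
#'
#' @param text full document text.
#' @param ann_lines character vector of standoff lines.
#' @param docId document identifier (defaults to `"doc"`).
#' @return an [AnnotatedDocument-class].
#' @examples
#' txt <- "instaurandose tratamiento con corticoides"
#' parseBrat(txt, "T1\tNORMALIZABLES 30 41\tcorticoides")
#' @export
parseBrat <- function(text, ann_lines, docId = "doc") {
  ann_lines <- ann_lines[nzchar(trimws(ann_lines))]
  men <- emptyMentions()
  norm <- list()
  for (line in ann_lines) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    kind <- substr(fields[1L], 1L, 1L)
    if (kind == "T") {
      if (length(fields) < 2L) bratError("malformed entity line", line)
      head2 <- fields[2L]
      if (grepl(";", head2, fixed = TRUE))
        bratError("unsupported fragment span", line)
      parts <- strsplit(trimws(head2), "\\s+")[[1L]]
      if (length(parts) < 3L) bratError("malformed entity line", line)
      type <- parts[1L]
      start <- suppressWarnings(as.integer(parts[2L]))
      end <- suppressWarnings(as.integer(parts[3L]))
      if (is.na(start) || is.na(end)) bratError("non-integer offsets", line)
      if (start < 0L || end > nchar(text) || start >= end)
        bratError(sprintf("offset [%d, %d) out of range for text of length %d",
                          start, end, nchar(text)), line)
      extracted <- substring(text, start + 1L, end)
      stated <- if (length(fields) >= 3L) fields[3L] else extracted
      if (extracted != stated)
        bratError(sprintf("surface mismatch: annotation says '%s', text has '%s'",
                          stated, extracted), line)
      men <- rbind(men, data.frame(
        mention_id = fields[1L], entity_type = type,
        start = start, end = end, surface = extracted,
        concept_id = NA_character_, stringsAsFactors = FALSE))
    } else if (kind == "N") {
      toks <- strsplit(trimws(fields[2L]), "\\s+")[[1L]]
      tref <- grep("^T[0-9]+$", toks, value = TRUE)
      if (length(tref) == 1L && length(toks) >= 2L)
        norm[[tref]] <- toks[length(toks)]
      else message("skipping unparseable normalization line: ", line)
    } else if (kind == "#") {
      toks <- strsplit(trimws(fields[2L]), "\\s+")[[1L]]
      tref <- grep("^T[0-9]+$", toks, value = TRUE)
      if (length(tref) == 1L && length(fields) >= 3L)
        norm[[tref]] <- trimws(fields[3L])
      else message("skipping comment line: ", line)
    } else if (kind %in% c("R", "E", "A", "M")) {
      message("skipping unsupported annotation kind '", kind, "': ", line)
    } else {
      message("skipping unrecognized annotation line: ", line)
    }
  }
  if (length(norm) && nrow(men)) {
    idx <- match(names(norm), men$mention_id)
    ok <- !is.na(idx)
    men$concept_id[idx[ok]] <- unlist(norm, use.names = FALSE)[ok]
  }
  annotatedDocument(docId, text, men)
}

#' Write an AnnotatedDocument as BRAT standoff lines
#'
#' Emits one `T` line per mention in ascending `(start, end)` order, followed
#' by one `N` line per mention that carries a concept id.
#' `parseBrat(writeBrat(doc))` reproduces `doc` exactly.
#'
#' @param doc an [AnnotatedDocument-class].
#' @return character vector of standoff lines (length 0 for no mentions).
#' @export
writeBrat <- function(doc) {
  stopifnot(is(doc, "AnnotatedDocument"))
  m <- mentions(doc)
  if (nrow(m) == 0L) return(character())
  m <- m[order(m$start, m$end), , drop = FALSE]
  tl <- sprintf("%s\t%s %d %d\t%s", m$mention_id, m$entity_type,
                m$start, m$end, m$surface)
  has <- !is.na(m$concept_id)
  nl <- if (any(has))
    sprintf("N%d\tReference %s %s\t%s", seq_len(sum(has)),
            m$mention_id[has], m$concept_id[has], m$surface[has])
  else character()
  c(tl, nl)
}

#' Read a BRAT corpus directory
#'
#' A corpus is a directory of paired UTF-8 `<id>.txt` / `<id>.ann` files.
#' A missing `.ann` file yields a document with zero mentions.
#'
#' @param dir directory path.
#' @return named list of [AnnotatedDocument-class] (names = doc ids).
#' @export
readBratCorpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, function(tf) {
    id <- sub("\\.txt$", "", basename(tf))
    text <- paste(readLines(tf, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
    af <- file.path(dir, paste0(id, ".ann"))
    ann <- if (file.exists(af))
      readLines(af, encoding = "UTF-8", warn = FALSE) else character()
    parseBrat(text, ann, docId = id)
  })
  names(docs) <- vapply(docs, docId, character(1))
  docs
}

#' Write a BRAT corpus directory
#'
#' @param docs list of [AnnotatedDocument-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBratCorpus <- function(docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in docs) {
    writeLines(docText(d), file.path(dir, paste0(docId(d), ".txt")),
               useBytes = FALSE)
    writeLines(writeBrat(d), file.path(dir, paste0(docId(d), ".ann")))
  }
  invisible(dir)
}

## Pairwise span relations via IRanges; identical spans count as overlapping,
## proper containment as nesting.
spanPairCounts <- function(m) {
  if (nrow(m) < 2L) return(c(nested = 0L, overlap = 0L))
  ir <- IRanges::IRanges(start = m$start + 1L, end = m$end)
  hits <- IRanges::findOverlaps(ir, ir, type = "any")
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- q < s  # each unordered pair once, no self-hits
  q <- q[keep]; s <- s[keep]
  if (length(q) == 0L) return(c(nested = 0L, overlap = 0L))
  s1 <- m$start[q]; e1 <- m$end[q]; s2 <- m$start[s]; e2 <- m$end[s]
  nested <- (s1 <= s2 & e2 <= e1 & (s1 < s2 | e2 < e1)) |
            (s2 <= s1 & e1 <= e2 & (s2 < s1 | e1 < e2))
  c(nested = sum(nested), overlap = sum(!nested))
}

#' Validate a corpus of annotated documents
#'
#' Reports, per document, the mention count, the number of strictly nested
#' mention pairs, the number of overlapping (non-nested, including
#' identical-span) pairs, and any invariant violations (duplicate ids,
#' out-of-range offsets, surface/text mismatches). A valid corpus has an
#' empty violation list.
#'
#' @param docs list of [AnnotatedDocument-class].
#' @return list with elements `summary` (per-document `data.frame`) and
#'   `violations` (character vector), class `"corpusValidation"`.
#' @export
validateCorpus <- function(docs) {
  rows <- list(); viols <- character()
  for (d in docs) {
    m <- mentions(d)
    v <- character()
    if (anyDuplicated(m$mention_id))
      v <- c(v, paste0(docId(d), ": duplicated mention_id ",
                       m$mention_id[duplicated(m$mention_id)][1L]))
    n <- nchar(docText(d))
    bad <- which(!(m$start >= 0L & m$start < m$end & m$end <= n))
    for (i in bad)
      v <- c(v, sprintf("%s: mention %s offsets [%d, %d) out of range",
                        docId(d), m$mention_id[i], m$start[i], m$end[i]))
    ok <- setdiff(seq_len(nrow(m)), bad)
    if (length(ok)) {
      slice <- substring(docText(d), m$start[ok] + 1L, m$end[ok])
      for (i in ok[slice != m$surface[ok]])
        v <- c(v, sprintf("%s: mention %s surface mismatch", docId(d),
                          m$mention_id[i]))
    }
    mok <- m[setdiff(seq_len(nrow(m)), bad), , drop = FALSE]
    pc <- spanPairCounts(mok)
    rows[[length(rows) + 1L]] <- data.frame(
      doc_id = docId(d), n_mentions = nrow(m),
      nested_pairs = unname(pc["nested"]),
      overlap_pairs = unname(pc["overlap"]),
      n_violations = length(v), stringsAsFactors = FALSE)
    viols <- c(viols, v)
  }
  out <- list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              violations = viols)
  class(out) <- "corpusValidation"
  out
}

#' @export
print.corpusValidation <- function(x, ...) {
  cat("Corpus validation:", nrow(x$summary), "documents,",
      sum(x$summary$n_mentions), "mentions,",
      length(x$violations), "violations\n")
  print(x$summary, row.names = FALSE)
  if (length(x$violations)) {
    cat("Violations:\n")
    cat(paste0("  - ", x$violations), sep = "\n")
  }
  invisible(x)
}
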