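## BMEWO-V tag scheme: inventory construction, encoding of (possibly nested)
## mention sets to per-token tags, decoding back to mentions, deterministic
## repair of raw model output, and CoNLL-2003 interchange.
##
## Encode convention for the V tag: a token covered by two or more mentions
## is tagged V-<type> where <type> comes from the innermost (shortest)
## covering mention.  Decoding a run containing V tokens emits the enclosing
## run's mention plus one single-token mention per V token, which round-trips
## the recoverable nesting pattern (single-token inner mention inside a
## longer mention); multi-token inner mentions are not recoverable.

#' The four PharmaCoNER-style entity type labels
#' @return character vector of 4 labels.
#' @export
pharmaconerTypes <- function() {
  c("NORMALIZABLES", "NO_NORMALIZABLES", "PROTEINAS", "UNCLEAR")
}

#' Build the BMEWO-V tag inventory
#'
#' @param entity_types non-empty character vector of unique type labels.
#' @return character vector of `5 * length(entity_types) + 1` tags in
#'   deterministic order: type order times prefix order B, M, E, W, V,
#'   then `"O"`.
#' @examples
#' length(buildTagset(pharmaconerTypes()))  # 21
#' @export
buildTagset <- function(entity_types) {
  if (length(entity_types) == 0L) stop("entity_types must be non-empty")
  if (anyDuplicated(entity_types))
    stop("duplicate entity type label: ",
         entity_types[duplicated(entity_types)][1L])
  c(as.vector(t(outer(entity_types, c("B", "M", "E", "W", "V"),
                      function(ty, p) paste0(p, "-", ty)))), "O")
}

#' Construct a TagSchema
#'
#' @param entity_types character vector of unique type labels (default: the
#'   four PharmaCoNER-style labels).
#' @return a [TagSchema-class].
#' @export
tagSchema <- function(entity_types = pharmaconerTypes()) {
  new("TagSchema", entityTypes = as.character(entity_types),
      inventory = buildTagset(entity_types))
}

tagPrefix <- function(tags) ifelse(tags == "O", "O", substr(tags, 1L, 1L))
tagType <- function(tags) ifelse(tags == "O", NA_character_,
                                 substring(tags, 3L))

#' Encode mentions as BMEWO-V tags over sentence tokens
#'
#' A token covered by exactly one mention gets `W` (single-token mention) or
#' `B`/`M`/`E` by position inside the mention; a token covered by two or more
#' mentions gets `V-<type>` of the innermost (shortest) covering mention;
#' tokens outside all mentions get `O`.
#'
#' @param tokens token `data.frame` (columns `text`, `start`, `end`) from
#'   [tokenize()].
#' @param mentions mention `data.frame` (columns `entity_type`, `start`,
#'   `end`) intersecting the sentence.
#' @param schema a [TagSchema-class]; every mention type must be in it.
#' @param misaligned what to do when a mention boundary falls inside a
#'   token: `"error"` (default) or `"snap"` (expand to covering tokens, with
#'   a warning).
#' @return character vector of tags, one per token.
#' @examples
#' toks <- tokenize("calcio ionico corregido")
#' men <- data.frame(entity_type = c("NORMALIZABLES", "NORMALIZABLES"),
#'                   start = c(0L, 0L), end = c(23L, 6L))
#' encodeTags(toks, men, tagSchema())
#' @export
encodeTags <- function(tokens, mentions, schema,
                       misaligned = c("error", "snap")) {
  misaligned <- match.arg(misaligned)
  nT <- nrow(tokens)
  tags <- rep("O", nT)
  if (is.null(mentions) || nrow(mentions) == 0L) return(tags)
  bad <- !(mentions$entity_type %in% entityTypes(schema))
  if (any(bad))
    stop("mention type not in schema: ", mentions$entity_type[bad][1L])
  ms <- mentions$start; me <- mentions$end
  for (k in seq_len(nrow(mentions))) {
    if (!(ms[k] %in% tokens$start) || !(me[k] %in% tokens$end)) {
      if (misaligned == "error")
        stop("misaligned mention [", ms[k], ", ", me[k],
             "): boundary inside a token")
      cov <- which(tokens$end > ms[k] & tokens$start < me[k])
      if (length(cov) == 0L) next
      warning("snapping misaligned mention [", ms[k], ", ", me[k],
              ") to token boundaries")
      ms[k] <- tokens$start[min(cov)]
      me[k] <- tokens$end[max(cov)]
    }
  }
  ord <- order(me - ms, ms)  # innermost-first for V type lookup
  for (i in seq_len(nT)) {
    cov <- which(ms <= tokens$start[i] & tokens$end[i] <= me)
    if (length(cov) == 0L) next
    if (length(cov) >= 2L) {
      inner <- ord[ord %in% cov][1L]
      tags[i] <- paste0("V-", mentions$entity_type[inner])
    } else {
      k <- cov
      atStart <- tokens$start[i] == ms[k]
      atEnd <- tokens$end[i] == me[k]
      pre <- if (atStart && atEnd) "W" else if (atStart) "B"
             else if (atEnd) "E" else "M"
      tags[i] <- paste0(pre, "-", mentions$entity_type[k])
    }
  }
  stopifnot(all(tags %in% tagInventory(schema)))
  tags
}

#' Decode a BMEWO-V tag sequence into mentions
#'
#' `B..(M)*..E` runs and `W` tokens become mentions with offsets from the
#' first/last covered token; every maximal run containing `V` tokens yields
#' the enclosing run's mention plus one single-token mention per `V` token.
#' Identical (start, end, type) mentions are deduplicated.
#'
#' @param tokens token `data.frame` with `start`, `end` (and `text`).
#' @param tags character tag vector, same length as `tokens` rows; must be
#'   well-formed (apply [repairTags()] to raw model output first).
#' @param schema a [TagSchema-class].
#' @param text optional document text used to extract mention surfaces;
#'   when missing, surfaces are rebuilt from token texts.
#' @return mention `data.frame` (`mention_id`, `entity_type`, `start`, `end`,
#'   `surface`, `concept_id = NA`).
#' @export
decodeTags <- function(tokens, tags, schema, text = NULL) {
  stopifnot(length(tags) == nrow(tokens))
  pre <- tagPrefix(tags); typ <- tagType(tags)
  out <- list()
  add <- function(i, j, type) {
    s <- tokens$start[i]; e <- tokens$end[j]
    surf <- if (!is.null(text)) substring(text, s + 1L, e)
            else paste(tokens$text[i:j], collapse = " ")
    out[[length(out) + 1L]] <<- data.frame(
      entity_type = type, start = s, end = e, surface = surf,
      stringsAsFactors = FALSE)
  }
  open <- FALSE; runStart <- NA_integer_; runType <- NA_character_
  vPos <- integer()
  closeRun <- function(j) {
    if (!open) return(invisible())
    type <- if (!is.na(runType)) runType else typ[vPos[1L]]
    add(runStart, j, type)
    for (v in vPos) add(v, v, typ[v])
    open <<- FALSE; runType <<- NA_character_; vPos <<- integer()
  }
  lastIdx <- NA_integer_
  for (i in seq_along(tags)) {
    p <- pre[i]
    if (p == "O") {
      closeRun(lastIdx)
    } else if (p == "W") {
      closeRun(lastIdx)
      add(i, i, typ[i])
    } else if (p == "B") {
      closeRun(lastIdx)
      open <- TRUE; runStart <- i; runType <- typ[i]; lastIdx <- i
    } else if (p == "M") {
      if (!open) { open <- TRUE; runStart <- i }
      if (is.na(runType)) runType <- typ[i]
      lastIdx <- i
    } else if (p == "E") {
      if (!open) { open <- TRUE; runStart <- i }
      if (is.na(runType)) runType <- typ[i]
      closeRun(i)
    } else if (p == "V") {
      if (!open) { open <- TRUE; runStart <- i }
      vPos <- c(vPos, i); lastIdx <- i
    }
  }
  closeRun(lastIdx)
  if (length(out) == 0L) return(emptyMentions())
  m <- unique(do.call(rbind, out))
  m <- m[m$start < m$end, , drop = FALSE]
  m <- m[order(m$start, m$end, m$entity_type), , drop = FALSE]
  m <- data.frame(mention_id = paste0("T", seq_len(nrow(m))), m,
                  concept_id = NA_character_, stringsAsFactors = FALSE)
  rownames(m) <- NULL
  m
}

#' Repair a raw model-output tag sequence
#'
#' Deterministic repair into a well-formed BMEWO-V sequence: an orphan `M` is
#' promoted to start a run, an orphan `E` becomes `W`, a run left open at a
#' boundary is closed by rewriting its last tag (`B` to `W`, `M` to `E`), and
#' a mid-run type change closes the previous run. Idempotent: repairing a
#' well-formed sequence returns it unchanged.
#'
#' @param tags character tag vector (raw model output).
#' @param schema a [TagSchema-class] (checked for membership).
#' @return well-formed character tag vector of the same length.
#' @examples
#' repairTags(c("M-PROTEINAS"), tagSchema())           # "W-PROTEINAS"
#' repairTags(c("B-PROTEINAS", "O"), tagSchema())      # "W-PROTEINAS" "O"
#' @export
repairTags <- function(tags, schema) {
  stopifnot(all(tags %in% tagInventory(schema)))
  out <- tags
  pre <- tagPrefix(tags); typ <- tagType(tags)
  open <- FALSE; runType <- NA_character_; lastIdx <- NA_integer_
  closeRun <- function() {
    if (!open) return(invisible())
    p <- substr(out[lastIdx], 1L, 1L)
    if (p == "B") out[lastIdx] <<- sub("^B", "W", out[lastIdx])
    else if (p == "M") out[lastIdx] <<- sub("^M", "E", out[lastIdx])
    open <<- FALSE; runType <<- NA_character_
  }
  for (i in seq_along(tags)) {
    p <- pre[i]; ty <- typ[i]
    if (p == "O") {
      closeRun()
    } else if (p == "W") {
      closeRun()
    } else if (p == "B") {
      closeRun()
      open <- TRUE; runType <- ty; lastIdx <- i
    } else if (p == "M") {
      if (open && !is.na(runType) && runType != ty) closeRun()
      if (!open) { out[i] <- paste0("B-", ty); open <- TRUE }
      runType <- ty; lastIdx <- i
    } else if (p == "E") {
      if (open && !is.na(runType) && runType != ty) closeRun()
      if (!open) out[i] <- paste0("W-", ty)
      else { runType <- ty; lastIdx <- i; closeRun() }
    } else if (p == "V") {
      if (!open) { open <- TRUE; runType <- NA_character_ }
      lastIdx <- i
    }
  }
  closeRun()
  out
}

#' Is a tag sequence well-formed?
#'
#' A sequence is well-formed when [repairTags()] leaves it unchanged.
#'
#' @inheritParams repairTags
#' @return logical scalar.
#' @export
isWellFormedTags <- function(tags, schema) {
  identical(repairTags(tags, schema), tags)
}

#' Convert BMEWO-V tags to the BIO scheme
#'
#' Interoperability shim: `W` and `B` map to `B-`, `M` and `E` to `I-`, and
#' `V` to `B-` of the inner type; `O` stays `O`.
#'
#' @param tags BMEWO-V tag vector.
#' @return BIO tag vector.
#' @export
bmewovToBio <- function(tags) {
  pre <- tagPrefix(tags); typ <- tagType(tags)
  ifelse(pre == "O", "O",
         paste0(ifelse(pre %in% c("M", "E"), "I", "B"), "-", typ))
}

#' Convert an AnnotatedDocument to a CoNLL-2003 token table
#'
#' Sentences are split and tokenized, mentions encoded to BMEWO-V tags, and
#' one row emitted per token with columns `sentence`, `token`, `entity_type`
#' (`"Others"` for O tokens, else the tag's type), `start`, `end`, `tag`,
#' and optionally a BIO column. Mentions crossing a sentence boundary are
#' dropped with a warning.
#'
#' @param doc an [AnnotatedDocument-class].
#' @param schema a [TagSchema-class].
#' @param hyphen_split passed to [tokenize()].
#' @param bio also emit a `bio` column (default `FALSE`).
#' @param misaligned passed to [encodeTags()].
#' @return `data.frame`, one row per token.
#' @export
toConll <- function(doc, schema, hyphen_split = TRUE, bio = FALSE,
                    misaligned = "error") {
  sents <- splitSentences(docText(doc))
  m <- mentions(doc)
  rows <- list()
  for (si in seq_len(nrow(sents))) {
    sp <- c(sents$start[si], sents$end[si])
    toks <- tokenize(docText(doc), sp, hyphen_split = hyphen_split)
    if (nrow(toks) == 0L) next
    inside <- m[m$start >= sp[1L] & m$end <= sp[2L], , drop = FALSE]
    crossing <- m$end > sp[1L] & m$start < sp[2L] &
      !(m$start >= sp[1L] & m$end <= sp[2L])
    if (any(crossing))
      warning("dropping ", sum(crossing),
              " mention(s) crossing a sentence boundary in ", docId(doc))
    tags <- encodeTags(toks, inside, schema, misaligned = misaligned)
    r <- data.frame(sentence = si, token = toks$text,
                    entity_type = ifelse(tags == "O", "Others", tagType(tags)),
                    start = toks$start, end = toks$end, tag = tags,
                    stringsAsFactors = FALSE)
    if (bio) r$bio <- bmewovToBio(tags)
    rows[[length(rows) + 1L]] <- r
  }
  if (length(rows) == 0L)
    return(data.frame(sentence = integer(), token = character(),
                      entity_type = character(), start = integer(),
                      end = integer(), tag = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a CoNLL token table to text lines
#'
#' Tab-separated columns `token`, `entity_type`, `start`, `end`, `tag`, with
#' a blank line between sentences.
#'
#' @param conll `data.frame` from [toConll()].
#' @return character vector of lines.
#' @export
writeConllLines <- function(conll) {
  out <- character()
  for (si in unique(conll$sentence)) {
    s <- conll[conll$sentence == si, , drop = FALSE]
    out <- c(out, sprintf("%s\t%s\t%d\t%d\t%s", s$token, s$entity_type,
                          s$start, s$end, s$tag), "")
  }
  if (length(out)) out[-length(out)] else out
}

#' Parse CoNLL-2003 lines back into a token table
#'
#' Inverse of [writeConllLines()]: `fromConll(writeConllLines(x))` recovers
#' tokens, offsets and tags exactly. `-DOCSTART-` lines are skipped.
#'
#' @param lines character vector of CoNLL lines.
#' @return `data.frame` with columns `sentence`, `token`, `entity_type`,
#'   `start`, `end`, `tag`.
#' @export
fromConll <- function(lines) {
  rows <- list(); si <- 1L; sawRow <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) {
      if (sawRow) { si <- si + 1L; sawRow <- FALSE }
      next
    }
    if (startsWith(line, "-DOCSTART-")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 5L)
      stop("ragged CoNLL row at line ", ln, ": expected 5+ columns, got ",
           length(f))
    s <- suppressWarnings(as.integer(f[3L]))
    e <- suppressWarnings(as.integer(f[4L]))
    if (is.na(s) || is.na(e))
      stop("non-integer offsets in CoNLL row at line ", ln)
    rows[[length(rows) + 1L]] <- data.frame(
      sentence = si, token = f[1L], entity_type = f[2L], start = s, end = e,
      tag = f[5L], stringsAsFactors = FALSE)
    sawRow <- TRUE
  }
  if (length(rows) == 0L)
    return(data.frame(sentence = integer(), token = character(),
                      entity_type = character(), start = integer(),
                      end = integer(), tag = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname fromConll
#' @param path file to read.
#' @export
readConll <- function(path) {
  fromConll(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' @rdname writeConllLines
#' @param path file to write.
#' @export
writeConll <- function(conll, path) {
  writeLines(writeConllLines(conll), path)
  invisible(path)
}
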