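## Entity-level exact-match scoring (a prediction is a true positive iff its
## (start, end, type) triple matches a gold mention one-to-one) and
## token-level confusion matrices with tag prefixes collapsed to types.

mentionKeys <- function(m) {
  if (is(m, "AnnotatedDocument")) m <- mentions(m)
  if (nrow(m) == 0L) return(character())
  paste(m$entity_type, m$start, m$end, sep = "\r")
}

prfFrom <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f, tp = tp, fp = fp, fn = fn,
       zero_denominator = (tp + fp == 0) || (tp + fn == 0))
}

#' Entity-level precision, recall and F1
#'
#' Strict matching: a predicted mention is a true positive iff a gold
#' mention with exactly the same start, end and entity type exists in the
#' same document, matched one-to-one. Nested gold mentions are scored
#' independently. Reports per-type and micro-averaged scores as percentages.
#'
#' @param gold,pred named lists (names = doc ids) of mention `data.frame`s
#'   or [AnnotatedDocument-class] objects. The two lists must cover the
#'   same doc ids.
#' @param dedupe drop duplicate predicted (start, end, type) triples before
#'   matching (default `TRUE`); with `FALSE`, surplus duplicates count as
#'   false positives.
#' @return object of class `"prfReport"`: list with `per_type`
#'   (`data.frame`) and `micro` (list with `precision`, `recall`, `f1`,
#'   counts, and a `zero_denominator` flag).
#' @examples
#' g <- list(d1 = data.frame(entity_type = "PROTEINAS", start = 0, end = 2))
#' entityPRF(g, g)$micro$f1  # 100
#' @export
entityPRF <- function(gold, pred, dedupe = TRUE) {
  gi <- names(gold); pi <- names(pred)
  if (is.null(gi) || is.null(pi) || !setequal(gi, pi) ||
      length(gi) != length(pi))
    stop("gold and pred must be named lists over the same doc ids")
  types <- character(); perDoc <- list()
  for (id in gi) {
    gk <- mentionKeys(gold[[id]])
    pk <- mentionKeys(pred[[id]])
    if (dedupe) pk <- unique(pk)
    perDoc[[id]] <- list(g = gk, p = pk)
    types <- union(types, sub("\r.*", "", c(gk, pk)))
  }
  types <- sort(types)
  rows <- lapply(types, function(ty) {
    tp <- fp <- fn <- 0L
    for (d in perDoc) {
      g <- d$g[startsWith(d$g, paste0(ty, "\r"))]
      p <- d$p[startsWith(d$p, paste0(ty, "\r"))]
      gt <- table(g); pt <- table(p)
      common <- intersect(names(gt), names(pt))
      m <- sum(pmin(as.integer(gt[common]), as.integer(pt[common])))
      tp <- tp + m; fp <- fp + length(p) - m; fn <- fn + length(g) - m
    }
    s <- prfFrom(tp, fp, fn)
    data.frame(entity_type = ty, precision = s$precision, recall = s$recall,
               f1 = s$f1, tp = tp, fp = fp, fn = fn,
               stringsAsFactors = FALSE)
  })
  per_type <- if (length(rows)) do.call(rbind, rows)
    else data.frame(entity_type = character(), precision = numeric(),
                    recall = numeric(), f1 = numeric(), tp = integer(),
                    fp = integer(), fn = integer())
  micro <- prfFrom(sum(per_type$tp), sum(per_type$fp), sum(per_type$fn))
  structure(list(per_type = per_type, micro = micro), class = "prfReport")
}

#' @export
print.prfReport <- function(x, ...) {
  cat("Entity-level evaluation (strict boundary + type match)\n")
  if (nrow(x$per_type)) {
    df <- x$per_type
    df$precision <- sprintf("%.2f", df$precision)
    df$recall <- sprintf("%.2f", df$recall)
    df$f1 <- sprintf("%.2f", df$f1)
    print(df, row.names = FALSE)
  }
  cat(sprintf("micro-avg  P %.2f  R %.2f  F1 %.2f  (TP %d FP %d FN %d)\n",
              x$micro$precision, x$micro$recall, x$micro$f1,
              x$micro$tp, x$micro$fp, x$micro$fn))
  if (x$micro$zero_denominator)
    cat("note: a zero denominator was reported as 0\n")
  invisible(x)
}

#' Format a PRF report as a TSV table
#'
#' @param x a `"prfReport"` from [entityPRF()].
#' @return character vector of tab-separated lines (header included).
#' @export
prfToTsv <- function(x) {
  df <- rbind(x$per_type,
              data.frame(entity_type = "micro-avg",
                         precision = x$micro$precision,
                         recall = x$micro$recall, f1 = x$micro$f1,
                         tp = x$micro$tp, fp = x$micro$fp, fn = x$micro$fn))
  c("entity_type\tprecision\trecall\tf1\ttp\tfp\tfn",
    sprintf("%s\t%.2f\t%.2f\t%.2f\t%d\t%d\t%d", df$entity_type,
            df$precision, df$recall, df$f1, df$tp, df$fp, df$fn))
}

#' Token-level confusion matrix over entity types
#'
#' Collapses tag prefixes to their entity types (`O` becomes `"Others"`,
#' `V` counts as its inner type) and cross-tabulates aligned gold and
#' predicted tag streams. The leading diagonal holds correctly classified
#' tokens; the matrix total equals the token count.
#'
#' @param gold_tags,pred_tags character tag vectors (or lists of per-sentence
#'   vectors, which are concatenated); must align one-to-one.
#' @param schema a [TagSchema-class].
#' @return integer matrix with gold types in rows, predicted in columns.
#' @export
confusionMatrix <- function(gold_tags, pred_tags, schema) {
  if (is.list(gold_tags)) gold_tags <- unlist(gold_tags)
  if (is.list(pred_tags)) pred_tags <- unlist(pred_tags)
  if (length(gold_tags) != length(pred_tags))
    stop("gold and predicted tag streams differ in length (",
         length(gold_tags), " vs ", length(pred_tags), ")")
  lev <- c(entityTypes(schema), "Others")
  collapse <- function(tags) {
    ty <- tagType(tags)
    factor(ifelse(is.na(ty), "Others", ty), levels = lev)
  }
  tbl <- table(gold = collapse(gold_tags), pred = collapse(pred_tags))
  m <- matrix(as.integer(tbl), nrow(tbl), ncol(tbl),
              dimnames = dimnames(tbl))
  m
}

#' Evaluate predicted against gold documents with an F1 gate
#'
#' Convenience wrapper: scores with [entityPRF()] and returns whether the
#' micro F1 reaches `min_f1` (used by the command-line `evaluate` gate).
#'
#' @inheritParams entityPRF
#' @param min_f1 required micro F1 in percent (default 0: always passes).
#' @return list with `report` and logical `pass`.
#' @export
evaluateCorpus <- function(gold, pred, min_f1 = 0, dedupe = TRUE) {
  rep <- entityPRF(gold, pred, dedupe = dedupe)
  list(report = rep, pass = rep$micro$f1 >= min_f1)
}
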