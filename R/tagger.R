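## The sequence tagger: a character-level bidirectional LSTM whose final
## states are concatenated with word and sense embeddings, a bidirectional
## sentence LSTM, a linear emission layer, and a linear-chain CRF trained by
## per-sentence stochastic gradient descent on the negative path
## log-likelihood (logZ - gold path score).  All backward passes are
## hand-derived; the test suite checks them against numeric gradients.

MODEL_FORMAT_VERSION <- "clinner-model-1"
UNK <- "<UNK>"

#' Tagger configuration
#'
#' Defaults follow the reference hyperparameter set for this architecture:
#' 25-dimensional character embeddings with a 25-unit character LSTM per
#' direction (so the bidirectional character feature is 50-dimensional),
#' 300-dimensional word and 128-dimensional sense embeddings, 100 LSTM units
#' per direction, SGD with learning rate 0.005, dropout 0.5 on the feature
#' vectors, 100 epochs.
#'
#' @param char_dim character embedding dimension.
#' @param char_hidden character LSTM hidden units per direction.
#' @param word_dim word embedding dimension.
#' @param sense_dim sense embedding dimension.
#' @param lstm_hidden sentence LSTM hidden units per direction.
#' @param dropout dropout probability on feature vectors (training only).
#' @param learning_rate SGD learning rate.
#' @param optimizer only `"sgd"` is supported.
#' @param epochs training epochs.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param gradient_clip element-wise gradient value clip (each gradient
#'   component is limited to `[-gradient_clip, gradient_clip]`), matching
#'   the reference sequence-tagger implementation this model follows.
#' @param constrain_transitions hard-mask impossible BMEWO-V transitions.
#' @param oov_policy for randomly initialized tables: `"trainable-unk"`
#'   (default) or `"zero"`; pre-trained tables always resolve OOV to a zero
#'   vector and are frozen.
#' @param patience optional early-stopping patience on a dev set
#'   (`NULL` = off).
#' @return named list of class `"taggerConfig"`.
#' @export
taggerConfig <- function(char_dim = 25L, char_hidden = 25L, word_dim = 300L,
                         sense_dim = 128L, lstm_hidden = 100L, dropout = 0.5,
                         learning_rate = 0.005, optimizer = "sgd",
                         epochs = 100L, seed = 42L, gradient_clip = 5,
                         constrain_transitions = TRUE,
                         oov_policy = c("trainable-unk", "zero"),
                         patience = NULL) {
  stopifnot(char_dim > 0L, char_hidden > 0L, word_dim > 0L, sense_dim > 0L,
            lstm_hidden > 0L, dropout >= 0, dropout < 1, learning_rate > 0,
            identical(optimizer, "sgd"), epochs >= 1L, gradient_clip > 0)
  structure(list(char_dim = as.integer(char_dim),
                 char_hidden = as.integer(char_hidden),
                 word_dim = as.integer(word_dim),
                 sense_dim = as.integer(sense_dim),
                 lstm_hidden = as.integer(lstm_hidden),
                 dropout = dropout, learning_rate = learning_rate,
                 optimizer = optimizer, epochs = as.integer(epochs),
                 seed = as.integer(seed), gradient_clip = gradient_clip,
                 constrain_transitions = isTRUE(constrain_transitions),
                 oov_policy = match.arg(oov_policy),
                 patience = patience),
            class = "taggerConfig")
}

#' Read a whitespace-delimited embedding text file
#'
#' One token per line followed by its vector components; an optional first
#' header line `count dim` is skipped. Gzip files are read transparently.
#'
#' @param path file path (`.gz` allowed).
#' @return list with `vocab` (character) and `vectors`
#'   (numeric matrix, one row per token).
#' @export
readEmbeddings <- function(path) {
  con <- gzfile(path, "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  first <- strsplit(lines[1L], "\\s+")[[1L]]
  if (length(first) == 2L &&
      !anyNA(suppressWarnings(as.numeric(first))))
    lines <- lines[-1L]
  parts <- strsplit(lines, "\\s+")
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L)
    stop("inconsistent vector dimensions in embedding file")
  vocab <- vapply(parts, `[[`, character(1), 1L)
  vec <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
                nrow = length(parts), byrow = TRUE)
  rownames(vec) <- vocab
  list(vocab = vocab, vectors = vec)
}

uniformInit <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -scale, scale), nr, nc)
}

## Build an embedding block: vocabulary + matrix + OOV resolution.
## Pre-trained tables are frozen and resolve OOV to the zero vector; random
## tables get a trainable UNK row (or a fixed zero row under oov_policy
## "zero").
makeTable <- function(seen, dim, pretrained = NULL, oov_policy) {
  if (!is.null(pretrained)) {
    if (ncol(pretrained$vectors) != dim)
      stop("pre-trained table dimension ", ncol(pretrained$vectors),
           " does not match configured dimension ", dim)
    vocab <- c(UNK, pretrained$vocab)
    mat <- rbind(0, pretrained$vectors)
    rownames(mat) <- NULL
    list(vocab = vocab, mat = mat, frozen = TRUE)
  } else {
    vocab <- c(UNK, sort(unique(seen)))
    mat <- uniformInit(length(vocab), dim)
    if (oov_policy == "zero") mat[1L, ] <- 0
    list(vocab = vocab, mat = mat, frozen = FALSE)
  }
}

senseKeys <- function(texts, pos) {
  c(paste0(tolower(texts), "|", pos), tolower(texts))
}

charVec <- function(x) strsplit(x, "", fixed = FALSE)[[1L]]

## 1-based row indices into an embedding block; unknown symbols map to UNK.
lookupIds <- function(keys, vocab) {
  i <- match(keys, vocab)
  i[is.na(i)] <- 1L
  i
}

senseIds <- function(texts, pos, vocab) {
  k1 <- match(paste0(tolower(texts), "|", pos), vocab)
  k2 <- match(tolower(texts), vocab)
  out <- ifelse(is.na(k1), ifelse(is.na(k2), 1L, k2), k1)
  as.integer(out)
}

#' Initialize an untrained tagger model
#'
#' Builds vocabularies from the training sentences and initializes all
#' parameters (seeded). Pre-trained word or sense tables, when given, are
#' frozen; tables initialized randomly are trainable.
#'
#' @param sentences list of sentences, each a list with elements `tokens`
#'   (a [tokenize()] `data.frame`) and `tags` (character BMEWO-V vector).
#' @param schema a [TagSchema-class].
#' @param config a [taggerConfig()].
#' @param word_embeddings,sense_embeddings optional [readEmbeddings()]
#'   results.
#' @return an untrained [TaggerModel-class].
#' @export
initTaggerModel <- function(sentences, schema, config = taggerConfig(),
                            word_embeddings = NULL, sense_embeddings = NULL) {
  set.seed(config$seed)
  texts <- unlist(lapply(sentences, function(s) s$tokens$text))
  pos <- unlist(lapply(sentences, function(s) s$tokens$pos))
  wordTab <- makeTable(tolower(texts), config$word_dim, word_embeddings,
                       config$oov_policy)
  senseTab <- makeTable(senseKeys(texts, pos), config$sense_dim,
                        sense_embeddings, config$oov_policy)
  chars <- unique(unlist(strsplit(texts, "", fixed = FALSE)))
  charVocab <- c(UNK, sort(chars))
  K <- length(tagInventory(schema))
  ch <- config$char_hidden; H <- config$lstm_hidden
  D <- config$word_dim + config$sense_dim + 2L * ch
  ## Forget-gate biases start at 1 (gate rows i,f,o,g; bias in the last
  ## column) so memory cells pass state through early in training.
  lstmInit <- function(h, d) {
    W <- uniformInit(4L * h, d + h + 1L)
    W[h + seq_len(h), d + h + 1L] <- 1
    W
  }
  params <- list(
    charEmb = uniformInit(length(charVocab), config$char_dim),
    charWf = lstmInit(ch, config$char_dim),
    charWb = lstmInit(ch, config$char_dim),
    wordEmb = wordTab$mat,
    senseEmb = senseTab$mat,
    Wf = lstmInit(H, D),
    Wb = lstmInit(H, D),
    outW = uniformInit(K, 2L * H),
    outb = rep(0, K),
    trans = transitionMask(schema, config$constrain_transitions))
  frozen <- c(if (wordTab$frozen) "wordEmb", if (senseTab$frozen) "senseEmb")
  new("TaggerModel", config = unclass(config), schema = schema,
      vocab = list(words = wordTab$vocab, chars = charVocab,
                   senses = senseTab$vocab),
      params = params, frozen = as.character(frozen),
      version = MODEL_FORMAT_VERSION)
}

#' Character-level encoding of one token
#'
#' Runs the model's character bidirectional LSTM over the token's character
#' embeddings and concatenates the two final hidden states. Deterministic
#' for fixed parameters; characters outside the character vocabulary map to
#' the UNK character.
#'
#' @param model a [TaggerModel-class].
#' @param token_text non-empty token string.
#' @return numeric vector of length `2 * char_hidden`.
#' @export
charEncode <- function(model, token_text) {
  stopifnot(nzchar(token_text))
  p <- model@params
  ids <- lookupIds(charVec(token_text), model@vocab$chars)
  res <- cpp_char_encode(list(as.integer(ids)), p$charEmb, p$charWf, p$charWb)
  as.numeric(res$feats[, 1L])
}

#' Assemble per-token feature vectors for a sentence
#'
#' Each token's feature vector is the concatenation of its word embedding,
#' sense embedding (keyed `token|POS` with token-only fallback) and
#' character-LSTM feature, giving dimension
#' `word_dim + sense_dim + 2 * char_hidden`.
#'
#' @param model a [TaggerModel-class].
#' @param tokens token `data.frame` with columns `text` and `pos`.
#' @return numeric matrix, one column per token.
#' @export
assembleFeatures <- function(model, tokens) {
  fw <- forwardSentence(model, tokens, training = FALSE)
  fw$X
}

## Full forward pass over one sentence; returns every intermediate needed
## by the backward pass.
forwardSentence <- function(model, tokens, training = FALSE,
                            featuresOnly = FALSE) {
  p <- model@params; cfg <- model@config
  L <- nrow(tokens)
  stopifnot(L >= 1L)
  wid <- lookupIds(tolower(tokens$text), model@vocab$words)
  sid <- senseIds(tokens$text, tokens$pos, model@vocab$senses)
  cid <- lapply(tokens$text, function(t)
    as.integer(lookupIds(charVec(t), model@vocab$chars)))
  ce <- cpp_char_encode(cid, p$charEmb, p$charWf, p$charWb)
  X <- rbind(t(p$wordEmb[wid, , drop = FALSE]),
             t(p$senseEmb[sid, , drop = FALSE]),
             ce$feats)
  mask <- NULL
  if (training && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix(stats::rbinom(length(X), 1L, keep) / keep,
                   nrow(X), ncol(X))
    X <- X * mask
  }
  if (featuresOnly)
    return(list(X = X, wid = wid, sid = sid, cid = cid, ce = ce, mask = mask))
  fw <- cpp_lstm_forward(X, p$Wf)
  rev <- seq.int(L, 1L)
  bw <- cpp_lstm_forward(X[, rev, drop = FALSE], p$Wb)
  Hmat <- rbind(fw$h, bw$h[, rev, drop = FALSE])
  E <- p$outW %*% Hmat + p$outb
  rownames(E) <- tagInventory(model@schema)
  list(X = X, wid = wid, sid = sid, cid = cid, ce = ce, mask = mask,
       fw = fw, bw = bw, Hmat = Hmat, E = E, L = L)
}

## Loss and gradients for one sentence; goldIdx are 1-based tag indices.
sentenceLossGrad <- function(model, tokens, goldIdx, training = FALSE,
                             grad = TRUE) {
  p <- model@params
  f <- forwardSentence(model, tokens, training = training)
  crf <- cpp_crf_forward(f$E, p$trans, grad)
  gold <- cpp_crf_score(f$E, p$trans, as.integer(goldIdx))
  loss <- crf$logZ - gold
  if (!grad) return(list(loss = loss))
  L <- f$L; K <- nrow(f$E); H <- model@config$lstm_hidden
  dE <- crf$dE
  dE[cbind(goldIdx, seq_len(L))] <- dE[cbind(goldIdx, seq_len(L))] - 1
  dT <- crf$dT
  prev <- K + 1L
  for (t in seq_len(L)) {
    dT[prev, goldIdx[t]] <- dT[prev, goldIdx[t]] - 1
    prev <- goldIdx[t]
  }
  dT[prev, K + 2L] <- dT[prev, K + 2L] - 1
  doutW <- dE %*% t(f$Hmat)
  doutb <- rowSums(dE)
  dH <- t(p$outW) %*% dE
  rev <- seq.int(L, 1L)
  gf <- cpp_lstm_backward(f$X, p$Wf, f$fw$h, f$fw$c, f$fw$gates,
                          dH[seq_len(H), , drop = FALSE])
  gb <- cpp_lstm_backward(f$X[, rev, drop = FALSE], p$Wb, f$bw$h, f$bw$c,
                          f$bw$gates,
                          dH[H + seq_len(H), rev, drop = FALSE])
  dX <- gf$dX + gb$dX[, rev, drop = FALSE]
  if (!is.null(f$mask)) dX <- dX * f$mask
  wd <- model@config$word_dim; sd_ <- model@config$sense_dim
  dXw <- dX[seq_len(wd), , drop = FALSE]
  dXs <- dX[wd + seq_len(sd_), , drop = FALSE]
  dXc <- dX[wd + sd_ + seq_len(2L * model@config$char_hidden), ,
            drop = FALSE]
  cb <- cpp_char_encode_backward(f$cid, p$charEmb, p$charWf, p$charWb,
                                 f$ce$caches, dXc)
  dWord <- matrix(0, nrow(p$wordEmb), ncol(p$wordEmb))
  for (t in seq_len(L)) dWord[f$wid[t], ] <- dWord[f$wid[t], ] + dXw[, t]
  dSense <- matrix(0, nrow(p$senseEmb), ncol(p$senseEmb))
  for (t in seq_len(L)) dSense[f$sid[t], ] <- dSense[f$sid[t], ] + dXs[, t]
  grads <- list(charEmb = cb$dEmb, charWf = cb$dWf, charWb = cb$dWb,
                wordEmb = dWord, senseEmb = dSense,
                Wf = gf$dW, Wb = gb$dW, outW = doutW, outb = doutb,
                trans = dT)
  list(loss = loss, grads = grads)
}

applySgd <- function(model, grads) {
  cfg <- model@config
  for (nm in model@frozen) grads[[nm]] <- NULL
  if (cfg$oov_policy == "zero") {
    # keep the fixed zero OOV row fixed
    if (!is.null(grads$wordEmb)) grads$wordEmb[1L, ] <- 0
    if (!is.null(grads$senseEmb)) grads$senseEmb[1L, ] <- 0
  }
  lr <- cfg$learning_rate
  clip <- cfg$gradient_clip
  mask <- !is.finite(model@params$trans)
  for (nm in names(grads)) {
    g <- pmin(pmax(grads[[nm]], -clip), clip)
    model@params[[nm]] <- model@params[[nm]] - lr * g
  }
  model@params$trans[mask] <- -Inf
  model
}

#' Train the bidirectional LSTM-CRF tagger
#'
#' Per-sentence stochastic gradient descent on the CRF negative path
#' log-likelihood, with inverted dropout on the feature vectors during
#' training only and element-wise gradient value clipping. Fully deterministic for
#' a fixed configuration seed. Per-epoch mean training loss is recorded in
#' the returned model's config (`loss_history`) and optionally printed.
#'
#' @inheritParams initTaggerModel
#' @param dev optional held-out sentence list; when `config$patience` is an
#'   integer, training stops after that many epochs without improvement of
#'   dev micro-F1 and the best parameters are kept.
#' @param verbose print per-epoch loss (default `FALSE`).
#' @return a trained [TaggerModel-class].
#' @examples
#' \donttest{
#' dict <- makeDictionary(10, seed = 1)
#' corp <- generateCorpus(syntheticCorpusSpec(n_docs = 2, seed = 1),
#'                        dict$concepts, dict$abbreviations)
#' cfg <- taggerConfig(word_dim = 20, sense_dim = 8, char_dim = 8,
#'                     char_hidden = 8, lstm_hidden = 10, epochs = 2)
#' model <- trainTagger(corp$sentences, corp$schema, cfg)
#' }
#' @export
trainTagger <- function(sentences, schema, config = taggerConfig(),
                        word_embeddings = NULL, sense_embeddings = NULL,
                        dev = NULL, verbose = FALSE) {
  stopifnot(length(sentences) >= 1L)
  inv <- tagInventory(schema)
  goldIdx <- lapply(sentences, function(s) {
    i <- match(s$tags, inv)
    if (anyNA(i)) stop("gold tag outside schema inventory: ",
                       s$tags[is.na(i)][1L])
    i
  })
  model <- initTaggerModel(sentences, schema, config, word_embeddings,
                           sense_embeddings)
  history <- numeric(0)
  bestF1 <- -Inf; bestParams <- NULL; sinceBest <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(sentences))
    total <- 0
    for (si in ord) {
      res <- sentenceLossGrad(model, sentences[[si]]$tokens, goldIdx[[si]],
                              training = TRUE)
      if (!is.finite(res$loss))
        stop("training aborted: non-finite loss at epoch ", epoch,
             ", sentence ", si,
             " (consider a lower learning rate or stronger clipping)")
      total <- total + res$loss
      model <- applySgd(model, res$grads)
    }
    history <- c(history, total / length(sentences))
    if (verbose)
      message(sprintf("epoch %3d  mean loss %.4f", epoch,
                      total / length(sentences)))
    if (!is.null(dev) && !is.null(config$patience)) {
      f1 <- sentenceMicroF1(model, dev)
      if (f1 > bestF1 + 1e-9) {
        bestF1 <- f1; bestParams <- model@params; sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$patience) break
      }
    }
  }
  if (!is.null(bestParams)) model@params <- bestParams
  model@config$loss_history <- history
  model@config$epochs_trained <- length(history)
  model
}

## Entity-level micro-F1 of model predictions against gold tags, treating
## each sentence as a document.
sentenceMicroF1 <- function(model, sentences) {
  pred <- predictTagger(model, lapply(sentences, `[[`, "tokens"))
  schema <- model@schema
  gold <- lapply(sentences, function(s)
    decodeTags(s$tokens, s$tags, schema))
  hyp <- lapply(seq_along(sentences), function(i)
    decodeTags(sentences[[i]]$tokens, pred[[i]], schema))
  names(gold) <- names(hyp) <- paste0("s", seq_along(sentences))
  entityPRF(gold, hyp)$micro$f1 / 100
}

#' Predict tags for sentences
#'
#' Viterbi decoding with dropout disabled; raw model output is passed
#' through [repairTags()] by default.
#'
#' @param model a trained [TaggerModel-class].
#' @param token_tables list of token `data.frame`s (columns `text`, `pos`).
#' @param repair repair raw tag output to well-formedness (default `TRUE`).
#' @return list of character tag vectors, one per sentence; the raw
#'   unrepaired tags are kept in attribute `"raw"`.
#' @export
predictTagger <- function(model, token_tables, repair = TRUE) {
  if (length(token_tables) == 0L) return(list())
  inv <- tagInventory(model@schema)
  raw <- lapply(token_tables, function(tok) {
    stopifnot(nrow(tok) >= 1L)
    f <- forwardSentence(model, tok, training = FALSE)
    res <- cpp_crf_viterbi(f$E, model@params$trans)
    inv[res$path]
  })
  if (!repair) return(raw)
  out <- lapply(raw, repairTags, schema = model@schema)
  attr(out, "raw") <- raw
  out
}

#' Save / load a tagger model
#'
#' Single-file serialization holding the format version, configuration,
#' schema, vocabularies and all parameter arrays.
#'
#' @param model a [TaggerModel-class].
#' @param path file path.
#' @return `path` (save) or the restored [TaggerModel-class] (load).
#' @export
saveTaggerModel <- function(model, path) {
  saveRDS(list(version = model@version, config = model@config,
               entity_types = entityTypes(model@schema),
               vocab = model@vocab, params = model@params,
               frozen = model@frozen), path)
  invisible(path)
}

#' @rdname saveTaggerModel
#' @export
loadTaggerModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, MODEL_FORMAT_VERSION))
    stop("unsupported model format version: ", x$version)
  new("TaggerModel", config = x$config, schema = tagSchema(x$entity_types),
      vocab = x$vocab, params = x$params, frozen = x$frozen,
      version = x$version)
}
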