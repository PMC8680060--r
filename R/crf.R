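## R surface of the linear-chain CRF: path scoring, log-partition (forward
## algorithm), Viterbi decoding, and the BMEWO-V transition mask.
##
## Emissions are K x L matrices (tags in rows); the transition matrix is
## (K+2) x (K+2) with the two extra states being virtual START and STOP.

#' Virtual-state transition matrix for a tag schema
#'
#' Builds the `(K+2) x (K+2)` transition matrix (last two rows/columns are
#' the virtual START and STOP states), optionally hard-masking transitions
#' that are impossible under BMEWO-V well-formedness (for example `O` to
#' `M-t`, or `B-t1` to `E-t2`) at `-Inf`. Transitions into and out of `V`
#' tags are unconstrained: under the encode convention `V` can legally
#' begin, continue or end a run.
#'
#' @param schema a [TagSchema-class].
#' @param constrain apply the BMEWO-V mask (default `TRUE`); `FALSE` gives
#'   an all-zero (fully connected) matrix.
#' @return numeric matrix with dimnames (tags plus `"<START>"`, `"<STOP>"`).
#' @export
transitionMask <- function(schema, constrain = TRUE) {
  inv <- tagInventory(schema)
  K <- length(inv)
  states <- c(inv, "<START>", "<STOP>")
  m <- matrix(0, K + 2L, K + 2L, dimnames = list(states, states))
  if (!constrain) {
    m[, K + 1L] <- -Inf; m[K + 2L, ] <- -Inf  # nothing enters START/leaves STOP
    return(m)
  }
  pre <- c(tagPrefix(inv), "S", "X")
  typ <- c(tagType(inv), NA, NA)
  for (i in seq_len(K + 2L)) {
    for (j in seq_len(K + 2L)) {
      a <- pre[i]; b <- pre[j]
      ok <- if (a == "X" || b == "S") FALSE                 # out of STOP / into START
      else if (b == "X") a %in% c("O", "W", "E", "V")        # run must be closed
      else if (b == "V" || a == "V") TRUE
      else if (a %in% c("O", "W", "E", "S")) b %in% c("O", "B", "W")
      else if (a %in% c("B", "M")) b %in% c("M", "E") && typ[i] == typ[j]
      else FALSE
      if (!ok) m[i, j] <- -Inf
    }
  }
  m
}

#' Score one tag path under a linear-chain CRF
#'
#' The score is the sum of per-position emission scores plus transition
#' scores, including the `START -> tag_1` and `tag_L -> STOP` terms.
#'
#' @param emissions `K x L` numeric matrix of per-tag scores.
#' @param transitions `(K+2) x (K+2)` transition matrix (see
#'   [transitionMask()]).
#' @param tags integer tag indices in `1..K`, or character tags resolved
#'   against `rownames(emissions)`.
#' @return numeric path score.
#' @export
crfScore <- function(emissions, transitions, tags) {
  if (is.character(tags)) {
    tags <- match(tags, rownames(emissions))
    if (anyNA(tags)) stop("tag not found in emission rownames")
  }
  cpp_crf_score(emissions, transitions, as.integer(tags))
}

#' Log-partition of a linear-chain CRF
#'
#' Computes `log sum over all K^L paths of exp(score)` by the forward
#' recursion in log space (log-sum-exp at every step, so no overflow).
#'
#' @inheritParams crfScore
#' @param grad also return gradients of `logZ`: posterior marginals `dE`
#'   and expected transition counts `dT` (forward-backward).
#' @return `logZ` (numeric) when `grad = FALSE`, else a list
#'   `(logZ, dE, dT)`.
#' @export
crfLogPartition <- function(emissions, transitions, grad = FALSE) {
  res <- cpp_crf_forward(emissions, transitions, grad)
  if (!grad) res$logZ else res
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Returns the highest-scoring tag path and its score; ties are broken
#' deterministically toward the lowest tag index at every backpointer.
#'
#' @inheritParams crfScore
#' @return list with `path` (integer indices), `tags` (character, when
#'   `emissions` has rownames) and `score`.
#' @export
viterbiDecode <- function(emissions, transitions) {
  res <- cpp_crf_viterbi(emissions, transitions)
  if (!is.null(rownames(emissions)))
    res$tags <- rownames(emissions)[res$path]
  res
}
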