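---
title: "Nested NER with BMEWO-V tags and a Bi-LSTM-CRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested NER with BMEWO-V tags and a Bi-LSTM-CRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinner)
```

## Problem

Clinical entity mentions nest: a multi-token mention such as *calcio
ionico* may contain the shorter mention *calcio* starting at the same
offset. Standard BIO tagging cannot represent both at once, so `clinner`
uses the BMEWO-V scheme: sequence tagging with one flat tag per token,
plus a codec that maps tag rows back to (possibly nested) mention tables.

## The BMEWO-V codec

For each entity type `X` there are five tags:

- `B-X` / `M-X` / `E-X` — begin, middle, end of a multi-token mention;
- `W-X` — a whole single-token mention;
- `V-X` — a token covered by **more than one** mention, typed by the
  innermost one.

Together with the single `O` tag, four entity types give the 21-tag
inventory:

```{r}
buildTagset(pharmaconerTypes())
```

Decoding inverts this deterministically: a maximal `B/M/E/V` run of one
type yields the enclosing mention, and every `V` token inside it
additionally yields a single-token inner mention. The codec is exercised
as a property in the test suite: for thousands of generated sentences
(including nested ones), `decodeTags(encodeTags(...))` reproduces the
gold mention set exactly.

```{r}
text <- "nivel de calcio ionico alto"
tk <- tokenize(text)
m <- data.frame(entity_type = c("NORMALIZABLES", "NORMALIZABLES"),
                start = c(9L, 9L), end = c(22L, 15L),
                surface = c("calcio ionico", "calcio"))
tags <- encodeTags(tk, m, tagSchema())
tags
decodeTags(tk, tags, tagSchema(), text = text)[, 1:5]
```

The limitation is inherited from the scheme itself: only one level of
nesting is representable (the `V` tag carries a single inner type), and
two nested mentions must share the innermost-token typing. The synthetic
generator therefore only emits one-level nesting.

## The tagger

Each token is represented by three concatenated channels:

1. **character channel** — a bidirectional LSTM over character embeddings
   (dimension 50, hidden size 100 per direction by default), using the
   final states of both directions;
2. **word channel** — a word embedding (dimension 300), optionally
   initialized from a pre-trained file and frozen, with out-of-vocabulary
   words mapped to a zero vector;
3. **sense channel** — an embedding (dimension 128) of a coarse
   `token|POS` key built by a deliberately naive deterministic POS
   labeler; it stands in for an external word-sense or concept-class
   signal.

The concatenation feeds a token-level bidirectional LSTM (hidden size 100
per direction) whose outputs are projected to per-tag emission scores. A
linear-chain CRF with virtual START/STOP states defines the sentence
likelihood; training minimizes the exact negative log-likelihood per
sentence by plain SGD (learning rate 0.005, dropout 0.5 on the LSTM
input, at most 100 epochs by default).

### Numerical choices

- The CRF forward pass runs in log space with log-sum-exp at every step;
  the partition function and Viterbi decoder are tested against
  brute-force enumeration over all `K^L` paths at tolerance `1e-9`.
- Gradients are exact (forward–backward marginals for the CRF, full
  backpropagation through time for both LSTM levels) and are verified
  against central finite differences in the test suite.
- Gradient clipping is **element-wise value clipping** at ±5, not global
  norm scaling. With typical initial gradient norms well above 5, norm
  scaling would silently shrink the effective learning rate; value
  clipping preserves SGD step sizes except on extreme coordinates.
- LSTM weights use Glorot-uniform initialization and forget-gate biases
  start at 1, the standard recipe for trainable gates at small scale.
- Every run is seeded: same seed, same loss history, bit for bit.

## Synthetic corpus generator

`generateCorpus()` writes BRAT corpora from a seeded specification:
carrier sentence templates, a concept dictionary of pairwise-separated
pseudo-Spanish terms, and per-mention perturbations (misspellings at an
exact Levenshtein distance, abbreviation substitution). Two design points
matter for learnability:

- **Nesting is decided once per concept**, not per occurrence: a
  multi-token concept either always carries its single-token inner
  mention (with a fixed inner type derived from the term) or never does.
  Deciding per occurrence would make the same surface string carry
  different gold tags in different sentences — label noise that no
  tagger can resolve and that silently caps attainable F1.
- Misspellings are generated at an exact, configurable edit distance, so
  normalization experiments can place surfaces just inside or just
  outside the matcher's bounds.

The default problem sizes (10 documents × 5 sentences, 20 concepts) are
the package's own choice: large enough to exercise every tag kind and
both nesting branches, small enough that a full 100-epoch training run
finishes in about two minutes on one CPU.

## Concept normalization

`normalizeMention()` lowercases, expands known abbreviations, then tries
three stages in order: exact dictionary lookup; bounded Levenshtein
search (distance ≤ 1 by default); fuzzy matching accepted only when the
normalized similarity `1 - d / max(|a|, |b|)` reaches the 0.80 threshold.
Ambiguous terms (one surface, several concept ids) follow a configurable
policy: deterministic first-by-id, or reject.

```{r}
dict <- conceptDictionary(data.frame(
  concept_id = c("C1", "C2"), term = c("prednisona", "tenecteplasa")))
normalizeMention("prednisena", dict)$stage     # distance 1
normalizeMention("tenecteplosas", dict)$stage  # similarity 11/13
normalizeMention("xyzzy", dict)$stage
```

The Levenshtein implementation operates on code points (so `á` vs `a` is
one substitution) and is validated against `utils::adist` on tens of
thousands of random pairs.

## Evaluation

`entityPRF()` scores strict entity-level matches — exact (type, start,
end) triples, nested gold mentions counted independently — and reports
per-type and micro-averaged precision/recall/F1 on a 0–100 scale.
`confusionMatrix()` collapses tag prefixes to entity types (everything
else becomes `Others`) for token-level error analysis.
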