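# clinner

Nested clinical named-entity recognition and concept normalization in R.

`clinner` is a self-contained toolkit for recognizing possibly **nested**
entity mentions in clinical text and linking them to dictionary concept
identifiers. It provides:

- **BRAT standoff and CoNLL-2003 I/O** — read/write `.txt`/`.ann` corpora
  (`T` entity lines with concept ids on `N` reference lines) and token
  tables, with code-point (not byte) offsets throughout.
- **Deterministic preprocessing** — abbreviation-aware sentence splitting
  and an offset-preserving tokenizer.
- **BMEWO-V tag codec** — encodes nested mentions into one flat tag
  sequence per token (`B`/`M`/`E` for multi-token spans, `W` for
  single-token mentions, `V` for tokens covered by more than one mention,
  plus `O`), and decodes tag sequences back to mention tables. For the four
  built-in entity types the inventory has exactly 21 tags.
- **A Bi-LSTM-CRF sequence tagger** — character, word, and sense ("concept
  class") embedding channels feed a bidirectional LSTM with an exact
  linear-chain CRF output layer (log-space forward algorithm, Viterbi
  decoding, virtual START/STOP states). Training is plain SGD with
  element-wise gradient value clipping, dropout on the LSTM input, and a
  seeded, fully deterministic loop. The numerical core is hand-written
  C++ (Rcpp/RcppArmadillo); gradients are exact and verified against
  finite differences and brute-force path enumeration in the test suite.
- **Strict entity-level evaluation** — micro/per-type precision, recall
  and F1 over exact (type, start, end) triples, plus token-level confusion
  matrices collapsed to entity types.
- **Two-stage concept normalization** — abbreviation expansion, exact
  lookup, bounded Levenshtein search (distance ≤ 1 by default), then
  fuzzy matching gated by a normalized-similarity threshold (0.80 by
  default), with a configurable ambiguity policy.
- **A seeded synthetic corpus generator** — produces BRAT corpora with
  controllable mention, nesting, misspelling and abbreviation rates, used
  for end-to-end and acceptance testing without any external data.
- **A CLI** — `synth`, `train`, `predict`, `evaluate`, `normalize`,
  `convert`, and `pipeline` subcommands via `clinnerMain()`.

## Worked example

Tokenize a sentence, decode a gold tag row, and normalize a misspelled
mention:

```r
library(clinner)

text <- "instaurándose tratamiento con corticoides orales en forma de prednisona oral"
tk <- tokenize(text)
head(tk, 4)
#>            text start end  pos
#> 1 instaurándose     0  13 NOUN
#> 2   tratamiento    14  25 NOUN
#> 3           con    26  29 NOUN
#> 4   corticoides    30  41 NOUN

tags <- rep("O", nrow(tk))
tags[tk$text %in% c("corticoides", "prednisona")] <- "W-NORMALIZABLES"
decodeTags(tk, tags, tagSchema(), text = text)
#>   mention_id   entity_type start end     surface concept_id
#> 1         T1 NORMALIZABLES    30  41 corticoides       <NA>
#> 2         T2 NORMALIZABLES    61  71  prednisona       <NA>

dict <- conceptDictionary(data.frame(concept_id = "C0032950",
                                     term = "prednisona"))
normalizeMention("prednisena", dict)   # one substitution away
#> $concept_id   [1] "C0032950"
#> $stage        [1] "levenshtein"
#> $score        [1] 1
#> $matched_term [1] "prednisona"
#> $ambiguous    [1] FALSE
```

Generate a small synthetic corpus and train a tagger on it:

```r
dict <- makeDictionary(12, seed = 42)
corp <- generateCorpus(syntheticCorpusSpec(n_docs = 2, seed = 42),
                       dict$concepts, dict$abbreviations)
substr(docText(corp$docs[[1]]), 1, 66)
#> [1] "Se administra tuno junto con melura fuvoropaasa durante el ingreso"
head(mentions(corp$docs[[1]]), 3)
#>   mention_id   entity_type start end            surface concept_id
#> 1         T1 NORMALIZABLES    14  18               tuno    SC00005
#> 2         T2       UNCLEAR    29  47 melura fuvoropaasa    SC00004
#> 3         T3 NORMALIZABLES    94 110   supaina lunasaol    SC00009

model <- trainTagger(corp$sentences, corp$schema,
                     taggerConfig(seed = 42, epochs = 30L))
pred <- predictTagger(model, lapply(corp$sentences, `[[`, "tokens"))
```

The same pipeline is available from the shell:

```sh
Rscript -e 'clinner::clinnerMain(commandArgs(TRUE))' synth \
    --out corpus/ --n-docs 10 --seed 42
Rscript -e 'clinner::clinnerMain(commandArgs(TRUE))' train \
    --corpus corpus/ --out model.rds
```

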