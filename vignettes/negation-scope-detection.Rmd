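---
title: "One-stage negation and speculation scope detection with nested sequence labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-stage negation and speculation scope detection with nested sequence labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negscope)
```

## The task and the modeling idea

Clinical and biomedical text is dense with negation ("no masas ni
megalias") and speculation ("may have provided"). An information-extraction
system that misses them inverts the meaning of what it extracts: a negated
finding read as asserted is a false clinical fact. The task has two parts —
find the **cue** (the word or multiword expression carrying the negation or
hedge) and delimit its **scope** (the span whose truth value it affects).

Most systems solve this in two stages: first cue detection, then scope
resolution per cue. `negscope` instead treats cues, scopes and the clinical
entities inside scopes as *nested named entities* and recognizes all of
them in a **single** sequence-labeling pass. A scope is simply a mention
that contains its cue(s); one tagging decision per token captures both
layers at once, so cue and scope detection share every parameter and are
never trained against inconsistent intermediate targets.

## The BMEWO-V tag codec

Each token receives a shape tag: **B**egin, **M**iddle, **E**nd of a
multi-token mention, **W**hole single-token mention, **O**utside, and
**V** for tokens of a mention that *overlaps/nests other mentions*.
Mentions nest to depth two, which covers the corpora this design targets
(cues and findings inside scopes). A sentence is encoded in two layers:

* outer layer: top-level mentions; a mention containing others is tagged
  `V-label` on *all* of its tokens, a childless one gets `B/M/E/W`;
* inner layer: the contained mentions, tagged `B/M/E/W`; a token inside an
  outer mention but in no inner mention copies its outer tag down.

For the clinical sentence *"Abdomen blando, depresible, no masas ni
megalias, no doloroso."*:

```{r codec-example}
s <- ns_tokenize("Abdomen blando, depresible, no masas ni megalias, no doloroso.")[[1]]
s$mentions <- list(
  mention("NegMarker", 28, 30), mention("Phrase", 31, 48),
  mention("DISO", 31, 36), mention("NegPolItem", 37, 39),
  mention("DISO", 40, 48), mention("NegMarker", 50, 52),
  mention("DISO", 53, 61))
tags <- bmewov_encode(s)
data.frame(token = s$tokens$text, outer = tags$outer, inner = tags$inner,
           joint = tags$joint)
```

The two layers are flattened to one **joint label** per token — `outer|inner`,
with `O` for doubly-outside tokens and the plain single-layer tag when the
inner layer merely copies the outer one. With a single entity label the
joint vocabulary is exactly the six BMEWO-V tags; with several labels it is
all single-layer tags plus the outer|inner pairs observed in training.
The model therefore predicts both layers *in one stage* through one CRF
over this finite joint vocabulary.

Design choices where the encoding was genuinely open:

* **V on every token of the nesting mention**, not only on shared tokens —
  this matches the two-column reference encoding above, where all three
  scope tokens carry `V-Phrase`.
* **Discontinuous mentions** ("no ... ni") are encoded fragment-by-fragment
  as same-label mentions. Tag sequences carry no mention identity, so the
  decoder cannot know which predicted fragments belong together; predicted
  fragments stay separate mentions, and rejoining is only meaningful
  against gold standoff annotations.
* **Partially overlapping (non-nested) mentions and depth-3 nesting are
  rejected** with an error naming the mentions: the corpora this codec
  models contain proper nesting only, and silently mis-encoding such input
  would corrupt training data. Two mentions with identical token spans are
  likewise ambiguous (either could be the outer one) and rejected.
* **Decoding is total**: model output is first passed through a
  deterministic repair — `M`/`E` with no open entity of their label start a
  new entity, an entity left open closes at its last consistent token, a
  single-token entity becomes `W`. Repair is idempotent and never changes
  sequence length, so every label sequence decodes to a valid mention set.

## The sequence model

Emission scores come from a two-level bidirectional recurrent encoder:

1. a character-level BiLSTM (embedding dimension 25, hidden 25 per
   direction) whose final states form a 50-wide morphological feature per
   token — valuable for morphologically rich languages such as Spanish and
   for the misspelling-heavy clinical register;
2. the concatenation of that feature with a word vector (trainable
   embedding, or a pretrained word2vec-format table) and an optional sense
   vector (sense-disambiguated embeddings such as sense2vec; a zero vector
   when no resource is configured);
3. a token-level BiLSTM (hidden 100 per direction) and a linear projection
   to one unnormalized score per joint label.

A linear-chain CRF sits on top: a path `y` is scored as the sum of its
emission scores plus label-transition scores with explicit start/stop
states. Training minimizes the negative log-likelihood
`log Z − score(gold)` computed by the forward recursion in log space;
prediction is Viterbi decoding with ties broken toward the lowest label
index. With constraint mode on (the default), transitions that are
shape-invalid in either layer (`O→M`, `B-X→E-Y`, start→`E`, `B`→stop, ...)
carry `−Inf` and can never be predicted, so decoded sequences pass the
codec validity check without repair changes. The CRF operates on
unnormalized emission scores; per-token normalization would only shift
each token's column by a constant, which the partition function absorbs
(the shift-invariance property tested in the suite).

### Hyperparameters and their defaults

| parameter | default | rationale |
|---|---|---|
| optimizer | SGD, lr 0.005 | reference training regime for this architecture |
| dropout | 0.5 | on concatenated token features and encoder output |
| epochs | 100 | fixed-length schedule; optional patience |
| token hidden | 100/direction | reference setting for BiLSTM-CRF taggers |
| char embedding / hidden | 25 / 25 | yields the reference 50-wide char feature |
| word embedding | table dimension, else 50 trainable | 200/300-dim pretrained tables plug in unchanged; 50 is ample for the synthetic vocabularies |
| sense embedding | table dimension, else 0 | 128-dim sense tables plug in; absent resource contributes nothing |
| gradient clip | L2 norm 5.0 | standard recurrent-training safeguard at this learning rate |
| mini-batch | 1 sentence | per-sentence SGD, order reshuffled each epoch |

All randomness — initialization, epoch shuffles, dropout masks — flows from
the single integer `seed` in `crf_config()`; two runs with one seed are
bitwise identical. After each epoch the entity-level F on the validation
documents is logged and the best-F parameters are kept.

## The synthetic corpus generator

Real negation corpora cannot be redistributed with a package, so
`generate_corpus()` builds seeded corpora exhibiting the structural
phenomena the codec and model must handle: cue-bearing sentences (rate
`p_cue`), scopes running from the cue to the next punctuation (or starting
after the cue, for corpora that exclude left context from the scope),
inner entity mentions inside scopes at rate `p_inner_entity` (these force
V tags), multiword cue locutions ("ausencia de", "en ningun momento"),
double negation (two cues in one scope) and discontinuous cues
("no ... ni"). Noise words are nonsense syllable strings, entity words
carry label-specific suffixes, and cue forms come from a small Spanish
lexicon, so the mapping from surface to annotation is learnable without
any external embedding resource.

What the generator deliberately does **not** emulate: lexical ambiguity
(real cues like "ni" are cues only half the time), long-range syntactic
scope boundaries not marked by punctuation, misspellings, and
document-level structure. A high F on synthetic held-out data therefore
demonstrates that the one-stage nested pipeline — codec, encoder, CRF,
decoding — learns cues, scopes and entities *jointly and correctly*, not
that it reaches any particular accuracy on clinical text.

## Evaluation levels

`evaluate_all()` reports precision/recall/F (printed to one decimal, as a
percentage) at four levels:

* **token**: per-token joint-tag agreement on non-`O` tags;
* **entity / cue**: exact label + fragment-set match (partial or
  boundary-shifted matches count as one false positive plus one false
  negative); the cue view is the same tally restricted to cue labels;
* **scope**: a predicted scope is correct only if its boundaries *and* the
  set of cue mentions nested inside it both match the gold scope exactly;
* **sentence**: F of the positive class, a sentence being positive when it
  contains at least one cue.

Degenerate denominators (no predictions, or no gold items) report 0 and
are flagged in the report rather than silently dropped.

## Problem sizes and numerical checks

The test suite verifies the CRF against exhaustive enumeration (200 random
instances with up to 8 tokens and 6 labels; forward log-partition within
1e-6 of the enumerated log-sum-exp, Viterbi equal to the enumerated
argmax, path probabilities summing to 1 within 1e-6), the analytic
gradients of the full network against central finite differences, the
codec round-trip `decode(encode(s)) = mentions(s)` on 1000 generated
nested/discontinuous sentences, and a learning experiment: 500 synthetic
training sentences (cue rate 0.5, inner-entity rate 0.4), 100 sentences
for checkpoint selection, entity-level F measured on 200 held-out
sentences, with the default hyperparameters above. These sizes were chosen
as the smallest at which each property is meaningfully exercised.
`scripts/acceptance.R` re-runs the same computations end to end and writes
the measured numbers as JSON.

## Known limitations

* Nesting depth is capped at two layers; a third layer (an entity inside
  an entity inside a scope) is rejected rather than approximated.
* Predicted discontinuous cues are emitted as separate fragments, which
  a strict exact-match evaluation against fragment-joined gold counts as
  errors; the corpora's own annotation of multiword cues is itself
  inconsistent in this regard.
* Adjacent same-label scopes with no intervening `O`/punctuation token
  would merge into one V run; sentence-internal punctuation makes this
  configuration rare in practice.
* The trainable-embedding path builds its vocabulary from training data
  only; generalization to unseen word forms rests on the character
  encoder and (when supplied) pretrained vectors.
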