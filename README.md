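# negscope

Detection of negation and speculation cues **and** their scopes in clinical
and biomedical text, in a single sequence-labeling stage.

Most pipelines detect cues first and resolve each cue's scope in a second
pass. `negscope` instead treats cues, scopes and the clinical entities
inside scopes as *nested named entities*: a scope is a mention that contains
its cue(s). Every token gets one tag from the **BMEWO-V** scheme — Begin /
Middle / End / Whole / Outside plus **V** for tokens of a mention that
overlaps (nests) other mentions — in two layers (outer = top-level mention,
inner = contained mentions), flattened to a single joint label per token.
One model then recognizes cues, scopes and entities jointly.

The sequence model is a recurrent CRF: a character-level BiLSTM (a 50-wide
morphological feature per token), concatenated with word vectors (trainable
or pretrained word2vec-text format) and optional sense vectors, feeds a
token-level BiLSTM (hidden 100/direction) and a linear-chain CRF. A path
`y` over joint labels is scored

    score(y) = T[start, y1] + sum_t E[t, y_t] + sum_{t>1} T[y_{t-1}, y_t] + T[y_n, stop]

trained by the forward-algorithm likelihood (SGD, lr 0.005, dropout 0.5,
100 epochs) and decoded by Viterbi; shape-invalid transitions (`O -> M-X`,
`B-X -> E-Y`, ...) are forbidden with `-Inf` scores so predictions always
decode to well-formed mentions.

The package also provides BRAT standoff and CoNLL-2003-style readers and
writers, a rule-based offset-preserving tokenizer, four evaluation levels
(token, entity/cue, scope — boundaries *and* nested cues exact —, and
sentence), a seeded synthetic corpus generator covering multiword cues,
double negation, discontinuous cues and nested entities, and a command-line
interface.

## Worked example

Encode the clinical sentence *"Abdomen blando, depresible, no masas ni
megalias, no doloroso."* ("soft, depressible abdomen, no masses or
megalias, not painful"), whose scope `Phrase(31,48)` nests two findings and
a negative-polarity item:

```r
library(negscope)

s <- ns_tokenize("Abdomen blando, depresible, no masas ni megalias, no doloroso.")[[1]]
s$mentions <- list(
  mention("NegMarker", 28, 30), mention("Phrase", 31, 48),
  mention("DISO", 31, 36), mention("NegPolItem", 37, 39),
  mention("DISO", 40, 48), mention("NegMarker", 50, 52),
  mention("DISO", 53, 61))
tags <- bmewov_encode(s)
data.frame(token = s$tokens$text, outer = tags$outer, inner = tags$inner)
#>         token       outer        inner
#> 1     Abdomen           O            O
#> 2      blando           O            O
#> 3           ,           O            O
#> 4  depresible           O            O
#> 5           ,           O            O
#> 6          no W-NegMarker  W-NegMarker
#> 7       masas    V-Phrase       W-DISO
#> 8          ni    V-Phrase W-NegPolItem
#> 9    megalias    V-Phrase       W-DISO
#> 10          ,           O            O
#> 11         no W-NegMarker  W-NegMarker
#> 12   doloroso      W-DISO       W-DISO
#> 13          .           O            O
```

The `V-Phrase` run marks the scope that overlaps the inner findings;
`bmewov_decode(tags, s$tokens)` recovers all seven mentions exactly.

Train and evaluate on a synthetic corpus (no external data):

```r
train   <- generate_corpus(gen_config(seed = 11, n_sentences = 500))
dev     <- generate_corpus(gen_config(seed = 13, n_sentences = 100))
heldout <- generate_corpus(gen_config(seed = 12, n_sentences = 200))

ck   <- train_model(train, dev, crf_config(seed = 42), quiet = TRUE)
pred <- predict_mentions(ck, heldout)
print(entity_eval(heldout, pred))
#> == entity-level evaluation ==
#>      label  tp fp fn precision recall    f1 degenerate
#>       DISO  51  0  6     100.0   89.5  94.4      FALSE
#>  NegMarker 103  7  5      93.6   95.4  94.5      FALSE
#>       PROC  52  1  1      98.1   98.1  98.1      FALSE
#>      Scope 102  0  0     100.0  100.0 100.0      FALSE
#> overall: P 97.5  R 96.2  F 96.9  (tp 308 fp 8 fn 12)
```

(Exact numbers for this seed; each mention counts only on an exact
label + span match.) The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/negscope.R synth --seed 7 --n 100 --out gold/
Rscript inst/cli/negscope.R train --config train.cfg
Rscript inst/cli/negscope.R predict --checkpoint model.rds --in gold/ --out pred/
Rscript inst/cli/negscope.R evaluate --gold gold/ --pred pred/ --json eval.json
```

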