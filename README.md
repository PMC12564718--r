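# racnlp

A desk-scale clinical NLP pipeline for identifying and predicting
malnutrition from free-text nursing progress notes in residential aged
care (RAC), written for health-informatics researchers who want the full
mechanism — domain-adaptive pretraining, long-note encoding, multimodal
fusion, cross-validated evaluation — runnable and testable on one CPU
without access to protected health records.

## What it implements

**Path 1 — domain-adaptive pretraining.** A compact transformer encoder
(2 layers, 4 heads, width 64 by default; implemented in base R with
hand-derived backpropagation and AdamW) is trained with whole-word masked
language modelling: 15% of words per 512-token chunk are selected, every
subword of a selected word is corrupted together (80% mask / 10% random /
10% keep), and masks are re-drawn each time a chunk is served.

**Path 2 — malnutrition note identification.** A dropout → linear →
sigmoid head over the masked-mean pooled last hidden state,

```
v = ( Σ_i m_i e_i ) / n ,    p = σ( w·v + b ),
```

trained with class-weighted binary cross-entropy
(`pos_weight = N_neg / N_pos`), 85/15 stratified holdout, best
validation-loss epoch kept.

**Path 3 — malnutrition prediction.** Each client's notes from the 30
days before onset (half-open window, earliest note first) are
concatenated. A sequence of C content tokens is split into
`ceil(C / 510)` parts of exactly 512 positions (start/end tokens
reserved, trailing padding, manual attention masks); parts are encoded
independently and content-token embeddings are summed across parts and
divided by the tracked token count n — for short notes this reduces
exactly to masked mean pooling. The pooled vector is concatenated with a
46-dimension one-hot risk-factor vector (dictionary matching with
negation detection: a cue like "no sign of" within the 5 preceding
same-sentence tokens negates a mention) and classified through a fully
connected sigmoid layer.

**Evaluation.** Stratified 5-fold cross-validation reporting precision,
recall, F1, specificity, AUPRC and AUROC with 95% t-intervals; two-sided
Mann-Whitney U comparison of per-fold metrics (exact permutation null for
small k); bag-of-words and static-embedding baselines under a ridge
logistic head.

**Synthetic data.** Since the motivating EHR corpus is not publicly
available, `synthetic_config()` / `generate_clients()` emulate its shape:
~64-token notes (negative-binomial lengths), ~644-token 30-day windows,
26% / 30% female / male malnutrition prevalence, keyword-borne signal
gated by `signal_strength`, and negated factor mentions.

## Worked example

```r
library(racnlp)

cfg     <- synthetic_config(n_clients = 200, seed = 0, signal_strength = 1)
clients <- generate_clients(cfg)
corpus  <- clean_text(generate_pretrain_corpus(cfg, 1500))
tok     <- train_tokenizer(corpus, vocab_size = 2000)
chunks  <- chunk_corpus(corpus, tok, chunk_len = 128)
split   <- split_train_val(chunks, 0.8, seed = 0)

ck <- pretrain(split$train, split$val,
               pretrain_config(max_steps = 50, seed = 0),
               masking_config(seed = 0), tok)
ck
#> <rac_checkpoint> mlm_pretrain - 50 steps, val loss 5.542

notes <- notes_frame(clients)
set.seed(0)
idx   <- c(sample(which(notes$label == 1), 200), sample(which(notes$label == 0), 200))
fit   <- train_note_classifier(notes[sample(idx), ], ck,
                               classifier_config(learning_rate = 3e-3,
                                                 batch_size = 8, epochs = 4,
                                                 seed = 0))
fit
#> <rac fitted classifier> best epoch 4 | holdout F1 0.935 AUROC 0.972

predict_note(fit, "resident reviewed. severe malnutrition noted. ate some lunch")
#> $probability
#> [1] 0.9842991
#> $label
#> [1] 1
```

The pretraining validation loss falls from 5.741 to 5.542 in 50 steps
(the tiny encoder is learning the synthetic domain); the classifier
reaches holdout F1 0.935 because at `signal_strength = 1` every
malnutrition-labelled note carries a detectable statement phrase. A
5-fold evaluation of the same chain (`kfold_cv()` with
`note_cv_trainer()`) averages F1 ≈ 0.98 across folds.

The same pipeline is exposed as a command line (the script installs to
`<library>/racnlp/exec/racnlp`; alias it or call it via `Rscript`):

```sh
racnlp generate-data --n-clients 200 --seed 0 --out data/
racnlp prepare-corpus --in data/notes.jsonl --out corpus/ --chunk-len 128 --seed 0
racnlp pretrain --corpus corpus/ --out ckpt/ --steps 50 --seed 0
racnlp train-notes --data data/notes.jsonl --checkpoint ckpt/ --out model/ \
       --learning-rate 0.003 --batch-size 8 --seed 0
racnlp evaluate --data data/notes.jsonl --checkpoint ckpt/ --out eval/ --k 5 \
       --learning-rate 0.003 --batch-size 8 --seed 0
```

Every command writes a `manifest.json` with the fully resolved
configuration, seed, package version and input digests.

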