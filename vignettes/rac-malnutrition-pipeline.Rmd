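---
title: "Methods: a desk-scale clinical NLP pipeline for malnutrition in residential aged care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale clinical NLP pipeline for malnutrition in residential aged care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most of what is known about a resident of an aged-care facility lives in
free-text nursing progress notes. Malnutrition — common, serious and
under-screened in this population — is typically documented there long
before it appears in any structured field. `racnlp` implements a
transformer-based pipeline over such notes with three paths:

1. **Domain-adaptive pretraining.** A compact encoder is (further) trained
   with whole-word masked-language modelling on a corpus of nursing notes,
   so that its embeddings reflect aged-care vocabulary, shorthand and
   abbreviations (`prn`, `adls`, `obs`, ...) that general-English models
   handle poorly.
2. **Malnutrition note identification.** A binary classifier over the
   masked-mean pooled last hidden state decides whether a note reports
   malnutrition.
3. **Malnutrition prediction.** For each client, the notes from the 30
   days before a malnutrition onset (or an anchor date for unaffected
   clients) are aggregated, encoded through a chunked long-text pathway,
   fused with a 46-dimension one-hot risk-factor vector, and classified
   through a fully connected sigmoid layer.

Because real aged-care notes are protected health information, the package
ships a synthetic-data generator that reproduces the statistical shape of
the problem, and every mechanism is tested against it.

## The encoder

No deep-learning runtime is assumed: the package implements its own
compact transformer encoder (token + position embeddings; post-LayerNorm
blocks of multi-head self-attention and a GELU feed-forward; AdamW with
decoupled weight decay; global gradient-norm clipping at 1). The default
profile — 2 layers, 4 heads, width 64, feed-forward 128, 512 positions —
is deliberately tiny: it runs the full pretraining and fine-tuning
machinery in minutes on one CPU. The analytic backpropagation is verified
against central finite differences in the test suite, which is the
load-bearing correctness argument for everything downstream.

Padding is always trailing, so each sequence is processed on its unpadded
prefix; this is numerically identical to masked attention over the padded
row and makes padding-invariance exact rather than approximate.

## Whole-word masking

Masking for pretraining is drawn at the *word* level: 15% of
whitespace-level words are selected per row (`mask_prob`, the standard
rate), and every subword token of a selected word is corrupted together —
80% replaced by the mask token, 10% by random tokens, 10% kept, the
original masked-LM recipe. The corruption split and the convergence rule
are configurable defaults, not claims: early stopping triggers when
relative validation improvement over a 5-evaluation window falls below
0.5%. Masking is re-drawn every time a chunk is served, so no fixed
pattern can be memorised across epochs.

Word boundaries are defined on the whitespace-delimited words of the
cleaned text before subword tokenisation. The bundled tokeniser is a
trained word-level vocabulary with character-piece fallback; rare words
tokenise to several `##`-pieces of one word, which is exactly the case
whole-word masking must treat atomically.

## The long-note mechanism

Encoders of this family accept at most 512 positions, but a 30-day window
of notes averages ~644 tokens. `segment()` splits a token sequence into
equal 512-position parts; each part starts with a start token, ends with
an end token, and the last part is padded. Attention masks are 0 exactly
on padding. Each part is encoded independently, the last-hidden-state
vectors at content positions are summed across all parts, and the sum is
divided by the tracked content-token count *n*.

Two design choices deserve explanation:

* **Capacity is 510 content tokens per part** (512 minus the two
  specials), so a note of *C* content tokens yields `ceiling(C / 510)`
  parts; a 1530-token note yields exactly 3 parts of 512 positions.
* **Start/end tokens are attended to but excluded from the pool.**
  Segmentation multiplies the number of special tokens, so including them
  would make a long note's pooled embedding depend on how many parts it
  was cut into. Excluding them preserves the exact identity: for any note
  that fits in one part, segmented pooling equals plain masked mean
  pooling (tested to 1e-5 for every C ≤ 510).

Parts are encoded independently — there is no cross-part attention — and
the division uses the tracked count *n*, not a mean of per-part means, so
the pool is token-weighted regardless of how unevenly tokens fall across
parts.

## Classification heads

Both downstream tasks share one training core: dropout (50%) on the head
input, a single linear layer, a sigmoid, and class-weighted binary
cross-entropy with `pos_weight = N_neg / N_pos` computed on the training
split ("auto"; any positive number may be fixed instead). The data is
split stratified into 15% holdout and, of the remainder, 80/20
train/validation (i.e. 68/17/15 overall — the internal ratio mirrors the
pretraining split convention). Training runs a small, fixed number of
epochs (default 4, to limit overfitting); the epoch state with the lowest
validation loss is kept. Hard labels use a fixed 0.5 threshold with the
`>=` convention.

The predictor concatenates the pooled window embedding with the one-hot
risk-factor vector before the linear layer (`use_risk_factors = FALSE`
gives the text-only ablation). The encoder is fine-tuned jointly by
default; `freeze_encoder = TRUE` trains the head only on embeddings
computed once.

### Learning rates at desk scale

The configuration defaults (fine-tuning at 3e-5, pretraining at 1e-4,
batch sizes 16/32, weight decay 0.01) are the recipe appropriate to a
large pretrained encoder. The tiny test-profile encoder starts from
near-random weights, and at 3e-5 a 4-epoch run barely moves it. The
package's desk-scale protocol — used throughout the tests — is therefore
learning rate 3e-3 with batch size 8 for fine-tuning, chosen once as the
stable setting for a width-64 encoder under gradient clipping. This is a
property of model scale, not of the task.

## Risk factors and negation

Risk-factor extraction is a pluggable dictionary matcher: a catalogue CSV
of 46 factors with synonym phrases, and a negation rule — a factor mention
counts as confirmed only if no negation cue ("no", "no sign of",
"denies", "without", ...) ends within the 5 tokens immediately preceding
it in the same sentence. "no sign of cancer" therefore sets no bit, while
"no weight loss. poor appetite noted" sets only the poor-appetite bit.
The bundled catalogue is an *illustrative synthetic fixture*: any real
deployment should curate its own factor list, so the catalogue ships as
an editable CSV whose ordering is serialised with any fitted model. A richer extractor (e.g. a UMLS-linked NER system) can be
swapped in behind the same interface.

The 30-day window is half-open, `[index − 30, index)`: "before the onset"
excludes the onset day itself. For clients without malnutrition the
anchor is their latest note date; this anchoring is a modelling choice
(an onset-matched anchor is equally defensible) and is recorded as such.

## Evaluation

`kfold_cv()` performs stratified 5-fold cross-validation: stratification
is this package's choice (with ~27% positives, unstratified folds are
fragile at small n). Each fold's trainer keeps its own internal
validation split for best-epoch selection. Reported metrics — precision,
recall, F1, specificity, AUPRC, AUROC — are averaged with the arithmetic
mean, with two-sided 95% t-intervals on k − 1 degrees of freedom —
the standard k-fold summary. AUPRC is average precision (step-wise sum), not
trapezoidal interpolation, which is optimistic in PR space. AUROC is
computed by midranks and is tested to be identical to the Mann-Whitney U
statistic divided by n₊·n₋.

Model comparison uses the two-sided Mann-Whitney U test on per-fold
metric values (k = 5 per model — the package's reading of what the
samples are, flagged in the comparison report), with the exact
permutation null (midranks, so ties are handled exactly) for n ≤ 8 per
group and the tie-corrected normal approximation otherwise. Significance
requires p strictly below 0.05.

Baselines: bag-of-words counts and averaged static word vectors, both
under a ridge-regularised logistic head — deliberately the weakest
reasonable head, so comparisons reflect the representation.

## The synthetic generator

The generator emulates the conditions of the motivating clinical setting:

* **Cohort structure.** Sex is drawn with female fraction 2797/4405;
  malnutrition prevalence is 26% for females and 30% for males; ages are
  ~N(85.2, 8.9).
* **Note lengths.** Negative binomial around a 64-token mean (dispersion
  `size = 8`, a free parameter: only the mean is pinned, and real
  note lengths are overdispersed). Some windows therefore exceed 512
  tokens, exercising the chunked pathway.
* **Cadence.** Note timestamps follow a renewal process whose mean
  interval is derived as `30 × 64 / 644 ≈ 2.98` days, so a 30-day window
  averages ~644 tokens by construction; intervals are bounded (0.3–1.7 ×
  the mean) so every window holds at least five notes.
* **Signal.** Three injection channels: malnutrition-*statement* phrases
  tied to note labels (the note-identification signal), affirmative
  risk-factor phrases at a rate elevated in malnourished clients' notes
  (the prediction signal), and negated factor mentions ("no sign of X")
  at a label-independent rate. All label-text coupling is gated by
  `signal_strength`: at 0 the note distribution is identical across
  labels (tested), at 1 the keyword signal gives a known separability
  floor.

What the generator does *not* model — grammar, coreference, comorbidity
structure, documentation drift — bounds what passing tests show: they
validate the mechanisms (masking, chunked pooling, fusion, evaluation),
not clinical performance. Scores attainable on real, governed EHR
corpora cannot be reproduced from synthetic data and are not targets
here.

## Problem sizes and numerical choices

The test suite uses a fixed desk-scale protocol chosen once: 200 synthetic
clients (seed 0, full signal), a 1500-note pretraining corpus chunked at
128 tokens, 50 masked-LM steps on the tiny profile, 400 labelled notes
for the note classifier, and ~200 windows with a frozen encoder for the
predictor benchmarks (head-only training on precomputed pooled
embeddings, which is exact for a frozen encoder). Pretraining the tiny
encoder for 50 steps reliably reduces validation loss; the 5-fold smoke
chain reaches mean F1 well above 0.9 on the fully separable signal.

Numerical details: probabilities in the weighted cross-entropy are
clamped at 1e-7; softmax rows subtract their maximum; LayerNorm uses
eps = 1e-5; undefined metric ratios (zero denominators) are reported as 0
with a warning flag; ties in timestamps are broken by insertion order;
and every stochastic stage (data, splits, masking, initialisation,
dropout) draws from named substreams of one manifest seed, so identical
configurations reproduce identical artifacts bit for bit.

## Known limitations

* The tiny encoder demonstrates mechanism, not clinical accuracy; nothing
  here should be used for care decisions without fine-tuning a properly
  pretrained checkpoint on real, governed data.
* The dictionary-based negation rule covers the common clinical patterns
  but not scope-breaking constructions ("cannot rule out cancer").
* The catalogue is synthetic; with a different 46 factors the risk-vector
  semantics change while the mechanics stay identical.
* Pure-R training is practical only at the bundled scale; swapping in a
  GPU-backed encoder behind the same interfaces is the intended path to
  production scale.
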