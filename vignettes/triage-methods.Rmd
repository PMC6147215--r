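---
title: "Neural document triage: models, training and the synthetic evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural document triage: models, training and the synthetic evaluation protocol}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Curation pipelines for biomedical databases begin with *document triage*:
deciding, from title and abstract alone, whether an article is relevant to
the curation target before any expensive annotation happens.  The target
class motivating this package is articles describing protein–protein
interactions (PPI) affected by genetic mutations — a narrow class nested
inside the broader "describes a PPI" class, with only a few thousand
labeled examples available.  `triagenn` implements a complete triage stack
for this situation: five neural document classifiers, an auxiliary encoder
pre-trained on the broader class and fused into each classifier, and three
ways of combining the five models into an ensemble.

Everything is implemented from first principles in R (there is no GPU or
deep-learning framework dependency); the backward pass of every layer is
hand-derived and verified against central finite differences in the test
suite.

## Preprocessing

Titles and abstracts are split into sentences by a deterministic rule
(sentence-final punctuation followed by whitespace and an uppercase letter,
with an abbreviation guard list; the uppercase requirement keeps genus
initials like "E. coli" intact), tokenized, and lowercased.  One rule is
domain-specific and matters: biomedical text joins interacting protein
names with a dash ("Utp6–Utp21 interaction"), and a tokenizer that keeps
the pair as one token hides both names.  Every dash character
(hyphen-minus, en dash, em dash — print glyphs are unreliable, so all
three are treated alike) therefore becomes its own token:
`utp6`, `–`, `utp21`.  The title is prepended as one pseudo-sentence;
numerals and punctuation are kept.  No stemming, no stop-word removal.

## Features

Tokens map through a vocabulary with two reserved ids: PAD (0), whose
embedding is frozen at zero so padded positions are inert, and UNK (1) for
out-of-vocabulary tokens.  Word embeddings are 50-dimensional, either
loaded from a plain-text word2vec/fastText file or initialized from a
seeded uniform on [−0.05, 0.05]; they are ordinary trainable parameters.
Optional POS-tag and BIO entity-tag streams add 5-dimensional embeddings
each (input width 50, 55 or 60).  Tags are *inputs* here — real pipelines
obtain them from external taggers; the synthetic module fabricates them —
because a self-contained artifact cannot ship a tagger.

## The five document encoders

All architectures share a classification head: a dense layer and a softmax
over {negative, positive} applied to a fixed-length document vector
**D**.  They differ in how **D** is produced from the embedded token
sequence.

* **LSTM** — a single forward LSTM over the token stream, max-pooled over
  time.  The cell follows the standard gated recurrence with one
  peculiarity kept deliberately: the output gate sees the *current* cell
  state through a full peephole matrix, `o = σ(W x + U h + V c + b)`.  A
  diagonal peephole would be the other defensible reading; the full matrix
  is the literal one and is what the gradient checks verify.
* **CNN** — two consecutive convolution layers (window k = 3, shared
  affine map, ReLU), max-pool, a tanh dense layer, softmax.  Convolutions
  use symmetric zero padding so every sequence yields one output per
  position; outputs at padded centres are zeroed so stacking convolutions
  preserves padding invariance.
* **LSTM-CNN** — BiLSTM (forward and backward encoders with separate
  parameters, concatenated per position), elementwise tanh, one
  convolution layer, max-pool, tanh dense layer, softmax.
* **RCNN** — per-position left context `c_l(t) = h_fwd(t−1)` and right
  context `c_r(t) = h_bwd(t+1)` from two LSTMs; the word representation is
  the concatenation `[c_l; x; c_r]` passed through tanh *directly* (no
  extra projection — the source description applies the activation to the
  concatenation itself), then max-pooled.
* **HieLSTM** — hierarchical: a shared unidirectional word-level LSTM
  max-pooled per sentence gives sentence vectors; a sentence-level BiLSTM
  encodes those; the document vector is the BiLSTM output *at the last
  valid time step*, i.e. `[h_fwd(S); h_bwd(S)]`.  Note the literal reading:
  the backward state at step S has read only the last sentence.  Using
  `h_bwd(1)` instead would summarize the whole reversed sequence; we keep
  the literal form and note it as a known modeling quirk.

Non-hierarchical models consume the sentences concatenated into one token
stream.  Padded batches are masked everywhere: states at padded positions
are forced to zero, pooling ignores them, and the test suite asserts that
a document's output is identical whether it is padded or not.

## The auxiliary pre-trained module

The target class is data-poor, but the broader PPI class has much larger
labeled corpora, and the class relationship is directional: an article
irrelevant to PPI is certainly irrelevant to mutation-affected PPI.  The
package exploits this with an attention-based BiLSTM trained on the
auxiliary corpus (word features only): BiLSTM, attention pooling
(`u_i = tanh(w·h_i + b)`, weights `α = softmax(u)`, `v = Σ α_i h_i`), two
tanh dense layers, softmax.  After training, the classification layer is
stripped; what remains maps any document to an auxiliary representation
`D_aux`.

A target model then classifies from the concatenation `[D_target; D_aux]`.
Two fusion modes: **static** freezes every auxiliary parameter (it is
excluded from the optimizer's update set; activations still flow), and
**tuned** fine-tunes the whole auxiliary module on the target task.

## Training

Mean categorical cross-entropy, minimized with RMSprop (lr 0.002, decay
0.9) for all models except the CNN, which uses Adadelta (lr 1.0, ρ 0.95) —
the optimizer split mirrors the original setup.  Batch size 32, global
gradient-norm clipping at 5, no dropout by default.  After each epoch the
positive-class F1 on a held-out development split (conventionally 10%,
sizes rounded half-up) is recorded; training stops once the best epoch
lies `patience` epochs back, and the best epoch's parameters are returned.
Hidden sizes default to 64 (per direction), 64 convolution filters, dense
width 32; the original study tuned these by random search against its
development set, which is out of scope here — they are explicit
configuration instead.  A single seed drives initialization, the
development split and the shuffling order, making prediction files
byte-identical across reruns.  Adadelta's self-tuning step sizes start
tiny, so the CNN typically needs most of its 10-epoch budget where the
RMSprop models converge in 3–5 epochs; that is expected behavior, not a
defect.

## Ensembles

Three combiners over the five models' outputs:

* **Majority vote**, ties to the negative class (triage prefers missing a
  paper over flooding curators — and the tie rule is fixed by the source).
* **Weighted majority vote** with weights found by exhaustive search over
  the simplex quantized at 0.1 (weights generated as integer tenths and
  divided once, so Σw = 1 is exact; 1001 candidates for five models).
  F1 ties break to the lexicographically smallest tuple.  A consequence
  worth knowing: when one model is perfect on the development set, every
  vector giving it more weight than all others combined is optimal, and
  the lex-smallest winner concentrates *just enough* weight (e.g.
  (0, 0, 0.6, 0, 0.4)), not all of it.
* **Logistic-regression stacking** over the 2N per-model class
  probabilities (p_neg, p_pos per model, fixed order).  The model has no
  intercept — each model's two features already sum to one — and carries a
  small ridge penalty (1e-4) because the unpenalized likelihood diverges
  on separable stacking features; it is fitted by Newton iterations.  The
  stacker and the weight search both use the development split.

## Evaluation

Precision, recall and F1 on the positive class, reported as percentages
rounded half-up to two decimals, with 0/0 defined as 0.  Paired models are
compared with McNemar's test on the discordant-pair counts (b, c):
continuity-corrected statistic `(|b−c|−1)²/(b+c)`, chi-square p-value with
1 df, switching to the exact two-sided binomial p below 25 discordant
pairs (desk-scale runs are small; the exact form is always valid there).

## The synthetic world

Real triage corpora cannot ship with the package, so every stage is
exercised against a generator that emulates the *data situation*, not the
language: a class-conditional token mixture in which positive documents
carry positive-indicator keywords at a per-token `signal_rate`, negatives
symmetrically, with optional cross-class leakage (`noise_rate`) — the
error analysis of the motivating study attributes triage signal almost
entirely to such lexical indicators.  Documents are short toy abstracts
(2–4 sentences of 4–9 tokens plus a 3–6 token title, positive prior 0.5,
vocabulary 200 with 8 + 8 signal keywords); occasional dash-joined protein
pairs exercise the tokenizer and give the synthetic NER tagger gene spans
(`B-gene`, dash `O`, `B-gene`).  An auxiliary corpus shares a configurable
fraction of the target's positive-signal vocabulary (default 0.8), and its
negative documents never contain target signal, encoding the directional
class relationship above.

Default rates (`signal_rate` 0.25, `noise_rate` 0) give an essentially
separable world: the end-to-end acceptance check trains all five
architectures on 2000 documents and requires test F1 ≥ 0.9 within ten
epochs.  The transfer acceptance check instead needs a *hard* low-resource
target or pre-training has nothing to add; it uses `signal_rate` 0.12 and
`noise_rate` 0.05 with 200 target documents against a 2000-document
auxiliary corpus (overlap 0.8), and asserts the mean-over-five-seeds
ordering tuned ≥ static ≥ plain − 0.02.  These rates were fixed once, on
the grounds that a realistic scarce-signal triage problem should leave the
plain model well below ceiling; they are not tuned quantities.  The
transfer check runs at the default model capacity (hidden 64): at reduced
capacity the fine-tuned auxiliary module can destabilize on 180 target
documents, which is a capacity artifact rather than a property of the
transfer mechanism.

A green synthetic suite establishes that the machinery — gradients,
masking, early stopping, fusion, combiners — behaves as specified on data
whose structure matches the triage problem's lexical-signal hypothesis.
It does not establish performance on real abstracts: the generator has no
syntax, no discourse, no tagger errors beyond uniform leakage, and its
vocabulary is tiny.  Published dataset-level scores are therefore *not*
reproduced here; the one exactly-reproducible number (the best ensemble's
confusion-matrix arithmetic: precision 62.94, recall 81.53, F1 71.04) is
asserted in the acceptance suite.

## Numerical choices and degenerate inputs

* Softmax and attention weights are computed with max-subtraction;
  cross-entropy clamps probabilities at 1e-12.
* Argmax decisions break exact ties toward the negative class, matching
  the ensemble tie rule.
* Max pooling or attention over an all-masked sequence, empty documents,
  zero-sentence hierarchical input, degenerate train/dev splits, unlabeled
  training documents and all-one-class stacker labels are errors, not
  silent results.
* Finite-difference gradient checks tolerate 1e-3 relative error — ReLU
  kinks make central differences locally inexact — which is still three
  orders of magnitude below any real gradient defect observed during
  development.

## Known limitations

* Only binary labels; no multi-class head.
* The hierarchical model's document vector uses the literal last-time-step
  BiLSTM output (see above).
* POS/NER tags must be supplied; no tagger is bundled.
* Training is CPU-bound, single-threaded R; fine for 10³–10⁴ short
  documents, not for full-scale literature corpora.
* Checkpoints use R serialization (RDS); they are bit-exact across
  sessions but not a cross-language format.
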