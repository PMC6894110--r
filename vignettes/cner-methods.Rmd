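---
title: "Character-level clinical NER with a BiLSTM-attention-CRF tagger: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Character-level clinical NER with a BiLSTM-attention-CRF tagger: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cner)
```

## The problem

Clinical named entity recognition (CNER) extracts typed spans — anatomical
parts, symptom descriptions, independent symptoms, drugs, operations — from
free-text electronic medical records. Chinese clinical text has no word
boundaries, and word segmenters make boundary errors precisely on the
nested clinical terms that matter (an anatomy term embedded in an operation
term), so this package works **character by character**: every character of
a clause receives one BIESO tag (`B-t`/`I-t`/`E-t`/`S-t` for a span of type
`t`, `O` outside), and spans are recovered from the tag sequence.

Mentions are addressed by **0-based character offsets with an inclusive
end**. This convention is fixed by the worked annotation example the
package tests against: in
`患者1个月前无明显诱因出现上腹部不适`, the anatomy span `上腹部` sits at
(13, 15) and the symptom `不适` at (16, 17). All functions use this
convention; `parse_annotations()` refuses any tuple whose text slice does
not equal its surface.

Records are split into clauses before tagging, because clinical semantics
in this genre is clause-local: `"short"` mode splits on commas and periods
(both full-width `，。` and ASCII `,.`; no other punctuation), `"long"`
mode on periods only. Delimiters are recorded so the record reconstructs
exactly, and mention offsets are remapped per clause. A mention spanning a
clause boundary is an error by default; a per-record fallback to long mode
is available, since a minority of real annotations do relate material
across commas. Clauses beyond the 150-character time-step budget are
hard-truncated with a warning (the corpus statistics the generator follows
put average clause length near 15, so this is a tail event); mentions past
the cut are dropped, also with a warning.

## The network

Each character is looked up in a 200-dimensional embedding table
(optionally pre-trained vectors loaded from a text file; characters below a
frequency cutoff map to `<UNK>`, and the `<PAD>` row is frozen at zero).
Two optional 100-dimensional feature embeddings are concatenated to it:

* **Dictionary feature.** Bi-directional maximum matching against term
  dictionaries (anatomy / drug / operation): a greedy scan from each end
  takes the longest dictionary term at each position; the two match sets
  are merged with a deterministic conflict cascade — longer match wins,
  then the forward-scan match, then the leftmost, then the dictionary
  earlier in the configured precedence order. Surviving matches are encoded
  per character as `B/I/E/S-<dictionary name>`, else `O`. One tag per
  character is enforced. The cascade is our design: only "longest match"
  is inherent to the method, and the remaining ties need a deterministic
  rule for reproducibility.
* **POS feature.** A pluggable word-level tagger (any function returning a
  `(word, tag)` segmentation covering the text) is broadcast to
  characters; with no tagger every character gets `NONE`. No segmenter is
  bundled — that would pin a language-specific dependency — but a
  deterministic toy tagger ships for exercising the pathway in tests.

The concatenation feeds a bidirectional LSTM with 300 hidden units per
direction; forward and backward states are concatenated to
\(h_t \in \mathbb{R}^{600}\). On top sits a **windowed additive attention**
layer computed per clause:

\[
e_{tj} = \tanh\!\big(w_a^\top [x_t ; x_j]\big), \qquad
\alpha_{tj} = \frac{\exp e_{tj}}{\sum_k \exp e_{tk}}, \qquad
c_t = \sum_j \alpha_{tj} h_j, \qquad
z_t = \tanh\!\big(W_z [c_t ; h_t]\big).
\]

Two reading choices here were genuinely open and are both supported:

* **Alignment source.** The alignment score is written over the inputs
  \(x_t, x_j\) while the context sums the encoder outputs \(h_j\). The
  default follows that literally (`alignment_source = "inputs"`);
  `"hidden"` aligns over encoder states instead, the more common variant.
* **Scalar scores.** \(w_a\) maps the concatenation to a scalar (a
  \(1 \times 2d\) map before the tanh); the row softmax requires scalar
  scores, so a matrix-valued alignment is not meaningful here.

The **attention width** \(r\) confines position \(t\) to the window
\(|t-j| \le r\) — \(2r+1\) positions including the center. Off-window and
padded positions get score \(-\infty\) before the softmax and therefore
weight exactly zero; any \(r \ge n-1\) is bit-for-bit identical to the
unwindowed model. `width_experiment()` trains one model per (width, split
mode) combination under a shared seed and tabulates strict F1, the harness
for studying how much context the tagger actually needs.

A dense layer maps \(z_t\) to one emission score per tag. The layer as
printed in the source architecture applies a final tanh, bounding emissions
to \((-1, 1)\). We implement both but default to the **linear** scoring
layer, for a reason worth recording: with tanh emissions and a heavily
imbalanced tag distribution (roughly half of all characters are `O`), early
training drives the `O` score to \(+1\) and all rare entity tags to
\(-1\); the tanh derivative \(1 - s^2\) then vanishes exactly where
learning is still needed, and at small-corpus scale the model never escapes
the all-`O` solution. The linear dense layer is the standard choice for
CRF emissions and has no such trap; `emission_activation = "tanh"` restores
the bounded variant.

The attention output size \(d_z\) is not pinned by the architecture
description; we project the 1200-dimensional concatenation \([c_t; h_t]\)
back to 300 dimensions (the encoder width per direction) by default
(`d_attn`).

## The CRF layer

Tagging decisions are decoded jointly by a linear-chain CRF. With emission
matrix \(P\) (one row per character) and transition matrix \(T\) over the
tag set extended by `START`/`STOP` boundary states, a path \(Y\) scores

\[
S(X, Y) = \sum_{i=0}^{n} T_{y_i, y_{i+1}} + \sum_{i=1}^{n} P_{i, y_i},
\]

where the \(i = 0\) and \(i = n\) transition terms are the `START` and
`STOP` boundaries — the reading that makes the distribution over
variable-length paths well defined. Training maximizes
\(\log P(Y \mid X) = S(X, Y) - \log \sum_{y'} e^{S(X, y')}\); the
normalizer runs through the forward recursion **entirely in log space**
(no probability-space fallback: 150-step sequences would underflow), and
inference is Viterbi with deterministic lowest-index tie-breaking so runs
are reproducible. Transitions are **learned unconstrained by default**; an
opt-in structural mask (`constrained_transitions()`) forbids BIESO-invalid
bigrams (`O → I-t`, `B-t → B-u`, `E-t → I-u`, cross-type `B-t → E-u`, …)
and guarantees every decoded path is well formed. Without the mask, raw
Viterbi output is repaired conservatively at decode time: only maximal
well-formed spans are kept, malformed stretches yield no mentions.

Both the forward scores and the Viterbi maximum are checked in the test
suite against exhaustive enumeration of all \(k^n\) paths on small random
instances, and the analytic gradients of the loss (for emissions and
transitions, and through the whole network by finite differences) are
verified the same way.

## Training

The trainer uses the standard schedule for this architecture: at most 30
epochs, batch size 32, Adam with learning rate 0.001 and default moment
parameters (only the learning rate is prescribed; the moments are the
optimizer's defaults), dropout 0.2 applied to the embedding concatenation
and the encoder output (training only — where to apply it is unstated, so
we chose the two standard sites), and a 150-character sequence budget.
Weights are Glorot-uniform from a configured seed; the LSTM forget-gate
bias starts at 1 (remember by default), a common stabilization. There is
no early stopping — the epoch budget is fixed — but when a dev set is
supplied the weights of the best dev-F1 epoch are retained, which changes
nothing about the schedule itself.

Batches are packed with explicit padding masks. Padded positions are
zeroed inside the LSTM, excluded from attention entirely, and never reach
the CRF, so a sentence produces the same emissions alone or inside any
batch; with a fixed seed the initialization, shuffling order and dropout
masks — hence the entire loss curve — are bitwise reproducible on one CPU
thread. A non-finite loss aborts with diagnostics rather than continuing.

Evaluation is **strict**: a prediction counts only when start, end and
type all equal a gold mention, compared at record level after clause
predictions are mapped back through their record offsets. Each gold
mention is consumed by at most one prediction; a duplicate exact match is
a false positive (the strictest consistent reading of the metric).
Precision, recall and F1 use the zero-division-is-zero convention, and
micro counts are sums of per-type counts.

## The synthetic corpus generator

The real clinical corpora this family of models is evaluated on are
license-restricted, so the package ships a generator (`gen_corpus()`)
whose **defaults are the study conditions**, and every artifact is a pure
function of `(spec, seed)`:

* five entity types with the standard clinical proportions — anatomical
  part 0.52, symptom description 0.14, independent symptom 0.20, drug
  0.07, operation 0.07 — checked empirically to ±3 points at 500+
  mentions;
* comma-delimited clauses with truncated log-normal lengths (mean ≈ 15
  characters, capped at 176; the real-data summary gives only the mean and
  maximum, so the log-normal shape is our choice for a right-skewed
  length law);
* keyword cues around operation entities: with probability 0.9 an
  operation surface ends in a designated suffix character and is preceded
  by a prefix cue, emulating the fixed "undergo …surgery" pattern around
  real operation mentions;
* nested-term ambiguity: some anatomy surfaces are proper prefixes of
  operation surfaces, the boundary ambiguity that motivates joint
  decoding;
* feature dictionaries covering 70% of the relevant entity vocabulary
  plus 20% distractor terms, so the dictionary feature is informative but
  not an oracle;
* a train/test record split (60/40) in which test-split mentions draw
  from held-out out-of-vocabulary surfaces at rate 0.2, emulating the
  unseen-mention difficulty real systems show on drug names.

Entity and filler characters come from disjoint CJK code-point pools and
carry **no linguistic meaning**. That makes the mapping from character to
entity type far easier than in real clinical text: passing tests show the
pipeline and optimization are correct and that the model can exploit
contextual cues, not that real-corpus F1 would reach any particular level.
Real EMR phenomena the generator does not emulate include inconsistent
gold labeling, abbreviation/alias variation within a document,
alphanumeric lab strings inside entities, and semantic dependencies that
cross clause boundaries.

## Problem sizes and numerical choices

The test suite and the acceptance script work at desk scale, chosen so the
whole suite trains several full-size models in minutes: CRF oracles are
checked on 200 random instances with \(n \le 6\), \(k \le 4\) against full
path enumeration (1e-6); the BIESO round-trip runs on 1000 generated
clauses; maximum matching is compared with an all-substrings oracle on 500
random instances; and the learning-capacity check trains the full
configuration (300 hidden units, 200-dim embeddings, 30 epochs, batch 32)
on a 200-clause corpus over three seeds, requiring mean training-set
strict F1 ≥ 0.95. Attention row sums are verified to 1e-6; checkpoint
round-trips to 1e-6; forward batch-invariance to 1e-6.

Other conventions: softmax rows are computed with max-shifting; a fully
masked attention row is an error rather than a NaN; `<PAD>` embeddings are
frozen at zero and excluded from gradients; JSON checkpoints store weights
at full precision and reload to identical forward outputs up to
floating-point round-off. A POS tagger, being a function, does not
serialize — it is re-supplied at load time.

## Known limitations

* No subword/stroke-level representations and no transformer variants;
  the encoder is exactly the BiLSTM-attention stack described above.
* Nested or overlapping gold entities are rejected at parse time; the tag
  scheme cannot express them.
* Attention is strictly clause-level in short mode, so cross-clause cues
  are invisible by construction — the motivation for the width/mode
  experiment harness rather than a limitation it hides.
* The pure-R training loop is sized for research corpora (thousands of
  clauses), not production-scale pretraining.
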