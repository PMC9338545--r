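---
title: "Soft-lattice Transformer-CRF tagging: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-lattice Transformer-CRF tagging: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softlattice)
```

## The problem

Clinical named entity recognition (CNER) in Chinese extracts mentions of
diseases, drugs, tests, treatments, imaging findings and anatomical sites
from electronic health records. Chinese has no word boundaries, clinical
terms are long (frequently more than six characters), and records mix
Chinese terminology with Latin-letter abbreviations and numerals. A
character-level tagger avoids segmentation errors but throws away word
information; a word-level tagger propagates whatever mistakes the segmenter
makes. The word-character *lattice* keeps both: every character of the
sentence plus dictionary-matched word spans, each span carrying its head
and tail character indices.

This package implements a *soft* lattice: rather than adding every
dictionary match, alternative segmentations of the sentence are scored, a
single segmentation is selected, and only its multi-character spans join
the character sequence. The flat token sequence (characters first, then
word spans) is encoded by stacked self-attention layers whose attention
biases come from relative span positions, and a linear-chain CRF decodes
per-character BIO tags.

## Lexicon induction and the TF-CR score

The subword lexicon is induced from raw (unannotated) records by byte-pair
encoding: starting from single characters, the most frequent adjacent
symbol pair is merged iteratively until the vocabulary reaches a target
size `D` or no pair repeats. Pair-frequency ties are broken by
lexicographic order of the pair, making induction fully deterministic.
Merging stops below pair frequency 2 because a merge seen once cannot
generalize. The target size is a free parameter; the package default is
the alphabet plus 3000 merges, and the synthetic-corpus experiments use
the alphabet plus a few hundred merges, matched to corpus size.

From a BIO-annotated corpus, each lexicon subword receives per-category
occurrence statistics: an occurrence counts toward category $c$ when the
subword's character span lies entirely inside a single gold entity of
category $c$. A segmentation layer (a tiling of the sentence by subwords)
is scored by

$$ f(\mathrm{TF},\mathrm{CR}) \;=\; \sum_{i=1}^{L} \mathrm{TF}_i \times \mathrm{CR}_i,
\qquad
\mathrm{TF}_i = \frac{|x^i_{c^*}|}{N_{c^*}}, \quad
\mathrm{CR}_i = \frac{|x^i_{c^*}|}{x^i}, $$

where $x^i_{c^*}$ is the count of span $i$'s subword inside entities of its
dominant category $c^*$ (the argmax over per-category counts, ties to the
lexicographically first category), $N_{c^*}$ is the total number of subword
tokens inside category-$c^*$ entities, and $x^i$ is the subword's total
in-entity count. A note on the TF denominator: reading $N_c^i$ as "the
count of subword $i$ in category $c$" would make TF identically one and the
score collapse to CR alone, so the term-frequency denominator is taken
over *all* subword tokens of the category, giving a genuine within-category
term frequency. Spans never seen inside an entity contribute zero, which
also guards every division.

Candidate layers are built by greedy longest-match tiling under a
granularity cap: layer $g$ may only use subwords up to
$\lceil n/g \rceil$ characters, so early layers admit whole-sentence
spans and later layers approach the character tiling; duplicate tilings
are dropped. Selection takes the layer with the largest score (softmax
over layer scores preserves the argmax); score ties go to the finest
granularity, which is the conservative choice — shorter spans claim less.
Only the winning layer contributes word tokens: the sentence text supports
hard selection ("the result with the largest score"), and a soft mixture
of layers would reintroduce exactly the all-matches clutter the mechanism
is meant to remove.

## The lattice encoder

Characters and selected word spans form one flat token sequence; token
$k \le n$ is the $k$-th character with head = tail = $k$, and each word
token carries its span $(b, e)$ with length $d_{b,e} = e - b$. Every
ordered token pair $(i, j)$ gets a relative position code: the four
distances $b_i - b_j$, $b_i - e_j$, $e_i - b_j$, $e_i - e_j$ are each
sinusoid-encoded,

$$ P_d^{(2k)} = \sin\!\big(d / 10000^{2k/d_\mathrm{model}}\big), \qquad
   P_d^{(2k+1)} = \cos\!\big(d / 10000^{2k/d_\mathrm{model}}\big), $$

concatenated, projected by a learned $W_r$ and passed through ReLU:
$R_{ij} = \mathrm{ReLU}(W_r P_{ij})$. A single span-length code (using
only $e_j - b_j$) cannot distinguish token pairs — two characters at
different offsets would share one code — so the four-distance construction
is the default; `position_mode = "span_length"` retains the degenerate
variant for ablation.

Attention scores combine content and position in four terms per head:

$$ A_{ij} = E_i^\top W_q^\top W_{k,E}\, E_j
          + E_i^\top W_q^\top W_{k,R}\, R_{ij}
          + u^\top W_{k,E}\, E_j
          + v^\top W_{k,R}\, R_{ij}, $$

scaled by $1/\sqrt{d_\mathrm{head}}$ before the row softmax (unscaled
logits grow with width and saturate the softmax). Each layer applies
multi-head attention with a value projection, a residual connection and
layer normalization, then a position-wise feed-forward block (inner width
$2 d_\mathrm{model}$, ReLU) with a second residual and normalization.
Dropout (default 0.1) acts on attention weights and on each sublayer
output, only during training. A learned linear map over the first $n$
rows produces the $n \times |\mathcal{T}|$ emission matrix: word tokens
inform the characters through attention but are never tagged themselves.

Embeddings are looked up by surface string for characters and words alike,
initialized uniform $(-0.1, 0.1)$ from the configured seed, or seeded from
an external text embedding table; when the table width differs from
$d_\mathrm{model}$, a learned input projection bridges the two. No
pretrained language model is involved anywhere: the encoder trains from
random initialization.

The forward pass and its analytic backward pass are written in base R
matrix algebra; the backward pass is verified against central finite
differences for every parameter tensor in the test suite (relative error
below $10^{-4}$ at perturbation $10^{-5}$).

## The CRF layer

Emissions $p_{i,y_i}$ and a learned transition matrix $A$ over the 13 BIO
tags plus explicit START and END states give the sequence score

$$ \mathrm{score}(x, y) = \sum_{i=1}^{n} p_{i, y_i}
   + \sum_{i=0}^{n} A_{y_i, y_{i+1}}, $$

with $y_0 = \mathrm{START}$, $y_{n+1} = \mathrm{END}$. The partition
function is computed exactly by the forward recursion in log space
(log-sum-exp at every step), decoding by Viterbi with ties resolved toward
the smallest tag index, and training minimizes the negative log-likelihood
$\log Z - \mathrm{score}(x, y^\mathrm{gold})$. Transitions are treated as
unnormalized scores, the standard neural-CRF reading — row-normalizing
them would forfeit the global normalization that makes the model a CRF
rather than an MEMM. Illegal BIO transitions (such as `O -> I-X`) are not
masked by default — the CRF learns tag constraints from data — but
`bio_mask = TRUE` sets them to $-\infty$ for strictly legal decoding.

## Training recipe

`sl_config()` defaults follow the published recipe: SGD at initial
learning rate 6e-4, 100 epochs, batch size 10, early-stop patience 25,
dropout 0.1, one encoder layer of width 512 with 8 heads, learning rate
linearly warmed up and then linearly decayed to zero. A 50k-step warmup
only makes sense at corpus scale, so `warmup_steps = NULL` resolves to
`min(50000, 10%)` of the total step count. When no dev set is supplied the
last 10% of the training sentences are held out, mirroring the usual
90/10 convention. Batches group sentences of similar length; within a
batch, gradients are accumulated per sentence and averaged, which is
mathematically identical to masked padded batching for a summed loss and
avoids padding entirely. Optional momentum and global-norm gradient
clipping (default 5) are available; training aborts with a diagnostic on a
non-finite loss. Dev strict-F1 is evaluated every epoch; the best-dev
checkpoint is restored at the end (the final-epoch parameters are also
kept, which is what a capacity check wants).

The desk-scale experiments in the tests and the acceptance script use an
intentionally small model — $d_\mathrm{model}$ 64, one layer, 4 heads —
and a learning rate of 0.2: plain SGD on a freshly initialized network of
this width needs a far larger step size than a fine-tuned 512-wide model,
and 0.2 with gradient clipping at 5 converges smoothly on corpora of one
to two hundred sentences within 15–30 epochs. These overrides are explicit
in every call; the package defaults remain the published recipe.

## The synthetic corpus generator

The clinical datasets the method targets are access-restricted, so the
package carries a seeded generator that emulates their statistical
structure: a gazetteer of unique multi-character terms in six categories
(disease, image_review, test, treatment, drug, anatomy), with
configurable fractions of long terms (more than six characters) and of
terms carrying ASCII letters/digits (abbreviations and numbers);
sentences interleave filler character runs with gazetteer terms sampled
with Zipf-like skew (exponent 1.2) so term frequencies — and hence TF-CR
scores — are non-degenerate; BIO tags mark exactly the injected terms;
sentences end with a full stop and concatenate into records that invert
exactly under `split_sentences()`. Characters are drawn from CJK code
points; the method never inspects character identity, so no real clinical
vocabulary is needed. By default the filler alphabet is disjoint from the
term alphabet, which guarantees zero spurious gazetteer matches; the
boundary experiment below deliberately overrides this.

What the generator does *not* emulate: real orthographic and semantic
regularities among terms of one category, negation and speculation,
nested or discontinuous entities, annotation noise, and natural sentence
grammar. Passing tests on this corpus therefore demonstrate that the
machinery — lexicon, lattice, encoder, CRF, evaluation — is correct and
trainable, not that the model reaches any particular accuracy on real
clinical text.

## The boundary-information experiment

To probe whether lattice word spans carry boundary information the model
can use, `boundary_experiment()` trains the same small model on corpora
whose *lexicon-building* text retains a proportion $p \in \{0, 0.5, 1\}$
of the gazetteer terms (the annotated corpus is untouched; only what BPE
can learn changes, so lattice word coverage of gold entity spans scales
with $p$). Its one deliberate departure from the generator defaults is
`filler_mode = "term_fragments"`: filler runs are stitched from short
substrings of the gazetteer terms, so non-entity text is locally
indistinguishable from entity text. With the default disjoint filler
alphabet a character-only model reads entity boundaries straight off the
alphabet switch and word spans are redundant; boundary information can
only matter when boundaries are ambiguous. The suite checks that mean
test F1 over three training seeds is non-decreasing in $p$; absolute F1
values are irrelevant, only the trend.

A candid caveat on expected effect size: in this package the embedding
table is randomly initialized, and on corpora of a few hundred sentences
the character path can memorize the training data before attention learns
to exploit word spans, so the word channel's marginal contribution is
small. The large boundary-information effects reported for lattice models
in the literature are obtained on top of pretrained representations,
which are out of scope here. The experiment is therefore a qualitative
probe under fixed, pre-registered conditions, not a reproduction of any
published curve.

## Numerical choices and degenerate inputs

* Log-sum-exp guards every forward-algorithm step; $-\infty$ transitions
  (masked or structural) propagate correctly and receive zero gradient.
* Layer normalization uses population variance with $\varepsilon = 10^{-5}$.
* Xavier-uniform initialization for weight matrices; zeros for biases and
  the attention offsets $u$, $v$; layer-norm gain 1.
* Empty sentences are rejected by the lattice builder and skipped by
  `predict()`; unknown characters tokenize as single-character subwords
  and embed as `<unk>`.
* BPE pair ties and dominant-category ties are resolved lexicographically;
  layer-score ties by finest granularity; Viterbi ties toward the smallest
  tag index — every tie-break is deterministic, and all randomness
  (initialization, shuffling, dropout, generation) flows from explicit
  seeds, so every stage is bit-reproducible.

## Known limitations

* Pure-R training is practical at desk scale (hundreds of sentences,
  width 64) but not at the 512-wide, multi-thousand-record scale of the
  original recipe.
* Only the winning segmentation layer contributes word spans; a term
  missed by every layer (e.g. not in the lexicon) leaves its characters
  without word support.
* The CRF is first-order; no semi-Markov or higher-order structure.
* `evaluate_strict()` implements strict span-and-category matching as
  defined here; the "official" matching script of the shared tasks is not
  public, so minor divergences are possible.
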