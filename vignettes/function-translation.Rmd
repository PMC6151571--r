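---
title: "Predicting protein function by translating sequence words into GO code words"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein function by translating sequence words into GO code words}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seq2go)
```

## The idea

Protein function prediction assigns Gene Ontology (GO) terms to an amino-acid
sequence. `seq2go` treats this multi-label problem as *machine translation*
between two constructed languages:

* **the sequence side** — each protein becomes a sentence of "words": k-mers
  (k in 3..5 by default) that are frequent across the training corpus, plus
  *fallback words*, maximal runs of residues that match no frequent k-mer;
* **the function side** — each GO term becomes a short code word: the term's
  position in a deterministic post-order depth-first traversal of the
  ontology graph, written in base 26 with letters A–Z. Four letters cover
  26^4 = 456,976 terms, more than the ontology contains, and nearby terms in
  the graph receive nearby ordinals, so the code embeds a little of the graph
  structure into the token itself.

A recurrent encoder–decoder network with additive attention is then trained
to translate word sentences into code-word sentences; decoding a new protein
yields scored GO terms. Around that core the package provides a
descendant-expanded model variant for proteins with many functions, a
weighted combination of the two translators, a noisy-OR probabilistic
baseline, and propagation-based evaluation.

## Encoding the ontology

`parse_obo()` reads OBO 1.2, keeping non-obsolete terms and treating `is_a`
and `part_of` identically as parent edges; other relationship types carry no
parent semantics here. Each namespace must have exactly one parentless term,
its root.

`dfs_postorder()` fixes the ordinal numbering. Three choices were genuinely
open and are resolved as follows:

* **post-order, not pre-order** — the root of a namespace must be the *last*
  node of its block to receive a number, which matches the worked example in
  which the Biological Process root of a 28,678-term tree receives ordinal
  28,678 (code word `BQKZ`);
* **continuous numbering across namespaces** in the fixed order biological
  process, cellular component, molecular function — restarting per namespace
  would give different terms the same code word;
* **children are expanded in ascending term-id order**, which makes the
  traversal (and hence every code word) reproducible; any fixed order
  preserves the root-last property but permutes interior ordinals.

```{r}
decode_alphabet("BQKZ")
encode_ordinal(c(1, 26, 27, 28678))
```

## Tokenizing sequences

`count_kmers()` counts every overlapping window of each k; a k-mer enters the
core vocabulary iff its corpus count is *strictly greater* than `min_freq`
(default 1000 at corpus scale; desk-scale examples use smaller thresholds
scaled to their corpus size). `segment()` scans left to right, trying the
longest core word first at each position; residues that match nothing
accumulate into a single fallback word. Two properties are worth stating
explicitly:

* segmentation is a *lossless cover*: concatenating the tokens reproduces the
  sequence byte for byte;
* fallback words are recorded in the vocabulary (they are real tokens of the
  sequence language) but never participate in matching, so segmentation does
  not depend on the order in which the corpus was processed.

Nonstandard residue letters (B, J, O, U, X, Z) pass through unmapped and,
being rare, end up inside fallback runs.

## The translation model

`nmt_train()` trains an encoder–decoder GRU (three layers per side by
default) with additive alignment attention; the output layer reads both the
decoder state and the attention context, as in the attention mechanism the
architecture follows. All forward and backward passes are plain R matrix
code; the analytic gradients are verified against central finite differences
in the test suite, which is the package's substitute for trusting a
framework's autograd.

Sentence pairs are padded into *buckets* — `(source capacity, target
capacity)` pairs. A pair uses the first bucket that fits both lengths; a pair
exceeding the largest bucket is truncated to it. The standard set is
`[(64,3), (109,4), (164,6), (300,10)]` (so at most ten functions are
predicted per protein) and the extended set `[(64,25), (164,50), (250,60)]`
accommodates descendant-expanded targets of up to sixty code words.

Training choices, all recorded in `seq2seq_config()` and in the returned
trace rather than presented as "the" canonical values, since the original
recipe leaves them open: GRU cells (the config accepts only `"gru"`; an LSTM
option was considered and deliberately not implemented, to keep the
hand-verified backward pass small), plain SGD with gradient-norm clipping at
5, initial learning rate 0.5 in (0, 1], multiplied by 0.99 whenever training
perplexity fails to improve at an evaluation, evaluation every 200 steps,
sampled softmax (512 samples) only when the target vocabulary is larger than
the sample count, and full softmax always at evaluation. The checkpoint with
the best mean per-bucket test perplexity is the model returned.

Greedy decoding emits tokens until `<eos>` or the bucket's target capacity;
each token's score is its softmax probability at its step, and duplicate
tokens keep the higher score. Beam search is not implemented: the method's
known weakness is the *ranking* of its outputs, which a wider beam does not
repair, and greedy decoding keeps the scores interpretable.

## Extended model, combination, baseline

For proteins with more than ten functions the extended model rewrites each
training annotation as the terms plus **all their descendants**
(`extend_terms()`); at prediction time `expand_with_descendants()` gives a
descendant at edge distance $k$ below an original term with score $s_0$ the
score $s_0 r^k$. The decay rate $r$ defaults to 0.8 — the original
description says only that scores *decrease* with distance, so the value is a
package choice, configurable, and applied both when building extended
training targets (where scores are ignored) and when post-processing
predictions (where they are not).

`combine_predictions()` merges the two translators per (protein, term) as
$\max(w_\mathrm{nmt} s_\mathrm{nmt}, w_\mathrm{ext} s_\mathrm{ext})$, with
weights proportional to each model's area under the top-n precision–recall
curve on data with known truth (`calibrate_weights()`). A weighted maximum
rather than a sum keeps combined scores within (0, 1] without clipping;
deduplication by maximum was likewise an open choice.

The baseline scores term $y$ for a sentence $x_1,\dots,x_n$ by noisy-OR:

$$P(y \mid x_1,\dots,x_n) = 1 - \prod_{i=1}^{n} (1 - P(y \mid x_i)),$$

where $P(y\mid x)$ is fitted by counting, over training proteins, how often a
protein whose sentence contains $x$ is annotated with $y$. A word counts once
per protein at *fit* time (document frequency), but every token occurrence
contributes a factor at *prediction* time, because $n$ is defined as the
number of fragments of the sentence.

## Evaluation

All metrics first **propagate** term sets to the namespace root
(`propagate()`: the union of reflexive ancestor closures). A propagated
predicted term is correct iff it lies in the propagated truth. Precision
divides by the *propagated* prediction set (the propagated-versus-raw choice
is not recoverable from the method description; propagated is the default
and the raw variant is one line away), recall by the propagated truth;
macro-averaging over proteins skips zero-prediction proteins in the
precision mean while counting them as recall zero. `go_pair_similarity()` is
the shared-closure fraction
$|A \cap B| / \max(|A|, |B|)$ of two terms' closures, `average_similarity()`
averages it over predicted–true pairs under top-n or threshold selection,
and `pr_auc()` integrates precision over the observed recall range by the
trapezoid rule, without extrapolation.

## Synthetic data: what it emulates and what it does not

`simulate_dag()` grows, per namespace, a rooted random DAG (each new term
attaches to 1..`max_parents` earlier terms) and emits it as OBO text.
`simulate_corpus()` assigns each *leaf* term a distinct motif (4–5 residues,
mutually substring-free) — leaves only, so propagation-based evaluation has
nontrivial ancestor structure — and plants the motifs of each protein's true
terms at non-overlapping positions in an i.i.d.-uniform background
(default: 150 proteins of 80–120 residues, 1–3 terms each, 2 insertions per
term, zero dropout and zero spurious insertions unless configured).
Background stretches that happen to spell a motif are resampled, so at zero
noise motif presence reflects annotation *exactly*; this is what makes exact
parameter recovery ($P(\text{term}\mid\text{motif}) = 1$, and every true term
ranked above every false one by the baseline) a theorem about the generator
rather than a statistical accident. The `dropout` and `spurious_rate`
parameters reintroduce noise in controlled amounts.

The generator reproduces the one statistical assumption the method rests on —
recurrent sequence words co-occurring with specific functions — and nothing
else: no homology structure, no domain grammar, no compositional bias, no
realistic annotation depth. Passing tests on this corpus show the pipeline's
machinery is correct and learnable at desk scale; they say nothing about
accuracy on real proteomes.

## Problem sizes and numerical choices

The test suite runs everything at desk scale, chosen so the full suite
completes in a few minutes of one CPU: the translator's learnability check
uses a deterministic toy language (40 source words mapping one-to-one onto 20
target tokens, 300 sentence pairs, 20% held out) trained for 2,000 steps with
a single hidden layer of 32 units, where greedy decoding reproduces over 90%
of training sentences and over 70% of held-out sentences exactly; the
end-to-end pipeline check trains on a 120-protein zero-noise corpus for 1,500
steps. The exhaustive base-26 round-trip covers all 456,976 four-letter
ordinals. Numerical details: softmax rows are max-shifted before
exponentiation; log-likelihoods floor token probabilities at 1e-300; padded
source positions are masked out of attention with a large negative logit;
the noisy-OR product is accumulated in log space (`log1p`); ties in scored
term lists break by term id so every ranking is deterministic.

## Limitations

* The translator is a faithful small-scale implementation; corpus-scale
  training (hundreds of thousands of proteins) would need GPU-backed
  infrastructure out of scope here.
* Only the GRU cell is provided, and decoding is greedy.
* The frequency threshold variant of vocabulary construction is implemented;
  ranking k-mers and keeping a fixed top count per k is a plausible
  alternative reading of the recipe and is not implemented.
* Annotations are consumed as a plain two-column TSV; GAF/GPAD parsing,
  evidence codes and GO slims are out of scope.
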