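---
title: "Bimodal temporal relation extraction with event knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimodal temporal relation extraction with event knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temporalkg)
```

## The problem

Clinical narratives record what happened to a patient, but rarely in
chronological order. Reconstructing the order — did the jaundice precede
the admission, did the seizure overlap the surgery? — is the temporal
relation extraction task: for a pair of annotated event mentions, predict
`BEFORE`, `AFTER` or `OVERLAP` between their occurrence times. Purely
textual classifiers see only a local window around the two mentions;
they miss two other sources of evidence that a clinician uses freely:
the *other* temporal relations stated elsewhere in the same report, and
background knowledge about how events of those kinds are typically
ordered. `temporalkg` implements a bimodal classifier that adds both,
by encoding an event-centric knowledge graph next to the text.

## The model

The classifier has two branches and a late fusion:

**Text branch.** The event pair is marked in the token sequence with the
special tokens `<e1>`, `</e1>`, `<e2>`, `</e2>`. A backbone produces one
contextual embedding per token; the embeddings of each event's own
tokens (markers excluded) are mean-pooled into two vectors $v_1, v_2$.
For single-modality prediction these are concatenated and passed through
a feed-forward head (one rectified hidden layer with dropout) and a
softmax. A sequence-level embedding (mean over all tokens, in the role a
classifier token plays for transformer encoders) is available behind an
experimental flag for ablation, but is not used by default: pooled event
embeddings classify better. The backbone is a pluggable contract — any
function from token sequences to equal-length embedding sequences with a
fixed dimension. The bundled backbone is a deliberately small trainable
contextualizer (learned token embeddings followed by two width-5
bidirectional convolutional mixing layers with tanh), sized so that a
sentence-level cue word lies within the receptive field of the event
tokens it modifies. A pretrained clinical transformer can be adapted
behind the same contract but is never required.

**Graph branch.** An event graph has one node per medical *concept*
(all mentions linked to the same concept consolidate into one node) and
directed edges for temporal relations. Edges may be hard-labelled
(one-hot) or carry a full probability vector over the relation
vocabulary, as produced by a model. Node embeddings are initialized from
word vectors of the concept's canonical name (hash-based deterministic
fallback for out-of-vocabulary tokens; a text-format vector file can be
supplied) and refined by three relational graph convolution layers:

$$h_i' = \sigma\Big(W_0 h_i + \frac{1}{c_i}\sum_{e=(j \to i)}\sum_r
p_e(r)\, W_r h_j + b\Big),$$

with one transformation matrix $W_r$ per relation type, probability
weights $p_e(r)$, and $c_i = \max(1, \text{in-degree}(i))$. The two
target nodes' final embeddings $u_1, u_2$ are read out. With three
layers, nodes farther than three hops from both targets cannot influence
the output, which is why per-instance subgraphs are cut at three hops.

Two design notes on the convolution. First, the normalization constant
is the node's total in-degree rather than a per-relation count: with
probability-vector edges, per-relation degrees are fractional and
noisier. Second, no basis decomposition of the $W_r$ is used — with
three relation types the parameter count is already small. Messages flow
along edge direction only; reverse influence comes from the
inverse-enriched edges themselves, avoiding a duplicate set of reversed
relation types.

**Fusion.** A single linear layer (no hidden layer) maps
$[v_1; v_2; u_1; u_2]$ to label logits. Keeping the branches separate up
to this point means predictions remain available from a single modality
when the other input is missing.

## The event-graph pipeline

*Consolidation.* Mentions are linked to concepts either by a dictionary
linker over a lexicon of surface forms (exact normalized match first,
then longest token subsequence, ties broken by concept id — linking is
context-free by design, with the known failure mode that generic phrases
link to generic concepts), or by a pass-through linker that trusts
concept annotations already present. Unlinked mentions become
pseudo-concepts keyed by their normalized surface so that every event is
always representable as a node.

*Enrichment.* For every edge $(u, v, \ell)$ the inverse edge
$(v, u, \ell^{-1})$ is added if absent (`BEFORE` and `AFTER` are
mutually inverse, `OVERLAP` is self-inverse; probability vectors are
permuted accordingly). Then transitive edges are added to a fixpoint:
$(u, v, \ell_1)$ and $(v, w, \ell_2)$ yield $(u, w, \ell_1 \circ \ell_2)$
when the composition is unambiguous, the pair $(u, w)$ has no edge yet,
and $u \neq w$. Two composition presets ship: `strict` composes only
`BEFORE∘BEFORE` and `AFTER∘AFTER` (sound under interval semantics
without further assumptions) and `approx`, which additionally treats
`OVERLAP` as near-simultaneity (`BEFORE∘OVERLAP → BEFORE` and so on).
In a three-class scheme where `OVERLAP` absorbs everything from
containment to simultaneity, the strict table fires so rarely that the
enriched graph adds little; the standard experiments therefore use
`approx`, accepting a small rate of unsound inferences (on the synthetic
corpus about nine in ten inferred target-pair edges are correct). Both
presets are available everywhere; closures are deterministic (canonical
tie-breaks) and never delete or relabel an existing edge. Every derived
edge records its parents, so removals cascade correctly.

*Per-instance slicing.* Before classifying a pair, every base edge
between the two target nodes — in both directions, along with every
derived edge whose derivation involves one — is masked out, and
transitive edges are re-derived from the surviving edges. A relation
between the targets that follows purely from the document's *other*
relations is retained: it is precisely the kind of inferred context the
graph branch exists to exploit, and it is invariant to the target pair's
own gold label, so no label information leaks (a property test verifies
that flipping a pair's gold label leaves its subgraph bit-identical).
Then the induced subgraph within three undirected hops of either target
is extracted; it always contains at least the two target nodes.

## Synthetic corpus

The restricted clinical corpora the method is aimed at cannot ship with
a package, so `generate_corpus()` emulates the statistical structure the
method needs, with a latent-truth sidecar for oracle tests:

- A shared vocabulary of 40 concepts (pseudo-clinical adjective–noun
  names, UMLS-style identifiers), each with a *canonical position* on a
  bounded timeline (horizon 20 time units) — the typical place of that
  kind of event in a clinical course. Concept draws are Zipf-weighted so
  consolidation produces hub nodes.
- Each document samples 5–8 distinct concepts; an event's realised start
  is its concept's position plus Gaussian jitter (sd 1.0), its duration
  log-normal (meanlog 0.7, sdlog 0.6). Gold labels are derived from the
  realised intervals: `BEFORE`/`AFTER` when intervals are disjoint,
  `OVERLAP` otherwise. These values were fixed at design time so that
  all three classes carry at least ~20% mass and concept positions alone
  predict relations at about 0.77 — informative but far from ceiling.
- Events are rendered one per short sentence in *random* narrative
  order, so sentence position carries no temporal signal. With
  probability 0.7 an adjacent pair's sentence begins with a connective
  consistent with the gold relation (`Subsequently` / `Previously` /
  `Concurrently`); otherwise a neutral connective. Two additional
  long-range pairs per document are annotated between non-adjacent
  mentions and never receive a cue: they are unanswerable from local
  text by construction, which creates the measurable headroom for the
  graph branch.

What the generator does not emulate: clinical language (negation,
hedging, tense, abbreviation), context-sensitive concept ambiguity,
annotation noise, and document-level discourse structure. Passing the
synthetic experiments therefore demonstrates that the architecture and
pipeline work as designed — not that these accuracy levels transfer to
clinical text.

## Training procedure

Training is staged, using two training splits and a validation split
(documents are split 0.6/0.2/0.2 at the document level to prevent
relation leakage):

1. **Text stage** — the text branch (backbone + feed-forward head) is
   trained on the first split with cross-entropy, Adam (learning rate
   1e-3), minibatches of 128, early stopping on validation accuracy.
   Classes are balanced beforehand by duplicate-to-majority
   oversampling.
2. **Graph stage** — the graph encoder and a linear graph head are
   trained on per-instance masked subgraphs. With gold training graphs
   (the default) both training splits are used — gold graphs carry no
   prediction noise, so there is no reason to hold data back. With
   bootstrapped training graphs, only the second split is used: its
   graphs are built from the text branch's predictions on documents the
   text branch never saw, so they carry realistic errors. Decoupled
   weight decay (1e-3) counters the strong memorization capacity of
   per-relation matrices over a 40-concept vocabulary.
3. **Fusion stage** — the single linear fusion layer is fitted on frozen
   features. Each instance contributes one sample per graph condition
   (gold-masked and bootstrapped), so one layer learns a trust level
   that is valid in both regimes.
4. **Joint stage** — end-to-end fine-tuning of backbone, graph encoder
   and fusion under the bimodal loss (the branch heads stay fixed; they
   serve the single-modality paths). With a frozen-feature linear fusion
   most of the attainable bimodal gain is left on the table — the
   encoders were never trained to be linearly fusable — so this short
   stage is on by default. The fine-tuned parameters are kept separately
   for the bimodal path, so text-only and graph-only predictions are
   still produced by exactly the models their heads were fitted to.

Model selection for the fusion and joint stages uses the mean validation
accuracy across all three graph regimes the scenarios exercise —
gold-masked, bootstrapped, and oracle-filtered — even though training
sees only the first two: the selected model should not trade one
evaluation regime against another.

Every stage's randomness derives from one master seed; on a single
BLAS thread the whole pipeline is bit-reproducible (a property the test
suite asserts end to end). Multi-threaded BLAS relaxes this to small
numeric jitter.

Why two training splits? The corpora this method targets come with such
a split, but its role is not stated by convention. The reading
implemented here is the one that makes the bootstrap scenario
self-consistent: bootstrap graphs for training must come from text
predictions on documents the text branch has not memorized, and the
second split is exactly that.

## Evaluation scenarios

- **Scenario 1 (gold graph):** the evaluation documents' own annotated
  relations build the graph; per instance the target pair's relations
  are masked as above. Default scope is per-document — the premise is
  that some relations of the report under analysis are already known.
  A dataset-wide scope is available, but consolidating realized
  relations from many reports into concept-level edges blurs them into
  concept-typical tendencies, which the text branch can partly learn on
  its own, so the document scope is the informative setting.
- **Scenario 2 (bootstrapped graph):** the text branch predicts every
  annotated pair of a document; the probability vectors become soft
  edges, enriched (inverse by vector permutation, transitive from argmax
  labels with confidence the product of the parents'), optionally
  filtered by a softmax-confidence threshold (edges kept when
  confidence ≥ threshold). The report also states the bootstrap graph's
  own expanded-set accuracy against the enriched gold graph.
- **Scenario 3 (oracle filter):** scenario-2 graphs with every
  incorrectly predicted base edge removed using gold labels, derived
  edges following their parents. Diagnostic only — it requires the
  correct answers — but it separates the cost of *missing* edges from
  the cost of *wrong* ones.

A threshold sweep (`sweep_threshold()`) re-runs scenario 2 over a
threshold grid; kept-edge counts are non-increasing by construction and
a zero threshold reproduces the unfiltered run.

## Numerical and degenerate-case choices

- Offsets are 0-based half-open and checked against surfaces on load.
- Argmax label assignment breaks ties by the lowest label index.
- Transitive closure resolves multiple candidate labels for a pair in
  the same round by the smallest label index, then lexicographic parent
  ids; the closure is input-order independent and matched in the test
  suite against an independent brute-force enumerator.
- Probability vectors must sum to one within 1e-6; serialization keeps
  them to better than 1e-9.
- Empty graphs are legal everywhere: an isolated target pair encodes
  through the self-transformation chain alone, and the fused model
  degrades gracefully toward its text coordinates (tested).
- Token budget for the text window defaults to 128; when the span
  between events exceeds it, the middle is elided with a `<gap>` token,
  both event spans always retained.
- Out-of-vocabulary tokens map to `<unk>`; word-vector lookups fall back
  to a deterministic hash-seeded vector, so unseen concept names still
  get stable embeddings.

## Problem sizes

The standard experiment trains on 200 documents (~1,500 relation
instances) and evaluates on 50 held-out documents from the same
generator run — held out from the same run because a fresh generator
seed would resample the concept world itself, unlike the fixed concept
space shared by a real corpus's train and test portions. The reference
schedule (13/14/8 epoch caps for text/graph/joint with early stopping)
was fixed from validation curves. On one CPU core a full
generate–train–evaluate cycle takes a few minutes.

## Known limitations

- The bundled backbone is a small contextualizer, not a pretrained
  clinical language model; absolute accuracies on real clinical text
  will differ substantially.
- The dictionary linker is context-free; homonymous surface forms link
  to one concept.
- The approximate composition preset can derive edges that interval
  semantics does not guarantee; the strict preset is available when
  soundness matters more than coverage.
- Candidate pair identification is out of scope: the system classifies
  annotated pairs, it does not propose them.
- No cross-document statistical filtering of predicted relations is
  implemented; the confidence threshold is the only filter.
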