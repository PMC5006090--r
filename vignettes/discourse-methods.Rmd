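---
title: "Models and methods: discourse segment and experiment-type classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: discourse segment and experiment-type classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discoseg)
```

# The problem

Results sections of molecular-biology papers narrate many small experiments
in quick succession. Curators mining such text need two distinctions that
sentence-by-sentence event extraction does not give them: the *epistemic
status* of each statement (is this background fact, the authors' own
measurement, or an interpretation?), and the *experiment* each passage
belongs to (in this literature, almost always identified by a subfigure
such as 2B). `discoseg` implements both layers plus the evaluation algebra
used to score them.

# Clause-level discourse classification

## Units and labels

The classification unit is the clause. Sentences are found with a
deterministic rule-based splitter (terminal `.`/`!`/`?` followed by a
sentence-initial character, with an abbreviation list covering `Fig.`,
`et al.`, `e.g.`, `i.e.`, `vs.` and similar), and split into clauses at a
configurable delimiter set: `";"`, `", which"`, `", suggesting"`,
`", indicating"`, `", whereas"`, `", while"`, `", because"`, and
`", and"`/`", but"` when followed by a finite verb phrase. This rule-based
splitter is a stated approximation to full syntactic clause analysis; the
interface is pluggable so a parser-based splitter can be substituted
without touching anything downstream. All-caps sentences are treated as
headings, emitted as single clauses eligible for the reserved label
`none`, and excluded from modeling — the classifiers are strictly
seven-way over `problem`, `fact`, `hypothesis`, `goal`, `method`,
`result`, `implication` (that fixed order is also the deterministic
tie-break order everywhere).

## Features

Each clause is a sparse vector from four families:

* `pos:T` — counts of Penn-style part-of-speech tags from a pluggable
  tagger. The shipped default is a dictionary-plus-suffix rule tagger;
  any `function(tokens) -> tags` can replace it.
* `lex:w` — binary indicators for tokens tagged verb (`VB*`) or adverb
  (`RB*`); these word classes carry most of the epistemic signal
  ("observed", "suggest", "markedly").
* `link:figure`, `link:citation` — binary flags set when a
  figure-reference or citation annotation intersects the clause span.
  A figure pointer marks the authors' own results; a citation marks
  attributed (fact-like) material.
* `cue:p` — indicators for case-insensitive substring hits from a cue
  lexicon. The core attested cues are `possible → hypothesis`,
  `data not shown → result`, and `demonstrate`/`suggest → implication`;
  the shipped lexicon adds about twenty conservative extensions
  (`we sought to → goal`, `it is known → fact`, `taken together →
  implication`, ...). The extension set is deliberately modest — larger
  lexicons have not been found to help this task — and every entry can be
  overridden key-by-key from a two-column TSV.

Feature values are counts for `pos:*` and binary for the other families,
matching the presence/absence reading of the lexicon features. Extraction
is a pure function of (clause text, annotations, lexicon), which the test
suite asserts directly.

## Models

**SVM baseline.** Seven one-vs-all linear SVMs (via `e1071`, cost 1, no
scaling); prediction is the argmax of the seven margins, ties broken by the
fixed label order. No class reweighting is applied by default — the
imbalance behavior of the baseline is part of what the evaluation layer is
meant to expose — but inverse-frequency weighting is available as a flag.

**Linear-chain CRF.** The sequence unit is the paragraph, where the
archetypal narrative order (context → goal → method → result →
implication) lives. The model scores a label sequence by per-clause
emission weights plus adjacent-label transition weights and a start
vector; training maximizes the penalized conditional log-likelihood with
exact forward–backward gradients and L-BFGS (`stats::optim`), L2 strength
1, up to 120 iterations, zero initialization — all deterministic, so a
(data, config, seed) triple fully determines the model and every
prediction. Decoding is Viterbi with ties broken toward the earlier label.
Numerical care: forward/backward passes use per-position scaling plus a
per-row max-shift on emission scores, so no log-sum-exp is needed in the
inner loop and sequences of any length are stable.

Model archives are JSON (metadata + flat parameter vectors) stamped with a
feature `schema_version`; loading or predicting across mismatched schema
versions is refused rather than silently mis-aligned.

# Experiment linkage and type classification

The linkage layer assumes one figure per experiment and one subfigure per
sub-experiment — the convention under which curated interaction databases
record their evidence. Narrative passages are whole paragraphs containing
at least one figure reference, linked to all subfigures they mention in
first-mention order; figure-caption sentences beginning `"(A)"` are linked
to exactly their letter. Passages whose subfigures map to more than one
curated assay code are discarded (they cannot carry a single gold label);
the kept/discarded/unmapped partition is conserved and reported. Code
merging (e.g. anti-tag and anti-bait coimmunoprecipitation onto
coimmunoprecipitation) is data, not code: a two-column map applied before
restricting to the top-k most frequent codes, frequency ties broken by
code string order.

The type classifier is tf.idf nearest-centroid, fixed exactly so results
are bit-reproducible: lowercase alphanumeric tokens, a small stopword
list, natural term frequency, `idf = ln((1+N)/(1+df)) + 1`, L2-normalized
vectors, per-class centroids (re-normalized), cosine argmax with ties
broken by code order. Passages with no in-vocabulary tokens fall back to
the most frequent training class and are flagged. A top-m
discriminative-term voting variant is available behind a switch; the
centroid form is the default because it is deterministic and standard.
Cross-validation is stratified by class, seeded, and pools out-of-fold
predictions into one confusion matrix before computing metrics — pooling
(rather than averaging per-fold scores) is the documented choice, and it
guarantees every passage is predicted exactly once.

# Evaluation algebra

Reports derive from a gold × predicted count matrix: precision
`diag/colsum` (0 when the column is empty), recall `diag/rowsum` (0 when
the row is empty), F1 the harmonic mean (0 when both are 0), and the
support-weighted F1. The most-frequent-class baseline has the closed form
`p·2p/(1+p)` for majority share `p`; the tests verify it against the
explicit constant-predictor construction, and verify the whole report
against a brute-force per-item oracle on random matrices. Rounding
(half-up, 2 decimals) happens only at presentation; published tables are
compared on rounded values.

# The synthetic corpus generators

No annotated corpus of this kind is publicly deposited, so the package
ships generators that emulate the *statistical structure* the classifiers
assume — deliberately stylized English, not realistic prose.

**Discourse corpus.** Paragraph label sequences are drawn from a Markov
chain over the seven labels. The default transition matrix encodes the
archetypal order as five stages (context = {fact, hypothesis, problem},
goal, method, result, implication) with probability 0.8 of stepping
forward, 0.1 of staying, 0.1 of skipping a stage; stages cycle, so an
implication is followed by the context of the next experiment (without the
cycle the chain would be absorbed in `implication`). Context-stage mass is
split fact : hypothesis : problem ≈ 0.55 : 0.40 : 0.05, reflecting how
rare explicit problem statements are in Results sections. Each clause is
rendered from a label-specific cue-bearing template with probability
`cue_emission × (1 − cue_dropout)` (defaults 0.75 and 0.1); otherwise it
comes from a template pool *shared across all labels*, so cue-dropped
clauses are lexically uninformative and only sequence context can label
them — this is precisely what separates the CRF from the SVM, and makes
the separation detectable at the default scale (20 documents × 8
paragraphs ≈ 2000 clauses) within a minute of training. Result clauses
carry figure references at rate 0.7 and fact clauses citations at rate
0.6. A uniform-row transition matrix (`iid_transitions`) removes the
ordering signal for ablations while fixing the marginal label
distribution; with the reference prior (the 445-clause ground-truth
frequencies: problem 2, fact 53, hypothesis 36, goal 30, method 98,
result 182, implication 44) it reproduces those frequencies to within 2%
at 3600 clauses.

**Experiment-type corpus.** Five PSI-MI classes with pairwise-disjoint
term pools (two hybrid, coimmunoprecipitation, pull down, fluorescence
microscopy, confocal microscopy), class frequencies (57, 332, 125, 34,
33)/581 matching the caption-set supports, 581 passages by default. Each
passage carries at least two class terms plus shared filler vocabulary;
with probability `term_bleed` (default 0.15) a class term is replaced by a
draw from the union of all pools. Captions receive twice the narrative
class-term density and fewer fillers, encoding the observation that
captions are terser and more assay-explicit than narrative — which is why
caption-trained models dominate narrative-trained ones in the tests.
Because the pools are disjoint and every passage carries class terms, the
zero-bleed limit is exactly separable (cross-validated weighted F1 = 1.0).

**What passing tests do and do not show.** The generators control their
own nuisance structure, so passing the property tests demonstrates the
*mechanics* — the CRF really exploits label order, cue features really
flow from lexicon to prediction, the arithmetic really matches a
brute-force oracle — not that these accuracy levels transfer to real
articles, whose vocabulary, clause structure and annotation noise are far
richer. Published-table reproductions, by contrast, are exact because
they recompute metrics from printed counts.

## A known limit of the no-signal regime

In the full-bleed limit (`term_bleed = 1`, all passages drawn from the
same term distribution), cross-validated weighted F1 settles at chance
level, about 0.24–0.30 under the default class imbalance. That is *below*
the most-frequent-class baseline (≈ 0.42): a cosine nearest-centroid
without prior-aware scoring keeps its predictions spread over classes
instead of collapsing to the majority, and the chance-level weighted F1
under imbalance is strictly smaller than the majority predictor's. So "no
signal" and "majority baseline" are different operating points for this
classifier family; the tests assert the one-sided fact (the no-signal
limit does not beat the baseline) and this gap is documented rather than
papered over.

# Numerical and design choices, in brief

* Coordinates are 0-based, half-open character offsets everywhere.
* Figure-mention grammar: anchor tokens (`Fig.`, `Figure`, ...) followed by
  integer + optional letter, conjoined lists expanded per panel, bare
  parenthesized panels (`"(2B, 2C)"`) accepted only with an anchor earlier
  in the same sentence — permissive enough for caption exemplars, strict
  enough not to fire on gene names. Subfigure letters normalize to
  uppercase.
* Citations: numeric-bracket and author-year textual patterns plus markup;
  parenthesized panel tokens are never citations, and citation spans never
  overlap figure-reference spans.
* Degenerate inputs fail loudly: single-label training sets name the
  missing classes, empty supports and non-square matrices are rejected,
  unmapped subfigures are warned about and counted separately.
* Problem sizes in the test suite (5–20 documents, 581 passages, 5 seeds
  for every statistical property) are chosen so the full suite runs in a
  few minutes on one core while keeping each property's effect size well
  clear of its threshold.

# Known limitations

* The clause splitter and POS tagger are rule-based approximations;
  both are pluggable, and swapping in syntactic tooling is the expected
  upgrade path for real-corpus work.
* The shipped cue lexicon beyond the four attested phrases is a
  configuration-visible approximation.
* Paragraph-level passage linkage is a stated simplification; sub-paragraph
  experiment delineation is out of scope.
* The generators make no attempt at prose realism; their contract is
  statistical structure only.
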