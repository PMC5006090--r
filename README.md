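# discoseg

Text-mining tools for the Results sections of molecular-biology articles,
aimed at biocuration workflows that need to know not just *what* a paper
claims but *how each statement relates to the experimental evidence*.

The package does two things:

1. **Discourse segment classification.** Results-section narrative is split
   into sentences and clause-level units, and each clause is assigned one of
   seven epistemic types — `fact`, `hypothesis`, `problem`, `goal`,
   `method`, `result`, `implication` (headings may carry the reserved label
   `none` and are excluded from modeling). Two classifiers are provided
   over a shared four-family feature scheme (part-of-speech tag counts,
   verb/adverb identities, figure-reference/citation links, cue-lexicon
   hits): a one-vs-all linear SVM baseline, and a linear-chain conditional
   random field (CRF) that also scores adjacent-label transitions. Authors
   tend to narrate each experiment in an archetypal order — context
   (fact/hypothesis/problem), then goal, method, result, implication — and
   the CRF exploits exactly this sequence structure.

2. **Experiment-type classification.** Narrative paragraphs and lettered
   figure-caption sentences (`"(A) …"`) are linked to the subfigures they
   reference (working assumption: one figure ≙ one experiment, one
   subfigure ≙ one sub-experiment), passages mapping to more than one
   curated assay code are discarded, and the remaining single-type passages
   are classified by assay code (PSI-MI `MI:nnnn` codes such as MI:0019
   coimmunoprecipitation, or Pathway Logic codes such as `copptby`) with a
   tf.idf nearest-centroid classifier under stratified 5-fold
   cross-validation.

An evaluation layer implements the confusion-matrix algebra used
throughout: per-class precision/recall/F1 with the zero-denominator
convention, support-weighted F1

    weighted F1 = Σᵢ sᵢ·F1ᵢ / Σᵢ sᵢ ,

and the most-frequent-class baseline `p·2p/(1+p)` for majority share `p`.
A seeded synthetic-corpus generator produces labeled Results-section
documents (Markov label sequences with cue-bearing templates, figure
references and citations) and experiment-type passages (assay term pools
with controllable lexical-overlap noise), so every model property is
testable without any corpus download.

## Worked example

```r
library(discoseg)

# simulate a labeled corpus, train both models, evaluate held-out paragraphs
res <- benchmark_discourse(corpus_spec(seed = 1))
print(res$crf$report)
round(c(crf = weighted_f1(res$crf$report),
        svm = weighted_f1(res$svm$report),
        baseline = res$crf$baseline), 2)
```

```
       label support predictions correct precision recall   f1
     problem       7           3       3      1.00   0.43 0.60
        fact      46          52      43      0.83   0.93 0.88
  hypothesis      35          25      23      0.92   0.66 0.77
        goal      77          82      70      0.85   0.91 0.88
      method      79          79      71      0.90   0.90 0.90
      result      75          76      72      0.95   0.96 0.95
 implication      62          64      61      0.95   0.98 0.97
Weighted F1: 0.90  (n = 381)
     crf      svm baseline
    0.90     0.79     0.07
```

The CRF's advantage over the SVM (0.90 vs 0.79 here) comes from clauses
whose wording alone is ambiguous: the transition weights recover the
archetypal ordering, e.g. `coef(res$crf$model)$transitions` has
goal→method, method→result and result→implication all strongly positive.

Scoring a published confusion matrix reproduces its metric table:

```r
cm <- read_confusion_tsv(system.file("extdata",
        "table_discourse_confusion.tsv", package = "discoseg"))
print(report_from_matrix(cm))
```

```
       label support predictions correct precision recall   f1
     problem       2           2       0      0.00   0.00 0.00
        fact      53          30      14      0.47   0.26 0.34
  hypothesis      36          17      12      0.71   0.33 0.45
        goal      30          26      18      0.69   0.60 0.64
      method      98          90      66      0.73   0.67 0.70
      result     182         216     147      0.68   0.81 0.74
 implication      44          64      31      0.48   0.70 0.57
Weighted F1: 0.63  (n = 445)
```

A thin command-line interface (`inst/cli/discoseg.R`) exposes the same
pipeline as shell commands (`simulate`, `segment`, `train-discourse`,
`label`, `evaluate`, `link-experiments`, `train-exptype`, `score-table`).

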