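# End-to-end glue: align gold labels onto re-segmented clauses, and run the
# simulate -> segment -> train -> label -> evaluate loop.

#' Attach gold labels to clauses by span overlap
#'
#' Labels each clause with the gold label of the maximally overlapping gold
#' clause from the same document (used when text is re-segmented and clause
#' boundaries may differ slightly from the generator's).
#'
#' @param clauses clause table (e.g. from \code{\link{segment_document}}).
#' @param gold gold clause table with \code{doc_id}, \code{start},
#'   \code{end}, \code{gold_label} (and optionally \code{paragraph_idx},
#'   copied over).
#' @return \code{clauses} with \code{gold_label} (and \code{paragraph_idx}
#'   if available) filled in; clauses with no overlap keep \code{NA}.
#' @export
attach_gold <- function(clauses, gold) {
  if (!nrow(clauses)) return(clauses)
  has_para <- "paragraph_idx" %in% names(gold)
  if (has_para && !"paragraph_idx" %in% names(clauses))
    clauses$paragraph_idx <- NA_integer_
  for (i in seq_len(nrow(clauses))) {
    g <- gold[gold$doc_id == clauses$doc_id[i], , drop = FALSE]
    if (!nrow(g)) next
    ov <- pmin(g$end, clauses$end[i]) - pmax(g$start, clauses$start[i])
    j <- which.max(ov)
    if (ov[j] > 0) {
      clauses$gold_label[i] <- g$gold_label[j]
      if (has_para) clauses$paragraph_idx[i] <- g$paragraph_idx[j]
    }
  }
  clauses
}

#' Evaluate predicted discourse labels against gold
#'
#' @param labeled clause table with \code{gold_label} and
#'   \code{predicted_label} columns (rows without gold are dropped).
#' @param labels label order (default the seven discourse types).
#' @return an \code{\link{eval_report}}.
#' @export
evaluate_labels <- function(labeled, labels = discourse_labels()) {
  keep <- !is.na(labeled$gold_label) & labeled$gold_label != "none"
  labeled <- labeled[keep, , drop = FALSE]
  report_from_matrix(matrix_from_predictions(labeled$gold_label,
                                             labeled$predicted_label,
                                             labels))
}

#' Train/test split over sequences
#'
#' Deterministically assigns whole sequences (paragraphs) to a held-out set.
#' @param sequences list of clause sequences.
#' @param test_fraction fraction of sequences held out.
#' @param seed RNG seed.
#' @return list with \code{train} and \code{test} sequence lists.
#' @export
split_sequences <- function(sequences, test_fraction = 0.2, seed = 1L) {
  set.seed(seed)
  n <- length(sequences)
  n_test <- max(1L, round(n * test_fraction))
  test_idx <- sort(sample.int(n, n_test))
  list(train = sequences[-test_idx], test = sequences[test_idx])
}

#' Simulate, train and evaluate in one pass
#'
#' Generates a synthetic discourse corpus, extracts features, fits a CRF
#' and/or SVM on a training split of paragraphs, and evaluates on the
#' held-out split. The whole run is determined by the spec's seed.
#'
#' @param spec a \code{\link{corpus_spec}}.
#' @param kinds model kinds to fit.
#' @param test_fraction held-out fraction of paragraphs.
#' @param ... passed to \code{\link{discourse_model}}.
#' @return named list per kind: list(model, report, baseline).
#' @export
benchmark_discourse <- function(spec = corpus_spec(),
                                kinds = c("crf", "svm"),
                                test_fraction = 0.2, ...) {
  corpus <- generate_discourse_corpus(spec)
  seqs <- clause_sequences(corpus$clauses, corpus$documents)
  parts <- split_sequences(seqs, test_fraction, seed = spec$seed)
  gold_test <- unlist(lapply(parts$test, function(s) s$clauses$gold_label))
  supports <- table(factor(gold_test, levels = discourse_labels()))
  baseline <- most_frequent_baseline(as.integer(supports))
  out <- list()
  for (kind in kinds) {
    model <- discourse_model(parts$train, kind = kind, seed = spec$seed, ...)
    labeled <- predict(model, parts$test)
    out[[kind]] <- list(model = model,
                        report = evaluate_labels(labeled),
                        baseline = baseline)
  }
  out
}
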