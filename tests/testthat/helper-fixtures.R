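# Shared fixtures built in code.

# the printed 7x7 discourse confusion matrix (rows gold, cols predicted)
discourse_confusion_fixture <- function() {
  labs <- discourse_labels()
  m <- rbind(c(0, 0, 0, 0, 0, 2, 0),
             c(1, 14, 2, 2, 2, 26, 6),
             c(0, 2, 12, 5, 3, 6, 8),
             c(0, 0, 0, 18, 9, 2, 1),
             c(0, 4, 0, 1, 66, 26, 1),
             c(1, 7, 2, 0, 8, 147, 17),
             c(0, 3, 1, 0, 2, 7, 31))
  confusion_matrix(m, labs)
}

# the printed 5x5 caption-set confusion matrix
caption_confusion_fixture <- function() {
  codes <- c("MI:0018", "MI:0019", "MI:0096", "MI:0416", "MI:0663")
  m <- rbind(c(25, 29, 3, 0, 0),
             c(0, 321, 9, 0, 2),
             c(1, 53, 71, 0, 0),
             c(0, 26, 0, 4, 4),
             c(0, 20, 0, 3, 10))
  confusion_matrix(m, codes)
}

# a tiny document with one results paragraph and one caption
tiny_document <- function() {
  body <- paste0(
    "RESULTS\n\n",
    "It is known that RAF1 regulates MEK1 [3]. ",
    "We sought to examine binding of RAF1 to MEK1. ",
    "Binding increased (Fig. 2B), suggesting a direct interaction.")
  cap <- "(A) Lysates were blotted. (B) Quantification of binding."
  text <- paste0(body, "\n\n", cap)
  secs <- data.frame(kind = c("results", "caption"),
                     start = c(0L, nchar(body) + 2L),
                     end = c(nchar(body), nchar(text)),
                     heading = c(NA, "Figure 2"),
                     stringsAsFactors = FALSE)
  document("tiny", text, sections = secs,
           figure_refs = detect_figure_refs(text),
           citations = detect_citations(text))
}

# random confusion matrix for oracle comparisons
random_confusion <- function(k, max_count = 20L) {
  m <- matrix(sample(0:max_count, k * k, replace = TRUE), k, k)
  if (sum(m) == 0) m[1, 1] <- 1L
  confusion_matrix(m, paste0("c", seq_len(k)))
}

# independent per-item oracle: expand a confusion matrix to item-level
# (gold, predicted) pairs and recompute all metrics directly
oracle_report <- function(cm) {
  labs <- rownames(cm)
  gold <- character(); pred <- character()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    n <- cm[i, j]
    if (n > 0) {
      gold <- c(gold, rep(labs[i], n))
      pred <- c(pred, rep(labs[j], n))
    }
  }
  per <- lapply(labs, function(l) {
    tp <- sum(gold == l & pred == l)
    p <- if (sum(pred == l) > 0) tp / sum(pred == l) else 0
    r <- if (sum(gold == l) > 0) tp / sum(gold == l) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(support = sum(gold == l), precision = p, recall = r, f1 = f)
  })
  per <- do.call(rbind, per)
  list(per = per,
       weighted_F1 = sum(per[, "support"] * per[, "f1"]) / sum(per[, "support"]))
}

# small fully-labeled synthetic training set (shared across model tests)
small_corpus <- function(seed = 1L, n_documents = 5L) {
  generate_discourse_corpus(corpus_spec(n_documents = n_documents,
                                        seed = seed))
}
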