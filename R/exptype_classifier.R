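# tf.idf nearest-centroid classification of experiment type from passage or
# caption text. Weighting is fixed so results are bit-reproducible:
# natural term frequency, idf = ln((1+N)/(1+df)) + 1, L2-normalized vectors,
# cosine-similarity argmax over per-class centroids with ties broken by code
# string order.

exptype_stopwords <- function() {
  c("a", "an", "the", "of", "in", "on", "at", "by", "with", "for", "from",
    "to", "and", "or", "was", "were", "is", "are", "be", "been", "we",
    "this", "these", "that", "as", "using", "used", "then", "after",
    "into", "which", "it", "its", "not", "no")
}

tokenize_passage <- function(text) {
  toks <- regmatches(tolower(text),
                     gregexpr("[a-z0-9]+", tolower(text)))[[1L]]
  toks[!toks %in% exptype_stopwords()]
}

tfidf_matrix <- function(token_lists, vocab, idf) {
  n <- length(token_lists)
  ii <- list(); jj <- list(); xx <- list()
  for (i in seq_len(n)) {
    tf <- table(token_lists[[i]])
    j <- match(names(tf), vocab)
    keep <- !is.na(j)
    if (!any(keep)) next
    ii[[length(ii) + 1L]] <- rep.int(i, sum(keep))
    jj[[length(jj) + 1L]] <- j[keep]
    xx[[length(xx) + 1L]] <- as.numeric(tf)[keep] * idf[j[keep]]
  }
  X <- Matrix::sparseMatrix(i = as.integer(unlist(ii)),
                            j = as.integer(unlist(jj)),
                            x = as.numeric(unlist(xx)),
                            dims = c(n, length(vocab)))
  nrm <- sqrt(Matrix::rowSums(X^2))
  nrm[nrm == 0] <- 1
  X / nrm
}

#' Fit a tf.idf nearest-centroid experiment-type classifier
#'
#' Passages are tokenized (lowercase alphanumeric tokens, a small stopword
#' list removed), weighted by smoothed tf.idf, L2-normalized, and averaged
#' into one centroid per experiment-type code. Classification is the
#' cosine-similarity argmax over centroids. A top-m discriminative-term
#' voting variant is available via \code{method = "terms"}: each class is
#' represented by its \code{m} highest-scoring centroid terms and a passage
#' votes by counting term overlaps.
#'
#' @param passages data frame with columns \code{text} and \code{code}
#'   (exactly one gold code per passage).
#' @param method \code{"centroid"} (default) or \code{"terms"}.
#' @param m number of discriminative terms per class for
#'   \code{method = "terms"}.
#' @return object of class \code{exptype_tfidf}.
#' @export
exptype_tfidf <- function(passages, method = c("centroid", "terms"),
                          m = 20L) {
  method <- match.arg(method)
  if (!nrow(passages)) stop("empty passage list")
  if (anyNA(passages$code)) stop("every passage needs exactly one gold code")
  classes <- sort(unique(passages$code))
  if (length(classes) < 2L)
    stop("need at least two classes, got: ", paste(classes, collapse = ", "))
  toks <- lapply(passages$text, tokenize_passage)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  if (!length(vocab)) stop("no in-vocabulary tokens in training passages")
  N <- length(toks)
  df_counts <- table(factor(unlist(lapply(toks, unique), use.names = FALSE),
                            levels = vocab))
  idf <- log((1 + N) / (1 + as.numeric(df_counts))) + 1
  X <- tfidf_matrix(toks, vocab, idf)
  cls <- factor(passages$code, levels = classes)
  centroids <- t(sapply(classes, function(cl)
    Matrix::colMeans(X[cls == cl, , drop = FALSE])))
  rownames(centroids) <- classes
  # normalize centroids so cosine similarity is a plain inner product
  cn <- sqrt(rowSums(centroids^2))
  cn[cn == 0] <- 1
  centroids <- centroids / cn
  term_lists <- NULL
  if (method == "terms") {
    term_lists <- lapply(classes, function(cl) {
      sc <- centroids[cl, ]
      vocab[order(-sc)[seq_len(min(m, sum(sc > 0)))]]
    })
    names(term_lists) <- classes
  }
  structure(list(classes = classes, vocab = vocab, idf = idf,
                 centroids = centroids, method = method,
                 term_lists = term_lists,
                 majority = classes[which.max(table(cls))],
                 class_counts = table(cls)),
            class = "exptype_tfidf")
}

#' @export
print.exptype_tfidf <- function(x, ...) {
  cat(sprintf("<exptype_tfidf (%s): %d classes, %d terms>\n",
              x$method, length(x$classes), length(x$vocab)))
  invisible(x)
}

#' Classify passage text by experiment type
#'
#' Cosine-similarity argmax over the fitted class centroids (or term-overlap
#' vote for the \code{"terms"} variant); similarity ties are broken by code
#' string order. Passages with zero in-vocabulary tokens fall back to the
#' most frequent training class and are flagged.
#'
#' @param object a fitted \code{\link{exptype_tfidf}} model.
#' @param texts character vector of passage texts.
#' @param ... unused.
#' @return character vector of predicted codes with logical attribute
#'   \code{flagged} marking out-of-vocabulary fallbacks.
#' @export
predict.exptype_tfidf <- function(object, texts, ...) {
  toks <- lapply(texts, tokenize_passage)
  X <- tfidf_matrix(toks, object$vocab, object$idf)
  oov <- Matrix::rowSums(X != 0) == 0
  pred <- character(length(texts))
  if (object$method == "centroid") {
    sims <- as.matrix(X %*% t(object$centroids))
    # which.max returns the first maximum; classes are in string order
    pick <- apply(sims, 1L, which.max)
    pred <- object$classes[pick]
  } else {
    for (i in seq_along(toks)) {
      votes <- vapply(object$term_lists, function(tl)
        sum(toks[[i]] %in% tl), numeric(1L))
      pred[i] <- object$classes[which.max(votes)]
    }
  }
  pred[oov] <- object$majority
  structure(pred, flagged = as.vector(oov))
}

#' Stratified k-fold cross-validation of the tf.idf classifier
#'
#' Folds are stratified by class and seeded; out-of-fold predictions are
#' pooled into a single confusion matrix from which the report is computed
#' (every passage is predicted exactly once). Classes with fewer than
#' \code{k} members fall back to non-stratified round-robin assignment for
#' that class (noted via a message).
#'
#' @param passages data frame with \code{text} and \code{code}.
#' @param k number of folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param method,m passed to \code{\link{exptype_tfidf}}.
#' @return an \code{\link{eval_report}} with attributes \code{accuracy} and
#'   \code{confusion} (the pooled matrix).
#' @export
cv_exptype <- function(passages, k = 5L, seed = 1L,
                       method = "centroid", m = 20L) {
  n <- nrow(passages)
  if (n < k) stop("need at least k passages")
  classes <- sort(unique(passages$code))
  if (length(classes) < 2L) stop("need at least two classes")
  set.seed(seed)
  fold <- integer(n)
  for (cl in classes) {
    idx <- which(passages$code == cl)
    if (length(idx) < k)
      message("class ", cl, " has fewer than k members; ",
              "using round-robin assignment")
    fold[idx] <- (sample(seq_along(idx)) - 1L) %% k + 1L
  }
  gold <- character(n)
  pred <- character(n)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    model <- exptype_tfidf(passages[train, , drop = FALSE], method, m)
    pred[test] <- as.character(predict(model, passages$text[test]))
    gold[test] <- passages$code[test]
  }
  cm <- matrix_from_predictions(gold, pred, classes)
  rep <- report_from_matrix(cm)
  attr(rep, "accuracy") <- mean(gold == pred)
  attr(rep, "confusion") <- cm
  rep
}

#' Write per-passage predictions as TSV
#'
#' Columns: doc_id, figure, subfigure, gold_code, predicted_code.
#' @param passages passage table with a \code{code} column.
#' @param predicted character vector of predicted codes.
#' @param path output path.
#' @export
write_exptype_predictions <- function(passages, predicted, path) {
  rows <- lapply(seq_len(nrow(passages)), function(i) {
    sub <- passages$subfigures[[i]]
    data.frame(doc_id = passages$doc_id[i],
               figure = sub$figure[1L], subfigure = sub$subfigure[1L],
               gold_code = passages$code[i], predicted_code = predicted[i],
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
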