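# Confusion-matrix algebra: per-class precision/recall/F1, support-weighted
# F1, and the most-frequent-class baseline. Rows are gold labels, columns
# predictions. Rates use the zero-denominator convention: precision (recall)
# is 0 when the column (row) sum is 0; F1 is 0 when both are 0.

#' Construct a confusion matrix
#'
#' @param counts square integer matrix, rows = gold labels, columns =
#'   predicted labels (same order).
#' @param labels character vector of labels, one per row/column.
#' @return object of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(counts, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("confusion matrix must be square")
  if (any(counts < 0)) stop("confusion matrix counts must be >= 0")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(counts)))
  if (length(labels) != nrow(counts))
    stop("label count does not match matrix dimension")
  dimnames(counts) <- list(gold = labels, predicted = labels)
  structure(counts, class = c("confusion_matrix", class(counts)))
}

#' Build a confusion matrix from (gold, predicted) pairs
#'
#' @param gold,predicted character vectors of equal length.
#' @param labels label order for rows/columns; every value in \code{gold}
#'   and \code{predicted} must appear here.
#' @return a \code{\link{confusion_matrix}}.
#' @export
matrix_from_predictions <- function(gold, predicted, labels) {
  stopifnot(length(gold) == length(predicted))
  bad <- setdiff(unique(c(gold, predicted)), labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(gold, levels = labels),
               factor(predicted, levels = labels))
  confusion_matrix(matrix(as.integer(tab), length(labels), length(labels)),
                   labels)
}

#' Metrics report from a confusion matrix
#'
#' Computes per-label support, prediction count, correct count, precision,
#' recall and F1, plus the support-weighted F1
#' \eqn{\sum_i s_i F1_i / \sum_i s_i}. Values are reported at full precision;
#' the print method rounds half-up to 2 decimals, which is also the rounding
#' used when comparing against published tables.
#'
#' @param matrix a \code{\link{confusion_matrix}} (or square count matrix
#'   with labeled rows).
#' @return object of class \code{eval_report}: data frame of per-label rows
#'   with attributes \code{weighted_F1} and \code{total}.
#' @export
report_from_matrix <- function(matrix) {
  if (!inherits(matrix, "confusion_matrix"))
    matrix <- confusion_matrix(matrix)
  support <- rowSums(matrix)
  predictions <- colSums(matrix)
  correct <- diag(matrix)
  precision <- ifelse(predictions > 0, correct / predictions, 0)
  recall <- ifelse(support > 0, correct / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  total <- sum(support)
  if (total == 0) stop("confusion matrix is empty")
  wf1 <- sum(support * f1) / total
  df <- data.frame(label = rownames(matrix), support = as.integer(support),
                   predictions = as.integer(predictions),
                   correct = as.integer(correct),
                   precision = unname(precision), recall = unname(recall),
                   f1 = unname(f1), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, weighted_F1 = unname(wf1), total = as.integer(total),
            class = c("eval_report", "data.frame"))
}

#' Support-weighted F1 of a report
#' @param report an \code{eval_report}.
#' @export
weighted_f1 <- function(report) attr(report, "weighted_F1")

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @export
print.eval_report <- function(x, digits = 2L, ...) {
  df <- as.data.frame(x)
  for (col in c("precision", "recall", "f1"))
    df[[col]] <- sprintf(paste0("%.", digits, "f"),
                         round_half_up(df[[col]], digits))
  print(df, row.names = FALSE)
  cat(sprintf("Weighted F1: %s  (n = %d)\n",
              sprintf(paste0("%.", digits, "f"),
                      round_half_up(attr(x, "weighted_F1"), digits)),
              attr(x, "total")))
  invisible(x)
}

#' Most-frequent-class baseline weighted F1
#'
#' The support-weighted F1 of the constant predictor that labels every item
#' with the most frequent class. With \eqn{p} the majority class share,
#' only the majority class has nonzero F1 (\eqn{2p/(1+p)}, since its
#' precision is \eqn{p} and recall 1), so the weighted value is
#' \eqn{p \cdot 2p/(1+p)}. Ties in the maximum leave the value unchanged.
#'
#' @param supports non-negative per-label counts with positive total.
#' @return the baseline weighted F1 (numeric scalar).
#' @export
most_frequent_baseline <- function(supports) {
  supports <- as.numeric(supports)
  if (!length(supports) || any(supports < 0))
    stop("supports must be non-empty and non-negative")
  total <- sum(supports)
  if (total == 0) stop("total support must be > 0")
  p <- max(supports) / total
  p * (2 * p / (1 + p))
}

# ---- TSV input/output ------------------------------------------------------

#' Read a confusion matrix from TSV
#'
#' Expects a header row of predicted labels and a first column of gold
#' labels (the layout written by \code{\link{write_confusion_tsv}}).
#' @param path input path.
#' @export
read_confusion_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  labels <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (!identical(colnames(m), labels))
    stop("row and column labels disagree in ", path)
  rownames(m) <- labels
  confusion_matrix(m, labels)
}

#' Write a confusion matrix as TSV
#' @param matrix a \code{confusion_matrix}.
#' @param path output path.
#' @export
write_confusion_tsv <- function(matrix, path) {
  df <- data.frame(label = rownames(matrix), as.data.frame(unclass(matrix)),
                   check.names = FALSE)
  names(df)[1L] <- "label"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report as TSV
#' @param report an \code{eval_report}.
#' @param path output path.
#' @export
write_report_tsv <- function(report, path) {
  df <- as.data.frame(report)
  df$weighted_F1 <- attr(report, "weighted_F1")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
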