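test_that("the published discourse confusion matrix reproduces its metric table", {
  r <- report_from_matrix(discourse_confusion_fixture())
  rr <- function(x) discoseg:::round_half_up(x, 2L)
  expected <- data.frame(
    label = discourse_labels(),
    support = c(2L, 53L, 36L, 30L, 98L, 182L, 44L),
    predictions = c(2L, 30L, 17L, 26L, 90L, 216L, 64L),
    correct = c(0L, 14L, 12L, 18L, 66L, 147L, 31L),
    precision = c(0.00, 0.47, 0.71, 0.69, 0.73, 0.68, 0.48),
    recall = c(0.00, 0.26, 0.33, 0.60, 0.67, 0.81, 0.70),
    f1 = c(0.00, 0.34, 0.45, 0.64, 0.70, 0.74, 0.57))
  expect_equal(r$label, expected$label)
  expect_equal(r$support, expected$support)
  expect_equal(r$predictions, expected$predictions)
  expect_equal(r$correct, expected$correct)
  expect_equal(rr(r$precision), expected$precision)
  expect_equal(rr(r$recall), expected$recall)
  expect_equal(rr(r$f1), expected$f1)
  expect_equal(rr(weighted_f1(r)), 0.63)
})

test_that("identity matrices score perfectly and invalid matrices are rejected", {
  r <- report_from_matrix(confusion_matrix(diag(3L) * 5L, c("a", "b", "c")))
  expect_true(all(r$precision == 1))
  expect_true(all(r$recall == 1))
  expect_equal(weighted_f1(r), 1)
  expect_error(confusion_matrix(matrix(1, 2, 3)), "square")
  expect_error(confusion_matrix(matrix(-1, 2, 2)), ">= 0")
})

test_that("reports agree with a per-item expansion oracle on random matrices", {
  set.seed(7)
  for (trial in 1:25) {
    k <- sample(2:6, 1L)
    cm <- random_confusion(k)
    r <- report_from_matrix(cm)
    o <- oracle_report(cm)
    expect_equal(r$precision, unname(o$per[, "precision"]))
    expect_equal(r$recall, unname(o$per[, "recall"]))
    expect_equal(r$f1, unname(o$per[, "f1"]))
    expect_equal(weighted_f1(r), o$weighted_F1)
  }
})

test_that("matrix_from_predictions counts pairs correctly", {
  cm <- matrix_from_predictions(character(), character(), c("a", "b"))
  expect_true(all(cm == 0))
  cm1 <- matrix_from_predictions("a", "a", c("a", "b"))
  expect_equal(as.vector(unclass(cm1)), c(1L, 0L, 0L, 0L))
  expect_error(matrix_from_predictions("a", "z", c("a", "b")), "z")
  set.seed(11)
  gold <- sample(letters[1:4], 1000L, replace = TRUE)
  pred <- sample(letters[1:4], 1000L, replace = TRUE)
  cm2 <- matrix_from_predictions(gold, pred, letters[1:4])
  expect_equal(unname(rowSums(cm2)), as.vector(table(gold)))
  expect_equal(unname(colSums(cm2)), as.vector(table(pred)))
})

test_that("most-frequent baseline matches its closed form and construction", {
  expect_equal(discoseg:::round_half_up(
    most_frequent_baseline(c(57, 332, 125, 34, 33)), 2L), 0.42)
  expect_equal(most_frequent_baseline(10), 1.0)
  expect_equal(most_frequent_baseline(c(5, 5)), 1 / 3)
  expect_error(most_frequent_baseline(c(0, 0)), "> 0")
  # closed form equals the report of the explicit constant-predictor matrix
  set.seed(13)
  for (trial in 1:25) {
    k <- sample(2:7, 1L)
    s <- sample(0:40, k, replace = TRUE)
    if (sum(s) == 0) s[1L] <- 1L
    m <- matrix(0L, k, k)
    m[, which.max(s)] <- s
    built <- weighted_f1(report_from_matrix(confusion_matrix(m, paste0("c", 1:k))))
    expect_equal(most_frequent_baseline(s), built)
  }
})

test_that("weighted F1 is invariant under label permutation", {
  set.seed(17)
  for (trial in 1:10) {
    cm <- random_confusion(5L)
    perm <- sample(5L)
    cm2 <- confusion_matrix(unclass(cm)[perm, perm], rownames(cm)[perm])
    expect_equal(weighted_f1(report_from_matrix(cm)),
                 weighted_f1(report_from_matrix(cm2)))
  }
})

test_that("confusion matrices and reports round-trip through TSV", {
  cm <- caption_confusion_fixture()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_confusion_tsv(cm, p)
  back <- read_confusion_tsv(p)
  expect_equal(unclass(back), unclass(cm))
  # shipped fixture of the same table matches the in-code fixture
  shipped <- read_confusion_tsv(system.file("extdata",
    "table_caption_confusion.tsv", package = "discoseg"))
  expect_equal(unclass(shipped), unclass(cm))
  shipped_disc <- read_confusion_tsv(system.file("extdata",
    "table_discourse_confusion.tsv", package = "discoseg"))
  expect_equal(unclass(shipped_disc), unclass(discourse_confusion_fixture()))
})
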