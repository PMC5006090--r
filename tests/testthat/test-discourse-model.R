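make_seqs <- function(seed = 1L, n_documents = 5L) {
  corpus <- small_corpus(seed = seed, n_documents = n_documents)
  clause_sequences(corpus$clauses, corpus$documents)
}

test_that("degenerate training sets are rejected with the missing classes named", {
  seqs <- make_seqs()
  one_label <- lapply(seqs[1:3], function(s) {
    s$clauses$gold_label <- "result"
    s
  })
  expect_error(discourse_model(one_label, "svm"), "missing classes")
  expect_error(discourse_model(one_label, "crf"), "missing classes")
  expect_error(discourse_model(list(), "crf"), "empty")
})

test_that("training is deterministic: same seed, same predictions", {
  seqs <- make_seqs(seed = 2L)
  parts <- split_sequences(seqs, 0.25, seed = 2L)
  for (kind in c("svm", "crf")) {
    m1 <- discourse_model(parts$train, kind, seed = 7L)
    m2 <- discourse_model(parts$train, kind, seed = 7L)
    p1 <- predict(m1, parts$test)
    p2 <- predict(m2, parts$test)
    expect_identical(p1$predicted_label, p2$predicted_label)
  }
})

test_that("predictions are closed over the seven discourse types", {
  seqs <- make_seqs(seed = 3L)
  for (kind in c("svm", "crf")) {
    model <- discourse_model(seqs, kind, seed = 1L)
    lab <- predict(model, seqs)
    expect_true(all(lab$predicted_label %in% discourse_labels()))
    expect_false(any(lab$predicted_label == "none"))
    # input order preserved
    expect_equal(lab$text,
                 unlist(lapply(seqs, function(s) s$clauses$text)))
  }
})

test_that("single-clause sequences are valid chains", {
  seqs <- make_seqs(seed = 4L)
  model <- discourse_model(seqs, "crf", seed = 1L)
  single <- list(list(clauses = seqs[[1L]]$clauses[1L, , drop = FALSE],
                      features = seqs[[1L]]$features[1L]))
  lab <- predict(model, single)
  expect_equal(nrow(lab), 1L)
  expect_true(lab$predicted_label %in% discourse_labels())
})

test_that("models beat the most-frequent-class baseline on training data", {
  seqs <- make_seqs(seed = 5L)
  gold <- unlist(lapply(seqs, function(s) s$clauses$gold_label))
  base <- most_frequent_baseline(as.integer(
    table(factor(gold, levels = discourse_labels()))))
  for (kind in c("svm", "crf")) {
    model <- discourse_model(seqs, kind, seed = 1L)
    rep <- evaluate_labels(predict(model, seqs))
    expect_gt(weighted_f1(rep), base)
  }
})

test_that("a result clause with its cues is labeled result in context", {
  seqs <- make_seqs(seed = 6L, n_documents = 8L)
  model <- discourse_model(seqs, "crf", seed = 1L)
  lab <- predict(model, seqs)
  hits <- grepl("data not shown", lab$text, fixed = TRUE)
  expect_gt(sum(hits), 0L)
  expect_gt(mean(lab$predicted_label[hits] == "result"), 0.9)
})

test_that("without ordering signal the CRF and SVM perform alike", {
  prior <- reference_label_prior()
  diffs <- sapply(1:5, function(s) {
    res <- benchmark_discourse(
      corpus_spec(n_documents = 5L,
                  transitions = iid_transitions(prior),
                  start_dist = prior, seed = s))
    weighted_f1(res$crf$report) - weighted_f1(res$svm$report)
  })
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("schema version mismatches are refused at predict time", {
  seqs <- make_seqs(seed = 7L, n_documents = 3L)
  model <- discourse_model(seqs, "crf", seed = 1L)
  tampered <- lapply(seqs, function(s) {
    s$features <- lapply(s$features, function(f) {
      attr(f, "schema_version") <- "999"
      f
    })
    s
  })
  expect_error(predict(model, tampered), "schema_version")
  p <- withr::local_tempfile(fileext = ".json")
  save_discourse_model(model, p)
  back <- load_discourse_model(p)
  lab1 <- predict(model, seqs)
  lab2 <- predict(back, seqs)
  expect_equal(lab1$predicted_label, lab2$predicted_label)
  # a stored model with a foreign schema version is refused
  obj <- jsonlite::fromJSON(p)
  obj$schema_version <- "999"
  jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
  expect_error(load_discourse_model(p), "schema")
})

test_that("CRF coefficients expose informative transition structure", {
  seqs <- make_seqs(seed = 8L, n_documents = 8L)
  model <- discourse_model(seqs, "crf", seed = 1L)
  co <- coef(model)
  expect_equal(dim(co$transitions), c(7L, 7L))
  # the archetypal forward steps outweigh their reverses
  expect_gt(co$transitions["goal", "method"],
            co$transitions["method", "goal"])
  expect_gt(co$transitions["method", "result"],
            co$transitions["result", "method"])
  expect_gt(co$transitions["result", "implication"],
            co$transitions["implication", "result"])
})
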