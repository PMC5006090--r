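test_that("cue features fire on the attested lexicon phrases", {
  cl <- data.frame(text = "it is possible that RAF1 binds MEK1",
                   start = 0L, end = 35L)
  f <- extract_features(cl)
  expect_true("cue:possible" %in% names(f))
  expect_equal(lookup_cue(default_lexicon(), "possible"), "hypothesis")

  cl2 <- data.frame(text = "binding increased, data not shown",
                    start = 0L, end = 33L)
  f2 <- extract_features(cl2)
  expect_true("cue:data_not_shown" %in% names(f2))
  expect_equal(lookup_cue(default_lexicon(), "data not shown"), "result")

  expect_equal(lookup_cue(default_lexicon(), "suggest"), "implication")
  expect_equal(lookup_cue(default_lexicon(), "demonstrate"), "implication")
  expect_true(is.na(lookup_cue(default_lexicon(), "zzz")))
})

test_that("empty clause text yields an empty vector with a schema version", {
  f <- extract_features(data.frame(text = "", start = 0L, end = 0L))
  expect_length(f, 0L)
  expect_equal(attr(f, "schema_version"), discoseg:::FEATURE_SCHEMA_VERSION)
})

test_that("feature extraction is a pure function of its inputs", {
  d <- tiny_document()
  cl <- segment_document(d)
  f1 <- extract_features(cl[3L, ], d)
  f2 <- extract_features(cl[3L, ], d)
  expect_identical(f1, f2)
})

test_that("link features come from annotations intersecting the clause span", {
  d <- tiny_document()
  cl <- segment_document(d, kinds = "results")
  has_fig <- vapply(seq_len(nrow(cl)), function(i)
    "link:figure" %in% names(extract_features(cl[i, ], d)), logical(1L))
  has_cit <- vapply(seq_len(nrow(cl)), function(i)
    "link:citation" %in% names(extract_features(cl[i, ], d)), logical(1L))
  expect_true(any(has_fig))
  expect_true(any(has_cit))
  # the figure reference sits in the clause containing "(Fig. 2B)"
  expect_true(all(grepl("Fig", cl$text[has_fig])))
  expect_true(all(grepl("\\[", cl$text[has_cit])))
})

test_that("removing the lexicon removes exactly the cue features", {
  d <- tiny_document()
  cl <- segment_document(d, kinds = "results")
  for (i in seq_len(nrow(cl))) {
    with_lex <- extract_features(cl[i, ], d)
    no_lex <- extract_features(cl[i, ], d, lexicon = c())
    cue <- grepl("^cue:", names(with_lex))
    expect_identical(with_lex[!cue], no_lex[names(with_lex)[!cue]])
    expect_false(any(grepl("^cue:", names(no_lex))))
  }
})

test_that("user lexicon files override shipped entries key by key", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("possible\tfact", "novel phrase\tgoal"), p)
  lex <- read_lexicon(p)
  expect_equal(lookup_cue(lex, "possible"), "fact")       # overridden
  expect_equal(lookup_cue(lex, "novel phrase"), "goal")   # added
  expect_equal(lookup_cue(lex, "suggest"), "implication") # kept from base
})

test_that("the rule tagger produces Penn-style tags for verbs and adverbs", {
  tags <- pos_tag_rules(c("We", "observed", "markedly", "increased",
                          "binding", "of", "RAF1"))
  expect_equal(tags[1L], "PRP")
  expect_true(startsWith(tags[2L], "VB"))
  expect_equal(tags[3L], "RB")
  expect_equal(tags[6L], "IN")
  expect_equal(tags[7L], "NNP")
  # a misconfigured tagger is reported as a configuration error
  expect_error(extract_features(data.frame(text = "x", start = 0L, end = 1L),
                                tagger = NULL), "tagger")
})

test_that("'none'-labeled clauses and headings are excluded from sequences", {
  cl <- data.frame(doc_id = "d", section_idx = 0L,
                   sentence_idx = 0:2, clause_idx = 0L,
                   start = c(0L, 10L, 20L), end = c(8L, 18L, 28L),
                   text = c("RESULTS", "we observed binding", "so it binds"),
                   heading = c(TRUE, FALSE, FALSE),
                   gold_label = c("none", "result", "implication"),
                   stringsAsFactors = FALSE)
  seqs <- clause_sequences(cl)
  expect_length(seqs, 1L)
  expect_equal(nrow(seqs[[1L]]$clauses), 2L)
  expect_false(any(seqs[[1L]]$clauses$gold_label == "none"))
})
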