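# helper: build a document whose results section has the given paragraphs
make_linked_doc <- function(paragraphs, doc_id = "d1") {
  text <- paste(paragraphs, collapse = "\n\n")
  document(doc_id, text,
           sections = data.frame(kind = "results", start = 0L,
                                 end = nchar(text), heading = NA),
           figure_refs = detect_figure_refs(text),
           citations = detect_citations(text))
}

test_that("paragraphs link to the subfigures they reference, in mention order", {
  d <- make_linked_doc(c(
    "We measured binding in Fig. 2B, 2C, 2E, 3A and 3B of this work.",
    "This paragraph has no figure reference at all.",
    "A later paragraph also cites Fig. 2B again."))
  p <- link_paragraphs(d)
  expect_equal(nrow(p), 2L)           # middle paragraph contributes nothing
  expect_equal(nrow(p$subfigures[[1L]]), 5L)
  expect_equal(p$subfigures[[1L]]$subfigure, c("B", "C", "E", "A", "B"))
  expect_equal(p$subfigures[[1L]]$figure, c(2L, 2L, 2L, 3L, 3L))
  # same subfigure in two paragraphs: two separate passages, no merging
  expect_equal(p$subfigures[[2L]]$subfigure, "B")
})

test_that("linking is invariant to citation annotations", {
  base <- "Binding rose in Fig. 1A as expected."
  d1 <- make_linked_doc(base)
  d2 <- make_linked_doc(paste(base, "This matches prior work [12]."))
  p1 <- link_paragraphs(d1); p2 <- link_paragraphs(d2)
  expect_equal(p1$subfigures, p2$subfigures)
})

test_that("single-type filtering conserves passages and reproduces kept counts", {
  # fixture with the multi-code proportions of the two curated corpora:
  # 372 passages of which 114 multi-code, and 359 of which 136 multi-code
  build_fixture <- function(n_total, n_multi, doc_id) {
    n_single <- n_total - n_multi
    passages <- data.frame(
      doc_id = doc_id, source = "narrative",
      text = sprintf("passage %d", seq_len(n_total)),
      stringsAsFactors = FALSE)
    passages$subfigures <- c(
      lapply(seq_len(n_single), function(i)
        data.frame(figure = i, subfigure = "A", stringsAsFactors = FALSE)),
      lapply(seq_len(n_multi), function(i)
        data.frame(figure = n_single + i, subfigure = c("A", "B"),
                   stringsAsFactors = FALSE)))
    gold <- do.call(rbind, lapply(seq_len(n_total), function(i) {
      if (i <= n_single)
        data.frame(doc_id = doc_id, figure = i, subfigure = "A",
                   code = "copptby", stringsAsFactors = FALSE)
      else
        data.frame(doc_id = doc_id, figure = i,
                   subfigure = c("A", "B"), code = c("copptby", "phos"),
                   stringsAsFactors = FALSE)
    }))
    list(passages = passages, gold = gold)
  }
  pl <- build_fixture(372L, 114L, "pl")
  res <- filter_single_type(pl$passages, pl$gold)
  expect_equal(nrow(res$kept), 258L)
  expect_equal(nrow(res$discarded), 114L)
  mint <- build_fixture(359L, 136L, "mint")
  res2 <- filter_single_type(mint$passages, mint$gold)
  expect_equal(nrow(res2$kept), 223L)
  # conservation
  expect_equal(nrow(res$kept) + nrow(res$discarded) + nrow(res$unmapped),
               nrow(pl$passages))
  # all-single-code corpus discards nothing
  all_single <- build_fixture(10L, 0L, "s")
  res3 <- filter_single_type(all_single$passages, all_single$gold)
  expect_equal(nrow(res3$discarded), 0L)
})

test_that("unmapped subfigures are warned about and counted separately", {
  passages <- data.frame(doc_id = "d", source = "narrative", text = "p",
                         stringsAsFactors = FALSE)
  passages$subfigures <- list(data.frame(figure = 9L, subfigure = "Z"))
  gold <- data.frame(doc_id = "d", figure = 1L, subfigure = "A",
                     code = "phos", stringsAsFactors = FALSE)
  expect_warning(res <- filter_single_type(passages, gold), "absent")
  expect_equal(nrow(res$unmapped), 1L)
  expect_equal(nrow(res$kept) + nrow(res$discarded) + nrow(res$unmapped), 1L)
})

test_that("category merging sums counts before ranking and breaks ties by code", {
  counts <- c("MI:0007" = 40L, "MI:0006" = 30L, "MI:0018" = 50L,
              "MI:0096" = 20L, "MI:0416" = 5L)
  mm <- data.frame(leaf_code = c("MI:0007", "MI:0006"),
                   merged_code = c("MI:0019", "MI:0019"),
                   stringsAsFactors = FALSE)
  out <- merge_categories(counts, mm, top_k = 2L)
  expect_equal(out$code, c("MI:0019", "MI:0018"))   # 70 > 50
  expect_equal(out$count, c(70, 50))
  # top_k = 1 keeps only the most frequent
  expect_equal(nrow(merge_categories(counts, mm, 1L)), 1L)
  # ties broken by code string order
  tied <- c(b = 5L, a = 5L, c = 1L)
  expect_equal(merge_categories(tied, NULL, 2L)$code, c("a", "b"))
  expect_warning(merge_categories(tied, NULL, 99L), "exceeds")
})

test_that("caption linking assigns one subfigure per caption passage", {
  d <- tiny_document()
  cp <- link_captions(d)
  expect_equal(nrow(cp), 2L)
  expect_equal(vapply(cp$subfigures, nrow, integer(1L)), c(1L, 1L))
  expect_equal(cp$subfigures[[1L]]$figure, 2L)  # from heading "Figure 2"
  expect_equal(cp$subfigures[[1L]]$subfigure, "A")
})
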