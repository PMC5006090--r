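test_that("plain and empty inputs produce well-formed documents", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), p, sep = "")
  d <- read_document(p, "plain")
  expect_s3_class(d, "discoseg_document")
  expect_equal(nrow(d$sections), 0L)
  expect_equal(nrow(d$figure_refs), 0L)

  writeLines("Binding increased.", p, sep = "")
  d2 <- read_document(p, "plain")
  expect_equal(d2$sections$kind, "results")
  expect_equal(d2$sections$end, nchar(d2$text))
})

test_that("jsonl round-trip is the identity, field for field and byte for byte", {
  doc <- tiny_document()
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_documents(doc, p)
  back <- read_document(p, "jsonl")
  expect_equal(back$doc_id, doc$doc_id)
  expect_equal(back$text, doc$text)
  expect_equal(back$sections, doc$sections)
  expect_equal(back$figure_refs, doc$figure_refs)
  expect_equal(back$citations, doc$citations)
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_documents(back, p2)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("bioc-xml-subset reader recovers annotations at the right offsets", {
  xml <- paste0(
    '<collection><document id="d9">',
    '<passage kind="results"><text>Binding rose (Fig. 2B) as reported.</text>',
    '<xref type="fig" figure="2" subfigure="b" offset="19" length="2"/>',
    '<xref type="bibr" offset="26" length="8"/>',
    "</passage></document></collection>")
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, p)
  d <- read_document(p, "bioc-xml-subset")
  expect_equal(d$doc_id, "d9")
  expect_equal(nrow(d$figure_refs), 1L)
  # hand-counted: "2B" starts at 0-based offset 19 of the passage text
  expect_equal(d$figure_refs$start, 19L)
  expect_equal(d$figure_refs$end, 21L)
  expect_equal(substr(d$text, 20, 21), "2B")
  expect_equal(d$figure_refs$subfigure, "B")
  expect_equal(d$citations$style, "markup")

  writeLines("<collection><document><bogus/>", p)
  expect_error(read_document(p, "bioc-xml-subset"), "malformed")

  writeLines(paste0("<collection><document id='d'><passage>",
                    "<text>x</text><junk/></passage></document></collection>"), p)
  expect_warning(read_document(p, "bioc-xml-subset"), "junk")
})

test_that("figure-mention grammar expands conjoined subfigure lists", {
  txt <- paste0("The results of five separate experiments are shown in ",
                "Fig. 2B, 2C, 2E, 3A and 3B of this study.")
  fr <- detect_figure_refs(txt)
  expect_equal(nrow(fr), 5L)
  expect_equal(fr$figure, c(2L, 2L, 2L, 3L, 3L))
  expect_equal(fr$subfigure, c("B", "C", "E", "A", "B"))
  expect_true(all(diff(fr$start) > 0))
  for (i in seq_len(nrow(fr)))
    expect_equal(substr(txt, fr$start[i] + 1, fr$end[i]),
                 paste0(fr$figure[i], fr$subfigure[i]))

  expect_equal(nrow(detect_figure_refs("no figures here")), 0L)

  f3 <- detect_figure_refs("Figure 3")
  expect_equal(f3$figure, 3L)
  expect_true(is.na(f3$subfigure))

  # bare letters carry the figure number forward; case is normalized
  fb <- detect_figure_refs("see Fig. 2a and B for details")
  expect_equal(fb$subfigure, c("A", "B"))
  expect_equal(fb$figure, c(2L, 2L))

  # bare parenthesized panels need an anchor earlier in the same sentence
  expect_equal(nrow(detect_figure_refs("values rose sharply (2B, 2C)")), 0L)
  anchored <- detect_figure_refs(
    "As shown in Fig. 2, binding rose sharply (2B, 2C).")
  expect_true(all(c("B", "C") %in% anchored$subfigure))
})

test_that("citation detection finds both styles and never figure parentheticals", {
  ci <- detect_citations("as shown previously [3,7]")
  expect_equal(nrow(ci), 1L)
  expect_equal(ci$style, "numeric-bracket")
  expect_equal(nrow(detect_citations("")), 0L)
  expect_equal(nrow(detect_citations("(2B)")), 0L)
  ay <- detect_citations("as reported (Smith et al., 2004)")
  expect_equal(ay$style, "author-year")
  # disjointness with figure refs on mixed text
  txt <- "Binding rose (Fig. 2B) as in [12] and (Jones and Lee, 1999)."
  fr <- detect_figure_refs(txt); cz <- detect_citations(txt)
  expect_equal(nrow(cz), 2L)
  for (i in seq_len(nrow(cz)))
    expect_false(any(cz$start[i] < fr$end & fr$start < cz$end[i]))
})

test_that("caption splitting yields lettered subfigure sentences", {
  out <- extract_caption_subfigures("(A) Lysates were blotted. (B) Quantification.")
  expect_equal(out$subfigure, c("A", "B"))
  expect_equal(out$text, c("Lysates were blotted.", "Quantification."))
  expect_equal(nrow(extract_caption_subfigures("Overview of the pathway.")), 0L)
  dup <- extract_caption_subfigures("(A) x (A) y")
  expect_equal(dup$subfigure, c("A", "A"))
  expect_equal(dup$text, c("x", "y"))
  # concatenated texts are a subsequence of the caption
  cap <- "(A) First panel. (B) Second panel with detail. (C) Third."
  out2 <- extract_caption_subfigures(cap)
  pos <- 0L
  for (t in out2$text) {
    hit <- regexpr(t, substring(cap, pos + 1L), fixed = TRUE)
    expect_gt(hit, 0L)
    pos <- pos + as.integer(hit) + nchar(t) - 1L
  }
})

test_that("document constructor enforces span and kind invariants", {
  expect_error(document("d", "abc",
    sections = data.frame(kind = "results", start = 0L, end = 9L)),
    "out of bounds")
  expect_error(document("d", "abcdef",
    sections = data.frame(kind = c("results", "other"),
                          start = c(0L, 2L), end = c(4L, 6L))),
    "overlap")
  expect_error(document("d", "abc",
    sections = data.frame(kind = "weird", start = 0L, end = 3L)),
    "unknown section kind")
  expect_error(document("d", "abcdef",
    figure_refs = data.frame(figure = 1L, subfigure = "AB",
                             start = 0L, end = 2L)),
    "single letter")
})
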