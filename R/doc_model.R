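#' @importFrom stats optim predict rbinom rmultinom rpois runif setNames
#' @importFrom utils head read.delim write.table
NULL

# ---- document container ----------------------------------------------------
# All spans are 0-based, half-open [start, end) character offsets into the
# document text. This convention is used by every module in the package.

#' Construct a document
#'
#' A document is the unit the toolkit consumes: the full character sequence of
#' an article (or a fragment such as a Results section), plus stand-off
#' annotations for sections, figure references and citations. All spans are
#' 0-based half-open character intervals into \code{text}.
#'
#' @param doc_id opaque identifier string.
#' @param text full character sequence of the document.
#' @param sections data frame with columns \code{kind} (one of
#'   \code{"results"}, \code{"caption"}, \code{"other"}), \code{start},
#'   \code{end}, and optionally \code{heading}.
#' @param figure_refs data frame with columns \code{figure} (positive
#'   integer), \code{subfigure} (single uppercase letter or \code{NA}),
#'   \code{start}, \code{end}.
#' @param citations data frame with columns \code{start}, \code{end},
#'   \code{style} (one of \code{"numeric-bracket"}, \code{"author-year"},
#'   \code{"markup"}).
#' @return an object of class \code{discoseg_document}.
#' @export
document <- function(doc_id, text, sections = empty_sections(),
                     figure_refs = empty_figure_refs(),
                     citations = empty_citations()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  sections <- as_sections(sections)
  figure_refs <- as_figure_refs(figure_refs)
  citations <- as_citations(citations)
  n <- nchar(text)
  check_spans(sections, n, "sections")
  check_spans(figure_refs, n, "figure_refs")
  check_spans(citations, n, "citations")
  if (nrow(sections) > 1L) {
    o <- order(sections$start)
    s <- sections[o, , drop = FALSE]
    if (any(s$start[-1L] < s$end[-nrow(s)]))
      stop("sections overlap")
  }
  structure(list(doc_id = doc_id, text = text, sections = sections,
                 figure_refs = figure_refs, citations = citations),
            class = "discoseg_document")
}

#' @export
print.discoseg_document <- function(x, ...) {
  cat(sprintf("<document %s: %d chars, %d section(s), %d figure ref(s), %d citation(s)>\n",
              x$doc_id, nchar(x$text), nrow(x$sections),
              nrow(x$figure_refs), nrow(x$citations)))
  invisible(x)
}

empty_sections <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             heading = character(), stringsAsFactors = FALSE)
}
empty_figure_refs <- function() {
  data.frame(figure = integer(), subfigure = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}
empty_citations <- function() {
  data.frame(start = integer(), end = integer(), style = character(),
             stringsAsFactors = FALSE)
}

as_sections <- function(x) {
  if (is.null(x) || NROW(x) == 0L) return(empty_sections())
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$heading)) x$heading <- NA_character_
  bad <- setdiff(unique(x$kind), c("results", "caption", "other"))
  if (length(bad)) stop("unknown section kind: ", paste(bad, collapse = ", "))
  x[, c("kind", "start", "end", "heading")]
}
as_figure_refs <- function(x) {
  if (is.null(x) || NROW(x) == 0L) return(empty_figure_refs())
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$subfigure)) x$subfigure <- NA_character_
  x$subfigure <- ifelse(is.na(x$subfigure) | x$subfigure == "",
                        NA_character_, toupper(x$subfigure))
  ok <- is.na(x$subfigure) | grepl("^[A-Z]$", x$subfigure)
  if (!all(ok)) stop("subfigure must be a single letter")
  if (any(x$figure < 1)) stop("figure numbers must be positive")
  x$figure <- as.integer(x$figure)
  x[, c("figure", "subfigure", "start", "end")]
}
as_citations <- function(x) {
  if (is.null(x) || NROW(x) == 0L) return(empty_citations())
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  bad <- setdiff(unique(x$style), c("numeric-bracket", "author-year", "markup"))
  if (length(bad)) stop("unknown citation style: ", paste(bad, collapse = ", "))
  if (any(x$end <= x$start)) stop("citation spans must be non-empty")
  x[, c("start", "end", "style")]
}

check_spans <- function(df, n, what) {
  if (nrow(df) == 0L) return(invisible())
  if (any(df$start < 0L) || any(df$end > n) || any(df$start > df$end))
    stop("annotation span out of bounds in ", what)
  invisible()
}

# ---- readers / writers -----------------------------------------------------

#' Read documents from a file
#'
#' Three dialects are supported: \code{"plain"} (the whole file is one
#' document whose text is a single results-kind section), \code{"jsonl"} (one
#' JSON object per line with keys \code{doc_id}, \code{text},
#' \code{sections}, \code{figure_refs}, \code{citations}; round-trips
#' bit-exactly through \code{\link{write_documents}}), and
#' \code{"bioc-xml-subset"} (a minimal XML dialect with \code{<passage>},
#' \code{<text>} and \code{<xref type="fig|bibr">} elements; other elements
#' are ignored with a warning).
#'
#' @param path path to the input file.
#' @param format one of \code{"plain"}, \code{"jsonl"},
#'   \code{"bioc-xml-subset"}.
#' @param doc_id identifier used for \code{format = "plain"} (defaults to the
#'   file name without extension).
#' @return a list of \code{discoseg_document} objects.
#' @export
read_documents <- function(path, format = c("jsonl", "plain", "bioc-xml-subset"),
                           doc_id = NULL) {
  format <- match.arg(format)
  switch(format,
         plain = {
           txt <- readChar(path, file.size(path), useBytes = FALSE)
           Encoding(txt) <- "UTF-8"
           if (is.null(doc_id))
             doc_id <- tools::file_path_sans_ext(basename(path))
           if (nchar(txt) == 0L)
             return(list(document(doc_id, txt)))
           list(document(doc_id, txt,
                         sections = data.frame(kind = "results", start = 0L,
                                               end = nchar(txt),
                                               heading = NA_character_)))
         },
         jsonl = {
           lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
           lines <- lines[nzchar(trimws(lines))]
           lapply(lines, function(l) document_from_json(jsonlite::fromJSON(l,
             simplifyDataFrame = TRUE)))
         },
         `bioc-xml-subset` = read_bioc_subset(path))
}

#' Read a single document
#'
#' Convenience wrapper around \code{\link{read_documents}} for files holding
#' exactly one document.
#' @inheritParams read_documents
#' @return a \code{discoseg_document}.
#' @export
read_document <- function(path, format = c("jsonl", "plain", "bioc-xml-subset"),
                          doc_id = NULL) {
  docs <- read_documents(path, format, doc_id)
  if (length(docs) != 1L)
    stop("expected exactly one document, found ", length(docs))
  docs[[1L]]
}

document_from_json <- function(x) {
  document(doc_id = x$doc_id, text = x$text,
           sections = x$sections, figure_refs = x$figure_refs,
           citations = x$citations)
}

document_to_json <- function(doc) {
  secs <- lapply(seq_len(nrow(doc$sections)), function(i) {
    s <- doc$sections[i, ]
    out <- list(kind = s$kind, start = s$start, end = s$end)
    if (!is.na(s$heading)) out$heading <- s$heading
    out
  })
  frs <- lapply(seq_len(nrow(doc$figure_refs)), function(i) {
    f <- doc$figure_refs[i, ]
    out <- list(figure = f$figure)
    if (!is.na(f$subfigure)) out$subfigure <- f$subfigure
    out$start <- f$start; out$end <- f$end
    out
  })
  cits <- lapply(seq_len(nrow(doc$citations)), function(i) {
    ci <- doc$citations[i, ]
    list(start = ci$start, end = ci$end, style = ci$style)
  })
  jsonlite::toJSON(list(doc_id = doc$doc_id, text = doc$text,
                        sections = secs, figure_refs = frs, citations = cits),
                   auto_unbox = TRUE, digits = NA)
}

#' Write documents as JSON lines
#'
#' One JSON object per document; \code{read_documents(..., "jsonl")} restores
#' the objects field-for-field.
#' @param docs a \code{discoseg_document} or list of them.
#' @param path output path.
#' @export
write_documents <- function(docs, path) {
  if (inherits(docs, "discoseg_document")) docs <- list(docs)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (d in docs)
    writeLines(as.character(document_to_json(d)), con, useBytes = TRUE)
  invisible(path)
}

read_bioc_subset <- function(path) {
  xml <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in ", path, ": ", conditionMessage(e), call. = FALSE))
  docs <- xml2::xml_find_all(xml, ".//document")
  if (length(docs) == 0L && xml2::xml_name(xml) == "document") docs <- list(xml)
  lapply(docs, function(dnode) {
    doc_id <- xml2::xml_attr(dnode, "id")
    if (is.na(doc_id)) doc_id <- "doc"
    known <- c("passage", "text", "xref")
    extra <- setdiff(unique(xml2::xml_name(xml2::xml_find_all(dnode, ".//*"))),
                     known)
    if (length(extra))
      warning("ignoring unrecognized element(s): ",
              paste(extra, collapse = ", "), call. = FALSE)
    passages <- xml2::xml_find_all(dnode, "./passage")
    text <- ""
    secs <- empty_sections(); frs <- empty_figure_refs(); cits <- empty_citations()
    for (p in passages) {
      ptxt <- xml2::xml_text(xml2::xml_find_first(p, "./text"))
      if (is.na(ptxt)) ptxt <- ""
      base <- nchar(text)
      if (base > 0L) { text <- paste0(text, "\n\n"); base <- base + 2L }
      kind <- xml2::xml_attr(p, "kind")
      if (is.na(kind) || !kind %in% c("results", "caption", "other"))
        kind <- "other"
      heading <- xml2::xml_attr(p, "heading")
      secs <- rbind(secs, data.frame(kind = kind, start = base,
                                     end = base + nchar(ptxt),
                                     heading = heading,
                                     stringsAsFactors = FALSE))
      for (x in xml2::xml_find_all(p, "./xref")) {
        off <- as.integer(xml2::xml_attr(x, "offset"))
        len <- as.integer(xml2::xml_attr(x, "length"))
        type <- xml2::xml_attr(x, "type")
        if (is.na(off) || is.na(len)) next
        if (identical(type, "fig")) {
          frs <- rbind(frs, data.frame(
            figure = as.integer(xml2::xml_attr(x, "figure")),
            subfigure = toupper(xml2::xml_attr(x, "subfigure")),
            start = base + off, end = base + off + len,
            stringsAsFactors = FALSE))
        } else if (identical(type, "bibr")) {
          cits <- rbind(cits, data.frame(start = base + off,
                                         end = base + off + len,
                                         style = "markup",
                                         stringsAsFactors = FALSE))
        }
      }
      text <- paste0(text, ptxt)
    }
    document(doc_id, text, secs, frs, cits)
  })
}

# ---- figure-reference / citation detection ---------------------------------

fig_anchor_re <- "(?:Figures?|Figs?\\.?)"
fig_token_re <- "([0-9]+)\\s*([A-Za-z])?\\b"

#' Detect figure references in text
#'
#' Figure mentions are matched by a grammar anchored on the tokens
#' \code{Fig.}, \code{Fig}, \code{Figs}, \code{Figure} or \code{Figures}
#' followed by an integer and optional panel letter. Conjoined lists
#' ("Fig. 2B, 2C and 2E") yield one reference per panel, carrying the figure
#' number forward for bare letters ("Fig. 2A and B"). Bare panel tokens
#' inside parentheses ("(2B, 3A)") are accepted only when an anchor token
#' occurred earlier in the same sentence. Panel letters are normalized to
#' uppercase.
#'
#' @param text a character string.
#' @return data frame with columns \code{figure}, \code{subfigure},
#'   \code{start}, \code{end} (0-based half-open spans), in text order.
#' @export
detect_figure_refs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- empty_figure_refs()
  if (!nzchar(text)) return(out)
  refs <- list()
  push <- function(fig, sub, start, end) {
    refs[[length(refs) + 1L]] <<- list(
      figure = as.integer(fig),
      subfigure = if (is.na(sub) || !nzchar(sub)) NA_character_ else toupper(sub),
      start = start, end = end)
  }
  anchors <- gregexpr(fig_anchor_re, text, perl = TRUE)[[1L]]
  anchor_pos <- if (anchors[1L] == -1L) integer() else as.integer(anchors)
  # scan a run of reference tokens starting at 1-based position `at`;
  # capture positions from PCRE give exact token spans
  scan_run <- function(at, cur_fig) {
    repeat {
      rest <- substring(text, at)
      m <- regexpr("^\\s*([0-9]+)\\s*([A-Za-z])?\\b", rest, perl = TRUE)
      advanced <- FALSE
      if (m != -1L) {
        cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
        num <- substr(rest, cs[1L], cs[1L] + cl[1L] - 1L)
        let <- if (cl[2L] > 0L) substr(rest, cs[2L], cs[2L] + cl[2L] - 1L)
               else NA_character_
        tok_start <- at + cs[1L] - 1L                       # 1-based in text
        tok_end <- at + (if (cl[2L] > 0L) cs[2L] + cl[2L] - 1L
                         else cs[1L] + cl[1L] - 1L) - 1L    # inclusive
        push(num, let, tok_start - 1L, tok_end)             # to 0-based [s,e)
        cur_fig <- as.integer(num)
        at <- tok_end + 1L
        advanced <- TRUE
      } else if (!is.na(cur_fig)) {
        # bare letter continuing the current figure: "Fig. 2A and B"
        m2 <- regexpr("^([A-Za-z])\\b", rest, perl = TRUE)
        if (m2 != -1L) {
          push(cur_fig, substr(rest, 1L, 1L), at - 1L, at)
          at <- at + 1L
          advanced <- TRUE
        }
      }
      if (!advanced) break
      sep <- regexpr("^\\s*(?:,|;|and|&|or)\\s+|^\\s*(?:,|;|&)\\s*",
                     substring(text, at), perl = TRUE)
      if (sep == -1L) break
      at <- at + attr(sep, "match.length")
    }
    at
  }
  for (ap in anchor_pos) {
    alen <- attr(regexpr(fig_anchor_re, substring(text, ap), perl = TRUE),
                 "match.length")
    scan_run(ap + alen, NA_integer_)
  }
  # bare parenthesized panel lists, licensed by an anchor earlier in sentence;
  # periods belonging to anchor tokens ("Fig.") do not end a sentence here
  chs <- strsplit(text, "")[[1L]]
  period_pos <- which(chs %in% c(".", "!", "?"))
  is_anchor_dot <- vapply(period_pos, function(q)
    q >= 4L && substr(text, q - 3L, q - 1L) %in% c("Fig", "igs"),
    logical(1L))
  sent_breaks <- c(0L, period_pos[!is_anchor_dot])
  parens <- gregexpr("\\(([0-9]+[A-Za-z](\\s*(,|and|&)\\s*[0-9]+[A-Za-z])*)\\)",
                     text, perl = TRUE)[[1L]]
  if (parens[1L] != -1L) {
    for (i in seq_along(parens)) {
      pp <- as.integer(parens[i])
      sb <- max(sent_breaks[sent_breaks < pp])
      has_anchor <- any(anchor_pos > sb & anchor_pos < pp)
      if (has_anchor) scan_run(pp + 1L, NA_integer_)
    }
  }
  if (!length(refs)) return(out)
  df <- do.call(rbind, lapply(refs, function(r)
    data.frame(figure = r$figure, subfigure = r$subfigure,
               start = r$start, end = r$end, stringsAsFactors = FALSE)))
  df <- df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Detect citations in text
#'
#' Matches numeric-bracket citations (\code{[12]}, \code{[3,7]},
#' \code{(12)}) and author-year citations (\code{(Smith et al., 2004)}).
#' Parentheticals that look like figure panels (e.g. \code{(2B)}) are never
#' citations, and spans overlapping detected figure references are dropped,
#' so the two annotation sets are disjoint on any text.
#'
#' @param text a character string.
#' @return data frame with columns \code{start}, \code{end}, \code{style}.
#' @export
detect_citations <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- empty_citations()
  if (!nzchar(text)) return(out)
  add <- function(df, pattern, style) {
    m <- gregexpr(pattern, text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(df)
    rbind(df, data.frame(start = as.integer(m) - 1L,
                         end = as.integer(m) + attr(m, "match.length") - 1L,
                         style = style, stringsAsFactors = FALSE))
  }
  num <- "[0-9]+(\\s*[,–-]\\s*[0-9]+)*"
  out <- add(out, paste0("\\[", num, "\\]"), "numeric-bracket")
  out <- add(out, paste0("\\((?![0-9]+[A-Za-z])", num, "\\)"), "numeric-bracket")
  out <- add(out,
             paste0("\\([A-Z][A-Za-z'’-]+",
                    "(\\s+(et\\s+al\\.?|and\\s+[A-Z][A-Za-z'’-]+))?,?\\s+",
                    "(19|20)[0-9]{2}[a-z]?",
                    "(\\s*;\\s*[^()]*?(19|20)[0-9]{2}[a-z]?)*\\)"),
             "author-year")
  if (nrow(out)) {
    figs <- detect_figure_refs(text)
    if (nrow(figs)) {
      keep <- vapply(seq_len(nrow(out)), function(i)
        !any(out$start[i] < figs$end & figs$start < out$end[i]), logical(1L))
      out <- out[keep, , drop = FALSE]
    }
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Split a figure caption into lettered subfigure sentences
#'
#' Well-defined subfigure caption sentences begin with a single letter in
#' parentheses, e.g. \code{"(A) Lysates were blotted."}. Each entry's text
#' runs from after its marker to the start of the next marker (or the end of
#' the caption). Captions without markers yield an empty result; duplicate
#' letters are preserved in order.
#'
#' @param caption_text the caption string.
#' @return data frame with columns \code{subfigure}, \code{text}.
#' @export
extract_caption_subfigures <- function(caption_text) {
  stopifnot(is.character(caption_text), length(caption_text) == 1L)
  out <- data.frame(subfigure = character(), text = character(),
                    stringsAsFactors = FALSE)
  if (!nzchar(caption_text)) return(out)
  m <- gregexpr("(?<=^|\\s)\\(([A-Za-z])\\)", caption_text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  letters_found <- toupper(substring(caption_text, starts + 1L, starts + 1L))
  n <- length(starts)
  texts <- character(n)
  for (i in seq_len(n)) {
    from <- starts[i] + lens[i]
    to <- if (i < n) starts[i + 1L] - 1L else nchar(caption_text)
    texts[i] <- trimws(substr(caption_text, from, to))
  }
  data.frame(subfigure = letters_found, text = texts, stringsAsFactors = FALSE)
}
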