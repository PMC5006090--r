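# Sentence and clause segmentation. Coordinates follow the package-wide
# convention: 0-based half-open character spans into the document text.

abbrev_tokens <- c("Fig", "Figs", "al", "e.g", "i.e", "vs", "cf", "ca",
                   "No", "approx", "etc", "resp")

#' Split text into sentence spans
#'
#' Deterministic rule-based splitter: sentences end at \code{.}, \code{!} or
#' \code{?} followed by whitespace and an uppercase letter, digit or opening
#' bracket, except after common abbreviations (\code{Fig.}, \code{et al.},
#' \code{e.g.}, \code{i.e.}, \code{vs.} ...). Newlines separating paragraphs
#' also terminate sentences. The returned spans are ordered, non-overlapping
#' and cover all non-whitespace characters of the input.
#'
#' @param text a character string (typically one section of a document).
#' @param offset integer added to all returned offsets (position of
#'   \code{text} within the full document, 0-based).
#' @return data frame with columns \code{start}, \code{end}.
#' @export
split_sentences <- function(text, offset = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- data.frame(start = integer(), end = integer())
  if (!nzchar(trimws(text))) return(out)
  chars <- strsplit(text, "")[[1L]]
  n <- length(chars)
  breaks <- integer()  # index of last char of each sentence (1-based)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("!", "?")) {
      breaks <- c(breaks, i)
    } else if (ch == ".") {
      # look back for an abbreviation token
      j <- i - 1L
      while (j >= 1L && grepl("[A-Za-z.]", chars[j])) j <- j - 1L
      tok <- paste(chars[seq.int(j + 1L, max(j + 1L, i - 1L))], collapse = "")
      tok <- sub("\\.$", "", tok)
      is_abbrev <- tok %in% abbrev_tokens || tok %in% c("e.g", "i.e")
      # sentence break only if followed by space + sentence-initial character
      k <- i + 1L
      while (k <= n && chars[k] %in% c(" ", "\t")) k <- k + 1L
      follows <- k > n || chars[k] == "\n" ||
        (k > i + 1L && grepl("[A-Z0-9(\\[]", chars[k]))
      if (!is_abbrev && follows)
        breaks <- c(breaks, i)
    } else if (ch == "\n" && (i == n || chars[i + 1L] == "\n")) {
      breaks <- c(breaks, i)
    }
    i <- i + 1L
  }
  breaks <- sort(unique(c(breaks, n)))
  starts <- c(1L, head(breaks, -1L) + 1L)
  res <- data.frame(start = starts, end = breaks)
  # trim whitespace at both ends of each span
  keep <- logical(nrow(res))
  for (r in seq_len(nrow(res))) {
    s <- res$start[r]; e <- res$end[r]
    while (s <= e && grepl("\\s", chars[s])) s <- s + 1L
    while (e >= s && grepl("\\s", chars[e])) e <- e - 1L
    res$start[r] <- s; res$end[r] <- e
    keep[r] <- s <= e
  }
  res <- res[keep, , drop = FALSE]
  if (!nrow(res)) return(out)
  data.frame(start = res$start - 1L + offset, end = res$end + offset)
}

#' Default clause delimiter set
#'
#' Clause boundaries are placed at these markers (plus coordinations
#' \code{", and"} / \code{", but"} when followed by a finite verb phrase).
#' The set is configurable so a syntactic parser can be swapped in for the
#' rule-based splitter.
#' @return character vector of delimiter strings.
#' @export
default_clause_delimiters <- function() {
  c(";", ", which", ", suggesting", ", indicating", ", whereas", ", while",
    ", because", " whereas ", " because ")
}

finite_verb_re <- paste0(
  "^\\s*(we|they|this|these|it|there|the|[A-Z][A-Za-z0-9-]*)\\b[^,;.]*?",
  "\\b(is|are|was|were|has|have|had|did|does|show(s|ed)?|suggest(s|ed)?|",
  "indicate(s|d)?|observ(e|es|ed)|increas(e|es|ed)|decreas(e|es|ed)|",
  "remain(s|ed)?|found|failed|[a-z]+ed)\\b")

#' Split a sentence span into clauses
#'
#' Clause boundaries are placed at delimiters from \code{delimiters} and at
#' \code{", and"} / \code{", but"} coordinations followed by a finite verb
#' phrase. Every non-empty sentence yields at least one clause; clause spans
#' are ordered, non-overlapping and jointly cover the sentence's
#' non-whitespace text. All-caps sentences (headings) are returned as a
#' single clause flagged \code{heading}, eligible for the 'none' label.
#'
#' @param sentence_span one row of \code{\link{split_sentences}} output
#'   (list or single-row data frame with \code{start}, \code{end}).
#' @param document the \code{discoseg_document} the span came from.
#' @param delimiters delimiter strings, by default
#'   \code{\link{default_clause_delimiters}}.
#' @return data frame with columns \code{start}, \code{end}, \code{text},
#'   \code{heading} (logical).
#' @export
split_clauses <- function(sentence_span, document,
                          delimiters = default_clause_delimiters()) {
  s0 <- as.integer(sentence_span$start); e0 <- as.integer(sentence_span$end)
  txt <- substr(document$text, s0 + 1L, e0)
  out0 <- data.frame(start = integer(), end = integer(), text = character(),
                     heading = logical(), stringsAsFactors = FALSE)
  if (!nzchar(trimws(txt))) return(out0)
  letters_only <- gsub("[^A-Za-z]", "", txt)
  if (nzchar(letters_only) && letters_only == toupper(letters_only)) {
    return(data.frame(start = s0, end = e0, text = trimws(txt),
                      heading = TRUE, stringsAsFactors = FALSE))
  }
  cuts <- integer()  # 1-based position in txt where a new clause starts
  for (d in delimiters) {
    m <- gregexpr(d, txt, fixed = TRUE)[[1L]]
    # new clause starts just after the leading ","/";"/space of the delimiter
    if (m[1L] != -1L) cuts <- c(cuts, as.integer(m) + 1L)
  }
  # ", and"/", but" followed by a finite verb phrase
  co <- gregexpr(",\\s+(and|but)\\s+", txt, perl = TRUE)[[1L]]
  if (co[1L] != -1L) {
    for (k in seq_along(co)) {
      after <- substring(txt, as.integer(co[k]) + attr(co, "match.length")[k])
      if (grepl(finite_verb_re, after, perl = TRUE))
        cuts <- c(cuts, as.integer(co[k]) + 1L)
    }
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 1L & cuts <= nchar(txt)]
  bounds <- c(1L, cuts, nchar(txt) + 1L)
  res <- out0
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L] - 1L
    piece <- substr(txt, a, b)
    # trim to non-whitespace extent
    lead <- attr(regexpr("^\\s*", piece), "match.length")
    trail <- attr(regexpr("\\s*$", piece), "match.length")
    a2 <- a + lead; b2 <- b - trail
    if (a2 > b2) next
    res <- rbind(res, data.frame(start = s0 + a2 - 1L, end = s0 + b2,
                                 text = trimws(piece),
                                 heading = FALSE, stringsAsFactors = FALSE))
  }
  if (!nrow(res))
    res <- data.frame(start = s0, end = e0, text = trimws(txt),
                      heading = FALSE, stringsAsFactors = FALSE)
  res
}

#' Segment a document into gold-ready clauses
#'
#' Runs \code{\link{split_sentences}} and \code{\link{split_clauses}} over
#' every section of a document (or only its results/caption sections) and
#' returns the clause table used throughout the package.
#'
#' @param document a \code{discoseg_document}.
#' @param kinds section kinds to segment (default results and caption).
#' @param delimiters passed to \code{\link{split_clauses}}.
#' @return data frame with columns \code{doc_id}, \code{section_idx},
#'   \code{sentence_idx}, \code{clause_idx}, \code{start}, \code{end},
#'   \code{text}, \code{heading}, \code{gold_label} (all \code{NA} until
#'   attached).
#' @export
segment_document <- function(document, kinds = c("results", "caption"),
                             delimiters = default_clause_delimiters()) {
  out <- data.frame(doc_id = character(), section_idx = integer(),
                    sentence_idx = integer(), clause_idx = integer(),
                    start = integer(), end = integer(), text = character(),
                    heading = logical(), gold_label = character(),
                    stringsAsFactors = FALSE)
  secs <- document$sections
  if (!nrow(secs)) return(out)
  acc <- list()
  for (si in seq_len(nrow(secs))) {
    if (!secs$kind[si] %in% kinds) next
    stext <- substr(document$text, secs$start[si] + 1L, secs$end[si])
    sents <- split_sentences(stext, offset = secs$start[si])
    if (!nrow(sents)) next
    for (qi in seq_len(nrow(sents))) {
      cls <- split_clauses(sents[qi, ], document, delimiters)
      if (!nrow(cls)) next
      acc[[length(acc) + 1L]] <- data.frame(
        doc_id = document$doc_id, section_idx = si - 1L,
        sentence_idx = qi - 1L, clause_idx = seq_len(nrow(cls)) - 1L,
        start = cls$start, end = cls$end, text = cls$text,
        heading = cls$heading, gold_label = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(acc)) out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}

#' Write clauses as CoNLL-style TSV
#'
#' Columns: doc_id, section_idx, sentence_idx, clause_idx, start, end,
#' gold_label, text, and (if present) predicted_label.
#' @param clauses a clause table from \code{\link{segment_document}}.
#' @param path output path.
#' @export
write_clause_tsv <- function(clauses, path) {
  cols <- c("doc_id", "section_idx", "sentence_idx", "clause_idx",
            "start", "end", "gold_label", "text")
  if ("predicted_label" %in% names(clauses))
    cols <- c(cols, "predicted_label")
  write.table(clauses[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clause TSV written by \code{\link{write_clause_tsv}}
#' @param path input path.
#' @return clause data frame.
#' @export
read_clause_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   colClasses = "character")
  for (col in c("section_idx", "sentence_idx", "clause_idx", "start", "end"))
    df[[col]] <- as.integer(df[[col]])
  df$gold_label[df$gold_label %in% c("NA", "")] <- NA_character_
  df
}
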