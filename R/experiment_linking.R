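# Linking Results-section text to subfigure-level experiments. The working
# assumption (supported by curated interaction databases): one figure = one
# experiment, one subfigure = one sub-experiment. Narrative passages are
# whole paragraphs matched to the subfigures they reference; caption
# passages are the lettered subfigure sentences of figure captions.

#' Partition a document's Results sections into experiment passages
#'
#' One passage per Results paragraph (paragraphs are separated by blank
#' lines) containing at least one figure reference; the linked subfigures
#' are the set referenced in that paragraph in first-mention order.
#' Paragraphs without figure references contribute nothing; two paragraphs
#' referencing the same subfigure stay separate (no merging). Citation
#' annotations have no effect on the output.
#'
#' @param document a \code{discoseg_document} with results sections and
#'   \code{figure_refs}.
#' @return data frame with columns \code{doc_id}, \code{source}
#'   (\code{"narrative"}), \code{text}, and list-column \code{subfigures}
#'   (each element a data frame \code{figure}, \code{subfigure}).
#' @export
link_paragraphs <- function(document) {
  out <- data.frame(doc_id = character(), source = character(),
                    text = character(), stringsAsFactors = FALSE)
  out$subfigures <- list()
  secs <- document$sections
  fr <- document$figure_refs
  res_secs <- which(secs$kind == "results")
  acc <- list()
  for (si in res_secs) {
    stext <- substr(document$text, secs$start[si] + 1L, secs$end[si])
    # paragraph spans within the section (split on blank lines)
    para_bounds <- gregexpr("\n[ \t]*\n", stext, perl = TRUE)[[1L]]
    cuts <- if (para_bounds[1L] == -1L) integer() else
      as.integer(para_bounds) + attr(para_bounds, "match.length")
    p_starts <- c(1L, cuts)
    p_ends <- c(if (para_bounds[1L] == -1L) integer() else
      as.integer(para_bounds) - 1L, nchar(stext))
    for (k in seq_along(p_starts)) {
      ps <- secs$start[si] + p_starts[k] - 1L       # 0-based doc offsets
      pe <- secs$start[si] + p_ends[k]
      ptxt <- trimws(substr(document$text, ps + 1L, pe))
      if (!nzchar(ptxt)) next
      hit <- fr[fr$start >= ps & fr$end <= pe, , drop = FALSE]
      if (!nrow(hit)) next
      hit <- hit[order(hit$start), , drop = FALSE]
      sub <- unique(hit[, c("figure", "subfigure")])
      rownames(sub) <- NULL
      acc[[length(acc) + 1L]] <- list(text = ptxt, subfigures = sub)
    }
  }
  if (!length(acc)) return(out)
  out <- data.frame(doc_id = document$doc_id, source = "narrative",
                    text = vapply(acc, `[[`, character(1L), "text"),
                    stringsAsFactors = FALSE)
  out$subfigures <- lapply(acc, `[[`, "subfigures")
  out
}

#' Extract caption passages (one per lettered subfigure sentence)
#'
#' Runs \code{\link{extract_caption_subfigures}} over every caption-kind
#' section of a document. The figure number is taken from the section
#' heading (first integer found) when present.
#'
#' @param document a \code{discoseg_document}.
#' @return passage data frame as in \code{\link{link_paragraphs}}, with
#'   \code{source = "caption"}; each passage links exactly one subfigure.
#' @export
link_captions <- function(document) {
  secs <- document$sections
  acc <- list()
  for (si in which(secs$kind == "caption")) {
    stext <- substr(document$text, secs$start[si] + 1L, secs$end[si])
    fig <- NA_integer_
    h <- secs$heading[si]
    if (!is.na(h)) {
      m <- regmatches(h, regexpr("[0-9]+", h))
      if (length(m)) fig <- as.integer(m)
    }
    entries <- extract_caption_subfigures(stext)
    for (k in seq_len(nrow(entries))) {
      acc[[length(acc) + 1L]] <- list(
        text = entries$text[k],
        subfigures = data.frame(figure = fig,
                                subfigure = entries$subfigure[k],
                                stringsAsFactors = FALSE))
    }
  }
  out <- data.frame(doc_id = character(), source = character(),
                    text = character(), stringsAsFactors = FALSE)
  out$subfigures <- list()
  if (!length(acc)) return(out)
  out <- data.frame(doc_id = document$doc_id, source = "caption",
                    text = vapply(acc, `[[`, character(1L), "text"),
                    stringsAsFactors = FALSE)
  out$subfigures <- lapply(acc, `[[`, "subfigures")
  out
}

#' Keep passages whose subfigures map to exactly one experiment-type code
#'
#' A passage referencing several subfigures is kept only if all its mapped
#' subfigures share one distinct code; passages mapping to more than one
#' code are discarded (they describe more than one kind of experiment and
#' cannot carry a single gold label). Passages with any subfigure missing
#' from the gold table are counted separately as unmapped, with a warning.
#'
#' @param passages passage data frame (see \code{\link{link_paragraphs}}).
#' @param gold_codes data frame with columns \code{doc_id}, \code{figure},
#'   \code{subfigure}, \code{code}.
#' @return list with elements \code{kept} (passages, plus a \code{code}
#'   column), \code{discarded}, \code{unmapped};
#'   \code{nrow(kept) + nrow(discarded) + nrow(unmapped) = nrow(passages)}.
#' @export
filter_single_type <- function(passages, gold_codes) {
  n <- nrow(passages)
  codes_of <- function(i) {
    sub <- passages$subfigures[[i]]
    key <- paste(passages$doc_id[i], sub$figure, sub$subfigure, sep = "\r")
    gkey <- paste(gold_codes$doc_id, gold_codes$figure, gold_codes$subfigure,
                  sep = "\r")
    hit <- match(key, gkey)
    if (anyNA(hit)) return(NULL)
    unique(gold_codes$code[hit])
  }
  status <- character(n)
  code <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cs <- codes_of(i)
    if (is.null(cs)) {
      status[i] <- "unmapped"
    } else if (length(cs) == 1L) {
      status[i] <- "kept"; code[i] <- cs
    } else status[i] <- "discarded"
  }
  if (any(status == "unmapped"))
    warning(sum(status == "unmapped"),
            " passage(s) reference subfigures absent from the gold table",
            call. = FALSE)
  kept <- passages[status == "kept", , drop = FALSE]
  kept$code <- code[status == "kept"]
  list(kept = kept,
       discarded = passages[status == "discarded", , drop = FALSE],
       unmapped = passages[status == "unmapped", , drop = FALSE])
}

#' Merge and restrict experiment-type codes to the top-k most frequent
#'
#' Leaf codes are first mapped through \code{merge_map} (e.g. anti-tag and
#' anti-bait coimmunoprecipitation onto coimmunoprecipitation); merged
#' counts are summed; then only the \code{top_k} most frequent merged codes
#' are retained. Frequency ties are broken by code string order.
#'
#' @param counts named integer vector of per-code frequencies (leaf codes).
#' @param merge_map data frame with columns \code{leaf_code},
#'   \code{merged_code}; codes absent from the map are kept as-is.
#' @param top_k number of merged codes to retain.
#' @return data frame with columns \code{code}, \code{count}, sorted by
#'   decreasing count (ties by code), restricted to the top \code{top_k}.
#' @export
merge_categories <- function(counts, merge_map = NULL, top_k = length(counts)) {
  stopifnot(top_k >= 1L)
  codes <- names(counts)
  if (is.null(codes)) stop("counts must be a named vector")
  if (!is.null(merge_map) && nrow(merge_map)) {
    hit <- match(codes, merge_map$leaf_code)
    codes <- ifelse(is.na(hit), codes, merge_map$merged_code[hit])
  }
  agg <- tapply(as.numeric(counts), codes, sum)
  df <- data.frame(code = names(agg), count = as.numeric(agg),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$code), , drop = FALSE]
  rownames(df) <- NULL
  if (top_k > nrow(df)) {
    warning("top_k (", top_k, ") exceeds number of distinct codes (",
            nrow(df), "); returning all", call. = FALSE)
    top_k <- nrow(df)
  }
  df[seq_len(top_k), , drop = FALSE]
}

#' Apply a merge map to passage codes and restrict to the top-k codes
#'
#' Convenience wrapper combining \code{merge_categories} with passage
#' filtering: passage codes are merged, and passages whose merged code
#' falls outside the top-k are dropped.
#' @param passages kept passages with a \code{code} column.
#' @param merge_map,top_k see \code{\link{merge_categories}}.
#' @return passages with merged codes, restricted to the top-k code set.
#' @export
restrict_passages <- function(passages, merge_map = NULL,
                              top_k = Inf) {
  codes <- passages$code
  if (!is.null(merge_map) && nrow(merge_map)) {
    hit <- match(codes, merge_map$leaf_code)
    codes <- ifelse(is.na(hit), codes, merge_map$merged_code[hit])
  }
  passages$code <- codes
  counts <- table(codes)
  k <- min(top_k, length(counts))
  top <- merge_categories(setNames(as.integer(counts), names(counts)),
                          NULL, k)
  passages[passages$code %in% top$code, , drop = FALSE]
}

#' Read / write the gold subfigure-to-code table
#'
#' TSV with columns doc_id, figure, subfigure, code.
#' @param path file path.
#' @export
read_gold_codes <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character",
                                  "character"))
  names(df) <- c("doc_id", "figure", "subfigure", "code")
  df
}

#' @rdname read_gold_codes
#' @param gold_codes the table to write.
#' @export
write_gold_codes <- function(gold_codes, path) {
  write.table(gold_codes[, c("doc_id", "figure", "subfigure", "code")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
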