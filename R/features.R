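# Feature extraction: four families over each clause.
#   pos:*  -- counts of Penn-style part-of-speech tags
#   lex:*  -- indicators for tokens tagged verb (VB*) or adverb (RB*)
#   link:* -- figure-reference / citation flags from document annotations
#   cue:*  -- indicators for cue-lexicon phrase hits

FEATURE_SCHEMA_VERSION <- "1"

#' The seven discourse segment types, in canonical (tie-break) order
#' @return character vector of the seven labels.
#' @export
discourse_labels <- function() {
  c("problem", "fact", "hypothesis", "goal", "method", "result", "implication")
}

# ---- part-of-speech tagging (pluggable) ------------------------------------

pos_dictionary <- local({
  d <- new.env(parent = emptyenv())
  put <- function(words, tag) for (w in words) assign(w, tag, envir = d)
  put(c("the", "a", "an", "this", "these", "that", "those", "each", "no"), "DT")
  put(c("of", "in", "on", "at", "by", "with", "for", "from", "to", "into",
        "after", "before", "between", "during", "under", "through",
        "via", "upon", "within"), "IN")
  put(c("and", "or", "but", "nor"), "CC")
  put(c("we", "it", "they", "he", "she", "i", "our", "its", "their"), "PRP")
  put(c("is", "are", "be", "been", "being", "am"), "VB")
  put(c("was", "were"), "VBD")
  put(c("has", "does", "shows", "suggests", "indicates", "demonstrates",
        "reveals", "remains", "confirms", "supports", "appears",
        "regulates", "binds", "requires", "induces", "blocks",
        "phosphorylates", "interacts", "activates", "inhibits"), "VBZ")
  put(c("have", "do", "show", "suggest", "indicate", "demonstrate",
        "reveal", "remain", "confirm", "support", "appear", "determine",
        "test", "examine", "investigate", "assess", "define", "measure",
        "detect", "identify", "regulate", "bind", "require", "induce",
        "block", "phosphorylate", "interact", "activate", "inhibit",
        "sought", "performed", "used", "observed", "found", "detected",
        "measured", "incubated", "transfected", "immunoprecipitated",
        "blotted", "analyzed", "quantified", "probed", "stained",
        "treated", "increased", "decreased", "reduced", "abolished",
        "enhanced", "impaired", "shown", "seen", "known", "reported",
        "established", "hypothesized", "asked", "aimed", "failed",
        "co-precipitated", "coprecipitated", "precipitated"), "VB")
  put(c("can", "could", "may", "might", "must", "should", "would",
        "will"), "MD")
  put(c("not", "also", "however", "therefore", "thus", "together",
        "markedly", "strongly", "significantly", "specifically",
        "previously", "consistently", "robustly", "clearly", "notably",
        "similarly", "next", "then", "first", "subsequently", "hereby",
        "only", "still", "unclear"), "RB")
  put(c("possible", "unknown", "direct", "consistent", "specific",
        "essential", "necessary", "sufficient", "dependent"), "JJ")
  put(c("whether", "that", "which", "because", "while", "whereas",
        "if"), "IN")
  d
})

#' Rule-based Penn-style part-of-speech tagger
#'
#' A deterministic dictionary-plus-suffix tagger producing Penn-Treebank
#' style tags (VB*, RB, NN, NNS, NNP, JJ, CD, DT, IN, PRP, MD, CC, SYM).
#' It implements the pluggable tagger interface: any function mapping a
#' character vector of tokens to an equal-length character vector of tags
#' can be supplied wherever a \code{tagger} argument is accepted.
#'
#' @param tokens character vector of tokens.
#' @return character vector of tags, one per token.
#' @export
pos_tag_rules <- function(tokens) {
  vapply(tokens, function(tok) {
    lower <- tolower(tok)
    hit <- if (exists(lower, envir = pos_dictionary, inherits = FALSE))
      get(lower, envir = pos_dictionary) else NA_character_
    if (!is.na(hit)) return(hit)
    if (grepl("^[0-9.]+$", tok)) return("CD")
    if (grepl("ly$", lower)) return("RB")
    if (grepl("ing$", lower) && nchar(lower) > 4L) return("VBG")
    if (grepl("ed$", lower) && nchar(lower) > 3L) return("VBD")
    if (grepl("^[A-Z][A-Z0-9-]+$", tok)) return("NNP")
    if (grepl("^[A-Z]", tok)) return("NNP")
    if (grepl("s$", lower) && nchar(lower) > 3L) return("NNS")
    if (grepl("^[[:punct:]]+$", tok)) return("SYM")
    "NN"
  }, character(1L), USE.NAMES = FALSE)
}

tokenize_words <- function(text) {
  toks <- regmatches(text,
                     gregexpr("[A-Za-z0-9][A-Za-z0-9'’.-]*", text))[[1L]]
  toks[nzchar(toks)]
}

# ---- cue lexicon -----------------------------------------------------------

#' Default cue lexicon
#'
#' A small list of words and phrases indicative of each discourse type,
#' matched case-insensitively as substrings of the clause text. The core
#' entries are 'possible' (hypothesis), 'data not shown' (result), and
#' 'demonstrate' / 'suggest' (implication); a modest set of conservative
#' extensions is shipped alongside. Entries can be overridden key-by-key by
#' \code{\link{read_lexicon}}.
#'
#' @return named character vector: names are lowercase phrases, values are
#'   discourse labels.
#' @export
default_lexicon <- function() {
  c("possible" = "hypothesis",
    "data not shown" = "result",
    "demonstrate" = "implication",
    "suggest" = "implication",
    # conservative extensions
    "we sought to" = "goal",
    "to determine whether" = "goal",
    "to test whether" = "goal",
    "to examine" = "goal",
    "we asked whether" = "goal",
    "we aimed to" = "goal",
    "it is known" = "fact",
    "is known to" = "fact",
    "has been shown" = "fact",
    "previous studies" = "fact",
    "taken together" = "implication",
    "these results indicate" = "implication",
    "consistent with" = "implication",
    "we hypothesized" = "hypothesis",
    "may be" = "hypothesis",
    "it is unclear" = "problem",
    "remains unclear" = "problem",
    "remains unknown" = "problem",
    "little is known" = "problem",
    "we performed" = "method",
    "were incubated" = "method",
    "was used to" = "method",
    "we observed" = "result",
    "we found that" = "result")
}

#' Read a cue lexicon from a two-column TSV (phrase, label)
#'
#' Entries override the base lexicon key-by-key: a phrase present in both
#' takes the file's label, phrases only in the base are kept.
#'
#' @param path TSV path with columns phrase and label (no header).
#' @param base lexicon to merge over (default \code{\link{default_lexicon}});
#'   pass \code{NULL} to use the file alone.
#' @return named character vector lexicon.
#' @export
read_lexicon <- function(path, base = default_lexicon()) {
  df <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE,
                   col.names = c("phrase", "label"))
  user <- setNames(df$label, tolower(df$phrase))
  if (is.null(base)) return(user)
  merged <- base
  merged[names(user)] <- user
  merged
}

#' Look up the discourse label hinted by a cue phrase
#' @param lexicon a cue lexicon (named character vector).
#' @param phrase phrase to look up (case-insensitive).
#' @return the hinted label, or \code{NA} if absent.
#' @export
lookup_cue <- function(lexicon, phrase) {
  phrase <- tolower(phrase)
  if (phrase %in% names(lexicon)) unname(lexicon[[phrase]]) else NA_character_
}

cue_feature_name <- function(phrase) {
  paste0("cue:", gsub("\\s+", "_", tolower(phrase)))
}

# ---- feature extraction ----------------------------------------------------

#' Extract the feature vector for one clause
#'
#' Builds the four feature families: \code{pos:T} counts for each
#' part-of-speech tag \code{T}; \code{lex:w} indicators for each token
#' tagged verb (VB*) or adverb (RB*); \code{link:figure} and
#' \code{link:citation} flags when a document annotation intersects the
#' clause span; and \code{cue:p} indicators for case-insensitive substring
#' hits of lexicon phrases. Extraction is a pure function of the clause
#' text, the document annotations and the lexicon.
#'
#' @param clause one row of a clause table (needs \code{text}, \code{start},
#'   \code{end}).
#' @param document the owning \code{discoseg_document} (or \code{NULL} to
#'   skip link features).
#' @param lexicon cue lexicon (default \code{\link{default_lexicon}}).
#' @param tagger token-tagging function (default \code{\link{pos_tag_rules}}).
#' @return named numeric vector (sparse: only nonzero features), with
#'   attribute \code{schema_version}.
#' @export
extract_features <- function(clause, document = NULL,
                             lexicon = default_lexicon(),
                             tagger = pos_tag_rules) {
  if (!is.function(tagger))
    stop("no part-of-speech tagger configured: supply `tagger` as a ",
         "function(tokens) -> tags (see ?pos_tag_rules)")
  text <- clause$text
  feats <- numeric()
  if (nzchar(trimws(text))) {
    toks <- tokenize_words(text)
    if (length(toks)) {
      tags <- tagger(toks)
      tab <- table(tags)
      feats[paste0("pos:", names(tab))] <- as.numeric(tab)
      vb <- tolower(toks[startsWith(tags, "VB") | startsWith(tags, "RB")])
      if (length(vb)) feats[paste0("lex:", unique(vb))] <- 1
    }
    lowered <- tolower(text)
    for (phrase in names(lexicon)) {
      if (grepl(phrase, lowered, fixed = TRUE))
        feats[cue_feature_name(phrase)] <- 1
    }
    if (!is.null(document)) {
      s <- clause$start; e <- clause$end
      fr <- document$figure_refs
      if (nrow(fr) && any(fr$start < e & s < fr$end))
        feats["link:figure"] <- 1
      ci <- document$citations
      if (nrow(ci) && any(ci$start < e & s < ci$end))
        feats["link:citation"] <- 1
    }
  }
  structure(feats, schema_version = FEATURE_SCHEMA_VERSION)
}

#' Build clause sequences with features for model training
#'
#' Groups gold-ready clauses by (document, paragraph) and attaches feature
#' vectors. Clauses labeled \code{'none'} (headings and non-narrative
#' fragments) are excluded: the classifiers are seven-way.
#'
#' @param clauses clause table (from \code{\link{segment_document}} or a
#'   generator), with a \code{gold_label} column (may be all \code{NA} for
#'   prediction-time sequences) and a \code{paragraph_idx} or
#'   \code{section_idx} grouping column.
#' @param documents named list of \code{discoseg_document} keyed by doc_id
#'   (or \code{NULL}: link features are skipped).
#' @param lexicon,tagger passed to \code{\link{extract_features}}.
#' @param drop_none drop clauses labeled "none" or flagged as headings
#'   (default \code{TRUE}).
#' @return list of sequences; each sequence is a list with \code{clauses}
#'   (data frame) and \code{features} (list of named numeric vectors).
#' @export
clause_sequences <- function(clauses, documents = NULL,
                             lexicon = default_lexicon(),
                             tagger = pos_tag_rules, drop_none = TRUE) {
  if (!nrow(clauses)) return(list())
  if (drop_none) {
    drop <- (!is.na(clauses$gold_label) & clauses$gold_label == "none")
    if ("heading" %in% names(clauses))
      drop <- drop | (!is.na(clauses$heading) & as.logical(clauses$heading))
    clauses <- clauses[!drop, , drop = FALSE]
  }
  if (!nrow(clauses)) return(list())
  group_col <- if ("paragraph_idx" %in% names(clauses)) "paragraph_idx"
               else "section_idx"
  key <- paste(clauses$doc_id, clauses[[group_col]], sep = "\r")
  out <- lapply(split(seq_len(nrow(clauses)), factor(key, unique(key))),
    function(idx) {
      cl <- clauses[idx, , drop = FALSE]
      cl <- cl[order(cl$start), , drop = FALSE]
      doc <- if (!is.null(documents)) documents[[cl$doc_id[1L]]] else NULL
      feats <- lapply(seq_len(nrow(cl)), function(i)
        extract_features(cl[i, ], doc, lexicon, tagger))
      list(clauses = cl, features = feats)
    })
  names(out) <- NULL
  out
}
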