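# Seeded generators for (i) Results-section documents whose clause labels
# follow the archetypal discourse order with label-indicative lexical cues,
# figure references and citations, and (ii) experiment-type passages with
# assay-specific terminology and controllable lexical-overlap noise.
# Templates are deliberately stylized English: the contract is statistical
# structure, not prose realism.

#' Default label-transition matrix (archetypal discourse order)
#'
#' Encodes the canonical ordering context (fact/hypothesis/problem) ->
#' goal -> method -> result -> implication as a Markov chain over the seven
#' labels, with 0.8 probability of stepping forward one stage, 0.1 of
#' staying, and 0.1 of skipping a stage. Within the context stage,
#' probability mass is split fact : hypothesis : problem in proportion to
#' their corpus frequencies.
#'
#' @return a 7x7 row-stochastic matrix with dimnames =
#'   \code{\link{discourse_labels}}.
#' @export
archetypal_transitions <- function() {
  labs <- discourse_labels()
  stage_of <- c(problem = 1, fact = 1, hypothesis = 1, goal = 2, method = 3,
                result = 4, implication = 5)
  # relative frequency within the context stage (problem rare)
  ctx_w <- c(problem = 0.05, fact = 0.55, hypothesis = 0.40)
  stage_members <- split(names(stage_of), stage_of)
  P <- matrix(0, 7, 7, dimnames = list(labs, labs))
  for (from in labs) {
    st <- stage_of[[from]]
    dist <- c(0.1, 0.8, 0.1)                 # stay, forward, skip
    # stages cycle: after the implication a new experiment context begins
    stages <- c(st, st %% 5 + 1, (st + 1) %% 5 + 1)
    row <- setNames(numeric(7), labs)
    for (k in 1:3) {
      members <- stage_members[[as.character(stages[k])]]
      w <- if (identical(members, names(ctx_w))) ctx_w[members]
           else setNames(rep(1 / length(members), length(members)), members)
      row[members] <- row[members] + dist[k] * w / sum(w)
    }
    P[from, ] <- row / sum(row)
  }
  P
}

#' Uniform-row transition matrix (labels i.i.d. from a prior)
#'
#' Every row equals \code{prior}, so consecutive labels are independent:
#' the ordering signal is removed while the marginal label distribution is
#' exactly \code{prior}. Used for ablations of the sequence model.
#' @param prior named numeric vector over the seven labels, summing to 1.
#' @export
iid_transitions <- function(prior) {
  labs <- discourse_labels()
  stopifnot(setequal(names(prior), labs))
  prior <- prior[labs] / sum(prior)
  matrix(rep(prior, each = 7), 7, 7, dimnames = list(labs, labs),
         byrow = FALSE)
}

#' Label prior observed in a curated Results-section test corpus
#'
#' Ground-truth frequencies problem 2, fact 53, hypothesis 36, goal 30,
#' method 98, result 182, implication 44 (per 445 clauses), used as the
#' default class prior for prior-matched generation.
#' @export
reference_label_prior <- function() {
  setNames(c(2, 53, 36, 30, 98, 182, 44) / 445, discourse_labels())
}

#' Specification of a synthetic discourse corpus
#'
#' @param n_documents number of documents.
#' @param paragraphs_per_doc paragraphs per document.
#' @param clauses_per_paragraph expected clauses per paragraph (actual
#'   lengths vary by +-2).
#' @param transitions 7x7 row-stochastic label-transition matrix (default
#'   \code{\link{archetypal_transitions}}).
#' @param start_dist start distribution over labels (default: contextual
#'   stage weights).
#' @param cue_emission per-label probability that a clause carries its
#'   label's cue phrase (before dropout).
#' @param cue_dropout probability that an emitted cue is dropped.
#' @param figure_ref_rate probability that a result clause carries a figure
#'   reference.
#' @param citation_rate probability that a fact clause carries a citation.
#' @param seed RNG seed; the corpus is fully reproducible from it.
#' @return object of class \code{corpus_spec}.
#' @export
corpus_spec <- function(n_documents = 20L, paragraphs_per_doc = 8L,
                        clauses_per_paragraph = 12L,
                        transitions = archetypal_transitions(),
                        start_dist = NULL,
                        cue_emission = 0.75, cue_dropout = 0.1,
                        figure_ref_rate = 0.7, citation_rate = 0.6,
                        seed = 1L) {
  labs <- discourse_labels()
  transitions <- as.matrix(transitions)
  if (!all(dim(transitions) == c(7L, 7L)) ||
      any(transitions < 0) ||
      any(abs(rowSums(transitions) - 1) > 1e-8))
    stop("transitions must be a 7x7 row-stochastic matrix")
  if (is.null(dimnames(transitions)))
    dimnames(transitions) <- list(labs, labs)
  if (is.null(start_dist)) {
    start_dist <- setNames(c(0.05, 0.45, 0.30, 0.15, 0.05, 0, 0), labs)
  }
  start_dist <- start_dist / sum(start_dist)
  cue_emission <- rep_len(cue_emission, 7L)
  names(cue_emission) <- labs
  stopifnot(all(cue_emission >= 0 & cue_emission <= 1),
            cue_dropout >= 0, cue_dropout <= 1,
            figure_ref_rate >= 0, figure_ref_rate <= 1,
            citation_rate >= 0, citation_rate <= 1)
  structure(list(n_documents = as.integer(n_documents),
                 paragraphs_per_doc = as.integer(paragraphs_per_doc),
                 clauses_per_paragraph = as.integer(clauses_per_paragraph),
                 transitions = transitions, start_dist = start_dist,
                 cue_emission = cue_emission, cue_dropout = cue_dropout,
                 figure_ref_rate = figure_ref_rate,
                 citation_rate = citation_rate, seed = as.integer(seed)),
            class = "corpus_spec")
}

protein_names <- function() {
  c("RAF1", "MEK1", "ERK2", "AKT1", "EGFR", "KRAS", "SRC2", "GRB2",
    "SHC1", "PTEN", "MTOR", "RHEB", "TSC2", "JAK2", "STAT3", "PLCG")
}

# cue phrase per label, drawn from the shipped lexicon so that cue features
# fire; generic alternatives used when the cue is dropped
label_cues <- function() {
  list(problem = c("remains unclear", "it is unclear", "remains unknown"),
       fact = c("it is known", "has been shown", "previous studies"),
       hypothesis = c("possible", "we hypothesized", "may be"),
       goal = c("we sought to", "to determine whether", "to test whether"),
       method = c("we performed", "were incubated", "was used to"),
       result = c("we observed", "we found that", "data not shown"),
       implication = c("suggest", "demonstrate", "taken together"))
}

render_clause <- function(label, with_cue, prots, rng_cue) {
  a <- prots[1L]; b <- prots[2L]
  if (with_cue) {
    cue <- rng_cue
    switch(label,
      problem = sprintf("however the role of %s %s", a, cue),
      fact = sprintf("%s that %s regulates %s", cue, a, b),
      hypothesis = if (cue == "possible")
        sprintf("it is possible that %s binds %s", a, b)
        else sprintf("%s that %s binds %s", cue, a, b),
      goal = sprintf("%s examine binding of %s to %s", cue, a, b),
      method = if (cue == "were incubated")
        sprintf("lysates were incubated with %s beads", a)
        else sprintf("%s immunoprecipitation of %s", cue, a),
      result = if (cue == "data not shown")
        sprintf("binding of %s increased markedly, data not shown", a)
        else sprintf("%s increased binding of %s to %s", cue, a, b),
      implication = if (cue == "taken together")
        sprintf("taken together these findings support a role for %s", a)
        else sprintf("these results %s that %s activates %s", cue, a, b))
  } else {
    # cue dropped: render from a pool shared by all labels, so the clause is
    # lexically uninformative and only the sequence context disambiguates it
    pool <- c("%s was associated with %s in these cells",
              "the pattern for %s was similar across samples of %s",
              "binding of %s to %s was then evaluated",
              "%s and %s were compared under the same conditions",
              "the signal for %s changed relative to %s",
              "this behavior of %s was noted for %s as well")
    sprintf(sample(pool, 1L), a, b)
  }
}

#' Generate a synthetic labeled discourse corpus
#'
#' Each paragraph's label sequence is drawn from the Markov chain in the
#' spec; each clause is rendered from a label-specific template carrying a
#' lexicon cue with probability \code{cue_emission * (1 - cue_dropout)}.
#' Result clauses carry figure references (e.g. \code{"(Fig. 2B)"}) at the
#' specified rate and fact clauses carry bracketed citations. The output
#' flows through the real pipeline: documents are valid
#' \code{discoseg_document}s and clauses carry spans into the document text.
#'
#' @param spec a \code{\link{corpus_spec}}.
#' @return list with \code{documents} (named list of documents) and
#'   \code{clauses} (gold-labeled clause table with \code{paragraph_idx}).
#' @export
generate_discourse_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  labs <- discourse_labels()
  cues <- label_cues()
  docs <- list()
  clause_rows <- list()
  for (d in seq_len(spec$n_documents)) {
    doc_id <- sprintf("synth%03d", d)
    text <- ""
    fig_refs <- empty_figure_refs()
    cit_rows <- empty_citations()
    sec_rows <- list()
    fig_counter <- 0L
    for (p in seq_len(spec$paragraphs_per_doc)) {
      len <- max(2L, spec$clauses_per_paragraph +
                   sample(-2:2, 1L))
      lab_seq <- character(len)
      lab_seq[1L] <- sample(labs, 1L, prob = spec$start_dist)
      if (len > 1L) for (t in 2:len)
        lab_seq[t] <- sample(labs, 1L,
                             prob = spec$transitions[lab_seq[t - 1L], ])
      para_start <- nchar(text)
      if (nzchar(text)) { text <- paste0(text, "\n\n"); para_start <- para_start + 2L }
      pos <- para_start
      for (t in seq_len(len)) {
        lab <- lab_seq[t]
        with_cue <- runif(1L) < spec$cue_emission[[lab]] &&
          runif(1L) >= spec$cue_dropout
        prots <- sample(protein_names(), 2L)
        cue <- sample(cues[[lab]], 1L)
        ctext <- render_clause(lab, with_cue, prots, cue)
        extra <- ""
        if (lab == "result" && runif(1L) < spec$figure_ref_rate) {
          fig_counter <- fig_counter + 1L
          fig <- (fig_counter - 1L) %/% 4L + 1L
          sub <- LETTERS[(fig_counter - 1L) %% 4L + 1L]
          frag <- sprintf(" (Fig. %d%s)", fig, sub)
          tok_start <- pos + nchar(ctext) + nchar(" (Fig. ")
          fig_refs <- rbind(fig_refs, data.frame(
            figure = fig, subfigure = sub,
            start = tok_start, end = tok_start + nchar(sprintf("%d%s", fig, sub)),
            stringsAsFactors = FALSE))
          extra <- frag
        } else if (lab == "fact" && runif(1L) < spec$citation_rate) {
          cit_n <- sample(1:40, 1L)
          frag <- sprintf(" [%d]", cit_n)
          cit_rows <- rbind(cit_rows, data.frame(
            start = pos + nchar(ctext) + 1L,
            end = pos + nchar(ctext) + nchar(frag),
            style = "numeric-bracket", stringsAsFactors = FALSE))
          extra <- frag
        }
        sentence <- paste0(toupper(substr(ctext, 1L, 1L)),
                           substr(ctext, 2L, nchar(ctext)), extra, ".")
        cstart <- pos
        cend <- pos + nchar(sentence)
        clause_rows[[length(clause_rows) + 1L]] <- data.frame(
          doc_id = doc_id, paragraph_idx = p - 1L,
          sentence_idx = t - 1L, clause_idx = 0L,
          start = cstart, end = cend, text = sentence,
          heading = FALSE, gold_label = lab, stringsAsFactors = FALSE)
        text <- paste0(text, sentence)
        pos <- cend
        if (t < len) { text <- paste0(text, " "); pos <- pos + 1L }
      }
      sec_rows[[p]] <- data.frame(kind = "results", start = para_start,
                                  end = nchar(text), heading = NA_character_,
                                  stringsAsFactors = FALSE)
    }
    docs[[doc_id]] <- document(doc_id, text,
                               sections = do.call(rbind, sec_rows),
                               figure_refs = fig_refs, citations = cit_rows)
  }
  list(documents = docs, clauses = do.call(rbind, clause_rows))
}

# ---- experiment-type corpus ------------------------------------------------

#' Default experiment-type classes and term pools
#'
#' Five PSI-MI interaction-detection methods with characteristic assay
#' vocabulary: two hybrid (MI:0018), coimmunoprecipitation (MI:0019),
#' pull down (MI:0096), fluorescence microscopy (MI:0416) and confocal
#' microscopy (MI:0663).
#' @export
default_exptype_classes <- function() {
  list(
    "MI:0018" = c("yeast", "two", "hybrid", "bait", "prey", "galactosidase",
                  "reporter", "transformants", "plasmid", "interaction"),
    "MI:0019" = c("coimmunoprecipitation", "immunoprecipitated", "antibody",
                  "lysates", "immunoblot", "coprecipitated", "beads",
                  "western", "blotted", "precipitates"),
    "MI:0096" = c("pull", "down", "gst", "fusion", "glutathione", "resin",
                  "recombinant", "sepharose", "bound", "eluted"),
    "MI:0416" = c("fluorescence", "microscopy", "gfp", "fluorescent",
                  "imaging", "transfected", "localization", "signal",
                  "staining", "expressing"),
    "MI:0663" = c("confocal", "dapi", "colocalization", "merged",
                  "images", "costained", "nuclei", "sections", "overlap",
                  "channels"))
}

#' Specification of a synthetic experiment-type corpus
#'
#' @param classes named list: code -> term pool (default
#'   \code{\link{default_exptype_classes}}).
#' @param frequencies class frequency vector (default the caption-set
#'   supports 57, 332, 125, 34, 33 normalized).
#' @param n_passages number of passages.
#' @param term_bleed probability that a class term is replaced by a term
#'   from another class's pool (lexical-overlap noise).
#' @param caption_ratio cue-density multiplier for caption-source passages
#'   relative to narrative (captions are terser and denser in assay terms).
#' @param caption_fraction fraction of passages drawn as captions.
#' @param terms_per_passage expected number of class terms per narrative
#'   passage.
#' @param seed RNG seed.
#' @export
exp_corpus_spec <- function(classes = default_exptype_classes(),
                            frequencies = c(57, 332, 125, 34, 33),
                            n_passages = 581L, term_bleed = 0.15,
                            caption_ratio = 2.0, caption_fraction = 0.5,
                            terms_per_passage = 4L, seed = 1L) {
  stopifnot(length(classes) >= 2L, all(lengths(classes) > 0L),
            length(frequencies) == length(classes),
            all(frequencies > 0), term_bleed >= 0, term_bleed <= 1,
            caption_ratio > 0, caption_fraction >= 0, caption_fraction <= 1)
  structure(list(classes = classes,
                 frequencies = frequencies / sum(frequencies),
                 n_passages = as.integer(n_passages),
                 term_bleed = term_bleed, caption_ratio = caption_ratio,
                 caption_fraction = caption_fraction,
                 terms_per_passage = terms_per_passage,
                 seed = as.integer(seed)),
            class = "exp_corpus_spec")
}

filler_words <- function() {
  c("cells", "protein", "complex", "figure", "shown", "analysis", "levels",
    "binding", "described", "results", "assay", "performed", "indicated",
    "control", "experiments", "expression", "conditions", "samples")
}

#' Generate a synthetic experiment-type passage corpus
#'
#' Each passage draws a gold code from the class frequency vector and is
#' filled with terms from that class's pool; with probability
#' \code{term_bleed} an individual term is instead drawn from another
#' class's pool. Caption-source passages receive \code{caption_ratio} times
#' the narrative class-term density and are terser. Every passage carries
#' exactly one gold code and a subfigure link, so generated data flows
#' through \code{\link{filter_single_type}} and \code{\link{exptype_tfidf}}
#' end-to-end.
#'
#' @param spec an \code{\link{exp_corpus_spec}}.
#' @return passage data frame with columns \code{doc_id}, \code{source},
#'   \code{text}, \code{code} and list-column \code{subfigures}.
#' @export
generate_exptype_corpus <- function(spec = exp_corpus_spec()) {
  stopifnot(inherits(spec, "exp_corpus_spec"))
  set.seed(spec$seed)
  codes <- names(spec$classes)
  all_terms <- spec$classes
  n <- spec$n_passages
  cls_idx <- sample(seq_along(codes), n, replace = TRUE,
                    prob = spec$frequencies)
  is_caption <- runif(n) < spec$caption_fraction
  rows <- list()
  for (i in seq_len(n)) {
    code <- codes[cls_idx[i]]
    dens <- spec$terms_per_passage *
      if (is_caption[i]) spec$caption_ratio else 1
    # at least two class terms, so the zero-bleed corpus is separable
    n_class_terms <- max(2L, rpois(1L, dens))
    terms <- character(n_class_terms)
    # bleed replaces a class term by one drawn uniformly from the union of
    # all pools, so term_bleed = 1 removes the class signal entirely
    union_pool <- unlist(all_terms, use.names = FALSE)
    for (t in seq_len(n_class_terms)) {
      terms[t] <- if (runif(1L) < spec$term_bleed)
        sample(union_pool, 1L)
      else sample(all_terms[[cls_idx[i]]], 1L)
    }
    n_filler <- if (is_caption[i]) rpois(1L, 3L) else rpois(1L, 10L)
    words <- sample(c(terms, sample(filler_words(), n_filler,
                                    replace = TRUE)))
    fig <- (i - 1L) %/% 8L %% 6L + 1L
    sub <- LETTERS[(i - 1L) %% 8L %/% 2L + 1L]
    txt <- paste(words, collapse = " ")
    if (is_caption[i]) txt <- sprintf("(%s) %s.", sub, txt)
    rows[[i]] <- list(doc_id = sprintf("expdoc%03d", (i - 1L) %/% 20L + 1L),
                      source = if (is_caption[i]) "caption" else "narrative",
                      text = txt, code = code, figure = fig, subfigure = sub)
  }
  out <- data.frame(doc_id = vapply(rows, `[[`, character(1L), "doc_id"),
                    source = vapply(rows, `[[`, character(1L), "source"),
                    text = vapply(rows, `[[`, character(1L), "text"),
                    code = vapply(rows, `[[`, character(1L), "code"),
                    stringsAsFactors = FALSE)
  out$subfigures <- lapply(rows, function(r)
    data.frame(figure = r$figure, subfigure = r$subfigure,
               stringsAsFactors = FALSE))
  out
}

#' Gold code table for a generated experiment-type corpus
#'
#' Emits the (doc_id, figure, subfigure, code) table matching the corpus,
#' as consumed by \code{\link{filter_single_type}}.
#' @param passages output of \code{\link{generate_exptype_corpus}}.
#' @export
exptype_gold_codes <- function(passages) {
  rows <- lapply(seq_len(nrow(passages)), function(i) {
    sub <- passages$subfigures[[i]]
    data.frame(doc_id = passages$doc_id[i], figure = sub$figure,
               subfigure = sub$subfigure, code = passages$code[i],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[!duplicated(df[, c("doc_id", "figure", "subfigure")]), , drop = FALSE]
}
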