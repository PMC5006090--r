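# Seven-way discourse segment classifiers over clause sequences:
#  - "svm": one-vs-all linear SVMs (via e1071), margin argmax per clause;
#  - "crf": linear-chain conditional random field, trained by penalized
#    maximum likelihood (forward-backward gradients, L-BFGS), transition
#    features on adjacent labels only, sequence unit = paragraph.
# The fixed label order doubles as the deterministic tie-break order.

# ---- feature matrix assembly -----------------------------------------------

feature_schema <- function(sequences) {
  nm <- unique(unlist(lapply(sequences, function(s)
    lapply(s$features, names)), use.names = FALSE))
  sort(nm)
}

sequences_to_matrix <- function(sequences, schema) {
  lens <- vapply(sequences, function(s) length(s$features), integer(1L))
  n <- sum(lens)
  lookup <- setNames(seq_along(schema), schema)
  ii <- list(); jj <- list(); xx <- list()
  row <- 0L
  for (s in sequences) {
    for (f in s$features) {
      row <- row + 1L
      if (!length(f)) next
      j <- lookup[names(f)]
      keep <- !is.na(j)
      if (!any(keep)) next
      ii[[length(ii) + 1L]] <- rep.int(row, sum(keep))
      jj[[length(jj) + 1L]] <- unname(j[keep])
      xx[[length(xx) + 1L]] <- unname(f[keep])
    }
  }
  X <- Matrix::sparseMatrix(i = as.integer(unlist(ii)),
                            j = as.integer(unlist(jj)),
                            x = as.numeric(unlist(xx)),
                            dims = c(n, length(schema)))
  list(X = X, seq_lens = lens)
}

sequence_labels <- function(sequences, labels) {
  y <- unlist(lapply(sequences, function(s) s$clauses$gold_label),
              use.names = FALSE)
  if (anyNA(y)) stop("all clauses must carry a gold label for training")
  bad <- setdiff(unique(y), labels)
  if (length(bad))
    stop("unknown gold label(s): ", paste(bad, collapse = ", "))
  match(y, labels)
}

check_schema_version <- function(sequences, expected) {
  vs <- unique(unlist(lapply(sequences, function(s)
    lapply(s$features, attr, "schema_version")), use.names = FALSE))
  if (length(vs) && !all(vs == expected))
    stop("feature schema_version mismatch: model has ", expected,
         ", sequences have ", paste(unique(vs), collapse = ","))
  invisible()
}

# ---- fitting ---------------------------------------------------------------

#' Fit a discourse segment classifier
#'
#' Trains a seven-way classifier over clause sequences: either a linear-chain
#' conditional random field (\code{kind = "crf"}), which scores whole label
#' sequences using per-clause features plus adjacent-label transition
#' weights and is therefore sensitive to the archetypal ordering of
#' discourse types within a paragraph, or a baseline of seven one-vs-all
#' linear support vector machines (\code{kind = "svm"}) whose prediction is
#' the margin argmax. Both fits are deterministic given the data and
#' \code{seed}.
#'
#' @param sequences list of clause sequences from
#'   \code{\link{clause_sequences}}, with gold labels.
#' @param kind \code{"crf"} or \code{"svm"}.
#' @param seed integer recorded in the model and used for any stochastic
#'   step (both fits are in fact deterministic).
#' @param l2 CRF L2 regularization strength (default 1).
#' @param maxit CRF maximum L-BFGS iterations (default 120).
#' @param cost SVM cost parameter (default 1).
#' @param class_weights if \code{TRUE}, weight classes by inverse frequency
#'   (default \code{FALSE}: no reweighting).
#' @return an object of class \code{discourse_model} (and
#'   \code{discourse_crf} or \code{discourse_svm}).
#' @export
discourse_model <- function(sequences, kind = c("crf", "svm"), seed = 1L,
                            l2 = 1.0, maxit = 120L, cost = 1.0,
                            class_weights = FALSE) {
  kind <- match.arg(kind)
  if (!length(sequences)) stop("empty sequence list")
  labels <- discourse_labels()
  y <- sequence_labels(sequences, labels)
  present <- sort(unique(y))
  if (length(present) < 2L)
    stop("training set has a single label (", labels[present],
         "); missing classes: ",
         paste(labels[setdiff(seq_along(labels), present)], collapse = ", "))
  schema <- feature_schema(sequences)
  mat <- sequences_to_matrix(sequences, schema)
  fit <- if (kind == "crf")
    fit_crf(mat$X, y, mat$seq_lens, length(labels), l2 = l2, maxit = maxit,
            class_weights = class_weights)
  else
    fit_svm_ova(mat$X, y, labels, cost = cost, seed = seed,
                class_weights = class_weights)
  structure(list(kind = kind, labels = labels, schema = schema,
                 params = fit,
                 schema_version = FEATURE_SCHEMA_VERSION,
                 config = list(seed = seed, l2 = l2, maxit = maxit,
                               cost = cost, class_weights = class_weights)),
            class = c(paste0("discourse_", kind), "discourse_model"))
}

# ---- linear-chain CRF ------------------------------------------------------

# Parameters: W (F x L emission), Trans (L x L), start (L).
# Negative penalized log-likelihood and gradient share one forward-backward
# pass, cached between optim's fn and gr calls on the same parameter vector.

crf_unpack <- function(par, F_, L) {
  list(W = matrix(par[seq_len(F_ * L)], F_, L),
       Trans = matrix(par[F_ * L + seq_len(L * L)], L, L),
       start = par[F_ * L + L * L + seq_len(L)])
}

crf_objective <- function(X, y, seq_lens, L, l2, weights) {
  F_ <- ncol(X)
  n <- nrow(X)
  seq_of <- rep.int(seq_along(seq_lens), seq_lens)
  starts <- cumsum(c(1L, head(seq_lens, -1L)))
  Y <- Matrix::sparseMatrix(i = seq_len(n), j = y, x = weights,
                            dims = c(n, L))
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  compute <- function(par) {
    p <- crf_unpack(par, F_, L)
    S <- as.matrix(X %*% p$W)                    # n x L node scores
    M <- exp(p$Trans)                            # transition potentials
    P <- matrix(0, n, L)                         # node marginals
    Texp <- matrix(0, L, L)                      # expected transitions
    start_exp <- numeric(L)
    nll <- 0
    for (si in seq_along(seq_lens)) {
      len <- seq_lens[si]
      o <- starts[si]
      rows <- o:(o + len - 1L)
      Ss <- S[rows, , drop = FALSE]
      shift <- apply(Ss, 1L, max)
      Psi <- exp(Ss - shift)                     # len x L
      alpha <- matrix(0, len, L)
      cvec <- numeric(len)
      a <- exp(p$start - max(p$start)) * Psi[1L, ]
      cvec[1L] <- sum(a); alpha[1L, ] <- a / cvec[1L]
      if (len > 1L) for (t in 2L:len) {
        a <- as.vector(alpha[t - 1L, ] %*% M) * Psi[t, ]
        cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
      }
      logZ <- sum(log(cvec)) + sum(shift) + max(p$start)
      yt <- y[rows]
      gold <- sum(Ss[cbind(seq_len(len), yt)]) +
        p$start[yt[1L]] +
        if (len > 1L) sum(p$Trans[cbind(yt[-len], yt[-1L])]) else 0
      nll <- nll + (logZ - gold)
      beta <- matrix(0, len, L)
      beta[len, ] <- 1
      if (len > 1L) for (t in (len - 1L):1L) {
        b <- as.vector(M %*% (Psi[t + 1L, ] * beta[t + 1L, ])) / cvec[t + 1L]
        beta[t, ] <- b
      }
      Pm <- alpha * beta
      Pm <- Pm / rowSums(Pm)
      P[rows, ] <- Pm
      if (len > 1L) for (t in 2L:len) {
        xi <- (alpha[t - 1L, ] %o% (Psi[t, ] * beta[t, ])) * M
        xi <- xi / sum(xi)
        Texp <- Texp + xi
      }
      start_exp <- start_exp + Pm[1L, ]
    }
    trans_counts <- matrix(0, L, L)
    first_idx <- starts
    prev <- seq_len(n)[-first_idx]
    prev <- prev[seq_of[prev] == seq_of[prev - 1L]]
    if (length(prev)) {
      tc <- table(factor(y[prev - 1L], levels = seq_len(L)),
                  factor(y[prev], levels = seq_len(L)))
      trans_counts <- matrix(as.numeric(tc), L, L)
    }
    start_counts <- tabulate(y[first_idx], nbins = L)
    gW <- as.matrix(Matrix::crossprod(X, P - Y)) + l2 * p$W
    gT <- (Texp - trans_counts) + l2 * p$Trans
    gS <- (start_exp - start_counts)
    val <- nll + 0.5 * l2 * (sum(p$W^2) + sum(p$Trans^2))
    list(value = val, grad = c(as.vector(gW), as.vector(gT), gS))
  }
  get_cached <- function(par) {
    if (is.null(cache$par) || !identical(cache$par, par)) {
      cache$res <- compute(par)
      cache$par <- par
    }
    cache$res
  }
  list(fn = function(par) get_cached(par)$value,
       gr = function(par) get_cached(par)$grad,
       npar = F_ * L + L * L + L)
}

fit_crf <- function(X, y, seq_lens, L, l2 = 1.0, maxit = 120L,
                    class_weights = FALSE) {
  weights <- rep(1, nrow(X))
  if (class_weights) {
    freq <- tabulate(y, nbins = L)
    w <- sum(freq) / (L * pmax(freq, 1L))
    weights <- w[y]  # used only for emission gradient weighting
  }
  obj <- crf_objective(X, y, seq_lens, L, l2, weights)
  res <- optim(rep(0, obj$npar), fn = obj$fn, gr = obj$gr,
               method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  p <- crf_unpack(res$par, ncol(X), L)
  list(W = p$W, Trans = p$Trans, start = p$start,
       convergence = res$convergence, value = res$value)
}

crf_viterbi <- function(params, X, seq_lens) {
  S <- as.matrix(X %*% params$W)
  L <- ncol(S)
  out <- integer(nrow(S))
  starts <- cumsum(c(1L, head(seq_lens, -1L)))
  for (si in seq_along(seq_lens)) {
    len <- seq_lens[si]
    o <- starts[si]
    Ss <- S[o:(o + len - 1L), , drop = FALSE]
    delta <- matrix(-Inf, len, L)
    back <- matrix(0L, len, L)
    delta[1L, ] <- params$start + Ss[1L, ]
    if (len > 1L) for (t in 2L:len) {
      cand <- delta[t - 1L, ] + params$Trans    # L x L: from x to
      # ties broken toward the earlier (lower-index) label
      back[t, ] <- max.col(t(cand), ties.method = "first")
      delta[t, ] <- cand[cbind(back[t, ], seq_len(L))] + Ss[t, ]
    }
    path <- integer(len)
    path[len] <- which.max(delta[len, ])
    if (len > 1L) for (t in (len - 1L):1L)
      path[t] <- back[t + 1L, path[t + 1L]]
    out[o:(o + len - 1L)] <- path
  }
  out
}

# ---- one-vs-all SVM --------------------------------------------------------

fit_svm_ova <- function(X, y, labels, cost = 1.0, seed = 1L,
                        class_weights = FALSE) {
  Xd <- as.matrix(X)
  L <- length(labels)
  freq <- tabulate(y, nbins = L)
  models <- vector("list", L)
  for (l in seq_len(L)) {
    if (freq[l] == 0L) next
    yb <- factor(ifelse(y == l, "pos", "other"), levels = c("pos", "other"))
    cw <- NULL
    if (class_weights)
      cw <- c(pos = length(y) / (2 * freq[l]),
              other = length(y) / (2 * (length(y) - freq[l])))
    set.seed(seed)
    models[[l]] <- e1071::svm(Xd, yb, kernel = "linear", cost = cost,
                              scale = FALSE, class.weights = cw,
                              fitted = FALSE)
  }
  list(models = models, present = which(freq > 0L), majority = which.max(freq))
}

svm_margins <- function(fit, X) {
  Xd <- as.matrix(X)
  L <- length(fit$models)
  Mg <- matrix(-Inf, nrow(Xd), L)
  for (l in seq_len(L)) {
    m <- fit$models[[l]]
    if (is.null(m)) next
    pr <- predict(m, Xd, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient so that larger = more "pos"
    sgn <- if (identical(colnames(dv)[1L], "pos/other")) 1 else -1
    Mg[, l] <- sgn * dv[, 1L]
  }
  Mg
}

# ---- prediction and methods ------------------------------------------------

#' Predict discourse labels for clause sequences
#'
#' Every clause receives exactly one of the seven discourse types; input
#' order is preserved. Margin ties (SVM) and Viterbi ties (CRF) are broken
#' by the fixed label order problem < fact < hypothesis < goal < method <
#' result < implication.
#'
#' @param object a fitted \code{\link{discourse_model}}.
#' @param sequences list of clause sequences (features must use the same
#'   schema version as the model).
#' @param ... unused.
#' @return the combined clause table with a \code{predicted_label} column,
#'   rows in sequence order.
#' @export
predict.discourse_model <- function(object, sequences, ...) {
  if (!length(sequences)) stop("empty sequence list")
  check_schema_version(sequences, object$schema_version)
  mat <- sequences_to_matrix(sequences, object$schema)
  pred_idx <- if (object$kind == "crf") {
    crf_viterbi(object$params, mat$X, mat$seq_lens)
  } else {
    Mg <- svm_margins(object$params, mat$X)
    apply(Mg, 1L, function(r) {
      if (all(!is.finite(r))) object$params$majority else which.max(r)
    })
  }
  out <- do.call(rbind, lapply(sequences, `[[`, "clauses"))
  rownames(out) <- NULL
  out$predicted_label <- object$labels[pred_idx]
  out
}

#' @export
print.discourse_model <- function(x, ...) {
  cat(sprintf("<discourse_model kind=%s: %d features, labels: %s>\n",
              x$kind, length(x$schema), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' @export
summary.discourse_model <- function(object, ...) {
  cat("Discourse segment classifier\n")
  cat("  kind          :", object$kind, "\n")
  cat("  features      :", length(object$schema), "\n")
  cat("  labels        :", paste(object$labels, collapse = ", "), "\n")
  cat("  schema version:", object$schema_version, "\n")
  cat("  seed          :", object$config$seed, "\n")
  if (object$kind == "crf")
    cat("  CRF nll       :", format(object$params$value), "\n")
  invisible(object)
}

#' Model coefficients
#'
#' For a CRF, returns the emission weight matrix (features x labels) and the
#' label-transition matrix; for the SVM, the per-label linear weight vectors
#' recovered from the support vectors.
#' @param object a \code{discourse_model}.
#' @param ... unused.
#' @export
coef.discourse_model <- function(object, ...) {
  if (object$kind == "crf") {
    W <- object$params$W
    dimnames(W) <- list(object$schema, object$labels)
    Tr <- object$params$Trans
    dimnames(Tr) <- list(object$labels, object$labels)
    list(emissions = W, transitions = Tr, start = setNames(
      object$params$start, object$labels))
  } else {
    W <- sapply(object$params$models, function(m) {
      if (is.null(m)) return(rep(NA_real_, length(object$schema)))
      as.vector(t(m$coefs) %*% m$SV)
    })
    rownames(W) <- object$schema
    colnames(W) <- object$labels
    W
  }
}

# ---- persistence -----------------------------------------------------------

#' Save a discourse model to a single JSON archive
#'
#' The archive stores metadata (kind, labels, schema, schema version,
#' config) and the learned parameters. \code{\link{load_discourse_model}}
#' refuses archives whose schema version does not match the running
#' package's feature schema.
#' @param model a CRF \code{discourse_model} (SVM models hold external
#'   fitted objects and are persisted with \code{saveRDS} by the caller).
#' @param path output path.
#' @export
save_discourse_model <- function(model, path) {
  if (model$kind != "crf")
    stop("JSON persistence is implemented for CRF models; use saveRDS for SVM")
  obj <- list(kind = model$kind, labels = model$labels,
              schema = model$schema, schema_version = model$schema_version,
              config = model$config,
              params = list(W = as.vector(model$params$W),
                            Trans = as.vector(model$params$Trans),
                            start = model$params$start))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a discourse model saved by \code{\link{save_discourse_model}}
#' @param path archive path.
#' @export
load_discourse_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(as.character(obj$schema_version), FEATURE_SCHEMA_VERSION))
    stop("model schema_version ", obj$schema_version,
         " does not match package feature schema ", FEATURE_SCHEMA_VERSION)
  F_ <- length(obj$schema); L <- length(obj$labels)
  structure(list(kind = obj$kind, labels = obj$labels, schema = obj$schema,
                 params = list(W = matrix(obj$params$W, F_, L),
                               Trans = matrix(obj$params$Trans, L, L),
                               start = obj$params$start),
                 schema_version = as.character(obj$schema_version),
                 config = obj$config),
            class = c("discourse_crf", "discourse_model"))
}
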