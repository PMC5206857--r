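#' Joint scoring of predicted events
#'
#' Each predicted event (typ, (t_i, a_j, a_k)) is scored by combining two
#' signals: the maximum semantic similarity between its sentence and the
#' training sentences containing the same trigger, and the importance of
#' the trigger estimated from the training annotations.  Predictions whose
#' joint score falls below a threshold delta are treated as false
#' positives and removed.  The default similarity backend is a
#' deterministic letter-trigram bag-of-words cosine; a convolutional
#' semantic model (word hashing, convolution over a token window,
#' element-wise max pooling, tanh semantic layer) is available with
#' loadable or seeded-random weights.
#'
#' @name jointscore
NULL

#' Letter n-gram word hashing
#'
#' Counts the letter n-grams of a term wrapped in word-boundary marks
#' (\code{#}), the classic trick that shrinks a word vocabulary to a
#' bounded n-gram vocabulary.
#'
#' @param term Single string.
#' @param n Gram length, at least 1.
#' @return Named integer vector of n-gram counts (empty for an empty
#'   term).
#' @export
#' @examples
#' word_hash("cat", 3)   # "#ca", "cat", "at#"
word_hash <- function(term, n = 3L) {
  stopifnot(n >= 1L)
  if (!nzchar(term)) return(stats::setNames(integer(0), character(0)))
  padded <- paste0("#", tolower(term), "#")
  chars <- strsplit(padded, "")[[1L]]
  if (length(chars) < n) return(stats::setNames(1L, padded))
  grams <- vapply(seq_len(length(chars) - n + 1L),
                  function(i) paste(chars[i:(i + n - 1L)], collapse = ""),
                  character(1L))
  tab <- table(grams)
  stats::setNames(as.integer(tab), names(tab))
}

# sum of sparse named count vectors
add_sparse <- function(vecs) {
  all <- unlist(vecs)
  if (is.null(all) || !length(all)) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(as.numeric(all), names(all), sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Letter-trigram embedding of a token sequence
#'
#' The default sentence representation: the sum of the word-hash vectors
#' of the tokens.
#'
#' @param tokens Character vector of tokens.
#' @param n Gram length.
#' @return Named numeric count vector.
#' @export
trigram_embedding <- function(tokens, n = 3L) {
  add_sparse(lapply(tokens, word_hash, n = n))
}

#' Cosine relevance of two semantic vectors
#'
#' Sparse (named) and dense vectors are both accepted; named vectors are
#' aligned on their union of names.  A zero vector yields 0 with a
#' warning.
#'
#' @param a,b Numeric vectors, named (sparse counts) or plain
#'   equal-length.
#' @return Cosine similarity in \eqn{[-1, 1]}.
#' @export
relevance <- function(a, b) {
  if (!is.null(names(a)) || !is.null(names(b))) {
    keys <- union(names(a), names(b))
    av <- stats::setNames(rep(0, length(keys)), keys)
    bv <- av
    av[names(a)] <- a
    bv[names(b)] <- b
    a <- av; b <- bv
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("zero vector in relevance(); returning 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' Random or degenerate weights for the convolutional semantic model
#'
#' @param hash_dim Dimension the letter trigrams are hashed into.
#' @param conv_dim Convolutional feature dimension.
#' @param sem_dim Semantic output dimension.
#' @param window Token window width of the convolution; \code{Inf} treats
#'   the whole sentence as one window.
#' @param activation \code{"tanh"} (default) or \code{"linear"}.
#' @param seed Seed for the random Gaussian weights; ignored when
#'   \code{identity = TRUE}.
#' @param identity Use identity weight matrices and zero biases (requires
#'   equal dimensions); with \code{window = Inf} and linear activation the
#'   model degenerates to the letter-trigram bag embedding.
#' @return Weight list consumed by [cdssm_forward()].
#' @export
cdssm_weights <- function(hash_dim = 300L, conv_dim = 128L, sem_dim = 64L,
                          window = 3L, activation = c("tanh", "linear"),
                          seed = 1L, identity = FALSE) {
  activation <- match.arg(activation)
  if (identity) {
    conv_dim <- hash_dim; sem_dim <- hash_dim
    Wc <- diag(hash_dim); Ws <- diag(hash_dim)
    bc <- rep(0, conv_dim); bs <- rep(0, sem_dim)
  } else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(as.integer(seed))
    Wc <- matrix(stats::rnorm(conv_dim * hash_dim, sd = 1 / sqrt(hash_dim)),
                 conv_dim, hash_dim)
    bc <- rep(0, conv_dim)
    Ws <- matrix(stats::rnorm(sem_dim * conv_dim, sd = 1 / sqrt(conv_dim)),
                 sem_dim, conv_dim)
    bs <- rep(0, sem_dim)
  }
  list(hash_dim = hash_dim, window = window, activation = activation,
       Wc = Wc, bc = bc, Ws = Ws, bs = bs)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# hash a named trigram count vector into a fixed-dimension dense vector
hash_to_dense <- function(counts, dim) {
  v <- rep(0, dim)
  if (!length(counts)) return(v)
  idx <- (vapply(names(counts), function(g) {
    sum(utf8ToInt(g) * seq_len(nchar(g))^2)
  }, numeric(1L)) %% dim) + 1L
  for (k in seq_along(idx)) v[[idx[[k]]]] <- v[[idx[[k]]]] + counts[[k]]
  v
}

#' Convolutional semantic forward pass
#'
#' Word-hash layer (letter trigrams hashed to a fixed dimension), linear
#' convolution over a sliding token window, element-wise max pooling over
#' the windows, and a nonlinear semantic layer.  Deterministic given the
#' weights.
#'
#' @param tokens Character vector of sentence tokens.
#' @param weights From [cdssm_weights()] (or loaded from file).
#' @return Numeric semantic vector.
#' @export
cdssm_forward <- function(tokens, weights) {
  act <- switch(weights$activation, tanh = tanh, linear = identity,
                stop("unknown activation ", weights$activation))
  if (!length(tokens)) return(act(as.numeric(weights$Ws %*% rep(0, ncol(weights$Ws)) + weights$bs)))
  tok_vecs <- lapply(tokens, function(t) hash_to_dense(word_hash(t, 3L),
                                                       weights$hash_dim))
  n <- length(tok_vecs)
  win <- if (is.infinite(weights$window)) n else min(as.integer(weights$window), n)
  starts <- seq_len(n - win + 1L)
  conv <- vapply(starts, function(s) {
    x <- Reduce(`+`, tok_vecs[s:(s + win - 1L)])
    act(as.numeric(weights$Wc %*% x + weights$bc))
  }, numeric(nrow(weights$Wc)))
  pooled <- if (is.matrix(conv)) apply(conv, 1L, max) else conv
  act(as.numeric(weights$Ws %*% pooled + weights$bs))
}

#' Sentence embedding under a similarity backend
#'
#' @param tokens Character vector of tokens.
#' @param backend \code{"trigram"} (default, deterministic bag-of-trigrams)
#'   or \code{"cdssm"}.
#' @param weights Weights for the \code{"cdssm"} backend.
#' @return A vector suitable for [relevance()].
#' @export
embed_sentence <- function(tokens, backend = c("trigram", "cdssm"),
                           weights = NULL) {
  backend <- match.arg(backend)
  if (backend == "trigram") return(trigram_embedding(tokens))
  if (is.null(weights)) weights <- cdssm_weights()
  cdssm_forward(tokens, weights)
}

#' Maximum similarity to the same-trigger sentences
#'
#' The similarity of sentence \code{s_prime} to a set \code{d} of
#' sentences sharing its trigger is the maximum pairwise cosine relevance,
#' and exactly 0 when \code{d} is empty.
#'
#' @param s_prime Character vector: the tokens of the sentence holding the
#'   prediction.
#' @param d List of token vectors of the same-trigger sentences (possibly
#'   empty).
#' @inheritParams embed_sentence
#' @return Maximum relevance, or 0 for empty \code{d}.
#' @export
sentence_similarity <- function(s_prime, d, backend = c("trigram", "cdssm"),
                                weights = NULL) {
  backend <- match.arg(backend)
  if (!length(d)) return(0)
  e0 <- embed_sentence(s_prime, backend, weights)
  max(vapply(d, function(s) relevance(e0, embed_sentence(s, backend, weights)),
             numeric(1L)))
}

#' Trigger statistics from training annotations
#'
#' Counts, per trigger stem, the number of annotated event instances of
#' each type, plus the sentences (token vectors) in which each trigger
#' stem occurs (used for the similarity part of the joint score).
#'
#' @param docs Training documents with gold events.
#' @return List with \code{counts} (data.frame stem/type/count),
#'   \code{total} (total event count over all triggers) and
#'   \code{sentences} (stem-keyed list of token vectors).
#' @export
trigger_stats <- function(docs) {
  counts <- build_trigger_dictionary(docs)
  sentences <- list()
  for (doc in docs) {
    for (sent in doc$sentences) {
      stems <- unique(sent$tokens$stem[sent$tokens$pos != "."])
      hit <- intersect(stems, counts$stem)
      for (st in hit) {
        sentences[[st]] <- c(sentences[[st]], list(sent$tokens$text))
      }
    }
  }
  list(counts = counts, total = sum(counts$count), sentences = sentences)
}

#' Trigger importance
#'
#' P1 is the fraction of the trigger's annotated instances that carry the
#' predicted type; P2 is the trigger's share of all annotated event
#' instances; the importance is their weighted mean with weights w1 (how
#' often this trigger is predicted with this type in the result set) and
#' w2 (how often this trigger is predicted at all).
#'
#' @param trigger Trigger stem.
#' @param typ Predicted event type.
#' @param stats Trigger statistics from [trigger_stats()].
#' @param w1,w2 Non-negative weights from the predicted result set;
#'   \code{w1 + w2} must be positive.
#' @return List with \code{p1}, \code{p2}, \code{p} (all in \eqn{[0,1]})
#'   and \code{unseen} flag.
#' @export
trigger_importance <- function(trigger, typ, stats, w1, w2) {
  if (w1 + w2 <= 0) stop("w1 + w2 must be positive")
  cnt <- stats$counts[stats$counts$stem == trigger, , drop = FALSE]
  tot_i <- sum(cnt$count)
  if (tot_i == 0) {
    return(list(p1 = 0, p2 = 0, p = 0, unseen = TRUE))
  }
  f_typ <- sum(cnt$count[cnt$type == typ])
  p1 <- f_typ / tot_i
  p2 <- tot_i / stats$total
  list(p1 = p1, p2 = p2, p = (w1 * p1 + w2 * p2) / (w1 + w2), unseen = FALSE)
}

#' Joint score of a prediction
#'
#' \code{(1 - sigma) * p_ti + sigma * sim}.  Negative similarities are
#' clamped to 0 beforehand so the score lies in \eqn{[0,1]}.
#'
#' @param p_ti Trigger importance in \eqn{[0,1]}.
#' @param sim Sentence similarity; negatives are clamped to 0.
#' @param sigma Mixing weight in \eqn{[0,1]} on the similarity term.
#' @return Score in \eqn{[0,1]}.
#' @export
joint_score <- function(p_ti, sim, sigma = 0.7) {
  if (sigma < 0 || sigma > 1) stop("'sigma' must lie in [0, 1]")
  sim <- max(0, min(1, sim))
  (1 - sigma) * p_ti + sigma * sim
}

#' Score a set of predicted events
#'
#' Computes, for every prediction, the trigger importance (with w1/w2
#' counted over the prediction set itself), the maximum similarity of its
#' sentence to the training sentences containing the same trigger stem,
#' and the joint score.
#'
#' @param events Integrated predictions (rows of
#'   [integrate_predictions()] output, any number of documents).
#' @param docs The documents the predictions came from (for sentence
#'   tokens), keyed by document id.
#' @param stats Trigger statistics of the training corpus.
#' @param sigma Mixing weight.
#' @param backend,weights Similarity backend configuration.
#' @param same_type Restrict the same-trigger sentence set to training
#'   sentences whose trigger also carries the predicted type (off by
#'   default: stem match only).
#' @return \code{events} with columns \code{p1}, \code{p2}, \code{p_ti},
#'   \code{sim}, \code{score} appended.
#' @export
score_predictions <- function(events, docs, stats, sigma = 0.7,
                              backend = "trigram", weights = NULL,
                              same_type = FALSE) {
  n <- nrow(events)
  cols <- c("p1", "p2", "p_ti", "sim", "score")
  for (cl in cols) events[[cl]] <- numeric(n)
  if (!n) return(events)
  w2_tab <- table(events$trig_stem)
  w1_tab <- table(paste(events$trig_stem, events$type))
  # embeddings are cached: per trigger stem for the training-sentence set
  # d, per (doc, sentence) for the prediction sentences
  d_cache <- new.env(parent = emptyenv())
  s_cache <- new.env(parent = emptyenv())
  d_embeddings <- function(stem) {
    if (is.null(d_cache[[stem]])) {
      d_cache[[stem]] <- lapply(stats$sentences[[stem]], embed_sentence,
                                backend = backend, weights = weights)
    }
    d_cache[[stem]]
  }
  s_embedding <- function(doc_id, sent) {
    key <- paste(doc_id, sent)
    if (is.null(s_cache[[key]])) {
      s_cache[[key]] <- embed_sentence(
        docs[[doc_id]]$sentences[[sent]]$tokens$text, backend, weights)
    }
    s_cache[[key]]
  }
  for (i in seq_len(n)) {
    e <- events[i, , drop = FALSE]
    w1 <- as.integer(w1_tab[[paste(e$trig_stem, e$type)]])
    w2 <- as.integer(w2_tab[[e$trig_stem]])
    ti <- trigger_importance(e$trig_stem, e$type, stats, w1, w2)
    d <- stats$sentences[[e$trig_stem]]
    if (same_type && !is.null(d)) {
      keep_typ <- stats$counts$type[stats$counts$stem == e$trig_stem]
      if (!e$type %in% keep_typ) d <- NULL
    }
    sim <- if (is.null(d) || !length(d)) 0 else {
      e0 <- s_embedding(e$doc, e$sent)
      max(vapply(d_embeddings(e$trig_stem), relevance, numeric(1L), a = e0))
    }
    events$p1[[i]] <- ti$p1
    events$p2[[i]] <- ti$p2
    events$p_ti[[i]] <- ti$p
    events$sim[[i]] <- sim
    events$score[[i]] <- joint_score(ti$p, sim, sigma)
  }
  events
}

#' Threshold predictions on the joint score
#'
#' @param preds Scored predictions (with a \code{score} column).
#' @param delta Threshold in \eqn{[0,1]}; predictions with
#'   \code{score < delta} are removed as false positives.
#' @return List with \code{kept} and \code{removed} data.frames.
#' @export
filter_by_score <- function(preds, delta = 0.5) {
  if (delta < 0 || delta > 1) stop("'delta' must lie in [0, 1]")
  keep <- preds$score >= delta
  list(kept = preds[keep, , drop = FALSE],
       removed = preds[!keep, , drop = FALSE])
}
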