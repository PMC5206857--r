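#' One-vs-rest classification and pair/triplet integration
#'
#' Two multiclass linear models are trained on the selected samples: a pair
#' model over the nine event types plus an explicit negative class, and a
#' triplet model over the Binding/regulation types plus negative.  Each
#' class is a binary L2-regularised linear discriminant (one-vs-rest); a
#' candidate's predicted class is the argmax of the decision margins,
#' including the negative class.  Predicted triplets are then integrated
#' with pair predictions: a Binding triplet subsumes its two single-theme
#' Binding pairs, a regulation triplet emits its second argument as Cause,
#' and untouched pairs are emitted directly.
#'
#' @name classify_integrate
NULL

# sparse design matrix from a list of named feature vectors and a
# vocabulary (named index); unseen features are dropped
design_matrix <- function(maps, vocab) {
  idx <- lapply(maps, function(m) {
    j <- unname(vocab[names(m)])
    keep <- !is.na(j)
    cbind(j = j[keep], x = unname(m)[keep])
  })
  ni <- vapply(idx, nrow, integer(1L))
  i <- rep(seq_along(maps), ni)
  jm <- do.call(rbind, idx)
  Matrix::sparseMatrix(i = i, j = jm[, "j"], x = jm[, "x"],
                       dims = c(length(maps), length(vocab)))
}

# per-class binary ridge-logistic fits; class weights are a damped
# version of sklearn-style "balanced" (power 0.5 by default: residual,
# mild re-weighting on top of the pattern-based selection)
fit_ovr <- function(maps, labels, classes, lambda = 1e-3,
                    weight_power = 0.5) {
  feats <- sort(unique(unlist(lapply(maps, names), use.names = FALSE)))
  vocab <- stats::setNames(seq_along(feats), feats)
  X <- design_matrix(maps, vocab)
  coefs <- list()
  for (cl in classes) {
    y <- as.integer(labels == cl)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    if (n1 < 2L || n0 < 2L) {
      warning(sprintf(
        "class %s has too few training examples (%d vs %d); dropped", cl, n1, n0))
      next
    }
    w <- rep(1, length(y))
    if (weight_power > 0) {
      w[y == 1L] <- (length(y) / (2 * n1))^weight_power
      w[y == 0L] <- (length(y) / (2 * n0))^weight_power
    }
    fit <- glmnet::glmnet(X, y, family = "binomial", weights = w, alpha = 0,
                          lambda = c(1, 0.1, 0.01, lambda),
                          standardize = FALSE)
    b <- stats::coef(fit, s = lambda)
    coefs[[cl]] <- as.numeric(b)
  }
  list(vocab = vocab, coefs = coefs, classes = names(coefs), lambda = lambda)
}

ovr_margins <- function(model, maps) {
  X <- design_matrix(maps, model$vocab)
  out <- matrix(-Inf, nrow = length(maps), ncol = length(model$classes),
                dimnames = list(NULL, model$classes))
  for (cl in model$classes) {
    b <- model$coefs[[cl]]
    out[, cl] <- as.numeric(X %*% b[-1L] + b[[1L]])
  }
  out
}

# one-vs-rest decision: argmax of the per-type margins, negative when no
# margin exceeds 0 (logistic decision boundary)
ovr_predict <- function(model, maps) {
  if (!length(maps)) {
    return(data.frame(type = character(), margin = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(model) || !length(model$classes)) {
    return(data.frame(type = rep("negative", length(maps)),
                      margin = rep(0, length(maps)), stringsAsFactors = FALSE))
  }
  m <- ovr_margins(model, maps)
  best <- max.col(m, ties.method = "first")
  margin <- m[cbind(seq_along(best), best)]
  data.frame(type = ifelse(margin > 0, model$classes[best], "negative"),
             margin = margin, stringsAsFactors = FALSE)
}

#' Train the pair and triplet models
#'
#' @param pairs Selected labeled candidate pairs (label column: event type
#'   or \code{"negative"}).
#' @param triplets Selected labeled candidate triplets.
#' @param pair_maps,triplet_maps Feature maps aligned with the rows of
#'   \code{pairs}/\code{triplets} (lists of named numeric vectors).
#' @param lambda Ridge penalty of the per-class binary fits.
#' @param weight_power Damping exponent of the balanced class weights
#'   (0 = no weighting, 1 = fully balanced; default 0.5, mild).
#' @return A model bundle: \code{pair} and \code{triplet} one-vs-rest
#'   models (vocabulary plus per-class coefficients).
#' @export
train_event_models <- function(pairs, triplets, pair_maps, triplet_maps,
                               lambda = 1e-3, weight_power = 0.5) {
  pair_classes <- intersect(event_types(), unique(pairs$label))
  pair_model <- fit_ovr(pair_maps, pairs$label, pair_classes, lambda,
                        weight_power)
  triplet_model <- NULL
  if (!is.null(triplets) && nrow(triplets)) {
    tri_classes <- intersect(event_types(c("BIND", "REG")),
                             unique(triplets$label))
    triplet_model <- fit_ovr(triplet_maps, triplets$label, tri_classes, lambda,
                             weight_power)
  }
  structure(list(pair = pair_model, triplet = triplet_model, lambda = lambda),
            class = "event_models")
}

#' Classify the candidates of a document
#'
#' Generates candidate pairs and triplets, applies the sequential-pattern
#' filter, extracts features and assigns each surviving candidate its
#' argmax class with a decision margin.
#'
#' @param doc A \code{standoff_document} (no .a2 needed).
#' @param models An \code{event_models} bundle.
#' @param dict Trigger dictionary.
#' @param ls Mined \code{pattern_set} used for candidate selection.
#' @param theta Selection threshold (match count must exceed it).
#' @return List with data.frames \code{pairs} and \code{triplets}, each
#'   carrying \code{type} and \code{margin} columns (all candidates, with
#'   \code{"negative"} assignments retained).
#' @export
predict_events <- function(doc, models, dict, ls, theta = 2) {
  pairs <- generate_pairs(doc, dict)
  pairs$label <- NULL
  pairs <- select_samples(pairs, ls, theta)
  triplets <- generate_triplets(doc, dict)
  triplets$label <- NULL
  triplets <- filter_triplet_candidates(triplets, ls, theta)
  pp <- ovr_predict(models$pair, feature_maps(pairs, doc))
  pairs$type <- pp$type; pairs$margin <- pp$margin
  tp <- ovr_predict(models$triplet, feature_maps(triplets, doc))
  triplets$type <- tp$type; triplets$margin <- tp$margin
  list(pairs = pairs, triplets = triplets)
}

#' Integrate pair and triplet predictions into events
#'
#' Rules: (a) each positively predicted Binding triplet (c, a1, a2) becomes
#' one two-theme Binding event, and Binding pair predictions (c, a1) and
#' (c, a2) are removed as subsumed; (b) each REG-class triplet becomes an
#' event with a1 as Theme and a2 as Cause, and the same-type pair (c, a1)
#' is removed as subsumed; (c) pairs untouched by any triplet are emitted
#' directly; (d) SVT pairs are always emitted.  When the identical
#' (trigger, argument) pair is predicted with conflicting types only the
#' higher-margin prediction is kept.
#'
#' @param preds Prediction set from [predict_events()].
#' @return Data.frame of event predictions (type, trigger/argument tokens,
#'   margins); Theme2 filled for two-theme Binding, Cause for regulation.
#' @export
integrate_predictions <- function(preds) {
  pairs <- preds$pairs
  pairs <- pairs[pairs$type != "negative", , drop = FALSE]
  triplets <- preds$triplets
  if (!is.null(triplets) && nrow(triplets)) {
    triplets <- triplets[triplets$type != "negative", , drop = FALSE]
  }

  # conflicting types on the identical (trigger, argument): keep the
  # higher margin
  if (nrow(pairs)) {
    key <- paste(pairs$doc, pairs$sent, pairs$trig_tok, pairs$arg_tok)
    ord <- order(key, -pairs$margin)
    pairs <- pairs[ord, , drop = FALSE]
    dup <- duplicated(key[ord])
    if (any(dup)) {
      message(sprintf("integrate: %d conflicting pair prediction(s) dropped",
                      sum(dup)))
    }
    pairs <- pairs[!dup, , drop = FALSE]
  }

  events <- list()
  emit <- function(row) events[[length(events) + 1L]] <<- row
  pair_key <- if (nrow(pairs)) {
    paste(pairs$doc, pairs$sent, pairs$trig_tok, pairs$arg_tok, pairs$type)
  } else character(0)
  subsumed <- rep(FALSE, nrow(pairs))

  if (!is.null(triplets) && nrow(triplets)) {
    for (i in seq_len(nrow(triplets))) {
      tr <- triplets[i, , drop = FALSE]
      cls <- event_class(tr$type)
      if (cls == "BIND") {
        subsumed <- subsumed |
          pair_key %in% paste(tr$doc, tr$sent, tr$trig_tok,
                              c(tr$a1_tok, tr$a2_tok), tr$type)
        emit(data.frame(
          doc = tr$doc, sent = tr$sent, type = tr$type, trig_tok = tr$trig_tok,
          trig_stem = tr$trig_stem,
          theme_tok = tr$a1_tok, theme_kind = tr$a1_kind, theme_id = tr$a1_id,
          theme2_tok = tr$a2_tok, theme2_kind = tr$a2_kind, theme2_id = tr$a2_id,
          cause_tok = NA_integer_, cause_kind = NA_character_,
          cause_id = NA_character_, margin = tr$margin,
          stringsAsFactors = FALSE))
      } else if (cls == "REG") {
        subsumed <- subsumed |
          pair_key %in% paste(tr$doc, tr$sent, tr$trig_tok, tr$a1_tok, tr$type)
        emit(data.frame(
          doc = tr$doc, sent = tr$sent, type = tr$type, trig_tok = tr$trig_tok,
          trig_stem = tr$trig_stem,
          theme_tok = tr$a1_tok, theme_kind = tr$a1_kind, theme_id = tr$a1_id,
          theme2_tok = NA_integer_, theme2_kind = NA_character_,
          theme2_id = NA_character_,
          cause_tok = tr$a2_tok, cause_kind = tr$a2_kind, cause_id = tr$a2_id,
          margin = tr$margin, stringsAsFactors = FALSE))
      }
    }
  }
  pairs <- pairs[!subsumed, , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, , drop = FALSE]
    emit(data.frame(
      doc = p$doc, sent = p$sent, type = p$type, trig_tok = p$trig_tok,
      trig_stem = p$trig_stem,
      theme_tok = p$arg_tok, theme_kind = p$arg_kind, theme_id = p$arg_id,
      theme2_tok = NA_integer_, theme2_kind = NA_character_,
      theme2_id = NA_character_, cause_tok = NA_integer_,
      cause_kind = NA_character_, cause_id = NA_character_,
      margin = p$margin, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, events)
  if (is.null(out)) {
    out <- data.frame(doc = character(), sent = integer(), type = character(),
                      trig_tok = integer(), trig_stem = character(),
                      theme_tok = integer(), theme_kind = character(),
                      theme_id = character(), theme2_tok = integer(),
                      theme2_kind = character(), theme2_id = character(),
                      cause_tok = integer(), cause_kind = character(),
                      cause_id = character(), margin = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Assemble integrated predictions into standoff events
#'
#' Resolves nested regulation in one bottom-up pass: SVT and Binding
#' events are numbered first, then REG-class events whose Theme is a
#' trigger token are linked to the (highest-margin) event predicted at
#' that trigger; REG predictions with an unresolvable event Theme are
#' dropped.  Returns the .a2-style trigger and event tables for one
#' document.
#'
#' @param events Integrated predictions of one document
#'   (from [integrate_predictions()]).
#' @param doc The corresponding document.
#' @return List with \code{triggers} and \code{events} data.frames in the
#'   shape read_standoff produces; both empty when nothing was predicted.
#' @export
assemble_events <- function(events, doc) {
  empty <- list(triggers = empty_ann_df(), events = empty_event_df())
  if (!nrow(events)) return(empty)
  events <- events[order(-events$margin), , drop = FALSE]
  n_prot <- nrow(doc$proteins)
  trig_ids <- character(0)
  trig_df <- empty_ann_df()
  ev_df <- empty_event_df()
  next_t <- n_prot
  trigger_id_for <- function(sent, tok_row, type) {
    key <- paste(sent, tok_row, type)
    if (!is.null(trig_ids[key]) && !is.na(trig_ids[key])) return(trig_ids[[key]])
    tok <- doc$sentences[[sent]]$tokens[tok_row, ]
    next_t <<- next_t + 1L
    id <- sprintf("T%d", next_t)
    trig_df <<- rbind(trig_df, data.frame(
      id = id, type = type, char_start = tok$char_start,
      char_end = tok$char_end, text = tok$text, stringsAsFactors = FALSE))
    trig_ids[key] <<- id
    id
  }
  # event id of the best prediction anchored at a trigger token (for
  # nested Theme resolution)
  anchor_eid <- new.env(parent = emptyenv())
  classes <- event_class(events$type)
  n_e <- 0L
  build <- function(rows) {
    for (i in rows) {
      e <- events[i, , drop = FALSE]
      theme_ref <- if (e$theme_kind == "protein") e$theme_id else {
        akey <- paste(e$sent, e$theme_tok)
        if (is.null(anchor_eid[[akey]])) NA_character_ else anchor_eid[[akey]]
      }
      if (is.na(theme_ref)) next
      cause_ref <- NA_character_
      if (!is.na(e$cause_tok)) {
        cause_ref <- if (e$cause_kind == "protein") e$cause_id else {
          akey <- paste(e$sent, e$cause_tok)
          if (is.null(anchor_eid[[akey]])) NA_character_ else anchor_eid[[akey]]
        }
        if (is.na(cause_ref)) next
      }
      theme2_ref <- if (!is.na(e$theme2_tok)) e$theme2_id else NA_character_
      tid <- trigger_id_for(e$sent, e$trig_tok, e$type)
      n_e <<- n_e + 1L
      eid <- sprintf("E%d", n_e)
      ev_df <<- rbind(ev_df, data.frame(
        id = eid, type = e$type, trigger_id = tid, theme = theme_ref,
        theme2 = theme2_ref, cause = cause_ref, stringsAsFactors = FALSE))
      akey <- paste(e$sent, e$trig_tok)
      if (is.null(anchor_eid[[akey]])) anchor_eid[[akey]] <- eid
    }
  }
  build(which(classes != "REG"))
  build(which(classes == "REG"))
  list(triggers = trig_df, events = ev_df)
}
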