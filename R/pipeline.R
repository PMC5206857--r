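#' End-to-end training and prediction
#'
#' Orchestrates the full system: preprocessing, sequence-database
#' construction from labeled pairs, pattern mining, sample selection,
#' feature extraction, one-vs-rest training, prediction with pair/triplet
#' integration, joint rescoring and an internal evaluator with approximate
#' trigger-span and recursive argument matching (used on synthetic
#' corpora; it does not claim identity with the shared-task online
#' scorer).
#'
#' @name pipeline
NULL

as_docs <- function(corpus, with_a2 = TRUE) {
  if (is.character(corpus)) read_corpus(corpus, with_a2 = with_a2) else corpus
}

# feature maps for candidates spanning several documents, preserving row
# order
maps_for <- function(cands, docs, hypernyms = NULL) {
  maps <- vector("list", nrow(cands))
  for (d in unique(cands$doc)) {
    idx <- which(cands$doc == d)
    maps[idx] <- feature_maps(cands[idx, , drop = FALSE], docs[[d]], hypernyms)
  }
  maps
}

#' Train the full extraction system
#'
#' Runs preprocess, sequence-database construction (positive pairs only),
#' PrefixSpan mining, sample selection of the negative candidates, feature
#' extraction and one-vs-rest training of the pair and triplet models, and
#' collects the trigger statistics used by the joint score.
#'
#' @param corpus Corpus directory (txt/a1/a2/dep files) or a list of
#'   documents from [read_corpus()].
#' @param minsup Minimum support of the pattern miner (default 4, the
#'   operating point chosen on development data).
#' @param theta Selection threshold (default 2); a candidate survives when
#'   strictly more than \code{theta} mined patterns match its path.
#' @param lambda Ridge penalty of the classifiers.
#' @param hypernyms Optional stem-to-hypernym lookup for the external
#'   resource feature group.
#' @return A \code{bioevex_bundle}: dictionary, mined pattern set, models,
#'   trigger statistics, configuration and a manifest of before/after
#'   sample counts.
#' @export
run_train <- function(corpus, minsup = 4, theta = 2, lambda = 1e-3,
                      hypernyms = NULL) {
  docs <- as_docs(corpus)
  if (!length(docs)) stop("training stage failed: empty corpus")
  dict <- build_trigger_dictionary(docs)
  if (!nrow(dict)) stop("training stage failed: no annotated events in corpus")

  pairs <- do.call(rbind, lapply(docs, generate_pairs, dict = dict))
  rownames(pairs) <- NULL
  positives <- pairs[pairs$label != "negative", , drop = FALSE]
  negatives <- pairs[pairs$label == "negative", , drop = FALSE]
  if (!nrow(positives)) stop("sample-selection stage failed: no positive pairs")

  ds <- build_sequence_db(positives)
  ls <- mine_frequent_patterns(ds, minsup)
  neg_sel <- select_samples(negatives, ls, theta)
  sel_report <- attr(neg_sel, "selection_report")
  train_pairs <- rbind(positives, neg_sel)

  triplets <- do.call(rbind, lapply(docs, generate_triplets, dict = dict))
  rownames(triplets) <- NULL
  tri_pos <- triplets[triplets$label != "negative", , drop = FALSE]
  tri_neg <- triplets[triplets$label == "negative", , drop = FALSE]
  tri_neg_sel <- filter_triplet_candidates(tri_neg, ls, theta)
  train_tri <- rbind(tri_pos, tri_neg_sel)

  pair_maps <- maps_for(train_pairs, docs, hypernyms)
  tri_maps <- maps_for(train_tri, docs, hypernyms)
  models <- train_event_models(train_pairs, train_tri, pair_maps, tri_maps,
                               lambda = lambda)
  stats <- trigger_stats(docs)

  manifest <- list(
    n_docs = length(docs),
    minsup = minsup, theta = theta, lambda = lambda,
    pairs_positive = nrow(positives),
    pairs_negative_before = nrow(negatives),
    pairs_negative_after = nrow(neg_sel),
    negative_reduction = if (nrow(negatives) > 0)
      1 - nrow(neg_sel) / nrow(negatives) else NA_real_,
    ratio_before = if (nrow(positives) > 0)
      nrow(negatives) / nrow(positives) else NA_real_,
    ratio_after = if (nrow(positives) > 0)
      nrow(neg_sel) / nrow(positives) else NA_real_,
    db_skipped_pathless = attr(ds, "skipped"),
    triplets_positive = nrow(tri_pos),
    triplets_negative_before = nrow(tri_neg),
    triplets_negative_after = nrow(tri_neg_sel),
    n_patterns = length(ls$patterns)
  )
  structure(list(dict = dict, patterns = ls, models = models, stats = stats,
                 config = list(minsup = minsup, theta = theta, lambda = lambda),
                 manifest = manifest, version = "bioevex-bundle-1"),
            class = "bioevex_bundle")
}

#' @export
print.bioevex_bundle <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "bioevex bundle: %d docs, %d patterns (minsup %s, theta %s)\n",
    m$n_docs, m$n_patterns, format(m$minsup), format(m$theta)))
  cat(sprintf("  pairs: %d positive, negatives %d -> %d (ratio %.2f -> %.2f)\n",
              m$pairs_positive, m$pairs_negative_before,
              m$pairs_negative_after, m$ratio_before, m$ratio_after))
  invisible(x)
}

#' Predict, integrate, rescore and emit events
#'
#' Candidate generation, pattern-based selection, classification,
#' pair/triplet integration, joint scoring and threshold filtering, then
#' assembly into standoff events (optionally written as .a2 files).
#'
#' @param corpus Corpus directory or document list (gold .a2 files are not
#'   read).
#' @param bundle Trained \code{bioevex_bundle}.
#' @param sigma Joint-score mixing weight on similarity (default 0.7).
#' @param delta Joint-score threshold (default 0.5).
#' @param backend,weights Similarity backend passed to
#'   [score_predictions()].
#' @param out_dir When non-NULL, a \code{<doc>.a2} file is written per
#'   document.
#' @return List with \code{kept}/\code{removed} scored predictions, the
#'   per-document assembled \code{triggers}/\code{events}
#'   (\code{assembled}) and the score \code{report} data.frame.
#' @export
run_predict <- function(corpus, bundle, sigma = 0.7, delta = 0.5,
                        backend = "trigram", weights = NULL, out_dir = NULL) {
  if (!identical(bundle$version, "bioevex-bundle-1")) {
    stop("incompatible model bundle version")
  }
  docs <- as_docs(corpus, with_a2 = FALSE)
  ev_list <- lapply(docs, function(doc) {
    preds <- predict_events(doc, bundle$models, bundle$dict, bundle$patterns,
                            theta = bundle$config$theta)
    integrate_predictions(preds)
  })
  events <- do.call(rbind, ev_list)
  rownames(events) <- NULL
  scored <- score_predictions(events, docs, bundle$stats, sigma = sigma,
                              backend = backend, weights = weights)
  flt <- filter_by_score(scored, delta)
  assembled <- lapply(names(docs), function(d) {
    assemble_events(flt$kept[flt$kept$doc == d, , drop = FALSE], docs[[d]])
  })
  names(assembled) <- names(docs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (d in names(docs)) {
      lines <- write_a2(assembled[[d]]$events, assembled[[d]]$triggers,
                        docs[[d]]$proteins)
      writeLines(lines, file.path(out_dir, paste0(d, ".a2")))
    }
  }
  report <- scored[, c("doc", "sent", "type", "trig_stem",
                       "p1", "p2", "p_ti", "sim", "score")]
  report$kept <- scored$score >= delta
  list(kept = flt$kept, removed = flt$removed, assembled = assembled,
       report = report)
}

# resolve a document's event table into recursive structures for matching
resolve_events <- function(doc, triggers, events) {
  if (!nrow(events)) return(list())
  tmap <- map_annotations(doc, triggers)
  resolved <- vector("list", nrow(events))
  names(resolved) <- events$id
  for (i in seq_len(nrow(events))) {
    tr <- tmap[tmap$id == events$trigger_id[[i]], ]
    resolved[[i]] <- list(
      id = events$id[[i]], type = events$type[[i]],
      sent = if (nrow(tr)) tr$sent[[1L]] else NA_integer_,
      tok = if (nrow(tr)) tr$tok[[1L]] else NA_integer_,
      theme = events$theme[[i]], theme2 = events$theme2[[i]],
      cause = events$cause[[i]]
    )
  }
  resolved
}

# approximate recursive matching of one predicted against one gold event:
# same type, trigger in the same sentence within one token, and arguments
# matching (protein references by annotation span identity, event
# references recursively); Binding themes are order-insensitive
match_event_pair <- function(p, g, pred_res, gold_res, depth = 0L) {
  if (depth > 4L) return(FALSE)
  if (p$type != g$type) return(FALSE)
  if (is.na(p$sent) || is.na(g$sent) || p$sent != g$sent) return(FALSE)
  if (abs(p$tok - g$tok) > 1L) return(FALSE)
  arg_match <- function(pr, gr) {
    if (is.na(pr) && is.na(gr)) return(TRUE)
    if (is.na(pr) || is.na(gr)) return(FALSE)
    pe <- startsWith(pr, "E"); ge <- startsWith(gr, "E")
    if (pe != ge) return(FALSE)
    if (!pe) return(identical(pr, gr))
    match_event_pair(pred_res[[pr]], gold_res[[gr]], pred_res, gold_res,
                     depth + 1L)
  }
  if (p$type == "Binding") {
    pt <- c(p$theme, p$theme2); gt <- c(g$theme, g$theme2)
    direct <- arg_match(pt[[1L]], gt[[1L]]) && arg_match(pt[[2L]], gt[[2L]])
    crossed <- arg_match(pt[[1L]], gt[[2L]]) && arg_match(pt[[2L]], gt[[1L]])
    return(direct || crossed)
  }
  arg_match(p$theme, g$theme) && arg_match(p$cause, g$cause)
}

#' Evaluate predictions against gold annotations
#'
#' Event-level matching with a one-token trigger-span tolerance and
#' recursive argument matching; protein arguments must reference the same
#' .a1 annotation.  Gold events are greedily matched at most once.
#' Recall, precision and F-score (percent) are reported per event type,
#' per class and in total.
#'
#' @param gold_docs Documents carrying gold events (list from
#'   [read_corpus()]).
#' @param predictions Named list (by document id) of
#'   \code{list(triggers, events)} as produced by [run_predict()]'s
#'   \code{assembled} component, or a directory of predicted .a2 files.
#' @return Data.frame with columns \code{level} (type/class/total),
#'   \code{name}, \code{gold}, \code{predicted}, \code{tp},
#'   \code{recall}, \code{precision}, \code{f}.
#' @export
evaluate_events <- function(gold_docs, predictions) {
  if (is.character(predictions)) {
    pred_dir <- predictions
    predictions <- lapply(names(gold_docs), function(d) {
      f <- file.path(pred_dir, paste0(d, ".a2"))
      if (!file.exists(f)) return(list(triggers = empty_ann_df(),
                                       events = empty_event_df()))
      pd <- read_standoff(gold_docs[[d]]$text,
                          a1 = paste(sprintf("%s\t%s %d %d\t%s",
                                             gold_docs[[d]]$proteins$id,
                                             gold_docs[[d]]$proteins$type,
                                             gold_docs[[d]]$proteins$char_start,
                                             gold_docs[[d]]$proteins$char_end,
                                             gold_docs[[d]]$proteins$text),
                                     collapse = "\n"),
                          a2 = f, id = d)
      list(triggers = pd$triggers, events = pd$events)
    })
    names(predictions) <- names(gold_docs)
  }
  unknown <- setdiff(names(predictions), names(gold_docs))
  if (length(unknown)) {
    stop("predictions for unknown document(s): ", paste(unknown, collapse = ", "))
  }
  types <- event_types()
  tp <- stats::setNames(rep(0L, length(types)), types)
  gold_n <- tp; pred_n <- tp
  for (d in names(gold_docs)) {
    doc <- gold_docs[[d]]
    gold_res <- resolve_events(doc, doc$triggers, doc$events)
    pr <- predictions[[d]]
    pred_res <- if (is.null(pr)) list() else
      resolve_events(doc, pr$triggers, pr$events)
    for (g in gold_res) gold_n[[g$type]] <- gold_n[[g$type]] + 1L
    for (p in pred_res) pred_n[[p$type]] <- pred_n[[p$type]] + 1L
    matched_gold <- character(0)
    for (p in pred_res) {
      for (g in gold_res) {
        if (g$id %in% matched_gold) next
        if (match_event_pair(p, g, pred_res, gold_res)) {
          matched_gold <- c(matched_gold, g$id)
          tp[[p$type]] <- tp[[p$type]] + 1L
          break
        }
      }
    }
  }
  prf <- function(tp, gold, pred) {
    r <- if (gold > 0) 100 * tp / gold else 0
    p <- if (pred > 0) 100 * tp / pred else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(recall = r, precision = p, f = f)
  }
  rows <- list()
  sch <- event_schema()
  for (t in types) {
    m <- prf(tp[[t]], gold_n[[t]], pred_n[[t]])
    rows[[length(rows) + 1L]] <- data.frame(
      level = "type", name = t, gold = gold_n[[t]], predicted = pred_n[[t]],
      tp = tp[[t]], recall = m[["recall"]], precision = m[["precision"]],
      f = m[["f"]], stringsAsFactors = FALSE)
  }
  for (cl in c("SVT", "BIND", "REG")) {
    ts <- sch$type[sch$class == cl]
    m <- prf(sum(tp[ts]), sum(gold_n[ts]), sum(pred_n[ts]))
    rows[[length(rows) + 1L]] <- data.frame(
      level = "class", name = cl, gold = sum(gold_n[ts]),
      predicted = sum(pred_n[ts]), tp = sum(tp[ts]),
      recall = m[["recall"]], precision = m[["precision"]], f = m[["f"]],
      stringsAsFactors = FALSE)
  }
  m <- prf(sum(tp), sum(gold_n), sum(pred_n))
  rows[[length(rows) + 1L]] <- data.frame(
    level = "total", name = "ALL", gold = sum(gold_n), predicted = sum(pred_n),
    tp = sum(tp), recall = m[["recall"]], precision = m[["precision"]],
    f = m[["f"]], stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Majority-class baseline predictor
#'
#' Labels every dictionary-matched trigger token paired with every protein
#' in its sentence as an event of the corpus-majority event type.  Used as
#' the reference point the trained system must beat.
#'
#' @param docs Documents to predict on.
#' @param dict Trigger dictionary.
#' @return Named list per document of \code{list(triggers, events)}.
#' @export
predict_majority_baseline <- function(docs, dict) {
  agg <- stats::aggregate(list(count = dict$count), by = list(type = dict$type),
                          FUN = sum)
  majority <- agg$type[[which.max(agg$count)]]
  out <- lapply(docs, function(doc) {
    pairs <- generate_pairs(doc, dict)
    pairs <- pairs[pairs$arg_kind == "protein", , drop = FALSE]
    if (!nrow(pairs)) return(list(triggers = empty_ann_df(),
                                  events = empty_event_df()))
    pairs$type <- majority
    pairs$margin <- 0
    ev <- integrate_predictions(list(pairs = pairs, triplets = NULL))
    assemble_events(ev, doc)
  })
  names(out) <- names(docs)
  out
}
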