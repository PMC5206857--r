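#' Candidate generation and feature extraction
#'
#' Candidate pairs (trigger, argument) and triplets (trigger, argument,
#' argument2) are generated per sentence from a trigger dictionary built on
#' the training annotations.  Arguments are annotated proteins, plus other
#' dictionary-matched trigger tokens for regulation-capable triggers (whose
#' Theme may itself be an event).  Each candidate carries the
#' dependency-label path(s) from trigger to argument(s) and a sparse
#' feature map in four groups: token, sentence, dependency and (optional)
#' external-resource features.
#'
#' @name candidates_features
NULL

#' Build the trigger dictionary from training annotations
#'
#' Maps trigger stems to the event types they trigger, with instance
#' counts, using only gold .a2 annotations.
#'
#' @param docs List of \code{standoff_document}s with events.
#' @return Data.frame with \code{stem}, \code{type}, \code{count}.
#' @export
build_trigger_dictionary <- function(docs) {
  rows <- lapply(docs, function(doc) {
    if (!nrow(doc$events)) return(NULL)
    idx <- match(doc$events$trigger_id, doc$triggers$id)
    data.frame(stem = stem_token(doc$triggers$text[idx]),
               type = doc$events$type, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(stem = character(), type = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(all))),
                          by = all[c("stem", "type")], FUN = sum)
  agg[order(agg$stem, agg$type), , drop = FALSE]
}

dict_stems <- function(dict) unique(dict$stem)

dict_has_class <- function(dict, stem, class) {
  types <- dict$type[dict$stem == stem]
  length(types) > 0L && any(event_class(types) %in% class)
}

# igraph over one sentence's dependency edges (undirected, 0-based token
# indices as vertex names); NULL when there are no edges
sentence_graph <- function(sentence) {
  deps <- sentence$deps
  if (is.null(deps) || !nrow(deps)) return(NULL)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(deps$gov), to = as.character(deps$dep),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(nrow(sentence$tokens)) - 1L))
  )
  igraph::E(g)$label <- deps$label
  g
}

# label sequence along the unweighted shortest path between two tokens;
# NULL when disconnected
dep_path_labels <- function(g, from, to) {
  if (is.null(g) || from == to) return(NULL)
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = as.character(from), to = as.character(to), output = "epath"
  ))
  ep <- sp$epath[[1L]]
  if (length(ep) == 0L) return(NULL)
  igraph::E(g)$label[as.integer(ep)]
}

# annotation (proteins/triggers) rows mapped to (sentence position, token row)
map_annotations <- function(doc, ann) {
  if (!nrow(ann)) {
    return(data.frame(id = character(), sent = integer(), tok = integer(),
                      stringsAsFactors = FALSE))
  }
  hits <- lapply(seq_len(nrow(ann)), function(i) {
    h <- token_for_span(doc, ann$char_start[[i]], ann$char_end[[i]])
    if (is.null(h)) return(NULL)
    data.frame(id = ann$id[[i]], sent = h[[1L]], tok = h[[2L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(id = character(), sent = integer(),
                               tok = integer(), stringsAsFactors = FALSE) else out
}

# gold labels: positive (trigger token, arg token) pairs per sentence with
# their event type; args may be proteins or nested-event trigger tokens
gold_pair_labels <- function(doc) {
  ev <- doc$events
  if (!nrow(ev)) {
    return(data.frame(sent = integer(), trig_tok = integer(),
                      arg_tok = integer(), type = character(),
                      stringsAsFactors = FALSE))
  }
  pmap <- map_annotations(doc, doc$proteins)
  tmap <- map_annotations(doc, doc$triggers)
  ev_trig_tok <- function(eid) {
    tid <- ev$trigger_id[ev$id == eid]
    tmap[tmap$id == tid, c("sent", "tok")]
  }
  ref_tok <- function(ref) {
    if (startsWith(ref, "E")) ev_trig_tok(ref) else pmap[pmap$id == ref, c("sent", "tok")]
  }
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    tr <- tmap[tmap$id == ev$trigger_id[[i]], ]
    if (!nrow(tr)) next
    for (ref in stats::na.omit(c(ev$theme[[i]], ev$theme2[[i]], ev$cause[[i]]))) {
      at <- ref_tok(ref)
      if (!nrow(at) || at$sent[[1L]] != tr$sent[[1L]]) next
      rows[[length(rows) + 1L]] <- data.frame(
        sent = tr$sent[[1L]], trig_tok = tr$tok[[1L]], arg_tok = at$tok[[1L]],
        type = ev$type[[i]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(sent = integer(), trig_tok = integer(),
                               arg_tok = integer(), type = character(),
                               stringsAsFactors = FALSE) else out
}

# gold triplets: (trigger token, arg token, arg2 token, type); Binding two
# themes (unordered) or REG theme+cause (ordered)
gold_triplet_labels <- function(doc) {
  ev <- doc$events
  out <- data.frame(sent = integer(), trig_tok = integer(), a1 = integer(),
                    a2 = integer(), type = character(), stringsAsFactors = FALSE)
  if (!nrow(ev)) return(out)
  pmap <- map_annotations(doc, doc$proteins)
  tmap <- map_annotations(doc, doc$triggers)
  ref_tok <- function(ref) {
    if (startsWith(ref, "E")) {
      tid <- ev$trigger_id[ev$id == ref]
      tmap[tmap$id == tid, c("sent", "tok")]
    } else pmap[pmap$id == ref, c("sent", "tok")]
  }
  for (i in seq_len(nrow(ev))) {
    second <- if (!is.na(ev$theme2[[i]])) ev$theme2[[i]] else ev$cause[[i]]
    if (is.na(second)) next
    tr <- tmap[tmap$id == ev$trigger_id[[i]], ]
    t1 <- ref_tok(ev$theme[[i]]); t2 <- ref_tok(second)
    if (!nrow(tr) || !nrow(t1) || !nrow(t2)) next
    if (t1$sent[[1L]] != tr$sent[[1L]] || t2$sent[[1L]] != tr$sent[[1L]]) next
    out <- rbind(out, data.frame(
      sent = tr$sent[[1L]], trig_tok = tr$tok[[1L]], a1 = t1$tok[[1L]],
      a2 = t2$tok[[1L]], type = ev$type[[i]], stringsAsFactors = FALSE))
  }
  out
}

#' Generate candidate trigger-argument pairs for a document
#'
#' Every dictionary-matched token is paired with every protein in its
#' sentence and, when the token's dictionary types include a REG-class
#' type, with every other dictionary-matched token (candidate nested
#' Theme).  The dependency-label path over the sentence graph is attached;
#' when gold events are present, each pair is labeled with its event type
#' or \code{"negative"}.
#'
#' @param doc A \code{standoff_document}.
#' @param dict Trigger dictionary from [build_trigger_dictionary()].
#' @return Data.frame of candidate pairs with a \code{path} list-column.
#' @export
generate_pairs <- function(doc, dict) {
  stems <- dict_stems(dict)
  pmap <- map_annotations(doc, doc$proteins)
  gold <- gold_pair_labels(doc)
  rows <- list()
  for (si in seq_along(doc$sentences)) {
    sent <- doc$sentences[[si]]
    tok <- sent$tokens
    trig_rows <- which(tok$stem %in% stems & tok$pos != ".")
    if (!length(trig_rows)) next
    g <- sentence_graph(sent)
    sprot <- pmap[pmap$sent == si, , drop = FALSE]
    for (tr in trig_rows) {
      tstem <- tok$stem[[tr]]
      regcap <- dict_has_class(dict, tstem, "REG")
      args <- data.frame(tok = sprot$tok, kind = rep("protein", nrow(sprot)),
                         ann_id = sprot$id, stringsAsFactors = FALSE)
      if (regcap) {
        others <- setdiff(trig_rows, tr)
        if (length(others)) {
          args <- rbind(args, data.frame(
            tok = others, kind = "trigger", ann_id = NA_character_,
            stringsAsFactors = FALSE))
        }
      }
      args <- args[args$tok != tr, , drop = FALSE]
      for (ai in seq_len(nrow(args))) {
        at <- args$tok[[ai]]
        path <- dep_path_labels(g, tok$index[[tr]], tok$index[[at]])
        lbl <- gold$type[gold$sent == si & gold$trig_tok == tr & gold$arg_tok == at]
        rows[[length(rows) + 1L]] <- data.frame(
          doc = doc$id, sent = si, trig_tok = tr, trig_stem = tstem,
          arg_tok = at, arg_kind = args$kind[[ai]], arg_id = args$ann_id[[ai]],
          label = if (length(lbl)) lbl[[1L]] else "negative",
          stringsAsFactors = FALSE)
        rows[[length(rows)]]$path <- list(path)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc = character(), sent = integer(), trig_tok = integer(),
                      trig_stem = character(), arg_tok = integer(),
                      arg_kind = character(), arg_id = character(),
                      label = character(), stringsAsFactors = FALSE)
    out$path <- list()
  }
  out
}

#' Generate candidate triplets for a document
#'
#' For Binding-capable triggers: unordered protein pairs (two Themes).
#' For REG-capable triggers: ordered (Theme, Cause) pairs with the Theme a
#' protein or another dictionary-matched trigger token and the Cause a
#' protein.  Both trigger-to-argument dependency paths are attached.
#'
#' @inheritParams generate_pairs
#' @return Data.frame of candidate triplets with \code{path1}/\code{path2}
#'   list-columns.
#' @export
generate_triplets <- function(doc, dict) {
  stems <- dict_stems(dict)
  pmap <- map_annotations(doc, doc$proteins)
  gold <- gold_triplet_labels(doc)
  rows <- list()
  add_row <- function(doc_id, si, tr, tstem, a1, a2, kinds, ids, p1, p2, lbl) {
    r <- data.frame(doc = doc_id, sent = si, trig_tok = tr, trig_stem = tstem,
                    a1_tok = a1, a2_tok = a2, a1_kind = kinds[[1L]],
                    a2_kind = kinds[[2L]], a1_id = ids[[1L]], a2_id = ids[[2L]],
                    label = lbl, stringsAsFactors = FALSE)
    r$path1 <- list(p1); r$path2 <- list(p2)
    rows[[length(rows) + 1L]] <<- r
  }
  for (si in seq_along(doc$sentences)) {
    sent <- doc$sentences[[si]]
    tok <- sent$tokens
    trig_rows <- which(tok$stem %in% stems & tok$pos != ".")
    if (!length(trig_rows)) next
    g <- sentence_graph(sent)
    sprot <- pmap[pmap$sent == si, , drop = FALSE]
    path_cache <- new.env(parent = emptyenv())
    get_path <- function(a, b) {
      key <- paste(a, b)
      if (!is.null(path_cache[[key]])) return(path_cache[[key]])
      p <- dep_path_labels(g, tok$index[[a]], tok$index[[b]])
      path_cache[[key]] <- if (is.null(p)) list(NULL) else list(p)
      path_cache[[key]]
    }
    glab <- function(tr, x, y, ordered) {
      hit <- gold[gold$sent == si & gold$trig_tok == tr &
                  ((gold$a1 == x & gold$a2 == y) |
                   (!ordered & gold$a1 == y & gold$a2 == x)), ]
      if (nrow(hit)) hit$type[[1L]] else "negative"
    }
    for (tr in trig_rows) {
      tstem <- tok$stem[[tr]]
      bindcap <- dict_has_class(dict, tstem, "BIND")
      regcap <- dict_has_class(dict, tstem, "REG")
      prots <- sprot[sprot$tok != tr, , drop = FALSE]
      if (bindcap && nrow(prots) >= 2L) {
        cmb <- utils::combn(seq_len(nrow(prots)), 2L)
        for (k in seq_len(ncol(cmb))) {
          i1 <- cmb[1L, k]; i2 <- cmb[2L, k]
          add_row(doc$id, si, tr, tstem, prots$tok[[i1]], prots$tok[[i2]],
                  c("protein", "protein"), c(prots$id[[i1]], prots$id[[i2]]),
                  get_path(tr, prots$tok[[i1]])[[1L]],
                  get_path(tr, prots$tok[[i2]])[[1L]],
                  glab(tr, prots$tok[[i1]], prots$tok[[i2]], ordered = FALSE))
        }
      }
      if (regcap) {
        themes <- data.frame(tok = prots$tok, kind = rep("protein", nrow(prots)),
                             id = prots$id, stringsAsFactors = FALSE)
        others <- setdiff(trig_rows, tr)
        if (length(others)) {
          themes <- rbind(themes, data.frame(tok = others, kind = "trigger",
                                             id = NA_character_,
                                             stringsAsFactors = FALSE))
        }
        for (ti in seq_len(nrow(themes))) {
          for (ci in seq_len(nrow(prots))) {
            if (themes$tok[[ti]] == prots$tok[[ci]]) next
            add_row(doc$id, si, tr, tstem, themes$tok[[ti]], prots$tok[[ci]],
                    c(themes$kind[[ti]], "protein"),
                    c(themes$id[[ti]], prots$id[[ci]]),
                    get_path(tr, themes$tok[[ti]])[[1L]],
                    get_path(tr, prots$tok[[ci]])[[1L]],
                    glab(tr, themes$tok[[ti]], prots$tok[[ci]], ordered = TRUE))
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc = character(), sent = integer(), trig_tok = integer(),
                      trig_stem = character(), a1_tok = integer(),
                      a2_tok = integer(), a1_kind = character(),
                      a2_kind = character(), a1_id = character(),
                      a2_id = character(), label = character(),
                      stringsAsFactors = FALSE)
    out$path1 <- list(); out$path2 <- list()
  }
  out
}

char_ngrams <- function(x, ns = 1:3) {
  chars <- strsplit(x, "")[[1L]]
  unlist(lapply(ns, function(n) {
    if (length(chars) < n) return(character(0))
    vapply(seq_len(length(chars) - n + 1L),
           function(i) paste(chars[i:(i + n - 1L)], collapse = ""), character(1L))
  }), use.names = FALSE)
}

word_shape <- function(x) {
  s <- gsub("[A-Z]", "X", x)
  s <- gsub("[a-z]", "x", s)
  s <- gsub("[0-9]", "d", s)
  gsub("(.)\\1+", "\\1", s)
}

token_features <- function(tok_row, prefix) {
  txt <- tok_row$text
  feats <- c(
    paste0(prefix, "stem=", tok_row$stem),
    paste0(prefix, "pos=", tok_row$pos),
    paste0(prefix, "g=", char_ngrams(tolower(txt))),
    paste0(prefix, "shape=", word_shape(txt)),
    if (grepl("[0-9]", txt)) paste0(prefix, "hasdigit"),
    if (grepl("-", txt, fixed = TRUE)) paste0(prefix, "hashyphen"),
    if (grepl("^[A-Z]", txt)) paste0(prefix, "initcap")
  )
  feats
}

# all dependency-label chains of length 1..depth starting at a token, via
# simple paths in the undirected view of the sentence edge list (0-based
# token index)
dep_chains <- function(deps, from, depth = 3L) {
  if (is.null(deps) || !nrow(deps)) return(character(0))
  ends1 <- c(deps$gov, deps$dep)
  ends2 <- c(deps$dep, deps$gov)
  labs <- c(deps$label, deps$label)
  out <- character(0)
  walk <- function(v, labels, seen) {
    if (length(labels) >= depth) return()
    inc <- which(ends1 == v)
    for (e in inc) {
      nxt <- ends2[[e]]
      if (nxt %in% seen) next
      lab <- c(labels, labs[[e]])
      out[[length(out) + 1L]] <<- paste(lab, collapse = ".")
      walk(nxt, lab, c(seen, nxt))
    }
  }
  walk(from, character(0), from)
  out
}

pair_feature_names <- function(sent, trig_row, arg_row, path, arg_kind,
                               chains, prefix = "") {
  tok <- sent$tokens
  feats <- c(
    token_features(tok[trig_row, ], paste0(prefix, "t_")),
    token_features(tok[arg_row, ], paste0(prefix, "a_")),
    paste0(prefix, "akind=", arg_kind)
  )
  if (!is.null(path) && length(path)) {
    pg2 <- if (length(path) >= 2L) {
      vapply(seq_len(length(path) - 1L),
             function(i) paste(path[i:(i + 1L)], collapse = "."), character(1L))
    } else character(0)
    feats <- c(feats,
               paste0(prefix, "path=", paste(path, collapse = ".")),
               paste0(prefix, "plen=", length(path)),
               paste0(prefix, "pl=", unique(path)),
               paste0(prefix, "pl2=", pg2))
  } else {
    feats <- c(feats, paste0(prefix, "nopath"))
  }
  c(feats, paste0(prefix, "chain=", unique(chains)))
}

sentence_feature_names <- function(sent, n_entities) {
  c(paste0("bow=", unique(sent$tokens$stem)),
    paste0("nent=", min(n_entities, 6L)))
}

#' Extract the feature map of a candidate
#'
#' Deterministic union of token features of the trigger and argument(s)
#' (stem, POS, character 1-3-grams, shape/spelling), sentence features
#' (bag of stems, candidate-entity count), dependency features
#' (shortest-path label sequence, its labels and bigrams, length, and the
#' label chains up to depth 3 from the trigger), and optional hypernym
#' features for the trigger/argument stems from a user-supplied lookup.
#' Binary features, value 1 (sparse map; duplicated names collapse).
#'
#' @param cand One-row candidate (pair or triplet) from [generate_pairs()]
#'   or [generate_triplets()].
#' @param doc The document it came from.
#' @param hypernyms Optional named list mapping stems to hypernym strings.
#' @return Named numeric vector of features, all 1.
#' @export
extract_features <- function(cand, doc, hypernyms = NULL) {
  feature_maps(cand, doc, hypernyms)[[1L]]
}

# feature maps for every row of a candidate data.frame, caching the
# per-sentence context (entity count, bag of words, trigger chains)
feature_maps <- function(cands, doc, hypernyms = NULL) {
  if (!nrow(cands)) return(list())
  pmap <- map_annotations(doc, doc$proteins)
  hyp <- function(stem, prefix) {
    if (is.null(hypernyms)) return(character(0))
    h <- hypernyms[[stem]]
    if (is.null(h)) character(0) else paste0(prefix, "hyp=", h)
  }
  is_triplet <- !is.null(cands$a1_tok)
  sent_cache <- list()
  chain_cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    si <- cands$sent[[i]]
    key <- as.character(si)
    if (is.null(sent_cache[[key]])) {
      sent <- doc$sentences[[si]]
      sent_cache[[key]] <- list(
        sent = sent,
        base = sentence_feature_names(sent, sum(pmap$sent == si))
      )
    }
    ctx <- sent_cache[[key]]
    sent <- ctx$sent
    chains_for <- function(tok_row) {
      ck <- paste(si, tok_row)
      if (is.null(chain_cache[[ck]])) {
        chain_cache[[ck]] <- dep_chains(sent$deps, sent$tokens$index[[tok_row]])
      }
      chain_cache[[ck]]
    }
    tchains <- chains_for(cands$trig_tok[[i]])
    feats <- if (!is_triplet) {
      c(ctx$base,
        pair_feature_names(sent, cands$trig_tok[[i]], cands$arg_tok[[i]],
                           cands$path[[i]], cands$arg_kind[[i]], tchains),
        hyp(cands$trig_stem[[i]], "t_"),
        hyp(sent$tokens$stem[[cands$arg_tok[[i]]]], "a_"))
    } else {
      c(ctx$base,
        pair_feature_names(sent, cands$trig_tok[[i]], cands$a1_tok[[i]],
                           cands$path1[[i]], cands$a1_kind[[i]], tchains,
                           prefix = "A1_"),
        pair_feature_names(sent, cands$trig_tok[[i]], cands$a2_tok[[i]],
                           cands$path2[[i]], cands$a2_kind[[i]], tchains,
                           prefix = "A2_"),
        hyp(cands$trig_stem[[i]], "t_"))
    }
    feats <- unique(feats[!is.na(feats) & nzchar(feats)])
    out[[i]] <- stats::setNames(rep(1, length(feats)), feats)
  }
  out
}
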