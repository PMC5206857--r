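#' Synthetic corpus generation
#'
#' Emulates a GENIA-style event-extraction corpus in BioNLP-ST standoff
#' format: a type-skewed trigger lexicon over the nine event types, protein
#' mentions, nested regulation-over-simple events, and per-sentence
#' dependency graphs in which the label paths of annotated trigger-argument
#' pairs are drawn from a small pattern pool while the paths of negative
#' pairs are broader and noisier, so that pattern-based sample selection
#' has signal.  The realized positive:negative candidate-pair ratio tracks
#' the requested imbalance.
#'
#' @name fixtures
NULL

#' Trigger lexicon of the synthetic corpus
#'
#' @return Data.frame with \code{word}, \code{type} and a sampling
#'   \code{weight} (type-skewed frequencies).
#' @export
trigger_lexicon <- function() {
  data.frame(
    word = c("expression", "production", "transcription", "localization",
             "secretion", "degradation", "phosphorylation", "binding",
             "interaction", "regulation", "activation", "induction",
             "inhibition", "suppression"),
    type = c("Gene_expression", "Gene_expression", "Transcription",
             "Localization", "Localization", "Protein_catabolism",
             "Phosphorylation", "Binding", "Binding", "Regulation",
             "Positive_regulation", "Positive_regulation",
             "Negative_regulation", "Negative_regulation"),
    weight = c(3, 1, 2, 2, 1, 2, 2, 3, 1, 2, 3, 1, 2, 1),
    stringsAsFactors = FALSE
  )
}

fixture_proteins <- function() {
  c("IRF-4", "IFN-alpha", "IL-2", "IL-4", "IL-6", "IL-10", "TNF-alpha",
    "NF-kB", "STAT1", "STAT3", "STAT5", "JAK2", "CD28", "CD40", "TGF-beta",
    "GM-CSF", "IkB-alpha", "c-Fos", "c-Jun", "c-Myc", "p53", "p65", "RelA",
    "GATA3", "FOXP3", "IRF-1", "ICAM-1", "VCAM-1", "E-selectin", "CD4",
    "TRAF2", "SOCS1")
}

fixture_fillers <- function() {
  c("cells", "gene", "protein", "levels", "pathway", "response", "signal",
    "factor", "complex", "receptor", "activity", "human", "nuclear",
    "mediated", "dependent", "specific", "cultured", "primary", "murine",
    "lymphocytes", "monocytes", "stimulation", "treatment", "analysis")
}

# dependency-path pools: positives come from a small pool of short label
# sequences over a 6-label alphabet; negatives mix that alphabet with 9
# extra labels.  All paths are 2-3 labels long so that, with per-pair
# chains sharing only their endpoints, the planted chain is always the
# unique shortest path (any detour concatenates two chains, length >= 4).
fixture_pos_pool <- function() {
  list(c("nsubj", "dobj"), c("amod", "nn"), c("prep_of", "nn"),
       c("nsubj", "prep_of", "nn"), c("dobj", "prep_by", "nn"),
       c("amod", "prep_of", "nn"))
}

fixture_neg_alphabets <- function() {
  list(positive = c("nsubj", "dobj", "amod", "nn", "prep_of", "prep_by"),
       extra = c("prep_in", "prep_to", "prep_with", "conj_and", "appos",
                 "advmod", "nmod", "xcomp", "ccomp"))
}

sample_neg_path <- function() {
  ab <- fixture_neg_alphabets()
  len <- sample(c(2L, 3L), 1L, prob = c(0.4, 0.6))
  vapply(seq_len(len), function(i) {
    if (stats::runif(1L) < 0.6) sample(ab$positive, 1L) else sample(ab$extra, 1L)
  }, character(1L))
}

fixture_type_weights <- function() {
  c(Gene_expression = 25, Positive_regulation = 20, Binding = 14,
    Negative_regulation = 12, Transcription = 8, Regulation = 8,
    Phosphorylation = 6, Localization = 5, Protein_catabolism = 4)
}

# deterministic first pass over all nine types so small corpora still
# contain every type (an SVT type comes first)
fixture_type_cycle <- function() {
  c("Gene_expression", "Binding", "Positive_regulation", "Transcription",
    "Regulation", "Negative_regulation", "Localization", "Phosphorylation",
    "Protein_catabolism")
}

#' Generate a synthetic standoff corpus
#'
#' Writes \code{<doc>.txt}, \code{.a1}, \code{.a2} and \code{.dep} files
#' plus a \code{corpus_config.json} describing the generator settings.
#' Deterministic given \code{seed}.  The per-sentence plan chooses the
#' number of distractor proteins so that the cumulative candidate-pair
#' negative:positive ratio tracks \code{imbalance}.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_docs Number of documents, at least 1.
#' @param imbalance Target negative:positive candidate-pair ratio (>= 1);
#'   the default mirrors the class imbalance of annotated GENIA corpora.
#' @param seed Integer random seed.
#' @param sentences_per_doc Integer vector to sample the per-document
#'   sentence count from.
#' @param nested_prob Probability that a regulation event takes another
#'   (simple) event in the same sentence as its Theme.
#' @param binding_two_theme_prob Probability that a Binding event has two
#'   Themes.
#' @param reg_cause_prob Probability that a regulation event has a Cause.
#' @return Invisibly, a manifest list with realized pair counts and the
#'   realized negative:positive ratio.
#' @export
generate_fixture_corpus <- function(out_dir, n_docs, imbalance = 13.163,
                                    seed = 1L,
                                    sentences_per_doc = 2:4,
                                    nested_prob = 0.25,
                                    binding_two_theme_prob = 0.5,
                                    reg_cause_prob = 0.7) {
  stopifnot(n_docs >= 1, imbalance >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))

  lex <- trigger_lexicon()
  lex$class <- event_class(lex$type)
  prot_pool <- fixture_proteins()
  fillers <- fixture_fillers()
  pos_pool <- fixture_pos_pool()
  type_weights <- fixture_type_weights()
  cycle <- fixture_type_cycle()

  pos_tot <- 0L
  neg_tot <- 0L
  ev_sent_count <- 0L

  sample_word <- function(types, exclude = character(0)) {
    pool <- lex[lex$type %in% types & !lex$word %in% exclude, , drop = FALSE]
    pool$word[sample.int(nrow(pool), 1L, prob = pool$weight)]
  }

  for (d in seq_len(n_docs)) {
    doc_id <- sprintf("doc%04d", d)
    nsent <- if (length(sentences_per_doc) == 1L) sentences_per_doc else
      sample(sentences_per_doc, 1L)
    sent_texts <- character(0)
    dep_graphs <- list()
    a1 <- character(0); a2 <- character(0)
    t_count <- 0L; e_count <- 0L
    doc_offset <- 0L

    for (s in seq_len(nsent)) {
      ev_sent_count <- ev_sent_count + 1L
      typ <- if (ev_sent_count <= length(cycle)) cycle[[ev_sent_count]] else
        sample(names(type_weights), 1L, prob = type_weights)
      cls <- event_class(typ)
      trig <- sample_word(typ)
      nested <- cls == "REG" && stats::runif(1L) < nested_prob
      svt_typ <- NULL; svt_word <- NULL
      if (nested) {
        svt_typ <- sample(event_types("SVT"), 1L,
                          prob = type_weights[event_types("SVT")])
        svt_word <- sample_word(svt_typ, exclude = trig)
      }
      distractor <- sample_word(lex$type, exclude = c(trig, svt_word))

      trig_words <- c(trig, svt_word, distractor)
      trig_keys <- paste0("trig", seq_along(trig_words))
      reg_cap <- lex$class[match(stem_token(trig_words), stem_token(lex$word))] == "REG"
      T_n <- length(trig_words)
      R_n <- sum(reg_cap)

      # event argument plan (protein slot indices into the sentence proteins)
      has_theme2 <- cls == "BIND" && stats::runif(1L) < binding_two_theme_prob
      has_cause <- cls == "REG" && stats::runif(1L) < reg_cause_prob
      # positive pairs as (trigger key, arg key)
      pos_pairs <- list()
      if (nested) {
        pos_pairs <- c(pos_pairs, list(c("trig2", "prot1")))   # SVT theme
        pos_pairs <- c(pos_pairs, list(c("trig1", "trig2")))   # REG theme = event
        if (has_cause) pos_pairs <- c(pos_pairs, list(c("trig1", "prot2")))
      } else {
        pos_pairs <- c(pos_pairs, list(c("trig1", "prot1")))
        if (has_theme2) pos_pairs <- c(pos_pairs, list(c("trig1", "prot2")))
        if (has_cause) pos_pairs <- c(pos_pairs, list(c("trig1", "prot2")))
      }
      npos <- length(pos_pairs)
      min_p <- max(2L, max(as.integer(sub("prot", "",
                     grep("^prot", unlist(pos_pairs), value = TRUE)))))

      neg_target <- max(0L, as.integer(round(imbalance * (pos_tot + npos) - neg_tot)))
      P_n <- as.integer(round((npos + neg_target - R_n * (T_n - 1L)) / T_n))
      P_n <- min(max(P_n, min_p), 10L)
      ncand <- T_n * P_n + R_n * (T_n - 1L)
      nneg <- ncand - npos
      pos_tot <- pos_tot + npos
      neg_tot <- neg_tot + nneg

      prots <- sample(prot_pool, P_n)
      prot_keys <- paste0("prot", seq_len(P_n))

      # enumerate the candidate pairs exactly as the candidate generator
      # will, and attach a planted dependency path to each
      pos_key <- vapply(pos_pairs, paste, character(1L), collapse = "|")
      chains <- list()
      for (ti in seq_len(T_n)) {
        args <- prot_keys
        if (reg_cap[[ti]]) args <- c(args, trig_keys[-ti])
        for (ak in args) {
          key <- paste(trig_keys[[ti]], ak, sep = "|")
          path <- if (key %in% pos_key) {
            pos_pool[[sample.int(length(pos_pool), 1L)]]
          } else {
            sample_neg_path()
          }
          chains[[length(chains) + 1L]] <-
            list(from = trig_keys[[ti]], to = ak, path = path)
        }
      }

      # token assembly: fixed opening, shuffled middle, closing period
      items <- c(
        stats::setNames(trig_words, trig_keys),
        stats::setNames(prots, prot_keys)
      )
      inter_words <- character(0); inter_keys <- character(0)
      for (ci in seq_along(chains)) {
        k <- length(chains[[ci]]$path) - 1L
        if (k > 0L) {
          w <- sample(fillers, k, replace = TRUE)
          keys <- sprintf("int%d_%d", ci, seq_len(k))
          inter_words <- c(inter_words, w)
          inter_keys <- c(inter_keys, keys)
          chains[[ci]]$mids <- keys
        } else {
          chains[[ci]]$mids <- character(0)
        }
      }
      items <- c(items, stats::setNames(inter_words, inter_keys))
      head_keys <- c("trig1", "prot1")
      mid_keys <- setdiff(names(items), head_keys)
      mid_keys <- sample(mid_keys)
      ordered_keys <- c(head_keys[1L], NA, head_keys[2L], mid_keys)
      words <- c(items[["trig1"]], "of", items[["prot1"]], items[mid_keys])
      word_keys <- c("trig1", "", "prot1", mid_keys)
      sent_text <- paste0(paste(words, collapse = " "), ".")

      # token index (0-based) per key; the sentence tokenizer emits one
      # token per word plus the final period
      tok_index <- stats::setNames(seq_along(words) - 1L, word_keys)

      edges <- do.call(rbind, lapply(chains, function(ch) {
        nodes <- c(tok_index[[ch$from]],
                   unname(tok_index[ch$mids]),
                   tok_index[[ch$to]])
        data.frame(gov = nodes[-length(nodes)], dep = nodes[-1L],
                   label = ch$path, stringsAsFactors = FALSE)
      }))
      dep_graphs[[s]] <- edges

      # annotation offsets: walk the words of this sentence
      starts <- cumsum(c(0L, nchar(words) + 1L))[seq_along(words)] + doc_offset
      ends <- starts + nchar(words)
      for (pi in seq_len(P_n)) {
        w <- which(word_keys == prot_keys[[pi]])
        t_count <- t_count + 1L
        a1 <- c(a1, sprintf("T%d\tProtein %d %d\t%s", t_count,
                            starts[[w]], ends[[w]], words[[w]]))
      }
      trig_span <- function(key) {
        w <- which(word_keys == key)
        c(starts[[w]], ends[[w]], words[[w]])
      }
      prot_t_base <- t_count - P_n   # protein T ids precede the trigger ids
      prot_tid <- function(pi) sprintf("T%d", prot_t_base + pi)

      add_trigger <- function(key, type) {
        sp <- trig_span(key)
        t_count <<- t_count + 1L
        a2 <<- c(a2, sprintf("T%d\t%s %s %s\t%s", t_count, type,
                             sp[[1L]], sp[[2L]], sp[[3L]]))
        sprintf("T%d", t_count)
      }
      if (nested) {
        svt_tid <- add_trigger("trig2", svt_typ)
        e_count <- e_count + 1L
        svt_eid <- sprintf("E%d", e_count)
        a2 <- c(a2, sprintf("%s\t%s:%s Theme:%s", svt_eid, svt_typ, svt_tid,
                            prot_tid(1L)))
        reg_tid <- add_trigger("trig1", typ)
        e_count <- e_count + 1L
        args <- sprintf("Theme:%s", svt_eid)
        if (has_cause) args <- paste(args, sprintf("Cause:%s", prot_tid(2L)))
        a2 <- c(a2, sprintf("E%d\t%s:%s %s", e_count, typ, reg_tid, args))
      } else {
        tid <- add_trigger("trig1", typ)
        e_count <- e_count + 1L
        args <- sprintf("Theme:%s", prot_tid(1L))
        if (has_theme2) args <- paste(args, sprintf("Theme2:%s", prot_tid(2L)))
        if (has_cause) args <- paste(args, sprintf("Cause:%s", prot_tid(2L)))
        a2 <- c(a2, sprintf("E%d\t%s:%s %s", e_count, typ, tid, args))
      }

      sent_texts <- c(sent_texts, sent_text)
      doc_offset <- doc_offset + nchar(sent_text) + 1L   # joining space
    }

    text <- paste(sent_texts, collapse = " ")
    writeLines(text, file.path(out_dir, paste0(doc_id, ".txt")))
    writeLines(a1, file.path(out_dir, paste0(doc_id, ".a1")))
    writeLines(a2, file.path(out_dir, paste0(doc_id, ".a2")))
    write_dependencies(dep_graphs, file.path(out_dir, paste0(doc_id, ".dep")))
  }

  manifest <- list(
    n_docs = n_docs, seed = as.integer(seed), imbalance = imbalance,
    positive_pairs = pos_tot, negative_pairs = neg_tot,
    realized_ratio = if (pos_tot > 0) neg_tot / pos_tot else NA_real_,
    nested_prob = nested_prob,
    binding_two_theme_prob = binding_two_theme_prob,
    reg_cause_prob = reg_cause_prob,
    positive_path_pool = lapply(fixture_pos_pool(), paste, collapse = " "),
    negative_path_alphabets = fixture_neg_alphabets()
  )
  jsonlite::write_json(manifest, file.path(out_dir, "corpus_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
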