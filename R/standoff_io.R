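#' BioNLP-ST standoff input/output
#'
#' Documents arrive as plain text (.txt), protein annotations (.a1),
#' optional event annotations (.a2) and a per-sentence typed-dependency
#' edge list (.dep).  All character offsets are 0-based, half-open and
#' document-level.
#'
#' @name standoff_io
NULL

# accept either a file path or raw text / a character vector of lines
arg_lines <- function(x) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) return(readLines(x))
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' Light rule-based stemmer
#'
#' Lowercases and strips a few common English suffixes
#' (\code{-ies}, plural \code{-s}, \code{-ing}, \code{-ed}).  Intended only
#' to conflate inflectional variants of trigger words; it is not a full
#' stemmer.
#'
#' @param x Character vector of tokens.
#' @return Character vector of stems.
#' @export
stem_token <- function(x) {
  s <- tolower(x)
  s <- sub("ies$", "y", s)
  long <- nchar(s) > 3L
  s[long] <- sub("(?<![su])s$", "", s[long], perl = TRUE)
  long <- nchar(s) > 5L
  s[long] <- sub("ing$", "", s[long])
  long <- nchar(s) > 5L
  s[long] <- sub("ed$", "", s[long])
  s
}

pos_heuristic <- function(token) {
  closed <- c(the = "DT", a = "DT", an = "DT", of = "IN", "in" = "IN",
              by = "IN", to = "TO", with = "IN", on = "IN", at = "IN",
              and = "CC", or = "CC", is = "VBZ", are = "VBP", was = "VBD",
              via = "IN", through = "IN", during = "IN", for_ = "IN")
  lower <- tolower(token)
  out <- unname(closed[lower])
  out[is.na(out) & grepl("^[[:punct:]]$", token)] <- "."
  out[is.na(out) & grepl("ed$", token)] <- "VBD"
  out[is.na(out) & grepl("(s|z)es?$", token)] <- "VBZ"
  out[is.na(out)] <- "NN"
  out
}

#' Tokenize document text
#'
#' Splits text into sentences at sentence-final periods and into tokens by
#' a whitespace-and-punctuation rule (runs of alphanumerics, optionally
#' hyphen/apostrophe-joined, or single punctuation marks), tracking 0-based
#' half-open document offsets for every token.
#'
#' @param text Document text (single string).
#' @return List of sentences; each sentence is a list with \code{index}
#'   (0-based), \code{char_start}, \code{char_end} and a \code{tokens}
#'   data.frame (\code{index}, \code{text}, \code{stem}, \code{pos},
#'   \code{char_start}, \code{char_end}).
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  # sentence boundaries: '.' followed by whitespace or end of text
  bounds <- gregexpr("\\.(?=\\s|$)", text, perl = TRUE)[[1L]]
  ends <- if (bounds[[1L]] == -1L) integer(0) else as.integer(bounds)
  if (!length(ends) || max(ends) < nchar(text)) {
    tail_txt <- substr(text, if (length(ends)) max(ends) + 1L else 1L, nchar(text))
    if (grepl("[^[:space:]]", tail_txt)) ends <- c(ends, nchar(text))
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    seg <- substr(text, starts[[i]], ends[[i]])
    m <- gregexpr("[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]",
                  seg, perl = TRUE)[[1L]]
    if (m[[1L]] == -1L) next
    tok_start <- as.integer(m) + starts[[i]] - 1L          # 1-based doc pos
    tok_len <- attr(m, "match.length")
    toks <- substring(text, tok_start, tok_start + tok_len - 1L)
    out[[i]] <- list(
      index = i - 1L,
      char_start = tok_start[[1L]] - 1L,
      char_end = tok_start[[length(tok_start)]] + tok_len[[length(tok_len)]] - 1L,
      tokens = data.frame(
        index = seq_along(toks) - 1L,
        text = toks,
        stem = stem_token(toks),
        pos = pos_heuristic(toks),
        char_start = tok_start - 1L,
        char_end = tok_start + tok_len - 1L,
        stringsAsFactors = FALSE
      )
    )
  }
  out[!vapply(out, is.null, logical(1L))]
}

parse_t_line <- function(line, lineno, what) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(parts) < 3L) {
    stop(sprintf("malformed %s line %d: %s", what, lineno, line))
  }
  ann <- strsplit(parts[[2L]], " ", fixed = TRUE)[[1L]]
  if (length(ann) != 3L) {
    stop(sprintf("malformed %s annotation on line %d: %s", what, lineno, line))
  }
  list(id = parts[[1L]], type = ann[[1L]],
       char_start = as.integer(ann[[2L]]), char_end = as.integer(ann[[3L]]),
       text = parts[[3L]])
}

#' Read a standoff-annotated document
#'
#' Parses the text, the .a1 protein annotations, and optionally .a2 event
#' annotations and a .dep dependency file.  Every annotation is checked:
#' annotation text must equal the document substring at its offsets, and
#' every trigger/theme/cause reference must resolve, otherwise an error
#' naming the offending line is raised.  Tokenization is performed with
#' [tokenize_text()] and dependency edges are attached per sentence.
#'
#' @param txt Path to the .txt file (or the raw text).
#' @param a1 Path to the .a1 file (or its lines); may be empty.
#' @param a2 Optional path to the .a2 file (or its lines).
#' @param dep Optional path to the dependency file (or its lines).
#' @param id Document identifier; defaults to the .txt file name.
#' @return A \code{standoff_document}: list with \code{id}, \code{text},
#'   \code{sentences}, \code{proteins}, \code{triggers}, \code{events}.
#' @export
read_standoff <- function(txt, a1, a2 = NULL, dep = NULL, id = NULL) {
  if (is.null(id)) {
    id <- if (length(txt) == 1L && file.exists(txt)) {
      sub("\\.txt$", "", basename(txt))
    } else "doc"
  }
  text <- paste(arg_lines(txt), collapse = "\n")

  check_span <- function(x, lineno, what) {
    got <- substr(text, x$char_start + 1L, x$char_end)
    if (!identical(got, x$text)) {
      stop(sprintf(
        "integrity error in %s line %d: annotation text %s != document span %s",
        what, lineno, dQuote(x$text), dQuote(got)))
    }
  }

  a1_lines <- arg_lines(a1)
  a1_lines <- a1_lines[!is.null(a1_lines) & nzchar(a1_lines)]
  proteins <- empty_ann_df()
  for (i in seq_along(a1_lines)) {
    p <- parse_t_line(a1_lines[[i]], i, ".a1")
    check_span(p, i, ".a1")
    proteins <- rbind(proteins, as.data.frame(p, stringsAsFactors = FALSE))
  }

  triggers <- empty_ann_df()
  events <- empty_event_df()
  a2_lines <- arg_lines(a2)
  a2_lines <- a2_lines[!is.null(a2_lines) & nzchar(a2_lines)]
  for (i in seq_along(a2_lines)) {
    line <- a2_lines[[i]]
    if (startsWith(line, "T")) {
      tr <- parse_t_line(line, i, ".a2")
      check_span(tr, i, ".a2")
      triggers <- rbind(triggers, as.data.frame(tr, stringsAsFactors = FALSE))
    } else if (startsWith(line, "E")) {
      events <- rbind(events, parse_e_line(line, i))
    } else {
      stop(sprintf("unsupported .a2 line %d: %s", i, line))
    }
  }
  validate_events(events, proteins, triggers)

  sentences <- tokenize_text(text)
  dep_lines <- arg_lines(dep)
  if (!is.null(dep_lines)) {
    graphs <- parse_dependency_lines(dep_lines)
    for (i in seq_along(sentences)) {
      si <- sentences[[i]]$index
      sentences[[i]]$deps <- if (si + 1L <= length(graphs)) graphs[[si + 1L]] else empty_dep_df()
    }
  } else {
    for (i in seq_along(sentences)) sentences[[i]]$deps <- empty_dep_df()
  }

  structure(list(id = id, text = text, sentences = sentences,
                 proteins = proteins, triggers = triggers, events = events),
            class = "standoff_document")
}

empty_ann_df <- function() {
  data.frame(id = character(), type = character(), char_start = integer(),
             char_end = integer(), text = character(), stringsAsFactors = FALSE)
}

empty_event_df <- function() {
  data.frame(id = character(), type = character(), trigger_id = character(),
             theme = character(), theme2 = character(), cause = character(),
             stringsAsFactors = FALSE)
}

empty_dep_df <- function() {
  data.frame(gov = integer(), dep = integer(), label = character(),
             stringsAsFactors = FALSE)
}

parse_e_line <- function(line, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop(sprintf("malformed .a2 event line %d: %s", lineno, line))
  fields <- strsplit(parts[[2L]], " ", fixed = TRUE)[[1L]]
  kv <- strsplit(fields, ":", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- vapply(kv, `[[`, character(1L), 2L)
  ev <- data.frame(id = parts[[1L]], type = keys[[1L]], trigger_id = vals[[1L]],
                   theme = NA_character_, theme2 = NA_character_,
                   cause = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_along(keys)[-1L]) {
    switch(keys[[j]],
      Theme = ev$theme <- vals[[j]],
      Theme2 = ev$theme2 <- vals[[j]],
      Cause = ev$cause <- vals[[j]],
      stop(sprintf("unsupported argument role %s on .a2 line %d", keys[[j]], lineno))
    )
  }
  ev
}

validate_events <- function(events, proteins, triggers) {
  if (!nrow(events)) return(invisible(TRUE))
  sch <- event_schema()
  t_ids <- c(proteins$id, triggers$id)
  e_ids <- events$id
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!ev$type %in% sch$type) {
      stop(sprintf("event %s has unknown type %s", ev$id, ev$type))
    }
    if (!ev$trigger_id %in% triggers$id) {
      stop(sprintf("event %s references undeclared trigger %s", ev$id, ev$trigger_id))
    }
    if (is.na(ev$theme)) stop(sprintf("event %s has no Theme", ev$id))
    for (ref in stats::na.omit(c(ev$theme, ev$theme2, ev$cause))) {
      pool <- if (startsWith(ref, "E")) e_ids else t_ids
      if (!ref %in% pool) {
        stop(sprintf("event %s references undeclared %s", ev$id, ref))
      }
    }
    cls <- sch$class[sch$type == ev$type]
    if (!is.na(ev$cause) && cls != "REG") {
      stop(sprintf("event %s (%s) carries a Cause but is not a REG-class event",
                   ev$id, ev$type))
    }
    if (!is.na(ev$theme2) && cls != "BIND") {
      stop(sprintf("event %s (%s) carries a second Theme but is not Binding",
                   ev$id, ev$type))
    }
  }
  invisible(TRUE)
}

#' Serialize events to .a2 lines
#'
#' Emits the trigger T lines followed by the event E lines in the standard
#' tab-separated standoff syntax.  Events are validated against the event
#' schema first; reading the output back with [read_standoff()] recovers
#' the identical event set.
#'
#' @param events Event data.frame (\code{id}, \code{type},
#'   \code{trigger_id}, \code{theme}, optional \code{theme2}/\code{cause}).
#' @param triggers Trigger annotation data.frame (\code{id}, \code{type},
#'   \code{char_start}, \code{char_end}, \code{text}).
#' @param proteins Protein annotations, used only to validate references.
#' @return Character vector of .a2 lines (empty for an empty event set).
#' @export
write_a2 <- function(events, triggers, proteins = empty_ann_df()) {
  if (is.null(events) || !nrow(events)) return(character(0))
  if (!"theme2" %in% names(events)) events$theme2 <- NA_character_
  if (!"cause" %in% names(events)) events$cause <- NA_character_
  used <- unique(events$trigger_id)
  triggers <- triggers[triggers$id %in% used, , drop = FALSE]
  validate_events(events, proteins, triggers)
  t_lines <- sprintf("%s\t%s %d %d\t%s", triggers$id, triggers$type,
                     triggers$char_start, triggers$char_end, triggers$text)
  e_lines <- vapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    args <- sprintf("Theme:%s", ev$theme)
    if (!is.na(ev$theme2)) args <- paste(args, sprintf("Theme2:%s", ev$theme2))
    if (!is.na(ev$cause)) args <- paste(args, sprintf("Cause:%s", ev$cause))
    sprintf("%s\t%s:%s %s", ev$id, ev$type, ev$trigger_id, args)
  }, character(1L))
  c(t_lines, e_lines)
}

#' Write dependency graphs to a .dep file
#'
#' One block per sentence: a \code{\%\% sentence <i>} header followed by one
#' \code{gov dep label} line per edge, token indices 0-based within the
#' sentence.
#'
#' @param graphs List of data.frames (\code{gov}, \code{dep}, \code{label}).
#' @param path Output path; when \code{NULL} the lines are returned.
#' @return The lines, invisibly when written to \code{path}.
#' @export
write_dependencies <- function(graphs, path = NULL) {
  lines <- unlist(lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    c(sprintf("%%%% sentence %d", i - 1L),
      if (nrow(g)) sprintf("%d %d %s", g$gov, g$dep, g$label))
  }), use.names = FALSE)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

parse_dependency_lines <- function(lines) {
  lines <- lines[nzchar(lines)]
  graphs <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    graphs[[length(graphs) + 1L]] <<- if (length(cur)) {
      parts <- strsplit(cur, " ", fixed = TRUE)
      data.frame(gov = vapply(parts, function(p) as.integer(p[[1L]]), integer(1L)),
                 dep = vapply(parts, function(p) as.integer(p[[2L]]), integer(1L)),
                 label = vapply(parts, `[[`, character(1L), 3L),
                 stringsAsFactors = FALSE)
    } else empty_dep_df()
  }
  for (line in lines) {
    if (startsWith(line, "%%")) {
      flush()
      cur <- character(0)
    } else {
      if (is.null(cur)) stop("dependency file must start with a '%% sentence' header")
      cur <- c(cur, line)
    }
  }
  flush()
  graphs
}

#' Read a corpus directory
#'
#' Loads every \code{<id>.txt} with its sibling \code{.a1} and, when
#' present, \code{.a2} and \code{.dep} files.
#'
#' @param dir Corpus directory.
#' @param with_a2 Read .a2 files when present (set \code{FALSE} for test
#'   mode).
#' @return Named list of \code{standoff_document}s.
#' @export
read_corpus <- function(dir, with_a2 = TRUE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, function(txt) {
    base <- sub("\\.txt$", "", txt)
    a2 <- paste0(base, ".a2")
    dep <- paste0(base, ".dep")
    read_standoff(
      txt, paste0(base, ".a1"),
      a2 = if (with_a2 && file.exists(a2)) a2 else NULL,
      dep = if (file.exists(dep)) dep else NULL
    )
  })
  names(docs) <- sub("\\.txt$", "", basename(txts))
  docs
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf("standoff_document %s: %d sentence(s), %d protein(s), %d event(s)\n",
              x$id, length(x$sentences), nrow(x$proteins), nrow(x$events)))
  invisible(x)
}

# locate the token covering a document-offset span; returns c(sentence_pos,
# token_row) into doc$sentences or NULL
token_for_span <- function(doc, char_start, char_end) {
  for (i in seq_along(doc$sentences)) {
    tok <- doc$sentences[[i]]$tokens
    hit <- which(tok$char_start < char_end & tok$char_end > char_start)
    if (length(hit)) return(c(i, hit[[1L]]))
  }
  NULL
}
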