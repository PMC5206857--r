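#' Sequential pattern mining over dependency-label paths
#'
#' A dependency path is represented as a character vector of typed-dependency
#' labels (one label per position).  A sequence database is a list of such
#' vectors.  A pattern is frequent when it occurs as an order-preserving,
#' not necessarily contiguous, subsequence of at least \code{minsup}
#' database sequences.
#'
#' @name seqmine
NULL

#' Order-preserving subsequence containment
#'
#' Tests whether \code{a} embeds into \code{b} via a strictly increasing
#' index map, i.e. whether \code{a} is a (non-contiguous) subsequence of
#' \code{b}.  The empty sequence is a subsequence of everything.
#'
#' @param a,b Character vectors of labels.
#' @return \code{TRUE} iff \code{a} is a subsequence of \code{b}.
#' @export
#' @examples
#' is_subsequence(c("amod", "nn"), c("amod", "prep_to", "prep_in", "nn"))
is_subsequence <- function(a, b) {
  na <- length(a)
  if (na == 0L) return(TRUE)
  nb <- length(b)
  if (na > nb) return(FALSE)
  i <- 1L
  for (j in seq_len(nb)) {
    if (a[[i]] == b[[j]]) {
      if (i == na) return(TRUE)
      i <- i + 1L
    }
  }
  FALSE
}

#' Support of a sequence in a sequence database
#'
#' Counts the database sequences that contain \code{s} as a subsequence.
#' Duplicate database sequences each contribute one (multiset semantics),
#' and a sequence contains itself.
#'
#' @param s Character vector of labels (the pattern).
#' @param db List of character vectors (the sequence database).
#' @return Integer count in \code{0:length(db)}.
#' @export
seq_support <- function(s, db) {
  sum(vapply(db, function(t) is_subsequence(s, t), logical(1L)))
}

#' Mine frequent sequential patterns (PrefixSpan)
#'
#' Pattern-growth mining by recursive prefix projection: the database is
#' projected on each frequent label, and each projection is mined for the
#' frequent labels extending the prefix, so no candidate sequences are ever
#' generated and counted wholesale.  Returns exactly the non-empty sequences
#' with support at least \code{minsup}, each with its true support.
#'
#' @param db List of character vectors (the sequence database).
#' @param minsup Minimum support, an absolute sequence count, at least 1.
#' @return An object of class \code{pattern_set}: a list with
#'   \code{patterns} (list of character vectors, ordered by length then
#'   lexicographically), \code{support} (integer vector) and \code{minsup}.
#' @export
#' @examples
#' db <- list(c("amod", "prep_to", "prep_in", "nn"),
#'            c("prep_to", "nn", "prep_in"),
#'            c("amod", "nn"),
#'            c("prep_to", "dobj", "prep_in", "nn"),
#'            c("dobj", "amod", "prep_to", "nn"),
#'            c("prep_to", "nn"))
#' ls <- mine_frequent_patterns(db, minsup = 3)
mine_frequent_patterns <- function(db, minsup) {
  if (!is.numeric(minsup) || length(minsup) != 1L || minsup < 1) {
    stop("'minsup' must be a single count >= 1")
  }
  minsup <- as.integer(minsup)
  db <- lapply(db, as.character)
  acc_pat <- list()
  acc_sup <- integer()

  # proj: integer matrix-ish, parallel vectors of (sequence id, suffix start)
  grow <- function(prefix, sid, pos) {
    # distinct items per projected suffix, then frequency across sequences
    item_lists <- lapply(seq_along(sid), function(k) {
      s <- db[[sid[[k]]]]
      p <- pos[[k]]
      if (p > length(s)) character(0) else unique(s[p:length(s)])
    })
    tab <- table(unlist(item_lists))
    freq_items <- sort(names(tab)[tab >= minsup])
    for (it in freq_items) {
      newprefix <- c(prefix, it)
      acc_pat[[length(acc_pat) + 1L]] <<- newprefix
      acc_sup[[length(acc_sup) + 1L]] <<- as.integer(tab[[it]])
      keep <- integer(0)
      newpos <- integer(0)
      for (k in seq_along(sid)) {
        s <- db[[sid[[k]]]]
        p <- pos[[k]]
        if (p > length(s)) next
        hit <- which(s[p:length(s)] == it)
        if (length(hit)) {
          keep <- c(keep, sid[[k]])
          newpos <- c(newpos, p + hit[[1L]])
        }
      }
      grow(newprefix, keep, newpos)
    }
  }
  if (length(db)) grow(character(0), seq_along(db), rep(1L, length(db)))

  ord <- pattern_order(acc_pat)
  structure(
    list(patterns = acc_pat[ord], support = acc_sup[ord], minsup = minsup),
    class = "pattern_set"
  )
}

# canonical ordering: length, then lexicographic on the joined labels
pattern_order <- function(patterns) {
  if (!length(patterns)) return(integer(0))
  len <- lengths(patterns)
  key <- vapply(patterns, paste, character(1L), collapse = " ")
  order(len, key, method = "radix")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: %d frequent patterns (minsup = %d)\n",
              length(x$patterns), x$minsup))
  n <- min(length(x$patterns), 10L)
  for (i in seq_len(n)) {
    cat(sprintf("  <%s>  support %d\n",
                paste(x$patterns[[i]], collapse = " "), x$support[[i]]))
  }
  if (length(x$patterns) > n) cat(sprintf("  ... %d more\n", length(x$patterns) - n))
  invisible(x)
}

#' Serialize a pattern set to a delimited text file
#'
#' One pattern per line: space-separated labels, a tab, and the support.
#' The \code{minsup} is stored on a leading comment line.
#'
#' @param ls A \code{pattern_set}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pattern_set <- function(ls, path) {
  stopifnot(inherits(ls, "pattern_set"))
  lines <- c(
    sprintf("# minsup\t%d", ls$minsup),
    vapply(seq_along(ls$patterns), function(i) {
      sprintf("%s\t%d", paste(ls$patterns[[i]], collapse = " "), ls$support[[i]])
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a pattern set written by [write_pattern_set()]
#'
#' @param path File path.
#' @return A \code{pattern_set}.
#' @export
read_pattern_set <- function(path) {
  lines <- readLines(path)
  minsup <- 1L
  head_line <- grepl("^# minsup\t", lines)
  if (any(head_line)) {
    minsup <- as.integer(sub("^# minsup\t", "", lines[head_line][[1L]]))
    lines <- lines[!head_line]
  }
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  patterns <- lapply(parts, function(p) strsplit(p[[1L]], " ", fixed = TRUE)[[1L]])
  support <- vapply(parts, function(p) as.integer(p[[2L]]), integer(1L))
  structure(list(patterns = patterns, support = support, minsup = minsup),
            class = "pattern_set")
}
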