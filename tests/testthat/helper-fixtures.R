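# shared fixtures and independent oracles

# the six-sequence dependency-path database used throughout the worked
# examples
table2_db <- function() {
  list(c("amod", "prep_to", "prep_in", "nn"),
       c("prep_to", "nn", "prep_in"),
       c("amod", "nn"),
       c("prep_to", "dobj", "prep_in", "nn"),
       c("dobj", "amod", "prep_to", "nn"),
       c("prep_to", "nn"))
}

make_pattern_set <- function(patterns, support = NULL, minsup = 1L) {
  if (is.null(support)) support <- rep(minsup, length(patterns))
  structure(list(patterns = patterns, support = as.integer(support),
                 minsup = as.integer(minsup)),
            class = "pattern_set")
}

# brute-force miner: enumerate every subsequence of every DB sequence,
# count containment directly
all_subsequences <- function(s) {
  n <- length(s)
  out <- list()
  for (m in 1:(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0L)
    out[[length(out) + 1L]] <- s[idx]
  }
  out
}

brute_force_mine <- function(db, minsup) {
  cand <- unique(unlist(lapply(db[lengths(db) > 0L], all_subsequences),
                        recursive = FALSE))
  sup <- vapply(cand, seq_support, integer(1L), db = db)
  keep <- sup >= minsup
  res <- list(patterns = cand[keep], support = sup[keep])
  key <- vapply(res$patterns, paste, character(1L), collapse = " ")
  ord <- order(lengths(res$patterns), key, method = "radix")
  list(patterns = res$patterns[ord], support = unname(res$support[ord]))
}

random_db <- function(n_seq = 8L, alphabet = 5L, max_len = 6L) {
  ab <- letters[seq_len(alphabet)]
  lapply(seq_len(sample.int(n_seq, 1L)), function(i) {
    sample(ab, sample.int(max_len, 1L), replace = TRUE)
  })
}

# hand BFS over an undirected edge list: distance between two 0-based
# token indices, NA when disconnected
bfs_distance <- function(deps, from, to) {
  if (from == to) return(0L)
  frontier <- from
  seen <- from
  dist <- 0L
  while (length(frontier)) {
    dist <- dist + 1L
    nxt <- integer(0)
    for (v in frontier) {
      nb <- c(deps$dep[deps$gov == v], deps$gov[deps$dep == v])
      nxt <- c(nxt, setdiff(nb, seen))
    }
    nxt <- unique(nxt)
    if (to %in% nxt) return(dist)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  NA_integer_
}

# generate a corpus once per session and cache the directory
fixture_corpus_dir <- local({
  cache <- new.env(parent = emptyenv())
  function(n_docs, seed, ...) {
    key <- paste(n_docs, seed, ...)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), sprintf("bioevex-fx-%d-%d", n_docs, seed))
      if (!dir.exists(dir)) {
        generate_fixture_corpus(dir, n_docs = n_docs, seed = seed, ...)
      }
      cache[[key]] <- dir
    }
    cache[[key]]
  }
})

# a small handcrafted document: one sentence, one Binding trigger, three
# proteins, one REG trigger, explicit dependency edges
toy_doc <- function() {
  #        0       1  2    3    4    5          6
  text <- "binding of IL-2 IL-4 IL-6 activation STAT1."
  a1 <- c("T1\tProtein 11 15\tIL-2",
          "T2\tProtein 16 20\tIL-4",
          "T3\tProtein 21 25\tIL-6",
          "T4\tProtein 37 42\tSTAT1")
  a2 <- c("T5\tBinding 0 7\tbinding",
          "T6\tPositive_regulation 26 36\tactivation",
          "E1\tBinding:T5 Theme:T1 Theme2:T2",
          "E2\tPositive_regulation:T6 Theme:T4 Cause:T1")
  dep <- c("%% sentence 0",
           "0 2 dobj", "0 3 prep_of", "0 4 prep_to",
           "5 6 dobj", "5 2 prep_by", "5 3 nn", "5 4 prep_in",
           "5 0 conj_and")
  read_standoff(text, a1, a2 = a2, dep = dep, id = "toy")
}

toy_dict <- function() build_trigger_dictionary(list(toy = toy_doc()))
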