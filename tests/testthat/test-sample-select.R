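test_that("the sequence database is the multiset of labeled-pair paths", {
  paths <- table2_db()
  labeled <- data.frame(label = rep("Gene_expression", 6L))
  labeled$path <- paths
  db <- build_sequence_db(labeled)
  expect_identical(unclass(db)[seq_along(paths)], paths)
  # duplicates kept, pathless skipped with a count
  labeled2 <- data.frame(label = c("x", "x", "x"))
  labeled2$path <- list(c("nn", "amod"), c("nn", "amod"), NULL)
  db2 <- build_sequence_db(labeled2)
  expect_length(db2, 2L)
  expect_identical(attr(db2, "skipped"), 1L)
  expect_length(build_sequence_db(list()), 0L)
})

test_that("match count reproduces the threshold worked example", {
  ls <- make_pattern_set(list(c("prep_of", "nn"), c("nn"),
                              c("nsubj", "prep_of", "nn")))
  path <- c("nsubj", "prep_of", "nn")
  expect_identical(match_count(path, ls), 3L)
  expect_gt(match_count(path, ls), 2L)
  cand <- data.frame(label = "unlabeled"); cand$path <- list(path)
  sel <- select_samples(cand, ls, theta = 2)
  expect_identical(nrow(sel), 1L)
  # strict inequality: theta equal to the count rejects
  expect_identical(nrow(select_samples(cand, ls, theta = 3)), 0L)
  expect_identical(match_count(path, make_pattern_set(list())), 0L)
})

test_that("match count equals the loop-over-patterns oracle on random input", {
  set.seed(31)
  ab <- letters[1:5]
  for (rep in seq_len(50L)) {
    ls <- make_pattern_set(lapply(seq_len(sample.int(6L, 1L)), function(i) {
      sample(ab, sample.int(3L, 1L), replace = TRUE)
    }))
    path <- sample(ab, sample.int(6L, 1L), replace = TRUE)
    oracle <- sum(vapply(ls$patterns, is_subsequence, logical(1L), b = path))
    expect_identical(match_count(path, ls), oracle)
  }
})

test_that("selection is monotone in theta and bounded by the pattern count", {
  set.seed(8)
  ab <- c("nsubj", "dobj", "nn", "amod", "prep_of")
  db <- lapply(1:12, function(i) sample(ab, sample(2:4, 1L), replace = TRUE))
  ls <- mine_frequent_patterns(db, minsup = 3)
  cands <- data.frame(label = rep("unlabeled", 40L))
  cands$path <- lapply(1:40, function(i) sample(ab, sample(1:5, 1L), replace = TRUE))
  sizes <- vapply(0:4, function(th) nrow(select_samples(cands, ls, th)),
                  integer(1L))
  expect_true(all(diff(sizes) <= 0L))
  expect_identical(nrow(select_samples(cands, ls, theta = length(ls$patterns))),
                   0L)
})

test_that("raising minsup shrinks the pattern set and the selected set", {
  dir <- fixture_corpus_dir(30, 555)
  docs <- read_corpus(dir)
  dict <- build_trigger_dictionary(docs)
  pairs <- do.call(rbind, lapply(docs, generate_pairs, dict = dict))
  pos <- pairs[pairs$label != "negative", , drop = FALSE]
  neg <- pairs[pairs$label == "negative", , drop = FALSE]
  db <- build_sequence_db(pos)
  prev_n <- Inf
  for (m in 2:6) {
    ls <- mine_frequent_patterns(db, m)
    n_sel <- nrow(select_samples(neg, ls, theta = 2))
    expect_lte(n_sel, prev_n)
    prev_n <- n_sel
  }
})

test_that("triplet filtering composes the pair criterion over both paths", {
  ls <- make_pattern_set(list(c("prep_of", "nn"), c("nn"),
                              c("nsubj", "prep_of", "nn")))
  good <- c("nsubj", "prep_of", "nn")   # F = 3
  weak <- c("dobj")                     # F = 0
  tri <- data.frame(label = c("a", "b", "c"))
  tri$path1 <- list(good, good, weak)
  tri$path2 <- list(good, weak, weak)
  both <- filter_triplet_candidates(tri, ls, theta = 2)
  expect_identical(both$label, "a")
  # oracle: apply the pair filter to each side
  pairf <- function(p) match_count(p, ls) > 2
  want <- vapply(seq_len(3L), function(i) pairf(tri$path1[[i]]) && pairf(tri$path2[[i]]),
                 logical(1L))
  expect_identical(tri$label[want], both$label)
  # sum rule admits one strong + one weak path when the total clears 2*theta
  sums <- filter_triplet_candidates(tri, ls, theta = 1, rule = "sum")
  expect_identical(sums$label, c("a", "b"))
})

test_that("labeled positives bypass the filter in training assembly", {
  dir <- fixture_corpus_dir(20, 303)
  docs <- read_corpus(dir)
  bundle <- suppressWarnings(run_train(docs, minsup = 6, theta = 3))
  # even with an aggressive filter, every positive pair is in training:
  # the manifest counts positives independently of the filter
  pairs <- do.call(rbind, lapply(docs, generate_pairs,
                                 dict = bundle$dict))
  pos <- pairs[pairs$label != "negative", , drop = FALSE]
  expect_identical(bundle$manifest$pairs_positive, nrow(pos))
  # the same filter applied to the positives would discard some of them,
  # so the training assembly demonstrably does not route them through it
  pos_filtered <- select_samples(pos, bundle$patterns,
                                 theta = bundle$config$theta)
  expect_lt(nrow(pos_filtered), nrow(pos))
})
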