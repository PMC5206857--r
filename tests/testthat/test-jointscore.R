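test_that("word hashing enumerates boundary-marked letter n-grams", {
  h <- word_hash("cat", 3L)
  expect_setequal(names(h), c("#ca", "cat", "at#"))
  expect_true(all(h == 1L))
  h2 <- word_hash("aaa", 3L)
  expect_identical(h2[["#aa"]], 1L)
  expect_identical(h2[["aaa"]], 1L)
  expect_identical(h2[["aa#"]], 1L)
  expect_identical(word_hash("cat", 3L), word_hash("cat", 3L))
  expect_length(word_hash("", 3L), 0L)
})

test_that("cosine relevance is symmetric, bounded, and guards zero vectors", {
  a <- c(x = 1, y = 2)
  expect_equal(relevance(a, a), 1)
  expect_equal(relevance(c(x = 1), c(y = 1)), 0)
  set.seed(4)
  for (i in 1:10) {
    u <- rnorm(5); v <- rnorm(5)
    expect_equal(relevance(u, v), relevance(v, u))
    expect_lte(abs(relevance(u, v)), 1 + 1e-12)
  }
  expect_warning(z <- relevance(numeric(5), rnorm(5)), "zero")
  expect_identical(z, 0)
})

test_that("sentence similarity is 0 for an empty set and 1 for self", {
  s <- c("IRF-4", "expression", "is", "induced")
  expect_identical(sentence_similarity(s, list()), 0)
  expect_equal(sentence_similarity(s, list(s)), 1)
  d <- list(c("completely", "different", "words"),
            c("IRF-4", "expression", "rises"),
            s)
  got <- sentence_similarity(s, d)
  e0 <- trigram_embedding(s)
  want <- max(vapply(d, function(x) relevance(e0, trigram_embedding(x)),
                     numeric(1L)))
  expect_equal(got, want)
})

test_that("trigger importance follows the weighted-mean arithmetic", {
  stats <- list(
    counts = data.frame(stem = c("expr", "expr"),
                        type = c("Gene_expression", "Positive_regulation"),
                        count = c(4L, 1L), stringsAsFactors = FALSE),
    total = 10L, sentences = list()
  )
  ti <- trigger_importance("expr", "Gene_expression", stats, w1 = 2, w2 = 3)
  expect_equal(ti$p1, 0.8, tolerance = 1e-12)
  expect_equal(ti$p2, 0.5, tolerance = 1e-12)
  expect_equal(ti$p, 0.62, tolerance = 1e-12)
  # w1 = 0 degenerates to p2
  expect_equal(trigger_importance("expr", "Gene_expression", stats, 0, 3)$p,
               0.5)
  # unseen trigger flags and zeroes; zero total weight errors
  un <- trigger_importance("unknown", "Binding", stats, 1, 1)
  expect_true(un$unseen)
  expect_identical(un$p, 0)
  expect_error(trigger_importance("expr", "Binding", stats, 0, 0), "positive")
})

test_that("per-trigger type fractions sum to one on fixture statistics", {
  dir <- fixture_corpus_dir(20, 303)
  docs <- read_corpus(dir)
  st <- trigger_stats(docs)
  for (stem in unique(st$counts$stem)) {
    p1s <- vapply(unique(st$counts$type[st$counts$stem == stem]),
                  function(ty) trigger_importance(stem, ty, st, 1, 1)$p1,
                  numeric(1L))
    expect_equal(sum(p1s), 1, tolerance = 1e-12)
  }
})

test_that("the joint score mixes importance and similarity linearly", {
  expect_equal(joint_score(0.62, 0.5, sigma = 0.7), 0.536, tolerance = 1e-12)
  expect_equal(joint_score(0.3, 0.9, sigma = 1), 0.9)
  expect_equal(joint_score(0.3, 0.9, sigma = 0), 0.3)
  # negative similarity clamps to zero
  expect_equal(joint_score(0.4, -0.5, sigma = 0.5), 0.2)
  expect_error(joint_score(0.5, 0.5, sigma = 1.2), "sigma")
  # monotone in both arguments
  expect_gte(joint_score(0.7, 0.5), joint_score(0.6, 0.5))
  expect_gte(joint_score(0.6, 0.6), joint_score(0.6, 0.5))
})

test_that("score filtering partitions by threshold, monotonically in delta", {
  preds <- data.frame(id = 1:6, score = c(0, 0.2, 0.5, 0.5, 0.8, 1))
  f0 <- filter_by_score(preds, 0)
  expect_identical(nrow(f0$kept), 6L)
  f1 <- filter_by_score(preds, 1)
  expect_identical(nrow(f1$kept), 1L)
  f5 <- filter_by_score(preds, 0.5)
  expect_identical(f5$kept$id, c(3:6))
  expect_identical(f5$removed$id, 1:2)
  sizes <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                  function(d) nrow(filter_by_score(preds, d)$kept), integer(1L))
  expect_true(all(diff(sizes) <= 0L))
  expect_error(filter_by_score(preds, 1.5), "delta")
})

test_that("the convolutional backend is deterministic and degenerates correctly", {
  tokens <- c("IRF-4", "binds", "IL-2")
  w <- cdssm_weights(hash_dim = 64L, conv_dim = 16L, sem_dim = 8L, seed = 9L)
  expect_identical(cdssm_forward(tokens, w), cdssm_forward(tokens, w))
  w2 <- cdssm_weights(hash_dim = 64L, conv_dim = 16L, sem_dim = 8L, seed = 9L)
  expect_identical(w$Wc, w2$Wc)
  # all-zero weights with an odd activation give the zero vector
  w0 <- w; w0$Wc[] <- 0; w0$Ws[] <- 0
  expect_identical(unique(cdssm_forward(tokens, w0)), 0)
  # single token: max pooling over one window is the identity
  wl <- cdssm_weights(hash_dim = 32L, conv_dim = 8L, sem_dim = 8L,
                      window = 3L, seed = 2L)
  one <- cdssm_forward("IRF-4", wl)
  wl1 <- wl; wl1$window <- 1L
  expect_identical(one, cdssm_forward("IRF-4", wl1))
  # identity weights, whole-sentence window and linear activation recover
  # the hashed letter-trigram bag representation
  wi <- cdssm_weights(hash_dim = 128L, window = Inf, activation = "linear",
                      identity = TRUE)
  got <- cdssm_forward(tokens, wi)
  want <- bioevex:::hash_to_dense(trigram_embedding(tokens), 128L)
  expect_identical(got, want)
  # hence identical cosine relevance under both representations
  t2 <- c("IL-2", "expression")
  expect_equal(relevance(got, cdssm_forward(t2, wi)),
               relevance(bioevex:::hash_to_dense(trigram_embedding(tokens), 128L),
                         bioevex:::hash_to_dense(trigram_embedding(t2), 128L)))
})
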