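test_that("the trigger dictionary maps stems to observed types with counts", {
  dict <- toy_dict()
  expect_setequal(dict$stem, c("bind", "activation"))
  expect_identical(dict$type[dict$stem == "bind"], "Binding")
  expect_true(all(dict$count >= 1L))
})

test_that("pair generation crosses dictionary triggers with sentence arguments", {
  doc <- toy_doc()
  pairs <- generate_pairs(doc, toy_dict())
  # binding trigger x 4 proteins; REG-capable activation x 4 proteins +
  # the other trigger token
  bind <- pairs[pairs$trig_stem == "bind", ]
  act <- pairs[pairs$trig_stem == "activation", ]
  expect_identical(nrow(bind), 4L)
  expect_identical(nrow(act), 5L)
  expect_true(all(pairs$trig_tok != pairs$arg_tok))
  # gold labels recovered from the .a2
  expect_setequal(pairs$label[pairs$label != "negative"],
                  c("Binding", "Positive_regulation"))
  # a dictionary with no matching stems yields no candidates
  other <- data.frame(stem = "phosphorylation", type = "Phosphorylation",
                      count = 1L)
  expect_identical(nrow(generate_pairs(doc, other)), 0L)
})

test_that("triplet generation enumerates unordered Binding and ordered REG pairs", {
  doc <- toy_doc()
  tri <- generate_triplets(doc, toy_dict())
  bind <- tri[tri$trig_stem == "bind", ]
  # C(4,2) unordered protein pairs for the Binding trigger
  expect_identical(nrow(bind), as.integer(choose(4L, 2L)))
  expect_true(all(bind$a1_tok < bind$a2_tok))
  act <- tri[tri$trig_stem == "activation", ]
  # ordered (theme, cause): theme in 4 proteins + 1 trigger token, cause
  # in 4 proteins, minus theme == cause
  expect_identical(nrow(act), 5L * 4L - 4L)
  # gold Binding triplet labeled irrespective of argument order
  expect_identical(sum(bind$label == "Binding"), 1L)
  expect_identical(sum(act$label == "Positive_regulation"), 1L)
})

test_that("dependency paths come from shortest paths; length matches BFS oracle", {
  set.seed(12)
  dir <- fixture_corpus_dir(8, 808)
  docs <- read_corpus(dir)
  dict <- build_trigger_dictionary(docs)
  for (doc in docs[1:4]) {
    pairs <- generate_pairs(doc, dict)
    take <- utils::head(seq_len(nrow(pairs)), 25L)
    for (i in take) {
      sent <- doc$sentences[[pairs$sent[[i]]]]
      d <- bfs_distance(sent$deps,
                        sent$tokens$index[[pairs$trig_tok[[i]]]],
                        sent$tokens$index[[pairs$arg_tok[[i]]]])
      p <- pairs$path[[i]]
      if (is.null(p)) expect_true(is.na(d)) else expect_identical(length(p), as.integer(d))
    }
  }
})

test_that("feature extraction is pure and covers the four groups", {
  doc <- toy_doc()
  pairs <- generate_pairs(doc, toy_dict())
  cand <- pairs[pairs$label == "Binding", ][1L, ]
  f1 <- extract_features(cand, doc)
  f2 <- extract_features(cand, doc)
  expect_identical(f1, f2)
  nm <- names(f1)
  # token group: stem, POS, character n-grams, shape
  expect_true("t_stem=bind" %in% nm)
  expect_true(any(startsWith(nm, "t_g=")))
  expect_true(any(startsWith(nm, "a_shape=")))
  # sentence group
  expect_true("nent=4" %in% nm)
  expect_true(any(startsWith(nm, "bow=")))
  # dependency group: path labels and trigger chains
  expect_true(any(startsWith(nm, "path=")))
  expect_true(any(startsWith(nm, "chain=")))
  expect_true(all(f1 == 1))
})

test_that("character n-grams and shapes behave as defined", {
  expect_setequal(bioevex:::char_ngrams("irf-4", 1L),
                  c("i", "r", "f", "-", "4"))
  expect_true("irf" %in% bioevex:::char_ngrams("irf-4", 3L))
  expect_identical(bioevex:::word_shape("IRF-4"), "X-d")
  expect_identical(bioevex:::word_shape("IkB-alpha"), "XxX-x")
})

test_that("hypernym features appear only when a lookup is supplied", {
  doc <- toy_doc()
  pairs <- generate_pairs(doc, toy_dict())
  cand <- pairs[1L, ]
  hyp <- list(bind = c("attach", "join"))
  with_h <- extract_features(cand, doc, hypernyms = hyp)
  without <- extract_features(cand, doc)
  expect_true(all(c("t_hyp=attach", "t_hyp=join") %in% names(with_h)))
  expect_false(any(startsWith(names(without), "t_hyp=")))
})

test_that("disconnected pairs carry a no-path flag instead of path features", {
  text <- "expression of STAT1."
  a1 <- "T1\tProtein 14 19\tSTAT1"
  # dependency graph with no edges at all
  doc <- read_standoff(text, a1, dep = "%% sentence 0", id = "d")
  dict <- data.frame(stem = "expression", type = "Gene_expression", count = 1L)
  pairs <- generate_pairs(doc, dict)
  expect_identical(nrow(pairs), 1L)
  expect_null(pairs$path[[1L]])
  f <- extract_features(pairs[1L, ], doc)
  expect_true("nopath" %in% names(f))
  expect_false(any(startsWith(names(f), "path=")))
})
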