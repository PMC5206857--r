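# minimal prediction-set builders for the integration rules
mk_pairs <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(doc = "d", sent = 1L, trig_tok = r$c, trig_stem = "t",
               arg_tok = r$a, arg_kind = "protein",
               arg_id = sprintf("T%d", r$a), type = r$type,
               margin = if (is.null(r$margin)) 1 else r$margin,
               stringsAsFactors = FALSE)
  }))
  out
}

mk_triplets <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(doc = "d", sent = 1L, trig_tok = r$c, trig_stem = "t",
               a1_tok = r$a1, a2_tok = r$a2, a1_kind = "protein",
               a2_kind = "protein", a1_id = sprintf("T%d", r$a1),
               a2_id = sprintf("T%d", r$a2), type = r$type,
               margin = if (is.null(r$margin)) 1 else r$margin,
               stringsAsFactors = FALSE)
  }))
}

test_that("a Binding triplet subsumes its two pairs; the third pair survives", {
  preds <- list(
    pairs = mk_pairs(list(c = 1L, a = 11L, type = "Binding"),
                     list(c = 1L, a = 12L, type = "Binding"),
                     list(c = 1L, a = 13L, type = "Binding")),
    triplets = mk_triplets(list(c = 1L, a1 = 11L, a2 = 12L, type = "Binding"))
  )
  ev <- integrate_predictions(preds)
  expect_identical(nrow(ev), 2L)
  two <- ev[!is.na(ev$theme2_tok), ]
  one <- ev[is.na(ev$theme2_tok), ]
  expect_identical(sort(c(two$theme_tok, two$theme2_tok)), c(11L, 12L))
  expect_identical(one$theme_tok, 13L)
  expect_true(all(ev$type == "Binding"))
})

test_that("with no triplets, integration is the identity on pair predictions", {
  preds <- list(
    pairs = mk_pairs(list(c = 1L, a = 11L, type = "Gene_expression"),
                     list(c = 2L, a = 12L, type = "Binding")),
    triplets = NULL
  )
  ev <- integrate_predictions(preds)
  expect_identical(nrow(ev), 2L)
  expect_setequal(ev$type, c("Gene_expression", "Binding"))
  expect_true(all(is.na(ev$theme2_tok)) && all(is.na(ev$cause_tok)))
})

test_that("a REG triplet emits theme and cause and subsumes its theme pair", {
  preds <- list(
    pairs = mk_pairs(list(c = 1L, a = 11L, type = "Positive_regulation"),
                     list(c = 1L, a = 13L, type = "Positive_regulation")),
    triplets = mk_triplets(list(c = 1L, a1 = 11L, a2 = 12L,
                                type = "Positive_regulation"))
  )
  ev <- integrate_predictions(preds)
  expect_identical(nrow(ev), 2L)
  tri <- ev[!is.na(ev$cause_tok), ]
  expect_identical(tri$theme_tok, 11L)
  expect_identical(tri$cause_tok, 12L)
  # the pair at a different argument is emitted directly
  expect_identical(ev$theme_tok[is.na(ev$cause_tok)], 13L)
})

test_that("conflicting types on one pair keep the higher margin", {
  preds <- list(
    pairs = mk_pairs(list(c = 1L, a = 11L, type = "Regulation", margin = 0.2),
                     list(c = 1L, a = 11L, type = "Positive_regulation",
                          margin = 0.9)),
    triplets = NULL
  )
  ev <- suppressMessages(integrate_predictions(preds))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$type, "Positive_regulation")
})

test_that("integration is idempotent on its own output", {
  preds <- list(
    pairs = mk_pairs(list(c = 1L, a = 11L, type = "Binding"),
                     list(c = 1L, a = 13L, type = "Binding"),
                     list(c = 2L, a = 11L, type = "Gene_expression")),
    triplets = mk_triplets(list(c = 1L, a1 = 11L, a2 = 12L, type = "Binding"))
  )
  once <- integrate_predictions(preds)
  # re-feed the surviving single-theme events as pairs, two-theme ones as
  # triplets
  pairs2 <- once[is.na(once$theme2_tok), ]
  pairs2 <- data.frame(doc = pairs2$doc, sent = pairs2$sent,
                       trig_tok = pairs2$trig_tok, trig_stem = pairs2$trig_stem,
                       arg_tok = pairs2$theme_tok, arg_kind = pairs2$theme_kind,
                       arg_id = pairs2$theme_id, type = pairs2$type,
                       margin = pairs2$margin, stringsAsFactors = FALSE)
  tri2 <- once[!is.na(once$theme2_tok), ]
  tri2 <- data.frame(doc = tri2$doc, sent = tri2$sent, trig_tok = tri2$trig_tok,
                     trig_stem = tri2$trig_stem, a1_tok = tri2$theme_tok,
                     a2_tok = tri2$theme2_tok, a1_kind = tri2$theme_kind,
                     a2_kind = tri2$theme2_kind, a1_id = tri2$theme_id,
                     a2_id = tri2$theme2_id, type = tri2$type,
                     margin = tri2$margin, stringsAsFactors = FALSE)
  twice <- integrate_predictions(list(pairs = pairs2, triplets = tri2))
  key <- function(x) {
    x <- x[order(x$trig_tok, x$theme_tok), ]
    paste(x$type, x$trig_tok, x$theme_tok, x$theme2_tok, x$cause_tok)
  }
  expect_identical(key(twice), key(once))
})

test_that("training is deterministic and degenerate label sets are dropped", {
  dir <- fixture_corpus_dir(20, 303)
  docs <- read_corpus(dir)
  b1 <- suppressWarnings(run_train(docs))
  b2 <- suppressWarnings(run_train(docs))
  expect_identical(b1$models$pair$coefs, b2$models$pair$coefs)
  expect_identical(b1$manifest, b2$manifest)
  # all-negative labels leave no usable class
  cand <- data.frame(label = rep("negative", 4L))
  maps <- replicate(4L, c(f1 = 1), simplify = FALSE)
  expect_warning(m <- bioevex:::fit_ovr(maps, cand$label, "negative"),
                 "dropped")
  expect_length(m$classes, 0L)
})

test_that("prediction on a document without candidates is empty and stable", {
  dir <- fixture_corpus_dir(20, 303)
  docs <- read_corpus(dir)
  bundle <- suppressWarnings(run_train(docs))
  text <- "Nothing happens here."
  doc <- read_standoff(text, character(0), id = "empty")
  p <- predict_events(doc, bundle$models, bundle$dict, bundle$patterns)
  expect_identical(nrow(p$pairs), 0L)
  expect_identical(nrow(p$triplets), 0L)
  d1 <- predict_events(docs[[1L]], bundle$models, bundle$dict, bundle$patterns)
  d2 <- predict_events(docs[[1L]], bundle$models, bundle$dict, bundle$patterns)
  expect_identical(d1, d2)
})
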