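fig1_doc <- function() {
  text <- "IRF-4 expression was induced by IFN-alpha."
  a1 <- c("T1\tProtein 0 5\tIRF-4", "T2\tProtein 32 41\tIFN-alpha")
  a2 <- c("T3\tGene_expression 6 16\texpression",
          "T4\tPositive_regulation 21 28\tinduced",
          "E1\tGene_expression:T3 Theme:T1",
          "E2\tPositive_regulation:T4 Theme:E1 Cause:T2")
  list(text = text, a1 = a1, a2 = a2)
}

test_that("standoff reading resolves proteins, triggers and nested events", {
  f <- fig1_doc()
  doc <- read_standoff(f$text, f$a1, a2 = f$a2, id = "fig1")
  expect_s3_class(doc, "standoff_document")
  expect_identical(doc$proteins$text, c("IRF-4", "IFN-alpha"))
  expect_identical(nrow(doc$events), 2L)
  expect_identical(doc$events$theme, c("T1", "E1"))
  expect_identical(doc$events$cause, c(NA_character_, "T2"))
})

test_that("an absent or empty .a2 yields a document with zero events", {
  f <- fig1_doc()
  doc <- read_standoff(f$text, f$a1, id = "fig1")
  expect_identical(nrow(doc$events), 0L)
  expect_identical(nrow(read_standoff(f$text, f$a1, a2 = character(0))$events), 0L)
})

test_that("dangling references and offset mismatches are rejected by name", {
  f <- fig1_doc()
  bad_a2 <- c(f$a2[1:3], "E2\tPositive_regulation:T4 Theme:E1 Cause:T9")
  expect_error(read_standoff(f$text, f$a1, a2 = bad_a2), "T9")
  bad_a1 <- c("T1\tProtein 0 5\tIRF-X")
  expect_error(read_standoff(f$text, bad_a1), "integrity")
  # cause on a non-REG event violates the schema
  bad_a2 <- c("T3\tGene_expression 6 16\texpression",
              "E1\tGene_expression:T3 Theme:T1 Cause:T2")
  expect_error(read_standoff(f$text, f$a1, a2 = bad_a2), "Cause")
})

test_that("write_a2 then read_standoff is the identity on the event set", {
  f <- fig1_doc()
  doc <- read_standoff(f$text, f$a1, a2 = f$a2)
  lines <- write_a2(doc$events, doc$triggers, doc$proteins)
  back <- read_standoff(f$text, f$a1, a2 = lines)
  expect_identical(back$events, doc$events)
  expect_identical(back$triggers, doc$triggers)
  expect_identical(write_a2(empty_events <- doc$events[0, ], doc$triggers),
                   character(0))
})

test_that("tokenization yields sorted, non-overlapping, offset-faithful tokens", {
  text <- "IRF-4 expression was induced by IFN-alpha. STAT1 binds IL-2."
  sents <- tokenize_text(text)
  expect_length(sents, 2L)
  for (s in sents) {
    tok <- s$tokens
    expect_true(all(tok$char_start < tok$char_end))
    expect_true(all(diff(tok$char_start) > 0))
    expect_true(all(tok$char_end[-nrow(tok)] <= tok$char_start[-1L]))
    expect_identical(substring(text, tok$char_start + 1L, tok$char_end),
                     tok$text)
  }
  expect_identical(sents[[1L]]$tokens$text[[1L]], "IRF-4")
})

test_that("dependency files round-trip per sentence", {
  graphs <- list(
    data.frame(gov = c(0L, 1L), dep = c(1L, 2L), label = c("nsubj", "dobj"),
               stringsAsFactors = FALSE),
    data.frame(gov = integer(), dep = integer(), label = character(),
               stringsAsFactors = FALSE)
  )
  path <- tempfile(fileext = ".dep")
  write_dependencies(graphs, path)
  back <- bioevex:::parse_dependency_lines(readLines(path))
  expect_identical(back, graphs)
})

test_that("fixture corpora are deterministic, schema-valid and ratio-faithful", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture_corpus(d1, n_docs = 6, seed = 99)
  generate_fixture_corpus(d2, n_docs = 6, seed = 99)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # reading validates every event against the schema (errors otherwise)
  docs <- read_corpus(d1)
  expect_length(docs, 6L)
  # a one-document corpus still contains a simple event
  d3 <- tempfile()
  generate_fixture_corpus(d3, n_docs = 1, seed = 5)
  doc <- read_corpus(d3)[[1L]]
  expect_true(any(event_class(doc$events$type) == "SVT"))
})

test_that("the realized candidate-pair imbalance tracks the requested ratio", {
  dir <- fixture_corpus_dir(60, 2024)
  docs <- read_corpus(dir)
  dict <- build_trigger_dictionary(docs)
  pairs <- do.call(rbind, lapply(docs, generate_pairs, dict = dict))
  ratio <- sum(pairs$label == "negative") / sum(pairs$label != "negative")
  expect_gte(ratio, 13.163 * 0.8)
  expect_lte(ratio, 13.163 * 1.2)
})
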