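test_that("interval relation derivation matches its definition and is antisymmetric", {
  expect_equal(derive_interval_relation(c(0, 2), c(3, 5)), "BEFORE")
  expect_equal(derive_interval_relation(c(3, 5), c(0, 2)), "AFTER")
  expect_equal(derive_interval_relation(c(0, 4), c(3, 5)), "OVERLAP")
  set.seed(5)
  for (i in 1:50) {
    a <- sort(runif(2)); b <- sort(runif(2))
    if (a[1] == a[2] || b[1] == b[2]) next
    l <- derive_interval_relation(a, b)
    expect_equal(derive_interval_relation(b, a),
                 scheme_inverse(basic_scheme, l))
  }
})

test_that("timelines have the configured size, concepts and determinism", {
  cfg <- generator_config(n_docs = 1L, events_per_doc = c(5L, 5L), seed = 3L)
  tl1 <- with_seed_tl <- temporalkg:::with_local_seed(9L, sample_timeline(cfg))
  expect_equal(nrow(tl1), 5L)
  expect_true(all(tl1$t_start < tl1$t_end))
  tl2 <- temporalkg:::with_local_seed(9L, sample_timeline(cfg))
  expect_identical(tl1, tl2)

  cfg1 <- generator_config(n_docs = 1L, concept_count = 1L, seed = 3L)
  tl3 <- temporalkg:::with_local_seed(2L, sample_timeline(cfg1))
  expect_equal(unique(tl3$concept_id), "C0000001")
})

test_that("rendering controls cues exactly", {
  base <- generator_config(n_docs = 1L, events_per_doc = c(6L, 6L),
                           long_range_pairs_per_doc = 0L, seed = 5L)
  cues <- unname(temporalkg:::cue_words)
  # cue_probability = 1: every adjacent-pair sentence carries the matching
  # connective
  cfg1 <- base; cfg1$cue_probability <- 1
  doc1 <- generate_corpus(cfg1)$documents[[1]]
  sentences <- strsplit(doc1$text, " \\. ?")[[1]][-1]
  expect_equal(length(sentences), nrow(doc1$relations))
  for (i in seq_along(sentences)) {
    lab <- doc1$relations$label[i]
    expect_match(sentences[i], temporalkg:::cue_words[[lab]], fixed = TRUE)
  }
  # cue_probability = 0: no temporal connective anywhere
  cfg0 <- base; cfg0$cue_probability <- 0
  doc0 <- generate_corpus(cfg0)$documents[[1]]
  for (w in cues) expect_false(grepl(w, doc0$text, fixed = TRUE))
})

test_that("long-range pairs are cue-free relations between non-adjacent mentions", {
  cfg <- generator_config(n_docs = 1L, events_per_doc = c(6L, 6L),
                          long_range_pairs_per_doc = 2L,
                          cue_probability = 1, seed = 8L)
  doc <- generate_corpus(cfg)$documents[[1]]
  expect_equal(nrow(doc$relations), 5L + 2L)
  # narrative position = order of appearance in the events table
  pos <- stats::setNames(seq_len(nrow(doc$events)), doc$events$id)
  lr <- doc$relations[6:7, ]
  expect_true(all(pos[lr$target] - pos[lr$source] >= 2L))
})

test_that("corpus generation is deterministic and latent-truth consistent", {
  cfg <- generator_config(n_docs = 6L, seed = 21L)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_jsonl_corpus(c1$documents, p1)
  write_jsonl_corpus(c2$documents, p2)
  expect_identical(readLines(p1), readLines(p2))

  # gold labels equal interval-derived labels from the emitted sidecar
  sidecar <- withr::local_tempfile()
  write_latent_sidecar(c1$latent, sidecar)
  lat <- read_latent_sidecar(sidecar)
  for (doc in c1$documents) {
    L <- lat[lat$doc_id == doc$doc_id, ]
    for (i in seq_len(nrow(doc$relations))) {
      r <- doc$relations[i, ]
      a <- unlist(L[L$id == r$source, c("t_start", "t_end")])
      b <- unlist(L[L$id == r$target, c("t_start", "t_end")])
      expect_equal(derive_interval_relation(a, b), r$label)
    }
  }
  # all documents pass validation with concept ids usable for linking
  for (doc in c1$documents) {
    expect_silent(validate_document(doc, basic_scheme))
    expect_false(anyNA(doc$events$concept_id))
  }
})

test_that("class frequencies respond to duration scale as intervals dictate", {
  short <- generator_config(n_docs = 30L, duration_meanlog = -1.5,
                            duration_sdlog = 0.3, seed = 4L)
  long <- generator_config(n_docs = 30L, duration_meanlog = 3.0,
                           duration_sdlog = 0.3, seed = 4L)
  freq <- function(corp) {
    labs <- unlist(lapply(corp$documents, function(d) d$relations$label))
    mean(labs == "OVERLAP")
  }
  expect_lt(freq(generate_corpus(short)), 0.2)
  expect_gt(freq(generate_corpus(long)), 0.5)
})
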