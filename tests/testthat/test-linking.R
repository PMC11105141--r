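test_that("normalization lowercases, collapses and strips; idempotent", {
  expect_equal(normalize_mention("  Painless Jaundice, "), "painless jaundice")
  expect_equal(normalize_mention("ICU"), "icu")
  set.seed(2)
  for (i in 1:20) {
    x <- paste(sample(c(LETTERS, letters, " ", ",", ".", "-"), 12,
                      replace = TRUE), collapse = "")
    expect_identical(normalize_mention(normalize_mention(x)),
                     normalize_mention(x))
  }
})

lex <- concept_lexicon(data.frame(
  surface = c("liposuction", "procedures", "painless jaundice"),
  concept_id = c("C0038640", "C0025664", "C0022346"),
  canonical_name = c("Suction Lipectomy", "Methods aspects",
                     "Painless jaundice"),
  stringsAsFactors = FALSE))

test_that("linking: exact match, longest-subsequence fallback, no-link", {
  # the canonical terminology example: a long mention links through its
  # contained head phrase
  hit <- link_mention("liposuction of varying areas", lex)
  expect_equal(hit$concept_id, "C0038640")
  # the documented context-free failure mode: generic phrases link to a
  # generic concept
  hit2 <- link_mention("both procedures", lex)
  expect_equal(hit2$concept_id, "C0025664")
  expect_null(link_mention("zzz-unknown", lex))
  # exact normalized match wins and is deterministic
  expect_equal(link_mention("  Painless JAUNDICE ", lex)$concept_id,
               "C0022346")
  expect_identical(link_mention("both procedures", lex),
                   link_mention("both procedures", lex))
})

test_that("ties break lexicographically by concept id", {
  tie <- concept_lexicon(data.frame(
    surface = c("alpha", "beta"),
    concept_id = c("C2", "C1"),
    canonical_name = c("A", "B"), stringsAsFactors = FALSE))
  hit <- link_mention("beta alpha thing", tie)
  expect_equal(hit$concept_id, "C1")
})

test_that("lexicon TSV round trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  lex2 <- read_lexicon(path)
  expect_identical(lex$entries, lex2$entries)
})

test_that("consolidation groups by concept with pseudo-concept fallback", {
  mk <- function(doc_id, surf, cid = NA_character_) {
    document(doc_id, paste(surf, "seen ."),
             data.frame(id = "E1", start = 0L, end = nchar(surf),
                        surface = surf, concept_id = cid,
                        stringsAsFactors = FALSE))
  }
  docs <- list(mk("d1", "liposuction"), mk("d2", "liposuction"),
               mk("d3", "Mystery Thing"), mk("d4", "mystery  thing"),
               mk("d5", "painless jaundice"))
  cons <- consolidate_events(docs, dictionary_linker(lex))
  # liposuction x2 -> one concept node; the two unlinked mentions share a
  # pseudo-concept keyed by normalized surface
  expect_equal(nrow(cons$nodes), 3L)
  lip <- cons$nodes[cons$nodes$concept_id == "C0038640", ]
  expect_equal(lip$mention_count, 2L)
  pseudo <- cons$nodes[startsWith(cons$nodes$concept_id, "SURF:"), ]
  expect_equal(pseudo$mention_count, 2L)
  expect_equal(pseudo$canonical_name, "mystery thing")
  # total single-valued map
  expect_equal(nrow(cons$node_map), 5L)
  expect_false(anyNA(cons$node_map$node_id))

  # permutation invariance up to node ids (which are canonical anyway)
  cons2 <- consolidate_events(rev(docs), dictionary_linker(lex))
  expect_identical(cons$nodes, cons2$nodes)

  # all-distinct concepts give one node per mention
  docs3 <- list(mk("a", "liposuction"), mk("b", "painless jaundice"),
                mk("c", "procedures"))
  expect_equal(nrow(consolidate_events(docs3,
                                       dictionary_linker(lex))$nodes), 3L)
})

test_that("passthrough linker trusts concept_id fields", {
  d <- chain_doc(c("BEFORE", "BEFORE"))
  cons <- consolidate_events(list(d), passthrough_linker())
  expect_equal(nrow(cons$nodes), 3L)
  expect_setequal(cons$nodes$concept_id, c("C1", "C2", "C3"))
})
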