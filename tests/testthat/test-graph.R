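test_that("gold graph construction maps, dedups and rejects dangling events", {
  d <- chain_doc(c("BEFORE", "BEFORE"))
  cons <- consolidate_events(list(d))
  g <- build_event_graph(list(d), cons)
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_true(all(g$edges$provenance == "gold"))
  expect_true(all(g$edges$confidence == 1))

  # two relations collapsing to the same (node, node, label) deduplicate:
  # two docs, same concept pair, same label
  d2 <- chain_doc("BEFORE", "other")
  d2$events$concept_id <- c("C1", "C2")
  cons2 <- consolidate_events(list(chain_doc("BEFORE"), d2))
  g2 <- build_event_graph(list(chain_doc("BEFORE"), d2), cons2)
  expect_equal(nrow(g2$edges), 1L)

  expect_equal(nrow(build_event_graph(list(), cons)$edges), 0L)
})

test_that("inverse enrichment adds permuted reverse edges, idempotently", {
  d <- chain_doc(c("BEFORE", "OVERLAP"))
  cons <- consolidate_events(list(d))
  g <- add_inverse_edges(build_event_graph(list(d), cons))
  e <- g$edges
  expect_equal(nrow(e), 4L)
  n <- stats::setNames(cons$nodes$node_id, cons$nodes$concept_id)
  expect_true(any(e$src == n["C2"] & e$dst == n["C1"] & e$label == "AFTER" &
                    e$provenance == "inverse"))
  expect_true(any(e$src == n["C3"] & e$dst == n["C2"] & e$label == "OVERLAP"))
  # probability vector permuted by the inverse map
  inv <- e[e$provenance == "inverse" & e$label == "AFTER", ]
  expect_equal(inv$prob[[1]], c(0, 1, 0))
  # idempotent
  expect_identical(add_inverse_edges(g)$edges$id, g$edges$id)
  # derivation ref points at the gold source edge
  expect_true(all(unlist(inv$deriv) %in% e$id[e$provenance == "gold"]))
})

test_that("transitive closure follows the composition table", {
  sch <- basic_scheme
  mkg <- function(labels) {
    d <- chain_doc(labels)
    cons <- consolidate_events(list(d))
    list(g = build_event_graph(list(d), cons),
         n = stats::setNames(cons$nodes$node_id, cons$nodes$concept_id))
  }
  x <- mkg(c("BEFORE", "BEFORE"))
  ge <- enrich_graph(x$g)
  e <- ge$edges
  expect_true(any(e$src == x$n["C1"] & e$dst == x$n["C3"] &
                    e$label == "BEFORE" & e$provenance == "transitive"))
  expect_true(any(e$src == x$n["C3"] & e$dst == x$n["C1"] &
                    e$label == "AFTER"))
  # fixpoint: a second call adds nothing
  expect_identical(add_transitive_edges(ge)$edges$id, ge$edges$id)

  # (BEFORE, OVERLAP) is ambiguous under strict: no C1-C3 edge
  y <- mkg(c("BEFORE", "OVERLAP"))
  ye <- enrich_graph(y$g)
  expect_false(any(ye$edges$src == y$n["C1"] & ye$edges$dst == y$n["C3"]))

  # contradictory input A BEFORE B, B BEFORE A: no self-loops ever
  d0 <- chain_doc("BEFORE")
  d <- document(d0$doc_id, d0$text, d0$events,
                data.frame(source = c("E1", "E2"), target = c("E2", "E1"),
                           label = "BEFORE", stringsAsFactors = FALSE),
                basic_scheme)
  cons <- consolidate_events(list(d))
  gz <- enrich_graph(build_event_graph(list(d), cons))
  expect_false(any(gz$edges$src == gz$edges$dst))
})

test_that("closure equals the brute-force fixpoint oracle on random graphs", {
  set.seed(1234)
  for (preset in c("strict", "approx")) {
    sch <- label_scheme(composition = preset)
    for (rep in 1:100) {
      g <- random_graph(sample(3:10, 1), p_edge = runif(1, 0.05, 0.35),
                        scheme = sch)
      if (nrow(g$edges) > 20L)
        g$edges <- g$edges[1:20, , drop = FALSE]
      ge <- enrich_graph(g)
      expect_identical(graph_to_label_array(ge),
                       oracle_enrich(g, sch$composition))
    }
  }
})

test_that("subgraph extraction equals a BFS oracle and keeps targets", {
  # path graph: n0 - n1 - ... - n5
  d <- chain_doc(rep("BEFORE", 5))
  cons <- consolidate_events(list(d))
  g <- build_event_graph(list(d), cons)
  ids <- cons$nodes$node_id[order(cons$nodes$concept_id)]
  sg <- extract_subgraph(g, ids[1], max_hops = 3)
  expect_setequal(sg$nodes$node_id, ids[1:4])
  sg2 <- extract_subgraph(g, c(ids[1], ids[6]), max_hops = 3)
  expect_setequal(sg2$nodes$node_id, ids)
  expect_error(extract_subgraph(g, "N9999"), "N9999")

  # isolated targets: 2 nodes, 0 edges
  g0 <- event_graph(g$nodes, NULL, g$scheme)
  sg0 <- extract_subgraph(g0, ids[c(2, 5)], max_hops = 3)
  expect_setequal(sg0$nodes$node_id, ids[c(2, 5)])
  expect_equal(nrow(sg0$edges), 0L)

  set.seed(77)
  for (rep in 1:20) {
    rg <- random_graph(sample(10:50, 1), p_edge = 0.06)
    targets <- sample(rg$nodes$node_id, 2)
    hops <- sample(1:4, 1)
    sg <- extract_subgraph(rg, targets, hops)
    dist <- pmin(bfs_distances(rg, targets[1]), bfs_distances(rg, targets[2]))
    expect_setequal(sg$nodes$node_id,
                    union(targets, names(dist)[dist <= hops]))
  }
})

test_that("masking removes the target pair and its whole derived shadow", {
  d <- chain_doc(c("BEFORE", "BEFORE"))
  cons <- consolidate_events(list(d))
  n <- stats::setNames(cons$nodes$node_id, cons$nodes$concept_id)
  ge <- enrich_graph(build_event_graph(list(d), cons))
  gm <- mask_target_edges(ge, n[["C1"]], n[["C2"]])
  # gold (C1,C2), its inverse, and the transitive (C1,C3) derived from it
  # (plus that edge's own inverse) are all gone
  expect_false(any((gm$edges$src == n[["C1"]] & gm$edges$dst == n[["C2"]]) |
                     (gm$edges$src == n[["C2"]] & gm$edges$dst == n[["C1"]])))
  expect_false(any(gm$edges$src == n[["C1"]] & gm$edges$dst == n[["C3"]]))
  # the untouched C2-C3 gold edge survives
  expect_true(any(gm$edges$src == n[["C2"]] & gm$edges$dst == n[["C3"]] &
                    gm$edges$provenance == "gold"))
  # masking a non-adjacent pair changes nothing
  gu <- mask_target_edges(ge, n[["C1"]], "N9999")
  expect_identical(gu$edges$id, ge$edges$id)
})

test_that("masking re-derives edges that have a derivation avoiding the pair", {
  # diamond: A->B->D and A->C->D all BEFORE. The transitive A->D edge must
  # survive masking of (A,B) because the A-C-D derivation remains.
  nodes <- data.frame(node_id = c("A", "B", "C", "D"),
                      concept_id = c("A", "B", "C", "D"),
                      canonical_name = letters[1:4], mention_count = 1L,
                      stringsAsFactors = FALSE)
  mke <- function(s, d) temporalkg:::make_edges(
    s, d, "BEFORE", 1, "gold", list(character(0)), list(c(1, 0, 0)))
  g <- event_graph(nodes, do.call(rbind, list(
    mke("A", "B"), mke("B", "D"), mke("A", "C"), mke("C", "D"))),
    basic_scheme)
  ge <- enrich_graph(g)
  gm <- mask_target_edges(ge, "A", "B")
  expect_true(any(gm$edges$src == "A" & gm$edges$dst == "D" &
                    gm$edges$label == "BEFORE"))
  # and the masked graph equals enrichment of the graph without the A-B
  # base edge (no leakage through the derivation order)
  g2 <- g; g2$edges <- g2$edges[!(g2$edges$src == "A" & g2$edges$dst == "B"), ]
  ge2 <- enrich_graph(g2)
  expect_setequal(gm$edges$id, ge2$edges$id)
})

test_that("confidence filtering keeps >= threshold and cascades to children", {
  d <- chain_doc(c("BEFORE", "BEFORE"))
  cons <- consolidate_events(list(d))
  g <- build_event_graph(list(d), cons)
  g$edges$confidence <- c(0.4, 0.9)
  ge <- enrich_graph(g)
  f <- filter_by_confidence(ge, 0.5)
  # the 0.4 edge, its inverse, and the transitive edge (conf 0.36) are gone
  expect_true(all(f$edges$confidence >= 0.5))
  expect_false(any(f$edges$provenance == "transitive"))
  # boundary: >= keeps an exactly-at-threshold edge
  g2 <- build_event_graph(list(d), cons)
  g2$edges$confidence <- c(0.4, 0.5)
  f2 <- filter_by_confidence(g2, 0.5)
  expect_equal(nrow(f2$edges), 1L)
  expect_equal(f2$edges$confidence, 0.5)
  # identity and monotonicity
  expect_equal(nrow(filter_by_confidence(ge, 0)$edges), nrow(ge$edges))
  counts <- vapply(seq(0, 1, 0.1), function(t)
    nrow(filter_by_confidence(ge, t)$edges), 0L)
  expect_true(all(diff(counts) <= 0L))
  expect_error(filter_by_confidence(ge, 1.2), "outside")
})

test_that("oracle filtering keeps only label-matching predicted edges", {
  nodes <- data.frame(node_id = c("A", "B", "C"), concept_id = c("A", "B", "C"),
                      canonical_name = letters[1:3], mention_count = 1L,
                      stringsAsFactors = FALSE)
  mke <- function(s, d, l, conf, prov) temporalkg:::make_edges(
    s, d, l, conf, prov, list(character(0)),
    list(temporalkg:::one_hot(match(l, basic_scheme$labels), 3L)))
  gold <- event_graph(nodes, rbind(mke("A", "B", "BEFORE", 1, "gold"),
                                   mke("B", "C", "OVERLAP", 1, "gold")),
                      basic_scheme)
  pred <- event_graph(nodes, rbind(mke("A", "B", "BEFORE", 0.8, "predicted"),
                                   mke("B", "C", "BEFORE", 0.6, "predicted"),
                                   mke("A", "C", "BEFORE", 0.7, "predicted")),
                      basic_scheme)
  pe <- enrich_graph(pred)
  out <- oracle_filter_graph(pe, gold)
  base <- out$edges[out$edges$provenance == "predicted", ]
  expect_equal(nrow(base), 1L)             # only the correct A->B survives
  expect_equal(base$label, "BEFORE")
  # result is a subset of the predicted graph
  expect_true(all(out$edges$id %in% pe$edges$id))
  # derived edges whose parents died are gone
  expect_false(any(out$edges$src == "C" & out$edges$dst == "B"))
})

test_that("graph serialization round-trips exactly", {
  d <- chain_doc(c("BEFORE", "OVERLAP"))
  cons <- consolidate_events(list(d))
  g <- enrich_graph(build_event_graph(list(d), cons))
  # give one edge a soft probability vector to exercise precision
  g$edges$prob[[1]] <- c(0.600000000123, 0.3, 0.099999999877)
  g$edges$confidence[[1]] <- 0.600000000123
  dir <- withr::local_tempdir()
  export_graph(g, dir)
  g2 <- import_graph(dir)
  expect_identical(g2$nodes, g$nodes)
  expect_identical(g2$edges$id, g$edges$id)
  expect_identical(g2$edges$provenance, g$edges$provenance)
  expect_identical(g2$edges$deriv, g$edges$deriv)
  for (i in seq_len(nrow(g$edges)))
    expect_lt(max(abs(g2$edges$prob[[i]] - g$edges$prob[[i]])), 1e-9)
  expect_identical(g2$scheme$labels, g$scheme$labels)
})

test_that("enrichment never deletes or relabels a gold edge", {
  set.seed(42)
  for (rep in 1:10) {
    g <- random_graph(6, p_edge = 0.3)
    ge <- enrich_graph(g)
    gold_before <- g$edges$id
    expect_true(all(gold_before %in%
                      ge$edges$id[ge$edges$provenance == "gold"]))
  }
})
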