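test_that("soft edges with one-hot vectors equal the hard-label convolution", {
  set.seed(31)
  for (rep in 1:100) {
    g <- random_graph(sample(3:8, 1), p_edge = 0.4)
    d <- 6L
    h <- matrix(rnorm(nrow(g$nodes) * d), ncol = d)
    W0 <- matrix(rnorm(d * d, sd = 0.3), d, d)
    Wr <- array(rnorm(d * d * 3, sd = 0.3), dim = c(d, d, 3))
    b <- rnorm(d)
    soft <- relational_conv_layer(h, g, W0, Wr, b, activation = "relu")
    hard <- hard_conv_oracle(h, g, W0, Wr, b)
    expect_lt(max(abs(soft - hard)), 1e-6)
  }
})

test_that("isolated nodes see only their self-transformation", {
  g <- random_graph(4, p_edge = 0)
  d <- 5L
  h <- matrix(rnorm(4 * d), ncol = d)
  W0 <- matrix(rnorm(d * d), d, d)
  Wr <- array(rnorm(d * d * 3), dim = c(d, d, 3))
  out <- relational_conv_layer(h, g, W0, Wr, activation = "identity")
  expect_equal(out, h %*% W0)
})

test_that("uniform probability vectors average the per-relation messages", {
  g <- random_graph(5, p_edge = 0.5)
  g$edges$prob <- replicate(nrow(g$edges), rep(1 / 3, 3), simplify = FALSE)
  d <- 4L
  h <- matrix(rnorm(5 * d), ncol = d)
  W0 <- matrix(0, d, d)
  Wr <- array(rnorm(d * d * 3), dim = c(d, d, 3))
  soft <- relational_conv_layer(h, g, W0, Wr, activation = "identity")
  # oracle: mean of the three hard single-relation passes
  per_rel <- lapply(1:3, function(r) {
    gh <- g
    gh$edges$prob <- replicate(nrow(g$edges),
                               temporalkg:::one_hot(r, 3), simplify = FALSE)
    relational_conv_layer(h, gh, W0, Wr, activation = "identity")
  })
  expect_lt(max(abs(soft - Reduce(`+`, per_rel) / 3)), 1e-10)
})

test_that("word-vector lookup: table hits, hash fallback, file loading", {
  mat <- rbind(suction = c(1, 0, 3, 1), lipectomy = c(3, 2, 1, 1))
  tab <- word_vector_table(vectors = mat)
  node <- data.frame(canonical_name = "suction lipectomy",
                     stringsAsFactors = FALSE)
  expect_equal(init_node_embedding(node, tab), c(2, 1, 2, 1))
  single <- data.frame(canonical_name = "suction", stringsAsFactors = FALSE)
  expect_equal(init_node_embedding(single, tab), c(1, 0, 3, 1))
  # deterministic out-of-vocabulary fallback
  oov <- data.frame(canonical_name = "zzz qqq", stringsAsFactors = FALSE)
  v1 <- init_node_embedding(oov, tab)
  v2 <- init_node_embedding(oov, tab)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
  # text-embedding file round trip
  path <- withr::local_tempfile()
  writeLines(c("suction 1 0 3 1", "lipectomy 3 2 1 1"), path)
  tab2 <- read_word_vectors(path)
  expect_equal(init_node_embedding(node, tab2), c(2, 1, 2, 1))
})

test_that("pair encoding is isomorphism-invariant and 3-hop local", {
  gp <- graph_encoder_params(8L, 10L, 3L, seed = 5L)
  vec <- word_vector_table(8L)
  # path graph of length 5 around targets at one end
  d <- chain_doc(rep("BEFORE", 5))
  cons <- consolidate_events(list(d))
  g <- add_inverse_edges(build_event_graph(list(d), cons))
  ids <- cons$nodes$node_id[order(cons$nodes$concept_id)]
  u_full <- encode_graph_pair(g, ids[1:2], gp, vec)

  # deleting nodes > 3 hops from both targets leaves the encoding unchanged
  dist <- pmin(bfs_distances(g, ids[1]), bfs_distances(g, ids[2]))
  keep <- names(dist)[dist <= 3]
  g_cut <- g
  g_cut$nodes <- g$nodes[g$nodes$node_id %in% keep, , drop = FALSE]
  g_cut$edges <- g$edges[g$edges$src %in% keep & g$edges$dst %in% keep, ,
                         drop = FALSE]
  u_cut <- encode_graph_pair(g_cut, ids[1:2], gp, vec)
  expect_lt(max(abs(u_full$u1 - u_cut$u1)), 1e-6)
  expect_lt(max(abs(u_full$u2 - u_cut$u2)), 1e-6)
  # whereas deleting a 2-hop node changes it (locality is tight)
  g_cut2 <- g_cut
  drop <- ids[3]
  g_cut2$nodes <- g_cut2$nodes[g_cut2$nodes$node_id != drop, , drop = FALSE]
  g_cut2$edges <- g_cut2$edges[g_cut2$edges$src != drop &
                                 g_cut2$edges$dst != drop, , drop = FALSE]
  u_cut2 <- encode_graph_pair(g_cut2, ids[1:2], gp, vec)
  expect_gt(max(abs(u_full$u1 - u_cut2$u1)), 1e-8)

  # node-id relabeling (isomorphism) leaves target outputs unchanged
  g_rel <- g
  relab <- stats::setNames(sprintf("M%02d", seq_len(nrow(g$nodes))),
                           g$nodes$node_id)
  g_rel$nodes$node_id <- unname(relab[g_rel$nodes$node_id])
  g_rel$edges$src <- unname(relab[g_rel$edges$src])
  g_rel$edges$dst <- unname(relab[g_rel$edges$dst])
  g_rel$edges$id <- temporalkg:::edge_id(g_rel$edges$src, g_rel$edges$dst,
                                         g_rel$edges$label)
  # reorder rows to exercise input-order independence too
  g_rel$nodes <- g_rel$nodes[rev(seq_len(nrow(g_rel$nodes))), , drop = FALSE]
  u_rel <- encode_graph_pair(g_rel, unname(relab[ids[1:2]]), gp, vec)
  expect_lt(max(abs(u_full$u1 - u_rel$u1)), 1e-6)
  expect_lt(max(abs(u_full$u2 - u_rel$u2)), 1e-6)

  # two isolated nodes: output depends only on their own initial vectors
  g0 <- event_graph(g$nodes[1:2, ], NULL, basic_scheme)
  g0$nodes$node_id <- ids[1:2]
  u0a <- encode_graph_pair(g0, ids[1:2], gp, vec)
  g0b <- g0; g0b$nodes <- g0b$nodes[2:1, , drop = FALSE]
  u0b <- encode_graph_pair(g0b, ids[1:2], gp, vec)
  expect_equal(u0a, u0b)
  expect_error(encode_graph_pair(g0, c(ids[1], "N9999"), gp, vec), "missing")
})

test_that("a structure-only task is learnable above the majority baseline", {
  # labels recoverable from graph structure alone: the masked document
  # graph of a cue-free corpus still determines many pairs through
  # surviving chains and concept regularity
  corp <- generate_corpus(generator_config(n_docs = 60L, cue_probability = 0,
                                           seed = 9L))
  docs <- corp$documents
  sp <- split_training_data(docs[1:48], c(0.2, 0.6, 0.2), seed = 2L)
  test_docs <- docs[49:60]
  cfg <- train_config(seed = 3L, text_epochs = 0L, graph_epochs = 25L,
                      graph_lr = 3e-3, patience = 6L, graph_source = "gold",
                      stages = "graph")
  bundle <- train_model(sp$train1, sp$train2, sp$val, cfg)
  cons <- consolidate_events(test_docs)
  graphs <- temporalkg:::document_graphs(test_docs, cons, bundle$scheme,
                                         "strict", source = "gold")
  pr <- predict_relations(test_docs, bundle, mode = "graph", graph = graphs,
                          consolidation = cons)
  golds <- build_instances(test_docs)$gold
  acc <- mean(pr$instances$predicted == golds)
  majority <- max(table(golds)) / length(golds)
  expect_gt(acc, majority + 0.1)
})
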