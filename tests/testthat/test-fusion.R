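test_that("fusion is a single linear layer with softmax semantics", {
  fp <- fusion_params(d_t = 3L, d_g = 2L, n_labels = 3L, seed = 2L)
  v1 <- c(0.3, -1, 2); v2 <- c(1, 0, 0.5); u1 <- c(0.2, -0.4); u2 <- c(1, 1)
  p <- fuse_and_classify(v1, v2, u1, u2, fp)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # zero graph vectors reduce to the text-coordinate restriction plus bias
  z <- numeric(2)
  logits_manual <- c(c(v1, v2, z, z) %*% fp$params$W) + fp$params$b
  expect_equal(fuse_and_classify(v1, v2, z, z, fp),
               temporalkg:::softmax_vec(logits_manual))
  # doubling all inputs doubles the affine part of the logits
  p2 <- fuse_and_classify(2 * v1, 2 * v2, 2 * u1, 2 * u2, fp)
  logits1 <- c(c(v1, v2, u1, u2) %*% fp$params$W) + fp$params$b
  expect_equal(p2, temporalkg:::softmax_vec(2 * (logits1 - fp$params$b) +
                                              fp$params$b))
  expect_error(fuse_and_classify(v1, v2, u1, c(1, 2, 3), fp), "dimension")
})

test_that("training is deterministic: same seed, same model; seeds differ", {
  corp <- generate_corpus(generator_config(n_docs = 24L, seed = 13L))
  sp <- split_training_data(corp$documents, seed = 2L)
  cfg <- train_config(seed = 5L, text_epochs = 3L, graph_epochs = 3L,
                      fusion_epochs = 40L, joint_epochs = 2L, patience = 2L)
  b1 <- train_model(sp$train1, sp$train2, sp$val, cfg)
  b2 <- train_model(sp$train1, sp$train2, sp$val, cfg)
  cks <- function(b) param_checksum(list(b$backbone$params,
                                         b$text_head$params,
                                         b$graph_params$params,
                                         b$graph_head$params,
                                         b$fusion$params))
  expect_identical(cks(b1), cks(b2))
  expect_identical(b1$logs$text[[3]]$val_acc, b2$logs$text[[3]]$val_acc)
  cfg3 <- cfg; cfg3$seed <- 6L
  b3 <- train_model(sp$train1, sp$train2, sp$val, cfg3)
  expect_false(identical(cks(b1), cks(b3)))

  # bundle JSON round trip preserves behaviour exactly
  path <- withr::local_tempfile(fileext = ".json")
  save_bundle(b1, path)
  b1r <- load_bundle(path)
  docs <- sp$val
  cons <- consolidate_events(docs)
  graphs <- temporalkg:::document_graphs(docs, cons, b1$scheme, "strict",
                                         source = "gold")
  p_a <- predict_relations(docs, b1, "bimodal", graphs, cons)
  p_b <- predict_relations(docs, b1r, "bimodal", graphs, cons)
  expect_equal(p_a$probs, p_b$probs, tolerance = 1e-12)
})

test_that("modality isolation and mode requirements hold", {
  corp <- generate_corpus(generator_config(n_docs = 8L, seed = 17L))
  docs <- corp$documents
  bundle <- tiny_bundle(docs)
  cons <- consolidate_events(docs)
  graphs <- temporalkg:::document_graphs(docs, cons, bundle$scheme, "strict",
                                         source = "gold")
  # text-only ignores any provided graph
  t1 <- predict_relations(docs, bundle, "text")
  t2 <- predict_relations(docs, bundle, "text", graph = graphs,
                          consolidation = cons)
  expect_identical(t1$probs, t2$probs)
  # bimodal needs a graph
  expect_error(predict_relations(docs, bundle, "bimodal"), "graph")
  # bimodal on graphs whose targets are isolated still yields proper
  # distributions (the subgraph minimum contract)
  empty <- lapply(graphs, function(g) event_graph(g$nodes, NULL, g$scheme))
  names(empty) <- names(graphs)
  pb <- predict_relations(docs, bundle, "bimodal", graph = empty,
                          consolidation = cons)
  expect_true(all(abs(rowSums(pb$probs) - 1) < 1e-6))
  # inference is exactly reproducible
  pb2 <- predict_relations(docs, bundle, "bimodal", graph = empty,
                           consolidation = cons)
  expect_identical(pb$probs, pb2$probs)
})
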