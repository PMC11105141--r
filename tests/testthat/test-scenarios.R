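# one small corpus and one cheap (minimally trained) bundle shared by the
# scenario plumbing tests
scenario_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    corp <- generate_corpus(generator_config(n_docs = 30L, seed = 23L))
    sp <- split_training_data(corp$documents[1:24], seed = 3L)
    cfg <- train_config(seed = 4L, text_epochs = 4L, graph_epochs = 4L,
                        fusion_epochs = 60L, joint_epochs = 2L, patience = 2L)
    bundle <- train_model(sp$train1, sp$train2, sp$val, cfg)
    cache <<- list(test_docs = corp$documents[25:30], bundle = bundle)
    cache
  }
})

test_that("scenario reports are deterministic and carry all three modes", {
  fx <- scenario_fixture()
  r1a <- run_scenario1(fx$test_docs, fx$bundle)
  r1b <- run_scenario1(fx$test_docs, fx$bundle)
  expect_identical(r1a$table, r1b$table)
  expect_setequal(r1a$table$mode, c("text", "graph", "bimodal"))
  expect_true(all(r1a$table$accuracy >= 0 & r1a$table$accuracy <= 1))
  expect_error(run_scenario1(lapply(fx$test_docs, function(d) {
    d$relations <- d$relations[0, , drop = FALSE]; d
  }), fx$bundle), "gold relations")
})

test_that("scenario-1 subgraphs leak nothing from the target pair's label", {
  fx <- scenario_fixture()
  docs <- fx$test_docs
  scheme <- fx$bundle$scheme
  cons <- consolidate_events(docs)
  node_of <- stats::setNames(cons$node_map$node_id,
                             paste(cons$node_map$doc_id,
                                   cons$node_map$event_id, sep = "\01"))
  build_masked <- function(docs) {
    graphs <- temporalkg:::document_graphs(docs, cons, scheme, "strict",
                                           source = "gold")
    inst <- build_instances(docs)
    lapply(seq_len(nrow(inst)), function(i) {
      g <- graphs[[inst$doc_id[i]]]
      n1 <- node_of[[paste(inst$doc_id[i], inst$e1[i], sep = "\01")]]
      n2 <- node_of[[paste(inst$doc_id[i], inst$e2[i], sep = "\01")]]
      sg <- extract_subgraph(mask_target_edges(g, n1, n2), c(n1, n2), 3L)
      sg$edges[, c("src", "dst", "label", "provenance")]
    })
  }
  ref <- build_masked(docs)
  # flip every target-pair gold label (a cyclic permutation of the scheme)
  flipped <- lapply(docs, function(d) {
    labs <- d$relations$label
    d$relations$label <- scheme$labels[(match(labs, scheme$labels) %% 3L) + 1L]
    d
  })
  # relations are both the targets and the graph source; masking is at the
  # node-pair level, so each instance's own subgraph must be invariant to
  # ITS pair's label. Flipping all labels changes other pairs' edges, so
  # compare per instance against a corpus where only that instance's
  # relation is flipped.
  inst <- build_instances(docs)
  for (i in seq_len(nrow(inst))) {
    one <- lapply(docs, function(d) {
      if (d$doc_id != inst$doc_id[i]) return(d)
      hit <- d$relations$source == inst$e1[i] &
        d$relations$target == inst$e2[i]
      labs <- d$relations$label
      labs[hit] <- flipped[[match(d$doc_id, vapply(docs, `[[`, "",
                                                   "doc_id"))]]$relations$label[hit]
      d$relations$label <- labs
      d
    })
    got <- build_masked(one)[[i]]
    expect_identical(got, ref[[i]])
  }
})

test_that("scenario 2 reports bootstrap accuracy; thresholds behave", {
  fx <- scenario_fixture()
  r2 <- run_scenario2(fx$test_docs, fx$bundle)
  expect_true(is.finite(r2$bootstrap_accuracy))
  expect_gt(r2$bootstrap_edges, 0L)
  # threshold NULL vs 0 give identical reports
  r2z <- run_scenario2(fx$test_docs, fx$bundle,
                       scenario_config(2L, threshold = 0))
  expect_identical(r2$table, r2z$table)
  expect_identical(r2$kept_edges, r2z$kept_edges)
  # validation happens before any computation
  expect_error(sweep_threshold(fx$test_docs, fx$bundle,
                               thresholds = c(0, 0.5, 1.01)), "1.01")
  tab <- sweep_threshold(fx$test_docs, fx$bundle,
                         thresholds = c(0, 0.4, 0.8))
  expect_true(all(diff(tab$kept_edges) <= 0L))
  expect_equal(tab$accuracy[1],
               r2$table$accuracy[r2$table$mode == "bimodal"])
})

test_that("scenario-3 graphs are subsets of scenario-2 graphs", {
  fx <- scenario_fixture()
  cfg <- scenario_config(2L)
  gs <- temporalkg:::scenario2_graphs(fx$test_docs, fx$bundle, cfg,
                                      passthrough_linker())
  filtered <- Map(oracle_filter_graph, gs$boot, gs$gold)
  for (doc_id in names(gs$boot))
    expect_true(all(filtered[[doc_id]]$edges$id %in%
                      gs$boot[[doc_id]]$edges$id))
  r3 <- run_scenario3(fx$test_docs, fx$bundle)
  expect_true(isTRUE(r3$diagnostic_only))
  expect_lte(r3$kept_edges, run_scenario2(fx$test_docs, fx$bundle)$kept_edges)
})

test_that("with empty graphs the bimodal path degrades gracefully to text", {
  # two-event documents: after masking the only pair, every graph is
  # empty, so the graph branch carries nothing and fusion must lean on
  # its text coordinates
  corp <- generate_corpus(generator_config(n_docs = 90L,
                                           events_per_doc = c(2L, 2L),
                                           long_range_pairs_per_doc = 0L,
                                           cue_probability = 1,
                                           seed = 29L))
  sp <- split_training_data(corp$documents[1:50], seed = 1L)
  cfg <- train_config(seed = 2L, text_epochs = 8L, graph_epochs = 3L,
                      joint_epochs = 2L, patience = 3L)
  bundle <- train_model(sp$train1, sp$train2, sp$val, cfg)
  test_docs <- corp$documents[51:90]
  r1 <- run_scenario1(test_docs, bundle)
  acc <- stats::setNames(r1$table$accuracy, r1$table$mode)
  expect_lt(abs(acc[["bimodal"]] - acc[["text"]]), 0.1 + 1e-9)
})

test_that("reports serialize to metrics JSON and predictions TSV", {
  fx <- scenario_fixture()
  r2 <- run_scenario2(fx$test_docs, fx$bundle)
  dir <- withr::local_tempdir()
  write_report(r2, dir)
  m <- jsonlite::read_json(file.path(dir, "metrics.json"),
                           simplifyVector = TRUE)
  expect_equal(m$scenario, 2L)
  expect_equal(m$metrics$bimodal$accuracy,
               r2$table$accuracy[r2$table$mode == "bimodal"])
  preds <- utils::read.delim(file.path(dir, "predictions.tsv"))
  expect_equal(nrow(preds), nrow(build_instances(fx$test_docs)))
  expect_true(all(c("doc_id", "e1", "e2", "gold", "predicted") %in%
                    names(preds)))
})
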