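#' Scenario configuration
#'
#' Scenario 1 evaluates with a gold event graph built from the evaluation
#' corpus's own annotated relations (excluding, per instance, everything
#' between the two target nodes); scenario 2 with a graph bootstrapped
#' from the text branch's own predictions; scenario 3 with the bootstrap
#' graph oracle-filtered against gold labels (diagnostic only — it
#' requires knowing the correct relations, so it does not simulate a
#' practical application).
#'
#' @param scenario 1, 2 or 3.
#' @param graph_scope `"document"` (per-report graphs, the default: the
#'   scenario-1 premise is that some relations of the report under
#'   analysis are already known) or `"dataset"` (one graph pooled over
#'   all evaluation documents; concept-level information only, since
#'   same-concept mentions from different reports consolidate into the
#'   same nodes).
#' @param max_hops subgraph hop budget.
#' @param composition composition-table preset.
#' @param threshold optional confidence threshold for predicted edges
#'   (kept when confidence >= threshold); `NULL` disables filtering.
#' @param masking `"target-pair"` or `"none"`; `NULL` inherits the
#'   bundle's training-time setting.
#' @param seed evaluation seed (recorded in reports; evaluation itself is
#'   deterministic).
#' @return Object of class `tkg_scenario_config`.
#' @export
scenario_config <- function(scenario, graph_scope = NULL, max_hops = 3L,
                            composition = "strict", threshold = NULL,
                            masking = NULL, seed = 1L) {
  stopifnot(scenario %in% 1:3)
  graph_scope <- graph_scope %||% "document"
  stopifnot(graph_scope %in% c("dataset", "document"))
  if (!is.null(threshold) && (threshold < 0 || threshold > 1))
    stop_tkg("threshold %.3f outside [0, 1]", threshold)
  structure(list(scenario = scenario, graph_scope = graph_scope,
                 max_hops = max_hops, composition = composition,
                 threshold = threshold, masking = masking, seed = seed),
            class = "tkg_scenario_config")
}

apply_scenario_cfg <- function(bundle, cfg) {
  if (!is.null(cfg$masking)) bundle$config$masking <- cfg$masking
  bundle$config$max_hops <- cfg$max_hops
  bundle
}

evaluate_modes <- function(test_docs, bundle, graphs, consolidation) {
  inst <- build_instances(test_docs)
  golds <- inst$gold
  # subgraph preparation is mode-independent; do it once
  node_of <- stats::setNames(consolidation$node_map$node_id,
                             paste(consolidation$node_map$doc_id,
                                   consolidation$node_map$event_id,
                                   sep = "\01"))
  prepared <- lapply(seq_len(nrow(inst)), function(i) {
    g <- if (inherits(graphs, "tkg_graph")) graphs
    else graphs[[inst$doc_id[i]]]
    n1 <- node_of[[paste(inst$doc_id[i], inst$e1[i], sep = "\01")]]
    n2 <- node_of[[paste(inst$doc_id[i], inst$e2[i], sep = "\01")]]
    g <- ensure_nodes(g, consolidation, c(n1, n2))
    prepare_graph_instance(g, n1, n2, bundle$vectors,
                           bundle$config$masking, bundle$config$max_hops)
  })
  out <- list()
  preds <- list()
  for (mode in c("text", "graph", "bimodal")) {
    pr <- predict_relations(test_docs, bundle, mode, graph = graphs,
                            consolidation = consolidation,
                            prepared = prepared)
    out[[mode]] <- compute_metrics(pr$instances$predicted, golds,
                                   bundle$scheme)
    preds[[mode]] <- pr
  }
  list(metrics = out, predictions = preds)
}

scenario_report <- function(scenario, cfg, ev, extra = list()) {
  bi <- ev$predictions$bimodal
  tab <- data.frame(
    mode = c("text", "graph", "bimodal"),
    accuracy = vapply(ev$metrics, `[[`, 0, "accuracy"),
    micro_f1 = vapply(ev$metrics, `[[`, 0, "micro_f1"),
    row.names = NULL)
  structure(c(list(scenario = scenario, config = cfg, table = tab,
                   metrics = ev$metrics,
                   predictions = cbind(
                     bi$instances,
                     as.data.frame(bi$probs, optional = TRUE))),
              extra),
            class = "tkg_report")
}

#' @export
print.tkg_report <- function(x, ...) {
  cat(sprintf("Scenario %d (%s graph)\n", x$scenario,
              x$config$graph_scope))
  print(transform(x$table, accuracy = round(accuracy, 4),
                  micro_f1 = round(micro_f1, 4)), row.names = FALSE)
  if (!is.null(x$bootstrap_accuracy))
    cat(sprintf("bootstrap expanded-set accuracy: %.4f (%d edges)\n",
                x$bootstrap_accuracy, x$bootstrap_edges))
  invisible(x)
}

#' Scenario 1: gold knowledge graph
#'
#' Builds the gold event graph at the configured scope from the
#' evaluation documents' annotated relations, enriches it with inverse
#' and transitive edges, and evaluates text-only, graph-only and bimodal
#' prediction side by side. Per instance, every edge between the two
#' target nodes (with its derived shadow) is masked before the 3-hop
#' subgraph is extracted, so the target relation itself never leaks into
#' the graph branch.
#'
#' @param test_docs evaluation documents (must carry gold relations).
#' @param bundle trained `tkg_bundle`.
#' @param cfg a [scenario_config()].
#' @param linker entity linker (pass-through by default).
#' @return A `tkg_report`.
#' @export
run_scenario1 <- function(test_docs, bundle, cfg = scenario_config(1L),
                          linker = passthrough_linker()) {
  if (!sum(vapply(test_docs, function(d) nrow(d$relations), 0L)))
    stop_tkg("scenario 1 requires gold relations on the evaluation corpus")
  bundle <- apply_scenario_cfg(bundle, cfg)
  cons <- consolidate_events(test_docs, linker)
  graphs <- if (cfg$graph_scope == "dataset") {
    enrich_graph(build_event_graph(test_docs, cons, bundle$scheme),
                 composition_table(cfg$composition, bundle$scheme$labels))
  } else {
    document_graphs(test_docs, cons, bundle$scheme, cfg$composition,
                    source = "gold")
  }
  ev <- evaluate_modes(test_docs, bundle, graphs, cons)
  scenario_report(1L, cfg, ev)
}

# per-document bootstrap graphs plus the gold graphs needed by scenarios
# 2 and 3
scenario2_graphs <- function(test_docs, bundle, cfg, linker) {
  cons <- consolidate_events(test_docs, linker)
  boot <- document_graphs(test_docs, cons, bundle$scheme, cfg$composition,
                          source = "bootstrap", bundle = bundle,
                          threshold = cfg$threshold)
  gold <- document_graphs(test_docs, cons, bundle$scheme, cfg$composition,
                          source = "gold")
  list(cons = cons, boot = boot, gold = gold)
}

# accuracy of the enriched bootstrap graph's argmax labels against the
# enriched gold graph, over pairs present in both
bootstrap_graph_accuracy <- function(boot, gold) {
  correct <- 0L; total <- 0L
  for (doc_id in names(boot)) {
    pe <- boot[[doc_id]]$edges
    ge <- gold[[doc_id]]$edges
    if (!nrow(pe) || !nrow(ge)) next
    gold_lab <- stats::setNames(ge$label, paste(ge$src, ge$dst, sep = "\01"))
    key <- paste(pe$src, pe$dst, sep = "\01")
    hit <- key %in% names(gold_lab)
    total <- total + sum(hit)
    correct <- correct + sum(pe$label[hit] == gold_lab[key[hit]])
  }
  list(accuracy = if (total) correct / total else NA_real_, n = total)
}

#' Scenario 2: automatically inferred (bootstrap) knowledge graph
#'
#' The text branch first predicts every annotated pair of each document;
#' the predicted probability vectors become soft edges of a per-document
#' event graph, which is enriched (inverse edges by probability-vector
#' permutation; transitive edges composed from argmax labels with
#' confidence equal to the product of the parents'), optionally filtered
#' by confidence, and then used for bimodal re-prediction. The report
#' additionally carries the bootstrap graph's own expanded-set accuracy
#' against the enriched gold graph.
#'
#' @inheritParams run_scenario1
#' @param graphs optional precomputed result of the internal
#'   bootstrap/gold graph construction, for reuse across scenarios 2-3.
#' @return A `tkg_report` with `bootstrap_accuracy` and `kept_edges`.
#' @export
run_scenario2 <- function(test_docs, bundle, cfg = scenario_config(2L),
                          linker = passthrough_linker(), graphs = NULL) {
  bundle <- apply_scenario_cfg(bundle, cfg)
  gs <- graphs %||% scenario2_graphs(test_docs, bundle, cfg, linker)
  ev <- evaluate_modes(test_docs, bundle, gs$boot, gs$cons)
  ba <- bootstrap_graph_accuracy(gs$boot, gs$gold)
  scenario_report(2L, cfg, ev,
                  extra = list(bootstrap_accuracy = ba$accuracy,
                               bootstrap_edges = ba$n,
                               kept_edges = sum(vapply(gs$boot, function(g)
                                 nrow(g$edges), 0L))))
}

#' Scenario 3: oracle-filtered bootstrap graph (ablation)
#'
#' Builds the scenario-2 bootstrap graphs, removes every incorrectly
#' predicted base edge using the gold labels (derived edges follow their
#' parents), and re-evaluates. Diagnostic only: it quantifies how much of
#' the scenario-2 gap comes from incorrect edges rather than missing
#' ones, and does not simulate a practical application.
#'
#' @inheritParams run_scenario1
#' @param graphs optional precomputed graph construction shared with
#'   [run_scenario2()].
#' @return A `tkg_report`.
#' @export
run_scenario3 <- function(test_docs, bundle, cfg = scenario_config(3L),
                          linker = passthrough_linker(), graphs = NULL) {
  if (!sum(vapply(test_docs, function(d) nrow(d$relations), 0L)))
    stop_tkg("scenario 3 requires gold relations for the oracle filter")
  bundle <- apply_scenario_cfg(bundle, cfg)
  gs <- graphs %||% scenario2_graphs(test_docs, bundle, cfg, linker)
  filtered <- Map(oracle_filter_graph, gs$boot, gs$gold)
  ev <- evaluate_modes(test_docs, bundle, filtered, gs$cons)
  scenario_report(3L, cfg, ev,
                  extra = list(kept_edges = sum(vapply(filtered, function(g)
                    nrow(g$edges), 0L)),
                    diagnostic_only = TRUE))
}

#' Confidence-threshold sweep over scenario-2 graphs
#'
#' Re-runs the scenario-2 evaluation for each threshold (edges kept when
#' confidence >= threshold; derived edges follow their parents).
#' Kept-edge counts are non-increasing across sorted thresholds by set
#' inclusion; a zero threshold reproduces the unfiltered run.
#'
#' @param test_docs evaluation documents.
#' @param bundle trained `tkg_bundle`.
#' @param cfg a [scenario_config()] (scenario 2).
#' @param thresholds numeric vector in `[0, 1]`; validated before any
#'   computation.
#' @param linker entity linker.
#' @return data.frame: `threshold`, `kept_edges`, `accuracy`, `micro_f1`,
#'   `bootstrap_accuracy`.
#' @export
sweep_threshold <- function(test_docs, bundle, cfg = scenario_config(2L),
                            thresholds = c(0, 0.25, 0.5, 0.75, 0.9),
                            linker = passthrough_linker()) {
  bad <- thresholds[thresholds < 0 | thresholds > 1]
  if (length(bad))
    stop_tkg("threshold %.3f outside [0, 1]", bad[[1L]])
  rows <- lapply(thresholds, function(th) {
    cfg$threshold <- th
    rep2 <- run_scenario2(test_docs, bundle, cfg, linker)
    data.frame(threshold = th, kept_edges = rep2$kept_edges,
               accuracy = rep2$table$accuracy[rep2$table$mode == "bimodal"],
               micro_f1 = rep2$table$micro_f1[rep2$table$mode == "bimodal"],
               bootstrap_accuracy = rep2$bootstrap_accuracy)
  })
  do.call(rbind, rows)
}

#' Write a scenario report (metrics JSON + per-instance predictions TSV)
#'
#' @param report a `tkg_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- lapply(report$metrics, function(m)
    m[c("accuracy", "micro_precision", "micro_recall", "micro_f1", "n")])
  obj <- list(scenario = report$scenario,
              config = unclass(report$config), metrics = metrics)
  for (f in c("bootstrap_accuracy", "bootstrap_edges", "kept_edges"))
    if (!is.null(report[[f]])) obj[[f]] <- report[[f]]
  jsonlite::write_json(obj, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(report$predictions, file.path(dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
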