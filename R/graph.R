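#' @import data.table
NULL

edge_id <- function(src, dst, label) paste(src, dst, label, sep = "|")

empty_edges <- function() {
  e <- data.frame(id = character(), src = character(), dst = character(),
                  label = character(), confidence = numeric(),
                  provenance = character(), stringsAsFactors = FALSE)
  e$deriv <- list()
  e$prob <- list()
  e
}

canonical_edge_order <- function(edges) {
  order(edges$src, edges$dst, edges$label, edges$provenance)
}

#' Construct an event graph
#'
#' Nodes are consolidated event concepts; edges are directed temporal
#' relations carrying a hard label, a probability vector over the scheme
#' labels (one-hot for hard labels), a confidence scalar (the vector
#' maximum; gold edges carry 1), a provenance marker (gold / inverse /
#' transitive / predicted) and derivation references to parent edges.
#' At most one edge may exist per (src, dst, label); edges are kept in a
#' canonical order so all graph operations are input-order independent.
#'
#' @param nodes data.frame with `node_id`, `concept_id`, `canonical_name`,
#'   `mention_count`.
#' @param edges edge data.frame (see above); may be `NULL` for an empty
#'   graph.
#' @param scheme a [label_scheme()].
#' @param meta free-form metadata list.
#' @return Object of class `tkg_graph`.
#' @export
event_graph <- function(nodes, edges = NULL, scheme = label_scheme(),
                        meta = list()) {
  if (is.null(edges)) edges <- empty_edges()
  k <- length(scheme$labels)
  if (nrow(edges)) {
    bad <- !(edges$src %in% nodes$node_id) | !(edges$dst %in% nodes$node_id)
    if (any(bad)) stop_tkg("edge endpoints missing from node table")
    for (i in seq_len(nrow(edges))) {
      p <- edges$prob[[i]]
      if (length(p) != k || abs(sum(p) - 1) > 1e-6)
        stop_tkg("edge %d: probability vector must have length %d and sum 1",
                 i, k)
    }
    if (anyDuplicated(edge_id(edges$src, edges$dst, edges$label)))
      stop_tkg("duplicate (src, dst, label) edge")
    edges <- edges[canonical_edge_order(edges), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, scheme = scheme, meta = meta),
            class = "tkg_graph")
}

#' @export
print.tkg_graph <- function(x, ...) {
  cat(sprintf("<tkg_graph> %d nodes, %d edges (%s)\n", nrow(x$nodes),
              nrow(x$edges),
              paste(sprintf("%s=%d", names(table(x$edges$provenance)),
                            as.integer(table(x$edges$provenance))),
                    collapse = ", ")))
  invisible(x)
}

make_edges <- function(src, dst, label, confidence, provenance, deriv, prob) {
  e <- data.frame(id = edge_id(src, dst, label), src = src, dst = dst,
                  label = label, confidence = confidence,
                  provenance = provenance, stringsAsFactors = FALSE)
  e$deriv <- deriv
  e$prob <- prob
  e
}

#' Build the gold event graph from annotated documents
#'
#' Adds one edge per annotated relation, mapped through the event-to-node
#' map from [consolidate_events()]; parallel relations collapsing to the
#' same (node, node, label) deduplicate. Self-loops arising when both
#' events of a relation consolidate to the same node are skipped.
#'
#' @param docs list of documents.
#' @param consolidation result of [consolidate_events()] (or a list with
#'   `nodes` and `node_map`).
#' @param scheme a [label_scheme()].
#' @return A `tkg_graph` with gold-provenance edges.
#' @export
build_event_graph <- function(docs, consolidation, scheme = label_scheme()) {
  nm <- consolidation$node_map
  key <- paste(nm$doc_id, nm$event_id, sep = "\01")
  lookup <- stats::setNames(nm$node_id, key)
  rows <- lapply(docs, function(d) {
    rel <- d$relations
    if (!nrow(rel)) return(NULL)
    s <- lookup[paste(d$doc_id, rel$source, sep = "\01")]
    t <- lookup[paste(d$doc_id, rel$target, sep = "\01")]
    if (anyNA(s) || anyNA(t))
      stop_tkg("doc '%s': event without node mapping", d$doc_id)
    keep <- s != t
    data.frame(src = unname(s[keep]), dst = unname(t[keep]),
               label = rel$label[keep], stringsAsFactors = FALSE)
  })
  rel <- do.call(rbind, rows)
  if (is.null(rel) || nrow(rel) == 0L)
    return(event_graph(consolidation$nodes, NULL, scheme))
  rel <- rel[!duplicated(edge_id(rel$src, rel$dst, rel$label)), , drop = FALSE]
  k <- length(scheme$labels)
  edges <- make_edges(rel$src, rel$dst, rel$label, 1.0, "gold",
                      replicate(nrow(rel), character(0), simplify = FALSE),
                      lapply(rel$label,
                             function(l) one_hot(label_index(scheme, l), k)))
  event_graph(consolidation$nodes, edges, scheme)
}

#' Add inverse edges
#'
#' For every edge (u, v, l) ensures an edge (v, u, inverse(l)) exists,
#' adding it with provenance `inverse`, a derivation reference to the
#' source edge, and the probability vector permuted by the inverse map.
#' Pre-existing reverse edges with a different label are left untouched
#' (their count is recorded in `meta$inverse_contradictions`). Idempotent.
#'
#' @param g a `tkg_graph`.
#' @return The enriched graph.
#' @export
add_inverse_edges <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(g)
  scheme <- g$scheme
  inv_lab <- vapply(e$label, function(l) scheme_inverse(scheme, l), "")
  want <- edge_id(e$dst, e$src, inv_lab)
  have <- e$id
  add <- which(!(want %in% have) & !duplicated(want))
  contradictions <- sum(vapply(seq_len(nrow(e)), function(i) {
    any(e$src == e$dst[i] & e$dst == e$src[i] & e$label != inv_lab[i])
  }, TRUE))
  g$meta$inverse_contradictions <- contradictions
  if (length(add)) {
    perm <- inverse_permutation(scheme)
    new <- make_edges(e$dst[add], e$src[add], inv_lab[add],
                      e$confidence[add], "inverse",
                      lapply(add, function(i) e$id[[i]]),
                      lapply(add, function(i) e$prob[[i]][perm]))
    g$edges <- rbind(e, new)
    g$edges <- g$edges[canonical_edge_order(g$edges), , drop = FALSE]
    rownames(g$edges) <- NULL
  }
  g
}

# One deterministic enrichment round restricted (optionally) to candidate
# (src,dst) pairs. Returns a data.frame of edges to add (possibly empty).
transitive_candidates <- function(edges, table, scheme,
                                  allowed_pairs = NULL) {
  if (nrow(edges) < 2L) return(NULL)
  dt1 <- data.table::data.table(id1 = edges$id, u = edges$src,
                                mid = edges$dst, l1 = edges$label,
                                c1 = edges$confidence)
  dt2 <- data.table::data.table(id2 = edges$id, mid = edges$src,
                                w = edges$dst, l2 = edges$label,
                                c2 = edges$confidence)
  joined <- merge(dt1, dt2, by = "mid", allow.cartesian = TRUE)
  joined <- joined[joined$u != joined$w, ]
  if (!nrow(joined)) return(NULL)
  comp <- table[cbind(joined$l1, joined$l2)]
  joined <- joined[!is.na(comp), ]
  comp <- comp[!is.na(comp)]
  if (!nrow(joined)) return(NULL)
  pair <- paste(joined$u, joined$w, sep = "\01")
  if (!is.null(allowed_pairs)) {
    keep <- pair %in% allowed_pairs
    joined <- joined[keep, ]; comp <- comp[keep]; pair <- pair[keep]
    if (!nrow(joined)) return(NULL)
  }
  linked <- unique(paste(edges$src, edges$dst, sep = "\01"))
  keep <- !(pair %in% linked)
  joined <- joined[keep, ]; comp <- comp[keep]; pair <- pair[keep]
  if (!nrow(joined)) return(NULL)
  # canonical choice per unlinked pair: smallest label index, then the
  # lexicographically smallest parent-edge id pair
  ord <- order(pair, match(comp, scheme$labels), joined$id1, joined$id2)
  joined <- joined[ord, ]; comp <- comp[ord]; pair <- pair[ord]
  first <- !duplicated(pair)
  data.frame(src = joined$u[first], dst = joined$w[first],
             label = comp[first],
             confidence = joined$c1[first] * joined$c2[first],
             parent1 = joined$id1[first], parent2 = joined$id2[first],
             stringsAsFactors = FALSE)
}

#' Add transitive edges (fixpoint closure)
#'
#' Repeatedly composes edge chains (u, v, l1), (v, w, l2) through the
#' composition table and adds (u, w, compose(l1, l2)) where the
#' composition is unambiguous, the pair (u, w) has no existing edge, and
#' u != w. Added edges carry provenance `transitive`, derivation
#' references to their two parents, a one-hot probability vector, and
#' confidence equal to the product of the parents' confidences. Rounds are
#' deterministic: when several chains would label the same pair in the
#' same round, the smallest label index wins, with parent-id tie-breaks.
#' Never deletes or relabels an existing edge; idempotent at the fixpoint.
#'
#' @param g a `tkg_graph` (inverse enrichment is normally applied first so
#'   chains through reversed edges are found).
#' @param table composition matrix; defaults to the scheme's.
#' @param max_iterations safety cap on rounds; exceeding it signals a
#'   composition-table bug.
#' @return The enriched graph; `meta$composition_preset` records the table.
#' @export
add_transitive_edges <- function(g, table = NULL, max_iterations = 100L) {
  table <- table %||% g$scheme$composition
  k <- length(g$scheme$labels)
  for (it in seq_len(max_iterations)) {
    cand <- transitive_candidates(g$edges, table, g$scheme)
    if (is.null(cand) || nrow(cand) == 0L) {
      g$meta$transitive_applied <- TRUE
      return(g)
    }
    new <- make_edges(cand$src, cand$dst, cand$label, cand$confidence,
                      "transitive",
                      lapply(seq_len(nrow(cand)), function(i)
                        c(cand$parent1[i], cand$parent2[i])),
                      lapply(cand$label, function(l)
                        one_hot(label_index(g$scheme, l), k)))
    g$edges <- rbind(g$edges, new)
    g$edges <- g$edges[canonical_edge_order(g$edges), , drop = FALSE]
    rownames(g$edges) <- NULL
  }
  stop_tkg("transitive closure did not converge in %d rounds", max_iterations)
}

#' Full enrichment: inverse edges, then transitive closure
#'
#' @param g a `tkg_graph`.
#' @param table optional composition matrix.
#' @return The enriched graph.
#' @export
enrich_graph <- function(g, table = NULL) {
  add_transitive_edges(add_inverse_edges(g), table)
}

# ids of edges whose derivation chain includes any edge in `ids`
edge_descendants <- function(edges, ids) {
  removed <- ids
  repeat {
    hit <- vapply(seq_len(nrow(edges)), function(i) {
      dv <- edges$deriv[[i]]
      length(dv) > 0L && any(dv %in% removed) && !(edges$id[i] %in% removed)
    }, TRUE)
    if (!any(hit)) return(removed)
    removed <- c(removed, edges$id[hit])
  }
}

# drop derived edges whose parents are no longer present, transitively
cascade_orphans <- function(edges) {
  repeat {
    present <- edges$id
    ok <- vapply(seq_len(nrow(edges)), function(i) {
      dv <- edges$deriv[[i]]
      length(dv) == 0L || all(dv %in% present)
    }, TRUE)
    if (all(ok)) return(edges)
    edges <- edges[ok, , drop = FALSE]
  }
}

#' Extract the k-hop subgraph around a target pair
#'
#' Induced subgraph on nodes whose undirected hop distance to either
#' target is at most `max_hops`. Hop distance is undirected because
#' inverse enrichment makes edge direction redundant for reachability.
#' Both targets are always present, even if isolated.
#'
#' @param g a `tkg_graph`.
#' @param targets character vector of one or two node ids.
#' @param max_hops hop budget (default 3, matching the 3-layer receptive
#'   field of the graph encoder).
#' @return A `tkg_graph`.
#' @export
extract_subgraph <- function(g, targets, max_hops = 3L) {
  missing <- setdiff(targets, g$nodes$node_id)
  if (length(missing))
    stop_tkg("target node '%s' not in graph", missing[[1L]])
  keep_nodes <- targets
  if (nrow(g$edges)) {
    ig <- igraph::graph_from_data_frame(
      g$edges[, c("src", "dst")], directed = FALSE,
      vertices = g$nodes$node_id)
    dmat <- igraph::distances(ig, v = targets, mode = "all")
    dmin <- apply(dmat, 2L, min)
    keep_nodes <- union(targets, colnames(dmat)[dmin <= max_hops])
  }
  nodes <- g$nodes[g$nodes$node_id %in% keep_nodes, , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- g$edges[g$edges$src %in% keep_nodes &
                     g$edges$dst %in% keep_nodes, , drop = FALSE]
  rownames(edges) <- NULL
  event_graph(nodes, edges, g$scheme, g$meta)
}

#' Mask the target pair's own relations out of a graph
#'
#' Removes every base (gold or predicted) edge between the two target
#' nodes, both directions, together with every derived edge whose
#' derivation chain includes a removed edge — the target relation's
#' inverse and transitive shadow. It then re-derives, from the surviving
#' edges only, transitive edges at the vacated pairs (including the
#' target pair itself): a relation between the targets that is implied
#' purely by the document's *other* relations is legitimate context, not
#' leakage — it is invariant to the target pair's gold label, which is
#' what the enrichment pipeline exists to provide. The result equals the
#' enrichment of the graph with the target-pair base edges absent.
#'
#' @param g an enriched `tkg_graph`.
#' @param e1_node,e2_node target node ids.
#' @return The masked graph.
#' @export
mask_target_edges <- function(g, e1_node, e2_node) {
  e <- g$edges
  if (!nrow(e)) return(g)
  direct <- (e$src == e1_node & e$dst == e2_node) |
    (e$src == e2_node & e$dst == e1_node)
  if (!any(direct)) return(g)
  removed_ids <- edge_descendants(e, e$id[direct])
  removed <- e[e$id %in% removed_ids, , drop = FALSE]
  keep <- e[!(e$id %in% removed_ids), , drop = FALSE]
  # pairs vacated by the removal are the only candidates for re-derivation
  pairs <- unique(paste(removed$src, removed$dst, sep = "\01"))
  table <- g$scheme$composition
  k <- length(g$scheme$labels)
  repeat {
    cand <- transitive_candidates(keep, table, g$scheme,
                                  allowed_pairs = pairs)
    if (is.null(cand) || nrow(cand) == 0L) break
    new <- make_edges(cand$src, cand$dst, cand$label, cand$confidence,
                      "transitive",
                      lapply(seq_len(nrow(cand)), function(i)
                        c(cand$parent1[i], cand$parent2[i])),
                      lapply(cand$label, function(l)
                        one_hot(label_index(g$scheme, l), k)))
    keep <- rbind(keep, new)
    keep <- keep[canonical_edge_order(keep), , drop = FALSE]
  }
  rownames(keep) <- NULL
  g$edges <- keep
  g$meta$masked_pair <- c(e1_node, e2_node)
  g
}

#' Filter edges by softmax confidence
#'
#' Keeps exactly the edges whose confidence is greater than or equal to
#' the threshold; derived edges whose parents are dropped are dropped too.
#'
#' @param g a `tkg_graph`.
#' @param threshold probability in `[0, 1]`.
#' @return The filtered graph.
#' @export
filter_by_confidence <- function(g, threshold) {
  if (threshold < 0 || threshold > 1)
    stop_tkg("threshold %.3f outside [0, 1]", threshold)
  e <- g$edges[g$edges$confidence >= threshold, , drop = FALSE]
  g$edges <- cascade_orphans(e)
  rownames(g$edges) <- NULL
  g
}

#' Oracle-filter a predicted graph against gold labels
#'
#' Diagnostic filter: keeps a base predicted edge if and only if a gold
#' edge with the same (src, dst) exists and the predicted argmax label
#' equals the gold label; predicted edges with no gold counterpart are
#' removed; derived (inverse/transitive) edges follow their parents. This
#' requires knowledge of the correct relations and does not simulate a
#' practical application.
#'
#' @param predicted a `tkg_graph` with predicted-provenance base edges.
#' @param gold a `tkg_graph` over the same node universe.
#' @return The filtered graph.
#' @export
oracle_filter_graph <- function(predicted, gold) {
  e <- predicted$edges
  if (!nrow(e)) return(predicted)
  gold_ids <- edge_id(gold$edges$src, gold$edges$dst, gold$edges$label)
  base <- !(e$provenance %in% c("inverse", "transitive"))
  ok <- !base | (e$id %in% gold_ids)
  predicted$edges <- cascade_orphans(e[ok, , drop = FALSE])
  rownames(predicted$edges) <- NULL
  predicted
}

#' Export / import an event graph as TSV + JSON
#'
#' Writes `nodes.tsv`, `edges.tsv` (probability vector semicolon-joined,
#' derivation refs comma-joined) and `graph.json` (label scheme,
#' composition table, metadata). The round trip preserves the graph
#' exactly, probability vectors to better than 1e-9.
#'
#' @param g a `tkg_graph`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_graph <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(g$nodes, file.path(dir, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  e <- g$edges
  flat <- data.frame(
    src = e$src, dst = e$dst, label = e$label,
    confidence = sprintf("%.12e", e$confidence),
    provenance = e$provenance,
    deriv = vapply(e$deriv, paste, "", collapse = ","),
    prob = vapply(e$prob, function(p)
      paste(sprintf("%.12e", p), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(flat, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(labels = g$scheme$labels,
         inverse_map = as.list(g$scheme$inverse_map),
         composition = as.vector(g$scheme$composition),
         preset = g$scheme$preset,
         meta = g$meta),
    file.path(dir, "graph.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @rdname export_graph
#' @export
import_graph <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "graph.json"),
                            simplifyVector = TRUE)
  comp <- matrix(as.character(js$composition), length(js$labels),
                 length(js$labels), dimnames = list(js$labels, js$labels))
  scheme <- label_scheme(js$labels, unlist(js$inverse_map), comp)
  scheme$preset <- js$preset
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"),
                             stringsAsFactors = FALSE)
  flat <- utils::read.delim(file.path(dir, "edges.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  if (nrow(flat)) {
    edges <- make_edges(flat$src, flat$dst, flat$label,
                        as.numeric(flat$confidence), flat$provenance,
                        lapply(strsplit(flat$deriv, ",", fixed = TRUE),
                               function(x) x[nzchar(x)]),
                        lapply(strsplit(flat$prob, ";", fixed = TRUE),
                               as.numeric))
  } else edges <- NULL
  meta <- js$meta
  if (length(meta) == 0L) meta <- list()
  event_graph(nodes, edges, scheme, as.list(meta))
}
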