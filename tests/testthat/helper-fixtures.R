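# Shared fixtures, built in code.

basic_scheme <- label_scheme()

# A two-event, one-relation document with hand-placed offsets.
tiny_doc <- function(doc_id = "d1") {
  text <- "He visited the ER with painless jaundice today ."
  document(
    doc_id, text,
    events = data.frame(
      id = c("E1", "E2"),
      start = c(3L, 23L), end = c(10L, 40L),
      surface = c("visited", "painless jaundice"),
      stringsAsFactors = FALSE),
    relations = data.frame(source = "E1", target = "E2", label = "OVERLAP",
                           stringsAsFactors = FALSE),
    scheme = basic_scheme)
}

# A document with n single-token events laid out as "e1 e2 ... en", with
# a chain of relations carrying the given labels.
chain_doc <- function(labels, doc_id = "chain") {
  n <- length(labels) + 1L
  names <- sprintf("ev%02d", seq_len(n))
  text <- paste(names, collapse = " ")
  starts <- cumsum(c(0L, rep(5L, n - 1L)))
  document(
    doc_id, text,
    events = data.frame(id = sprintf("E%d", seq_len(n)), start = starts,
                        end = starts + 4L, surface = names,
                        concept_id = sprintf("C%d", seq_len(n)),
                        stringsAsFactors = FALSE),
    relations = data.frame(source = sprintf("E%d", seq_len(n - 1L)),
                           target = sprintf("E%d", seq_len(n - 1L) + 1L),
                           label = labels, stringsAsFactors = FALSE),
    scheme = basic_scheme)
}

# Random small event graph over n nodes: each ordered pair gets a gold
# edge with probability p_edge and a uniform label.
random_graph <- function(n_nodes, p_edge = 0.25, scheme = basic_scheme) {
  nodes <- data.frame(node_id = sprintf("N%02d", seq_len(n_nodes)),
                      concept_id = sprintf("C%02d", seq_len(n_nodes)),
                      canonical_name = sprintf("concept %02d", seq_len(n_nodes)),
                      mention_count = 1L, stringsAsFactors = FALSE)
  pairs <- expand.grid(src = nodes$node_id, dst = nodes$node_id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$src != pairs$dst, ]
  pairs <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  g <- event_graph(nodes, NULL, scheme)
  if (!nrow(pairs)) return(g)
  lab <- sample(scheme$labels, nrow(pairs), replace = TRUE)
  keep <- !duplicated(paste(pairs$src, pairs$dst))
  pairs <- pairs[keep, , drop = FALSE]; lab <- lab[keep]
  k <- length(scheme$labels)
  edges <- temporalkg:::make_edges(
    pairs$src, pairs$dst, lab, 1.0, "gold",
    replicate(nrow(pairs), character(0), simplify = FALSE),
    lapply(lab, function(l) temporalkg:::one_hot(match(l, scheme$labels), k)))
  event_graph(nodes, edges, scheme)
}

# Independent brute-force enrichment oracle: label-indexed boolean
# adjacency matrices, rounds of inverse completion then transitive
# composition with the same canonical tie-break (smallest label index),
# never touching the package's edge machinery.
oracle_enrich <- function(g, table) {
  labs <- g$scheme$labels
  n <- nrow(g$nodes)
  ids <- g$nodes$node_id
  A <- array(FALSE, dim = c(n, n, length(labs)),
             dimnames = list(ids, ids, labs))
  for (i in seq_len(nrow(g$edges)))
    A[g$edges$src[i], g$edges$dst[i], g$edges$label[i]] <- TRUE
  # inverse completion (single pass is enough: involution)
  for (l in labs) {
    il <- unname(g$scheme$inverse_map[[l]])
    A[, , il] <- A[, , il] | t(A[, , l])
  }
  # transitive rounds: all candidates from the current edge set; a pair
  # with any existing edge is blocked; smallest-label candidate wins
  repeat {
    linked <- apply(A, c(1, 2), any)
    add <- matrix(NA_character_, n, n)
    for (l1 in labs) for (l2 in labs) {
      comp <- table[l1, l2]
      if (is.na(comp)) next
      reach <- (A[, , l1] %*% A[, , l2]) > 0
      cand <- reach & !linked & !diag(TRUE, n)
      pick <- cand & (is.na(add) |
                        match(comp, labs) < match(add, labs))
      add[pick] <- comp
    }
    if (!any(!is.na(add))) break
    for (l in labs) {
      sel <- !is.na(add) & add == l
      A[, , l] <- A[, , l] | sel
    }
  }
  A
}

graph_to_label_array <- function(g) {
  labs <- g$scheme$labels
  ids <- g$nodes$node_id
  n <- length(ids)
  A <- array(FALSE, dim = c(n, n, length(labs)),
             dimnames = list(ids, ids, labs))
  for (i in seq_len(nrow(g$edges)))
    A[g$edges$src[i], g$edges$dst[i], g$edges$label[i]] <- TRUE
  A
}

# Plain breadth-first-search distance oracle (no igraph).
bfs_distances <- function(g, from) {
  ids <- g$nodes$node_id
  adj <- lapply(stats::setNames(ids, ids), function(x) character(0))
  for (i in seq_len(nrow(g$edges))) {
    s <- g$edges$src[i]; d <- g$edges$dst[i]
    adj[[s]] <- union(adj[[s]], d)
    adj[[d]] <- union(adj[[d]], s)
  }
  dist <- stats::setNames(rep(Inf, length(ids)), ids)
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (is.infinite(dist[[w]])) {
        dist[[w]] <- dist[[v]] + 1
        nxt <- c(nxt, w)
      }
    }
    frontier <- nxt
  }
  dist
}

# Small trained-free bundle for plumbing tests: untrained parameters with
# tiny dimensions, real vocabulary from the given docs.
tiny_bundle <- function(docs, seed = 1L) {
  cfg <- train_config(seed = seed, d_t = 8L, text_hidden = 8L, d_w = 8L,
                      d_g = 8L, text_epochs = 0L, graph_epochs = 0L,
                      oversample = FALSE,
                      stages = character(0))
  inst <- build_instances(docs)
  marked <- temporalkg:::mark_instances(inst, docs, cfg$window)
  vocab <- build_vocab(lapply(marked, `[[`, "tokens"))
  scheme <- label_scheme()
  structure(list(
    scheme = scheme, config = cfg,
    backbone = bundled_backbone(vocab, d = 8L, seed = seed),
    text_head = text_head(8L, 3L, hidden = 8L, seed = seed),
    graph_params = graph_encoder_params(8L, 8L, 3L, seed = seed),
    graph_head = graph_head(8L, 3L, seed = seed),
    fusion = fusion_params(8L, 8L, 3L, seed = seed),
    vectors = word_vector_table(8L),
    linker_kind = "passthrough", seed = seed, logs = list()),
    class = "tkg_bundle")
}

# independent hard-label convolution used as the oracle for soft/hard
# equivalence: per-edge, look up the edge's single label and apply that
# relation's matrix only
hard_conv_oracle <- function(h, g, W0, Wr, b) {
  n <- nrow(g$nodes)
  idx <- stats::setNames(seq_len(n), g$nodes$node_id)
  msg <- matrix(0, n, ncol(W0))
  indeg <- integer(n)
  for (i in seq_len(nrow(g$edges))) {
    s <- idx[[g$edges$src[i]]]; t <- idx[[g$edges$dst[i]]]
    r <- match(g$edges$label[i], g$scheme$labels)
    msg[t, ] <- msg[t, ] + h[s, ] %*% Wr[, , r]
    indeg[t] <- indeg[t] + 1L
  }
  z <- h %*% W0 + msg / pmax(indeg, 1L) +
    matrix(b, n, ncol(W0), byrow = TRUE)
  pmax(z, 0)
}

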