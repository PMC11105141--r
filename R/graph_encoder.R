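#' Word-vector table for node initialization
#'
#' Maps tokens to fixed vectors of dimension `d`. Out-of-vocabulary tokens
#' receive a deterministic pseudo-random vector seeded by a hash of the
#' token, so every name yields a finite, reproducible vector even with an
#' empty table. A table can be loaded from a standard whitespace-separated
#' text-embedding file with [read_word_vectors()]; the default empty table
#' (hash fallback only) serves tests and the synthetic experiments, so no
#' download is ever needed.
#'
#' @param d vector dimension.
#' @param vectors optional numeric matrix with token rownames.
#' @return Object of class `tkg_wordvec`.
#' @export
word_vector_table <- function(d = 64L, vectors = NULL) {
  if (!is.null(vectors)) {
    stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
    d <- ncol(vectors)
  }
  structure(list(d = d, vectors = vectors), class = "tkg_wordvec")
}

#' @rdname word_vector_table
#' @param path text file: one token per line followed by its coordinates,
#'   whitespace-separated.
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  toks <- vapply(parts, `[[`, "", 1L)
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  rownames(mat) <- toks
  word_vector_table(vectors = mat)
}

lookup_word_vector <- function(table, token) {
  if (!is.null(table$vectors) && token %in% rownames(table$vectors))
    return(table$vectors[token, ])
  hash_vector(token, table$d)
}

#' Initial embedding of a concept node
#'
#' Mean of the token vectors of the node's canonical name when available,
#' else of the fallback mention surface. All-OOV names still yield a
#' finite vector via the hash fallback.
#'
#' @param node one row of a graph's node table (needs `canonical_name`,
#'   optionally `fallback_surface`).
#' @param vectors a [word_vector_table()].
#' @return Numeric vector of length `vectors$d`.
#' @export
init_node_embedding <- function(node, vectors) {
  name <- node$canonical_name
  if (is.na(name) || !nzchar(name)) name <- node$fallback_surface
  toks <- tokenize_text(name)
  if (!length(toks)) toks <- "<empty>"
  rowsum_mat <- vapply(toks, function(t) lookup_word_vector(vectors, t),
                       numeric(vectors$d))
  rowMeans(matrix(rowsum_mat, nrow = vectors$d))
}

node_init_matrix <- function(g, vectors) {
  X <- t(vapply(seq_len(nrow(g$nodes)), function(i)
    init_node_embedding(g$nodes[i, ], vectors), numeric(vectors$d)))
  rownames(X) <- g$nodes$node_id
  X
}

#' Graph-encoder parameters
#'
#' Per-layer, per-relation transformation matrices (one per scheme label)
#' plus a self-transformation per layer, and an input projection from the
#' word-vector dimension to the hidden dimension. Three convolution layers
#' by default, matching the 3-hop subgraph rule. No basis decomposition is
#' used: with three relation types the parameter count is small.
#'
#' @param d_w word-vector (input) dimension.
#' @param d_g hidden dimension.
#' @param n_labels number of relation types.
#' @param n_layers number of convolution layers.
#' @param seed initialization seed.
#' @return Object of class `tkg_graph_params`.
#' @export
graph_encoder_params <- function(d_w = 64L, d_g = 64L, n_labels = 3L,
                                 n_layers = 3L, seed = 1L) {
  stopifnot(n_layers >= 1L)
  params <- with_local_seed(seed, {
    p <- list(P_in = matrix(rnorm(d_w * d_g, sd = 1 / sqrt(d_w)), d_w, d_g))
    for (l in seq_len(n_layers)) {
      p[[paste0("W0_", l)]] <- matrix(rnorm(d_g * d_g, sd = 1 / sqrt(d_g)),
                                      d_g, d_g)
      p[[paste0("Wr_", l)]] <- array(rnorm(d_g * d_g * n_labels,
                                           sd = 1 / sqrt(d_g)),
                                     dim = c(d_g, d_g, n_labels))
      p[[paste0("b_", l)]] <- numeric(d_g)
    }
    p
  })
  structure(list(params = params, d_w = d_w, d_g = d_g,
                 n_labels = n_labels, n_layers = n_layers, seed = seed),
            class = "tkg_graph_params")
}

# Per-relation aggregation operators: A[[r]][i, j] is the total
# probability mass for relation r on edges j -> i, row-scaled by
# 1/c_i with c_i = max(1, in-degree of i). Returned as dense base
# matrices: concept graphs are small (tens of nodes), where sparse-matrix
# dispatch costs far more than it saves.
conv_operators <- function(g) {
  n <- nrow(g$nodes)
  k <- length(g$scheme$labels)
  idx <- stats::setNames(seq_len(n), g$nodes$node_id)
  e <- g$edges
  if (nrow(e) == 0L)
    return(lapply(seq_len(k), function(r) matrix(0, n, n)))
  for (i in seq_len(nrow(e))) {
    p <- e$prob[[i]]
    if (length(p) != k)
      stop_tkg("edge probability vector has length %d, expected %d",
               length(p), k)
  }
  dst <- idx[e$dst]; src <- idx[e$src]
  indeg <- tabulate(dst, nbins = n)
  scale <- 1 / pmax(indeg, 1)
  P <- do.call(rbind, e$prob)
  lapply(seq_len(k), function(r)
    as.matrix(Matrix::sparseMatrix(i = dst, j = src,
                                   x = P[, r] * scale[dst],
                                   dims = c(n, n))))
}

#' One relational convolution layer
#'
#' Updates every node embedding as
#' `h'_i = act( W0 h_i + (1/c_i) * sum_e sum_r p_e(r) W_r h_j + b )`
#' over incoming edges `e = (j -> i)` with probability vector `p_e`
#' (one-hot for hard labels) and `c_i = max(1, in-degree)`. Messages flow
#' along edge direction only; reverse influence comes from the
#' inverse-enriched edges themselves.
#'
#' @param h node-embedding matrix (rows follow `g$nodes`).
#' @param g a `tkg_graph`.
#' @param W0 self-transformation matrix.
#' @param Wr array `d x d x n_labels` of per-relation matrices.
#' @param b bias vector.
#' @param activation `"relu"` or `"identity"`.
#' @return Updated embedding matrix.
#' @export
relational_conv_layer <- function(h, g, W0, Wr, b = numeric(ncol(W0)),
                                  activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  A <- conv_operators(g)
  Z <- h %*% W0
  for (r in seq_along(A)) Z <- Z + A[[r]] %*% (h %*% Wr[, , r])
  Z <- sweep(Z, 2L, b, "+")
  if (activation == "relu") relu(Z) else Z
}

# Full forward over precomputed structures; returns target embeddings and
# (optionally) the cache for backprop.
graph_forward <- function(gp, X, A, t_idx, cache = FALSE) {
  p <- gp$params
  H <- X %*% p$P_in
  Hs <- list(H)
  Zs <- list()
  for (l in seq_len(gp$n_layers)) {
    W0 <- p[[paste0("W0_", l)]]
    Wr <- p[[paste0("Wr_", l)]]
    Z <- H %*% W0
    for (r in seq_len(gp$n_labels))
      Z <- Z + A[[r]] %*% (H %*% Wr[, , r])
    Z <- sweep(Z, 2L, p[[paste0("b_", l)]], "+")
    H <- if (l < gp$n_layers) relu(Z) else Z
    Zs[[l]] <- Z
    Hs[[l + 1L]] <- H
  }
  out <- list(U = H[t_idx, , drop = FALSE])
  if (cache) {
    out$Hs <- Hs; out$Zs <- Zs; out$X <- X; out$A <- A; out$t_idx <- t_idx
  }
  out
}

graph_backward <- function(gp, cache, dU) {
  p <- gp$params
  n <- nrow(cache$Hs[[1L]])
  dH <- matrix(0, n, gp$d_g)
  dH[cache$t_idx, ] <- dU
  grads <- list()
  for (l in rev(seq_len(gp$n_layers))) {
    Z <- cache$Zs[[l]]
    dZ <- if (l < gp$n_layers) dH * (Z > 0) else dH
    Hin <- cache$Hs[[l]]
    W0 <- p[[paste0("W0_", l)]]
    Wr <- p[[paste0("Wr_", l)]]
    grads[[paste0("b_", l)]] <-
      add_grad(grads[[paste0("b_", l)]], colSums(dZ))
    grads[[paste0("W0_", l)]] <-
      add_grad(grads[[paste0("W0_", l)]], crossprod(Hin, dZ))
    dHin <- dZ %*% t(W0)
    dWr <- array(0, dim = dim(Wr))
    for (r in seq_len(gp$n_labels)) {
      AH <- cache$A[[r]] %*% Hin
      dWr[, , r] <- crossprod(AH, dZ)
      dHin <- dHin + crossprod(cache$A[[r]], dZ) %*% t(Wr[, , r])
    }
    grads[[paste0("Wr_", l)]] <- dWr
    dH <- dHin
  }
  grads$P_in <- crossprod(cache$X, dH)
  grads
}

add_grad <- function(acc, g) if (is.null(acc)) g else acc + g

#' Encode a target pair through the graph branch
#'
#' Projects word-vector node initializations into the hidden space, runs
#' the relational convolution layers (rectifier on hidden layers, identity
#' on the last), and reads out the two target-node embeddings. With L
#' layers, nodes farther than L hops from both targets cannot influence
#' the result, which is what justifies the subgraph hop budget.
#'
#' @param g a `tkg_graph` containing both targets.
#' @param targets character vector of two node ids.
#' @param gp [graph_encoder_params()].
#' @param vectors [word_vector_table()].
#' @return List `(u1, u2)` of embeddings.
#' @export
encode_graph_pair <- function(g, targets, gp, vectors = word_vector_table(gp$d_w)) {
  t_idx <- match(targets, g$nodes$node_id)
  if (anyNA(t_idx)) stop_tkg("target nodes missing from graph")
  X <- node_init_matrix(g, vectors)
  fw <- graph_forward(gp, X, conv_operators(g), t_idx)
  list(u1 = fw$U[1L, ], u2 = fw$U[2L, ])
}

#' Linear classification head over the two graph embeddings
#'
#' @param d_g graph hidden dimension.
#' @param n_labels label count.
#' @param seed initialization seed.
#' @return Object of class `tkg_graph_head`.
#' @export
graph_head <- function(d_g, n_labels, seed = 1L) {
  params <- with_local_seed(seed, list(
    W = matrix(rnorm(2L * d_g * n_labels, sd = 1 / sqrt(2 * d_g)),
               2L * d_g, n_labels),
    b = numeric(n_labels)))
  structure(list(params = params, d_g = d_g, n_labels = n_labels),
            class = "tkg_graph_head")
}

#' Train the graph branch
#'
#' Minibatch Adam over per-instance subgraphs (precomputed conv operators
#' and node initializations), training the encoder and its linear head
#' jointly with cross-entropy; early stopping on validation accuracy.
#'
#' @param inputs list per instance: `X`, `A`, `t_idx` (see
#'   `prepare_graph_instance`).
#' @param y integer gold label indices.
#' @param val_inputs,y_val validation counterparts.
#' @param gp [graph_encoder_params()].
#' @param head [graph_head()].
#' @param epochs,batch_size,lr,patience optimization controls.
#' @param seed integer seed.
#' @param verbose print per-epoch log lines.
#' @return List `gp`, `head`, `log`, `val_acc`.
#' @export
train_graph_branch <- function(inputs, y, val_inputs, y_val, gp, head,
                               epochs = 30L, batch_size = 32L, lr = 1e-3,
                               patience = 4L, seed = 1L, weight_decay = 0,
                               verbose = FALSE) {
  n <- length(inputs)
  k <- head$n_labels
  params <- c(gp$params, head$params)
  n_gp <- length(gp$params)
  opt <- adam_init(params)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  log <- list()
  predict_all <- function(ins) {
    t(vapply(ins, function(inp) {
      fw <- graph_forward(gp, inp$X, inp$A, inp$t_idx)
      softmax_vec(c(fw$U[1L, ], fw$U[2L, ]) %*% head$params$W +
                    head$params$b)
    }, numeric(k)))
  }
  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      splits <- split(perm, ceiling(seq_along(perm) / batch_size))
      tr_loss <- 0
      for (bi in splits) {
        gp$params <- params[seq_len(n_gp)]
        head$params <- params[n_gp + 1:2]
        grads <- NULL
        for (ii in bi) {
          inp <- inputs[[ii]]
          fw <- graph_forward(gp, inp$X, inp$A, inp$t_idx, cache = TRUE)
          u <- c(fw$U[1L, ], fw$U[2L, ])
          probs <- softmax_vec(u %*% head$params$W + head$params$b)
          tr_loss <- tr_loss - log(max(probs[y[ii]], 1e-12)) / n
          dlog <- probs - one_hot(y[ii], k)
          gi <- list(W = outer(u, dlog), b = dlog)
          du <- as.numeric(head$params$W %*% dlog)
          dU <- rbind(du[seq_len(gp$d_g)], du[gp$d_g + seq_len(gp$d_g)])
          gb <- graph_backward(gp, fw, dU)
          gi <- c(gb, gi)
          grads <- if (is.null(grads)) gi
          else Map(function(a, b) a + b, grads, gi[names(grads)])
        }
        grads <- lapply(grads, function(g) g / length(bi))
        res <- adam_step(params, grads, opt, lr = lr,
                         weight_decay = weight_decay)
        params <- res$params
        opt <- res$state
      }
      gp$params <- params[seq_len(n_gp)]
      head$params <- params[n_gp + 1:2]
      vp <- predict_all(val_inputs)
      val_acc <- mean(max.col(vp, ties.method = "first") == y_val)
      log[[ep]] <- list(epoch = ep, train_loss = tr_loss, val_acc = val_acc)
      if (verbose)
        message(sprintf("graph epoch %d loss %.4f val_acc %.4f", ep,
                        tr_loss, val_acc))
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, params = params, epoch = ep)
      } else if (ep - best$epoch >= patience) break
    }
  })
  gp$params <- best$params[seq_len(n_gp)]
  head$params <- best$params[n_gp + 1:2]
  list(gp = gp, head = head, log = log, val_acc = best$acc)
}
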