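#' Mark an event pair with special tokens
#'
#' Inserts `<e1>`, `</e1>`, `<e2>`, `</e2>` around the two event spans (in
#' character order; the e1/e2 roles follow argument order, not text order)
#' and tokenizes the result. Context is truncated symmetrically to the
#' token budget while always retaining both marked spans; when the span
#' between the events alone exceeds the budget, its middle is elided with
#' a `<gap>` token.
#'
#' @param doc a `tkg_document`.
#' @param e1,e2 event ids (order defines the roles).
#' @param window token budget.
#' @return Object of class `tkg_marked`: `tokens`, `e1_idx`, `e2_idx`
#'   (token positions of the event tokens themselves, markers excluded).
#' @export
mark_events <- function(doc, e1, e2, window = 128L) {
  ev <- doc$events
  r1 <- ev[ev$id == e1, , drop = FALSE]
  r2 <- ev[ev$id == e2, , drop = FALSE]
  if (nrow(r1) != 1L || nrow(r2) != 1L)
    stop_tkg("events '%s'/'%s' not found in doc '%s'", e1, e2, doc$doc_id)
  if (max(r1$start, r2$start) < min(r1$end, r2$end))
    stop_tkg("overlapping or nested event spans (%s, %s)", e1, e2)
  first_is_e1 <- r1$start < r2$start
  f <- if (first_is_e1) r1 else r2
  s <- if (first_is_e1) r2 else r1
  seg <- function(a, b) if (b > a) substr(doc$text, a + 1L, b) else ""
  pre <- tokenize_text(seg(0L, f$start))
  evf <- tokenize_text(seg(f$start, f$end))
  mid <- tokenize_text(seg(f$end, s$start))
  evs <- tokenize_text(seg(s$start, s$end))
  post <- tokenize_text(seg(s$end, nchar(doc$text)))
  if (!length(evf) || !length(evs))
    stop_tkg("event span tokenizes to nothing")
  budget <- window - 4L - length(evf) - length(evs)
  if (budget < 0L) budget <- 0L
  per <- budget %/% 3L
  pre_k <- if (length(pre) > per) tail(pre, per) else pre
  post_k <- if (length(post) > per) head(post, per) else post
  mid_budget <- budget - length(pre_k) - length(post_k)
  mid_k <- if (length(mid) > mid_budget) {
    h <- max((mid_budget - 1L) %/% 2L, 0L)
    c(head(mid, h), "<gap>", tail(mid, h))
  } else mid
  mk <- if (first_is_e1) c("<e1>", "</e1>", "<e2>", "</e2>")
  else c("<e2>", "</e2>", "<e1>", "</e1>")
  tokens <- c(pre_k, mk[1L], evf, mk[2L], mid_k, mk[3L], evs, mk[4L], post_k)
  f_idx <- length(pre_k) + 1L + seq_along(evf)
  s_idx <- length(pre_k) + 2L + length(evf) + length(mid_k) + 1L +
    seq_along(evs)
  structure(list(tokens = tokens,
                 e1_idx = if (first_is_e1) f_idx else s_idx,
                 e2_idx = if (first_is_e1) s_idx else f_idx),
            class = "tkg_marked")
}

#' Mean-pool per-event token embeddings
#'
#' Aggregates the contextual embeddings at each event's token positions
#' (marker tokens excluded) by the arithmetic mean, yielding one vector
#' per event.
#'
#' @param seq a [mark_events()] result.
#' @param embeddings numeric matrix, one row per token of `seq$tokens`.
#' @return List `(v1, v2)` of pooled vectors.
#' @export
pool_event_embeddings <- function(seq, embeddings) {
  if (nrow(embeddings) != length(seq$tokens))
    stop_tkg("embeddings (%d rows) not aligned with tokens (%d)",
             nrow(embeddings), length(seq$tokens))
  if (!length(seq$e1_idx) || !length(seq$e2_idx))
    stop_tkg("empty event index set")
  list(v1 = colMeans(embeddings[seq$e1_idx, , drop = FALSE]),
       v2 = colMeans(embeddings[seq$e2_idx, , drop = FALSE]))
}

#' Feed-forward classification head for the text branch
#'
#' One hidden layer with rectifier nonlinearity and dropout, mapping the
#' concatenated event vectors (2 d) to label logits. A sequence-embedding
#' variant (classify the mean over all tokens instead of the marked
#' events) exists behind the experimental `use_sequence_embedding` flag
#' for ablation only; it is off by default because event-pooled vectors
#' classify better.
#'
#' @param d backbone embedding dimension.
#' @param n_labels label count.
#' @param hidden hidden width.
#' @param dropout dropout rate on the hidden layer during training.
#' @param use_sequence_embedding experimental ablation flag.
#' @param seed initialization seed.
#' @return Object of class `tkg_text_head`.
#' @export
text_head <- function(d, n_labels, hidden = 64L, dropout = 0.1,
                      use_sequence_embedding = FALSE, seed = 1L) {
  params <- with_local_seed(seed, list(
    W1 = matrix(rnorm(2L * d * hidden, sd = 1 / sqrt(2 * d)), 2L * d, hidden),
    b1 = numeric(hidden),
    W2 = matrix(rnorm(hidden * n_labels, sd = 1 / sqrt(hidden)), hidden,
                n_labels),
    b2 = numeric(n_labels)))
  structure(list(params = params, dropout = dropout,
                 use_sequence_embedding = use_sequence_embedding,
                 hidden = hidden, d = d, n_labels = n_labels, seed = seed),
            class = "tkg_text_head")
}

head_forward <- function(head, V, drop_mask = NULL, cache = FALSE) {
  Z1 <- sweep(V %*% head$params$W1, 2L, head$params$b1, "+")
  A <- relu(Z1)
  if (!is.null(drop_mask)) A <- A * drop_mask / (1 - head$dropout)
  logits <- sweep(A %*% head$params$W2, 2L, head$params$b2, "+")
  probs <- softmax_rows(logits)
  if (!cache) return(probs)
  list(probs = probs, A = A, Z1 = Z1, V = V, drop_mask = drop_mask)
}

head_backward <- function(head, cache, dlogits) {
  grads <- list(W2 = crossprod(cache$A, dlogits), b2 = colSums(dlogits))
  dA <- dlogits %*% t(head$params$W2)
  if (!is.null(cache$drop_mask))
    dA <- dA * cache$drop_mask / (1 - head$dropout)
  dZ1 <- dA * (cache$Z1 > 0)
  grads$W1 <- crossprod(cache$V, dZ1)
  grads$b1 <- colSums(dZ1)
  list(grads = grads, dV = dZ1 %*% t(head$params$W1))
}

# ---- batch plumbing -------------------------------------------------------

# Encode marked sequences into padded id/mask matrices plus sparse pooling
# operators for the two events (rows scaled 1/|event tokens|).
encode_text_batch <- function(marked_list, vocab) {
  n <- length(marked_list)
  L <- max(vapply(marked_list, function(m) length(m$tokens), 0L))
  ids <- matrix(1L, n, L)      # <pad>
  mask <- matrix(0, n, L)
  trip <- function(which_idx) {
    i <- integer(0); j <- integer(0); x <- numeric(0)
    for (b in seq_len(n)) {
      idx <- marked_list[[b]][[which_idx]]
      i <- c(i, rep(b, length(idx)))
      j <- c(j, (b - 1L) * L + idx)
      x <- c(x, rep(1 / length(idx), length(idx)))
    }
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n * L))
  }
  for (b in seq_len(n)) {
    tk <- marked_list[[b]]$tokens
    ids[b, seq_along(tk)] <- vocab_ids(vocab, tk)
    mask[b, seq_along(tk)] <- 1
  }
  all_trip <- {
    i <- integer(0); j <- integer(0); x <- numeric(0)
    for (b in seq_len(n)) {
      len <- length(marked_list[[b]]$tokens)
      i <- c(i, rep(b, len)); j <- c(j, (b - 1L) * L + seq_len(len))
      x <- c(x, rep(1 / len, len))
    }
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n * L))
  }
  list(ids = ids, mask = mask, P1 = trip("e1_idx"), P2 = trip("e2_idx"),
       Pall = all_trip, n = n, L = L)
}

# Pooled event vectors (and optionally head probabilities) for a batch.
text_batch_forward <- function(backbone, head, batch, drop_mask = NULL,
                               cache = FALSE) {
  bb <- backbone_forward(backbone, batch$ids, batch$mask, cache = cache)
  H <- if (cache) bb$H else bb
  if (!is.null(head) && head$use_sequence_embedding) {
    vs <- as.matrix(batch$Pall %*% H)
    V <- cbind(vs, vs)
  } else {
    V <- cbind(as.matrix(batch$P1 %*% H), as.matrix(batch$P2 %*% H))
  }
  if (is.null(head)) return(list(V = V, bb = bb))
  hf <- head_forward(head, V, drop_mask, cache = cache)
  if (!cache) return(list(probs = hf, V = V))
  list(probs = hf$probs, V = V, bb = bb, hf = hf)
}

#' Text-branch forward pass
#'
#' Runs the backbone over a marked sequence, mean-pools the two event
#' embeddings, and applies the feed-forward head, returning a probability
#' vector over the scheme labels (softmax; deterministic in inference
#' mode).
#'
#' @param seq a [mark_events()] result.
#' @param backbone a [bundled_backbone()] (or any object honouring the
#'   backbone contract via `backbone_forward`).
#' @param head a [text_head()].
#' @return Numeric probability vector.
#' @export
text_forward <- function(seq, backbone, head) {
  if (2L * backbone$dim != nrow(head$params$W1))
    stop_tkg("backbone dimension %d does not match head input %d",
             backbone$dim, nrow(head$params$W1))
  batch <- encode_text_batch(list(seq), backbone$vocab)
  as.numeric(text_batch_forward(backbone, head, batch)$probs)
}

# ---- training -------------------------------------------------------------

#' Train the text branch
#'
#' Minibatch Adam on the cross-entropy of the head over backbone-pooled
#' event vectors, with early stopping on validation accuracy. All
#' randomness (shuffling, dropout) derives from `seed`; with one BLAS
#' thread the trajectory is bit-reproducible.
#'
#' @param marked_train,marked_val lists of [mark_events()] sequences.
#' @param y_train,y_val integer label indices (1-based).
#' @param backbone,head model components (trained in place, returned).
#' @param epochs,batch_size,lr,patience optimization controls.
#' @param seed integer seed.
#' @param verbose print per-epoch log lines.
#' @return List `backbone`, `head`, `log` (per-epoch metrics).
#' @export
train_text_branch <- function(marked_train, y_train, marked_val, y_val,
                              backbone, head, epochs = 20L, batch_size = 128L,
                              lr = 1e-3, patience = 3L, seed = 1L,
                              verbose = FALSE) {
  n <- length(marked_train)
  k <- head$n_labels
  params <- c(backbone$params, head$params)
  opt <- adam_init(params)
  n_bb <- length(backbone$params)
  log <- list()
  best <- list(acc = -Inf, params = params, epoch = 0L)
  val_batch <- encode_text_batch(marked_val, backbone$vocab)
  with_local_seed(seed, {
    batches_idx <- NULL
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      splits <- split(perm, ceiling(seq_along(perm) / batch_size))
      tr_loss <- 0
      for (bi in splits) {
        batch <- encode_text_batch(marked_train[bi], backbone$vocab)
        drop_mask <- if (head$dropout > 0)
          matrix(runif(length(bi) * head$hidden) >= head$dropout,
                 length(bi), head$hidden)
        else NULL
        backbone$params <- params[seq_len(n_bb)]
        head$params <- params[n_bb + seq_len(length(head$params))]
        fw <- text_batch_forward(backbone, head, batch, drop_mask,
                                 cache = TRUE)
        Y <- matrix(0, length(bi), k)
        Y[cbind(seq_along(bi), y_train[bi])] <- 1
        tr_loss <- tr_loss -
          sum(log(pmax(fw$probs[Y == 1], 1e-12))) / n
        dlogits <- (fw$probs - Y) / length(bi)
        hb <- head_backward(head, fw$hf, dlogits)
        d <- backbone$dim
        dH <- as.matrix(Matrix::crossprod(batch$P1,
                                          hb$dV[, seq_len(d), drop = FALSE])) +
          as.matrix(Matrix::crossprod(batch$P2,
                                      hb$dV[, d + seq_len(d), drop = FALSE]))
        bg <- backbone_backward(backbone, fw$bb, dH)
        grads <- c(bg, hb$grads)
        res <- adam_step(params, grads, opt, lr = lr)
        params <- res$params
        opt <- res$state
        if (!all(is.finite(unlist(grads[c("b1", "b2")]))))
          stop_tkg("non-finite loss at epoch %d", ep)
      }
      backbone$params <- params[seq_len(n_bb)]
      head$params <- params[n_bb + seq_len(length(head$params))]
      vp <- text_batch_forward(backbone, head, val_batch)$probs
      val_acc <- mean(max.col(vp, ties.method = "first") == y_val)
      log[[ep]] <- list(epoch = ep, train_loss = tr_loss, val_acc = val_acc)
      if (verbose)
        message(sprintf("text epoch %d loss %.4f val_acc %.4f", ep, tr_loss,
                        val_acc))
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, params = params, epoch = ep)
      } else if (ep - best$epoch >= patience) break
    }
  })
  backbone$params <- best$params[seq_len(n_bb)]
  head$params <- best$params[n_bb + seq_len(length(head$params))]
  list(backbone = backbone, head = head, log = log, val_acc = best$acc)
}
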