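#' Fusion-layer parameters
#'
#' Exactly one linear map (no hidden layers) from the concatenation of the
#' two text-branch event vectors and the two graph-branch event embeddings
#' to the label logits.
#'
#' @param d_t text embedding dimension.
#' @param d_g graph embedding dimension.
#' @param n_labels label count.
#' @param seed initialization seed.
#' @return Object of class `tkg_fusion`.
#' @export
fusion_params <- function(d_t, d_g, n_labels, seed = 1L) {
  D <- 2L * d_t + 2L * d_g
  params <- with_local_seed(seed, list(
    W = matrix(rnorm(D * n_labels, sd = 1 / sqrt(D)), D, n_labels),
    b = numeric(n_labels)))
  structure(list(params = params, d_t = d_t, d_g = d_g,
                 n_labels = n_labels), class = "tkg_fusion")
}

#' Late fusion: classify from both branches' event embeddings
#'
#' Softmax of a single linear layer over `[v1; v2; u1; u2]`. Accepts
#' vectors (one instance) or row-aligned matrices (a batch).
#'
#' @param v1,v2 text-branch event vectors.
#' @param u1,u2 graph-branch event embeddings.
#' @param params a [fusion_params()].
#' @return Probability vector, or matrix with one row per instance.
#' @export
fuse_and_classify <- function(v1, v2, u1, u2, params) {
  single <- is.null(dim(v1))
  F <- cbind(rbind(v1), rbind(v2), rbind(u1), rbind(u2))
  if (ncol(F) != nrow(params$params$W))
    stop_tkg("fusion input dimension %d does not match parameters (%d)",
             ncol(F), nrow(params$params$W))
  probs <- softmax_rows(sweep(F %*% params$params$W, 2L, params$params$b, "+"))
  if (single) as.numeric(probs) else probs
}

# Full-batch Adam multinomial fit of the fusion layer on frozen features.
train_fusion_layer <- function(F_train, y_train, F_val, y_val, fusion,
                               epochs = 300L, lr = 0.02, patience = 25L,
                               seed = 1L) {
  k <- fusion$n_labels
  n <- nrow(F_train)
  params <- fusion$params
  opt <- adam_init(params)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), y_train)] <- 1
  best <- list(acc = -Inf, params = params, epoch = 0L)
  log <- list()
  for (ep in seq_len(epochs)) {
    logits <- sweep(F_train %*% params$W, 2L, params$b, "+")
    probs <- softmax_rows(logits)
    loss <- -sum(log(pmax(probs[Y == 1], 1e-12))) / n
    dlogits <- (probs - Y) / n
    grads <- list(W = crossprod(F_train, dlogits), b = colSums(dlogits))
    res <- adam_step(params, grads, opt, lr = lr)
    params <- res$params; opt <- res$state
    vp <- softmax_rows(sweep(F_val %*% params$W, 2L, params$b, "+"))
    val_acc <- mean(max.col(vp, ties.method = "first") == y_val)
    log[[ep]] <- list(epoch = ep, train_loss = loss, val_acc = val_acc)
    if (val_acc > best$acc + 1e-12) {
      best <- list(acc = val_acc, params = params, epoch = ep)
    } else if (ep - best$epoch >= patience) break
  }
  fusion$params <- best$params
  list(fusion = fusion, log = log, val_acc = best$acc)
}

# Joint fine-tuning: end-to-end bimodal cross-entropy through the fusion
# layer into the encoders (branch heads stay fixed; they only serve the
# single-modality paths). Each instance contributes one loss term per
# graph condition in `gin_conditions`, so the model stays calibrated for
# gold and bootstrapped graphs alike. `freeze_graph` holds the graph
# encoder fixed (its features are then precomputed once).
train_joint_stage <- function(marked, gin_conditions, y, marked_val,
                              gin_val_conditions, y_val, backbone, gp,
                              fusion, epochs = 10L, batch_size = 32L,
                              lr = 5e-4, patience = 3L, seed = 1L,
                              freeze_graph = FALSE, verbose = FALSE) {
  n <- length(marked)
  k <- fusion$n_labels
  d_t <- backbone$dim; d_g <- gp$d_g
  n_bb <- length(backbone$params); n_gp <- length(gp$params)
  params <- c(backbone$params, gp$params, fusion$params)
  opt <- adam_init(params)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  log <- list()
  set_params <- function(p) {
    backbone$params <<- p[seq_len(n_bb)]
    gp$params <<- p[n_bb + seq_len(n_gp)]
    fusion$params <<- p[n_bb + n_gp + 1:2]
  }
  val_batch <- encode_text_batch(marked_val, backbone$vocab)
  graph_feats <- function(gin) {
    t(vapply(gin, function(inp) {
      fw <- graph_forward(gp, inp$X, inp$A, inp$t_idx)
      c(fw$U[1L, ], fw$U[2L, ])
    }, numeric(2L * d_g)))
  }
  U_frozen <- if (freeze_graph) lapply(gin_conditions, graph_feats)
  U_val_frozen <- if (freeze_graph) lapply(gin_val_conditions, graph_feats)
  val_acc_fn <- function() {
    V <- text_batch_forward(backbone, NULL, val_batch)$V
    accs <- vapply(seq_along(gin_val_conditions), function(ci) {
      U <- if (freeze_graph) U_val_frozen[[ci]]
      else graph_feats(gin_val_conditions[[ci]])
      probs <- softmax_rows(sweep(cbind(V, U) %*% fusion$params$W, 2L,
                                  fusion$params$b, "+"))
      mean(max.col(probs, ties.method = "first") == y_val)
    }, 0)
    mean(accs)
  }
  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      splits <- split(perm, ceiling(seq_along(perm) / batch_size))
      tr_loss <- 0
      for (bi in splits) {
        set_params(params)
        batch <- encode_text_batch(marked[bi], backbone$vocab)
        tf <- text_batch_forward(backbone, NULL, batch, cache = TRUE)
        V <- tf$V
        dV <- matrix(0, length(bi), 2L * d_t)
        gW <- matrix(0, nrow(fusion$params$W), k); gb <- numeric(k)
        g_graph <- NULL
        m <- length(gin_conditions) * length(bi)
        for (ci in seq_along(gin_conditions)) {
          gin <- gin_conditions[[ci]]
          caches <- if (!freeze_graph)
            lapply(gin[bi], function(inp)
              graph_forward(gp, inp$X, inp$A, inp$t_idx, cache = TRUE))
          U <- if (freeze_graph) U_frozen[[ci]][bi, , drop = FALSE]
          else t(vapply(caches, function(fw) c(fw$U[1L, ], fw$U[2L, ]),
                        numeric(2L * d_g)))
          F <- cbind(V, U)
          probs <- softmax_rows(sweep(F %*% fusion$params$W, 2L,
                                      fusion$params$b, "+"))
          Y <- matrix(0, length(bi), k)
          Y[cbind(seq_along(bi), y[bi])] <- 1
          tr_loss <- tr_loss - sum(log(pmax(probs[Y == 1], 1e-12))) / n
          dlogits <- (probs - Y) / m
          gW <- gW + crossprod(F, dlogits); gb <- gb + colSums(dlogits)
          dF <- dlogits %*% t(fusion$params$W)
          dV <- dV + dF[, seq_len(2L * d_t), drop = FALSE]
          if (!freeze_graph) {
            dUm <- dF[, 2L * d_t + seq_len(2L * d_g), drop = FALSE]
            for (j in seq_along(bi)) {
              dU <- rbind(dUm[j, seq_len(d_g)], dUm[j, d_g + seq_len(d_g)])
              gj <- graph_backward(gp, caches[[j]], dU)
              g_graph <- if (is.null(g_graph)) gj
              else Map(`+`, g_graph, gj[names(g_graph)])
            }
          }
        }
        dH <- as.matrix(Matrix::crossprod(batch$P1,
                                          dV[, seq_len(d_t), drop = FALSE])) +
          as.matrix(Matrix::crossprod(batch$P2,
                                      dV[, d_t + seq_len(d_t), drop = FALSE]))
        g_bb <- backbone_backward(backbone, tf$bb, dH)
        grads <- c(g_bb, g_graph, list(W = gW, b = gb))
        res <- adam_step(params, grads, opt, lr = lr)
        params <- res$params; opt <- res$state
      }
      set_params(params)
      va <- val_acc_fn()
      log[[ep]] <- list(epoch = ep, train_loss = tr_loss, val_acc = va)
      if (verbose)
        message(sprintf("joint epoch %d loss %.4f val_acc %.4f", ep,
                        tr_loss, va))
      if (va > best$acc + 1e-12) {
        best <- list(acc = va, params = params, epoch = ep)
      } else if (ep - best$epoch >= patience) break
    }
  })
  set_params(best$params)
  list(backbone = backbone, gp = gp, fusion = fusion, log = log,
       val_acc = best$acc)
}

#' Training configuration
#'
#' Houses the staged procedure's controls. Stages: `text` fits the text
#' branch on the first training split; `graph` fits the graph encoder and
#' its head on per-instance masked subgraphs (gold graphs span both
#' training splits since they carry no prediction noise; bootstrap graphs
#' come from text predictions on the second split, which the text branch
#' never saw); `fusion` fits the single linear fusion layer on frozen
#' features; `joint` fine-tunes backbone, graph encoder and fusion
#' end-to-end under the bimodal loss (the fine-tuned copies serve only
#' the bimodal path). Early stopping everywhere is on validation
#' accuracy.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param window token budget around the event pair.
#' @param d_t,text_hidden,dropout,text_epochs,text_lr,text_batch text
#'   branch controls.
#' @param d_w,d_g,graph_layers,graph_epochs,graph_lr,graph_batch graph
#'   branch controls.
#' @param graph_wd decoupled weight decay for the graph stage (counters
#'   the per-relation matrices' capacity to memorize concept pairs).
#' @param fusion_epochs,fusion_lr,fusion_patience fusion controls.
#' @param joint_epochs,joint_lr,joint_batch joint fine-tuning controls
#'   (`joint_epochs = 0` disables the stage).
#' @param patience early-stopping patience (epochs) for all staged fits.
#' @param oversample balance classes by duplicate-to-majority resampling.
#' @param graph_source `"gold"` or `"bootstrap"` training graphs for the
#'   graph stage.
#' @param graph_scope scope of gold training graphs: `"document"`
#'   (per-report; matches the evaluation scenarios) or `"dataset"` (one
#'   pooled graph).
#' @param fusion_source graph conditions the fusion and joint stages see:
#'   `"clean"` (gold and oracle-filtered bootstrap, the default: the
#'   fused model learns to trust edges, so cleaner graphs help — the
#'   ordering the oracle ablation probes), `"all"` (additionally the raw
#'   bootstrap condition), `"both"` (gold + bootstrap) or `"match"` (the
#'   graph stage's source only).
#' @param masking `"target-pair"` removes every edge between the two
#'   target nodes (with its derived shadow) before encoding; `"none"`
#'   leaves graphs untouched.
#' @param max_hops subgraph hop budget.
#' @param composition composition-table preset for enrichment.
#' @param stages character subset of
#'   `c("text", "graph", "fusion", "joint")`.
#' @return Object of class `tkg_train_config`.
#' @export
train_config <- function(seed = 1L, window = 128L,
                         d_t = 48L, text_hidden = 64L, dropout = 0.1,
                         text_epochs = 20L, text_lr = 1e-3, text_batch = 128L,
                         d_w = 64L, d_g = 64L, graph_layers = 3L,
                         graph_epochs = 30L, graph_lr = 1e-3,
                         graph_batch = 32L, graph_wd = 3e-4,
                         fusion_epochs = 300L, fusion_lr = 0.02,
                         fusion_patience = 25L,
                         joint_epochs = 10L, joint_lr = 5e-4,
                         joint_batch = 32L,
                         patience = 3L, oversample = TRUE,
                         graph_source = c("gold", "bootstrap"),
                         graph_scope = c("document", "dataset"),
                         fusion_source = c("both", "clean", "all", "match"),
                         masking = c("target-pair", "none"),
                         max_hops = 3L,
                         composition = "strict",
                         stages = c("text", "graph", "fusion", "joint")) {
  graph_source <- match.arg(graph_source)
  graph_scope <- match.arg(graph_scope)
  fusion_source <- match.arg(fusion_source)
  masking <- match.arg(masking)
  stopifnot(patience >= 1L, text_epochs >= 0L, graph_epochs >= 0L)
  structure(as.list(environment()), class = "tkg_train_config")
}

derive_seed <- function(seed, offset) (as.integer(seed) * 97L + offset) %% 2147483L

mark_instances <- function(instances, docs, window) {
  doc_by_id <- stats::setNames(docs, vapply(docs, `[[`, "", "doc_id"))
  lapply(seq_len(nrow(instances)), function(i)
    mark_events(doc_by_id[[instances$doc_id[i]]], instances$e1[i],
                instances$e2[i], window))
}

# Build the per-document enriched graph for each doc id. source = "gold"
# uses annotated relations; "bootstrap" uses text-branch soft predictions.
document_graphs <- function(docs, consolidation, scheme, composition,
                            source = c("gold", "bootstrap", "oracle"),
                            bundle = NULL, threshold = NULL) {
  source <- match.arg(source)
  out <- list()
  table <- composition_table(composition, scheme$labels)
  for (d in docs) {
    cons_d <- list(
      nodes = consolidation$nodes,
      node_map = consolidation$node_map[
        consolidation$node_map$doc_id == d$doc_id, , drop = FALSE])
    # restrict node table to this document's concepts
    used <- unique(cons_d$node_map$node_id)
    cons_d$nodes <- consolidation$nodes[
      consolidation$nodes$node_id %in% used, , drop = FALSE]
    g <- if (source == "gold") {
      enrich_graph(build_event_graph(list(d), cons_d, scheme), table)
    } else {
      boot <- enrich_graph(bootstrap_graph(d, cons_d, bundle), table)
      if (source == "oracle") {
        gold <- enrich_graph(build_event_graph(list(d), cons_d, scheme),
                             table)
        oracle_filter_graph(boot, gold)
      } else boot
    }
    if (!is.null(threshold)) g <- filter_by_confidence(g, threshold)
    out[[d$doc_id]] <- g
  }
  out
}

# Soft event graph from the text branch's own predictions on one document.
bootstrap_graph <- function(doc, cons_d, bundle) {
  scheme <- bundle$scheme
  inst <- build_instances(list(doc))
  if (!nrow(inst)) return(event_graph(cons_d$nodes, NULL, scheme))
  marked <- mark_instances(inst, list(doc), bundle$config$window)
  batch <- encode_text_batch(marked, bundle$backbone$vocab)
  probs <- text_batch_forward(bundle$backbone, bundle$text_head, batch)$probs
  lk <- stats::setNames(cons_d$node_map$node_id, cons_d$node_map$event_id)
  src <- unname(lk[inst$e1]); dst <- unname(lk[inst$e2])
  lab <- scheme$labels[max.col(probs, ties.method = "first")]
  keep <- src != dst
  keep[keep] <- !duplicated(edge_id(src[keep], dst[keep], lab[keep]))
  if (!any(keep)) return(event_graph(cons_d$nodes, NULL, scheme))
  edges <- make_edges(src[keep], dst[keep], lab[keep],
                      apply(probs[keep, , drop = FALSE], 1L, max),
                      "predicted",
                      replicate(sum(keep), character(0), simplify = FALSE),
                      lapply(which(keep), function(i) as.numeric(probs[i, ])))
  event_graph(cons_d$nodes, edges, scheme)
}

# Per-instance masked subgraph plus precomputed encoder structures.
prepare_graph_instance <- function(g, n1, n2, vectors, masking = "target-pair",
                                   max_hops = 3L) {
  if (masking == "target-pair") g <- mask_target_edges(g, n1, n2)
  sg <- extract_subgraph(g, unique(c(n1, n2)), max_hops)
  t_idx <- match(c(n1, n2), sg$nodes$node_id)
  list(X = node_init_matrix(sg, vectors), A = conv_operators(sg),
       t_idx = t_idx, graph = sg)
}

#' Train the full bimodal model (staged)
#'
#' Stage 1 trains the text branch on `train1`. Stage 2 predicts `train2`
#' with the text branch to build bootstrap graphs (unless
#' `graph_source = "gold"`) and trains the graph branch on them — `train2`
#' is unseen by the text branch, so its bootstrap graphs carry realistic
#' prediction errors, mirroring inference-time conditions. Stage 3 fits
#' the single linear fusion layer on frozen features from both branches.
#' Deterministic under `config$seed` with single-threaded numerics.
#'
#' @param train1,train2,val lists of documents.
#' @param config a [train_config()].
#' @param linker entity linker for consolidation.
#' @param verbose print stage/epoch progress.
#' @return A model bundle of class `tkg_bundle`.
#' @export
train_model <- function(train1, train2, val, config = train_config(),
                        linker = passthrough_linker(), verbose = FALSE) {
  scheme <- label_scheme(composition = config$composition)
  k <- length(scheme$labels)
  inst1 <- build_instances(train1)
  inst2 <- build_instances(train2)
  inst_val <- build_instances(val)
  if (!nrow(inst1) || !nrow(inst2) || !nrow(inst_val))
    stop_tkg("all three splits need at least one relation instance")
  if (config$oversample) {
    inst1 <- oversample_instances(inst1, derive_seed(config$seed, 11L))
    inst2 <- oversample_instances(inst2, derive_seed(config$seed, 12L))
  }
  all_docs <- c(train1, train2, val)
  marked1 <- mark_instances(inst1, train1, config$window)
  marked2 <- mark_instances(inst2, train2, config$window)
  marked_val <- mark_instances(inst_val, val, config$window)
  vocab <- build_vocab(lapply(c(marked1, marked2), `[[`, "tokens"))
  backbone <- bundled_backbone(vocab, d = config$d_t,
                               seed = derive_seed(config$seed, 1L))
  thead <- text_head(config$d_t, k, hidden = config$text_hidden,
                     dropout = config$dropout,
                     seed = derive_seed(config$seed, 2L))
  y1 <- match(inst1$gold, scheme$labels)
  y2 <- match(inst2$gold, scheme$labels)
  y_val <- match(inst_val$gold, scheme$labels)
  logs <- list()
  if ("text" %in% config$stages && config$text_epochs > 0L) {
    tt <- train_text_branch(marked1, y1, marked_val, y_val, backbone, thead,
                            epochs = config$text_epochs,
                            batch_size = config$text_batch,
                            lr = config$text_lr, patience = config$patience,
                            seed = derive_seed(config$seed, 3L),
                            verbose = verbose)
    backbone <- tt$backbone; thead <- tt$head
    logs$text <- tt$log
  }
  vectors <- word_vector_table(config$d_w)
  gp <- graph_encoder_params(config$d_w, config$d_g, k,
                             n_layers = config$graph_layers,
                             seed = derive_seed(config$seed, 4L))
  ghead <- graph_head(config$d_g, k, seed = derive_seed(config$seed, 5L))
  fusion <- fusion_params(config$d_t, config$d_g, k,
                          seed = derive_seed(config$seed, 6L))
  bundle <- structure(
    list(scheme = scheme, config = config, backbone = backbone,
         text_head = thead, graph_params = gp, graph_head = ghead,
         fusion = fusion, vectors = vectors, linker_kind = linker$kind,
         seed = config$seed, logs = logs),
    class = "tkg_bundle")
  cons <- consolidate_events(all_docs, linker)
  training_graphs <- function(docs, source) {
    if (source == "gold" && config$graph_scope == "dataset")
      enrich_graph(build_event_graph(docs, cons, scheme),
                   composition_table(config$composition, scheme$labels))
    else
      document_graphs(docs, cons, scheme, config$composition,
                      source = source, bundle = bundle)
  }
  node_of <- stats::setNames(cons$node_map$node_id,
                             paste(cons$node_map$doc_id,
                                   cons$node_map$event_id, sep = "\01"))
  # memoized per-pair masked-subgraph preparation (oversampling duplicates
  # instances; the subgraph only depends on the pair and the graph source)
  prep_all <- function(inst, graphs) {
    key <- paste(inst$doc_id, inst$e1, inst$e2, sep = "\01")
    uniq <- !duplicated(key)
    prepped <- lapply(which(uniq), function(i) {
      g <- if (inherits(graphs, "tkg_graph")) graphs
      else graphs[[inst$doc_id[i]]]
      n1 <- node_of[[paste(inst$doc_id[i], inst$e1[i], sep = "\01")]]
      n2 <- node_of[[paste(inst$doc_id[i], inst$e2[i], sep = "\01")]]
      prepare_graph_instance(g, n1, n2, vectors, config$masking,
                             config$max_hops)
    })
    prepped[match(key, key[uniq])]
  }
  # --- training blocks: (instances, marked text, graph inputs) ------------
  # gold graphs carry no prediction noise, so the gold block can span both
  # training splits; bootstrap (and oracle-filtered bootstrap) graphs must
  # come from text predictions on documents the text branch has not seen,
  # i.e. train2 only
  fusing <- any(c("fusion", "joint") %in% config$stages)
  extra_sources <- switch(config$fusion_source,
                          clean = c("gold", "oracle"),
                          all = c("gold", "bootstrap", "oracle"),
                          both = c("gold", "bootstrap"),
                          match = config$graph_source)
  sources <- if (!fusing && !("graph" %in% config$stages)) character(0)
  else unique(c(config$graph_source, if (fusing) extra_sources))
  blocks <- list()
  for (src in sources) {
    if (src == "gold" && config$graph_source == "gold") {
      inst_g <- build_instances(c(train1, train2))
      if (config$oversample)
        inst_g <- oversample_instances(inst_g, derive_seed(config$seed, 13L))
      blocks$gold <- list(
        inst = inst_g,
        marked = mark_instances(inst_g, c(train1, train2), config$window),
        gin = prep_all(inst_g, training_graphs(c(train1, train2), "gold")),
        y = match(inst_g$gold, scheme$labels))
    } else {
      blocks[[src]] <- list(
        inst = inst2, marked = marked2,
        gin = prep_all(inst2, training_graphs(train2, src)),
        y = y2)
    }
  }
  # validation conditions: the fusion and joint stages are SELECTED on the
  # mean accuracy across every graph regime the scenarios exercise (gold,
  # bootstrap, oracle-filtered), even when they train on fewer
  conditions_val <- list()
  if (length(sources)) {
    gin_val <- prep_all(inst_val, training_graphs(val, config$graph_source))
    conditions_val <- list(gin_val)
    val_sources <- if (fusing) c("gold", "bootstrap", "oracle")
    else sources
    for (src in setdiff(val_sources, config$graph_source))
      conditions_val <- c(conditions_val,
                          list(prep_all(inst_val, training_graphs(val, src))))
  }
  if ("graph" %in% config$stages && config$graph_epochs > 0L) {
    prim <- blocks[[config$graph_source]]
    gt <- train_graph_branch(prim$gin, prim$y, gin_val, y_val, gp, ghead,
                             epochs = config$graph_epochs,
                             batch_size = config$graph_batch,
                             lr = config$graph_lr,
                             patience = config$patience,
                             seed = derive_seed(config$seed, 7L),
                             weight_decay = config$graph_wd %||% 0,
                             verbose = verbose)
    gp <- gt$gp; ghead <- gt$head
    logs$graph <- gt$log
    bundle$graph_params <- gp; bundle$graph_head <- ghead
  }
  # fusion and joint stages train on every block, so one fused model holds
  # a trust level that is valid under gold and bootstrapped graphs alike
  fuse_blocks <- if (config$fusion_source == "match")
    blocks[config$graph_source] else blocks
  marked_f <- do.call(c, lapply(fuse_blocks, `[[`, "marked"))
  gin_f <- do.call(c, lapply(fuse_blocks, `[[`, "gin"))
  y_f <- do.call(c, lapply(fuse_blocks, `[[`, "y"))
  gfeat <- function(gin) {
    t(vapply(gin, function(inp) {
      fw <- graph_forward(gp, inp$X, inp$A, inp$t_idx)
      c(fw$U[1L, ], fw$U[2L, ])
    }, numeric(2L * config$d_g)))
  }
  if ("fusion" %in% config$stages && length(fuse_blocks)) {
    tfeat <- function(marked) {
      batch <- encode_text_batch(marked, vocab)
      text_batch_forward(backbone, NULL, batch)$V
    }
    Tva <- tfeat(marked_val)
    Ftr <- cbind(tfeat(marked_f), gfeat(gin_f))
    Fva <- do.call(rbind, lapply(conditions_val, function(g)
      cbind(Tva, gfeat(g))))
    y_valf <- rep(y_val, length(conditions_val))
    ft <- train_fusion_layer(Ftr, y_f, Fva, y_valf, fusion,
                             epochs = config$fusion_epochs,
                             lr = config$fusion_lr,
                             patience = config$fusion_patience,
                             seed = derive_seed(config$seed, 8L))
    fusion <- ft$fusion
    logs$fusion <- ft$log
    bundle$fusion <- fusion
  }
  # the bimodal path may be fine-tuned end-to-end; the single-modality
  # paths keep the staged encoders their heads were fitted to
  bundle$backbone_bi <- backbone
  bundle$graph_params_bi <- gp
  if ("joint" %in% config$stages && config$joint_epochs > 0L &&
      length(fuse_blocks)) {
    jt <- train_joint_stage(marked_f, list(gin_f), y_f, marked_val,
                            conditions_val, y_val, backbone, gp, fusion,
                            epochs = config$joint_epochs,
                            batch_size = config$joint_batch,
                            lr = config$joint_lr,
                            patience = config$patience,
                            seed = derive_seed(config$seed, 9L),
                            verbose = verbose)
    logs$joint <- jt$log
    bundle$backbone_bi <- jt$backbone
    bundle$graph_params_bi <- jt$gp
    bundle$fusion <- jt$fusion
  }
  bundle$logs <- logs
  bundle
}

#' @export
print.tkg_bundle <- function(x, ...) {
  cat(sprintf("<tkg_bundle> labels: %s | d_t=%d d_g=%d | seed %s\n",
              paste(x$scheme$labels, collapse = "/"), x$config$d_t,
              x$config$d_g, format(x$seed)))
  invisible(x)
}

#' Predict temporal relations for annotated event pairs
#'
#' One probability vector per annotated pair. `mode = "text"` uses the
#' text branch alone and ignores any supplied graph; `"graph"` classifies
#' from the graph branch alone; `"bimodal"` fuses both. Hard labels use
#' argmax with a deterministic tie-break (lowest label index).
#'
#' @param docs list of documents.
#' @param bundle a trained `tkg_bundle`.
#' @param mode `"text"`, `"graph"` or `"bimodal"`.
#' @param graph an enriched `tkg_graph` (dataset scope), or a named list
#'   of per-document graphs; required for graph and bimodal modes.
#' @param consolidation optional [consolidate_events()] result matching
#'   `graph`; computed from `docs` with the bundle's linker when absent.
#' @param prepared optional list of per-instance prepared graph inputs
#'   (masked subgraph, conv operators, node initializations) to reuse
#'   across modes; computed when absent.
#' @return List: `instances` (with `predicted` labels), `probs` matrix.
#' @export
predict_relations <- function(docs, bundle,
                              mode = c("bimodal", "text", "graph"),
                              graph = NULL, consolidation = NULL,
                              prepared = NULL) {
  mode <- match.arg(mode)
  scheme <- bundle$scheme
  inst <- build_instances(docs)
  if (!nrow(inst))
    return(list(instances = inst, probs = matrix(0, 0, length(scheme$labels))))
  probs <- NULL
  marked <- mark_instances(inst, docs, bundle$config$window)
  batch <- encode_text_batch(marked, bundle$backbone$vocab)
  if (mode %in% c("text", "bimodal")) {
    tf <- text_batch_forward(bundle$backbone, bundle$text_head, batch)
    if (mode == "text") probs <- tf$probs
  }
  if (mode %in% c("graph", "bimodal")) {
    if (is.null(graph))
      stop_tkg("mode '%s' requires a graph", mode)
    if (is.null(consolidation)) {
      linker <- if (identical(bundle$linker_kind, "dictionary"))
        stop_tkg("dictionary-linker bundles require an explicit consolidation")
      else passthrough_linker()
      consolidation <- consolidate_events(docs, linker)
    }
    node_of <- stats::setNames(consolidation$node_map$node_id,
                               paste(consolidation$node_map$doc_id,
                                     consolidation$node_map$event_id,
                                     sep = "\01"))
    get_graph <- function(doc_id) {
      if (inherits(graph, "tkg_graph")) graph else graph[[doc_id]]
    }
    gp_use <- if (mode == "bimodal")
      bundle$graph_params_bi %||% bundle$graph_params
    else bundle$graph_params
    if (is.null(prepared)) {
      prepared <- lapply(seq_len(nrow(inst)), function(i) {
        g <- get_graph(inst$doc_id[i])
        n1 <- node_of[[paste(inst$doc_id[i], inst$e1[i], sep = "\01")]]
        n2 <- node_of[[paste(inst$doc_id[i], inst$e2[i], sep = "\01")]]
        g <- ensure_nodes(g, consolidation, c(n1, n2))
        prepare_graph_instance(g, n1, n2, bundle$vectors,
                               bundle$config$masking,
                               bundle$config$max_hops)
      })
    }
    U <- t(vapply(prepared, function(inp) {
      fw <- graph_forward(gp_use, inp$X, inp$A, inp$t_idx)
      c(fw$U[1L, ], fw$U[2L, ])
    }, numeric(2L * bundle$config$d_g)))
    if (mode == "graph") {
      probs <- softmax_rows(sweep(U %*% bundle$graph_head$params$W, 2L,
                                  bundle$graph_head$params$b, "+"))
    } else {
      bb_bi <- bundle$backbone_bi %||% bundle$backbone
      batch_bi <- encode_text_batch(marked, bb_bi$vocab)
      V <- text_batch_forward(bb_bi, NULL, batch_bi)$V
      d_t <- bundle$config$d_t; d_g <- bundle$config$d_g
      probs <- fuse_and_classify(V[, seq_len(d_t), drop = FALSE],
                                 V[, d_t + seq_len(d_t), drop = FALSE],
                                 U[, seq_len(d_g), drop = FALSE],
                                 U[, d_g + seq_len(d_g), drop = FALSE],
                                 bundle$fusion)
    }
  }
  colnames(probs) <- scheme$labels
  inst$predicted <- scheme$labels[max.col(probs, ties.method = "first")]
  list(instances = inst, probs = probs)
}

# add isolated nodes for concepts present in docs but absent from a graph
ensure_nodes <- function(g, consolidation, node_ids) {
  missing <- setdiff(node_ids, g$nodes$node_id)
  if (!length(missing)) return(g)
  add <- consolidation$nodes[consolidation$nodes$node_id %in% missing, ,
                             drop = FALSE]
  g$nodes <- rbind(g$nodes, add)
  rownames(g$nodes) <- NULL
  g
}

#' Save / load a model bundle as a single JSON checkpoint
#'
#' All parameters, configuration, label scheme, vocabulary and seeds in
#' one self-contained text file.
#'
#' @param bundle a `tkg_bundle`.
#' @param path output path.
#' @return `path` (saver) or the restored bundle (loader).
#' @export
save_bundle <- function(bundle, path) {
  ser_arr <- function(a) list(dim = dim(a) %||% length(a), data = as.numeric(a))
  ser_params <- function(pl) lapply(pl, ser_arr)
  obj <- list(
    labels = bundle$scheme$labels,
    inverse_map = as.list(bundle$scheme$inverse_map),
    composition_preset = bundle$scheme$preset,
    config = unclass(bundle$config),
    vocab = bundle$backbone$vocab$tokens,
    backbone = list(kind = bundle$backbone$kind, dim = bundle$backbone$dim,
                    n_layers = bundle$backbone$n_layers,
                    width = bundle$backbone$width,
                    params = ser_params(bundle$backbone$params)),
    text_head = list(hidden = bundle$text_head$hidden,
                     dropout = bundle$text_head$dropout,
                     params = ser_params(bundle$text_head$params)),
    graph_params = list(d_w = bundle$graph_params$d_w,
                        d_g = bundle$graph_params$d_g,
                        n_layers = bundle$graph_params$n_layers,
                        params = ser_params(bundle$graph_params$params)),
    graph_head = ser_params(bundle$graph_head$params),
    fusion = ser_params(bundle$fusion$params),
    backbone_bi = ser_params((bundle$backbone_bi %||% bundle$backbone)$params),
    graph_params_bi =
      ser_params((bundle$graph_params_bi %||% bundle$graph_params)$params),
    d_w = bundle$vectors$d,
    linker_kind = bundle$linker_kind,
    seed = bundle$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_arr <- function(a) {
    if (length(a$dim) > 1L) array(a$data, dim = a$dim) else as.numeric(a$data)
  }
  de_params <- function(pl) lapply(pl, de_arr)
  cfg <- obj$config
  cfg$stages <- as.character(cfg$stages)
  class(cfg) <- "tkg_train_config"
  scheme <- label_scheme(obj$labels, unlist(obj$inverse_map),
                         obj$composition_preset)
  vocab <- structure(list(tokens = obj$vocab,
                          index = stats::setNames(seq_along(obj$vocab),
                                                  obj$vocab)),
                     class = "tkg_vocab")
  backbone <- structure(list(kind = obj$backbone$kind, vocab = vocab,
                             dim = obj$backbone$dim,
                             n_layers = obj$backbone$n_layers,
                             width = obj$backbone$width,
                             params = de_params(obj$backbone$params),
                             seed = obj$seed),
                        class = "tkg_backbone")
  k <- length(scheme$labels)
  thead <- structure(list(params = de_params(obj$text_head$params),
                          dropout = obj$text_head$dropout,
                          use_sequence_embedding = FALSE,
                          hidden = obj$text_head$hidden,
                          d = obj$backbone$dim, n_labels = k),
                     class = "tkg_text_head")
  gp <- structure(list(params = de_params(obj$graph_params$params),
                       d_w = obj$graph_params$d_w,
                       d_g = obj$graph_params$d_g,
                       n_labels = k,
                       n_layers = obj$graph_params$n_layers),
                  class = "tkg_graph_params")
  ghead <- structure(list(params = de_params(obj$graph_head),
                          d_g = gp$d_g, n_labels = k),
                     class = "tkg_graph_head")
  fusion <- structure(list(params = de_params(obj$fusion),
                           d_t = obj$backbone$dim, d_g = gp$d_g,
                           n_labels = k),
                      class = "tkg_fusion")
  backbone_bi <- backbone
  backbone_bi$params <- de_params(obj$backbone_bi)
  gp_bi <- gp
  gp_bi$params <- de_params(obj$graph_params_bi)
  structure(list(scheme = scheme, config = cfg, backbone = backbone,
                 text_head = thead, graph_params = gp, graph_head = ghead,
                 fusion = fusion, backbone_bi = backbone_bi,
                 graph_params_bi = gp_bi,
                 vectors = word_vector_table(obj$d_w),
                 linker_kind = obj$linker_kind, seed = obj$seed,
                 logs = list()),
            class = "tkg_bundle")
}
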