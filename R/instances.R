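#' Build relation-classification instances from documents
#'
#' One instance per annotated (gold-provenance) relation: the pair of event
#' ids in annotation argument order plus the gold label. Candidate-pair
#' identification is out of scope; evaluation always runs on the annotated
#' pairs.
#'
#' @param docs list of `tkg_document`.
#' @return data.frame with columns `doc_id`, `e1`, `e2`, `gold`.
#' @export
build_instances <- function(docs) {
  rows <- lapply(docs, function(d) {
    rel <- d$relations
    rel <- rel[rel$provenance == "gold", , drop = FALSE]
    if (nrow(rel) == 0L) return(NULL)
    data.frame(doc_id = d$doc_id, e1 = rel$source, e2 = rel$target,
               gold = rel$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doc_id = character(), e1 = character(),
                      e2 = character(), gold = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Oversample instances to remove class imbalance
#'
#' Duplicates minority-class instances, drawn uniformly with replacement
#' under the given seed, until every class count equals the majority-class
#' count; the result is then shuffled deterministically.
#'
#' @param instances data.frame as from [build_instances()].
#' @param seed integer seed.
#' @return The balanced, shuffled data.frame.
#' @export
oversample_instances <- function(instances, seed) {
  counts <- table(instances$gold)
  if (any(counts == 0L) || nrow(instances) == 0L)
    stop_tkg("cannot balance: some class has zero instances")
  target <- max(counts)
  with_local_seed(seed, {
    idx <- unlist(lapply(names(counts), function(cl) {
      pool <- which(instances$gold == cl)
      extra <- target - length(pool)
      c(pool, if (extra > 0L) sample(pool, extra, replace = TRUE))
    }), use.names = FALSE)
    idx <- idx[sample.int(length(idx))]
  })
  out <- instances[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split documents into two training sets and a validation set
#'
#' Splitting is by document, never by relation, so no relation of a
#' document ever crosses partitions.
#'
#' @param docs list of documents.
#' @param fractions three proportions summing to 1.
#' @param seed integer seed.
#' @return Named list `train1`, `train2`, `val` of document lists.
#' @export
split_training_data <- function(docs, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop_tkg("fractions must be three proportions summing to 1")
  n <- length(docs)
  n1 <- round(n * fractions[[1L]])
  n2 <- round(n * fractions[[2L]])
  n3 <- n - n1 - n2
  if (n < sum(c(n1, n2, n3) > 0L) || n3 < 0L)
    stop_tkg("fewer documents (%d) than non-empty parts", n)
  perm <- with_local_seed(seed, sample.int(n))
  list(train1 = docs[perm[seq_len(n1)]],
       train2 = docs[perm[n1 + seq_len(n2)]],
       val = docs[perm[n1 + n2 + seq_len(n3)]])
}

#' Classification metrics: accuracy and micro-averaged P/R/F1
#'
#' Micro-averaging pools true positives, false positives and false
#' negatives over classes. When every instance receives exactly one
#' predicted label the pooled FP and FN totals coincide, so micro-F1
#' equals accuracy; both are reported for transparency.
#'
#' @param predictions,golds equal-length character vectors of labels.
#' @param scheme [label_scheme()].
#' @return List with `accuracy`, `micro_precision`, `micro_recall`,
#'   `micro_f1`, `n`, and a `per_class` data.frame of counts.
#' @export
compute_metrics <- function(predictions, golds, scheme = label_scheme()) {
  if (length(predictions) != length(golds))
    stop_tkg("predictions (%d) and golds (%d) differ in length",
             length(predictions), length(golds))
  labs <- scheme$labels
  pred <- factor(predictions, levels = labs)
  gold <- factor(golds, levels = labs)
  cm <- table(gold = gold, pred = pred)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  stp <- sum(tp); sfp <- sum(fp); sfn <- sum(fn)
  prec <- if (stp + sfp > 0) stp / (stp + sfp) else 0
  rec <- if (stp + sfn > 0) stp / (stp + sfn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = mean(pred == gold),
       micro_precision = prec, micro_recall = rec, micro_f1 = f1,
       n = length(golds),
       per_class = data.frame(label = labs, support = as.integer(rowSums(cm)),
                              predicted = as.integer(colSums(cm)),
                              correct = as.integer(tp),
                              stringsAsFactors = FALSE),
       confusion = cm)
}
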