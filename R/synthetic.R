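#' Configuration for the synthetic clinical-corpus generator
#'
#' The generator emulates the statistical structure the bimodal extractor
#' needs: event mentions linkable to a shared concept vocabulary, gold
#' relations derived from latent event time intervals, and a controllable
#' fraction of relations that are textually cued versus inferable only
#' through the graph. Each concept has a canonical position on a bounded
#' timeline (its typical place in a clinical course); an event's realised
#' start is the concept position plus Gaussian jitter, and its duration is
#' log-normal. Narrative order is randomised, so sentence position carries
#' no temporal signal; only connective cue words (and, for the graph
#' branch, the document's other relations) do.
#'
#' @param n_docs number of documents.
#' @param events_per_doc integer `c(min, max)` events per document.
#' @param concept_count size of the shared concept vocabulary.
#' @param cue_probability probability that a narrative-adjacent pair's
#'   sentence carries a connective consistent with the gold relation;
#'   otherwise a neutral connective is used.
#' @param long_range_pairs_per_doc extra annotated pairs between
#'   non-adjacent mentions, always rendered without cues.
#' @param horizon canonical concept positions are uniform on `[0, horizon]`
#'   (arbitrary time units).
#' @param jitter_sd standard deviation of the per-event start jitter.
#' @param duration_meanlog,duration_sdlog log-normal duration parameters.
#' @param modifier_probability probability that a mention surface carries a
#'   severity modifier in front of the canonical name.
#' @param seed integer seed; the whole corpus is a pure function of the
#'   configuration.
#' @return Object of class `tkg_gen_config`.
#' @export
generator_config <- function(n_docs = 200L,
                             events_per_doc = c(5L, 8L),
                             concept_count = 40L,
                             cue_probability = 0.7,
                             long_range_pairs_per_doc = 2L,
                             horizon = 20,
                             jitter_sd = 1.0,
                             duration_meanlog = 0.7,
                             duration_sdlog = 0.6,
                             modifier_probability = 0.2,
                             seed = 1L) {
  stopifnot(n_docs >= 1L, length(events_per_doc) == 2L,
            events_per_doc[1L] >= 2L,
            events_per_doc[2L] >= events_per_doc[1L],
            concept_count >= 1L,
            cue_probability >= 0, cue_probability <= 1,
            long_range_pairs_per_doc >= 0L,
            modifier_probability >= 0, modifier_probability <= 1,
            horizon > 0, jitter_sd >= 0)
  structure(as.list(environment()), class = "tkg_gen_config")
}

# Connective lexicons. Cue words are unambiguous single tokens describing
# the relation (previous event, current event); neutral connectives carry
# no temporal information.
cue_words <- c(BEFORE = "Subsequently", AFTER = "Previously",
               OVERLAP = "Concurrently")
neutral_words <- c("Additionally", "Notably")

.adjectives <- c("acute", "chronic", "renal", "hepatic", "cardiac",
                 "febrile", "nocturnal", "persistent", "painless",
                 "bilateral", "focal", "diffuse")
.nouns <- c("anemia", "jaundice", "biopsy", "dialysis", "seizure",
            "infusion", "lavage", "stenosis", "embolism", "fibrosis",
            "edema", "tachycardia", "lesion", "resection", "angiography")
.modifiers <- c("severe", "mild", "recurrent")

# Shared concept vocabulary: unique adjective-noun names, UMLS-style ids,
# a canonical timeline position each, and Zipf-like sampling weights so
# frequent concepts become hub nodes after consolidation.
sample_concepts <- function(config) {
  combos <- expand.grid(adj = .adjectives, noun = .nouns,
                        stringsAsFactors = FALSE)
  if (config$concept_count > nrow(combos))
    stop_tkg("concept_count exceeds available name combinations (%d)",
             nrow(combos))
  pick <- sample.int(nrow(combos), config$concept_count)
  data.frame(
    concept_id = sprintf("C%07d", seq_len(config$concept_count)),
    canonical_name = paste(combos$adj[pick], combos$noun[pick]),
    position = runif(config$concept_count, 0, config$horizon),
    weight = 1 / seq_len(config$concept_count),
    stringsAsFactors = FALSE)
}

#' Relation label implied by two latent time intervals
#'
#' `BEFORE` if `a` ends strictly before `b` starts, `AFTER` if `a` starts
#' strictly after `b` ends, `OVERLAP` otherwise. Antisymmetric: swapping
#' the arguments maps BEFORE and AFTER onto each other and fixes OVERLAP.
#'
#' @param a,b numeric `c(start, end)` with `start < end`.
#' @return A label string.
#' @export
derive_interval_relation <- function(a, b) {
  stopifnot(a[1L] < a[2L], b[1L] < b[2L])
  if (a[2L] < b[1L]) "BEFORE"
  else if (a[1L] > b[2L]) "AFTER"
  else "OVERLAP"
}

#' Sample a latent event timeline for one document
#'
#' Draws distinct concepts (Zipf-weighted, so the same concepts recur
#' across documents) and realises start times and durations. Draws from
#' the current RNG stream; [generate_corpus()] seeds it.
#'
#' @param config a [generator_config()].
#' @param concepts concept table from the generator (internal callers pass
#'   it; defaults to sampling a fresh one).
#' @return data.frame of latent events: `id`, `concept_id`,
#'   `canonical_name`, `t_start`, `t_end`.
#' @export
sample_timeline <- function(config, concepts = NULL) {
  if (is.null(concepts)) concepts <- sample_concepts(config)
  n_ev <- if (config$events_per_doc[1L] == config$events_per_doc[2L])
    config$events_per_doc[1L]
  else sample(seq(config$events_per_doc[1L], config$events_per_doc[2L]), 1L)
  n_ev <- min(n_ev, nrow(concepts))
  picks <- sample.int(nrow(concepts), n_ev, prob = concepts$weight)
  starts <- concepts$position[picks] + rnorm(n_ev, 0, config$jitter_sd)
  durs <- stats::rlnorm(n_ev, config$duration_meanlog, config$duration_sdlog)
  data.frame(id = sprintf("E%d", seq_len(n_ev)),
             concept_id = concepts$concept_id[picks],
             canonical_name = concepts$canonical_name[picks],
             t_start = starts, t_end = starts + durs,
             stringsAsFactors = FALSE)
}

sentence_frames <- c("%s , %s was noted .", "%s , %s was documented .",
                     "%s , %s occurred .")

#' Render a latent timeline as an annotated document
#'
#' Events are mentioned one per sentence in randomised narrative order.
#' Annotated pairs are the narrative-adjacent pairs plus
#' `long_range_pairs_per_doc` random distant pairs; adjacent pairs carry a
#' relation-consistent connective with probability `cue_probability` (else
#' a neutral one), long-range pairs are always cue-free. Gold labels come
#' from [derive_interval_relation()] on the latent intervals; character
#' offsets are exact.
#'
#' @param timeline data.frame from [sample_timeline()].
#' @param config a [generator_config()].
#' @param doc_id document id.
#' @param scheme label scheme.
#' @return A `tkg_document`.
#' @export
render_document <- function(timeline, config, doc_id = "doc1",
                            scheme = label_scheme()) {
  n <- nrow(timeline)
  stopifnot(n >= 1L)
  order_idx <- sample.int(n)          # narrative order
  tl <- timeline[order_idx, , drop = FALSE]
  surfaces <- vapply(seq_len(n), function(i) {
    if (runif(1) < config$modifier_probability)
      paste(sample(.modifiers, 1L), tl$canonical_name[i])
    else tl$canonical_name[i]
  }, "")
  interval <- function(i) c(tl$t_start[i], tl$t_end[i])
  text <- ""
  starts <- integer(n); ends <- integer(n)
  append_sentence <- function(prefix, surf, suffix) {
    sent <- paste0(prefix, surf, suffix)
    if (nzchar(text)) text <<- paste0(text, " ")
    off <- nchar(text)
    text <<- paste0(text, sent)
    c(off + nchar(prefix), off + nchar(prefix) + nchar(surf))
  }
  sp <- append_sentence("The patient presented with ", surfaces[1L], " .")
  starts[1L] <- sp[1L]; ends[1L] <- sp[2L]
  labels_adj <- character(max(n - 1L, 0L))
  for (i in seq_len(n)[-1L]) {
    lab <- derive_interval_relation(interval(i - 1L), interval(i))
    labels_adj[i - 1L] <- lab
    cued <- runif(1) < config$cue_probability
    conn <- if (cued) cue_words[[lab]] else sample(neutral_words, 1L)
    frame <- sample(sentence_frames, 1L)
    pieces <- strsplit(sprintf(frame, conn, "\01"), "\01", fixed = TRUE)[[1L]]
    sp <- append_sentence(pieces[[1L]], surfaces[i], pieces[[2L]])
    starts[i] <- sp[1L]; ends[i] <- sp[2L]
  }
  events <- data.frame(id = tl$id, start = starts, end = ends,
                       surface = surfaces, concept_id = tl$concept_id,
                       canonical_name = tl$canonical_name,
                       stringsAsFactors = FALSE)
  rels <- if (n >= 2L)
    data.frame(source = tl$id[seq_len(n - 1L)], target = tl$id[-1L],
               label = labels_adj, provenance = "gold",
               stringsAsFactors = FALSE)
  else NULL
  # long-range pairs: narrative distance >= 2, no cue by construction
  if (config$long_range_pairs_per_doc > 0L && n >= 3L) {
    cand <- expand.grid(i = seq_len(n), j = seq_len(n))
    cand <- cand[cand$j - cand$i >= 2L, , drop = FALSE]
    k <- min(config$long_range_pairs_per_doc, nrow(cand))
    pick <- cand[sample.int(nrow(cand), k), , drop = FALSE]
    lr <- data.frame(
      source = tl$id[pick$i], target = tl$id[pick$j],
      label = vapply(seq_len(k), function(r)
        derive_interval_relation(interval(pick$i[r]), interval(pick$j[r])), ""),
      provenance = "gold", stringsAsFactors = FALSE)
    rels <- rbind(rels, lr)
  }
  attr_doc <- document(doc_id, text, events, rels, scheme)
  attr(attr_doc, "latent") <- data.frame(
    id = tl$id, concept_id = tl$concept_id, t_start = tl$t_start,
    t_end = tl$t_end, stringsAsFactors = FALSE)
  attr_doc
}

#' Generate a synthetic annotated corpus
#'
#' Fully deterministic under `config$seed`. Returns the documents, the
#' surface-to-concept lexicon actually used, and a latent-truth sidecar
#' (the per-document event intervals) meant only for oracle tests — it is
#' never an input to any model stage.
#'
#' @param config a [generator_config()].
#' @param scheme label scheme.
#' @return List with `documents`, `lexicon` (data.frame `surface`,
#'   `concept_id`, `canonical_name`), `concepts`, and `latent` (data.frame
#'   keyed by `doc_id` and event `id`).
#' @export
generate_corpus <- function(config = generator_config(),
                            scheme = label_scheme()) {
  with_local_seed(config$seed, {
    concepts <- sample_concepts(config)
    docs <- vector("list", config$n_docs)
    latents <- vector("list", config$n_docs)
    for (d in seq_len(config$n_docs)) {
      tl <- sample_timeline(config, concepts)
      doc <- render_document(tl, config, doc_id = sprintf("doc%04d", d),
                             scheme = scheme)
      latents[[d]] <- cbind(doc_id = doc$doc_id, attr(doc, "latent"))
      attr(doc, "latent") <- NULL
      docs[[d]] <- doc
    }
    lex_surfaces <- unique(c(
      concepts$canonical_name,
      unlist(lapply(docs, function(d) d$events$surface), use.names = FALSE)))
    lex <- do.call(rbind, lapply(lex_surfaces, function(s) {
      hit <- concepts[concepts$canonical_name ==
                        sub(paste0("^(", paste(.modifiers, collapse = "|"),
                                   ") "), "", s), , drop = FALSE]
      if (nrow(hit) == 0L) return(NULL)
      data.frame(surface = s, concept_id = hit$concept_id[1L],
                 canonical_name = hit$canonical_name[1L],
                 stringsAsFactors = FALSE)
    }))
    # the canonical lexicon carries only canonical names; modified surfaces
    # exercise the linker's subsequence matching instead
    lex <- lex[lex$surface == lex$canonical_name, , drop = FALSE]
    rownames(lex) <- NULL
    list(documents = docs, lexicon = lex, concepts = concepts,
         latent = do.call(rbind, latents))
  })
}

#' Write the latent-truth sidecar as JSONL
#'
#' @param latent the `latent` element of [generate_corpus()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_latent_sidecar <- function(latent, path) {
  lines <- vapply(split(latent, latent$doc_id), function(df) {
    jsonlite::toJSON(list(doc_id = df$doc_id[[1L]],
                          events = df[, c("id", "concept_id", "t_start",
                                          "t_end")]),
                     auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a latent-truth sidecar
#'
#' @param path JSONL path written by [write_latent_sidecar()].
#' @return data.frame with `doc_id`, `id`, `concept_id`, `t_start`, `t_end`.
#' @export
read_latent_sidecar <- function(path) {
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  do.call(rbind, lapply(recs, function(r)
    cbind(doc_id = r$doc_id, r$events)))
}
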