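#' Normalize a mention surface form
#'
#' Lowercases, collapses internal whitespace, and strips leading/trailing
#' punctuation and whitespace. Idempotent.
#'
#' @param surface character vector.
#' @return Normalized character vector.
#' @export
normalize_mention <- function(surface) {
  x <- tolower(surface)
  x <- gsub("\\s+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  x
}

#' Concept lexicon mapping surface forms to concept identifiers
#'
#' The stand-in for a terminology-backed linker: a dictionary from
#' normalized surface phrases to (concept id, canonical name). Lookup is
#' deterministic.
#'
#' @param entries data.frame with columns `surface`, `concept_id`,
#'   `canonical_name`.
#' @return Object of class `tkg_lexicon`.
#' @export
concept_lexicon <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("surface", "concept_id", "canonical_name") %in%
                  names(entries)))
  if (any(!nzchar(entries$concept_id)))
    stop_tkg("empty concept_id in lexicon")
  entries$key <- normalize_mention(entries$surface)
  entries <- entries[!duplicated(entries$key), , drop = FALSE]
  entries <- entries[order(entries$key), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 key_tokens = strsplit(entries$key, " ", fixed = TRUE)),
            class = "tkg_lexicon")
}

#' Read / write a lexicon TSV (surface, concept_id, canonical_name)
#'
#' @param path TSV path.
#' @return For the reader, a `tkg_lexicon`; the writer returns `path`.
#' @export
read_lexicon <- function(path) {
  concept_lexicon(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_lexicon
#' @param lexicon a `tkg_lexicon` or its entries data.frame.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- if (inherits(lexicon, "tkg_lexicon")) lexicon$entries else lexicon
  utils::write.table(df[, c("surface", "concept_id", "canonical_name")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# tokens of `key` appear, in order, within `mention_tokens`?
is_subsequence <- function(key_tokens, mention_tokens) {
  pos <- 0L
  for (t in key_tokens) {
    hits <- which(mention_tokens == t)
    hits <- hits[hits > pos]
    if (!length(hits)) return(FALSE)
    pos <- hits[[1L]]
  }
  TRUE
}

#' Link one mention to a concept
#'
#' Exact normalized-surface match wins; otherwise the lexicon key with the
#' longest token subsequence contained in the mention; otherwise no link.
#' Ties break deterministically by lexicographic concept id. Linking is
#' context-free by design: it sees only the event phrase, which is the
#' documented failure mode for generic phrases.
#'
#' @param mention an event row (with `$surface`) or a character surface.
#' @param lexicon a [concept_lexicon()].
#' @return List `(concept_id, canonical_name)` or `NULL` for no-link.
#' @export
link_mention <- function(mention, lexicon) {
  surface <- if (is.character(mention)) mention else mention$surface
  key <- normalize_mention(surface)
  ex <- which(lexicon$entries$key == key)
  if (length(ex)) {
    hit <- lexicon$entries[ex[[1L]], ]
    return(list(concept_id = hit$concept_id,
                canonical_name = hit$canonical_name))
  }
  mt <- strsplit(key, " ", fixed = TRUE)[[1L]]
  lens <- lengths(lexicon$key_tokens)
  cand <- which(vapply(seq_along(lens), function(i)
    lens[[i]] <= length(mt) && is_subsequence(lexicon$key_tokens[[i]], mt),
    TRUE))
  if (!length(cand)) return(NULL)
  best_len <- max(lens[cand])
  cand <- cand[lens[cand] == best_len]
  cand <- cand[order(lexicon$entries$concept_id[cand])][[1L]]
  hit <- lexicon$entries[cand, ]
  list(concept_id = hit$concept_id, canonical_name = hit$canonical_name)
}

#' Entity linkers
#'
#' Linkers map event mentions to concepts. Two implementations are
#' bundled: `dictionary_linker()` wraps [link_mention()] over a
#' [concept_lexicon()]; `passthrough_linker()` trusts `concept_id` fields
#' already present on the events (as emitted by the synthetic generator or
#' an upstream terminology pipeline). A terminology-server-backed linker is
#' an extension point: any function `(surface) -> list(concept_id,
#' canonical_name) | NULL` works.
#'
#' @param lexicon a [concept_lexicon()].
#' @return A linker object of class `tkg_linker`.
#' @export
dictionary_linker <- function(lexicon) {
  structure(list(kind = "dictionary",
                 link = function(event_row)
                   link_mention(event_row$surface, lexicon)),
            class = "tkg_linker")
}

#' @rdname dictionary_linker
#' @export
passthrough_linker <- function() {
  structure(list(kind = "passthrough",
                 link = function(event_row) {
                   if (is.na(event_row$concept_id)) return(NULL)
                   list(concept_id = event_row$concept_id,
                        canonical_name =
                          if (is.na(event_row$canonical_name))
                            event_row$concept_id
                          else event_row$canonical_name)
                 }),
            class = "tkg_linker")
}

#' Consolidate same-concept event mentions into graph nodes
#'
#' Links every event in every document and groups mentions by concept: one
#' node per distinct concept id across all input documents. Unlinked
#' mentions fall back to a pseudo-concept keyed by their normalized
#' surface, so every event is always representable as a node. Node ids are
#' assigned canonically (sorted concept key), making the result
#' independent of document order.
#'
#' @param docs list of `tkg_document`.
#' @param linker a `tkg_linker` (default pass-through).
#' @return List with `nodes` (data.frame `node_id`, `concept_id`,
#'   `canonical_name`, `mention_count`) and `node_map` (data.frame
#'   `doc_id`, `event_id`, `node_id`).
#' @export
consolidate_events <- function(docs, linker = passthrough_linker()) {
  rows <- list()
  for (d in docs) {
    for (i in seq_len(nrow(d$events))) {
      ev <- d$events[i, ]
      hit <- linker$link(ev)
      if (is.null(hit)) {
        key <- paste0("SURF:", normalize_mention(ev$surface))
        hit <- list(concept_id = key,
                    canonical_name = normalize_mention(ev$surface))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = d$doc_id, event_id = ev$id, concept_id = hit$concept_id,
        canonical_name = hit$canonical_name, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(list(nodes = data.frame(node_id = character(),
                                   concept_id = character(),
                                   canonical_name = character(),
                                   mention_count = integer(),
                                   stringsAsFactors = FALSE),
                node_map = data.frame(doc_id = character(),
                                      event_id = character(),
                                      node_id = character(),
                                      stringsAsFactors = FALSE)))
  }
  all_rows <- do.call(rbind, rows)
  concepts <- sort(unique(all_rows$concept_id))
  nodes <- data.frame(
    node_id = sprintf("N%04d", seq_along(concepts)),
    concept_id = concepts,
    canonical_name = vapply(concepts, function(cid)
      all_rows$canonical_name[match(cid, all_rows$concept_id)], ""),
    mention_count = as.integer(table(factor(all_rows$concept_id,
                                            levels = concepts))),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  node_map <- data.frame(
    doc_id = all_rows$doc_id, event_id = all_rows$event_id,
    node_id = nodes$node_id[match(all_rows$concept_id, nodes$concept_id)],
    stringsAsFactors = FALSE)
  list(nodes = nodes, node_map = node_map)
}
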