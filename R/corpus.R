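#' Construct an annotated document
#'
#' A document couples raw text with gold event spans and pairwise temporal
#' relations. Offsets are 0-based, half-open character offsets into `text`;
#' each event's `surface` must equal `substr(text, start + 1, end)` and is
#' enforced on construction and on load.
#'
#' @param doc_id document identifier.
#' @param text document text.
#' @param events data.frame with columns `id`, `start`, `end`, `surface`
#'   and optionally `concept_id`, `canonical_name`.
#' @param relations data.frame with columns `source`, `target`, `label` and
#'   optionally `provenance` (gold/inverse/transitive/predicted) and a
#'   `confidence` list-column of probability vectors over the scheme.
#' @param scheme label scheme used to validate relation labels
#'   (`NULL` skips label validation).
#' @return Object of class `tkg_document`.
#' @export
document <- function(doc_id, text, events, relations = NULL, scheme = NULL) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  for (col in c("concept_id", "canonical_name"))
    if (is.null(events[[col]])) events[[col]] <- NA_character_
  if (is.null(relations) || NROW(relations) == 0L) {
    relations <- data.frame(source = character(), target = character(),
                            label = character(), provenance = character(),
                            stringsAsFactors = FALSE)
    relations$confidence <- list()
  } else {
    relations <- as.data.frame(relations, stringsAsFactors = FALSE)
    if (is.null(relations$provenance)) relations$provenance <- "gold"
    relations$provenance[is.na(relations$provenance)] <- "gold"
    if (is.null(relations$confidence))
      relations$confidence <- replicate(nrow(relations), NULL, simplify = FALSE)
  }
  doc <- structure(list(doc_id = doc_id, text = text, events = events,
                        relations = relations), class = "tkg_document")
  validate_document(doc, scheme)
  doc
}

#' Validate a document's invariants
#'
#' Checks offset bounds, surface/offset consistency, event-id uniqueness,
#' relation endpoints, self-relations, and (when a scheme is given) label
#' membership and confidence-vector coherence.
#'
#' @param doc a `tkg_document`.
#' @param scheme optional [label_scheme()].
#' @return `doc`, invisibly; errors name the offending document and ids.
#' @export
validate_document <- function(doc, scheme = NULL) {
  ev <- doc$events
  if (anyDuplicated(ev$id))
    stop_tkg("doc '%s': duplicate event ids", doc$doc_id)
  n <- nchar(doc$text)
  for (i in seq_len(nrow(ev))) {
    s <- ev$start[i]; e <- ev$end[i]
    if (!(s >= 0 && s < e && e <= n))
      stop_tkg("doc '%s': event '%s' offsets [%d,%d) out of bounds",
               doc$doc_id, ev$id[i], s, e)
    got <- substr(doc$text, s + 1L, e)
    if (!identical(got, ev$surface[i]))
      stop_tkg("doc '%s': event '%s' surface '%s' != text span '%s'",
               doc$doc_id, ev$id[i], ev$surface[i], got)
  }
  rel <- doc$relations
  for (i in seq_len(nrow(rel))) {
    for (side in c("source", "target")) {
      if (!rel[[side]][i] %in% ev$id)
        stop_tkg("doc '%s': relation %d references missing event id '%s'",
                 doc$doc_id, i, rel[[side]][i])
    }
    if (rel$source[i] == rel$target[i])
      stop_tkg("doc '%s': relation %d relates event '%s' to itself",
               doc$doc_id, i, rel$source[i])
    if (!is.null(scheme)) {
      if (!rel$label[i] %in% scheme$labels)
        stop_tkg("doc '%s': unknown relation label '%s'", doc$doc_id,
                 rel$label[i])
      cv <- rel$confidence[[i]]
      if (!is.null(cv)) {
        if (length(cv) != length(scheme$labels) || abs(sum(cv) - 1) > 1e-6)
          stop_tkg("doc '%s': relation %d confidence vector malformed",
                   doc$doc_id, i)
        if (scheme$labels[which.max(cv)] != rel$label[i])
          stop_tkg("doc '%s': relation %d label disagrees with confidence argmax",
                   doc$doc_id, i)
      }
    }
  }
  invisible(doc)
}

#' @export
print.tkg_document <- function(x, ...) {
  cat(sprintf("<tkg_document '%s'> %d chars, %d events, %d relations\n",
              x$doc_id, nchar(x$text), nrow(x$events), nrow(x$relations)))
  invisible(x)
}

doc_to_record <- function(doc) {
  ev <- lapply(seq_len(nrow(doc$events)), function(i) {
    e <- doc$events[i, ]
    r <- list(id = e$id, start = e$start, end = e$end, text = e$surface)
    if (!is.na(e$concept_id)) r$concept_id <- e$concept_id
    if (!is.na(e$canonical_name)) r$canonical_name <- e$canonical_name
    r
  })
  rel <- lapply(seq_len(nrow(doc$relations)), function(i) {
    r <- doc$relations[i, ]
    out <- list(source = r$source, target = r$target, label = r$label,
                provenance = r$provenance)
    cv <- r$confidence[[1L]]
    if (!is.null(cv)) out$confidence <- as.numeric(cv)
    out
  })
  list(doc_id = doc$doc_id, text = doc$text, events = ev, relations = rel)
}

record_to_doc <- function(rec, scheme, line = NA_integer_) {
  where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  need <- function(x, f) {
    if (is.null(x[[f]])) stop_tkg("JSONL record missing field '%s'%s", f, where)
    x[[f]]
  }
  events <- data.frame(
    id = vapply(rec$events, function(e) as.character(need(e, "id")), ""),
    start = vapply(rec$events, function(e) as.integer(need(e, "start")), 0L),
    end = vapply(rec$events, function(e) as.integer(need(e, "end")), 0L),
    surface = vapply(rec$events, function(e) as.character(need(e, "text")), ""),
    concept_id = vapply(rec$events, function(e)
      as.character(e$concept_id %||% NA_character_), ""),
    canonical_name = vapply(rec$events, function(e)
      as.character(e$canonical_name %||% NA_character_), ""),
    stringsAsFactors = FALSE)
  rels <- NULL
  if (length(rec$relations)) {
    rels <- data.frame(
      source = vapply(rec$relations, function(r) as.character(need(r, "source")), ""),
      target = vapply(rec$relations, function(r) as.character(need(r, "target")), ""),
      label = vapply(rec$relations, function(r) as.character(need(r, "label")), ""),
      provenance = vapply(rec$relations, function(r)
        as.character(r$provenance %||% "gold"), ""),
      stringsAsFactors = FALSE)
    rels$confidence <- lapply(rec$relations, function(r)
      if (is.null(r$confidence)) NULL else as.numeric(r$confidence))
  }
  document(need(rec, "doc_id"), need(rec, "text"), events, rels, scheme)
}

#' Read a corpus from canonical JSONL
#'
#' One JSON object per line:
#' `{"doc_id", "text", "events":[{"id","start","end","text","concept_id"?}],
#'   "relations":[{"source","target","label","provenance"?,"confidence"?}]}`.
#' Every document is validated on load; malformed lines raise an error
#' naming the line number, invariant violations name the `doc_id`.
#'
#' @param path file path.
#' @param scheme [label_scheme()] for relation-label validation.
#' @return List of `tkg_document`.
#' @export
read_jsonl_corpus <- function(path, scheme = label_scheme()) {
  if (!file.exists(path)) stop_tkg("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e)
                      stop_tkg("parse error at line %d: %s", i, conditionMessage(e)))
    out[[i]] <- record_to_doc(rec, scheme, line = i)
  }
  out
}

#' Write a corpus to canonical JSONL
#'
#' @param docs list of `tkg_document`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jsonl_corpus <- function(docs, path) {
  lines <- vapply(docs, function(d)
    jsonlite::toJSON(doc_to_record(d), auto_unbox = TRUE, digits = NA), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BRAT standoff document
#'
#' Expects T-lines for event spans (`T1\tEVENT 12 19\tvisited`) and R-lines
#' for binary relations (`R1\tBEFORE Arg1:T1 Arg2:T2`). Discontinuous spans
#' (offsets containing `;`) are rejected. Offsets are taken verbatim and
#' checked against the text.
#'
#' @param txt_path path to the `.txt` file.
#' @param ann_path path to the `.ann` file.
#' @param scheme [label_scheme()].
#' @param doc_id identifier; default is the `.txt` basename.
#' @return A `tkg_document`.
#' @export
read_brat_document <- function(txt_path, ann_path, scheme = label_scheme(),
                               doc_id = NULL) {
  text <- paste(readLines(txt_path, warn = FALSE), collapse = "\n")
  doc_id <- doc_id %||% sub("\\.txt$", "", basename(txt_path))
  ann <- readLines(ann_path, warn = FALSE)
  ann <- ann[nzchar(trimws(ann))]
  tl <- ann[startsWith(ann, "T")]
  rl <- ann[startsWith(ann, "R")]
  events <- do.call(rbind, lapply(tl, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop_tkg("malformed T-line: %s", line)
    meta <- strsplit(parts[[2L]], " ", fixed = TRUE)[[1L]]
    if (grepl(";", parts[[2L]], fixed = TRUE))
      stop_tkg("discontinuous span not supported: %s", line)
    data.frame(id = parts[[1L]], start = as.integer(meta[[2L]]),
               end = as.integer(meta[[3L]]), surface = parts[[3L]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(events))
    events <- data.frame(id = character(), start = integer(), end = integer(),
                         surface = character(), stringsAsFactors = FALSE)
  rels <- NULL
  if (length(rl)) {
    rels <- do.call(rbind, lapply(rl, function(line) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      fields <- strsplit(parts[[2L]], " ", fixed = TRUE)[[1L]]
      lab <- fields[[1L]]
      a1 <- sub("^Arg1:", "", fields[[2L]])
      a2 <- sub("^Arg2:", "", fields[[3L]])
      if (!lab %in% scheme$labels)
        stop_tkg("BRAT relation label '%s' not in scheme", lab)
      if (!a1 %in% events$id || !a2 %in% events$id)
        stop_tkg("BRAT relation %s cites unknown T id", parts[[1L]])
      data.frame(source = a1, target = a2, label = lab,
                 provenance = "gold", stringsAsFactors = FALSE)
    }))
  }
  document(doc_id, text, events, rels, scheme)
}

#' Write a document as BRAT standoff
#'
#' @param doc a `tkg_document`.
#' @param txt_path,ann_path output paths.
#' @return `ann_path`, invisibly.
#' @export
write_brat_document <- function(doc, txt_path, ann_path) {
  writeLines(doc$text, txt_path, sep = "")
  t_ids <- stats::setNames(sprintf("T%d", seq_len(nrow(doc$events))),
                           doc$events$id)
  t_lines <- vapply(seq_len(nrow(doc$events)), function(i) {
    e <- doc$events[i, ]
    sprintf("%s\tEVENT %d %d\t%s", t_ids[[e$id]], e$start, e$end, e$surface)
  }, "")
  r_lines <- vapply(seq_len(nrow(doc$relations)), function(i) {
    r <- doc$relations[i, ]
    sprintf("R%d\t%s Arg1:%s Arg2:%s", i, r$label, t_ids[[r$source]],
            t_ids[[r$target]])
  }, "")
  writeLines(c(t_lines, r_lines), ann_path)
  invisible(ann_path)
}
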