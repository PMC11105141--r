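#' Relation label schemes
#'
#' A label scheme is the vocabulary of temporal relation labels together
#' with its inverse map (the label obtained when the two arguments of a
#' relation are swapped) and a composition table used for transitive
#' enrichment. The default scheme is the three-class clinical inventory
#' `BEFORE`, `AFTER`, `OVERLAP` with `BEFORE <-> AFTER` and `OVERLAP`
#' self-inverse.
#'
#' @param labels character vector of relation names (order fixes the
#'   classifier head layout and probability-vector layout).
#' @param inverse_map named character vector mapping each label to its
#'   inverse; must be an involution.
#' @param composition preset name (see [composition_table()]) or a labelled
#'   square character matrix with `NA` for "no unambiguous composition".
#' @return An object of class `tkg_scheme`.
#' @export
#' @examples
#' sch <- label_scheme()
#' scheme_inverse(sch, "BEFORE")
label_scheme <- function(labels = c("BEFORE", "AFTER", "OVERLAP"),
                         inverse_map = c(BEFORE = "AFTER", AFTER = "BEFORE",
                                         OVERLAP = "OVERLAP"),
                         composition = "strict") {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop_tkg("duplicate labels in scheme")
  if (!setequal(names(inverse_map), labels))
    stop_tkg("inverse_map must cover exactly the scheme labels")
  if (!all(unname(inverse_map) %in% labels))
    stop_tkg("inverse_map values outside scheme")
  for (l in labels) {
    if (unname(inverse_map[[unname(inverse_map[[l]])]]) != l)
      stop_tkg("inverse_map is not an involution at label '%s'", l)
  }
  tab <- if (is.character(composition) && length(composition) == 1L)
    composition_table(composition, labels) else composition
  if (!is.matrix(tab) || !identical(rownames(tab), labels) ||
      !identical(colnames(tab), labels))
    stop_tkg("composition table must be a |labels| x |labels| labelled matrix")
  structure(list(labels = labels, inverse_map = inverse_map,
                 composition = tab,
                 preset = if (is.character(composition)) composition else "custom"),
            class = "tkg_scheme")
}

#' @export
print.tkg_scheme <- function(x, ...) {
  cat("<tkg_scheme> labels:", paste(x$labels, collapse = ", "),
      "| composition preset:", x$preset, "\n")
  invisible(x)
}

#' Inverse of a relation label
#'
#' @param scheme a [label_scheme()].
#' @param label a label in the scheme.
#' @return The inverse label.
#' @export
scheme_inverse <- function(scheme, label) {
  if (!label %in% scheme$labels) stop_tkg("unknown label '%s'", label)
  unname(scheme$inverse_map[[label]])
}

label_index <- function(scheme, label) match(label, scheme$labels)

# Permutation such that p[perm] is the probability vector of the inverse
# relation: entry for label l moves to position of inverse(l).
inverse_permutation <- function(scheme) {
  match(unname(scheme$inverse_map[scheme$labels]), scheme$labels)
}

#' Composition-table presets for transitive enrichment
#'
#' Two presets over the three-class scheme are bundled. `"strict"` keeps
#' only compositions sound under interval semantics without further
#' assumptions: BEFORE followed by BEFORE is BEFORE, AFTER followed by
#' AFTER is AFTER, everything else is ambiguous. `"approx"` additionally
#' treats OVERLAP as near-simultaneity, composing it through BEFORE/AFTER
#' and with itself.
#'
#' @param preset `"strict"` or `"approx"`.
#' @param labels label vector (must contain BEFORE, AFTER, OVERLAP for the
#'   bundled presets).
#' @return A labelled character matrix; `NA` entries mean "no edge inferred".
#' @export
composition_table <- function(preset = c("strict", "approx"),
                              labels = c("BEFORE", "AFTER", "OVERLAP")) {
  preset <- match.arg(preset)
  tab <- matrix(NA_character_, length(labels), length(labels),
                dimnames = list(labels, labels))
  if (!all(c("BEFORE", "AFTER", "OVERLAP") %in% labels))
    stop_tkg("bundled presets require the BEFORE/AFTER/OVERLAP labels")
  tab["BEFORE", "BEFORE"] <- "BEFORE"
  tab["AFTER", "AFTER"] <- "AFTER"
  if (preset == "approx") {
    tab["BEFORE", "OVERLAP"] <- "BEFORE"
    tab["OVERLAP", "BEFORE"] <- "BEFORE"
    tab["AFTER", "OVERLAP"] <- "AFTER"
    tab["OVERLAP", "AFTER"] <- "AFTER"
    tab["OVERLAP", "OVERLAP"] <- "OVERLAP"
  }
  tab
}

#' Compose two relation labels
#'
#' Looks up the composition of `(A l1 B)` and `(B l2 C)`; `NA` means the
#' composition is ambiguous (several interval configurations are possible)
#' and no edge is inferred.
#'
#' @param l1,l2 labels.
#' @param table composition matrix from [composition_table()] or a scheme's
#'   `$composition`.
#' @return A label or `NA_character_`.
#' @export
compose_labels <- function(l1, l2, table) {
  if (!l1 %in% rownames(table) || !l2 %in% colnames(table))
    stop_tkg("labels ('%s','%s') not covered by composition table", l1, l2)
  table[l1, l2]
}

#' Relabel corpus relations through a label mapping
#'
#' Applies a many-to-one label mapping to every relation in a corpus, e.g.
#' converting a fine-grained inventory (containment, initiation, ...) to
#' the basic three classes. Labels mapped to the sentinel `"drop"` are
#' removed. The bundled fine-grained-to-basic mapping ships as a TSV under
#' `inst/extdata/finegrained_to_basic.tsv`.
#'
#' @param docs list of documents.
#' @param mapping named character vector, `old -> new` (or `"drop"`).
#' @return List of documents with relabelled relations; attribute
#'   `"dropped"` records how many relations were removed.
#' @export
convert_labels <- function(docs, mapping) {
  dropped <- 0L
  out <- lapply(docs, function(d) {
    if (nrow(d$relations) == 0L) return(d)
    lab <- d$relations$label
    missing <- setdiff(unique(lab), names(mapping))
    if (length(missing))
      stop_tkg("convert_labels: no mapping for label '%s'", missing[[1L]])
    new <- unname(mapping[lab])
    keep <- new != "drop"
    dropped <<- dropped + sum(!keep)
    d$relations <- d$relations[keep, , drop = FALSE]
    d$relations$label <- new[keep]
    rownames(d$relations) <- NULL
    d
  })
  attr(out, "dropped") <- dropped
  out
}

#' Read a label mapping from a two-column TSV
#'
#' @param path TSV with columns `from`, `to` (header included).
#' @return Named character vector usable with [convert_labels()].
#' @export
read_label_mapping <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$to, df$from)
}
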