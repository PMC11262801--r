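#' Read a WCON-like label JSON file
#'
#' The label file mirrors the Worm tracker Commons Object Notation layout:
#' top-level keys `units`, `metadata`, `labels` (ordered names plus display
#' colours) and `data`, the latter one entry per larva with its `id`,
#' timestamp vector `t` and per-timestep `labels` lists (label names; an
#' empty list means untagged). Unknown top-level keys are preserved in the
#' returned object's `extra` passthrough field and written back by
#' [write_labels_json()].
#'
#' @param path Path to the JSON file.
#' @return A [label_set()].
#' @export
read_labels_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("units", "labels", "data")) {
    if (is.null(doc[[key]]))
      stop(sprintf("label file misses required key at $.%s", key))
  }
  if (is.null(doc$labels$names))
    stop("label file misses required key at $.labels.names")
  nm <- unlist(doc$labels$names)
  cols <- if (!is.null(doc$labels$colors)) unlist(doc$labels$colors)
          else action_dictionary(nm)$color
  dict <- data.frame(name = nm, color = cols, stringsAsFactors = FALSE)

  assignments <- list(); tvecs <- list(); prov <- character()
  offenders <- character(0)
  for (entry in doc$data) {
    if (is.null(entry$id))
      stop("label file misses required key at $.data[].id")
    id <- as.character(entry$id)
    tvecs[[id]] <- as.numeric(unlist(entry$t))
    lab <- lapply(entry$labels, function(step) {
      names_k <- unlist(step)
      if (is.null(names_k)) return(integer(0))
      idx <- match(names_k, dict$name)
      if (anyNA(idx))
        offenders <<- c(offenders, names_k[is.na(idx)])
      idx[!is.na(idx)]
    })
    assignments[[id]] <- lab
    prov[id] <- if (!is.null(entry$provenance)) entry$provenance else "imported"
  }
  if (length(offenders))
    stop(sprintf("labels reference undefined name(s): %s",
                 paste(unique(offenders), collapse = ", ")))
  known <- c("units", "metadata", "labels", "data")
  extra <- doc[setdiff(names(doc), known)]
  if (!is.null(doc$metadata)) extra[["metadata"]] <- doc$metadata
  label_set(dict, assignments, tvecs, prov, extra = extra)
}

#' Write a label set as WCON-like JSON
#'
#' Writes the canonical form: UTF-8, top-level and per-entry keys sorted,
#' label lists as arrays of label names, larvae sorted by id. Reading the
#' file back reproduces the label set exactly, and re-writing it reproduces
#' the file byte for byte.
#'
#' @param labels A [label_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels_json <- function(labels, path) {
  validate_label_set(labels)
  dict <- labels$dictionary
  ids <- names(labels$assignments)
  ids <- ids[order(as.integer(ids))]
  data_entries <- lapply(ids, function(id) {
    a <- labels$assignments[[id]]
    entry <- list(
      id = as.integer(id),
      labels = lapply(a, function(idx) as.list(dict$name[idx])),
      provenance = if (!is.na(labels$provenance[id])) labels$provenance[[id]]
                   else "imported",
      t = as.list(as.numeric(labels$t[[id]]))
    )
    entry[order(names(entry))]
  })
  doc <- list(
    data = data_entries,
    labels = list(colors = as.list(dict$color), names = as.list(dict$name)),
    units = list(t = "s")
  )
  extra <- labels$extra
  meta <- extra[["metadata"]]
  extra[["metadata"]] <- NULL
  doc$metadata <- if (is.null(meta)) stats::setNames(list(), character(0)) else meta
  for (key in names(extra)) doc[[key]] <- extra[[key]]
  doc <- doc[order(names(doc))]
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
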