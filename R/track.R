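#' Assay metadata
#'
#' Protocol-level metadata attached to every track of a behavioural assay:
#' an identifier, the stimulus onset and duration (e.g. an air puff delivered
#' at t = 45 s for 38 s in the screens this package models), an optional
#' frame-rate hint for formats that store frame indices rather than
#' timestamps, and a free-form key/value map.
#'
#' @param assay_id Character scalar identifying the assay.
#' @param stimulus_onset Stimulus onset in seconds, or `NULL`.
#' @param stimulus_duration Stimulus duration in seconds, or `NULL`.
#' @param frame_rate_hint Acquisition frame rate in Hz, or `NULL`.
#' @param extra Named character list of free-form metadata.
#'
#' @return An object of class `assay_metadata`.
#' @export
assay_metadata <- function(assay_id = "assay", stimulus_onset = NULL,
                           stimulus_duration = NULL, frame_rate_hint = NULL,
                           extra = list()) {
  if (!is.null(stimulus_onset) && stimulus_onset < 0)
    stop("stimulus_onset must be >= 0")
  if (!is.null(stimulus_duration) && stimulus_duration <= 0)
    stop("stimulus_duration must be > 0")
  structure(list(assay_id = as.character(assay_id),
                 stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration,
                 frame_rate_hint = frame_rate_hint,
                 extra = extra),
            class = "assay_metadata")
}

#' Single-larva track
#'
#' One larva's timestamped midline (spine) series, with an optional closed
#' contour per frame and assay metadata. The spine is stored head-first: row
#' `spine[i, 1, ]` is the head at frame `i`, row `spine[i, S, ]` the tail.
#'
#' @param larva_id Integer larva identifier.
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param spine Numeric array `T x S x 2` of planar spine coordinates
#'   (arena units; carried opaquely, normalization later removes scale).
#' @param outline Optional `T x C x 2` array of closed-contour coordinates.
#' @param assay An [assay_metadata()] object.
#'
#' @return An object of class `larva_track`.
#' @seealso [validate_track()]
#' @export
larva_track <- function(larva_id, t, spine, outline = NULL,
                        assay = assay_metadata()) {
  trk <- structure(list(larva_id = as.integer(larva_id),
                        t = as.numeric(t),
                        spine = spine,
                        outline = outline,
                        assay = assay),
                   class = "larva_track")
  validate_track(trk)
  trk
}

#' Validate a track against its structural invariants
#'
#' Checks the invariants every reader must guarantee: strictly increasing
#' timestamps, a constant number of spine points across frames, finite
#' coordinates, and a strictly positive body length at every frame.
#'
#' @param track A `larva_track`.
#' @return The track, invisibly; stops on violation.
#' @export
validate_track <- function(track) {
  stopifnot(inherits(track, "larva_track"))
  t <- track$t
  sp <- track$spine
  if (length(dim(sp)) != 3L || dim(sp)[3] != 2L)
    stop("spine must be a T x S x 2 array")
  if (dim(sp)[1] != length(t))
    stop("spine first dimension must match length(t)")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(!is.finite(sp)))
    stop("spine contains non-finite coordinates")
  bl <- body_lengths(sp)
  if (any(bl <= 0))
    stop("body length must be > 0 at every frame")
  invisible(track)
}

#' @export
print.larva_track <- function(x, ...) {
  d <- dim(x$spine)
  cat(sprintf("<larva_track> id=%d  T=%d frames  S=%d spine points  t=[%.3g, %.3g] s\n",
              x$larva_id, d[1], d[2], min(x$t), max(x$t)))
  invisible(x)
}

# Per-frame body length (sum of segment lengths) of a T x S x 2 spine array.
body_lengths <- function(spine) {
  S <- dim(spine)[2]
  if (S < 2L) return(rep(0, dim(spine)[1]))
  dx <- spine[, -1L, 1L, drop = FALSE] - spine[, -S, 1L, drop = FALSE]
  dy <- spine[, -1L, 2L, drop = FALSE] - spine[, -S, 2L, drop = FALSE]
  rowSums(sqrt(dx * dx + dy * dy))
}

#' Label set: per-track, per-timestep action labels
#'
#' Holds the ordered label dictionary (names plus display colours) and, per
#' larva, one list of label indices per timestep (an empty list means
#' untagged), together with a provenance flag per larva.
#'
#' @param dictionary Data frame with columns `name` and `color`; names must
#'   be unique.
#' @param assignments Named list (names = larva ids) of lists of integer
#'   vectors; element `[[i]][[k]]` holds the dictionary indices active for
#'   larva i at its k-th timestep.
#' @param t Named list of numeric timestamp vectors, parallel to
#'   `assignments`.
#' @param provenance Named character vector per larva, each one of
#'   `"manual"`, `"predicted"`, `"imported"`.
#' @param extra Passthrough list preserving unknown keys of a source file.
#'
#' @return An object of class `label_set`.
#' @export
label_set <- function(dictionary, assignments = list(), t = list(),
                      provenance = character(), extra = list()) {
  ls <- structure(list(dictionary = dictionary, assignments = assignments,
                       t = t, provenance = provenance, extra = extra),
                  class = "label_set")
  validate_label_set(ls)
  ls
}

#' Validate a label set
#'
#' @param labels A `label_set`.
#' @return The label set, invisibly; stops on violation.
#' @export
validate_label_set <- function(labels) {
  stopifnot(inherits(labels, "label_set"))
  d <- labels$dictionary
  if (!is.data.frame(d) || !all(c("name", "color") %in% names(d)))
    stop("dictionary must be a data.frame with columns name, color")
  if (anyDuplicated(d$name))
    stop("dictionary names must be unique")
  n <- nrow(d)
  for (id in names(labels$assignments)) {
    a <- labels$assignments[[id]]
    idx <- unlist(a, use.names = FALSE)
    if (length(idx) && (any(idx < 1L) || any(idx > n)))
      stop(sprintf("larva %s: label index out of dictionary range", id))
    if (!is.null(labels$t[[id]]) && length(labels$t[[id]]) != length(a))
      stop(sprintf("larva %s: timestamps and assignments differ in length", id))
  }
  invisible(labels)
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> %d labels (%s), %d larvae\n",
              nrow(x$dictionary), paste(x$dictionary$name, collapse = ", "),
              length(x$assignments)))
  invisible(x)
}

#' Default seven-class action dictionary
#'
#' The archetypal larval actions: forward crawl, head cast (bend), backward
#' crawl, hunch (rapid head retraction), roll, stop, plus a catch-all class
#' grouping small/weak versions of any action.
#'
#' @param names Ordered character vector of class names.
#' @param colors Optional display colours (hex); recycled defaults otherwise.
#' @return Data frame with columns `name`, `color`.
#' @export
action_dictionary <- function(names = c("crawl", "bend", "back", "hunch",
                                        "roll", "stop", "small_action"),
                              colors = NULL) {
  if (!length(names) || anyDuplicated(names))
    stop("action names must be non-empty and unique")
  defaults <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
                "#8c564b", "#7f7f7f", "#bcbd22", "#17becf")
  if (is.null(colors))
    colors <- rep_len(defaults, length(names))
  data.frame(name = as.character(names), color = as.character(colors),
             stringsAsFactors = FALSE)
}
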