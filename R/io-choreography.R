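#' Read Choreography-style spine (and outline) files
#'
#' Parses the whitespace-separated midline dialect emitted by Multi-Worm
#' Tracker / Choreography toolchains: one frame per line, `id t x1 y1 ...
#' xS yS`. The number of spine points S is free but must be constant within
#' a larva; it is inferred from each larva's first line and enforced. An
#' optional outline file shares the `id t` columns, followed by closed
#' contour coordinate pairs.
#'
#' Frames with unparseable or inconsistent coordinate counts are dropped
#' with a warning; duplicate timestamps keep the first occurrence.
#'
#' @param spine_path Path to the spine file.
#' @param outline_path Optional path to the matching outline file.
#' @param assay An [assay_metadata()] attached to every track.
#' @return List of [larva_track()] objects, one per distinct larva id,
#'   frames time-sorted.
#' @export
read_choreography <- function(spine_path, outline_path = NULL,
                              assay = assay_metadata()) {
  recs <- parse_frame_lines(spine_path)
  if (!length(recs)) return(list())
  tracks <- records_to_tracks(recs, what = "spine")
  if (!is.null(outline_path)) {
    orecs <- parse_frame_lines(outline_path)
    otracks <- records_to_tracks(orecs, what = "outline")
    omap <- stats::setNames(otracks, vapply(otracks, function(x) as.character(x$id),
                                            character(1)))
    for (i in seq_along(tracks)) {
      o <- omap[[as.character(tracks[[i]]$id)]]
      if (is.null(o)) next
      j <- match(round(tracks[[i]]$t, 9), round(o$t, 9))
      if (any(!is.na(j)))
        tracks[[i]]$outline <- o$coords[j, , , drop = FALSE]
    }
  }
  lapply(tracks, function(tr)
    larva_track(tr$id, tr$t, tr$coords, outline = tr$outline, assay = assay))
}

#' Write tracks as a Choreography-style spine (and outline) file
#'
#' Inverse of [read_choreography()]; coordinates are printed with enough
#' digits that a read/write round trip reproduces them to better than 1e-6.
#'
#' @param tracks List of `larva_track` objects.
#' @param spine_path Output path for the spine file.
#' @param outline_path Optional output path for the outline file; only
#'   tracks carrying an outline are written there.
#' @return Invisibly, `spine_path`.
#' @export
write_choreography <- function(tracks, spine_path, outline_path = NULL) {
  con <- file(spine_path, "w")
  on.exit(close(con), add = TRUE)
  ocon <- NULL
  if (!is.null(outline_path)) {
    ocon <- file(outline_path, "w")
    on.exit(close(ocon), add = TRUE)
  }
  fmt_row <- function(id, t, mat) {
    paste(id, format_num(t), paste(format_num(t(mat)), collapse = " "))
  }
  for (trk in tracks) {
    for (i in seq_along(trk$t)) {
      writeLines(fmt_row(trk$larva_id, trk$t[i], trk$spine[i, , ]), con)
      if (!is.null(ocon) && !is.null(trk$outline) &&
          all(is.finite(trk$outline[i, , ])))
        writeLines(fmt_row(trk$larva_id, trk$t[i], trk$outline[i, , ]), ocon)
    }
  }
  invisible(spine_path)
}

format_num <- function(x) formatC(x, format = "g", digits = 15)

# Parse "id t x1 y1 ..." lines into a list of records (id, t, xy vector).
parse_frame_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  bad <- 0L
  for (i in seq_along(lines)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]]))
    if (length(v) < 4L || any(is.na(v)) || length(v) %% 2L != 0L) {
      bad <- bad + 1L
      next
    }
    recs[[i]] <- list(id = as.integer(v[1]), t = v[2], xy = v[-(1:2)])
  }
  if (bad > 0L)
    warning(sprintf("%s: dropped %d unparseable line(s)", basename(path), bad))
  recs[!vapply(recs, is.null, logical(1))]
}

# Group records per larva id into time-sorted coordinate arrays.
records_to_tracks <- function(recs, what = "spine") {
  ids <- vapply(recs, `[[`, integer(1), "id")
  out <- list()
  for (id in unique(ids)) {
    sub <- recs[ids == id]
    npt <- length(sub[[1]]$xy) / 2L
    keep <- vapply(sub, function(r) length(r$xy) == 2L * npt, logical(1))
    if (any(!keep)) {
      warning(sprintf("larva %d: dropped %d frame(s) with inconsistent %s point count",
                      id, sum(!keep), what))
      sub <- sub[keep]
    }
    t <- vapply(sub, `[[`, numeric(1), "t")
    ord <- order(t)
    sub <- sub[ord]; t <- t[ord]
    dup <- duplicated(t)
    if (any(dup)) {
      warning(sprintf("larva %d: dropped %d duplicate timestamp(s), keeping first",
                      id, sum(dup)))
      sub <- sub[!dup]; t <- t[!dup]
    }
    coords <- array(NA_real_, c(length(sub), npt, 2L))
    for (i in seq_along(sub)) {
      xy <- sub[[i]]$xy
      coords[i, , 1L] <- xy[seq(1L, length(xy), by = 2L)]
      coords[i, , 2L] <- xy[seq(2L, length(xy), by = 2L)]
    }
    out[[length(out) + 1L]] <- list(id = id, t = t, coords = coords,
                                    outline = NULL)
  }
  out
}
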