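#' Read a FIMTrack-style table.csv
#'
#' Parses the semicolon-separated feature table dialect used by FIMTrack v2:
#' the first column holds feature keys, the remaining columns one larva
#' each. Spine coordinates live in rows keyed `spine_x_<j>(<k>)` and
#' `spine_y_<j>(<k>)` for spine point j at frame k (1-based); optional
#' `timestamp(<k>)` rows carry explicit times. Empty cells mean the larva
#' was not tracked at that frame, so gaps in a larva's frame coverage are
#' preserved as gaps in `t`.
#'
#' @param path Path to the table.
#' @param frame_rate Frames per second used to derive timestamps as
#'   `(k - 1) / frame_rate` when the table has no `timestamp` rows.
#' @param assay Assay metadata attached to every track; its
#'   `frame_rate_hint` is used when `frame_rate` is missing.
#' @return List of [larva_track()] objects, one per larva column.
#' @export
read_fimtrack_csv <- function(path, frame_rate = NULL,
                              assay = assay_metadata()) {
  tab <- utils::read.table(path, sep = ";", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"")
  if (ncol(tab) < 2L) stop("FIMTrack table needs a key column plus >= 1 larva column")
  keys <- tab[[1]]
  larvae <- names(tab)[-1]

  m_sp <- regmatches(keys, regexec("^spine_([xy])_([0-9]+)\\(([0-9]+)\\)$", keys))
  m_ts <- regmatches(keys, regexec("^timestamp\\(([0-9]+)\\)$", keys))
  is_sp <- lengths(m_sp) == 4L
  is_ts <- lengths(m_ts) == 2L
  if (!any(is_sp))
    stop("no spine_x_<j>(<k>)/spine_y_<j>(<k>) rows found in table")

  axis <- vapply(m_sp[is_sp], `[`, character(1), 2L)
  jpt <- as.integer(vapply(m_sp[is_sp], `[`, character(1), 3L))
  kfr <- as.integer(vapply(m_sp[is_sp], `[`, character(1), 4L))
  S <- max(jpt)
  frames <- sort(unique(kfr))

  ts <- NULL
  if (any(is_ts)) {
    kts <- as.integer(vapply(m_ts[is_ts], `[`, character(1), 2L))
    tvals <- suppressWarnings(as.numeric(tab[is_ts, 2L]))
    ts <- stats::setNames(tvals, kts)
  } else {
    if (is.null(frame_rate)) frame_rate <- assay$frame_rate_hint
    if (is.null(frame_rate))
      stop("table has no timestamp rows and no frame_rate was given")
  }

  tracks <- list()
  for (li in seq_along(larvae)) {
    col <- tab[[li + 1L]][is_sp]
    vals <- suppressWarnings(as.numeric(col))
    present_frames <- sort(unique(kfr[!is.na(vals) & nzchar(col)]))
    if (!length(present_frames)) next
    coords <- array(NA_real_, c(length(present_frames), S, 2L))
    for (r in seq_along(vals)) {
      if (is.na(vals[r])) next
      fi <- match(kfr[r], present_frames)
      coords[fi, jpt[r], if (axis[r] == "x") 1L else 2L] <- vals[r]
    }
    complete <- apply(coords, 1L, function(m) all(is.finite(m)))
    if (!all(complete))
      stop(sprintf("larva group '%s': missing spine columns at frame(s) %s",
                   larvae[li],
                   paste(present_frames[!complete], collapse = ", ")))
    t <- if (!is.null(ts)) unname(ts[as.character(present_frames)])
         else (present_frames - 1L) / frame_rate
    tracks[[length(tracks) + 1L]] <-
      larva_track(li, t, coords, assay = assay)
  }
  tracks
}

#' Write tracks as a FIMTrack-style table.csv
#'
#' Inverse of [read_fimtrack_csv()]; always writes `timestamp(<k>)` rows so
#' the round trip does not depend on a frame-rate hint. Frames are indexed
#' by each timestamp's position in the union of all timestamps, so per-larva
#' gaps appear as empty cells.
#'
#' @param tracks List of `larva_track` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fimtrack_csv <- function(tracks, path) {
  all_t <- sort(unique(round(unlist(lapply(tracks, `[[`, "t")), 9)))
  S <- if (length(tracks)) dim(tracks[[1]]$spine)[2] else 0L
  keys <- character(0)
  for (k in seq_along(all_t)) keys <- c(keys, sprintf("timestamp(%d)", k))
  for (k in seq_along(all_t))
    for (j in seq_len(S))
      keys <- c(keys, sprintf("spine_x_%d(%d)", j, k),
                sprintf("spine_y_%d(%d)", j, k))
  out <- matrix("", nrow = length(keys), ncol = length(tracks) + 1L)
  out[, 1L] <- keys
  nts <- length(all_t)
  out[seq_len(nts), -1L] <- rep(format_num(all_t), length(tracks))
  for (li in seq_along(tracks)) {
    trk <- tracks[[li]]
    ks <- match(round(trk$t, 9), all_t)
    for (i in seq_along(ks)) {
      base <- nts + (ks[i] - 1L) * 2L * S
      for (j in seq_len(S)) {
        out[base + 2L * (j - 1L) + 1L, li + 1L] <- format_num(trk$spine[i, j, 1L])
        out[base + 2L * j, li + 1L] <- format_num(trk$spine[i, j, 2L])
      }
    }
  }
  header <- paste(c("feature", sprintf("larva(%d)", seq_along(tracks))),
                  collapse = ";")
  writeLines(c(header, apply(out, 1L, paste, collapse = ";")), path)
  invisible(path)
}
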