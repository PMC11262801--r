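#' Windowing configuration
#'
#' Parameters that turn a raw track into fixed-shape posture windows. The
#' classifier looks at a 2-s horizon only; within that horizon time is
#' resampled to `samples_per_window` uniform samples and each midline to
#' `spine_points` arc-length-uniform points. `context_windows` past and
#' future window-lengths are additionally assembled as reconstruction
#' targets for self-supervised pre-training.
#'
#' @param window_seconds Window length in seconds (default 2).
#' @param samples_per_window L, number of uniform time samples per window.
#' @param spine_points S, number of arc-length-uniform spine points.
#' @param context_windows Number of past and of future window-lengths
#'   included in the extended reconstruction target (default 1 each).
#' @param stride_seconds Spacing between window centres; `NULL` (default)
#'   means one window per timestep.
#' @param pad_boundaries Replicate the first/last frame so that every
#'   timestep gets a window; if `FALSE`, windows overlapping the track ends
#'   are dropped instead.
#' @param max_gap_fraction Fraction of `window_seconds`; a between-frame gap
#'   longer than this within a window's span invalidates the window.
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(window_seconds = 2, samples_per_window = 20L,
                             spine_points = 5L, context_windows = 1L,
                             stride_seconds = NULL, pad_boundaries = TRUE,
                             max_gap_fraction = 0.5) {
  stopifnot(window_seconds > 0, samples_per_window >= 2L, spine_points >= 3L,
            context_windows >= 0L,
            is.null(stride_seconds) || stride_seconds > 0)
  structure(list(window_seconds = window_seconds,
                 samples_per_window = as.integer(samples_per_window),
                 spine_points = as.integer(spine_points),
                 context_windows = as.integer(context_windows),
                 stride_seconds = stride_seconds,
                 pad_boundaries = isTRUE(pad_boundaries),
                 max_gap_fraction = max_gap_fraction),
            class = "windowing_config")
}

#' Resample a midline to arc-length-uniform points
#'
#' Places `s_out` points equally spaced in cumulative arc length along the
#' piecewise-linear curve through `points`, preserving both endpoints.
#'
#' @param points Numeric `K x 2` matrix, K >= 2, consecutive points distinct.
#' @param s_out Number of output points.
#' @return Numeric `s_out x 2` matrix.
#' @export
resample_spine <- function(points, s_out) {
  points <- as.matrix(points)
  K <- nrow(points)
  if (K < 2L) stop("need at least 2 points to resample a midline")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-K, , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive midline points must be distinct")
  cum <- c(0, cumsum(seg))
  target <- seq(0, cum[K], length.out = s_out)
  cbind(stats::approx(cum, points[, 1L], xout = target)$y,
        stats::approx(cum, points[, 2L], xout = target)$y)
}

# Translation/scale/rotation transform computed from a window (L x S x 2):
# centroid over all samples and points, scale = mean body length, rotation
# aligning the first sample's head-to-tail axis with +x.
norm_transform <- function(arr) {
  centroid <- c(mean(arr[, , 1L]), mean(arr[, , 2L]))
  scale <- mean(body_lengths(arr))
  if (scale <= 0) stop("zero body length in window")
  S <- dim(arr)[2]
  v <- (arr[1L, S, ] - arr[1L, 1L, ])
  ang <- atan2(v[2], v[1])
  list(centroid = centroid, scale = scale, angle = ang)
}

apply_norm_transform <- function(arr, tf) {
  x <- (arr[, , 1L] - tf$centroid[1]) / tf$scale
  y <- (arr[, , 2L] - tf$centroid[2]) / tf$scale
  ca <- cos(-tf$angle); sa <- sin(-tf$angle)
  out <- array(0, dim(arr))
  out[, , 1L] <- ca * x - sa * y
  out[, , 2L] <- sa * x + ca * y
  out
}

#' Normalize a posture window
#'
#' Removes the similarity transform from a raw window: the window centroid
#' is moved to the origin, coordinates are divided by the mean body length
#' over the window, and the window is rotated so the head-to-tail axis of
#' its first time sample points along +x. The result is translation-,
#' rotation- and scale-invariant, and the operation is idempotent.
#'
#' @param raw Numeric `L x S x 2` array of spine coordinates.
#' @return Normalized array of the same shape, with attributes recording
#'   the removed transform.
#' @export
normalize_window <- function(raw) {
  if (any(!is.finite(raw))) stop("window contains non-finite coordinates")
  tf <- norm_transform(raw)
  out <- apply_norm_transform(raw, tf)
  attr(out, "transform") <- tf
  out
}

#' Extract normalized posture windows from a track
#'
#' Slides a `window_seconds` window over the track, one window per timestep
#' (or per `stride_seconds`). Each window is linearly interpolated onto a
#' uniform grid of L time samples, each midline resampled to S arc-length
#' uniform points, and the result normalized with [normalize_window()]. An
#' extended sequence spanning `context_windows` past and future
#' window-lengths is assembled with the same transform as the
#' reconstruction target for pre-training. Beyond the track ends the
#' first/last frame is replicated (when `pad_boundaries`); a between-frame
#' gap longer than `max_gap_fraction * window_seconds` inside a window's
#' span invalidates that window, so its timestep stays untagged downstream.
#'
#' @param track A [larva_track()].
#' @param cfg A [windowing_config()].
#' @return List of `posture_window` objects, each with fields `larva_id`,
#'   `t_center`, `x` (`L x S x 2`, normalized) and `x_ext`
#'   (`(1 + 2 * context_windows) * L x S x 2`).
#' @export
extract_windows <- function(track, cfg = windowing_config()) {
  validate_track(track)
  t <- track$t
  Tn <- length(t)
  if (Tn < 2L) return(list())
  if (max(t) - min(t) < cfg$window_seconds) return(list())
  if (any(!is.finite(track$spine)))
    stop("track contains non-finite coordinates")
  w <- cfg$window_seconds
  L <- cfg$samples_per_window
  S <- cfg$spine_points
  cw <- cfg$context_windows
  Lext <- (1L + 2L * cw) * L

  centers <- window_centers(t, cfg)
  if (!length(centers)) return(list())
  tc <- t[centers]

  # invalidate windows whose (clamped) span contains an over-long gap
  gaps <- diff(t)
  biggap <- which(gaps > cfg$max_gap_fraction * w)
  valid <- rep(TRUE, length(tc))
  for (g in biggap) {
    lo <- t[g]; hi <- t[g + 1L]
    valid <- valid & !(tc - w / 2 < hi & tc + w / 2 > lo &
                       (pmax(tc - w / 2, min(t)) < hi &
                        pmin(tc + w / 2, max(t)) > lo))
  }
  centers <- centers[valid]; tc <- tc[valid]
  if (!length(centers)) return(list())

  # per-frame arc-length resampling to S points, then temporal interpolation
  rs <- array(NA_real_, c(Tn, S, 2L))
  for (i in seq_len(Tn)) rs[i, , ] <- resample_spine(track$spine[i, , ], S)
  flat <- matrix(rs, nrow = Tn)  # T x (S*2), column-major over (S, axis)

  # uniform time offsets of the extended grid; centre window = middle L
  half_ext <- (cw + 0.5) * w
  offs <- seq(-half_ext, half_ext, length.out = Lext)
  grid <- outer(tc, offs, `+`)            # n x Lext
  q <- pmin(pmax(as.vector(grid), min(t)), max(t))
  interp <- matrix(NA_real_, length(q), ncol(flat))
  for (j in seq_len(ncol(flat)))
    interp[, j] <- stats::approx(t, flat[, j], xout = q)$y

  n <- length(tc)
  c_idx <- (cw * L + 1L):((cw + 1L) * L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- seq(i, by = n, length.out = Lext)  # grid is filled column-major
    ext <- array(interp[rows, ], c(Lext, S, 2L))
    tf <- norm_transform(ext[c_idx, , , drop = FALSE])
    ext_n <- apply_norm_transform(ext, tf)
    out[[i]] <- structure(list(larva_id = track$larva_id, t_center = tc[i],
                               x = ext_n[c_idx, , , drop = FALSE],
                               x_ext = ext_n),
                          class = "posture_window")
  }
  out
}

# Window centre indices into t, honouring stride and boundary padding.
window_centers <- function(t, cfg) {
  idx <- seq_along(t)
  if (!cfg$pad_boundaries) {
    eps <- 1e-9
    idx <- idx[t - cfg$window_seconds / 2 >= min(t) - eps &
               t + cfg$window_seconds / 2 <= max(t) + eps]
  }
  if (!is.null(cfg$stride_seconds) && length(idx)) {
    keep <- logical(length(idx))
    last <- -Inf
    for (k in seq_along(idx)) {
      if (t[idx[k]] >= last + cfg$stride_seconds - 1e-9) {
        keep[k] <- TRUE
        last <- t[idx[k]]
      }
    }
    idx <- idx[keep]
  }
  idx
}

#' @export
print.posture_window <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<posture_window> larva %d @ %.3f s, %d x %d x 2 (ext %d samples)\n",
              x$larva_id, x$t_center, d[1], d[2], dim(x$x_ext)[1]))
  invisible(x)
}

# Stack windows into design matrices: x -> n x (L*S*2), x_ext likewise.
windows_matrix <- function(windows, extended = FALSE) {
  field <- if (extended) "x_ext" else "x"
  do.call(rbind, lapply(windows, function(w) as.vector(w[[field]])))
}

#' Ground-truth class of each window
#'
#' Looks up, for every window, the label of its centre timestep in a label
#' set (by larva id and timestamp). Multi-label timesteps yield their first
#' label; untagged timesteps yield `NA`.
#'
#' @param windows List of `posture_window` objects.
#' @param labels A [label_set()].
#' @return Character vector of class names, one per window.
#' @export
window_labels <- function(windows, labels) {
  vapply(windows, function(w) {
    id <- as.character(w$larva_id)
    tv <- labels$t[[id]]
    if (is.null(tv)) return(NA_character_)
    k <- which.min(abs(tv - w$t_center))
    if (abs(tv[k] - w$t_center) > 1e-6) return(NA_character_)
    idx <- labels$assignments[[id]][[k]]
    if (!length(idx)) NA_character_ else labels$dictionary$name[idx[1]]
  }, character(1))
}
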