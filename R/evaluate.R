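#' Stimulus-aligned action-probability time series
#'
#' For each action and time bin, the fraction of larvae performing the
#' action: numerator = larvae labelled with the action at any timestep in
#' the bin, denominator = larvae tracked in the bin (untagged timesteps are
#' excluded from the numerator only). Bins with no tracked larva are
#' emitted as missing.
#'
#' @param labels A [label_set()] aligned to `tracks`.
#' @param tracks List of `larva_track` objects.
#' @param dictionary Action dictionary data frame.
#' @param bin_s Bin width in seconds.
#' @return Data frame with columns `action`, `bin_start`, `bin_mid`,
#'   `n_tracked`, `probability`.
#' @export
probability_timeseries <- function(labels, tracks,
                                   dictionary = action_dictionary(),
                                   bin_s = 1) {
  stopifnot(bin_s > 0, length(tracks) > 0)
  t_all <- unlist(lapply(tracks, `[[`, "t"))
  edges <- seq(floor(min(t_all) / bin_s) * bin_s, max(t_all) + bin_s, by = bin_s)
  nb <- length(edges) - 1L
  acts <- dictionary$name
  tracked <- integer(nb)
  hit <- matrix(0L, nb, length(acts))
  for (trk in tracks) {
    id <- as.character(trk$larva_id)
    bins_present <- unique(findInterval(trk$t, edges, rightmost.closed = FALSE))
    bins_present <- bins_present[bins_present >= 1L & bins_present <= nb]
    tracked[bins_present] <- tracked[bins_present] + 1L
    tv <- labels$t[[id]]
    if (is.null(tv)) next
    a <- labels$assignments[[id]]
    bin_of <- findInterval(tv, edges)
    for (ai in seq_along(acts)) {
      has <- vapply(seq_along(a), function(k) ai %in% a[[k]], logical(1))
      bs <- unique(bin_of[has])
      bs <- bs[bs >= 1L & bs <= nb]
      hit[bs, ai] <- hit[bs, ai] + 1L
    }
  }
  out <- expand.grid(bin = seq_len(nb), action = acts,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$bin_start <- edges[out$bin]
  out$bin_mid <- edges[out$bin] + bin_s / 2
  out$n_tracked <- tracked[out$bin]
  out$probability <- ifelse(out$n_tracked > 0,
                            hit[cbind(out$bin, match(out$action, acts))] /
                              out$n_tracked, NA_real_)
  out$bin <- NULL
  out[, c("action", "bin_start", "bin_mid", "n_tracked", "probability")]
}

#' Larvae (or frames) performing an action in a time window
#'
#' With the default larva-level counting over `[t0, t1)`, `n` is the
#' number of larvae with at least one tagged timestep in the window and
#' `k` the number whose label sequence in the window contains the action.
#' With `level = "frame"`, `n` counts tagged timesteps pooled over larvae
#' and `k` those carrying the action — an alternative reading of
#' "population probability" offered as an option.
#'
#' @param labels A [label_set()].
#' @param tracks List of `larva_track` objects.
#' @param action Action name.
#' @param window Numeric length-2 vector `c(t0, t1)`, `t1 > t0`.
#' @param level `"larva"` (default) or `"frame"`.
#' @return Integer vector `c(k = ..., n = ...)`.
#' @export
window_counts <- function(labels, tracks, action, window,
                          level = c("larva", "frame")) {
  stopifnot(window[2] > window[1])
  level <- match.arg(level)
  ai <- match(action, labels$dictionary$name)
  if (is.na(ai)) stop(sprintf("action '%s' not in dictionary", action))
  k <- 0L; n <- 0L
  for (trk in tracks) {
    id <- as.character(trk$larva_id)
    tv <- labels$t[[id]]
    if (is.null(tv)) next
    inwin <- which(tv >= window[1] & tv < window[2])
    if (!length(inwin)) next
    steps <- labels$assignments[[id]][inwin]
    has <- vapply(steps, function(s) ai %in% s, logical(1))
    if (level == "larva") {
      if (!any(lengths(steps) > 0L)) next
      n <- n + 1L
      if (any(has)) k <- k + 1L
    } else {
      n <- n + sum(lengths(steps) > 0L)
      k <- k + sum(has)
    }
  }
  c(k = k, n = n)
}

#' Pearson chi-squared comparison of two proportions
#'
#' Tests the 2x2 table `[[k_t, n_t - k_t], [k_c, n_c - k_c]]` with the
#' Pearson chi-squared statistic on 1 degree of freedom, without continuity
#' correction by default. Degenerate zero-margin tables (no larva, or all
#' larvae, performing the action in both groups) return `chi2 = 0, p = 1`.
#'
#' @param test,control Integer vectors `c(k, n)`.
#' @param correct Apply the Yates continuity correction.
#' @return Named numeric vector `c(chi2 = ..., p = ...)`.
#' @export
chi2_compare <- function(test, control, correct = FALSE) {
  k_t <- test[[1]]; n_t <- test[[2]]
  k_c <- control[[1]]; n_c <- control[[2]]
  stopifnot(n_t > 0, n_c > 0, k_t >= 0, k_t <= n_t, k_c >= 0, k_c <= n_c)
  tab <- matrix(c(k_t, n_t - k_t, k_c, n_c - k_c), 2L, byrow = TRUE)
  if (any(colSums(tab) == 0L))
    return(c(chi2 = 0, p = 1))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  c(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Screen comparison of lines against a control
#'
#' The screen-evaluation procedure: for every non-control line and every
#' action, count larvae performing the action in the analysis window
#' (typically the 1 s right after stimulus onset), test against the control
#' line with [chi2_compare()], Bonferroni-correct the p-values, and call a
#' three-level outcome: `positive` (corrected p below `alpha` and a higher
#' proportion than control), `negative` (lower), or `none`. Lines with no
#' tagged larva in the window are flagged untestable (`NA` outcome).
#'
#' @param lines Named list; each element a list with fields `labels`
#'   (a [label_set()]) and `tracks`.
#' @param control_name Name of the control line in `lines`.
#' @param dictionary Action dictionary data frame.
#' @param window Numeric `c(t0, t1)` analysis window in seconds.
#' @param m Number of comparisons for Bonferroni; defaults to the number
#'   of tests performed. The original screen's inventory (m = 471) is
#'   reproduced by setting it explicitly.
#' @param alpha Significance level after correction (default 0.05).
#' @param correct Yates continuity correction, passed to [chi2_compare()].
#' @param level Counting level, passed to [window_counts()].
#' @return Data frame of class `screen_comparison`: one row per line and
#'   action with counts, `chi2`, `p`, `p_corrected` and `outcome`.
#' @export
screen_compare <- function(lines, control_name,
                           dictionary = action_dictionary(), window,
                           m = NULL, alpha = 0.05, correct = FALSE,
                           level = c("larva", "frame")) {
  level <- match.arg(level)
  if (!control_name %in% names(lines))
    stop(sprintf("control line '%s' not found", control_name))
  test_names <- setdiff(names(lines), control_name)
  ctrl <- lines[[control_name]]
  rows <- list()
  for (ln in test_names) {
    for (act in dictionary$name) {
      tc <- window_counts(lines[[ln]]$labels, lines[[ln]]$tracks, act,
                          window, level)
      cc <- window_counts(ctrl$labels, ctrl$tracks, act, window, level)
      if (tc[["n"]] == 0L || cc[["n"]] == 0L) {
        rows[[length(rows) + 1L]] <-
          data.frame(line = ln, action = act, k_test = tc[["k"]],
                     n_test = tc[["n"]], k_control = cc[["k"]],
                     n_control = cc[["n"]], chi2 = NA_real_, p = NA_real_,
                     p_corrected = NA_real_, outcome = NA_character_,
                     stringsAsFactors = FALSE)
        next
      }
      ht <- chi2_compare(tc, cc, correct = correct)
      rows[[length(rows) + 1L]] <-
        data.frame(line = ln, action = act, k_test = tc[["k"]],
                   n_test = tc[["n"]], k_control = cc[["k"]],
                   n_control = cc[["n"]], chi2 = ht[["chi2"]], p = ht[["p"]],
                   p_corrected = NA_real_, outcome = NA_character_,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  performed <- !is.na(res$p)
  if (is.null(m)) m <- sum(performed)
  if (m < sum(performed))
    stop("m must be at least the number of tests performed")
  res$p_corrected[performed] <- stats::p.adjust(res$p[performed],
                                                method = "bonferroni", n = m)
  sig <- performed & res$p_corrected < alpha
  rate_t <- res$k_test / res$n_test
  rate_c <- res$k_control / res$n_control
  res$outcome[performed] <- "none"
  res$outcome[sig & rate_t > rate_c] <- "positive"
  res$outcome[sig & rate_t < rate_c] <- "negative"
  attr(res, "m") <- m
  attr(res, "alpha") <- alpha
  class(res) <- c("screen_comparison", "data.frame")
  res
}

#' Inter-tagger agreement on three-level outcomes
#'
#' Compares the three-level outcomes of two taggers over the same set of
#' comparisons and counts concordant pairs, effects lost by the candidate,
#' effects gained, and opposite calls (positive vs negative).
#'
#' @param reference,candidate `screen_comparison` data frames (or any data
#'   frames with columns `line`, `action`, `outcome`) over the same keys.
#' @return List of class `agreement_summary` with the four counts, `total`
#'   and `concordance` (fraction concordant).
#' @export
agreement <- function(reference, candidate) {
  key <- function(d) paste(d$line, d$action, sep = "\r")
  kr <- key(reference); kc <- key(candidate)
  if (!setequal(kr, kc) || length(kr) != length(kc))
    stop(sprintf("comparison keys differ: %s",
                 paste(union(setdiff(kr, kc), setdiff(kc, kr)),
                       collapse = "; ")))
  ref <- reference$outcome[order(kr)]
  cand <- candidate$outcome[order(kc)]
  concordant <- sum(ref == cand, na.rm = TRUE) + sum(is.na(ref) & is.na(cand))
  lost <- sum(ref %in% c("positive", "negative") & !is.na(cand) &
              cand == "none")
  gained <- sum(!is.na(ref) & ref == "none" &
                cand %in% c("positive", "negative"))
  opposite <- sum((!is.na(ref) & !is.na(cand)) &
                  ((ref == "positive" & cand == "negative") |
                   (ref == "negative" & cand == "positive")))
  structure(list(concordant = concordant, effect_lost = lost,
                 effect_gained = gained, opposite = opposite,
                 total = length(ref),
                 concordance = concordant / length(ref)),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement> %d/%d concordant (%.1f%%); lost %d, gained %d, opposite %d\n",
              x$concordant, x$total, 100 * x$concordance,
              x$effect_lost, x$effect_gained, x$opposite))
  invisible(x)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 over the classes present in the truth
#' or the predictions; pairs where either side is untagged (`NA`) are
#' excluded first. A class predicted but never true (or vice versa) scores
#' an F1 of 0.
#'
#' @param true_labels,predicted_labels Character vectors of equal length.
#' @param dictionary Optional dictionary restricting/ordering the classes.
#' @return Macro-F1 in `[0, 1]`.
#' @export
macro_f1 <- function(true_labels, predicted_labels, dictionary = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  keep <- !is.na(true_labels) & !is.na(predicted_labels)
  y <- true_labels[keep]; p <- predicted_labels[keep]
  if (!length(y)) stop("no labelled pairs left after excluding untagged")
  classes <- union(unique(y), unique(p))
  if (!is.null(dictionary))
    classes <- dictionary$name[dictionary$name %in% classes]
  f1 <- vapply(classes, function(cl) {
    tp <- sum(y == cl & p == cl)
    fp <- sum(y != cl & p == cl)
    fn <- sum(y == cl & p != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}
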