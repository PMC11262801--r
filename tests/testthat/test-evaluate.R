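# Independent Pearson chi-squared oracle, written out from the definition.
pearson_oracle <- function(k_t, n_t, k_c, n_c) {
  O <- matrix(c(k_t, n_t - k_t, k_c, n_c - k_c), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

test_that("chi2_compare matches hand calculations and the Pearson oracle", {
  expect_equal(chi2_compare(c(50, 100), c(50, 100)), c(chi2 = 0, p = 1))
  out <- chi2_compare(c(30, 100), c(10, 100))
  expect_equal(out[["chi2"]], 12.5, tolerance = 1e-9)
  expect_equal(out[["p"]], 4.07e-4, tolerance = 1e-2)
  # symmetry
  expect_equal(chi2_compare(c(10, 100), c(30, 100)), out, tolerance = 1e-12)
  # degenerate margins
  expect_equal(chi2_compare(c(0, 10), c(0, 20)), c(chi2 = 0, p = 1))
  expect_equal(chi2_compare(c(10, 10), c(20, 20)), c(chi2 = 0, p = 1))
  # dense brute-force agreement
  withr::with_seed(7, {
    for (i in 1:1000) {
      n_t <- sample(2:80, 1); n_c <- sample(2:80, 1)
      k_t <- sample(0:n_t, 1); k_c <- sample(0:n_c, 1)
      got <- chi2_compare(c(k_t, n_t), c(k_c, n_c))
      want <- if (k_t + k_c == 0 || (k_t == n_t && k_c == n_c))
        c(chi2 = 0, p = 1) else pearson_oracle(k_t, n_t, k_c, n_c)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("window_counts matches its definition (trivial and brute force)", {
  dict <- action_dictionary()
  mk_labels <- function(n, Tn, p_tag = 0.8) {
    assignments <- list(); tvecs <- list()
    for (i in seq_len(n)) {
      tvecs[[as.character(i)]] <- seq(0, by = 0.5, length.out = Tn)
      assignments[[as.character(i)]] <- lapply(seq_len(Tn), function(k)
        if (stats::runif(1) < p_tag) sample(nrow(dict), 1) else integer(0))
    }
    label_set(dict, assignments, tvecs)
  }
  mk_tracks <- function(labels) {
    lapply(names(labels$t), function(id) {
      t <- labels$t[[id]]
      sp <- array(0, c(length(t), 3, 2)); sp[, , 1] <- rep(0:2, each = length(t)) * 0
      for (i in seq_along(t)) sp[i, , 1] <- 0:2
      larva_track(as.integer(id), t, sp)
    })
  }
  withr::with_seed(13, {
    # constructed case: 4 of 10 larvae hunch in the window
    hunch_ix <- match("hunch", dict$name)
    assignments <- list(); tvecs <- list()
    for (i in 1:10) {
      tvecs[[as.character(i)]] <- c(0, 0.5)
      assignments[[as.character(i)]] <-
        list(if (i <= 4) hunch_ix else match("crawl", dict$name), integer(0))
    }
    ls <- label_set(dict, assignments, tvecs)
    trks <- mk_tracks(ls)
    expect_identical(window_counts(ls, trks, "hunch", c(0, 0.4)),
                     c(k = 4L, n = 10L))
    expect_identical(window_counts(ls, trks, "hunch", c(-5, -4)),
                     c(k = 0L, n = 0L))
    # brute-force recount on random fixtures
    for (rep in 1:20) {
      ls <- mk_labels(6, 8)
      trks <- mk_tracks(ls)
      win <- sort(stats::runif(2, 0, 4)); win[2] <- win[1] + max(diff(win), 0.3)
      act <- sample(dict$name, 1)
      got <- window_counts(ls, trks, act, win)
      k <- 0L; n <- 0L
      ai <- match(act, dict$name)
      for (id in names(ls$t)) {
        sel <- ls$t[[id]] >= win[1] & ls$t[[id]] < win[2]
        steps <- ls$assignments[[id]][sel]
        if (!any(lengths(steps) > 0)) next
        n <- n + 1L
        if (any(unlist(steps) == ai)) k <- k + 1L
      }
      expect_identical(got, c(k = k, n = n))
    }
  })
})

test_that("frame-level counting pools tagged timesteps across larvae", {
  dict <- action_dictionary()
  hunch <- match("hunch", dict$name); crawl <- match("crawl", dict$name)
  assignments <- list(); tvecs <- list()
  for (i in 1:3) {
    tvecs[[as.character(i)]] <- c(0, 0.5, 1)
    assignments[[as.character(i)]] <-
      list(if (i == 1) hunch else crawl, crawl, integer(0))
  }
  ls <- label_set(dict, assignments, tvecs)
  trks <- lapply(1:3, function(i) {
    sp <- array(0, c(3, 3, 2)); for (j in 1:3) sp[j, , 1] <- 0:2
    larva_track(i, c(0, 0.5, 1), sp)
  })
  # larva level: all 3 larvae tagged, 1 hunches
  expect_identical(window_counts(ls, trks, "hunch", c(0, 1)),
                   c(k = 1L, n = 3L))
  # frame level: 6 tagged frames in the window, 1 carries hunch
  expect_identical(window_counts(ls, trks, "hunch", c(0, 1), level = "frame"),
                   c(k = 1L, n = 6L))
  expect_identical(window_counts(ls, trks, "crawl", c(0, 1), level = "frame"),
                   c(k = 5L, n = 6L))
})

test_that("probability time series reflect labels and respect the partition bound", {
  dict <- action_dictionary()
  assay <- simulate_assay(20, stimulus_onset = 2, total_seconds = 4,
                          pre_mixture = c(crawl = 1),
                          post_mixture = c(crawl = 1), seed = 3)
  ts <- probability_timeseries(assay$labels, assay$tracks, dict, bin_s = 1)
  crawl <- ts[ts$action == "crawl", ]
  expect_true(all(crawl$probability[crawl$n_tracked > 0] == 1))
  other <- ts[ts$action != "crawl" & ts$n_tracked > 0, ]
  expect_true(all(other$probability == 0))
  # single-label partition bound: when no larva switches action inside a
  # bin, the per-bin action probabilities sum to at most 1; long segment
  # durations guarantee one action per larva per phase here
  assay2 <- simulate_assay(15, stimulus_onset = 2, total_seconds = 4,
                           duration_range = c(5, 6), seed = 8)
  ts2 <- probability_timeseries(assay2$labels, assay2$tracks, dict,
                                bin_s = 0.5)
  sums <- stats::aggregate(probability ~ bin_start, ts2, sum,
                           subset = ts2$bin_start != 1.5)
  expect_true(all(sums$probability <= 1 + 1e-9))
})

test_that("screen_compare calls outcomes and scales p-values per Bonferroni", {
  dict <- action_dictionary()
  mk_line <- function(post, seed)
    simulate_assay(60, stimulus_onset = 2, total_seconds = 4,
                   post_mixture = post, seed = seed)
  ctrl <- mk_line(c(hunch = 0.1, crawl = 0.9), 101)
  test <- mk_line(c(hunch = 0.7, crawl = 0.3), 202)
  lines <- list(control = list(labels = ctrl$labels, tracks = ctrl$tracks),
                lineA = list(labels = test$labels, tracks = test$tracks))
  res <- screen_compare(lines, "control", dict, window = c(2, 3))
  hunch <- res[res$action == "hunch", ]
  expect_identical(hunch$outcome, "positive")
  crawl <- res[res$action == "crawl", ]
  expect_identical(crawl$outcome, "negative")
  # Bonferroni: m = 471 scales the corrected p by exactly 471/m0, capped
  res471 <- screen_compare(lines, "control", dict, window = c(2, 3), m = 471)
  perf <- !is.na(res$p)
  expect_equal(res471$p_corrected[perf],
               pmin(1, res$p[perf] * 471), tolerance = 1e-12)
  # identical generating process: no outcome called
  same <- mk_line(c(hunch = 0.1, crawl = 0.9), 303)
  lines2 <- list(control = list(labels = ctrl$labels, tracks = ctrl$tracks),
                 lineB = list(labels = same$labels, tracks = same$tracks))
  res2 <- screen_compare(lines2, "control", dict, window = c(2, 3))
  expect_true(all(res2$outcome[!is.na(res2$outcome)] == "none"))
  # untestable window
  res3 <- screen_compare(lines, "control", dict, window = c(100, 101))
  expect_true(all(is.na(res3$outcome)))
  expect_error(screen_compare(lines, "nope", dict, window = c(2, 3)),
               "not found")
})

test_that("agreement counts concordance, gains, losses and opposites", {
  mk <- function(outcomes) {
    data.frame(line = paste0("l", seq_along(outcomes)), action = "hunch",
               outcome = outcomes, stringsAsFactors = FALSE)
  }
  a <- mk(c("positive", "none", "negative", "none"))
  expect_equal(agreement(a, a)$concordance, 1)
  expect_identical(agreement(a, a)$opposite, 0L)

  b <- mk(c("negative", "positive", "none", "none"))
  s <- agreement(a, b)
  expect_identical(s$concordant, 1L)
  expect_identical(s$opposite, 1L)
  expect_identical(s$effect_gained, 1L)
  expect_identical(s$effect_lost, 1L)
  expect_error(agreement(a, mk(c("none", "none", "none", "none"))[1:3, ]),
               "keys differ")

  # the headline framing: 232 concordant out of 293 comparisons
  withr::with_seed(41, {
    ref <- sample(c("positive", "negative", "none"), 293, replace = TRUE)
    cand <- ref
    flip <- sample(293, 61)
    cand[flip] <- vapply(cand[flip], function(o)
      setdiff(c("positive", "negative", "none"), o)[sample(2, 1)],
      character(1))
    keys <- data.frame(line = paste0("l", 1:293), action = "bend",
                       outcome = ref, stringsAsFactors = FALSE)
    cand_df <- keys; cand_df$outcome <- cand
    s <- agreement(keys, cand_df)
    expect_identical(s$concordant, 232L)
    expect_equal(s$concordance, 232 / 293, tolerance = 1e-12)
    expect_equal(round(100 * s$concordance), 79)
  })

  # brute-force pair counting on random outcome maps
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      ref <- sample(c("positive", "negative", "none"), n, replace = TRUE)
      cand <- sample(c("positive", "negative", "none"), n, replace = TRUE)
      rdf <- data.frame(line = paste0("l", 1:n), action = "roll",
                        outcome = ref, stringsAsFactors = FALSE)
      cdf <- rdf; cdf$outcome <- cand
      s <- agreement(rdf, cdf)
      expect_identical(s$concordant, sum(ref == cand))
      expect_identical(s$opposite,
                       sum((ref == "positive" & cand == "negative") |
                           (ref == "negative" & cand == "positive")))
      expect_identical(s$concordant + s$effect_lost + s$effect_gained +
                       s$opposite, n)
    }
  })
})

test_that("macro F1 matches closed forms and is class-order invariant", {
  expect_equal(macro_f1(c("a", "b", "a"), c("a", "b", "a")), 1)
  # constant single-class prediction on balanced 2-class truth:
  # f1(a) = 2/3, f1(b) = 0 -> macro = 1/3
  y <- rep(c("a", "b"), each = 10)
  expect_equal(macro_f1(y, rep("a", 20)), 1 / 3, tolerance = 1e-12)
  # order invariance via dictionary
  d1 <- action_dictionary(c("a", "b")); d2 <- action_dictionary(c("b", "a"))
  p <- withr::with_seed(2, sample(c("a", "b"), 20, replace = TRUE))
  expect_equal(macro_f1(y, p, d1), macro_f1(y, p, d2))
  # untagged pairs excluded pairwise
  expect_equal(macro_f1(c("a", NA, "b", "a"), c("a", "b", NA, "a")), 1)
  expect_error(macro_f1(c(NA, NA), c("a", "b")), "no labelled pairs")
  expect_error(macro_f1(c("a"), c("a", "b")), "equal length")
  # random cases against an independent per-class computation
  withr::with_seed(43, {
    for (rep in 1:25) {
      cls <- letters[1:sample(2:5, 1)]
      y <- sample(cls, 40, replace = TRUE)
      p <- sample(cls, 40, replace = TRUE)
      f1s <- vapply(union(unique(y), unique(p)), function(cl) {
        prec <- sum(y == cl & p == cl) / max(sum(p == cl), 1)
        rec <- sum(y == cl & p == cl) / max(sum(y == cl), 1)
        if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      }, numeric(1))
      expect_equal(macro_f1(y, p), mean(f1s), tolerance = 1e-12)
    }
  })
})
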