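test_that("choreography reader parses frames, groups larvae and sorts time", {
  f <- withr::local_tempfile()
  writeLines(c("7 0.0 0 0 1 0 2 0 3 0 4 0",
               "7 0.2 0 1 1 1 2 1 3 1 4 1",
               "7 0.1 0 2 1 2 2 2 3 2 4 2"), f)
  tracks <- read_choreography(f)
  expect_length(tracks, 1L)
  expect_identical(tracks[[1]]$larva_id, 7L)
  expect_identical(dim(tracks[[1]]$spine), c(3L, 5L, 2L))
  expect_identical(tracks[[1]]$t, c(0, 0.1, 0.2))
  expect_equal(tracks[[1]]$spine[2, , 2], rep(2, 5))  # time-sorted
})

test_that("interleaved larvae are partitioned without losing frames", {
  f <- withr::local_tempfile()
  lines <- character(0)
  for (i in 1:4) {
    lines <- c(lines,
               sprintf("1 %g 0 %d 1 %d 2 %d", i / 10, i, i, i),
               sprintf("2 %g 5 %d 6 %d 7 %d", i / 10, i, i, i))
  }
  writeLines(lines, f)
  tracks <- read_choreography(f)
  expect_length(tracks, 2L)
  expect_identical(sum(vapply(tracks, function(x) length(x$t), integer(1))),
                   length(lines))
  for (trk in tracks) expect_track_valid(trk)
})

test_that("malformed, inconsistent and duplicate frames are dropped with warnings", {
  f <- withr::local_tempfile()
  writeLines(c("1 0.0 0 0 1 0 2 0",
               "1 0.1 0 0 1 0",          # wrong point count
               "1 0.2 0 1 1 1 2 1",
               "1 0.2 9 9 9 9 9 9",      # duplicate timestamp
               "garbage line here x"), f)
  expect_warning(expect_warning(expect_warning(
    tracks <- read_choreography(f), "unparseable"),
    "inconsistent"), "duplicate")
  expect_length(tracks, 1L)
  expect_identical(length(tracks[[1]]$t), 2L)
  expect_equal(tracks[[1]]$spine[2, 1, ], c(0, 1))  # first dup kept
})

test_that("empty file gives an empty track list", {
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  expect_identical(read_choreography(f), list())
})

test_that("choreography round-trip reproduces simulator tracks and outlines", {
  sim <- simulate_assay(3, stimulus_onset = 2, total_seconds = 4, seed = 42)
  f <- withr::local_tempfile()
  write_choreography(sim$tracks, f)
  back <- read_choreography(f)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$t, sim$tracks[[i]]$t, tolerance = 1e-9)
    expect_lt(max(abs(back[[i]]$spine - sim$tracks[[i]]$spine)), 1e-6)
  }
  # outline file shares the id/t columns
  tr <- sim$tracks[[1]]
  tr$outline <- tr$spine + 0.5
  fo <- withr::local_tempfile()
  write_choreography(list(tr), f, outline_path = fo)
  back <- read_choreography(f, outline_path = fo)
  expect_lt(max(abs(back[[1]]$outline - tr$outline)), 1e-6)
})

test_that("fimtrack reader handles groups, gaps and round-trips", {
  sim <- simulate_assay(2, stimulus_onset = 2, total_seconds = 3.5, seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_fimtrack_csv(sim$tracks, f)
  back <- read_fimtrack_csv(f)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$t, sim$tracks[[i]]$t, tolerance = 1e-9)
    expect_lt(max(abs(back[[i]]$spine - sim$tracks[[i]]$spine)), 1e-6)
  }
  # a larva missing frames 4-6 keeps a gap in t
  tr <- sim$tracks[[1]]
  tr2 <- larva_track(2L, tr$t[-(4:6)], tr$spine[-(4:6), , ], assay = tr$assay)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_fimtrack_csv(list(tr, tr2), f2)
  back <- read_fimtrack_csv(f2)
  expect_identical(length(back[[2]]$t), length(tr$t) - 3L)
  expect_gt(max(diff(back[[2]]$t)), 1.5 * stats::median(diff(back[[2]]$t)))
})

test_that("fimtrack reader derives time from frame rate and fails cleanly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature;larva(1)",
               "spine_x_1(1);0", "spine_y_1(1);0",
               "spine_x_2(1);1", "spine_y_2(1);0",
               "spine_x_3(1);2", "spine_y_3(1);0",
               "spine_x_1(2);0", "spine_y_1(2);1",
               "spine_x_2(2);1", "spine_y_2(2);1",
               "spine_x_3(2);2", "spine_y_3(2);1"), f)
  tracks <- read_fimtrack_csv(f, frame_rate = 5)
  expect_equal(tracks[[1]]$t, c(0, 0.2))
  expect_error(read_fimtrack_csv(f), "frame_rate")

  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature;larva(1)",
               "spine_x_1(1);0", "spine_y_1(1);0",
               "spine_x_2(1);1"), g)  # y of point 2 missing
  expect_error(read_fimtrack_csv(g, frame_rate = 5), "larva\\(1\\)")

  h <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature;larva(1)", "mom_x(1);0"), h)
  expect_error(read_fimtrack_csv(h, frame_rate = 5), "no spine")
})

test_that("label JSON round-trips bit-identically and exactly", {
  dict <- action_dictionary()
  ls1 <- label_set(
    dict,
    assignments = list(`3` = list(1L, integer(0), c(2L, 7L), 4L, 3L)),
    t = list(`3` = seq(0, 0.4, by = 0.1)),
    provenance = c(`3` = "manual"))
  f <- withr::local_tempfile(fileext = ".json")
  write_labels_json(ls1, f)
  ls2 <- read_labels_json(f)
  expect_identical(ls2$assignments, ls1$assignments)
  expect_identical(ls2$dictionary$name, dict$name)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_labels_json(ls2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("empty label set writes data: [] and validation errors are informative", {
  f <- withr::local_tempfile(fileext = ".json")
  write_labels_json(label_set(action_dictionary()), f)
  expect_match(paste(readLines(f), collapse = ""), "\"data\":\\[\\]")
  expect_identical(read_labels_json(f)$assignments, list())

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"units":{"t":"s"},"labels":{"names":["crawl"],"colors":["#111111"]},
    "data":[{"id":1,"t":[0.0],"labels":[["wiggle"]]}]}', bad)
  expect_error(read_labels_json(bad), "wiggle")
  bad2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"units":{"t":"s"},"data":[]}', bad2)
  expect_error(read_labels_json(bad2), "\\$\\.labels")
})

test_that("hand-written label file yields exactly one tagged timestep", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"units":{"t":"s"},"metadata":{},',
    '"labels":{"names":["crawl","bend","back","hunch","roll","stop",',
    '"small_action"],"colors":["#1","#2","#3","#4","#5","#6","#7"]},',
    '"data":[{"id":12,"t":[0,0.1,0.2,0.3,0.4],',
    '"labels":[[],[],[],["hunch"],[]]}]}'), f)
  ls <- read_labels_json(f)
  a <- ls$assignments[["12"]]
  expect_identical(sum(lengths(a) > 0), 1L)
  expect_identical(ls$dictionary$name[a[[4]]], "hunch")
  expect_identical(unname(ls$provenance["12"]), "imported")
})

test_that("unknown top-level keys survive a round trip", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"units":{"t":"s"},"labels":{"names":["crawl"],',
    '"colors":["#111111"]},"data":[],"x_custom":{"a":1}}'), f)
  ls <- read_labels_json(f)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_labels_json(ls, f2)
  expect_match(paste(readLines(f2), collapse = ""), "x_custom")
})

test_that("readers emit tracks satisfying the track invariants", {
  sim <- simulate_assay(3, stimulus_onset = 2, total_seconds = 4, seed = 9)
  f <- withr::local_tempfile(); write_choreography(sim$tracks, f)
  for (trk in read_choreography(f)) expect_track_valid(trk)
  g <- withr::local_tempfile(fileext = ".csv")
  write_fimtrack_csv(sim$tracks, g)
  for (trk in read_fimtrack_csv(g)) expect_track_valid(trk)
})
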