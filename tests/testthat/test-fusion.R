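# Fusion-event pipeline: interval averaging, LoG detection, clustering,
# event calling, release series, densities and the group test.

test_that("interval averaging floors partial intervals and preserves constants", {
  arr <- array(seq_len(3000 * 4 * 4), c(3000, 4, 4))
  expect_equal(dim(interval_mean_projection(arr, 100)), c(30, 4, 4))
  # trailing partial interval dropped
  arr250 <- array(rnorm(250 * 5 * 5), c(250, 5, 5))
  p <- interval_mean_projection(arr250, 100)
  expect_equal(dim(p)[1], 2)
  expect_equal(p[2, 3, 4], mean(arr250[101:200, 3, 4]))
  # constant movie projects to the constant
  const <- array(7, c(20, 6, 6))
  expect_true(all(interval_mean_projection(const, 10) == 7))
  expect_error(interval_mean_projection(array(0, c(5, 4, 4)), 10),
               "fewer than one")
})

test_that("LoG detection finds a centred Gaussian spot and nothing on blanks", {
  cfg <- detection_config(log_sigma = 1.5, detection_threshold = 1)
  blank <- matrix(5, 40, 40)
  expect_equal(nrow(detect_puncta(blank, cfg)), 0)
  img <- blank
  ys <- 1:40
  spot <- 60 * exp(-(outer((ys - 21)^2, (ys - 26)^2, "+")) / (2 * 1.5^2))
  img <- img + spot
  got <- detect_puncta(img, cfg)
  expect_equal(nrow(got), 1)
  expect_equal(got$y, 20)  # 0-based row of the centre pixel
  expect_equal(got$x, 25)
  # additive offsets change nothing at all
  shifted <- detect_puncta(img + 123.4, cfg)
  expect_equal(shifted[, c("x", "y", "t")], got[, c("x", "y", "t")])
  expect_equal(shifted$response, got$response, tolerance = 1e-9)
  expect_error(detect_puncta(matrix(c(1, NA, 3, 4), 2), cfg), "non-finite")
})

test_that("chebyshev clustering chains tracks and separates distant ones", {
  cfg <- detection_config()
  empty <- cluster_puncta(data.frame(x = integer(), y = integer(),
                                     t = integer()), cfg)
  expect_equal(nrow(empty$clusters), 0)
  # one punctum per interval at a fixed position, intervals 0-9
  track <- data.frame(x = 10L, y = 12L, t = 0:9)
  one <- cluster_puncta(track, cfg)
  expect_equal(max(one$clusters$cluster_id), 1)
  expect_equal(nrow(one$clusters), 10)
  # two tracks five pixels apart never merge under eps = 1
  two <- cluster_puncta(rbind(track, transform(track, x = 15L)), cfg)
  expect_equal(max(two$clusters$cluster_id), 2)
  # a jump of 2 intervals still chains (|dt| <= 2); a jump of 3 breaks
  gap2 <- data.frame(x = 5L, y = 5L, t = c(0:2, 4:6))
  expect_equal(max(cluster_puncta(gap2, cfg)$clusters$cluster_id), 1)
  gap3 <- data.frame(x = 5L, y = 5L, t = c(0:2, 5:7))
  expect_equal(max(cluster_puncta(gap3, cfg)$clusters$cluster_id), 2)
})

test_that("clustering agrees with a breadth-first components oracle", {
  cfg <- detection_config(min_cluster_size = 3)
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    puncta <- data.frame(x = sample(0:12, n, replace = TRUE),
                         y = sample(0:12, n, replace = TRUE),
                         t = sample(0:8, n, replace = TRUE))
    got <- cluster_puncta(puncta, cfg)
    oracle <- bfs_cluster_oracle(puncta, 1, 2, 3)
    expect_equal(length(unique(got$clusters$cluster_id)), oracle$n_kept)
    got_sizes <- sort(as.integer(table(got$clusters$cluster_id)),
                      decreasing = TRUE)
    expect_equal(got_sizes, oracle$kept_sizes)
    expect_equal(got$n_components, length(oracle$sizes))
  }
})

test_that("event calling encodes disappearance-before-end and event times", {
  cl <- list(clusters = data.frame(
    cluster_id = c(1, 1, 2, 2, 3),
    x = c(4, 4, 9, 9, 20), y = c(4, 4, 9, 9, 20),
    t = c(0, 1, 27, 29, 5)))
  ev <- call_events(cl, n_intervals = 30, interval_length = 100,
                    frame_rate = 10)
  expect_equal(ev$completed, c(TRUE, FALSE, TRUE))
  expect_equal(ev$event_time_s, c(20, NA, 60))
  # single-interval movie: nothing can complete
  ev1 <- call_events(list(clusters = data.frame(cluster_id = 1, x = 1,
                                                y = 1, t = 0)),
                     n_intervals = 1)
  expect_false(any(ev1$completed))
})

test_that("release series bins by 10 s with the documented labels", {
  ev <- data.frame(cluster_id = 1:3, n_puncta = 3,
                   centroid_x = 0, centroid_y = 0,
                   first_interval = 0, last_interval = c(0, 0, 5),
                   completed = TRUE,
                   event_time_s = c(10, 10, 60))
  rs <- cumulative_release(ev, n_intervals = 30)
  expect_equal(length(rs$counts), 30)
  expect_equal(rs$bin_start_s[1], 0)
  expect_equal(rs$bin_start_s[30], 290)
  expect_equal(rs$counts[1], 2)   # two events ending in interval 0
  expect_equal(rs$counts[6], 1)   # one at the 50 s bin
  expect_equal(tail(rs$cumulative, 1), 3)
  expect_true(all(diff(rs$cumulative) >= 0))
  none <- cumulative_release(ev[0, ], n_intervals = 30)
  expect_true(all(none$counts == 0))
})

test_that("event densities follow the pixel-area arithmetic", {
  mov <- movie(array(1, c(10, 20, 20)), stimulation_frame = 1)
  ev <- data.frame(cluster_id = 1, n_puncta = 3, centroid_x = 5,
                   centroid_y = 5, first_interval = 0, last_interval = 1,
                   completed = TRUE, event_time_s = 20)
  mask100 <- matrix(FALSE, 20, 20); mask100[1:10, 1:10] <- TRUE
  expect_equal(events_per_area(ev, mov, mask100), 1 / (100 * 0.106^2),
               tolerance = 1e-12)
  expect_equal(round(events_per_area(ev, mov, mask100), 3), 0.890)
  expect_equal(events_per_area(ev[0, ], mov, mask100), 0)
  mask200 <- matrix(FALSE, 20, 20); mask200[1:10, ] <- TRUE
  expect_equal(events_per_area(ev, mov, mask200),
               events_per_area(ev, mov, mask100) / 2)
  expect_error(events_per_area(ev, mov, matrix(FALSE, 20, 20)), "TRUE")
  # without stimulation metadata the whole acquisition is used, loudly
  mov_ns <- movie(array(1, c(10, 20, 20)))
  expect_warning(d <- events_per_area(ev, mov_ns, mask100),
                 "whole acquisition")
  expect_equal(d, 1 / (100 * 0.106^2))
})

test_that("Mann-Whitney U matches its identities and the enumeration oracle", {
  tie <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tie$u_statistic, 4.5)  # n_a n_b / 2 under symmetry
  sep <- mann_whitney_u(c(1, 2), c(10, 11))
  expect_equal(sep$u_statistic, 0)
  expect_equal(mann_whitney_u(c(10, 11), c(1, 2))$u_statistic, 4)
  expect_error(mann_whitney_u(numeric(0), 1), "at least one")
  set.seed(21)
  for (i in 1:15) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- sample(1:100, na); b <- sample(setdiff(1:100, a), nb)
    got <- mann_whitney_u(a, b)
    expect_equal(got$u_statistic + got$u_prime, na * nb)
    expect_equal(got$p_value, mw_exact_p_enumeration(a, b),
                 tolerance = 1e-12)
  }
  # U + U' holds with ties too
  with_ties <- mann_whitney_u(c(1, 1, 2, 5), c(1, 2, 2))
  expect_equal(with_ties$u_statistic + with_ties$u_prime, 12)
})

test_that("the pipeline is deterministic and offset-invariant end to end", {
  gm <- gen_small_movie(seed = 31)
  cfg <- small_movie_config()
  r1 <- detect_fusion_events(gm$movie, cfg)
  r2 <- detect_fusion_events(gm$movie, cfg)
  expect_identical(r1$events, r2$events)
  shifted <- movie(gm$movie$frames + 55, frame_rate = 10,
                   stimulation_frame = 1L)
  r3 <- detect_fusion_events(shifted, cfg)
  expect_identical(r1$events[, -1], r3$events[, -1])
  # cluster accounting: retained events + noise components = components
  expect_equal(nrow(r1$events) + r1$n_noise_components, r1$n_components)
})

test_that("detection recovers the scheduled events on a small movie", {
  gm <- gen_small_movie(seed = 41, n_events = 6, n_persistors = 2)
  res <- detect_fusion_events(gm$movie, small_movie_config())
  m <- match_events_to_truth(res, gm$truth)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  # ground truth lists exactly the scheduled completing events
  expect_equal(nrow(gm$truth), 6)
  # persistors are excluded from completed calls
  pers <- attr(gm$truth, "persistors")
  done <- res$events[res$events$completed, ]
  for (i in seq_len(nrow(pers))) {
    expect_false(any(abs(done$centroid_x - pers$x[i]) <= 2 &
                       abs(done$centroid_y - pers$y[i]) <= 2))
  }
  # cumulative series totals the completed events
  rs <- cumulative_release(res)
  expect_equal(tail(rs$cumulative, 1), sum(res$events$completed))
})

test_that("synthetic movies honour their schedule and seed contracts", {
  # empty schedule, zero noise: constant background
  sch0 <- fusion_schedule(NULL, noise_sd = 0)
  gm0 <- gen_movie(sch0, shape = c(16, 16), n_frames = 30)
  expect_true(all(gm0$movie$frames == 100))
  expect_equal(nrow(gm0$truth), 0)
  # same seed -> bit-identical; different seed -> different noise
  a1 <- gen_small_movie(seed = 5)
  a2 <- gen_small_movie(seed = 5)
  expect_identical(a1$movie$frames, a2$movie$frames)
  b <- gen_small_movie(seed = 6)
  expect_false(identical(a1$movie$frames, b$movie$frames))
  # out-of-bounds events are rejected
  bad <- fusion_schedule(data.frame(x = 99L, y = 5L, appear_frame = 1L,
                                    disappear_frame = 10L, amplitude = 50))
  expect_error(gen_movie(bad, shape = c(16, 16), n_frames = 30),
               "out of frame bounds")
  expect_error(fusion_schedule(data.frame(x = 1L, y = 1L, appear_frame = 5L,
                                          disappear_frame = 5L,
                                          amplitude = 1)),
               "exceed")
})

test_that("movie files round-trip through both storage formats", {
  gm <- gen_movie(fusion_schedule(
    data.frame(x = 8L, y = 8L, appear_frame = 1L, disappear_frame = 11L,
               amplitude = 50), noise_sd = 2, seed = 9),
    shape = c(24, 24), n_frames = 20)
  dir <- withr::local_tempdir()
  tif <- file.path(dir, "m.tif")
  write_movie(gm$movie, tif)
  back <- read_movie(tif)
  expect_equal(back$frames, gm$movie$frames, tolerance = 1e-5)
  expect_equal(back$frame_rate, 10)
  bin <- file.path(dir, "m.bin")
  write_movie(gm$movie, bin)
  expect_identical(read_movie(bin)$frames, gm$movie$frames)
})

test_that("footprint estimation picks the bright connected region", {
  frames <- array(10, c(5, 40, 40))
  frames[, 10:30, 8:25] <- 60  # the cell
  frames[, 38:40, 38:40] <- 55 # a small bright speck
  frames <- frames + array(rnorm(length(frames)), dim(frames))
  mask <- estimate_footprint(movie(pmax(frames, 0)))
  expect_true(all(mask[15:25, 12:20]))
  expect_false(any(mask[1:5, 1:5]))
  expect_false(mask[39, 39])  # not the largest component
})
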