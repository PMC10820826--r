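# Ground-truth-bearing synthetic TIRF movies: appearing/disappearing
# diffraction-limited Gaussian puncta on a noisy background, with the
# generating schedule returned as machine-readable truth.

#' Define a synthetic fusion schedule
#'
#' @param events data.frame with columns `x`, `y` (0-based pixel
#'   coordinates), `appear_frame`, `disappear_frame` (1-based; the spot is
#'   rendered on frames `[appear_frame, disappear_frame)`) and `amplitude`
#'   (peak counts above background). `disappear_frame` must exceed
#'   `appear_frame`.
#' @param persistors data.frame with columns `x`, `y`, `appear_frame`,
#'   `amplitude`: spots lasting to the end of the movie (docked,
#'   non-fusing vesicles).
#' @param psf_sigma Rendered spot standard deviation in pixels
#'   (default 1.5).
#' @param background Constant background level in counts (default 100).
#' @param noise_sd Gaussian noise standard deviation in counts
#'   (default 10); ignored for the Poisson model.
#' @param noise_model `"gaussian"` (default; bit-reproducible under a
#'   seed) or `"poisson"` (shot noise on the rendered intensity).
#' @param seed Integer seed fixing the noise draw.
#' @return A list of class `fusion_schedule`.
#' @export
fusion_schedule <- function(events, persistors = NULL, psf_sigma = 1.5,
                            background = 100, noise_sd = 10,
                            noise_model = c("gaussian", "poisson"),
                            seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.null(events))
    events <- data.frame(x = integer(), y = integer(),
                         appear_frame = integer(),
                         disappear_frame = integer(), amplitude = numeric())
  if (is.null(persistors))
    persistors <- data.frame(x = integer(), y = integer(),
                             appear_frame = integer(), amplitude = numeric())
  stopifnot(all(c("x", "y", "appear_frame", "disappear_frame",
                  "amplitude") %in% names(events)),
            all(c("x", "y", "appear_frame", "amplitude") %in%
                  names(persistors)))
  if (nrow(events) && any(events$disappear_frame <= events$appear_frame))
    stop("disappear_frame must exceed appear_frame for every event")
  structure(list(events = events, persistors = persistors,
                 psf_sigma = psf_sigma, background = background,
                 noise_sd = noise_sd, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "fusion_schedule")
}

#' Draw a random fusion schedule
#'
#' Samples well-separated spot positions and interval-scale lifetimes for
#' a requested number of completing events and end-persisting spots. Spot
#' amplitude is expressed as a signal-to-noise ratio relative to the frame
#' noise so detection thresholds are scale-free. Events appear after an
#' optional stimulation frame and disappear at least two intervals before
#' the movie ends; persistors appear early and last to the end.
#'
#' @param n_events Completing fusion events to schedule (default 10).
#' @param n_persistors Spots persisting to the end (default 2).
#' @param shape Frame shape `c(rows, cols)` (default `c(128, 128)`).
#' @param n_frames Total frames (default 3000).
#' @param interval_length Frames per detection interval (default 100);
#'   lifetimes are drawn in these units.
#' @param snr Peak amplitude over `noise_sd` (default 5).
#' @param noise_sd Frame noise sd in counts (default 10).
#' @param background Background counts (default 100).
#' @param psf_sigma Spot sd in pixels (default 1.5).
#' @param min_separation Minimum Chebyshev distance between spot centres in
#'   pixels (default 8).
#' @param min_life_intervals Minimum event lifetime in intervals
#'   (default 3, matching the default cluster-size filter).
#' @param stimulation_frame Events appear at or after this frame
#'   (default 1).
#' @param border Margin in pixels kept free of spot centres (default 10).
#' @param seed Integer seed.
#' @return A [fusion_schedule()].
#' @export
random_fusion_schedule <- function(n_events = 10, n_persistors = 2,
                                   shape = c(128, 128), n_frames = 3000,
                                   interval_length = 100, snr = 5,
                                   noise_sd = 10, background = 100,
                                   psf_sigma = 1.5, min_separation = 8,
                                   min_life_intervals = 3,
                                   stimulation_frame = 1, border = 10,
                                   seed = 1L) {
  set.seed(seed)
  n_int <- n_frames %/% interval_length
  first_int <- as.integer(ceiling((stimulation_frame - 1) / interval_length))
  # completed events must vanish before the final interval; leave one
  # interval of slack so partial-interval rendering cannot touch the last
  last_ok <- n_int - 2L
  if (last_ok - first_int + 1L < min_life_intervals)
    stop("movie too short for the requested lifetimes")
  n_total <- n_events + n_persistors
  pos <- sample_separated_positions(n_total, shape, border, min_separation)
  amp <- snr * noise_sd
  events <- NULL
  if (n_events > 0) {
    first <- first_int +
      floor(stats::runif(n_events) *
              pmax(1, last_ok - first_int - min_life_intervals + 1))
    life <- min_life_intervals +
      floor(stats::runif(n_events) *
              pmax(1, last_ok - first - min_life_intervals + 1))
    last <- pmin(first + life - 1L, last_ok)
    events <- data.frame(
      x = pos$x[seq_len(n_events)], y = pos$y[seq_len(n_events)],
      appear_frame = first * interval_length + 1L,
      disappear_frame = (last + 1L) * interval_length + 1L,
      amplitude = amp)
  }
  persistors <- NULL
  if (n_persistors > 0) {
    idx <- n_events + seq_len(n_persistors)
    persistors <- data.frame(
      x = pos$x[idx], y = pos$y[idx],
      appear_frame = 1L, amplitude = amp)
  }
  fusion_schedule(events, persistors, psf_sigma = psf_sigma,
                  background = background, noise_sd = noise_sd,
                  seed = seed)
}

# Rejection-sample spot centres at least min_sep apart (Chebyshev).
sample_separated_positions <- function(n, shape, border, min_sep) {
  xs <- ys <- integer(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > 10000L)
      stop("cannot place the requested number of separated spots; reduce n or min_separation")
    x <- sample(border:(shape[2] - 1L - border), 1L)
    y <- sample(border:(shape[1] - 1L - border), 1L)
    if (length(xs) == 0L ||
        all(pmax(abs(xs - x), abs(ys - y)) >= min_sep)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  list(x = xs, y = ys)
}

#' Render a synthetic TIRF movie from a schedule
#'
#' Each scheduled spot is an isotropic 2-D Gaussian of standard deviation
#' `psf_sigma` added to the constant background on its active frames;
#' seeded noise is applied last (Gaussian noise is bit-reproducible under
#' the seed). The returned ground truth lists the expected completed
#' events -- those disappearing before the movie end -- with their interval
#' indices.
#'
#' @param schedule A [fusion_schedule()].
#' @param shape Frame shape `c(rows, cols)` (default `c(128, 128)`).
#' @param n_frames Total frames (default 3000).
#' @param frame_rate Hz (default 10).
#' @param pixel_size_nm Pixel size (default 106).
#' @param interval_length Frames per interval used for the truth's
#'   interval bookkeeping (default 100).
#' @param stimulation_frame Optional stimulation frame stored in the movie
#'   metadata.
#' @return List with `movie` (a [movie()]) and `truth` (data.frame of
#'   expected completed events: `x`, `y`, `appear_interval`,
#'   `last_interval`; persistors and the full schedule are attached as
#'   attributes).
#' @export
gen_movie <- function(schedule, shape = c(128, 128), n_frames = 3000,
                      frame_rate = 10, pixel_size_nm = 106,
                      interval_length = 100, stimulation_frame = NULL) {
  stopifnot(inherits(schedule, "fusion_schedule"))
  ev <- schedule$events
  pe <- schedule$persistors
  all_x <- c(ev$x, pe$x); all_y <- c(ev$y, pe$y)
  if (length(all_x) &&
      (any(all_x < 0 | all_x >= shape[2]) ||
       any(all_y < 0 | all_y >= shape[1])))
    stop("scheduled spot out of frame bounds")
  if (nrow(ev) && any(ev$appear_frame < 1 | ev$appear_frame > n_frames))
    stop("event appear_frame outside the movie")

  frames <- array(schedule$background, c(n_frames, shape[1], shape[2]))
  render <- function(x, y, a_frame, d_frame, amp) {
    spot <- gaussian_spot(x, y, amp, schedule$psf_sigma, shape)
    rows <- spot$rows; cols <- spot$cols
    fr <- a_frame:(d_frame - 1L)
    frames[fr, rows, cols] <<-
      frames[fr, rows, cols, drop = FALSE] +
      rep(spot$patch, each = length(fr))
  }
  for (i in seq_len(nrow(ev)))
    render(ev$x[i], ev$y[i], ev$appear_frame[i],
           min(ev$disappear_frame[i], n_frames + 1L), ev$amplitude[i])
  for (i in seq_len(nrow(pe)))
    render(pe$x[i], pe$y[i], pe$appear_frame[i], n_frames + 1L,
           pe$amplitude[i])

  set.seed(schedule$seed)
  if (schedule$noise_model == "gaussian") {
    if (schedule$noise_sd > 0)
      frames <- frames + stats::rnorm(length(frames),
                                      sd = schedule$noise_sd)
  } else {
    frames <- array(stats::rpois(length(frames), lambda = frames),
                    dim(frames))
  }
  frames[frames < 0] <- 0

  completed <- ev[ev$disappear_frame <= n_frames, , drop = FALSE]
  truth <- data.frame(
    x = completed$x, y = completed$y,
    appear_interval = (completed$appear_frame - 1L) %/% interval_length,
    last_interval = (completed$disappear_frame - 2L) %/% interval_length)
  attr(truth, "persistors") <- pe
  attr(truth, "schedule") <- schedule
  list(movie = movie(frames, frame_rate = frame_rate,
                     pixel_size_nm = pixel_size_nm,
                     stimulation_frame = stimulation_frame),
       truth = truth)
}

# Precompute the local Gaussian patch for a spot centred on integer pixel
# (x = column, y = row), truncated at 4 sigma.
gaussian_spot <- function(x, y, amplitude, sigma, shape) {
  r <- ceiling(4 * sigma)
  rows <- max(1L, y + 1L - r):min(shape[1], y + 1L + r)
  cols <- max(1L, x + 1L - r):min(shape[2], x + 1L + r)
  dy <- rows - (y + 1L); dx <- cols - (x + 1L)
  patch <- amplitude * exp(-outer(dy^2, dx^2, "+") / (2 * sigma^2))
  list(rows = rows, cols = cols, patch = patch)
}

#' Match detected events to scheduled ground truth
#'
#' Greedy one-to-one matching of detected completed events to truth events
#' by centroid proximity and disappearance-interval agreement; used for
#' recall/precision benchmarking of the detection pipeline.
#'
#' @param events Completed-event table from [detect_fusion_events()].
#' @param truth Truth table from [gen_movie()].
#' @param max_dist_px Maximum centroid distance in pixels (default 2).
#' @param max_dt Maximum |interval difference| of disappearance
#'   (default 1).
#' @return List with `n_truth`, `n_detected`, `n_matched`, `recall`,
#'   `precision`.
#' @export
match_events_to_truth <- function(events, truth, max_dist_px = 2,
                                  max_dt = 1) {
  if (inherits(events, "fusion_events")) events <- events$events
  det <- events[events$completed, , drop = FALSE]
  n_t <- nrow(truth); n_d <- nrow(det)
  used <- rep(FALSE, n_d)
  matched <- 0L
  for (i in seq_len(n_t)) {
    if (!n_d) break
    dd <- sqrt((det$centroid_x - truth$x[i])^2 +
                 (det$centroid_y - truth$y[i])^2)
    dt <- abs(det$last_interval - truth$last_interval[i])
    cand <- which(!used & dd <= max_dist_px & dt <= max_dt)
    if (length(cand)) {
      used[cand[which.min(dd[cand])]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_truth = n_t, n_detected = n_d, n_matched = matched,
       recall = if (n_t) matched / n_t else NA_real_,
       precision = if (n_d) matched / n_d else NA_real_)
}

#' Simulate per-cell evoked event densities for a two-condition cohort
#'
#' Emulates a rescue-style exocytosis experiment: each synthetic cell is a
#' short TIRF movie with a Poisson-distributed number of scheduled
#' completing fusion events (plus persisting docked vesicles); the full
#' detection pipeline is run on every movie and the per-cell completed
#' evoked-event density (events per square micron over the whole frame) is
#' returned. Movies are deliberately compact (default 64 x 64 px, 400
#' frames at 10 Hz averaged in 40-frame intervals) so whole cohorts run in
#' seconds while exercising every pipeline stage.
#'
#' @param n_cells Number of cells (movies) to simulate.
#' @param event_rate Mean scheduled completed events per cell (Poisson;
#'   capped at `max_events` to keep spots placeable).
#' @param n_persistors Docked spots persisting to the movie end per cell
#'   (default 2).
#' @param shape,n_frames,interval_length,frame_rate,pixel_size_nm Movie
#'   geometry (defaults 64 x 64, 400 frames, 40-frame intervals, 10 Hz,
#'   106 nm).
#' @param snr Spot peak amplitude over frame noise sd (default 5).
#' @param max_events Cap on scheduled events per cell (default 24).
#' @param seed Integer seed for the whole cohort.
#' @return List with `densities` (per-cell events/um^2), `true_counts`
#'   (scheduled completed events per cell) and `detected_counts`.
#' @export
simulate_evoked_cohort <- function(n_cells, event_rate, n_persistors = 2,
                                   shape = c(64, 64), n_frames = 400,
                                   interval_length = 40, frame_rate = 10,
                                   pixel_size_nm = 106, snr = 5,
                                   max_events = 24, seed = 1L) {
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  n_events <- pmin(stats::rpois(n_cells, event_rate), max_events)
  config <- detection_config(interval_length = interval_length)
  mask <- matrix(TRUE, shape[1], shape[2])
  densities <- detected <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    sch <- random_fusion_schedule(
      n_events = n_events[i], n_persistors = n_persistors, shape = shape,
      n_frames = n_frames, interval_length = interval_length, snr = snr,
      min_separation = 7, border = 8, seed = cell_seeds[i])
    gm <- gen_movie(sch, shape = shape, n_frames = n_frames,
                    frame_rate = frame_rate, pixel_size_nm = pixel_size_nm,
                    interval_length = interval_length,
                    stimulation_frame = 1L)
    res <- detect_fusion_events(gm$movie, config)
    detected[i] <- sum(res$events$completed)
    densities[i] <- events_per_area(res, gm$movie, mask)
  }
  list(densities = densities, true_counts = n_events,
       detected_counts = detected)
}
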