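# Release time series, per-area event densities and two-group
# nonparametric comparison.

#' Cumulative release time series
#'
#' Bins completed fusion events into 10 s bins over the acquisition (a
#' 300 s movie gives 30 bins labelled by their start times 0-290 s) and
#' accumulates. An event falls in the bin containing the start of its last
#' interval, so an event whose cluster ends in the first interval counts in
#' the 0 s bin.
#'
#' @param events Event table from [call_events()] /
#'   [detect_fusion_events()]`$events`.
#' @param n_intervals Total intervals in the acquisition.
#' @param interval_length Frames per interval.
#' @param frame_rate Hz.
#' @param bin_width_s Bin width in seconds (default 10).
#' @return An object of class `release_series`: list with `bin_start_s`,
#'   `counts`, `cumulative`.
#' @export
cumulative_release <- function(events, n_intervals, interval_length = 100,
                               frame_rate = 10, bin_width_s = 10) {
  if (inherits(events, "fusion_events")) {
    n_intervals <- events$n_intervals
    interval_length <- events$config$interval_length
    frame_rate <- events$movie_info$frame_rate
    events <- events$events
  }
  total_s <- n_intervals * interval_length / frame_rate
  bin_start <- seq(0, total_s - bin_width_s, by = bin_width_s)
  counts <- integer(length(bin_start))
  done <- events[events$completed, , drop = FALSE]
  if (nrow(done)) {
    ev_start_s <- done$last_interval * interval_length / frame_rate
    idx <- findInterval(ev_start_s, c(bin_start, total_s),
                        rightmost.closed = TRUE)
    idx <- idx[idx >= 1 & idx <= length(counts)]
    tab <- table(idx)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  structure(list(bin_start_s = bin_start, counts = counts,
                 cumulative = cumsum(counts)),
            class = "release_series")
}

#' @export
print.release_series <- function(x, ...) {
  cat(sprintf("Release series: %d bins of %g s, %d events total\n",
              length(x$counts), diff(x$bin_start_s[1:2]),
              sum(x$counts)))
  invisible(x)
}

#' Evoked fusion-event density per square micron
#'
#' Counts completed events at or after the stimulation time and divides by
#' the footprint area. At 106 nm pixels one pixel is 0.011236 um^2. When
#' the movie carries no stimulation frame all completed events are counted
#' (whole-acquisition density) with a warning.
#'
#' @param events Event table (or [detect_fusion_events()] result).
#' @param mov The [movie()] the events came from (pixel size and
#'   stimulation metadata).
#' @param footprint_mask Logical matrix, same shape as a frame, marking
#'   the cell footprint; must contain at least one `TRUE` pixel.
#' @return Events per square micron (single number).
#' @export
events_per_area <- function(events, mov, footprint_mask) {
  if (inherits(events, "fusion_events")) events <- events$events
  stopifnot(inherits(mov, "movie"))
  d <- dim(mov$frames)
  if (!is.matrix(footprint_mask) ||
      !identical(dim(footprint_mask), d[2:3]))
    stop("footprint_mask must be a matrix with the frame dimensions")
  mask <- as.logical(footprint_mask)
  n_px <- sum(mask)
  if (n_px < 1L) stop("footprint_mask has no TRUE pixels")
  done <- events[events$completed, , drop = FALSE]
  if (is.null(mov$stimulation_frame)) {
    warning("movie has no stimulation_frame; computing density over the whole acquisition")
    n_ev <- nrow(done)
  } else {
    stim_s <- mov$stimulation_frame / mov$frame_rate
    n_ev <- sum(done$event_time_s >= stim_s)
  }
  px_um2 <- (mov$pixel_size_nm / 1000)^2
  n_ev / (n_px * px_um2)
}

#' Estimate the cell footprint from the time-mean image
#'
#' Otsu threshold on the normalised time-mean image, keeping the largest
#' connected component. Intended for movies with genuine cell/background
#' contrast; explicit masks can always be supplied instead.
#'
#' @param mov A [movie()].
#' @return Logical matrix marking the footprint.
#' @export
estimate_footprint <- function(mov) {
  stopifnot(inherits(mov, "movie"))
  avg <- apply(mov$frames, c(2, 3), mean)
  rng <- range(avg)
  if (diff(rng) < .Machine$double.eps)
    return(matrix(TRUE, nrow(avg), ncol(avg)))
  norm <- (avg - rng[1]) / diff(rng)
  thr <- EBImage::otsu(norm, range = c(0, 1))
  bw <- norm > thr
  lab <- EBImage::bwlabel(bw)
  if (max(lab) == 0) return(bw)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Mann-Whitney U comparison of two groups
#'
#' Rank-sum U statistic with midrank ties; the two-sided p-value is exact
#' (distribution enumeration) when `n_a * n_b <= 400` and there are no
#' ties, otherwise a normal approximation with tie and continuity
#' correction is used. The complementary statistic satisfies
#' `U + U' = n_a * n_b`.
#'
#' @param group_a,group_b Numeric vectors (each non-empty), e.g. per-cell
#'   event densities of two conditions.
#' @return An object of class `group_comparison`: list with
#'   `group_a_values`, `group_b_values`, `u_statistic` (for group A),
#'   `u_prime` (for group B), `p_value` (two-sided) and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must contain at least one value")
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  na <- length(group_a); nb <- length(group_b)
  r <- rank(c(group_a, group_b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (na * nb <= 400) && !has_ties
  p <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE,
                       alternative = "two.sided")$p.value)
  structure(
    list(group_a_values = group_a, group_b_values = group_b,
         u_statistic = u_a, u_prime = na * nb - u_a, p_value = p,
         method = if (exact) "exact" else "normal approximation with tie/continuity correction"),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: n = %d vs %d, U = %g (U' = %g), two-sided p = %.4g (%s)\n",
              length(x$group_a_values), length(x$group_b_values),
              x$u_statistic, x$u_prime, x$p_value, x$method))
  invisible(x)
}
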