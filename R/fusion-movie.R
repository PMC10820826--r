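# TIRF movie container and IO. Frames are a (time, row, column) array of
# non-negative intensities; acquisition defaults mirror a standard
# footprint-imaging setup (10 Hz, 106 nm pixels, 3000 frames = 300 s).

#' Construct a TIRF movie
#'
#' @param frames 3-D numeric array ordered (time, row, column), all values
#'   finite and non-negative.
#' @param frame_rate Acquisition rate in Hz (default 10, i.e. 100 ms
#'   frames).
#' @param pixel_size_nm Pixel size in nanometres (default 106).
#' @param stimulation_frame Optional frame index (1-based) at which
#'   secretagogue stimulation was applied.
#' @return An object of class `movie`.
#' @export
movie <- function(frames, frame_rate = 10, pixel_size_nm = 106,
                  stimulation_frame = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a 3-D array ordered (time, row, column)")
  if (dim(frames)[1] < 1L) stop("a movie needs at least one frame")
  if (any(!is.finite(frames))) stop("frames must be finite")
  if (any(frames < 0)) stop("frame intensities must be non-negative")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be positive")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size_nm = pixel_size_nm,
                 stimulation_frame = stimulation_frame),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("TIRF movie: %d frames of %dx%d px at %g Hz (%.1f s), %g nm/px\n",
              d[1], d[2], d[3], x$frame_rate, d[1] / x$frame_rate,
              x$pixel_size_nm))
  if (!is.null(x$stimulation_frame))
    cat(sprintf("  stimulation at frame %d (%.1f s)\n", x$stimulation_frame,
                x$stimulation_frame / x$frame_rate))
  invisible(x)
}

#' Read a movie from multi-frame TIFF or raw binary
#'
#' TIFF movies (`.tif`/`.tiff`) are read frame by frame; raw movies
#' (`.bin`) are read as doubles. Both formats use a sidecar JSON
#' (`<path>.json`) carrying `frame_rate_hz`, `pixel_size_nm`, optional
#' `stimulation_frame`, for raw files the array `dims` (time, row, column),
#' and for TIFFs written by [write_movie()] an intensity `scale` that is
#' multiplied back in.
#'
#' @param path Movie file path.
#' @param meta Optional sidecar JSON path (default `<path>.json`).
#' @return A [movie()].
#' @export
read_movie <- function(path, meta = NULL) {
  if (!file.exists(path)) stop(sprintf("movie not found: %s", path))
  if (is.null(meta)) meta <- paste0(path, ".json")
  md <- if (file.exists(meta))
    jsonlite::read_json(meta, simplifyVector = TRUE) else list()
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    fr <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(fr)) fr <- list(fr)
    arr <- array(0, c(length(fr), dim(fr[[1]])))
    for (i in seq_along(fr)) arr[i, , ] <- fr[[i]]
    if (!is.null(md$scale)) arr <- arr * md$scale
  } else if (ext == "bin") {
    if (is.null(md$dims))
      stop(sprintf("raw movie %s needs 'dims' in its sidecar JSON", path))
    vals <- readBin(path, "double", n = prod(md$dims))
    arr <- array(vals, md$dims)
  } else stop(sprintf("unsupported movie format '.%s'", ext))
  movie(arr,
        frame_rate = if (!is.null(md$frame_rate_hz)) md$frame_rate_hz else 10,
        pixel_size_nm = if (!is.null(md$pixel_size_nm)) md$pixel_size_nm else 106,
        stimulation_frame = md$stimulation_frame)
}

#' Write a movie with its sidecar JSON
#'
#' TIFF output is 32-bit float; intensities are scaled into `[0, 1]` (the
#' defined storage range) and the scale factor recorded in the sidecar so
#' [read_movie()] restores the original values. Raw `.bin` output stores
#' doubles losslessly.
#'
#' @param mov A [movie()].
#' @param path Output path ending in `.tif`/`.tiff` or `.bin`.
#' @return Invisibly, `path`.
#' @export
write_movie <- function(mov, path) {
  stopifnot(inherits(mov, "movie"))
  ext <- tolower(tools::file_ext(path))
  md <- list(frame_rate_hz = mov$frame_rate,
             pixel_size_nm = mov$pixel_size_nm,
             stimulation_frame = mov$stimulation_frame)
  if (ext %in% c("tif", "tiff")) {
    scale <- max(mov$frames, 1e-12)
    md$scale <- scale
    fr <- lapply(seq_len(dim(mov$frames)[1]),
                 function(i) mov$frames[i, , ] / scale)
    tiff::writeTIFF(fr, path, bits.per.sample = 32L)
  } else if (ext == "bin") {
    md$dims <- dim(mov$frames)
    writeBin(as.numeric(mov$frames), path)
  } else stop(sprintf("unsupported movie format '.%s'", ext))
  jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Average a movie over fixed-length frame intervals
#'
#' Divides the acquisition into consecutive `interval_length`-frame
#' intervals and returns the per-pixel mean image of each; a trailing
#' partial interval is dropped. With 3000 frames and 100-frame intervals
#' this yields 30 images spanning 10 s each.
#'
#' @param mov A [movie()] (or a bare 3-D array).
#' @param interval_length Frames per interval (>= 1, default 100).
#' @return A 3-D array (interval, row, column) of mean images.
#' @export
interval_mean_projection <- function(mov, interval_length = 100) {
  frames <- if (inherits(mov, "movie")) mov$frames else mov
  if (!is.array(frames) || length(dim(frames)) != 3L || dim(frames)[1] < 1L)
    stop("need a non-empty 3-D frame array")
  if (interval_length < 1L) stop("interval_length must be >= 1")
  d <- dim(frames)
  n_int <- d[1] %/% interval_length
  if (n_int < 1L)
    stop(sprintf("movie has %d frames, fewer than one %d-frame interval",
                 d[1], interval_length))
  used <- n_int * interval_length
  # (frame, pixel) matrix -> (interval_position, interval, pixel) array,
  # then mean over positions
  m <- matrix(frames[seq_len(used), , , drop = FALSE], nrow = used)
  dim(m) <- c(interval_length, n_int, d[2] * d[3])
  out <- colMeans(m)  # (interval, pixel)
  array(out, c(n_int, d[2], d[3]))
}
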