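#' TIRF movie container
#'
#' A `tirf_movie` bundles a single-channel time-lapse intensity stack with
#' its acquisition metadata. The stack is stored as a numeric array with
#' dimensions `(rows, cols, frames)`; frame indices in all tables produced
#' by the package are 0-based, as are pixel coordinates (`x` = column,
#' `y` = row, origin at the centre of the top-left pixel).
#'
#' @param data A numeric 3-D array `(rows, cols, frames)`, a matrix (taken
#'   as a single frame), or a list of equally sized matrices.
#' @param frame_interval Time between frames in seconds (`NA` if unknown).
#' @param pixel_size Pixel size in micrometres per pixel (`NA` if unknown).
#' @param source Optional label or path describing where the movie came from.
#' @param mask Optional logical array of the same dimensions marking valid
#'   pixels (`FALSE` where drift correction filled values in from outside
#'   the field). `NULL` means all pixels are valid.
#'
#' @return An object of class `tirf_movie`.
#' @examples
#' m <- tirf_movie(array(100, c(16, 16, 3)), frame_interval = 5)
#' n_frames(m)
#' @export
tirf_movie <- function(data, frame_interval = NA_real_, pixel_size = NA_real_,
                       source = NA_character_, mask = NULL) {
  if (is.list(data) && !is.array(data)) {
    dims <- unique(lapply(data, dim))
    if (length(dims) != 1L) {
      abort("All frames must have the same dimensions.")
    }
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dims[[1]], length(data)))
  }
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a (rows, cols, frames) array or list of matrices.")
  }
  if (any(dim(data) < 1L)) {
    abort("Movie must have positive field dimensions and at least one frame.")
  }
  if (!is.na(frame_interval) && frame_interval <= 0) {
    abort("`frame_interval` must be positive.")
  }
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == dim(data)))
  }
  structure(
    list(data = data, frame_interval = as.numeric(frame_interval),
         pixel_size = as.numeric(pixel_size), source = source, mask = mask),
    class = "tirf_movie"
  )
}

#' @rdname tirf_movie
#' @param movie A `tirf_movie`.
#' @export
n_frames <- function(movie) {
  stopifnot(inherits(movie, "tirf_movie"))
  dim(movie$data)[3]
}

#' Extract one frame of a movie as a matrix
#'
#' @param movie A `tirf_movie`.
#' @param frame 0-based frame index.
#' @return A numeric matrix.
#' @export
movie_frame <- function(movie, frame) {
  stopifnot(inherits(movie, "tirf_movie"))
  if (frame < 0 || frame >= n_frames(movie)) {
    abort(sprintf("Frame %d out of range [0, %d].", frame, n_frames(movie) - 1L))
  }
  movie$data[, , frame + 1L]
}

#' @export
print.tirf_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<tirf_movie> %d x %d px, %d frames\n", d[1], d[2], d[3]))
  cat(sprintf("  frame interval: %s s, pixel size: %s um/px\n",
              format(x$frame_interval), format(x$pixel_size)))
  if (!is.null(x$mask)) {
    cat(sprintf("  validity mask: %.2f%% valid\n", 100 * mean(x$mask)))
  }
  if (!is.na(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @export
dim.tirf_movie <- function(x) dim(x$data)
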