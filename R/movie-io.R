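#' Read a time-lapse movie from a multipage TIFF
#'
#' Accepts plain multipage greyscale TIFF and the ImageJ hyperstack
#' dialect. The frame interval is taken from an ImageJ description block
#' (`finterval=` or `fps=`) when present, otherwise from the
#' `frame_interval` argument, otherwise it is recorded as `NA`
#' ("unknown interval") with a message.
#'
#' @param path Path to a TIFF file.
#' @param frame_interval Fallback frame interval in seconds.
#' @param pixel_size Optional pixel size in micrometres per pixel.
#' @return A [tirf_movie()] with integer intensities in original ADU.
#' @export
read_movie <- function(path, frame_interval = NULL, pixel_size = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (is.array(pages) || is.matrix(pages)) pages <- list(pages)
  if (length(pages) == 0L) {
    abort(sprintf("'%s' contains no pages (empty movie).", path))
  }
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1)))) {
    abort(sprintf(
      "'%s' has multi-channel (RGB/multisample) pages; only single-channel movies are supported.",
      path
    ))
  }
  interval <- parse_imagej_interval(attr(pages[[1]], "description"))
  if (is.na(interval)) {
    if (!is.null(frame_interval)) {
      interval <- frame_interval
    } else {
      inform(sprintf("'%s': frame interval unknown; recorded as NA.",
                     basename(path)))
      interval <- NA_real_
    }
  }
  tirf_movie(pages, frame_interval = interval, pixel_size = pixel_size,
             source = path)
}

parse_imagej_interval <- function(desc) {
  if (is.null(desc) || !any(grepl("ImageJ", desc))) return(NA_real_)
  desc <- paste(desc, collapse = "\n")
  m <- regmatches(desc, regexec("finterval=([0-9.eE+-]+)", desc))[[1]]
  if (length(m) == 2L) return(as.numeric(m[2]))
  m <- regmatches(desc, regexec("fps=([0-9.eE+-]+)", desc))[[1]]
  if (length(m) == 2L && as.numeric(m[2]) > 0) return(1 / as.numeric(m[2]))
  NA_real_
}

#' Write a movie as a 16-bit multipage TIFF
#'
#' Intensities are rounded to integers; values outside `[0, 65535]` are
#' clipped with a warning reporting how many pixels saturated.
#'
#' @param movie A [tirf_movie()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "tirf_movie"))
  data <- round(movie$data)
  n_over <- sum(data > 65535)
  n_under <- sum(data < 0)
  if (n_over + n_under > 0) {
    warn(sprintf(
      "%d pixel(s) above 65535 and %d below 0 were clipped to the 16-bit range.",
      n_over, n_under
    ))
    data <- pmin(pmax(data, 0), 65535)
  }
  pages <- lapply(seq_len(dim(data)[3]), function(f) data[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW",
                  reduce = FALSE)
  invisible(path)
}

# ---- tabular round-trips -------------------------------------------------

read_checked_csv <- function(path, required, col_types) {
  tab <- readr::read_csv(path, col_types = col_types,
                         na = c("", "NA"), progress = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("'%s' is missing required column(s): %s",
                  path, toString(missing_cols)))
  }
  tab
}

#' Read and write package tables as CSV
#'
#' All tables round-trip through UTF-8 CSV with a mandatory header, "."
#' decimal separator and full numeric precision; rows are written in
#' stable `spot_id` (and `frame`) order. Readers fail with a schema error
#' naming the first missing required column.
#'
#' Schemas: spots (`spot_id,x,y,roi_radius,annulus_inner,annulus_outer`),
#' traces (`spot_id,frame,raw,normalized,valid,initial_intensity`, long
#' format), events (`spot_id,x,y,verdict,drop_frame,initial_intensity`),
#' truth (`spot_id,x,y,event_type,event_frame`).
#'
#' @param x A tibble of the corresponding type.
#' @param path File path.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_spots <- function(x, path) {
  stopifnot(all(c("spot_id", "x", "y") %in% names(x)))
  readr::write_csv(arrange(x, spot_id), path, progress = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_spots <- function(path) {
  read_checked_csv(path, c("spot_id", "x", "y"), readr::cols())
}

#' @rdname table_io
#' @export
write_traces <- function(x, path) {
  stopifnot(all(c("spot_id", "frame", "raw") %in% names(x)))
  readr::write_csv(arrange(x, spot_id, frame), path, progress = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_traces <- function(path) {
  read_checked_csv(path, c("spot_id", "frame", "raw"), readr::cols())
}

#' @rdname table_io
#' @export
write_events <- function(x, path) {
  stopifnot(all(c("spot_id", "verdict", "drop_frame") %in% names(x)))
  readr::write_csv(arrange(x, spot_id), path, progress = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_events <- function(path) {
  read_checked_csv(path, c("spot_id", "verdict", "drop_frame"),
                   readr::cols())
}

#' @rdname table_io
#' @export
write_truth <- function(x, path) {
  stopifnot(all(c("spot_id", "event_type", "event_frame") %in% names(x)))
  readr::write_csv(arrange(x, spot_id), path, progress = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_truth <- function(path) {
  read_checked_csv(path, c("spot_id", "event_type", "event_frame"),
                   readr::cols())
}

#' @rdname table_io
#' @export
write_plate <- function(x, path) {
  stopifnot(all(c("well_id", "role", "time_s", "signal") %in% names(x)))
  readr::write_csv(arrange(x, well_id, time_s), path, progress = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_plate <- function(path) {
  read_checked_csv(path, c("well_id", "role", "time_s", "signal"),
                   readr::cols())
}
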