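#' Build the reference image for spot detection
#'
#' Pixelwise mean of the first `n_reference_frames` frames of the
#' (drift-corrected) movie. Averaging a few early frames suppresses shot
#' noise by roughly the square root of the window length while preceding
#' almost all loss events.
#'
#' @param movie A [tirf_movie()].
#' @param n_reference_frames Number of initial frames to average
#'   (default 5).
#' @return A numeric matrix.
#' @export
build_reference <- function(movie, n_reference_frames = 5) {
  stopifnot(inherits(movie, "tirf_movie"))
  nf <- n_frames(movie)
  if (n_reference_frames < 1 || n_reference_frames > nf) {
    abort(sprintf("`n_reference_frames` must be in [1, %d].", nf))
  }
  if (n_reference_frames == 1) return(movie$data[, , 1])
  apply(movie$data[, , seq_len(n_reference_frames), drop = FALSE],
        c(1, 2), mean)
}

#' Detect diffraction-limited spots as local maxima
#'
#' The reference image is Gaussian-smoothed, local maxima above a
#' prominence threshold over the background median are found, and maxima
#' closer than `min_distance` are resolved by keeping the brighter one
#' (ties broken towards lower `(y, x)`). Maxima whose background annulus
#' would leave the field are dropped. Spots are detected once, on the
#' reference image, and held fixed: the molecules are
#' surface-immobilized and drift has been removed, and the assay only
#' loses signal over time.
#'
#' @param image Reference image matrix (see [build_reference()]).
#' @param smoothing_sigma Gaussian smoothing sigma in pixels, of the order
#'   of the PSF sigma (default 1.2).
#' @param threshold `"auto"` (background median + `k` robust SDs, where
#'   the robust SD is `1.4826 x MAD` of the smoothed image) or a numeric
#'   prominence in intensity units above the background median.
#' @param k Multiplier for the automatic threshold (default 5).
#' @param min_distance Minimum allowed distance between detections,
#'   pixels.
#' @param roi_radius Radius of the circular measurement ROI; default
#'   `ceiling(2 * smoothing_sigma)`.
#' @param annulus_gap,annulus_width Background annulus geometry: it spans
#'   radii `(roi_radius + annulus_gap, roi_radius + annulus_gap +
#'   annulus_width]`.
#' @return A tibble of spots: `spot_id`, `x`, `y` (0-based integer pixel
#'   coordinates), `roi_radius`, `annulus_inner`, `annulus_outer`, `peak`
#'   (smoothed peak intensity). IDs are assigned in `(y, x)` raster order.
#' @export
detect_spots <- function(image, smoothing_sigma = 1.2, threshold = "auto",
                         k = 5, min_distance = 5, roi_radius = NULL,
                         annulus_gap = 2, annulus_width = 2) {
  stopifnot(is.matrix(image), min_distance >= 1)
  roi_radius <- roi_radius %||% ceiling(2 * smoothing_sigma)
  annulus_inner <- roi_radius + annulus_gap
  annulus_outer <- annulus_inner + annulus_width
  sm <- gaussian_smooth(image, smoothing_sigma)
  bg <- median(sm)
  thr <- if (identical(threshold, "auto")) {
    bg + k * mad(sm)
  } else {
    bg + as.numeric(threshold)
  }
  cand <- local_maxima(sm)
  cand <- cand[sm[cand] > thr]
  if (length(cand) == 0L) {
    return(tibble(spot_id = integer(), x = integer(), y = integer(),
                  roi_radius = integer(), annulus_inner = integer(),
                  annulus_outer = integer(), peak = numeric()))
  }
  pos <- arrayInd(cand, dim(sm))
  pts <- tibble(y = pos[, 1] - 1L, x = pos[, 2] - 1L, peak = sm[cand]) |>
    arrange(desc(peak), y, x)
  keep <- logical(nrow(pts))
  min_sq <- min_distance^2
  for (i in seq_len(nrow(pts))) {
    if (!any(keep) ||
        all((pts$y[keep] - pts$y[i])^2 + (pts$x[keep] - pts$x[i])^2 >= min_sq)) {
      keep[i] <- TRUE
    }
  }
  pts <- pts[keep, ]
  # annulus must fit in the field
  nr <- nrow(image)
  nc <- ncol(image)
  pts <- filter(pts,
                y - annulus_outer >= 0, y + annulus_outer <= nr - 1,
                x - annulus_outer >= 0, x + annulus_outer <= nc - 1)
  pts |>
    arrange(y, x) |>
    mutate(spot_id = row_number(),
           roi_radius = roi_radius,
           annulus_inner = annulus_inner,
           annulus_outer = annulus_outer) |>
    select(spot_id, x, y, roi_radius, annulus_inner, annulus_outer, peak)
}

gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  sm <- EBImage::imageData(EBImage::gblur(image, sigma = sigma,
                                          boundary = "replicate"))
  matrix(as.numeric(sm), nrow(image), ncol(image))
}

# linear indices of pixels that are >= all 8 neighbours (border excluded)
local_maxima <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  if (nr < 3 || nc < 3) return(integer())
  core <- m[2:(nr - 1), 2:(nc - 1)]
  is_max <- matrix(TRUE, nr - 2, nc - 2)
  for (a in -1:1) {
    for (b in -1:1) {
      if (a == 0 && b == 0) next
      is_max <- is_max & core >= m[2:(nr - 1) + a, 2:(nc - 1) + b]
    }
  }
  idx <- which(is_max)
  pos <- arrayInd(idx, dim(is_max))
  (pos[, 2] + 1L - 1L) * nr + pos[, 1] + 1L
}

# integer pixel offsets (dy, dx) of a filled disk of given radius
disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

# offsets of an annulus inner < d <= outer
annulus_offsets <- function(inner, outer) {
  r <- ceiling(outer)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- g$dy^2 + g$dx^2
  g[d2 > inner^2 & d2 <= outer^2, , drop = FALSE]
}

#' Local background around a spot
#'
#' Median intensity of the pixels in the spot's background annulus
#' (radii in `(annulus_inner, annulus_outer]`). The median is robust to a
#' neighbouring spot or bright impulse overlapping part of the annulus.
#'
#' @param image An image matrix.
#' @param spots A spot tibble from [detect_spots()] (any subset of rows).
#' @return Numeric vector of background levels, one per spot row.
#' @export
measure_local_background <- function(image, spots) {
  nr <- nrow(image)
  nc <- ncol(image)
  vapply(seq_len(nrow(spots)), function(i) {
    off <- annulus_offsets(spots$annulus_inner[i], spots$annulus_outer[i])
    rr <- round(spots$y[i]) + 1L + off$dy
    cc <- round(spots$x[i]) + 1L + off$dx
    if (any(rr < 1 | rr > nr | cc < 1 | cc > nc)) {
      abort(sprintf("Annulus of spot %s leaves the field.", spots$spot_id[i]))
    }
    median(image[cbind(rr, cc)])
  }, numeric(1))
}
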