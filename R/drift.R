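#' Estimate the translation between two images
#'
#' Cross-correlation via FFT, with subpixel refinement by a localized
#' upsampled discrete Fourier transform (matrix-multiply DFT around the
#' integer peak). Returns the shift `s = (dy, dx)` such that `image_a` is
#' `image_b` translated by `s`; equivalently, translating `image_b` by `s`
#' aligns it to `image_a`.
#'
#' @param image_a,image_b Numeric matrices of equal dimensions.
#' @param upsample Upsampling factor; the shift is resolved to
#'   `1/upsample` pixels (default 20, i.e. 0.05 px).
#' @return Named numeric vector `c(dy = , dx = )`.
#' @export
estimate_pairwise_shift <- function(image_a, image_b, upsample = 20) {
  if (!all(dim(image_a) == dim(image_b))) {
    abort("Images must have identical dimensions.")
  }
  if (sd(image_a) == 0 || sd(image_b) == 0) {
    abort("Shift is undefined for a constant image.")
  }
  fa <- fft(image_a - mean(image_a))
  fb <- fft(image_b - mean(image_b))
  phase_corr_shift(fa, fb, upsample)
}

# core registration on precomputed FFTs (reference FFT reused across frames)
phase_corr_shift <- function(fa, fb, upsample = 20) {
  nr <- nrow(fa)
  nc <- ncol(fa)
  prod_f <- fa * Conj(fb)
  cc <- Re(fft(prod_f, inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc)) - 1L
  shift <- as.numeric(peak)
  if (shift[1] > nr / 2) shift[1] <- shift[1] - nr
  if (shift[2] > nc / 2) shift[2] <- shift[2] - nc
  if (upsample > 1) {
    region <- ceiling(upsample * 1.5)
    dftshift <- floor(region / 2)
    offsets <- dftshift - shift * upsample
    cc_up <- Mod(upsampled_dft(Conj(prod_f), region, upsample, offsets))
    pk <- arrayInd(which.max(cc_up), dim(cc_up)) - 1L
    shift <- shift + (as.numeric(pk) - dftshift) / upsample
  }
  c(dy = shift[1], dx = shift[2])
}

# localized matrix-multiply DFT upsampled by `upsample`, evaluated on a
# `region` x `region` grid offset by `offsets` (rows, cols)
upsampled_dft <- function(data, region, upsample, offsets) {
  nr <- nrow(data)
  nc <- ncol(data)
  fidx <- function(n) {
    f <- 0:(n - 1)
    f[f >= ceiling(n / 2)] <- f[f >= ceiling(n / 2)] - n
    f
  }
  kern_r <- exp((-2i * pi / (nr * upsample)) *
                  outer((0:(region - 1)) - offsets[1], fidx(nr)))
  kern_c <- exp((-2i * pi / (nc * upsample)) *
                  outer(fidx(nc), (0:(region - 1)) - offsets[2]))
  kern_r %*% data %*% kern_c
}

#' Estimate the drift trajectory of a movie
#'
#' Registers every frame either directly against frame 0
#' (`"to_reference"`, the default: spots are immobilized, so frame 0 is a
#' valid template throughout) or frame-to-frame with cumulative summation
#' (`"sequential"`, more robust when total drift is large compared with
#' the image texture). An optional centred moving-average smoother can be
#' applied to the trajectory.
#'
#' Frames are matched-filtered (Gaussian smoothing at `prefilter_sigma`,
#' of the order of the PSF sigma) before cross-correlation: the spot
#' signal is concentrated at the PSF scale while shot noise is white, so
#' the filter suppresses noise without biasing a pure translation.
#'
#' @param movie A [tirf_movie()] with at least 2 frames.
#' @param mode `"to_reference"` or `"sequential"`.
#' @param upsample Subpixel upsampling factor (default 20).
#' @param smooth_window Odd window length for moving-average smoothing of
#'   the trajectory; `NULL` (default) disables smoothing.
#' @param prefilter_sigma Matched-filter sigma in pixels (default 1.2;
#'   0 disables).
#' @return A tibble with columns `frame` (0-based), `dy`, `dx`: the
#'   cumulative shift of each frame relative to frame 0.
#' @export
estimate_drift <- function(movie, mode = c("to_reference", "sequential"),
                           upsample = 20, smooth_window = NULL,
                           prefilter_sigma = 1.2) {
  stopifnot(inherits(movie, "tirf_movie"))
  mode <- match.arg(mode)
  nf <- n_frames(movie)
  if (nf < 2L) abort("Drift estimation needs at least 2 frames.")
  ffts <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- movie$data[, , f]
    if (sd(fr) == 0) {
      abort(sprintf("Frame %d is constant; shift undefined.", f - 1L))
    }
    if (prefilter_sigma > 0) fr <- gaussian_smooth(fr, prefilter_sigma)
    ffts[[f]] <- fft(fr - mean(fr))
  }
  dy <- numeric(nf)
  dx <- numeric(nf)
  if (mode == "to_reference") {
    for (f in 2:nf) {
      s <- phase_corr_shift(ffts[[f]], ffts[[1]], upsample)
      dy[f] <- s[1]
      dx[f] <- s[2]
    }
  } else {
    for (f in 2:nf) {
      s <- phase_corr_shift(ffts[[f]], ffts[[f - 1]], upsample)
      dy[f] <- dy[f - 1] + s[1]
      dx[f] <- dx[f - 1] + s[2]
    }
  }
  traj <- tibble(frame = 0:(nf - 1L), dy = dy, dx = dx)
  if (!is.null(smooth_window) && smooth_window > 1) {
    traj$dy <- moving_average(traj$dy, smooth_window)
    traj$dx <- moving_average(traj$dx, smooth_window)
    traj$dy <- traj$dy - traj$dy[1]
    traj$dx <- traj$dx - traj$dx[1]
  }
  attr(traj, "mode") <- mode
  traj
}

# centred moving average with shrinking windows at the ends
moving_average <- function(x, window) {
  h <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Apply a drift correction to a movie
#'
#' Each frame is translated by minus its estimated shift using bilinear
#' interpolation, so that immobilized spots sit at their frame-0 positions
#' throughout. Pixels whose value would come from outside the field are
#' filled with the frame's median intensity and recorded as invalid in the
#' movie's validity mask; trace extraction flags frames whose ROI touches
#' such pixels.
#'
#' @param movie A [tirf_movie()].
#' @param trajectory A drift trajectory from [estimate_drift()] (tibble
#'   with `frame`, `dy`, `dx`), one row per frame.
#' @return A corrected [tirf_movie()] carrying a validity `mask`.
#' @export
apply_drift <- function(movie, trajectory) {
  stopifnot(inherits(movie, "tirf_movie"))
  nf <- n_frames(movie)
  if (nrow(trajectory) != nf) {
    abort(sprintf("Trajectory has %d rows but movie has %d frames.",
                  nrow(trajectory), nf))
  }
  d <- dim(movie$data)
  out <- array(0, dim = d)
  mask <- array(TRUE, dim = d)
  for (f in seq_len(nf)) {
    tr <- translate_bilinear(movie$data[, , f],
                             trajectory$dy[f], trajectory$dx[f])
    out[, , f] <- tr$image
    mask[, , f] <- tr$valid
  }
  tirf_movie(out, frame_interval = movie$frame_interval,
             pixel_size = movie$pixel_size, source = movie$source,
             mask = mask)
}

# sample M at (r + dy, c + dx) with bilinear interpolation; pixels drawing
# on out-of-field samples become the frame median and are flagged invalid
translate_bilinear <- function(M, dy, dx) {
  nr <- nrow(M)
  nc <- ncol(M)
  iy <- floor(dy)
  ix <- floor(dx)
  fy <- dy - iy
  fx <- dx - ix
  g00 <- shift_pad(M, iy, ix)
  if (fy == 0 && fx == 0) {
    img <- g00
  } else {
    g01 <- shift_pad(M, iy, ix + 1)
    g10 <- shift_pad(M, iy + 1, ix)
    g11 <- shift_pad(M, iy + 1, ix + 1)
    img <- (1 - fy) * (1 - fx) * g00 + (1 - fy) * fx * g01 +
      fy * (1 - fx) * g10 + fy * fx * g11
  }
  valid <- !is.na(img)
  if (!all(valid)) img[!valid] <- median(M)
  list(image = img, valid = valid)
}

# integer shift with NA padding: out[r, c] = M[r + a, c + b]
shift_pad <- function(M, a, b) {
  nr <- nrow(M)
  nc <- ncol(M)
  out <- matrix(NA_real_, nr, nc)
  r_dst <- max(1, 1 - a):min(nr, nr - a)
  c_dst <- max(1, 1 - b):min(nc, nc - b)
  if (length(r_dst) > 0 && length(c_dst) > 0 &&
      r_dst[1] <= r_dst[length(r_dst)] && c_dst[1] <= c_dst[length(c_dst)]) {
    out[r_dst, c_dst] <- M[r_dst + a, c_dst + b]
  }
  out
}
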