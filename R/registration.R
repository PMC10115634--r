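# Frame-to-first drift registration.
#
# Reference-channel preprocessing (Gaussian smooth -> percentile clip ->
# histogram match), subpixel shift estimation by phase correlation with DFT
# upsampling, and shift removal from all channels by crop-and-pad plus
# first-order interpolation of the fractional part.

#' Registration settings
#'
#' @param reference_channel 1-based index of the channel used for shift
#'   estimation (the channel holding the main structure of interest).
#' @param smooth_sigma Gaussian standard deviation (pixels) applied to each
#'   reference frame before clipping; default 1.
#' @param keep_percentile percentile below which smoothed pixels are set to
#'   zero; default 90, i.e. only the top decile of intensities drives the
#'   shift estimate.
#' @param upsample_factor subpixel precision of the shift estimate
#'   (1/`upsample_factor` px); default 100.
#' @param fill_value intensity for regions shifted in from outside the frame.
#' @param subpixel apply the fractional part of the shift by interpolation
#'   (`TRUE`, default) or round shifts to whole pixels (`FALSE`).
#' @return a `RegistrationConfig` object.
#' @export
registration_config <- function(reference_channel = 1L, smooth_sigma = 1,
                                keep_percentile = 90, upsample_factor = 100L,
                                fill_value = 0, subpixel = TRUE) {
  stopifnot(smooth_sigma > 0, keep_percentile >= 0, keep_percentile < 100,
            upsample_factor >= 1)
  structure(list(reference_channel = as.integer(reference_channel),
                 smooth_sigma = smooth_sigma,
                 keep_percentile = keep_percentile,
                 upsample_factor = as.integer(upsample_factor),
                 fill_value = fill_value,
                 subpixel = isTRUE(subpixel)),
            class = "RegistrationConfig")
}

#' Drift trace container
#'
#' Per-frame estimated shifts and the overlap masks valid after shift
#' removal. `shifts` is a `T x 2` matrix of `(dy, dx)` in pixels with frame 1
#' fixed at `(0, 0)`; `overlap` is a list of logical `(Y, X)` masks.
#'
#' @param shifts numeric `T x 2` matrix.
#' @param overlap list of logical matrices, or `NULL`.
#' @return a `DriftTrace` object.
#' @export
drift_trace <- function(shifts, overlap = NULL) {
  shifts <- matrix(as.numeric(shifts), ncol = 2,
                   dimnames = list(NULL, c("dy", "dx")))
  if (any(abs(shifts[1L, ]) > 1e-9))
    stop_exsrrf("first-frame shift must be (0, 0)", "exsrrf_value_error")
  structure(list(shifts = shifts, overlap = overlap), class = "DriftTrace")
}

#' @export
print.DriftTrace <- function(x, ...) {
  n <- norm_2(x$shifts)
  cat(sprintf("DriftTrace: %d frames, mean offset %.3f px, last offset %.3f px\n",
              nrow(x$shifts), mean(n[-1L]), n[length(n)]))
  invisible(x)
}

# row-wise 2-norms of a T x 2 shift matrix
norm_2 <- function(shifts) sqrt(rowSums(shifts^2))

#' Preprocess a reference frame for shift estimation
#'
#' Smooths with a Gaussian of `smooth_sigma` and zeroes every pixel at or
#' below the `keep_percentile` of the smoothed values, so only the brightest
#' structures remain. A constant frame comes back all zero.
#'
#' @param frame an `Image2D` or matrix (single channel).
#' @param config a [registration_config()].
#' @return an `Image2D` with clipped intensities.
#' @export
preprocess_reference <- function(frame, config = registration_config()) {
  m <- as_image_matrix(frame)
  s <- gaussian_blur(m, config$smooth_sigma)
  q <- stats::quantile(s, config$keep_percentile / 100, names = FALSE)
  s[s <= q] <- 0
  image2d(s, pixel_size_nm = if (inherits(frame, "Image2D")) frame$pixel_size_nm else NULL)
}

#' Match the intensity histogram of one image to another
#'
#' Monotone rank-preserving remap: the sorted values of the output equal the
#' sorted values of `reference`, with ranks taken from `moving`.
#'
#' @param moving,reference `Image2D` or matrices of equal size.
#' @return an `Image2D` with the intensity distribution of `reference`.
#' @export
match_histogram <- function(moving, reference) {
  m <- as_image_matrix(moving)
  r <- as_image_matrix(reference)
  stopifnot(length(m) == length(r))
  out <- m
  out[order(m)] <- sort(r)
  image2d(matrix(out, nrow(m), ncol(m)))
}

# FFT-based cross-correlation peak with matrix-multiply DFT refinement
# (Guizar-Sicairos, Thurman & Fienup 2008). Returns the (dy, dx) such that
# `moving` looks like `reference` translated by (dy, dx).
phase_corr_shift <- function(ref, mov, upsample_factor = 100L) {
  ny <- nrow(ref); nx <- ncol(ref)
  Fr <- stats::fft(ref)
  Fm <- stats::fft(mov)
  cps <- Fm * Conj(Fr)
  cc <- stats::fft(cps, inverse = TRUE) / length(cps)
  peak <- which.max(abs(cc))
  py <- (peak - 1) %% ny
  px <- (peak - 1) %/% ny
  if (py > ny / 2) py <- py - ny
  if (px > nx / 2) px <- px - nx
  shift <- c(py, px)
  usf <- as.integer(upsample_factor)
  if (usf > 1) {
    # refine in a 1.5 x 1.5 px neighbourhood at 1/usf resolution
    nr <- ceiling(1.5 * usf)
    off <- shift * usf - floor(nr / 2)
    ky <- seq.int(0, ny - 1); ky[ky > ny / 2] <- ky[ky > ny / 2] - ny
    kx <- seq.int(0, nx - 1); kx[kx > nx / 2] <- kx[kx > nx / 2] - nx
    wy <- exp((2i * pi / (ny * usf)) * outer(seq_len(nr) - 1 + off[1], ky))
    wx <- exp((2i * pi / (nx * usf)) * outer(kx, seq_len(nr) - 1 + off[2]))
    cc_up <- wy %*% cps %*% wx
    pk <- which.max(abs(cc_up))
    iy <- (pk - 1) %% nr
    ix <- (pk - 1) %/% nr
    shift <- c(iy + off[1], ix + off[2]) / usf
  }
  shift
}

#' Estimate the subpixel shift between two images
#'
#' Cross-correlation maximisation in the Fourier domain with
#' discrete-Fourier-transform upsampling to `1/upsample_factor` pixel
#' precision. Sign convention (fixed): the returned `(dy, dx)` is the
#' displacement of `moving` relative to `reference`, so translating `moving`
#' by `-(dy, dx)` aligns it to `reference`.
#'
#' @param reference,moving `Image2D` or matrices of identical size with at
#'   least one nonzero pixel each.
#' @param upsample_factor integer; subpixel precision denominator.
#' @return numeric `c(dy, dx)` in pixels.
#' @export
estimate_shift <- function(reference, moving, upsample_factor = 100L) {
  r <- as_image_matrix(reference)
  m <- as_image_matrix(moving)
  if (!all(dim(r) == dim(m)))
    stop_exsrrf("reference and moving frames differ in shape", "exsrrf_value_error")
  if (all(r == 0) || all(m == 0))
    stop_exsrrf("cannot estimate a shift from an all-zero frame",
                "exsrrf_estimation_error")
  phase_corr_shift(r, m, upsample_factor)
}

#' Translate an image, filling vacated regions
#'
#' `translate_image(img, ty, tx)` moves content down/right by `(ty, tx)`:
#' output(y, x) = input(y - ty, x - tx). The integer part is applied by
#' crop-and-pad; any fractional remainder by first-order (bilinear)
#' interpolation. Regions with no source data take `fill`.
#'
#' @param image matrix or `Image2D`.
#' @param ty,tx translation in pixels (may be fractional).
#' @param fill fill intensity.
#' @return matrix of the same size.
#' @export
translate_image <- function(image, ty, tx, fill = 0) {
  m <- as_image_matrix(image)
  ny <- nrow(m); nx <- ncol(m)
  iy <- round(ty); ix <- round(tx)
  fy <- ty - iy; fx <- tx - ix
  out <- matrix(fill, ny, nx)
  src_y <- seq_len(ny) - iy
  src_x <- seq_len(nx) - ix
  oky <- src_y >= 1 & src_y <= ny
  okx <- src_x >= 1 & src_x <= nx
  if (any(oky) && any(okx))
    out[oky, okx] <- m[src_y[oky], src_x[okx], drop = FALSE]
  if (abs(fy) > 1e-9 || abs(fx) > 1e-9) {
    # fractional remainder: sample at (y - fy, x - fx) with fill outside
    yy <- matrix(seq_len(ny) - 1, ny, nx) - fy
    xx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE) - fx
    inside <- yy >= 0 & yy <= ny - 1 & xx >= 0 & xx <= nx - 1
    vals <- bilinear_at(out, as.vector(yy), as.vector(xx))
    out <- matrix(ifelse(as.vector(inside), vals, fill), ny, nx)
  }
  out
}

# logical mask of pixels with full source support after translate_image
translation_overlap_mask <- function(ny, nx, ty, tx) {
  ones <- matrix(1, ny, nx)
  translate_image(ones, ty, tx, fill = 0) > 0.999
}

#' Register a time stack to its first frame
#'
#' Every frame of the reference channel is preprocessed
#' ([preprocess_reference()]), histogram-matched to the preprocessed first
#' frame, and its shift estimated by [estimate_shift()]. The negated shift is
#' then removed from all channels of that frame, cropped and padded with
#' `fill_value` to the original size. Frames whose preprocessed reference is
#' all zero fall back to raw-intensity correlation with a warning rather than
#' aborting the stack.
#'
#' @param stack a `TimeStack` with at least 2 frames.
#' @param config a [registration_config()].
#' @return a list with elements `stack` (registered `TimeStack`) and `trace`
#'   (a [drift_trace()] of the raw estimated shifts and per-frame overlap
#'   masks).
#' @export
register_stack <- function(stack, config = registration_config()) {
  stopifnot(inherits(stack, "TimeStack"))
  d <- dim(stack$data)
  if (d[1L] < 2L)
    stop_exsrrf("registration needs at least 2 frames", "exsrrf_value_error")
  rc <- config$reference_channel
  if (rc < 1L || rc > d[2L])
    stop_exsrrf(sprintf("reference channel %d out of range", rc),
                "exsrrf_value_error")
  ref_raw <- stack$data[1L, rc, , ]
  ref_pre <- preprocess_reference(ref_raw, config)$data
  ref_zero <- all(ref_pre == 0)

  shifts <- matrix(0, d[1L], 2L)
  out <- stack$data
  overlap <- vector("list", d[1L])
  overlap[[1L]] <- matrix(TRUE, d[3L], d[4L])
  for (t in seq.int(2L, d[1L])) {
    mov_raw <- stack$data[t, rc, , ]
    mov_pre <- preprocess_reference(mov_raw, config)$data
    if (ref_zero || all(mov_pre == 0)) {
      warning(sprintf("frame %d: preprocessed reference empty; falling back to raw-intensity correlation", t))
      s <- tryCatch(estimate_shift(ref_raw, mov_raw, config$upsample_factor),
                    error = function(e)
                      stop_exsrrf(sprintf("shift estimation failed on frame %d: %s",
                                          t, conditionMessage(e)),
                                  "exsrrf_estimation_error"))
    } else {
      mov_pre <- match_histogram(mov_pre, ref_pre)$data
      s <- tryCatch(estimate_shift(ref_pre, mov_pre, config$upsample_factor),
                    error = function(e)
                      stop_exsrrf(sprintf("shift estimation failed on frame %d: %s",
                                          t, conditionMessage(e)),
                                  "exsrrf_estimation_error"))
    }
    shifts[t, ] <- s
    appl <- if (config$subpixel) -s else -round(s)
    for (c in seq_len(d[2L]))
      out[t, c, , ] <- translate_image(stack$data[t, c, , ], appl[1L], appl[2L],
                                       fill = config$fill_value)
    overlap[[t]] <- translation_overlap_mask(d[3L], d[4L], appl[1L], appl[2L])
  }
  list(stack = time_stack(out, pixel_size_nm = stack$pixel_size_nm,
                          channel_names = stack$channel_names),
       trace = drift_trace(shifts, overlap))
}

#' Write / read a drift trace as CSV
#'
#' Columns `frame` (1-based), `dy_px`, `dx_px`.
#' @param trace a `DriftTrace`.
#' @param path CSV destination.
#' @return `path` (write) or a `DriftTrace` (read).
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(frame = seq_len(nrow(trace$shifts)),
                   dy_px = trace$shifts[, 1L], dx_px = trace$shifts[, 2L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  drift_trace(cbind(df$dy_px, df$dx_px))
}
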