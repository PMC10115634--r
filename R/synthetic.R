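# Seeded generators for every input class the pipeline needs: fluctuating
# point emitters with drift and noise, nanoruler pairs, ridge lattices and
# interdigitating foot-process phantoms — all with ground truth returned.

#' Specification of a synthetic emitter time stack
#'
#' @param image_shape `c(Y, X)` in pixels.
#' @param emitters matrix with columns `y`, `x`, `brightness` (0-based
#'   subpixel centre positions; brightness = expected photons per frame when
#'   on).
#' @param psf_sigma_px isotropic Gaussian PSF standard deviation, pixels.
#' @param frames number of frames T.
#' @param on_prob per-frame Bernoulli on-probability of each emitter
#'   (1 = always on).
#' @param brightness_lnsd log-normal standard deviation of per-frame
#'   brightness fluctuation (0 = none).
#' @param drift either a `T x 2` matrix of per-frame `(dy, dx)` shifts, a
#'   numeric `c(dy, dx)` linear rate per frame, or the string
#'   `"random_walk"` with `drift_step` controlling the per-frame step sd.
#' @param drift_step random-walk step standard deviation, pixels.
#' @param shot_noise apply Poisson noise to the expected signal.
#' @param read_noise_sd Gaussian read-noise standard deviation (intensity
#'   units).
#' @param baseline constant offset added before noise.
#' @param pixel_size_nm physical pixel size carried into the stack.
#' @param seed integer seed; identical spec + seed give identical output.
#' @return a `SyntheticSpec` object.
#' @export
synthetic_spec <- function(image_shape = c(64, 64), emitters,
                           psf_sigma_px = 1.3, frames = 50L, on_prob = 0.6,
                           brightness_lnsd = 0, drift = c(0, 0),
                           drift_step = 0.1, shot_noise = TRUE,
                           read_noise_sd = 0, baseline = 0,
                           pixel_size_nm = 65, seed = 1L) {
  emitters <- matrix(as.numeric(emitters), ncol = 3,
                     dimnames = list(NULL, c("y", "x", "brightness")))
  stopifnot(length(image_shape) == 2L, frames >= 1L, psf_sigma_px > 0,
            on_prob >= 0, on_prob <= 1)
  structure(list(image_shape = as.integer(image_shape), emitters = emitters,
                 psf_sigma_px = psf_sigma_px, frames = as.integer(frames),
                 on_prob = on_prob, brightness_lnsd = brightness_lnsd,
                 drift = drift, drift_step = drift_step,
                 shot_noise = isTRUE(shot_noise),
                 read_noise_sd = read_noise_sd, baseline = baseline,
                 pixel_size_nm = pixel_size_nm, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# per-frame drift trace (T x 2) from a spec's drift model
resolve_drift <- function(spec) {
  T <- spec$frames
  if (is.matrix(spec$drift)) {
    stopifnot(nrow(spec$drift) == T, ncol(spec$drift) == 2L)
    return(spec$drift)
  }
  if (is.character(spec$drift) && spec$drift == "random_walk") {
    steps <- matrix(stats::rnorm(2L * T, 0, spec$drift_step), T, 2L)
    steps[1L, ] <- 0
    return(apply(steps, 2L, cumsum))
  }
  rate <- as.numeric(spec$drift)
  stopifnot(length(rate) == 2L)
  cbind((seq_len(T) - 1L) * rate[1L], (seq_len(T) - 1L) * rate[2L])
}

# analytic Gaussian spot with unit total flux at subpixel centre (y0, x0)
render_spot <- function(ny, nx, y0, x0, sigma) {
  gy <- exp(-((seq_len(ny) - 1 - y0)^2) / (2 * sigma^2))
  gx <- exp(-((seq_len(nx) - 1 - x0)^2) / (2 * sigma^2))
  outer(gy, gx) / (2 * pi * sigma^2)
}

#' Simulate a fluctuating-emitter time stack
#'
#' Each frame is the sum of the PSFs of the emitters that are on in that
#' frame (independent Bernoulli blinking), shifted by the frame's drift,
#' plus optional shot (Poisson) and Gaussian read noise. Brightness is
#' normalised as total flux, so noise-free frames conserve the summed
#' emitter flux up to PSF truncation at the borders.
#'
#' @param spec a [synthetic_spec()]. Emitters must stay inside the image
#'   under the maximal drift.
#' @return list with `stack` (a [time_stack()]) and `truth` (list: `drift`
#'   `T x 2`, `positions`, `on` `T x E` logical matrix, `brightness`
#'   `T x E`).
#' @export
make_emitter_stack <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  ny <- spec$image_shape[1L]; nx <- spec$image_shape[2L]
  T <- spec$frames; E <- nrow(spec$emitters)
  drift <- resolve_drift(spec)
  pos_y <- outer(drift[, 1L], spec$emitters[, "y"], `+`)
  pos_x <- outer(drift[, 2L], spec$emitters[, "x"], `+`)
  if (any(pos_y < 0 | pos_y > ny - 1 | pos_x < 0 | pos_x > nx - 1))
    stop_exsrrf("emitters leave the image under the drift model",
                "exsrrf_validation_error")
  on <- matrix(stats::rbinom(T * E, 1L, spec$on_prob) == 1L, T, E)
  bright <- matrix(rep(spec$emitters[, "brightness"], each = T), T, E)
  if (spec$brightness_lnsd > 0)
    bright <- bright * matrix(stats::rlnorm(T * E, -spec$brightness_lnsd^2 / 2,
                                            spec$brightness_lnsd), T, E)
  arr <- array(0, c(T, 1L, ny, nx))
  for (t in seq_len(T)) {
    frame <- matrix(spec$baseline, ny, nx)
    for (e in seq_len(E)) {
      if (!on[t, e]) next
      frame <- frame + bright[t, e] *
        render_spot(ny, nx, pos_y[t, e], pos_x[t, e], spec$psf_sigma_px)
    }
    if (spec$shot_noise)
      frame <- matrix(stats::rpois(ny * nx, frame), ny, nx)
    if (spec$read_noise_sd > 0)
      frame <- frame + matrix(stats::rnorm(ny * nx, 0, spec$read_noise_sd), ny, nx)
    frame[frame < 0] <- 0
    arr[t, 1L, , ] <- frame
  }
  list(stack = time_stack(arr, pixel_size_nm = spec$pixel_size_nm),
       truth = list(drift = drift,
                    positions = spec$emitters[, c("y", "x"), drop = FALSE],
                    on = on, brightness = bright))
}

#' Simulate a nanoruler time stack
#'
#' Two blinking emitters at a fabricated distance, optionally scaled by an
#' expansion factor before projection to pixels: centre separation in pixels
#' is `distance_nm * expansion_factor / pixel_size_nm`. The pair is centred
#' in the frame along the x axis.
#'
#' @param distance_nm fabricated fluorophore distance (25–120 nm range in
#'   routine use).
#' @param expansion_factor physical expansion applied before imaging
#'   (1 = pre-expansion).
#' @param pixel_size_nm camera pixel size, nanometres.
#' @param image_shape,psf_sigma_px,frames,on_prob,brightness,seed,... passed
#'   to [synthetic_spec()].
#' @param brightness expected photons per frame and emitter when on.
#' @param mark_brightness_lnsd log-normal sd of the per-mark brightness
#'   (labelling stoichiometry can differ between the two marks of a ruler;
#'   default 0, equally bright marks).
#' @return list with `stack`, `truth` (as [make_emitter_stack()]) and
#'   `separation_px`, the true centre separation.
#' @export
make_nanoruler <- function(distance_nm, expansion_factor = 1,
                           pixel_size_nm = 65, image_shape = c(32, 32),
                           psf_sigma_px = 1.3, frames = 50L, on_prob = 0.6,
                           brightness = 1000, mark_brightness_lnsd = 0,
                           seed = 1L, ...) {
  stopifnot(distance_nm > 0, expansion_factor >= 1)
  sep <- distance_nm * expansion_factor / pixel_size_nm
  if (sep < 0.1)
    stop_exsrrf("separation below 0.1 px is not representable", "exsrrf_validation_error")
  cy <- (image_shape[1L] - 1) / 2
  cx <- (image_shape[2L] - 1) / 2
  set.seed(seed)
  bright <- brightness *
    stats::rlnorm(2, -mark_brightness_lnsd^2 / 2, mark_brightness_lnsd)
  emitters <- rbind(c(cy, cx - sep / 2, bright[1L]),
                    c(cy, cx + sep / 2, bright[2L]))
  spec <- synthetic_spec(image_shape = image_shape, emitters = emitters,
                         psf_sigma_px = psf_sigma_px, frames = frames,
                         on_prob = on_prob, pixel_size_nm = pixel_size_nm,
                         seed = seed, ...)
  out <- make_emitter_stack(spec)
  out$separation_px <- sep
  out
}

#' Simulate a drifting tissue-texture time stack
#'
#' Registration fixture: a fixed high-contrast blob texture (smoothed uniform
#' noise, contrast-stretched and squared — sparse bright structures on a dark
#' background, as in fluorescently labelled tissue) confined to the frame
#' interior by a margin at least as large as the maximal drift, translated
#' per frame along the drift trace, modulated by a global log-normal
#' intensity fluctuation, and degraded by shot noise plus Gaussian read
#' noise. The signal-to-noise ratio is defined as peak intensity over read
#' noise standard deviation.
#'
#' @param shape `c(Y, X)` in pixels.
#' @param frames number of frames.
#' @param drift per-frame rate `c(dy, dx)`, a `T x 2` trace, or
#'   `"random_walk"`.
#' @param drift_step random-walk step sd, pixels.
#' @param margin structure-free border, pixels (keep `>=` the maximal drift).
#' @param peak peak intensity, photons.
#' @param snr peak over read-noise sd.
#' @param texture_sigma blob scale of the texture, pixels.
#' @param intensity_lnsd log-normal sd of the global per-frame brightness.
#' @param seed integer seed.
#' @return list with `stack` (a [time_stack()]) and `truth` (list with
#'   `drift`).
#' @export
make_texture_stack <- function(shape = c(64, 64), frames = 50L,
                               drift = c(0, 0), drift_step = 0.1,
                               margin = 12L, peak = 800, snr = 5,
                               texture_sigma = 1.5, intensity_lnsd = 0.3,
                               seed = 1L) {
  set.seed(seed)
  ny <- shape[1L]; nx <- shape[2L]
  iy <- ny - 2L * margin; ix <- nx - 2L * margin
  stopifnot(iy > 4L, ix > 4L)
  base <- matrix(0, ny, nx)
  patch <- gaussian_blur(matrix(stats::runif(iy * ix), iy, ix), texture_sigma)
  base[(margin + 1L):(ny - margin), (margin + 1L):(nx - margin)] <-
    peak * rescale01(patch)^2
  spec <- synthetic_spec(image_shape = shape, emitters = cbind(1, 1, 0),
                         frames = frames, drift = drift,
                         drift_step = drift_step, seed = seed)
  tr <- resolve_drift(spec)
  if (max(abs(tr)) > margin)
    stop_exsrrf("drift exceeds the structure margin", "exsrrf_validation_error")
  read_sd <- peak / snr
  arr <- array(0, c(frames, 1L, ny, nx))
  for (t in seq_len(frames)) {
    fr <- translate_image(base, tr[t, 1L], tr[t, 2L]) *
      stats::rlnorm(1, 0, intensity_lnsd)
    fr <- matrix(stats::rpois(ny * nx, pmax(fr, 0)), ny, nx) +
      matrix(stats::rnorm(ny * nx, 0, read_sd), ny, nx)
    arr[t, 1L, , ] <- pmax(fr, 0)
  }
  list(stack = time_stack(arr), truth = list(drift = tr))
}

#' Generate a lattice of parallel anti-aliased ridges
#'
#' Bright lines of width `line_width_px` repeating every `period_px`, at any
#' orientation. Line intensity falls off linearly over one pixel at the
#' edges (anti-aliasing). Ground truth: density `line_width/period`, gap
#' `period - line_width`, and the midline offsets.
#'
#' @param period_px centre-to-centre line distance, pixels.
#' @param line_width_px line width, pixels (less than the period).
#' @param orientation_deg line direction in degrees (0 = vertical lines).
#' @param shape `c(Y, X)` image size.
#' @param amplitude peak line intensity.
#' @param phase sub-pixel offset of the midlines in units of pixels, or
#'   `NULL` for a grid-aligned default. Axis-aligned lattices quantise any
#'   measured width to whole pixels, so width measurements should be
#'   averaged over a few phases.
#' @param psf_sigma_px optional Gaussian optical blur applied to the drawn
#'   lattice (0 = none).
#' @return list with `image` (`Image2D`), `density`, `gap_px`, `period_px`,
#'   `line_width_px`, `orientation_deg`.
#' @export
make_ridge_lattice <- function(period_px, line_width_px, orientation_deg = 0,
                               shape = c(256, 256), amplitude = 1,
                               phase = NULL, psf_sigma_px = 0) {
  if (!(period_px > line_width_px && line_width_px >= 1))
    stop_exsrrf("need period > line width >= 1", "exsrrf_validation_error")
  ny <- shape[1L]; nx <- shape[2L]
  th <- orientation_deg * pi / 180
  # signed distance across the lines: coordinate perpendicular to direction
  yy <- matrix(seq_len(ny) - 1, ny, nx)
  xx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  u <- xx * cos(th) + yy * sin(th)
  # midlines at u = phase + k * period; the default phase makes the drawn
  # band cover whole pixels symmetrically (half-pixel shift for even widths)
  if (is.null(phase)) phase <- if (line_width_px %% 2 == 0) 0.5 else 0
  d <- abs(((u - phase + period_px / 2) %% period_px) - period_px / 2)
  img <- amplitude * pmin(pmax(line_width_px / 2 + 0.5 - d, 0), 1)
  if (psf_sigma_px > 0) img <- gaussian_blur(img, psf_sigma_px)
  list(image = image2d(img), density = line_width_px / period_px,
       gap_px = period_px - line_width_px, period_px = period_px,
       line_width_px = line_width_px, orientation_deg = orientation_deg,
       phase = phase)
}

#' Generate an interdigitating foot-process phantom
#'
#' Comb-like interlocking processes: vertical boundaries every
#' `fp_width_px`, alternately connected at the top and bottom of a central
#' band, so adjacent teeth belong to opposite combs — a stylised view of
#' foot processes interdigitating across the slit diaphragm. The `sd`
#' channel carries the separator curve as bright anti-aliased lines of width
#' `sd_gap_px`; the `fp` channel carries the filled processes. An "effaced"
#' variant deletes a fraction of the vertical separator segments (merging
#' the neighbouring processes), emulating foot-process effacement with slit
#' loss.
#'
#' @param fp_width_px tooth (foot-process) width, pixels.
#' @param sd_gap_px separator line width, pixels.
#' @param waviness amplitude (pixels) of a sinusoidal perturbation of the
#'   vertical boundaries.
#' @param shape `c(Y, X)` image size.
#' @param deletion_fraction fraction of vertical separator segments removed
#'   (0 = intact, 1 = no separator).
#' @param band_margin rows above/below the central band, pixels.
#' @param seed seed for the segment deletion draw.
#' @return list with `sd` and `fp` (`Image2D`s), `fp_count` (teeth drawn),
#'   `deleted` (logical per boundary), `fp_width_px`, `sd_gap_px`.
#' @export
make_interdigitation <- function(fp_width_px, sd_gap_px = 2, waviness = 0,
                                 shape = c(192, 192), deletion_fraction = 0,
                                 band_margin = 8L, seed = 1L) {
  stopifnot(fp_width_px >= 1, sd_gap_px >= 1)
  set.seed(seed)
  ny <- shape[1L]; nx <- shape[2L]
  y0 <- band_margin; y1 <- ny - 1 - band_margin
  xs <- seq(fp_width_px, nx - 1 - fp_width_px / 2, by = fp_width_px)
  n_bound <- length(xs)
  deleted <- stats::runif(n_bound) < deletion_fraction
  sd_img <- matrix(0, ny, nx)
  yy <- seq_len(ny) - 1
  half <- sd_gap_px / 2
  draw_v <- function(img, xc, yr) {
    # anti-aliased vertical segment at x = xc (optionally wavy), rows yr
    for (y in yr) {
      xc_y <- xc + waviness * sin(2 * pi * y / ny * 3)
      x_lo <- max(0, floor(xc_y - half - 1)); x_hi <- min(nx - 1, ceiling(xc_y + half + 1))
      for (x in x_lo:x_hi) {
        w <- min(1, max(0, half + 0.5 - abs(x - xc_y)))
        img[y + 1, x + 1] <- max(img[y + 1, x + 1], w)
      }
    }
    img
  }
  draw_h <- function(img, yc, xr) {
    for (x in xr) {
      y_lo <- max(0, floor(yc - half - 1)); y_hi <- min(ny - 1, ceiling(yc + half + 1))
      for (y in y_lo:y_hi) {
        w <- min(1, max(0, half + 0.5 - abs(y - yc)))
        img[y + 1, x + 1] <- max(img[y + 1, x + 1], w)
      }
    }
    img
  }
  for (i in seq_len(n_bound)) {
    if (deleted[i]) next
    sd_img <- draw_v(sd_img, xs[i], y0:y1)
    # connect alternately at top/bottom to the next surviving boundary
    if (i < n_bound && !deleted[i + 1L]) {
      yc <- if (i %% 2L == 0L) y0 else y1
      sd_img <- draw_h(sd_img, yc, round(xs[i]):round(xs[i + 1L]))
    }
  }
  # fp channel: band interior minus separator
  fp_img <- matrix(0, ny, nx)
  fp_img[(y0 + 1):(y1 + 1), ] <- 1
  fp_img <- pmax(fp_img - sd_img, 0)
  list(sd = image2d(sd_img), fp = image2d(fp_img),
       fp_count = sum(!deleted) + 1L, deleted = deleted,
       fp_width_px = fp_width_px, sd_gap_px = sd_gap_px)
}
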