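# Super-resolution radial fluctuations.
#
# Per-frame radiality on an M-times magnified grid, temporal radiality
# average, and anti-patterning correction. The radiality kernel lives in
# src/kernels.cpp (radiality_cpp) and is deliberately isolated so the
# convergence measure can be swapped.

#' SRRF settings
#'
#' The parameter set of the radiality transform. Two presets mirror the two
#' acquisition regimes the pipeline is used in:
#' `srrf_settings_preset("nanoruler")` gives ring radius 0.5, magnification
#' 10, 8 axes, gradient smoothing off; `srrf_settings_preset("tissue")` is
#' identical but with gradient smoothing on (tissue work may lower the
#' magnification and axes; ranges 0.5–2.0, 3–10 and 2–8 are accepted).
#'
#' @param ring_radius radius of the gradient-sampling ring, in source pixels
#'   (valid 0.5–2.0 in routine use; any positive value up to 2 is accepted).
#' @param magnification integer subpixels per source pixel and axis (1–10).
#' @param axes_in_ring number of symmetry axes sampled (2–8); the ring takes
#'   `2 * axes_in_ring` samples.
#' @param temporal_mode aggregation over frames; only `"average"` (temporal
#'   radiality average) is provided.
#' @param intensity_weighting multiply radiality by the interpolated frame
#'   intensity (default `TRUE`).
#' @param gradient_weighting accepted for completeness; only `FALSE` is
#'   implemented (the reference settings run it disabled).
#' @param gradient_smoothing pre-smooth the frame (Gaussian, sigma 1) before
#'   gradient computation.
#' @param positivity_constraint clamp negative radiality to zero (default
#'   `TRUE`).
#' @param minimize_patterning apply the anti-patterning correction in
#'   [srrf_process()] (default `TRUE`).
#' @param renormalize accepted for completeness; only `FALSE` is implemented.
#' @return an `SrrfSettings` object.
#' @export
srrf_settings <- function(ring_radius = 0.5, magnification = 10L,
                          axes_in_ring = 8L, temporal_mode = "average",
                          intensity_weighting = TRUE,
                          gradient_weighting = FALSE,
                          gradient_smoothing = FALSE,
                          positivity_constraint = TRUE,
                          minimize_patterning = TRUE,
                          renormalize = FALSE) {
  if (!(ring_radius > 0 && ring_radius <= 2))
    stop_exsrrf("ring_radius must be in (0, 2]", "exsrrf_config_error")
  magnification <- as.integer(magnification)
  axes_in_ring <- as.integer(axes_in_ring)
  if (magnification < 1L || magnification > 10L)
    stop_exsrrf("magnification must be an integer in 1..10", "exsrrf_config_error")
  if (axes_in_ring < 2L || axes_in_ring > 8L)
    stop_exsrrf("axes_in_ring must be an integer in 2..8", "exsrrf_config_error")
  temporal_mode <- match.arg(temporal_mode, "average")
  if (isTRUE(gradient_weighting))
    stop_exsrrf("gradient weighting is not implemented (reference settings run it disabled)",
                "exsrrf_not_implemented")
  if (isTRUE(renormalize))
    stop_exsrrf("renormalization is not implemented (reference settings run it disabled)",
                "exsrrf_not_implemented")
  structure(list(ring_radius = ring_radius, magnification = magnification,
                 axes_in_ring = axes_in_ring, temporal_mode = temporal_mode,
                 intensity_weighting = isTRUE(intensity_weighting),
                 gradient_weighting = FALSE,
                 gradient_smoothing = isTRUE(gradient_smoothing),
                 positivity_constraint = isTRUE(positivity_constraint),
                 minimize_patterning = isTRUE(minimize_patterning),
                 renormalize = FALSE),
            class = "SrrfSettings")
}

#' @rdname srrf_settings
#' @param preset `"nanoruler"` or `"tissue"`.
#' @param ... overrides passed to [srrf_settings()].
#' @export
srrf_settings_preset <- function(preset = c("nanoruler", "tissue"), ...) {
  preset <- match.arg(preset)
  args <- list(ring_radius = 0.5, magnification = 10L, axes_in_ring = 8L,
               gradient_smoothing = (preset == "tissue"))
  over <- list(...)
  args[names(over)] <- over
  do.call(srrf_settings, args)
}

#' Image gradients by centred differences
#'
#' @param frame matrix or `Image2D`, at least 3x3.
#' @param smoothing pre-convolve with a Gaussian (sigma 1) before
#'   differencing.
#' @return list with matrices `gy` and `gx`.
#' @export
compute_gradients <- function(frame, smoothing = FALSE) {
  m <- as_image_matrix(frame)
  if (nrow(m) < 3L || ncol(m) < 3L)
    stop_exsrrf("gradients need at least a 3x3 frame", "exsrrf_value_error")
  if (isTRUE(smoothing)) m <- gaussian_blur(m, 1)
  mp <- pad_reflect(m, 1L, 1L)
  ny <- nrow(m); nx <- ncol(m)
  gy <- (mp[3:(ny + 2), 2:(nx + 1)] - mp[1:ny, 2:(nx + 1)]) / 2
  gx <- (mp[2:(ny + 1), 3:(nx + 2)] - mp[2:(ny + 1), 1:nx]) / 2
  list(gy = gy, gx = gx)
}

#' Radiality map of a single frame
#'
#' For every position `c` of the `M`-times magnified grid, `2 * axes_in_ring`
#' points on a ring of radius `ring_radius` are sampled; the (bilinearly
#' interpolated) gradient at each ring point defines a line, and the sample
#' contributes `sign * max(0, 1 - d / r)^6` where `d` is the perpendicular
#' distance from `c` to that line and the sign is positive when the gradient
#' points toward `c` (convergent, i.e. a bright structure). The sixth-power
#' ramp keeps the convergence kernel tightly peaked, so the radiality of a
#' point emitter decays fast enough for nearby emitters to remain distinct.
#' Radiality is the mean contribution over the ring; flat samples (zero
#' gradient) contribute 0. With the positivity constraint the map is clamped
#' at 0; with intensity weighting it is multiplied by the
#' Catmull-Rom-interpolated frame intensity.
#'
#' @param frame matrix or `Image2D`.
#' @param settings an [srrf_settings()].
#' @return a `RadialityMap`: list with `data` (`M*Y x M*X` matrix) and
#'   `settings`.
#' @export
radiality_map <- function(frame, settings = srrf_settings()) {
  stopifnot(inherits(settings, "SrrfSettings"))
  m <- as_image_matrix(frame)
  g <- compute_gradients(m, smoothing = settings$gradient_smoothing)
  data <- radiality_cpp(m, g$gy, g$gx,
                        settings$ring_radius, settings$magnification,
                        2L * settings$axes_in_ring,
                        settings$positivity_constraint,
                        settings$intensity_weighting)
  structure(list(data = data, settings = settings), class = "RadialityMap")
}

#' Aggregate radiality maps over time
#'
#' Temporal radiality average: the pixelwise mean over frames.
#'
#' @param maps list of `RadialityMap`s (or matrices) of identical shape.
#' @param mode only `"average"`.
#' @return a `RadialityMap` (settings inherited from the first input).
#' @export
temporal_aggregate <- function(maps, mode = "average") {
  mode <- match.arg(mode, "average")
  if (length(maps) < 1L)
    stop_exsrrf("need at least one radiality map", "exsrrf_value_error")
  mats <- lapply(maps, function(x) if (inherits(x, "RadialityMap")) x$data else x)
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(x) all(dim(x) == d), logical(1))))
    stop_exsrrf("radiality maps differ in shape", "exsrrf_aggregation_error")
  acc <- Reduce(`+`, mats) / length(mats)
  settings <- if (inherits(maps[[1L]], "RadialityMap")) maps[[1L]]$settings else NULL
  structure(list(data = acc, settings = settings), class = "RadialityMap")
}

#' Suppress the M-periodic SRRF lattice artefact
#'
#' The magnified grid has `M x M` subpixel-offset classes; interpolation
#' biases give the classes systematically different mean levels, which shows
#' as an M-periodic lattice. The correction shifts each class by a constant
#' offset so every class mean equals the grand mean of the class means; the
#' additive form removes the lattice bias without rescaling localized
#' signal peaks. With equally sized classes the total image mean is
#' preserved exactly (up to an optional clamp of small negatives when the
#' input map is non-negative).
#'
#' @param map a `RadialityMap`, or a matrix plus `magnification`.
#' @param magnification required when `map` is a bare matrix.
#' @return same type as the input.
#' @export
minimize_patterning <- function(map, magnification = NULL) {
  m <- if (inherits(map, "RadialityMap")) map$data else map
  M <- if (inherits(map, "RadialityMap")) map$settings$magnification else magnification
  if (is.null(M)) stop_exsrrf("magnification required", "exsrrf_config_error")
  if (nrow(m) %% M != 0L || ncol(m) %% M != 0L)
    stop_exsrrf("map size must be divisible by the magnification", "exsrrf_value_error")
  cy <- ((seq_len(nrow(m)) - 1L) %% M)
  cx <- ((seq_len(ncol(m)) - 1L) %% M)
  out <- m
  mu <- matrix(0, M, M)
  for (a in 0:(M - 1L))
    for (b in 0:(M - 1L))
      mu[a + 1L, b + 1L] <- mean(m[cy == a, cx == b])
  target <- mean(mu)
  for (a in 0:(M - 1L))
    for (b in 0:(M - 1L))
      out[cy == a, cx == b] <- m[cy == a, cx == b] - mu[a + 1L, b + 1L] + target
  if (all(m >= 0)) out[out < 0] <- 0
  if (inherits(map, "RadialityMap")) {
    map$data <- out
    map
  } else out
}

#' Locate the brightest peak of an image with subpixel refinement
#'
#' Position of the global maximum refined by the intensity-weighted centroid
#' of its local neighbourhood — the standard way to read a peak position off
#' a noisy map at better-than-pixel precision.
#'
#' @param image matrix or `Image2D`.
#' @param refine_radius half-width of the centroid window, pixels (0 = raw
#'   argmax).
#' @param smooth_sigma Gaussian pre-smoothing of the map before the argmax
#'   (pixels; 0 = none). For an isolated symmetric peak, smoothing at the
#'   scale of the peak acts as a matched filter: it suppresses pixel noise
#'   without displacing the maximum.
#' @return numeric `c(y, x)`, 0-based pixel coordinates.
#' @export
peak_position <- function(image, refine_radius = 2L, smooth_sigma = 0) {
  m <- as_image_matrix(image)
  if (smooth_sigma > 0) m <- gaussian_blur(m, smooth_sigma)
  pk <- which(m == max(m), arr.ind = TRUE)[1L, ]
  r <- as.integer(refine_radius)
  if (r < 1L) return(c(y = pk[1L] - 1, x = pk[2L] - 1))
  rows <- max(1L, pk[1L] - r):min(nrow(m), pk[1L] + r)
  cols <- max(1L, pk[2L] - r):min(ncol(m), pk[2L] + r)
  w <- m[rows, cols, drop = FALSE]
  w <- pmax(w - min(w), 0)
  if (sum(w) == 0) return(c(y = pk[1L] - 1, x = pk[2L] - 1))
  c(y = sum(outer(rows - 1, rep(1, length(cols))) * w) / sum(w),
    x = sum(outer(rep(1, length(rows)), cols - 1) * w) / sum(w))
}

#' Run the SRRF pipeline on a time stack
#'
#' Per-frame [radiality_map()], [temporal_aggregate()] over all frames, and
#' (if enabled in the settings) [minimize_patterning()]. The stack should be
#' registered first; if no drift trace is supplied a note is emitted and the
#' stack is assumed aligned.
#'
#' @param stack a `TimeStack`.
#' @param channel 1-based channel index.
#' @param settings an [srrf_settings()].
#' @param trace the `DriftTrace` from [register_stack()], or `NULL`.
#' @return an `Image2D` holding the M-times magnified SRRF image; its
#'   `pixel_size_nm` is the stack's divided by the magnification.
#' @export
srrf_process <- function(stack, channel = 1L, settings = srrf_settings(),
                         trace = NULL) {
  stopifnot(inherits(stack, "TimeStack"))
  d <- dim(stack$data)
  channel <- as.integer(channel)
  if (channel < 1L || channel > d[2L])
    stop_exsrrf(sprintf("channel %d out of range (stack has %d)", channel, d[2L]),
                "exsrrf_index_error")
  if (is.null(trace))
    message("srrf_process: no drift trace supplied; assuming the stack is registered")
  maps <- vector("list", d[1L])
  for (t in seq_len(d[1L]))
    maps[[t]] <- radiality_map(stack$data[t, channel, , ], settings)
  agg <- temporal_aggregate(maps, settings$temporal_mode)
  if (settings$minimize_patterning) agg <- minimize_patterning(agg)
  px <- if (!is.null(stack$pixel_size_nm))
    stack$pixel_size_nm / settings$magnification else NULL
  image2d(agg$data, pixel_size_nm = px)
}
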