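# Nanoscale morphometrics: ROI extraction, Meijering ridge segmentation,
# ridge density, local spacing (greatest inscribed circle), width/peak
# profiling, PSF-separation calls and expansion-factor estimation.

#' Nanometrics configuration
#'
#' Two presets bundle the parameters of the two quantification pipelines:
#' `"sd"` for slit-diaphragm-like ridge patterns (noise threshold, one
#' Gaussian of sigma 8, fill-holes + closing, ridge threshold 0.2) and
#' `"er"` for endoplasmic-reticulum-like networks (Gaussians of sigma 8 and
#' 10 in sequence, fill-holes only, ridge threshold 0.25, small ridge objects
#' below 125 px removed). Any field can be overridden.
#'
#' @param preset `"sd"` or `"er"`.
#' @param downsample_fraction ROI extraction works at this fraction of the
#'   original size (default 0.25).
#' @param noise_threshold low-level cutoff before smoothing, as a fraction of
#'   the image maximum (sd preset only; default 0.05).
#' @param roi_sigmas Gaussian sigmas applied in sequence during ROI
#'   smoothing.
#' @param roi_closing apply binary closing after hole filling.
#' @param closing_radius disc radius (downsampled pixels) of the closing
#'   element.
#' @param min_component_px minimum ROI component area, in downsampled
#'   coordinates (default 5000).
#' @param ridge_threshold cut on the normalised ridge response.
#' @param min_ridge_object_px minimum ridge object area in pixels
#'   (`NULL` = keep all).
#' @param ridge_sigmas scales of the ridge detector.
#' @param opening_radius disc radius (full-resolution pixels) of the opening
#'   applied to the ridge mask.
#' @return a `NanometricsConfig` object.
#' @export
nanometrics_config <- function(preset = c("sd", "er"),
                               downsample_fraction = 0.25,
                               noise_threshold = if (preset == "sd") 0.05 else NULL,
                               roi_sigmas = if (preset == "sd") 8 else c(8, 10),
                               roi_closing = (preset == "sd"),
                               closing_radius = 5L,
                               min_component_px = 5000L,
                               ridge_threshold = if (preset == "sd") 0.2 else 0.25,
                               min_ridge_object_px = if (preset == "er") 125L else NULL,
                               ridge_sigmas = c(1, 2, 3),
                               opening_radius = 2L) {
  preset <- match.arg(preset)
  stopifnot(downsample_fraction > 0, downsample_fraction <= 1,
            ridge_threshold > 0, ridge_threshold < 1,
            min_component_px > 0)
  structure(list(preset = preset,
                 downsample_fraction = downsample_fraction,
                 noise_threshold = noise_threshold,
                 roi_sigmas = roi_sigmas,
                 roi_closing = isTRUE(roi_closing),
                 closing_radius = as.integer(closing_radius),
                 min_component_px = as.integer(min_component_px),
                 ridge_threshold = ridge_threshold,
                 min_ridge_object_px = min_ridge_object_px,
                 ridge_sigmas = ridge_sigmas,
                 opening_radius = as.integer(opening_radius)),
            class = "NanometricsConfig")
}

# mass-preserving block-mean downsample by an integer factor (trailing
# rows/cols beyond the last full block are dropped)
block_mean <- function(m, f) {
  ny <- (nrow(m) %/% f) * f
  nx <- (ncol(m) %/% f) * f
  m <- m[seq_len(ny), seq_len(nx), drop = FALSE]
  a <- array(m, c(f, ny %/% f, f, nx %/% f))
  apply(a, c(2, 4), mean)
}

# nearest-neighbour upsample of a mask back to (ny, nx)
upsample_nearest <- function(mask, f, ny, nx) {
  big <- mask[rep(seq_len(nrow(mask)), each = f),
              rep(seq_len(ncol(mask)), each = f), drop = FALSE]
  out <- matrix(FALSE, ny, nx)
  out[seq_len(min(ny, nrow(big))), seq_len(min(nx, ncol(big)))] <-
    big[seq_len(min(ny, nrow(big))), seq_len(min(nx, ncol(big)))]
  # pad any trailing rows/cols by repeating the last available row/col
  if (nrow(big) < ny) out[(nrow(big) + 1):ny, ] <-
    out[rep(nrow(big), ny - nrow(big)), ]
  if (ncol(big) < nx) out[, (ncol(big) + 1):nx] <-
    out[, rep(ncol(big), nx - ncol(big))]
  out
}

ebi_mat <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2L) m <- m[, , 1L]
  m
}

disc_brush <- function(radius) EBImage::makeBrush(2L * radius + 1L, shape = "disc")

#' Extract the tissue region of interest
#'
#' Works at `downsample_fraction` of the original size: optional low-level
#' noise cut (sd preset), Gaussian smoothing (one or two sigmas in sequence),
#' Otsu thresholding, binary hole filling (plus closing for the sd preset),
#' and removal of connected components not exceeding `min_component_px`
#' (counted in downsampled coordinates). The mask is upsampled back to the
#' original resolution by nearest neighbour.
#'
#' @param image `Image2D` or matrix.
#' @param config a [nanometrics_config()].
#' @return logical matrix at the original resolution; empty (with a warning)
#'   when no component survives.
#' @export
extract_roi <- function(image, config = nanometrics_config("sd")) {
  m <- as_image_matrix(image)
  f <- round(1 / config$downsample_fraction)
  if (nrow(m) < f || ncol(m) < f)
    stop_exsrrf("image smaller than one downsampling block", "exsrrf_value_error")
  down <- block_mean(m, f)
  if (!is.null(config$noise_threshold) && max(down) > 0)
    down[down < config$noise_threshold * max(down)] <- 0
  for (s in config$roi_sigmas) down <- gaussian_blur(down, s)
  rng <- range(down)
  if (rng[2] > rng[1]) {
    dn <- (down - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(dn), range = c(0, 1), levels = 256L)
    mask <- dn > thr
  } else {
    mask <- matrix(down > 0, nrow(down), ncol(down))
  }
  mask <- ebi_mat(EBImage::fillHull(EBImage::Image(mask * 1))) > 0.5
  if (config$roi_closing)
    mask <- ebi_mat(EBImage::closing(EBImage::Image(mask * 1),
                                     disc_brush(config$closing_radius))) > 0.5
  lab <- ebi_mat(EBImage::bwlabel(EBImage::Image(mask * 1)))
  keep <- which(tabulate(lab[lab > 0]) > config$min_component_px)
  mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  if (!any(mask))
    warning("empty ROI after component filtering; downstream density is undefined")
  upsample_nearest(mask, f, nrow(m), ncol(m))
}

#' Segment ridges within a region of interest
#'
#' Meijering ridge response at the configured scales (already normalised to
#' `[0, 1]`), thresholded at `ridge_threshold`; for the er preset, objects
#' smaller than `min_ridge_object_px` are removed; morphological opening with
#' a disc of `opening_radius` follows, and the mask is restricted to the ROI.
#'
#' @param image `Image2D` or matrix.
#' @param roi logical ROI mask (same size); `NULL` means the whole frame.
#' @param config a [nanometrics_config()].
#' @return logical ridge mask (an empty mask is valid).
#' @export
segment_ridges <- function(image, roi = NULL, config = nanometrics_config("sd")) {
  m <- as_image_matrix(image)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(m), ncol(m))
  resp <- meijering_ridge(m, sigmas = config$ridge_sigmas)
  resp <- rescale01(resp)
  mask <- resp > config$ridge_threshold
  if (!is.null(config$min_ridge_object_px) && any(mask)) {
    lab <- ebi_mat(EBImage::bwlabel(EBImage::Image(mask * 1)))
    keep <- which(tabulate(lab[lab > 0]) >= config$min_ridge_object_px)
    mask <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  if (config$opening_radius > 0 && any(mask))
    mask <- ebi_mat(EBImage::opening(EBImage::Image(mask * 1),
                                     disc_brush(config$opening_radius))) > 0.5
  mask & roi
}

#' Ridge density within the ROI
#'
#' Ratio of ridge pixels inside the ROI to ROI pixels, in `[0, 1]`.
#'
#' @param ridge_mask,roi_mask logical matrices of equal size.
#' @return scalar density; `NA` with a warning for an empty ROI.
#' @export
ridge_density <- function(ridge_mask, roi_mask) {
  stopifnot(all(dim(ridge_mask) == dim(roi_mask)))
  n_roi <- sum(roi_mask)
  if (n_roi == 0L) {
    warning("empty ROI: density undefined")
    return(NA_real_)
  }
  sum(ridge_mask & roi_mask) / n_roi
}

#' Local spacing between ridges (local-thickness transform)
#'
#' The spacing at a pixel is the diameter of the greatest circle that fits in
#' the ridge-free part of the ROI and contains the pixel. Concretely, with
#' `d(c)` the exact Euclidean distance from a free pixel `c` to the nearest
#' pixel that is a ridge, outside the ROI, or outside the image, the spacing
#' at `p` is `max 2 d(c)` over centres `c` with `||p - c|| < d(c)` (open-disk
#' convention). Statistics (mean, median, sd, and the area fraction of
#' free-space pixels with a defined spacing) are computed over ROI-minus-
#' ridges; the 8-bit display map is rescaled so the smallest defined spacing
#' maps to 0 and the largest to 255.
#'
#' @param ridge_mask,roi_mask logical matrices of equal size.
#' @return list with `spacing_map` (pixels; 0 outside ROI-minus-ridges),
#'   `spacing_stats` (named vector) and `spacing_map_8bit`.
#' @export
local_spacing <- function(ridge_mask, roi_mask) {
  stopifnot(all(dim(ridge_mask) == dim(roi_mask)))
  if (!any(roi_mask)) {
    warning("empty ROI: spacing undefined")
    return(list(spacing_map = NULL,
                spacing_stats = c(mean = NA, median = NA, sd = NA,
                                  area_fraction = NA),
                spacing_map_8bit = NULL))
  }
  free <- roi_mask & !ridge_mask
  ny <- nrow(free); nx <- ncol(free)
  if (!any(free)) {
    warning("ROI entirely covered by ridges: spacing undefined")
    return(list(spacing_map = matrix(0, ny, nx),
                spacing_stats = c(mean = NA, median = NA, sd = NA,
                                  area_fraction = 0),
                spacing_map_8bit = matrix(0L, ny, nx)))
  }
  padded <- matrix(FALSE, ny + 2L, nx + 2L)
  padded[2:(ny + 1L), 2:(nx + 1L)] <- free
  d2 <- edt_sq_cpp(padded)[2:(ny + 1L), 2:(nx + 1L), drop = FALSE]
  spacing <- paint_spacing_cpp(free, d2)
  vals <- spacing[free]
  stats <- c(mean = mean(vals), median = stats::median(vals),
             sd = stats::sd(vals), area_fraction = mean(vals > 0))
  rng <- range(vals)
  m8 <- matrix(0L, ny, nx)
  if (rng[2] > rng[1]) {
    m8[free] <- as.integer(round(255 * (vals - rng[1]) / (rng[2] - rng[1])))
  } else {
    m8[free] <- 255L
  }
  list(spacing_map = spacing, spacing_stats = stats, spacing_map_8bit = m8)
}

#' Full ridge quantification of one image
#'
#' Convenience wrapper running [extract_roi()], [segment_ridges()],
#' [ridge_density()] and [local_spacing()] in sequence.
#'
#' @param image `Image2D` or matrix.
#' @param config a [nanometrics_config()].
#' @param roi optional precomputed ROI mask (skips [extract_roi()]).
#' @return a `RidgeResult`: list with `roi_mask`, `ridge_mask`, `density`,
#'   `spacing_map`, `spacing_stats`, `spacing_map_8bit`.
#' @export
nanometrics_pipeline <- function(image, config = nanometrics_config("sd"),
                                 roi = NULL) {
  if (is.null(roi)) roi <- extract_roi(image, config)
  ridges <- segment_ridges(image, roi, config)
  density <- if (any(roi)) ridge_density(ridges, roi) else NA_real_
  sp <- if (any(roi)) local_spacing(ridges, roi) else
    list(spacing_map = NULL,
         spacing_stats = c(mean = NA, median = NA, sd = NA, area_fraction = NA),
         spacing_map_8bit = NULL)
  structure(list(roi_mask = roi, ridge_mask = ridges, density = density,
                 spacing_map = sp$spacing_map, spacing_stats = sp$spacing_stats,
                 spacing_map_8bit = sp$spacing_map_8bit),
            class = "RidgeResult")
}

#' @export
print.RidgeResult <- function(x, ...) {
  cat(sprintf("RidgeResult: ROI %d px, ridge density %.4f, median spacing %.2f px\n",
              sum(x$roi_mask), x$density, x$spacing_stats[["median"]]))
  invisible(x)
}

#' Sample an intensity profile along a line
#'
#' Bilinear sampling at `step`-pixel intervals between two endpoints given as
#' 0-based `(y, x)` coordinates.
#'
#' @param image `Image2D` or matrix.
#' @param line 2x2 matrix, rows = endpoints `(y, x)`.
#' @param step sampling interval along the line, pixels.
#' @return list with `t` (distance along the line) and `values`.
#' @export
profile_line <- function(image, line, step = 0.25) {
  m <- as_image_matrix(image)
  line <- matrix(as.numeric(line), 2, 2)
  L <- sqrt(sum((line[2, ] - line[1, ])^2))
  if (L <= 0) stop_exsrrf("line endpoints coincide", "exsrrf_value_error")
  t <- seq(0, L, by = step)
  dir <- (line[2, ] - line[1, ]) / L
  ys <- line[1, 1] + t * dir[1]
  xs <- line[1, 2] + t * dir[2]
  list(t = t, values = bilinear_at(m, ys, xs))
}

# subpixel threshold crossings around the run containing index i0
run_edges <- function(t, v, thr, i0) {
  n <- length(v)
  il <- i0
  while (il > 1L && v[il - 1L] > thr) il <- il - 1L
  ir <- i0
  while (ir < n && v[ir + 1L] > thr) ir <- ir + 1L
  left <- if (il == 1L) t[1L] else {
    t[il - 1L] + (t[il] - t[il - 1L]) * (thr - v[il - 1L]) / (v[il] - v[il - 1L])
  }
  right <- if (ir == n) t[n] else {
    t[ir] + (t[ir + 1L] - t[ir]) * (thr - v[ir]) / (v[ir + 1L] - v[ir])
  }
  c(left, right)
}

# local maxima (indices) with parabolic subpixel refinement
profile_peaks <- function(t, v) {
  n <- length(v)
  if (n < 3L) return(NULL)
  idx <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
  if (length(idx) == 0L) return(NULL)
  step <- t[2L] - t[1L]
  pos <- vapply(idx, function(i) {
    den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
    delta <- if (abs(den) > 1e-12) 0.5 * (v[i - 1L] - v[i + 1L]) / den else 0
    t[i] + max(-0.5, min(0.5, delta)) * step
  }, numeric(1))
  data.frame(index = idx, t = pos, value = v[idx])
}

#' Measure a structure width (and peak distance) along a line profile
#'
#' The image is auto-thresholded with the isodata (default intermeans)
#' algorithm; the width is the length of the contiguous above-threshold run
#' of the profile containing its brightest sample, with subpixel edges by
#' linear interpolation of the threshold crossing. When the profile shows two
#' (or more) local maxima, the distance between the two brightest is reported
#' as `peak_distance`. A line drawn at an oblique angle measures the
#' geometrically foreshortened width along the profile direction.
#'
#' @param image `Image2D` (its `pixel_size_nm` is used if set) or matrix.
#' @param line 2x2 matrix of endpoints, rows `(y, x)`, 0-based.
#' @param pixel_size_nm physical pixel size; overrides the image's.
#' @param expansion_factor divide nm lengths by this to report pre-expansion
#'   biological scale (default 1).
#' @param step profile sampling interval, pixels.
#' @return a `ProfileMeasurement`: list with `line`, `t`, `profile`,
#'   `threshold`, `width_px`, `width_nm`, `peak_distance_px`,
#'   `peak_distance_nm`.
#' @export
measure_sd_width <- function(image, line, pixel_size_nm = NULL,
                             expansion_factor = 1, step = 0.25) {
  m <- as_image_matrix(image)
  if (is.null(pixel_size_nm) && inherits(image, "Image2D"))
    pixel_size_nm <- image$pixel_size_nm
  thr <- isodata_threshold(m)
  pr <- profile_line(m, line, step)
  v <- pr$values
  imax <- which.max(v)
  if (v[imax] <= thr) {
    warning("profile crosses no above-threshold signal; width 0")
    width_px <- 0
  } else {
    e <- run_edges(pr$t, v, thr, imax)
    width_px <- e[2L] - e[1L]
  }
  pk <- profile_peaks(pr$t, v)
  peak_distance_px <- NA_real_
  if (!is.null(pk) && nrow(pk) >= 2L) {
    top2 <- pk[order(-pk$value)[1:2], ]
    peak_distance_px <- abs(diff(top2$t))
  }
  to_nm <- function(px) if (is.null(pixel_size_nm)) NA_real_ else
    px * pixel_size_nm / expansion_factor
  structure(list(line = line, t = pr$t, profile = v, threshold = thr,
                 width_px = width_px, width_nm = to_nm(width_px),
                 peak_distance_px = peak_distance_px,
                 peak_distance_nm = to_nm(peak_distance_px)),
            class = "ProfileMeasurement")
}

#' Segment foot-process-like regions
#'
#' Automatic stage of the foot-process pipeline: isodata thresholding picks
#' out the bright separator (slit-diaphragm) curve, the mask is inverted, and
#' watershed segmentation on the distance transform labels each enclosed
#' region. Separator pixels stay 0.
#'
#' @param image `Image2D` or matrix with bright ridge-like separators between
#'   darker regions.
#' @param tolerance watershed merging tolerance (distance-map units).
#' @return integer label matrix (0 = separator/background); all-zero when the
#'   image has no contrast.
#' @export
segment_fp <- function(image, tolerance = 1) {
  m <- as_image_matrix(image)
  if (max(m) == min(m)) return(matrix(0L, nrow(m), ncol(m)))
  thr <- isodata_threshold(m)
  sd_mask <- m > thr
  fp_mask <- !sd_mask
  if (!any(fp_mask)) return(matrix(0L, nrow(m), ncol(m)))
  dm <- EBImage::distmap(EBImage::Image(fp_mask * 1))
  lab <- EBImage::watershed(dm, tolerance = tolerance)
  matrix(as.integer(ebi_mat(lab)), nrow(m), ncol(m))
}

#' Width of one labelled region along a horizontal profile
#'
#' Helper for foot-process width: the contiguous run of the given label along
#' the horizontal line through the region's centroid (optionally at a
#' supplied row).
#'
#' @param labels integer label matrix from [segment_fp()].
#' @param id label to measure.
#' @param row optional 1-based row; default the label centroid row.
#' @return width in pixels (0 when the label is absent from that row).
#' @export
fp_width <- function(labels, id, row = NULL) {
  pos <- which(labels == id, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(0)
  if (is.null(row)) row <- round(mean(pos[, 1L]))
  in_row <- labels[row, ] == id
  if (!any(in_row)) return(0)
  runs <- rle(in_row)
  max(runs$lengths[runs$values])
}

#' Decide whether two point-spread functions are separated
#'
#' Emulates the visual separation call on histogram-adjusted crops: after
#' normalising to the maximum, pixels above `floor_fraction` count as signal;
#' the call is positive iff the signal splits into exactly two dominant
#' blobs (peak at least `dominant_fraction` of the maximum) with at least one
#' signal-free pixel on the segment between their maxima.
#'
#' @param x 2-D crop (matrix/`Image2D`) or 1-D profile (numeric vector).
#' @param floor_fraction signal floor as a fraction of the maximum
#'   (default 0.1).
#' @param dominant_fraction minimum peak height of a blob, relative to the
#'   global maximum, for it to count (default 0.3).
#' @param min_area minimum pixel count of a 2-D blob for it to count as a
#'   fluorescent maximum rather than pixel noise (default 4).
#' @param min_snr a dominant 2-D blob must additionally rise `min_snr`
#'   robust standard deviations (median absolute deviation) above the image
#'   median, so noise ripples in near-empty crops are not mistaken for
#'   fluorescent maxima (default 5).
#' @return list with `separated` (logical) and `maxima` (matrix of `(y, x)`
#'   positions, 0-based, or vector of profile positions).
#' @export
psf_separation <- function(x, floor_fraction = 0.1, dominant_fraction = 0.3,
                           min_area = 4L, min_snr = 5) {
  if (!inherits(x, "Image2D") && is.null(dim(x))) {
    v <- as.numeric(x)
    if (max(v) <= 0) return(list(separated = FALSE, maxima = numeric(0)))
    v <- v / max(v)
    above <- v > floor_fraction
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    peaks <- vapply(runs, function(i) max(v[starts[i]:ends[i]]), numeric(1))
    dom <- runs[peaks >= dominant_fraction]
    maxima <- vapply(dom, function(i) {
      seg <- starts[i]:ends[i]
      seg[which.max(v[seg])] - 1L
    }, numeric(1))
    return(list(separated = length(dom) == 2L, maxima = maxima))
  }
  m <- as_image_matrix(x)
  if (max(m) <= 0) return(list(separated = FALSE, maxima = matrix(0, 0, 2)))
  v <- m / max(m)
  mask <- v > floor_fraction
  lab <- ebi_mat(EBImage::bwlabel(EBImage::Image(mask * 1)))
  ids <- setdiff(unique(as.vector(lab)), 0)
  if (length(ids) == 0L) return(list(separated = FALSE, maxima = matrix(0, 0, 2)))
  peaks <- vapply(ids, function(i) max(v[lab == i]), numeric(1))
  areas <- vapply(ids, function(i) sum(lab == i), numeric(1))
  noise_gate <- stats::median(v) + min_snr * stats::mad(v)
  dom <- ids[peaks >= dominant_fraction & areas >= min_area &
               peaks >= noise_gate]
  maxima <- t(vapply(dom, function(i) {
    w <- which(lab == i & v == max(v[lab == i]), arr.ind = TRUE)[1L, ]
    c(w[1L], w[2L]) - 1
  }, numeric(2)))
  separated <- FALSE
  if (length(dom) == 2L) {
    # require a signal-free pixel on the segment between the two maxima
    p1 <- maxima[1L, ]; p2 <- maxima[2L, ]
    nstep <- max(2L, ceiling(2 * sqrt(sum((p2 - p1)^2))))
    tt <- seq(0, 1, length.out = nstep + 1L)
    vals <- bilinear_at(v, p1[1L] + tt * (p2[1L] - p1[1L]),
                        p1[2L] + tt * (p2[2L] - p1[2L]))
    separated <- any(vals <= floor_fraction)
  }
  list(separated = separated, maxima = maxima)
}

#' Expansion factor from paired pre-/post-expansion measurements
#'
#' Ratio of the post- to pre-expansion peak distance of the same structure
#' (the two fluorophore centres of a nanoruler). Distances in nanometres are
#' preferred; pixel distances are used when both sides lack a pixel size.
#'
#' @param pre,post `ProfileMeasurement`s with a defined `peak_distance`.
#' @return scalar dimensionless expansion factor.
#' @export
expansion_factor <- function(pre, post) {
  get_d <- function(p) {
    if (!is.na(p$peak_distance_nm)) p$peak_distance_nm else p$peak_distance_px
  }
  d_pre <- get_d(pre); d_post <- get_d(post)
  if (is.na(d_pre) || is.na(d_post))
    stop_exsrrf("both measurements need a defined peak distance", "exsrrf_value_error")
  if (d_pre <= 0)
    stop_exsrrf("pre-expansion distance is zero; factor undefined", "exsrrf_value_error")
  d_post / d_pre
}
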