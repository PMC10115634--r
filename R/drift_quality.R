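# Drift quantification: offset norms, MSSIM/MSE before vs after registration
# on overlap regions, low/high-drift stratification, and ridge-SSIM as a
# segmentation-readiness score.

#' Structural similarity index (SSIM)
#'
#' Mean SSIM between two images of equal size, computed with a
#' Gaussian-weighted window (default 7x7, sigma 1.5) and the standard
#' stabilising constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`. Inputs are
#' expected on a `[0, data_range]` scale.
#'
#' @param x,y matrices of identical size.
#' @param data_range dynamic range `L`; default 1.
#' @param win_size odd window width in pixels.
#' @param win_sigma Gaussian sigma of the window weights.
#' @param map return the SSIM map instead of its mean.
#' @return scalar mean SSIM in `[-1, 1]`, or the SSIM map.
#' @export
ssim_index <- function(x, y, data_range = 1, win_size = 7L, win_sigma = 1.5,
                       map = FALSE) {
  x <- as_image_matrix(x); y <- as_image_matrix(y)
  stopifnot(all(dim(x) == dim(y)), win_size %% 2L == 1L)
  r <- (win_size - 1L) %/% 2L
  t <- seq.int(-r, r)
  k <- exp(-t^2 / (2 * win_sigma^2)); k <- k / sum(k)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_x <- conv_sep(x, k); mu_y <- conv_sep(y, k)
  sxx <- conv_sep(x * x, k) - mu_x^2
  syy <- conv_sep(y * y, k) - mu_y^2
  sxy <- conv_sep(x * y, k) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
       ((mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2))
  if (map) s else mean(s)
}

#' Summarise a drift trace
#'
#' Mean of the per-frame 2-norm offsets over frames 2..T and the offset of
#' the final frame (usually the largest in a stack).
#'
#' @param trace a [drift_trace()].
#' @return named numeric `c(mean_offset, last_offset)` in pixels.
#' @export
offset_summary <- function(trace) {
  n <- norm_2(trace$shifts)
  if (length(n) == 1L) return(c(mean_offset = 0, last_offset = 0))
  c(mean_offset = mean(n[-1L]), last_offset = n[length(n)])
}

# bounding rectangle of a (rectangular) overlap mask
mask_rect <- function(mask) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  list(rows = rr[1]:rr[2], cols = cc[1]:cc[2])
}

#' Similarity metrics before and after registration
#'
#' For each frame `t > 1`, MSSIM and MSE against frame 1 are computed on the
#' overlap region (the rectangle valid after shift removal, from the drift
#' trace) for both the unregistered and the registered stack, on a common
#' `[0, 1]` rescaling of the cropped frames. Deltas are before minus after,
#' so `delta_mssim < 0` and `delta_mse > 0` both signal an improvement
#' through registration. Frames with an empty overlap are flagged missing and
#' excluded from the means with a warning.
#'
#' @param stack_before,stack_after `TimeStack`s of identical shape.
#' @param trace the `DriftTrace` from registering `stack_before`.
#' @param channel 1-based channel index.
#' @return a `DriftMetrics` object: per-frame vectors (`per_frame_offset`,
#'   `mssim_before`, `mssim_after`, `mse_before`, `mse_after`) and summary
#'   scalars (`mean_offset`, `last_offset`, `delta_mssim_mean`,
#'   `delta_mssim_last`, `delta_mse_mean`, `delta_mse_last`).
#' @export
similarity_metrics <- function(stack_before, stack_after, trace, channel = 1L) {
  stopifnot(inherits(stack_before, "TimeStack"), inherits(stack_after, "TimeStack"))
  db <- dim(stack_before$data)
  stopifnot(all(db == dim(stack_after$data)))
  T <- db[1L]
  ref_b <- stack_before$data[1L, channel, , ]
  ref_a <- stack_after$data[1L, channel, , ]
  mssim_b <- mssim_a <- mse_b <- mse_a <- rep(NA_real_, T - 1L)
  for (t in seq.int(2L, T)) {
    mask <- if (!is.null(trace$overlap)) trace$overlap[[t]] else
      matrix(TRUE, db[3L], db[4L])
    if (!any(mask)) {
      warning(sprintf("frame %d: empty overlap; metrics flagged missing", t))
      next
    }
    rect <- mask_rect(mask)
    crop <- function(m) m[rect$rows, rect$cols, drop = FALSE]
    pair <- function(a, b) {
      rng <- range(c(a, b))
      if (rng[2] > rng[1]) list((a - rng[1]) / (rng[2] - rng[1]),
                                (b - rng[1]) / (rng[2] - rng[1]))
      else list(a * 0, b * 0)
    }
    pb <- pair(crop(ref_b), crop(stack_before$data[t, channel, , ]))
    pa <- pair(crop(ref_a), crop(stack_after$data[t, channel, , ]))
    mssim_b[t - 1L] <- ssim_index(pb[[1]], pb[[2]])
    mssim_a[t - 1L] <- ssim_index(pa[[1]], pa[[2]])
    mse_b[t - 1L] <- mean((pb[[1]] - pb[[2]])^2)
    mse_a[t - 1L] <- mean((pa[[1]] - pa[[2]])^2)
  }
  off <- offset_summary(trace)
  dm <- mssim_b - mssim_a
  de <- mse_b - mse_a
  structure(list(per_frame_offset = norm_2(trace$shifts),
                 mean_offset = unname(off[1L]), last_offset = unname(off[2L]),
                 mssim_before = mssim_b, mssim_after = mssim_a,
                 mse_before = mse_b, mse_after = mse_a,
                 delta_mssim_mean = mean(dm, na.rm = TRUE),
                 delta_mssim_last = tail(dm, 1L),
                 delta_mse_mean = mean(de, na.rm = TRUE),
                 delta_mse_last = tail(de, 1L)),
            class = "DriftMetrics")
}

#' @export
print.DriftMetrics <- function(x, ...) {
  cat(sprintf("DriftMetrics: mean offset %.3f px, last offset %.3f px\n",
              x$mean_offset, x$last_offset))
  cat(sprintf("  delta MSSIM (before-after): mean %.4f, last %.4f\n",
              x$delta_mssim_mean, x$delta_mssim_last))
  cat(sprintf("  delta MSE   (before-after): mean %.2e, last %.2e\n",
              x$delta_mse_mean, x$delta_mse_last))
  invisible(x)
}

#' Stratify stacks into low- and high-drift groups
#'
#' Each stack is summarised by its mean offset; the threshold is the cohort
#' mean plus `0.5 * sd` of those summaries ("0.5 s.d. from the mean"), and
#' stacks above it are labelled high drift. `threshold_mode = "half_sd"`
#' gives the alternative absolute reading (threshold `0.5 * sd` alone).
#'
#' @param metrics list of `DriftMetrics` (or a numeric vector of per-stack
#'   mean offsets).
#' @param statistic `"mean_offset"` (default) or `"last_offset"`.
#' @param threshold_mode `"mean_plus_half_sd"` (default) or `"half_sd"`.
#' @return list with `labels` (factor `low drift` / `high drift`),
#'   `threshold` and the per-stack `values`.
#' @export
stratify_drift <- function(metrics, statistic = c("mean_offset", "last_offset"),
                           threshold_mode = c("mean_plus_half_sd", "half_sd")) {
  statistic <- match.arg(statistic)
  threshold_mode <- match.arg(threshold_mode)
  v <- if (is.numeric(metrics)) as.numeric(metrics)
       else vapply(metrics, function(m) m[[statistic]], numeric(1))
  if (length(v) < 2L)
    stop_exsrrf("stratification needs at least 2 stacks", "exsrrf_value_error")
  thr <- switch(threshold_mode,
                mean_plus_half_sd = mean(v) + 0.5 * stats::sd(v),
                half_sd = 0.5 * stats::sd(v))
  labels <- factor(ifelse(v > thr, "high drift", "low drift"),
                   levels = c("low drift", "high drift"))
  list(labels = labels, threshold = thr, values = v)
}

#' Ridge-image structural similarity
#'
#' Segmentation-readiness score: SSIM between an image and its detected
#' ridge response, both min-max rescaled to `[0, 1]`. Values closer to 1 mean
#' the computed ridges track the underlying structures better.
#'
#' @param image,ridges `Image2D` or matrices of equal size (`ridges` is
#'   typically the ridge-filter response of `image`).
#' @return scalar similarity in `[-1, 1]`.
#' @export
ridge_ssim <- function(image, ridges) {
  a <- rescale01(as_image_matrix(image))
  b <- rescale01(as_image_matrix(ridges))
  ssim_index(a, b, data_range = 1)
}
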