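# Meijering neuriteness ridge filter and the isodata (intermeans) automatic
# threshold. Both are authored here: the ridge filter is the published
# modified-Hessian neuriteness measure; the threshold is the classic
# Ridler-Calvard iteration that ImageJ exposes as its "Default" method.

# Gaussian-derivative Hessian (mirror boundary): Hyy, Hyx, Hxx at scale
# sigma, computed as a cascade of two first-order derivative passes at
# sigma/sqrt(2) each (total variance sigma^2). The cascade avoids the
# aliasing of directly sampled second-derivative kernels at small sigma; a
# wide truncation (8 sigma) keeps the slowly decaying tails.
hessian_gauss <- function(x, sigma) {
  s <- sigma / sqrt(2)
  g0 <- gauss_kernel(s, 0L, truncate = 8)
  g1 <- gauss_kernel(s, 1L, truncate = 8)
  dy <- conv_sep(x, g1, g0)  # first derivative along rows
  dx <- conv_sep(x, g0, g1)  # first derivative along cols
  list(hyy = conv_sep(dy, g1, g0),
       hyx = conv_sep(dy, g0, g1),
       hxx = conv_sep(dx, g0, g1))
}

#' Meijering neuriteness ridge response
#'
#' Multiscale ridge detector for curvilinear structures. At each scale the
#' Hessian (Gaussian derivatives) is modified with `alpha = 1/3`
#' (`l_i = e_i + alpha * e_j`), the eigenvalue of largest magnitude is taken,
#' negatives are clamped to zero and the scale response is normalised to a
#' maximum of 1; the output is the pixelwise maximum over scales, so it lies
#' in `[0, 1]` whenever any ridge is present.
#'
#' @param image matrix or `Image2D`.
#' @param sigmas numeric vector of detector scales (pixels).
#' @param bright_ridges detect bright (default) or dark ridges.
#' @return matrix of the same size with the ridge response in `[0, 1]`.
#' @export
meijering_ridge <- function(image, sigmas = c(1, 2, 3), bright_ridges = TRUE) {
  x <- as_image_matrix(image)
  if (bright_ridges) x <- -x # normalise to dark-ridge convention
  alpha <- 1 / 3
  out <- matrix(0, nrow(x), ncol(x))
  for (s in sigmas) {
    h <- hessian_gauss(x, s)
    # eigenvalues of [[hyy, hyx], [hyx, hxx]]
    tr2 <- (h$hyy + h$hxx) / 2
    disc <- sqrt(((h$hyy - h$hxx) / 2)^2 + h$hyx^2)
    e1 <- tr2 + disc
    e2 <- tr2 - disc
    v1 <- e1 + alpha * e2
    v2 <- e2 + alpha * e1
    vals <- ifelse(abs(v1) >= abs(v2), v1, v2)
    vals[vals < 0] <- 0
    mx <- max(vals)
    if (mx > 0) vals <- vals / mx
    out <- pmax(out, vals)
  }
  out
}

#' Isodata (iterative intermeans) threshold
#'
#' The "default" automatic threshold: starting from the histogram mid-range,
#' iterate `t <- (mean below or at t + mean above t) / 2` on a 256-bin
#' histogram until the integer split stabilises. Returns the threshold on the
#' intensity scale of the input; foreground is `x > threshold`.
#'
#' @param x numeric vector/matrix of intensities, or an `Image2D`.
#' @param nbins number of histogram bins (256, matching 8-bit practice).
#' @return scalar threshold.
#' @export
isodata_threshold <- function(x, nbins = 256L) {
  v <- as.numeric(as_image_matrix(x))
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  # bin values to 0..nbins-1
  b <- pmin(nbins - 1L, floor((v - rng[1]) / (rng[2] - rng[1]) * nbins))
  h <- tabulate(b + 1L, nbins)
  s <- isodata_split(h)
  # split s separates bins <= s from bins > s; threshold at the bin edge
  rng[1] + (s + 1) * (rng[2] - rng[1]) / nbins
}

# integer split on a histogram (bins 0..n-1): Ridler-Calvard fixed point
isodata_split <- function(h) {
  n <- length(h)
  bins <- seq.int(0L, n - 1L)
  nz <- which(h > 0) - 1L
  lo <- min(nz); hi <- max(nz)
  if (lo == hi) return(lo)
  s <- floor((lo + hi) / 2)
  for (iter in seq_len(1000L)) {
    below <- h[bins <= s]; above <- h[bins > s]
    mu1 <- sum(bins[bins <= s] * below) / sum(below)
    mu2 <- sum(bins[bins > s] * above) / sum(above)
    s_new <- floor((mu1 + mu2) / 2)
    if (is.na(s_new) || s_new == s) break
    s <- s_new
  }
  s
}
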