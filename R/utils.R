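# Internal numeric helpers shared across modules.

#' Reflect-pad a matrix
#'
#' Mirror padding (edge pixel not repeated), matching the "reflect" boundary
#' convention of standard image-processing libraries.
#' @noRd
pad_reflect <- function(x, py, px = py) {
  ny <- nrow(x); nx <- ncol(x)
  idx_ref <- function(n, p) {
    # mirror indices for 1..n padded by p on both sides
    i <- seq.int(1 - p, n + p)
    # reflect without repeating the edge sample; period 2(n-1)
    if (n == 1) return(rep(1L, length(i)))
    j <- abs(i - 1) %% (2L * (n - 1L))
    as.integer(ifelse(j >= n, 2L * (n - 1L) - j, j) + 1L)
  }
  x[idx_ref(ny, py), idx_ref(nx, px), drop = FALSE]
}

#' Separable convolution with reflect boundary
#'
#' @param x matrix
#' @param ky,kx 1-D kernels (odd length) applied along rows (y) and columns (x)
#' @noRd
conv_sep <- function(x, ky, kx = ky) {
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  xp <- pad_reflect(x, ry, rx)
  out <- conv_sep_cpp(xp, as.numeric(ky), as.numeric(kx))
  out[(ry + 1L):(ry + nrow(x)), (rx + 1L):(rx + ncol(x)), drop = FALSE]
}

#' Gaussian kernel and derivatives
#'
#' @param sigma standard deviation in pixels
#' @param order 0 (smooth), 1 (first derivative) or 2 (second derivative)
#' @noRd
gauss_kernel <- function(sigma, order = 0L, truncate = 4) {
  r <- max(1L, ceiling(truncate * sigma))
  t <- seq.int(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = g * (-t / sigma^2),
    "2" = g * ((t^2 - sigma^2) / sigma^4),
    stop("unsupported derivative order")
  )
}

#' Gaussian smoothing with reflect boundary
#' @noRd
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gauss_kernel(sigma, 0L)
  conv_sep(x, k, k)
}

#' Rescale to [0, 1]; constant input maps to all zeros
#' @noRd
rescale01 <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}

#' Bilinear sampling of a matrix at fractional (row, col) positions
#'
#' 0-based coordinates with pixel centres at integers; out-of-range positions
#' are clamped to the border (replicate).
#' @noRd
bilinear_at <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 0), ny - 1)
  x <- pmin(pmax(x, 0), nx - 1)
  y0 <- floor(y); x0 <- floor(x)
  y1 <- pmin(y0 + 1, ny - 1); x1 <- pmin(x0 + 1, nx - 1)
  fy <- y - y0; fx <- x - x0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Stop with a classed error
#' @noRd
stop_exsrrf <- function(msg, class) {
  stop(structure(class = c(class, "exsrrf_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
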