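# Independent brute-force oracles. These deliberately re-derive quantities
# from their definitions with naive algorithms, so they share no code path
# with the package implementations they check.

# Largest-inscribed-disk spacing by exhaustive double loop over pixel pairs:
# d(c) = distance from a free pixel c to the nearest non-free pixel (with a
# virtual background ring one pixel outside the frame); spacing(p) =
# max over centres c with ||p - c|| < d(c) of 2 d(c).
oracle_local_spacing <- function(ridge_mask, roi_mask) {
  free <- roi_mask & !ridge_mask
  ny <- nrow(free); nx <- ncol(free)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- free
  bg <- which(!pad, arr.ind = TRUE)
  cen <- which(pad, arr.ind = TRUE)
  d <- numeric(nrow(cen))
  for (i in seq_len(nrow(cen)))
    d[i] <- sqrt(min((bg[, 1L] - cen[i, 1L])^2 + (bg[, 2L] - cen[i, 2L])^2))
  out <- matrix(0, ny + 2L, nx + 2L)
  pix <- which(pad, arr.ind = TRUE)
  for (p in seq_len(nrow(pix))) {
    dd <- sqrt((cen[, 1L] - pix[p, 1L])^2 + (cen[, 2L] - pix[p, 2L])^2)
    cover <- dd < d
    if (any(cover)) out[pix[p, 1L], pix[p, 2L]] <- 2 * max(d[cover])
  }
  out[2:(ny + 1L), 2:(nx + 1L), drop = FALSE]
}

# All integer fixed points of the intermeans condition on a 256-bin
# histogram: s such that s == floor((mean of bins <= s + mean of bins > s)/2).
oracle_isodata_fixed_points <- function(h) {
  bins <- seq_along(h) - 1L
  out <- integer(0)
  for (s in 0:(length(h) - 2L)) {
    lo <- bins <= s
    if (sum(h[lo]) == 0 || sum(h[!lo]) == 0) next
    mu1 <- sum(bins[lo] * h[lo]) / sum(h[lo])
    mu2 <- sum(bins[!lo] * h[!lo]) / sum(h[!lo])
    if (floor((mu1 + mu2) / 2) == s) out <- c(out, s)
  }
  out
}

# magnified-grid coordinate (0-based) of a source-pixel position (0-based)
mag_coord <- function(pos, mag) (pos + 0.5) * mag - 0.5

# mean frame of one channel of a TimeStack (the widefield average image)
widefield_average <- function(stack, channel = 1L) {
  apply(stack$data[, channel, , , drop = FALSE], c(3, 4), mean)
}

quiet_srrf <- function(...) suppressMessages(srrf_process(...))
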