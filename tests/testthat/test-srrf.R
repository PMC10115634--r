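test_that("settings validate ranges and reject unimplemented modes", {
  s <- srrf_settings()
  expect_equal(s$ring_radius, 0.5)
  expect_equal(s$magnification, 10L)
  expect_equal(s$axes_in_ring, 8L)
  expect_error(srrf_settings(ring_radius = 0), class = "exsrrf_config_error")
  expect_error(srrf_settings(magnification = 12), class = "exsrrf_config_error")
  expect_error(srrf_settings(axes_in_ring = 1), class = "exsrrf_config_error")
  expect_error(srrf_settings(gradient_weighting = TRUE),
               class = "exsrrf_not_implemented")
  expect_error(srrf_settings(renormalize = TRUE),
               class = "exsrrf_not_implemented")
  expect_true(srrf_settings_preset("tissue")$gradient_smoothing)
  expect_false(srrf_settings_preset("nanoruler")$gradient_smoothing)
})

test_that("gradients are exact on constants and ramps, radial on a blob", {
  expect_equal(compute_gradients(matrix(3, 8, 8))$gx, matrix(0, 8, 8))
  ramp <- matrix(rep(0:9, each = 10), 10, 10) # column j holds value j - 1
  g <- compute_gradients(ramp) # I(y, x) = x
  expect_equal(g$gx[3:8, 3:8], matrix(1, 6, 6))
  expect_equal(g$gy[3:8, 3:8], matrix(0, 6, 6))
  # gradient of a radial Gaussian points along the radius
  yy <- outer(0:20, rep(1, 21)); xx <- t(yy)
  blob <- exp(-((yy - 10)^2 + (xx - 10)^2) / 8)
  g <- compute_gradients(blob)
  for (pt in list(c(6, 9), c(14, 15), c(9, 5))) {
    gv <- c(g$gy[pt[1] + 1, pt[2] + 1], g$gx[pt[1] + 1, pt[2] + 1])
    rv <- c(10 - pt[1], 10 - pt[2]) # toward the centre
    cosang <- sum(gv * rv) / sqrt(sum(gv^2) * sum(rv^2))
    expect_gt(cosang, 0.999)
  }
})

test_that("radiality peaks on point emitters and is lower on lines", {
  s <- srrf_settings(magnification = 5L)
  # constant frame: zero gradients contribute zero
  expect_equal(radiality_map(matrix(1, 12, 12), s)$data,
               matrix(0, 60, 60))
  # single emitter: global maximum within one magnified pixel of the centre
  pos <- c(7.3, 8.6)
  yy <- outer(0:15, rep(1, 16)); xx <- t(yy)
  frame <- exp(-((yy - pos[1])^2 + (xx - pos[2])^2) / (2 * 1.3^2))
  r <- radiality_map(frame, s)$data
  pk <- which(r == max(r), arr.ind = TRUE)[1, ] - 1
  expect_lt(max(abs(pk - mag_coord(pos, 5))), 1)
  # a straight line of the same brightness scores below the point emitter
  line <- exp(-(yy - 7.5)^2 / (2 * 1.3^2)) # bright horizontal line
  rl <- radiality_map(line, s)$data
  expect_lt(max(rl), max(r))
})

test_that("temporal aggregation is the frame mean and permutation-invariant", {
  set.seed(8)
  maps <- lapply(1:5, function(i) matrix(runif(36), 6))
  agg <- temporal_aggregate(maps)$data
  expect_equal(agg, Reduce(`+`, maps) / 5)
  expect_equal(temporal_aggregate(maps[c(3, 1, 5, 2, 4)])$data, agg)
  expect_equal(temporal_aggregate(list(maps[[1]], maps[[2]]))$data,
               (maps[[1]] + maps[[2]]) / 2)
  expect_equal(temporal_aggregate(rep(maps[1], 10))$data, maps[[1]])
  expect_error(temporal_aggregate(list(maps[[1]], matrix(0, 3, 3))),
               class = "exsrrf_aggregation_error")
})

test_that("anti-patterning equalises offset-class means and preserves the mean", {
  M <- 4L
  set.seed(13)
  base <- matrix(runif(32 * 32, 1, 2), 32, 32)
  # imprint an M-periodic lattice: alternating class gains
  cy <- ((seq_len(32) - 1) %% M); cx <- ((seq_len(32) - 1) %% M)
  gain <- 1 + 0.5 * ((outer(cy, cx, `+`) %% 2))
  patterned <- base * gain
  out <- minimize_patterning(patterned, magnification = M)
  mus <- sapply(0:(M - 1), function(a)
    sapply(0:(M - 1), function(b) mean(out[cy == a, cx == b])))
  expect_lt(diff(range(mus)), 1e-12)
  expect_equal(mean(out), mean(patterned), tolerance = 1e-9)
  # balanced map passes through unchanged
  flat <- matrix(1, 16, 16)
  expect_equal(minimize_patterning(flat, magnification = M), flat)
  # spectral power at the lattice frequency strictly decreases
  pow_at_lattice <- function(m) {
    f <- Mod(stats::fft(m))^2
    f[1 + 32 / M, 1] + f[1, 1 + 32 / M]
  }
  expect_lt(pow_at_lattice(out), pow_at_lattice(patterned))
})

test_that("srrf_process ties the pipeline together", {
  s <- srrf_settings(magnification = 5L)
  # all-zero stack maps to all-zero SRRF
  zero <- time_stack(array(0, c(3, 1, 8, 8)))
  expect_true(all(quiet_srrf(zero, 1, s)$data == 0))
  # single-frame stack equals the (anti-patterned) radiality of that frame
  set.seed(4)
  frame <- exsrrf:::gaussian_blur(matrix(runif(144), 12), 1)
  one <- time_stack(array(frame, c(1, 1, 12, 12)))
  direct <- minimize_patterning(radiality_map(frame, s))$data
  expect_equal(quiet_srrf(one, 1, s)$data, direct)
  expect_error(quiet_srrf(one, 3, s), class = "exsrrf_index_error")
  # a message is logged when no drift trace accompanies the stack
  expect_message(srrf_process(one, 1, s), "drift trace")
  # positivity constraint holds on noisy input
  noisy <- time_stack(array(abs(rnorm(5 * 144)), c(5, 1, 12, 12)))
  expect_true(all(quiet_srrf(noisy, 1, s)$data >= 0))
  # magnified pixel size
  ts <- time_stack(array(frame, c(1, 1, 12, 12)), pixel_size_nm = 65)
  expect_equal(quiet_srrf(ts, 1, s)$pixel_size_nm, 13)
})

test_that("a blinking emitter keeps its peak position and scaled height", {
  pos <- c(9.4, 10.2)
  yy <- outer(0:19, rep(1, 20)); xx <- t(yy)
  frame <- exp(-((yy - pos[1])^2 + (xx - pos[2])^2) / (2 * 1.3^2))
  s <- srrf_settings(magnification = 5L, minimize_patterning = FALSE)
  set.seed(31)
  on <- runif(50) < 0.6
  maps <- lapply(seq_len(50), function(t)
    radiality_map(frame * on[t], s))
  agg <- temporal_aggregate(maps)$data
  always <- radiality_map(frame, s)$data
  pk <- which(agg == max(agg), arr.ind = TRUE)[1, ] - 1
  expect_lt(max(abs(pk - mag_coord(pos, 5))), 1)
  expect_equal(max(agg), mean(on) * max(always), tolerance = 1e-9)
})
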