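test_that("reference preprocessing keeps only the top decile", {
  cfg <- registration_config()
  # constant frame: every pixel is at its own 90th percentile
  expect_true(all(preprocess_reference(matrix(5, 32, 32), cfg)$data == 0))
  # single bright pixel: the surviving blob stays centred on it
  frame <- matrix(0, 33, 33); frame[17, 17] <- 100
  out <- preprocess_reference(frame, cfg)$data
  expect_equal(unname(which(out == max(out), arr.ind = TRUE)[1, ]), c(17, 17))
  expect_equal(out, out[33:1, 33:1]) # symmetric support
  # seeded noise: nonzero count matches a direct percentile computation
  set.seed(21)
  noise <- matrix(runif(48 * 48), 48, 48)
  sm <- exsrrf:::gaussian_blur(noise, 1)
  q <- quantile(sm, 0.9, names = FALSE)
  out <- preprocess_reference(noise, cfg)$data
  expect_equal(sum(out > 0), sum(sm > q))
})

test_that("histogram matching reproduces the reference distribution", {
  set.seed(3)
  m <- matrix(rexp(400), 20)
  r <- matrix(rgamma(400, 2), 20)
  out <- match_histogram(m, r)$data
  expect_equal(sort(as.vector(out)), sort(as.vector(r)))
  # rank preservation
  expect_equal(order(out), order(m))
  # self-matching is the identity
  expect_equal(match_histogram(m, m)$data, m)
  # two-level remap
  a <- matrix(c(0, 10, 0, 10), 2)
  b <- matrix(c(0, 200, 200, 0), 2)
  expect_setequal(as.vector(match_histogram(a, b)$data), c(0, 200))
})

test_that("shift estimation recovers known integer and subpixel shifts", {
  set.seed(5)
  ref <- matrix(0, 64, 64)
  ref[20:44, 18:46] <- matrix(runif(25 * 29), 25, 29)
  ref <- exsrrf:::gaussian_blur(ref, 1.5)
  expect_equal(estimate_shift(ref, ref), c(0, 0))
  expect_equal(estimate_shift(ref, translate_image(ref, 3, -2)), c(3, -2),
               tolerance = 0.02)
  expect_equal(estimate_shift(ref, translate_image(ref, 1.25, -0.5), 100L),
               c(1.25, -0.5), tolerance = 0.1)
  expect_error(estimate_shift(ref, matrix(0, 64, 64)),
               class = "exsrrf_estimation_error")
  expect_error(estimate_shift(ref, ref[1:32, ]), class = "exsrrf_value_error")
})

test_that("translate_image applies crop-and-pad plus fractional interpolation", {
  m <- matrix(seq_len(36), 6)
  expect_equal(translate_image(m, 0, 0), m)
  s <- translate_image(m, 2, 0, fill = -1)
  expect_true(all(s[1:2, ] == -1))
  expect_equal(s[3:6, ], m[1:4, ])
  # half-pixel shift averages neighbours in the interior
  h <- translate_image(m, 0.5, 0)
  expect_equal(h[3, 3], (m[2, 3] + m[3, 3]) / 2)
})

test_that("stack registration recovers synthetic drift and is idempotent", {
  sim <- make_texture_stack(frames = 30, drift = c(0.15, -0.1), seed = 9)
  reg <- register_stack(sim$stack)
  err <- reg$trace$shifts - sim$truth$drift
  expect_lt(sqrt(mean(err^2)), 0.2)
  expect_equal(reg$trace$shifts[1, ], c(dy = 0, dx = 0))
  # frame 0 untouched
  expect_equal(reg$stack$data[1, 1, , ], sim$stack$data[1, 1, , ])
  # idempotence at high SNR: re-registering a registered stack finds
  # (near) zero shifts
  clean <- make_texture_stack(frames = 20, drift = c(0.2, -0.15), snr = 50,
                              seed = 11)
  reg1 <- register_stack(clean$stack)
  reg2 <- register_stack(reg1$stack)
  expect_lt(max(sqrt(rowSums(reg2$trace$shifts^2))), 0.1)
  # already-aligned stack: all shifts (near) zero
  still <- make_texture_stack(frames = 10, drift = c(0, 0), snr = 50, seed = 2)
  reg0 <- register_stack(still$stack)
  expect_lt(max(abs(reg0$trace$shifts)), 0.1)
})

test_that("every channel receives the identical per-frame shift", {
  sim <- make_texture_stack(frames = 8, drift = c(0.4, 0.25), seed = 14)
  # duplicate the reference channel: both channels must register identically
  d <- dim(sim$stack$data)
  arr <- array(0, c(d[1], 2, d[3], d[4]))
  arr[, 1, , ] <- sim$stack$data[, 1, , ]
  arr[, 2, , ] <- sim$stack$data[, 1, , ]
  reg <- register_stack(time_stack(arr))
  expect_equal(reg$stack$data[, 1, , ], reg$stack$data[, 2, , ])
})

test_that("integer-shift padding bands carry the fill value", {
  base <- matrix(0, 32, 32); base[8:24, 8:24] <- 1
  arr <- array(0, c(2, 1, 32, 32))
  arr[1, 1, , ] <- base
  arr[2, 1, , ] <- translate_image(base, 5, 0)
  reg <- register_stack(time_stack(arr),
                        registration_config(fill_value = 0, subpixel = FALSE))
  expect_equal(round(unname(reg$trace$shifts[2, 1])), 5)
  # removing the shift leaves a 5-row band at the bottom with the fill value
  expect_true(all(reg$stack$data[2, 1, 28:32, ] == 0))
  expect_false(all(reg$stack$data[2, 1, 1:27, ] == 0))
  # and the overlap mask excludes exactly that band
  expect_true(all(!reg$trace$overlap[[2]][28:32, ]))
  expect_true(all(reg$trace$overlap[[2]][1:27, ]))
})

test_that("drift traces survive the CSV round trip", {
  tr <- drift_trace(rbind(c(0, 0), c(1.25, -0.5), c(2.5, -1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$shifts, tr$shifts)
  expect_error(drift_trace(rbind(c(1, 0), c(0, 0))), class = "exsrrf_value_error")
})
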