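test_that("ROI extraction keeps only large bright components", {
  cfg <- nanometrics_config("sd")
  # all-zero image: empty ROI (warning logged)
  expect_warning(roi0 <- extract_roi(matrix(0, 400, 400), cfg), "empty ROI")
  expect_false(any(roi0))
  # full-intensity image: ROI covers the whole frame
  roi1 <- extract_roi(matrix(1, 400, 400), cfg)
  expect_true(all(roi1))
  # one big disk plus one small blob: only the disk survives the 5000-px cut
  yy <- outer(1:600, rep(1, 600)); xx <- t(yy)
  img <- 1 * ((yy - 300)^2 + (xx - 220)^2 < 180^2) +
         1 * ((yy - 100)^2 + (xx - 520)^2 < 30^2)
  roi <- extract_roi(img, cfg)
  expect_true(roi[300, 220])
  expect_false(roi[100, 520])
  # er preset: double smoothing, no closing, same size logic
  roi_er <- extract_roi(img, nanometrics_config("er"))
  expect_true(roi_er[300, 220])
  expect_false(roi_er[100, 520])
})

test_that("ridge segmentation follows midlines and counts lines", {
  # single straight line: one component, centred on the midline
  img <- matrix(0, 96, 96)
  img[, 47:49] <- 1 # 3-px vertical line, midline col 48
  img <- exsrrf:::gaussian_blur(img, 0.9)
  cfg <- nanometrics_config("sd", ridge_sigmas = 1.3, opening_radius = 0L)
  mask <- segment_ridges(img, NULL, cfg)
  expect_true(any(mask))
  cols <- which(mask, arr.ind = TRUE)[, 2]
  expect_lt(max(abs(cols - 48)), 3)
  # parallel lattice: one connected component per line (midlines phased to
  # 8, 24, ..., 88 so no line touches the frame border)
  lat <- make_ridge_lattice(16, 3, 0, shape = c(96, 96), phase = 8,
                            psf_sigma_px = 0.9)
  mask <- segment_ridges(lat$image, NULL, cfg)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  expect_equal(max(lab), 6)
  # blank image yields an empty mask
  expect_false(any(segment_ridges(matrix(0, 64, 64), NULL, cfg)))
})

test_that("ridge response matches the scikit-image reference filter", {
  # independent oracle: the reference implementation of the same published
  # neuriteness filter, run through the system python
  set.seed(3)
  img <- exsrrf:::gaussian_blur(matrix(runif(48 * 48), 48, 48), 2)
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  write.table(img, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- paste(
    "import numpy as np",
    "from skimage.filters import meijering",
    sprintf("x = np.loadtxt('%s', delimiter=',')", fin),
    "r = meijering(x, sigmas=[1, 2], black_ridges=False, mode='mirror')",
    sprintf("np.savetxt('%s', r, delimiter=',')", fout),
    sep = "\n")
  status <- system2("python", "-", input = code, stdout = NULL, stderr = NULL)
  expect_identical(status, 0L)
  ref <- as.matrix(read.table(fout, sep = ","))
  dimnames(ref) <- NULL
  expect_equal(meijering_ridge(img, sigmas = c(1, 2)), ref, tolerance = 1e-10)
})

test_that("ridge density is a masked ratio, blind to ROI-external content", {
  ridge <- matrix(FALSE, 20, 20); ridge[, 1:10] <- TRUE
  roi <- matrix(TRUE, 20, 20)
  expect_equal(ridge_density(ridge, roi), 0.5)
  expect_equal(ridge_density(matrix(FALSE, 20, 20), roi), 0)
  # content outside the ROI is irrelevant
  roi2 <- roi; roi2[, 11:20] <- FALSE
  ridge2 <- ridge; ridge2[, 11:20] <- TRUE
  expect_equal(ridge_density(ridge, roi2), ridge_density(ridge2, roi2))
  expect_warning(d <- ridge_density(ridge, matrix(FALSE, 20, 20)), "empty ROI")
  expect_true(is.na(d))
})

test_that("lattice densities recover width/period and survive rotation", {
  cfg <- nanometrics_config("sd", ridge_sigmas = 1.3, opening_radius = 0L)
  roi <- matrix(TRUE, 192, 192)
  phases <- (0:7 + 0.5) / 8
  lattice_density <- function(period, width, ang) {
    mean(vapply(phases, function(ph) {
      lat <- make_ridge_lattice(period, width, ang, shape = c(192, 192),
                                phase = ph, psf_sigma_px = 0.9)
      ridge_density(segment_ridges(lat$image, roi, cfg), roi)
    }, numeric(1)))
  }
  for (geom in list(c(20, 4), c(12, 3))) {
    d0 <- lattice_density(geom[1], geom[2], 0)
    d37 <- lattice_density(geom[1], geom[2], 37)
    truth <- geom[2] / geom[1]
    expect_lt(abs(d0 - truth) / truth, 0.10)
    expect_lt(abs(d37 - truth) / truth, 0.10)
    expect_lt(abs(d0 - d37) / d0, 0.05)
  }
})

test_that("local spacing equals the exhaustive inscribed-disk oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    ridge <- matrix(runif(48 * 48) < 0.08, 48, 48)
    roi <- matrix(TRUE, 48, 48)
    if (seed %% 2 == 0) roi[1:8, ] <- FALSE
    sp <- local_spacing(ridge, roi)
    expect_identical(sp$spacing_map, oracle_local_spacing(ridge, roi))
  }
  # two parallel ridges 16 px apart: median spacing in the gap equals the gap
  ridge <- matrix(FALSE, 64, 64); ridge[, 20] <- TRUE; ridge[, 37] <- TRUE
  roi <- matrix(TRUE, 64, 64)
  sp <- local_spacing(ridge, roi)
  expect_equal(median(sp$spacing_map[32, 21:36]), 16, tolerance = 1 / 16)
  # empty ridge mask in a disk ROI: spacing at the centre is the diameter
  yy <- outer(1:41, rep(1, 41)); xx <- t(yy)
  disk <- (yy - 21)^2 + (xx - 21)^2 <= 18^2
  sp <- local_spacing(matrix(FALSE, 41, 41), disk)
  expect_equal(sp$spacing_map[21, 21], 2 * 18, tolerance = 0.06)
  # constant spacing maps display as uniform maximum
  expect_true(all(sp$spacing_map_8bit[disk] == 255))
  # non-constant maps span the full display range
  ridge2 <- matrix(FALSE, 64, 64); ridge2[, 20] <- TRUE; ridge2[, 37] <- TRUE
  sp2 <- local_spacing(ridge2, matrix(TRUE, 64, 64))
  free2 <- !ridge2
  expect_equal(min(sp2$spacing_map_8bit[free2]), 0)
  expect_equal(max(sp2$spacing_map_8bit), 255)
})

test_that("adding ridges never increases the median spacing", {
  set.seed(42)
  roi <- matrix(TRUE, 40, 40)
  ridge <- matrix(runif(1600) < 0.03, 40, 40)
  base <- local_spacing(ridge, roi)$spacing_stats[["median"]]
  more <- ridge | matrix(runif(1600) < 0.05, 40, 40)
  expect_lte(local_spacing(more, roi)$spacing_stats[["median"]], base)
})

test_that("isodata threshold is a brute-force intermeans fixed point", {
  set.seed(99)
  for (i in 1:25) {
    n_modes <- sample(1:3, 1)
    v <- unlist(lapply(seq_len(n_modes), function(k)
      rnorm(sample(50:400, 1), runif(1, 20, 230), runif(1, 3, 40))))
    v <- pmin(255, pmax(0, round(v)))
    h <- tabulate(v + 1L, 256L)
    split <- exsrrf:::isodata_split(h)
    expect_true(split %in% oracle_isodata_fixed_points(h))
  }
})

test_that("width profiling measures runs with subpixel edges", {
  # 5-px binary band crossed perpendicularly
  img <- matrix(0, 32, 32); img[, 14:18] <- 1
  m <- measure_sd_width(img, rbind(c(15, 5), c(15, 26)))
  expect_equal(m$width_px, 5, tolerance = 0.02)
  # the same band crossed at 45 degrees is foreshortened by sqrt(2)
  m45 <- measure_sd_width(img, rbind(c(4, 5), c(27, 28)))
  expect_equal(m45$width_px, 5 * sqrt(2), tolerance = 0.15)
  # physical conversion divides by the expansion factor
  img2d <- image2d(img, pixel_size_nm = 65)
  mn <- measure_sd_width(img2d, rbind(c(15, 5), c(15, 26)),
                         expansion_factor = 3.8)
  expect_equal(mn$width_nm, 5 * 65 / 3.8, tolerance = 0.5)
  # no signal on the profile: zero width plus a warning
  expect_warning(m0 <- measure_sd_width(img, rbind(c(2, 1), c(2, 10))),
                 "no above-threshold")
  expect_equal(m0$width_px, 0)
})

test_that("double-line profiles recover the peak gap at biological scale", {
  # two parallel lines 40 nm apart (pre-expansion scale), imaged at 3.8x
  # expansion on a 10x SRRF grid (65 / 10 = 6.5 nm pixels)
  gaps <- vapply(1:10, function(seed) {
    set.seed(seed)
    gap_px <- 40 * 3.8 / 6.5
    img <- matrix(0, 64, 64)
    xx <- matrix(0:63, 64, 64, byrow = TRUE)
    for (s in c(-1, 1))
      img <- img + exp(-(xx - (31.5 + s * gap_px / 2))^2 / (2 * 3^2))
    img <- pmax(img + matrix(rnorm(64 * 64, 0, 0.02), 64), 0)
    m <- measure_sd_width(image2d(img, pixel_size_nm = 6.5),
                          rbind(c(32, 5), c(32, 58)), expansion_factor = 3.8)
    m$peak_distance_nm
  }, numeric(1))
  expect_lt(max(abs(gaps - 40)), 5)
})

test_that("foot-process segmentation separates regions across bright lines", {
  img <- matrix(0, 40, 60)
  img[, 30:31] <- 1 # full-height separator
  labs <- segment_fp(img)
  expect_equal(length(setdiff(unique(as.vector(labs)), 0L)), 2L)
  expect_true(labs[20, 10] != labs[20, 50])
  expect_equal(segment_fp(matrix(0, 16, 16)), matrix(0L, 16, 16))
  # widths of the two halves along the centroid rows
  ids <- setdiff(unique(as.vector(labs)), 0L)
  ws <- vapply(ids, function(i) fp_width(labs, i), numeric(1))
  expect_true(all(ws >= 27 & ws <= 31))
})

test_that("PSF separation calls demand two dominant maxima with a gap", {
  x <- seq(0, 40, by = 0.5)
  two_far <- exp(-(x - 10)^2 / 2) + exp(-(x - 30)^2 / 2)
  expect_true(psf_separation(two_far)$separated)
  expect_false(psf_separation(exp(-(x - 20)^2 / 8))$separated)
  # 2-D: two Gaussians ten sigma apart vs a single blob
  yy <- outer(0:40, rep(1, 41)); xx <- t(yy)
  g <- function(cy, cx) exp(-((yy - cy)^2 + (xx - cx)^2) / 2)
  expect_true(psf_separation(g(20, 10) + g(20, 30))$separated)
  expect_false(psf_separation(g(20, 20))$separated)
  # separability is monotone non-decreasing in distance
  seps <- vapply(seq(0.5, 5, by = 0.5), function(k)
    psf_separation(g(20, 20 - k) + g(20, 20 + k))$separated, logical(1))
  expect_true(all(diff(as.integer(seps)) >= 0))
})

test_that("expansion factors are peak-distance ratios", {
  fake <- function(d_nm) structure(list(peak_distance_nm = d_nm,
                                        peak_distance_px = NA_real_),
                                   class = "ProfileMeasurement")
  expect_equal(expansion_factor(fake(100), fake(380)), 3.8)
  expect_equal(expansion_factor(fake(70), fake(70)), 1)
  expect_error(expansion_factor(fake(0), fake(100)), class = "exsrrf_value_error")
  expect_error(expansion_factor(fake(NA_real_), fake(100)),
               class = "exsrrf_value_error")
})

test_that("normal and effaced phantoms separate in density and spacing", {
  cfg <- nanometrics_config("sd", ridge_sigmas = 1.3, opening_radius = 0L)
  res <- lapply(1:4, function(seed) {
    nrm <- make_interdigitation(12, 2, shape = c(160, 160), seed = seed)
    eff <- make_interdigitation(36, 2, shape = c(160, 160),
                                deletion_fraction = 0.5, seed = seed)
    roi <- matrix(TRUE, 160, 160)
    dn <- ridge_density(segment_ridges(nrm$sd, roi, cfg), roi)
    de <- ridge_density(segment_ridges(eff$sd, roi, cfg), roi)
    sn <- local_spacing(segment_ridges(nrm$sd, roi, cfg), roi)$spacing_stats[["median"]]
    se <- local_spacing(segment_ridges(eff$sd, roi, cfg), roi)$spacing_stats[["median"]]
    c(dn, de, sn, se)
  })
  for (r in res) {
    expect_gt(r[1], r[2]) # density drops with effacement
    expect_lt(r[3], r[4]) # spacing rises with effacement
  }
})
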