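# Stack and image containers + TIFF/PNG I/O.
#
# Canonical in-memory layout is (T, C, Y, X): TIFF pages map to frames unless
# the sidecar metadata (or a layout hint) says otherwise.

#' Time-stack container
#'
#' A `TimeStack` holds a 4-D intensity array in canonical `(T, C, Y, X)`
#' order — frames, channels, rows, columns — together with optional physical
#' pixel size and channel names. This is the unit of acquisition of the
#' pipeline: widefield time stacks of typically 20–200 frames per region.
#'
#' @param data numeric array. 2-D `(Y, X)`, 3-D `(T, Y, X)` or 4-D
#'   `(T, C, Y, X)`; missing leading axes are inserted with length 1.
#' @param pixel_size_nm physical size of one pixel in nanometres, or `NULL`.
#' @param channel_names optional character vector, one per channel.
#' @return an object of class `TimeStack` with elements `data` (always 4-D),
#'   `pixel_size_nm` and `channel_names`.
#' @examples
#' ts <- time_stack(array(runif(2 * 8 * 8), c(2, 8, 8)))
#' frame_count(ts)
#' @export
time_stack <- function(data, pixel_size_nm = NULL, channel_names = NULL) {
  d <- dim(data)
  if (is.null(d) || length(d) < 2L || length(d) > 4L)
    stop_exsrrf("stack data must have 2-4 dimensions", "exsrrf_layout_error")
  if (length(d) == 2L) data <- array(data, c(1L, 1L, d))
  if (length(dim(data)) == 3L) data <- array(data, c(dim(data)[1L], 1L, dim(data)[2:3]))
  if (any(!is.finite(data)))
    stop_exsrrf("stack contains non-finite intensities", "exsrrf_value_error")
  if (any(data < 0)) data[data < 0] <- 0
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(data)[2L]))
  stopifnot(length(channel_names) == dim(data)[2L])
  structure(list(data = data,
                 pixel_size_nm = pixel_size_nm,
                 channel_names = as.character(channel_names)),
            class = "TimeStack")
}

#' @rdname time_stack
#' @param x a `TimeStack`.
#' @export
frame_count <- function(x) dim(x$data)[1L]

#' @export
print.TimeStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("TimeStack: T=%d C=%d %dx%d px", d[1], d[2], d[3], d[4]))
  if (!is.null(x$pixel_size_nm)) cat(sprintf(", %.3g nm/px", x$pixel_size_nm))
  cat("\n")
  invisible(x)
}

#' Single-image container
#'
#' A 2-D intensity image with optional pixel size. An optional `bit_depth`
#' marks data that came from (or should be written as) unsigned integers of
#' that depth; [invert_intensity()] uses it to pick the inversion maximum.
#'
#' @param data numeric matrix `(Y, X)` of finite intensities.
#' @param pixel_size_nm physical pixel size in nanometres, or `NULL`.
#' @param bit_depth integer bit depth (e.g. 8 or 16) or `NULL` for real-valued
#'   data.
#' @return an object of class `Image2D`.
#' @export
image2d <- function(data, pixel_size_nm = NULL, bit_depth = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop_exsrrf("image must have at least one pixel", "exsrrf_value_error")
  if (any(!is.finite(data)))
    stop_exsrrf("image contains non-finite intensities", "exsrrf_value_error")
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 bit_depth = bit_depth),
            class = "Image2D")
}

#' @export
print.Image2D <- function(x, ...) {
  cat(sprintf("Image2D: %dx%d px", nrow(x$data), ncol(x$data)))
  if (!is.null(x$pixel_size_nm)) cat(sprintf(", %.3g nm/px", x$pixel_size_nm))
  cat("\n")
  invisible(x)
}

# coerce an Image2D or bare matrix to a matrix
as_image_matrix <- function(x) {
  if (inherits(x, "Image2D")) x$data else as.matrix(x)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Read an image stack from TIFF
#'
#' Reads a (multi-page) TIFF or OME-style TIFF into a [time_stack()] with
#' axes normalised to `(T, C, Y, X)`. Pages map to frames; if a JSON sidecar
#' written by [write_stack()] is present, its frame/channel counts and pixel
#' size are used to de-interleave channels. A `layout_hint` of `"CYX"` forces
#' pages to be interpreted as channels of a single frame.
#'
#' @param path path to a TIFF file.
#' @param layout_hint `NULL` (pages are frames), `"TYX"`, or `"CYX"`.
#' @return a `TimeStack`.
#' @export
read_stack <- function(path, layout_hint = NULL) {
  if (!file.exists(path))
    stop_exsrrf(sprintf("cannot read stack: no such file '%s'", path),
                "exsrrf_io_error")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop_exsrrf(sprintf("cannot read TIFF '%s': %s",
                                          path, conditionMessage(e)),
                                  "exsrrf_io_error"))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    # 8/16-bit pages hold unsigned integers scaled to [0, 1]; restore them.
    # 32-bit pages are IEEE floats and stay on their stored scale.
    bits <- attr(p, "bits.per.sample")
    if (!is.null(bits) && bits %in% c(8L, 16L)) p <- round(p * (2^bits - 1))
    if (length(dim(p)) == 3L) {
      # page carries samples-per-pixel channels
      return(p)
    }
    as.matrix(p)
  })
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)

  first <- pages[[1L]]
  if (length(dim(first)) > 3L)
    stop_exsrrf("more than 4 dimensions in TIFF page; supply a layout hint",
                "exsrrf_layout_error")

  if (length(dim(first)) == 3L) {
    # each page: (Y, X, S) -> channels from the sample axis
    arr <- array(0, c(length(pages), dim(first)[3L], dim(first)[1:2]))
    for (t in seq_along(pages))
      for (c in seq_len(dim(first)[3L]))
        arr[t, c, , ] <- pages[[t]][, , c]
  } else {
    n <- length(pages)
    tc <- c(n, 1L)
    if (!is.null(meta) && !is.null(meta$frames) && !is.null(meta$channels)) {
      if (meta$frames * meta$channels == n) tc <- c(meta$frames, meta$channels)
    } else if (!is.null(layout_hint)) {
      hint <- toupper(layout_hint)
      if (hint == "CYX") tc <- c(1L, n)
      else if (hint %in% c("TYX", "YX")) tc <- c(n, 1L)
      else stop_exsrrf(sprintf("unrecognised layout hint '%s'", layout_hint),
                       "exsrrf_layout_error")
    }
    arr <- array(0, c(tc[1L], tc[2L], dim(first)))
    p <- 1L
    for (t in seq_len(tc[1L])) # frame-major page order, channels inner
      for (c in seq_len(tc[2L])) {
        arr[t, c, , ] <- pages[[p]]
        p <- p + 1L
      }
  }
  px <- if (!is.null(meta)) meta$pixel_size_nm else NULL
  cn <- if (!is.null(meta) && !is.null(meta$channel_names)) meta$channel_names else NULL
  if (!is.null(meta) && !is.null(meta$value_range)) {
    vr <- as.numeric(meta$value_range)
    arr <- arr * max(vr[2L] - vr[1L], .Machine$double.eps) + vr[1L]
  }
  time_stack(arr, pixel_size_nm = px, channel_names = cn)
}

#' Write an image stack to TIFF
#'
#' Pages are written frame-major (`t1c1, t1c2, t2c1, ...`). Non-negative
#' integer-valued data are stored as 16-bit unsigned (lossless round trip
#' with [read_stack()] for values up to 65535); other data as 32-bit float.
#' Pixel size, axis counts and channel names go to a JSON sidecar
#' `<path>.meta.json`.
#'
#' @param stack a `TimeStack`.
#' @param path destination TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "TimeStack"))
  d <- dim(stack$data)
  integerish <- all(stack$data >= 0) && all(stack$data == round(stack$data)) &&
    max(stack$data) <= 65535
  # float data are stored on a [0, 1] scale (32-bit float pages); the
  # original range goes to the sidecar and is restored on read
  value_range <- NULL
  denom <- 1
  offset <- 0
  if (!integerish) {
    value_range <- range(stack$data)
    offset <- value_range[1L]
    denom <- max(value_range[2L] - value_range[1L], .Machine$double.eps)
  }
  pages <- vector("list", d[1L] * d[2L])
  p <- 1L
  for (t in seq_len(d[1L]))
    for (c in seq_len(d[2L])) {
      m <- stack$data[t, c, , ]
      pages[[p]] <- if (integerish) m / 65535 else (m - offset) / denom
      p <- p + 1L
    }
  ok <- tryCatch({
    tiff::writeTIFF(pages, path,
                    bits.per.sample = if (integerish) 16L else 32L,
                    compression = "none")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_exsrrf(sprintf("cannot write TIFF '%s': %s", path,
                        conditionMessage(ok)), "exsrrf_io_error")
  meta <- list(frames = d[1L], channels = d[2L],
               pixel_size_nm = stack$pixel_size_nm,
               channel_names = stack$channel_names,
               value_range = value_range,
               layout = "TCYX")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a single 2-D image (TIFF or PNG)
#'
#' @param path image path; format chosen by extension.
#' @return an `Image2D`; multi-channel files are averaged to one channel.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop_exsrrf(sprintf("cannot read image: no such file '%s'", path),
                "exsrrf_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
  } else {
    m <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(m, "bits.per.sample")
    if (!is.null(bits) && bits %in% c(8L, 16L)) m <- round(m * (2^bits - 1))
  }
  if (length(dim(m)) == 3L) m <- apply(m, c(1, 2), mean)
  px <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    px <- meta$pixel_size_nm
  }
  image2d(as.matrix(m), pixel_size_nm = px)
}

#' Invert image intensities
#'
#' Mirrors the ImageJ "Invert" operation used on NHS-ester channels before
#' SRRF: for unsigned-integer data of bit depth `b` the output is
#' `(2^b - 1) - x` (an involution); for real-valued data the per-image
#' maximum is used in place of the type maximum, which is reproducible but
#' only an involution when the minimum is 0.
#'
#' @param image an `Image2D` (set `bit_depth` for integer semantics) or a
#'   bare matrix.
#' @return an `Image2D` of the same shape; `bit_depth` is preserved.
#' @examples
#' img <- image2d(matrix(c(0, 100, 255, 40), 2), bit_depth = 8)
#' invert_intensity(img)$data
#' @export
invert_intensity <- function(image) {
  img <- if (inherits(image, "Image2D")) image else image2d(as.matrix(image))
  m <- if (!is.null(img$bit_depth)) 2^img$bit_depth - 1 else max(img$data)
  image2d(m - img$data, pixel_size_nm = img$pixel_size_nm,
          bit_depth = img$bit_depth)
}
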