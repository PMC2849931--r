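#' Fluorescence image time-series container
#'
#' An `image_stack` holds a single-channel fluorescence recording as a 3D
#' array indexed `[y, x, t]` (row, column, frame) together with its physical
#' scaling. Intensities are stored as doubles in arbitrary units.
#'
#' @param data 3D numeric array `[y, x, t]`. A matrix is promoted to a
#'   single-frame stack.
#' @param pixel_size_xy Pixel side length in micrometres (> 0).
#' @param frame_interval Time between consecutive frames in seconds (> 0).
#' @param notes Character vector of free-text acquisition metadata (e.g. a
#'   verbatim acquisition-software TIFF header). Stored, never parsed.
#' @return An object of class `image_stack` with fields `data`,
#'   `pixel_size_xy`, `frame_interval`, `notes` and `stage`
#'   (`"raw"` until background correction).
#' @seealso [load_stack()], [average_image()], [sd_image()]
#' @export
image_stack <- function(data, pixel_size_xy = 1, frame_interval = 1,
                        notes = character()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array [y, x, t] (or a matrix)")
  if (any(dim(data) < 1L)) stopf("all stack dimensions must be >= 1")
  if (!all(is.finite(data))) stopf("stack intensities must be finite")
  if (!is_scalar_num(pixel_size_xy) || pixel_size_xy <= 0)
    stopf("`pixel_size_xy` must be a positive number (um/pixel)")
  if (!is_scalar_num(frame_interval) || frame_interval <= 0)
    stopf("`frame_interval` must be a positive number (s/frame)")
  structure(list(data = data * 1.0,
                 pixel_size_xy = pixel_size_xy,
                 frame_interval = frame_interval,
                 notes = as.character(notes),
                 stage = "raw"),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d frame(s), %.3g um/px, %.3g s/frame, stage: %s\n",
              d[2], d[1], d[3], x$pixel_size_xy, x$frame_interval, x$stage))
  if (length(x$notes)) cat(sprintf("  notes: %d line(s) of acquisition metadata\n",
                                   length(x$notes)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3]

#' Single 2D image derived from a recording
#'
#' @param data Numeric matrix `[y, x]` of finite intensities.
#' @param pixel_size_xy Pixel side length in micrometres.
#' @return An object of class `fov_image`.
#' @export
fov_image <- function(data, pixel_size_xy = 1) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("`data` must be a numeric matrix")
  if (!all(is.finite(data))) stopf("image intensities must be finite")
  structure(list(data = data * 1.0, pixel_size_xy = pixel_size_xy),
            class = "fov_image")
}

#' @export
print.fov_image <- function(x, ...) {
  cat(sprintf("<fov_image> %d x %d px, %.3g um/px, range [%.4g, %.4g]\n",
              ncol(x$data), nrow(x$data), x$pixel_size_xy,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
plot.fov_image <- function(x, main = "", ...) {
  graphics::image(t(x$data)[, nrow(x$data):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(x$data) / ncol(x$data),
                  main = main, ...)
  invisible(x)
}

# Accept a fov_image or a bare matrix wherever a 2D image is expected.
image_data <- function(image) {
  if (inherits(image, "fov_image")) image$data
  else if (is.matrix(image) && is.numeric(image)) image
  else stopf("expected a `fov_image` or a numeric matrix")
}

#' Load a single- or multi-frame TIFF recording
#'
#' Frames are read in file order through [tiff::readTIFF()]. Integer TIFFs
#' are read with their stored sample values (no 0-1 rescaling); any
#' `ImageDescription` header text (as written by acquisition software) is
#' preserved verbatim in `notes` but never parsed -- physical scaling always
#' comes from the arguments.
#'
#' @param path Path to a readable grayscale TIFF.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
load_stack <- function(path, pixel_size_xy = 1, frame_interval = 1) {
  if (!file.exists(path)) stopf("cannot read TIFF: '%s' does not exist", path)
  frames <- tryCatch(
    # as.is keeps integer sample values unscaled; unsupported for float TIFFs
    suppressWarnings(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)),
    error = function(e) tryCatch(
      suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE)),
      error = function(e2) stopf("failed to read '%s': %s",
                                 path, conditionMessage(e2))))
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) {
      if (dim(f)[3] != 1L)
        stopf("'%s' is multi-channel; only single-channel stacks are supported", path)
      f <- f[, , 1]
    }
    f
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("'%s' contains frames of unequal size", path)
  notes <- unlist(lapply(frames, function(f) attr(f, "description")))
  data <- array(unlist(frames, use.names = FALSE),
                c(dims[1, 1], dims[2, 1], length(frames)))
  image_stack(data, pixel_size_xy, frame_interval,
              notes = unique(as.character(notes %||% character())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write images or a stack as 32-bit float TIFF
#'
#' Writes single-strip uncompressed grayscale TIFF with IEEE 32-bit float
#' samples, so intensities of any magnitude round-trip through
#' [load_stack()] to within single precision (exactly, for integer-valued
#' data below 2^24). The installed TIFF writers only store values in
#' `[0, 1]`, hence this dedicated writer.
#'
#' @param x An [image_stack()], [fov_image()], matrix, or 3D array.
#' @param path Output path.
#' @param description Optional text stored in the first frame's
#'   `ImageDescription` tag (round-trips into `notes`).
#' @return `path`, invisibly.
#' @export
save_stack <- function(x, path, description = NULL) {
  if (inherits(x, "image_stack")) {
    if (is.null(description) && length(x$notes))
      description <- paste(x$notes, collapse = "\n")
    x <- x$data
  }
  if (inherits(x, "fov_image")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L, all(is.finite(x)))
  write_float_tiff(x, path, description)
  invisible(path)
}

# Minimal little-endian uncompressed 32-bit-float grayscale TIFF writer.
write_float_tiff <- function(arr, path, description = NULL) {
  nr <- dim(arr)[1]; nc <- dim(arr)[2]; nt <- dim(arr)[3]
  desc <- NULL; desc_count <- 0L
  if (!is.null(description) && nzchar(description)) {
    desc <- c(charToRaw(paste(description, collapse = "\n")), as.raw(0))
    desc_count <- length(desc)                  # count includes the NUL
    if (length(desc) %% 2L) desc <- c(desc, as.raw(0))  # word-align padding
  }
  frame_bytes <- nr * nc * 4L
  data_off <- 8L + frame_bytes * (seq_len(nt) - 1L)
  ifd_start <- 8L + frame_bytes * nt
  n_entries <- function(i) if (i == 1L && !is.null(desc)) 11L else 10L
  ifd_size <- function(i) 2L + 12L * n_entries(i) + 4L
  ifd_off <- integer(nt); cur <- ifd_start
  for (i in seq_len(nt)) {
    ifd_off[i] <- cur
    cur <- cur + ifd_size(i) + if (i == 1L && !is.null(desc)) length(desc) else 0L
  }
  con <- file(path, "wb"); on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {  # type 2=ASCII 3=SHORT 4=LONG
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  writeBin(charToRaw("II"), con); w2(42L); w4(ifd_off[1])
  for (i in seq_len(nt))
    writeBin(as.numeric(t(arr[, , i])), con, size = 4, endian = "little")
  for (i in seq_len(nt)) {
    has_desc <- i == 1L && !is.null(desc)
    w2(n_entries(i))
    entry(256L, 4L, 1L, nc)                 # ImageWidth
    entry(257L, 4L, 1L, nr)                 # ImageLength
    entry(258L, 3L, 1L, 32L)                # BitsPerSample
    entry(259L, 3L, 1L, 1L)                 # Compression: none
    entry(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    if (has_desc)
      entry(270L, 2L, desc_count, ifd_off[i] + ifd_size(i))
    entry(273L, 4L, 1L, data_off[i])        # StripOffsets
    entry(277L, 3L, 1L, 1L)                 # SamplesPerPixel
    entry(278L, 4L, 1L, nr)                 # RowsPerStrip
    entry(279L, 4L, 1L, frame_bytes)        # StripByteCounts
    entry(339L, 3L, 1L, 3L)                 # SampleFormat: IEEE float
    w4(if (i < nt) ifd_off[i + 1] else 0L)
    if (has_desc) writeBin(desc, con)
  }
  invisible(path)
}

#' Register a time series by rigid translation
#'
#' Each frame is aligned to a reference frame by cross-correlation
#' (computed via FFT); the estimated per-frame displacement is removed and
#' pixels shifted in from outside the field of view are filled with the
#' frame median, which is neutral for later averaging. Motion correction
#' here is deliberately simple preprocessing: the `engine` argument accepts
#' any replacement of the form `function(frame, reference)` returning
#' `c(dx, dy)` so that other registration schemes can be plugged in.
#'
#' @param stack An [image_stack()].
#' @param reference Index of the reference frame.
#' @param subpixel If `TRUE`, refine the correlation peak by parabolic
#'   interpolation and shift frames with bilinear interpolation; the default
#'   recovers integer displacements exactly.
#' @param engine Shift estimator; the default is FFT cross-correlation.
#' @return The registered [image_stack()], with the per-frame displacements
#'   attached as attribute `"shifts"` (data frame with columns
#'   `frame`, `dx`, `dy`), retrievable via [registration_shifts()].
#' @export
register_stack <- function(stack, reference = 1L, subpixel = FALSE,
                           engine = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  nt <- n_frames(stack)
  if (reference < 1 || reference > nt)
    stopf("`reference` must be a frame index in 1..%d", nt)
  ref <- stack$data[, , reference]
  est <- engine %||% function(frame, reference)
    xcorr_shift(frame, reference, subpixel = subpixel)
  if (stats::sd(ref) == 0) {
    warnf("reference frame is featureless (constant); shifts will be (0, 0)")
    est <- function(frame, reference) c(0, 0)
  }
  out <- stack
  shifts <- matrix(0, nt, 2)
  for (t in seq_len(nt)) {
    fr <- stack$data[, , t]
    s <- if (t == reference) c(0, 0) else est(fr, ref)
    shifts[t, ] <- s
    if (any(s != 0)) {
      fill <- stats::median(fr)
      out$data[, , t] <- if (subpixel)
        translate_matrix_subpix(fr, -s[1], -s[2], fill)
      else translate_matrix(fr, -as.integer(round(s[1])),
                            -as.integer(round(s[2])), fill)
    }
  }
  attr(out, "shifts") <- data.frame(frame = seq_len(nt),
                                    dx = shifts[, 1], dy = shifts[, 2])
  out
}

#' @rdname register_stack
#' @export
registration_shifts <- function(stack) attr(stack, "shifts")

# Displacement (dx, dy) of `frame` relative to `ref`: positive dx means the
# frame content sits `dx` pixels to the right of where it is in `ref`.
xcorr_shift <- function(frame, ref, subpixel = FALSE) {
  f <- frame - mean(frame); g <- ref - mean(ref)
  if (all(f == 0) || all(g == 0)) {
    warnf("featureless frame: no signal to register, shift set to (0, 0)")
    return(c(0, 0))
  }
  nr <- nrow(frame); nc <- ncol(frame)
  cc <- Re(stats::fft(stats::fft(f) * Conj(stats::fft(g)), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) { d <- i - 1L; if (d > n / 2) d - n else d }
  dy <- wrap(pk[1], nr); dx <- wrap(pk[2], nc)
  if (subpixel) {
    iy <- (dy %% nr) + 1L; ix <- (dx %% nc) + 1L
    parab <- function(ym, y0, yp) {
      den <- ym - 2 * y0 + yp
      if (den == 0) 0 else 0.5 * (ym - yp) / den
    }
    dy <- dy + parab(cc[((dy - 1) %% nr) + 1L, ix], cc[iy, ix],
                     cc[((dy + 1) %% nr) + 1L, ix])
    dx <- dx + parab(cc[iy, ((dx - 1) %% nc) + 1L], cc[iy, ix],
                     cc[iy, ((dx + 1) %% nc) + 1L])
  }
  c(dx, dy)
}

#' Temporal-average source image
#'
#' Pixel-wise mean over the selected frames; averaging over a period of the
#' recording reduces noise and reveals all labelled structures, which makes
#' it the usual source image for ROI detection.
#'
#' @param stack An [image_stack()].
#' @param frames Frame indices to average (default: all).
#' @return A [fov_image()].
#' @export
average_image <- function(stack, frames = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- frames %||% seq_len(n_frames(stack))
  if (length(frames) == 0) stopf("`frames` must be a non-empty index range")
  if (any(frames < 1 | frames > n_frames(stack)))
    stopf("`frames` out of bounds (stack has %d frames)", n_frames(stack))
  m <- apply(stack$data[, , frames, drop = FALSE], c(1, 2), mean)
  fov_image(m, stack$pixel_size_xy)
}

#' Temporal standard-deviation source image
#'
#' Per-pixel standard deviation over time; highlights pixels whose
#' fluorescence fluctuates (active structures).
#'
#' @param stack An [image_stack()] with at least 2 frames.
#' @return A [fov_image()].
#' @export
sd_image <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (n_frames(stack) < 2) stopf("sd_image() needs at least 2 frames")
  m <- apply(stack$data, c(1, 2), stats::sd)
  fov_image(m, stack$pixel_size_xy)
}

#' Stimulus-response source image
#'
#' Mean over stimulus frames minus mean over rest frames, pixel-wise. The
#' result is signed: structures that brighten during the stimulus are
#' positive, structures that dim (OFF units) are negative.
#'
#' @param stack An [image_stack()].
#' @param rest_frames,stim_frames Disjoint, non-empty frame index sets.
#' @return A [fov_image()].
#' @export
response_image <- function(stack, rest_frames, stim_frames) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(rest_frames) == 0 || length(stim_frames) == 0)
    stopf("rest and stimulus frame sets must be non-empty")
  if (length(intersect(rest_frames, stim_frames)))
    stopf("rest and stimulus frame sets must be disjoint")
  nt <- n_frames(stack)
  if (any(c(rest_frames, stim_frames) < 1 | c(rest_frames, stim_frames) > nt))
    stopf("frame indices out of bounds (stack has %d frames)", nt)
  fov_image(average_image(stack, stim_frames)$data -
              average_image(stack, rest_frames)$data,
            stack$pixel_size_xy)
}
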