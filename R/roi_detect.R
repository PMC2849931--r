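#' Detection parameters for Laplacian ROI segmentation
#'
#' @param k Threshold expressed as a (negative) multiple of the standard
#'   deviation of the Laplacian image. Bright peaks in the source have
#'   negative Laplacian values, so `k` must be `< 0`; values below -10 are
#'   clamped to -10. The default -2.2 works well for fields of synaptic
#'   terminals; useful values typically range from -1.5 to -4.
#' @param min_size Minimum ROI area in pixels; smaller connected components
#'   are rejected (a size filter that also suppresses noise specks).
#' @param connectivity Pixel connectivity for component labelling, `4` or
#'   `8` (default 8: diagonal-touching pixels of one terminal belong
#'   together).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(k = -2.2, min_size = 4L, connectivity = 8L) {
  if (!is_scalar_num(k) || k >= 0)
    stopf("`k` must be a negative SD multiple (got %s)", format(k))
  if (k < -10) {
    warnf("k = %.3g clamped to -10", k)
    k <- -10
  }
  if (!is_scalar_num(min_size) || min_size < 0)
    stopf("`min_size` must be >= 0 pixels")
  if (!connectivity %in% c(4L, 8L)) stopf("`connectivity` must be 4 or 8")
  structure(list(k = k, min_size = as.integer(min_size),
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}

#' Discrete Laplace operator of an image
#'
#' The Laplacian, the sum of the unmixed second spatial derivatives, is
#' computed with the 4-neighbour finite-difference kernel (centre -4,
#' N/S/E/W +1) or, optionally, the 8-neighbour variant (centre -8, all
#' neighbours +1). Edges are handled by replicate padding so that no
#' spurious border responses arise. Because the Laplacian responds to
#' relative rather than absolute brightness, local peaks of very different
#' intensity produce comparable (negative) responses, which is what makes
#' threshold-based detection robust to a wide brightness range.
#'
#' @param image A [fov_image()] or numeric matrix, at least 3x3.
#' @param neighbours 4 (default) or 8.
#' @return An object of class `laplacian_image`: list with `data` (matrix,
#'   same shape as the source) and `sd`, the standard deviation of all its
#'   pixel values (used for thresholding).
#' @export
laplacian <- function(image, neighbours = 4L) {
  m <- image_data(image)
  if (nrow(m) < 3 || ncol(m) < 3) stopf("image must be at least 3x3")
  if (!neighbours %in% c(4L, 8L)) stopf("`neighbours` must be 4 or 8")
  p <- pad_replicate(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  ys <- 2:(nr + 1); xs <- 2:(nc + 1)
  lap <- p[ys - 1, xs] + p[ys + 1, xs] + p[ys, xs - 1] + p[ys, xs + 1] - 4 * m
  if (neighbours == 8L)
    lap <- lap + p[ys - 1, xs - 1] + p[ys - 1, xs + 1] +
      p[ys + 1, xs - 1] + p[ys + 1, xs + 1] - 4 * m
  # SD over ALL pixels of the Laplacian image, including zeros
  n <- length(lap)
  s <- sqrt(sum((lap - mean(lap))^2) / (n - 1))
  structure(list(data = lap, sd = s), class = "laplacian_image")
}

#' @export
print.laplacian_image <- function(x, ...) {
  cat(sprintf("<laplacian_image> %d x %d px, sd = %.4g\n",
              ncol(x$data), nrow(x$data), x$sd))
  invisible(x)
}

#' Threshold a Laplacian image
#'
#' A pixel is included iff its Laplacian value is `<= k * sd`, where `sd`
#' is the standard deviation of all pixels of the Laplacian image and `k`
#' is negative: bright peaks in the source image have negative Laplacian.
#'
#' @param lap A [laplacian()] result.
#' @param k Negative SD multiple.
#' @return Logical matrix (`TRUE` = included), with the absolute threshold
#'   attached as attribute `"threshold"`.
#' @export
threshold_laplacian <- function(lap, k = -2.2) {
  stopifnot(inherits(lap, "laplacian_image"))
  if (!is_scalar_num(k) || k >= 0) stopf("`k` must be < 0")
  thr <- k * lap$sd
  # degenerate flat image: sd = 0 leaves nothing below the threshold
  inc <- if (lap$sd == 0) matrix(FALSE, nrow(lap$data), ncol(lap$data))
  else lap$data <= thr
  structure(inc, threshold = thr)
}

#' Label connected components into a signed ROI mask
#'
#' Connected components of the included pixel set are found at the
#' requested connectivity; components smaller than `min_size` pixels are
#' dropped and the survivors are numbered 1..n in raster order (row-major)
#' of their first pixel. The result uses the signed mask encoding:
#' background pixels carry the value 1 and pixels of ROI n the value -n.
#'
#' @param binary Logical matrix of included pixels.
#' @param min_size Minimum component area in pixels.
#' @param connectivity 4 or 8.
#' @return An object of class `roi_mask`: list with `labels` (integer
#'   matrix), `n_rois` and `roi_areas`.
#' @export
segment_rois <- function(binary, min_size = 0L, connectivity = 8L) {
  if (!is.matrix(binary) || !is.logical(binary))
    stopf("`binary` must be a logical matrix")
  if (!connectivity %in% c(4L, 8L)) stopf("`connectivity` must be 4 or 8")
  nr <- nrow(binary); nc <- ncol(binary)
  ids <- which(binary)
  labels <- matrix(1L, nr, nc)
  if (length(ids) == 0)
    return(structure(list(labels = labels, n_rois = 0L, roi_areas = integer()),
                     class = "roi_mask"))
  id <- matrix(0L, nr, nc)
  id[ids] <- seq_along(ids)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  el <- list()
  for (off in offs) {
    dy <- off[1]; dx <- off[2]
    ys <- seq_len(nr - dy)
    xs <- if (dx >= 0) seq_len(nc - dx) else seq(1L - dx, nc)
    a <- binary[ys, xs, drop = FALSE]
    b <- binary[ys + dy, xs + dx, drop = FALSE]
    hit <- a & b
    if (any(hit))
      el[[length(el) + 1]] <- cbind(id[ys, xs, drop = FALSE][hit],
                                    id[ys + dy, xs + dx, drop = FALSE][hit])
  }
  membership <- if (length(el)) {
    g <- igraph::make_graph(edges = as.vector(t(do.call(rbind, el))),
                            n = length(ids), directed = FALSE)
    igraph::components(g)$membership
  } else seq_along(ids)
  # raster (row-major) key of each included pixel
  rows <- ((ids - 1L) %% nr) + 1L
  cols <- ((ids - 1L) %/% nr) + 1L
  raster_key <- (rows - 1L) * nc + cols
  sizes <- tabulate(membership)
  keep <- which(sizes >= max(min_size, 1L))
  if (length(keep) == 0)
    return(structure(list(labels = labels, n_rois = 0L, roi_areas = integer()),
                     class = "roi_mask"))
  first_key <- vapply(keep, function(cmp) min(raster_key[membership == cmp]),
                      numeric(1))
  keep <- keep[order(first_key)]
  new_id <- integer(max(membership))
  new_id[keep] <- seq_along(keep)
  roi_of_pixel <- new_id[membership]
  sel <- roi_of_pixel > 0L
  labels[ids[sel]] <- -roi_of_pixel[sel]
  structure(list(labels = labels, n_rois = length(keep),
                 roi_areas = as.integer(sizes[keep])),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d ROI(s)",
              ncol(x$labels), nrow(x$labels), x$n_rois))
  if (x$n_rois)
    cat(sprintf(", areas %d-%d px", min(x$roi_areas), max(x$roi_areas)))
  cat("\n")
  invisible(x)
}

#' @export
plot.roi_mask <- function(x, ...) {
  cols <- c("black", grDevices::hcl.colors(max(x$n_rois, 1L), "Set 3"))
  idx <- ifelse(x$labels == 1L, 0L, -x$labels) + 1L
  graphics::image(t(matrix(idx, nrow(x$labels)))[, nrow(x$labels):1,
                                                 drop = FALSE],
                  col = cols[sort(unique(as.vector(idx)))], axes = FALSE,
                  asp = nrow(x$labels) / ncol(x$labels), ...)
  invisible(x)
}

# Pixel indices (linear) of ROI n.
roi_pixels <- function(mask, roi_id) which(mask$labels == -as.integer(roi_id))

#' Detect ROIs in a source image via the Laplace operator
#'
#' End-to-end detection: Laplacian transform, SD-multiple thresholding and
#' connected-component labelling with a minimum-size filter. The absolute
#' threshold actually used is attached to the result (attribute
#' `"threshold"`) so it can be inspected and adjusted interactively.
#'
#' @param source Source [fov_image()] or matrix (typically a temporal
#'   average; an SD image or a stimulus-response image may be used to bias
#'   detection toward active or responsive structures).
#' @param params A [detection_params()] object.
#' @param neighbours Laplacian kernel, 4 (default) or 8 neighbours.
#' @return An `roi_mask` with attributes `"threshold"` (absolute Laplacian
#'   threshold) and `"k"`.
#' @export
detect_rois <- function(source, params = detection_params(), neighbours = 4L) {
  stopifnot(inherits(params, "detection_params"))
  lap <- laplacian(source, neighbours)
  binary <- threshold_laplacian(lap, params$k)
  mask <- segment_rois(binary, params$min_size, params$connectivity)
  attr(mask, "threshold") <- attr(binary, "threshold")
  attr(mask, "k") <- params$k
  mask
}

#' Detect ROIs in a high-resolution image via blur-and-downsample
#'
#' Structures with flat-topped (plateau) cross-sections defeat direct
#' Laplacian detection at high magnification: only their edges respond.
#' This path first smooths the image with a Gaussian filter, detects on a
#' block-averaged lower-resolution version, and then resamples the label
#' mask back to the original resolution by pixel replication -- labels are
#' never interpolated, so the up-sampled mask contains only values present
#' in the low-resolution mask.
#'
#' @inheritParams detect_rois
#' @param sigma Gaussian pre-filter width in pixels (> 0).
#' @param factor Integer downsampling factor (>= 2).
#' @return An `roi_mask` at the original resolution.
#' @export
detect_rois_highres <- function(source, sigma, factor,
                                params = detection_params(),
                                neighbours = 4L) {
  m <- image_data(source)
  if (!is_scalar_num(sigma) || sigma <= 0) stopf("`sigma` must be > 0")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L)
    stopf("`factor` must be an integer >= 2; use detect_rois() otherwise")
  low <- block_downsample(gaussian_blur(m, sigma), factor)
  mask_low <- detect_rois(low, params, neighbours)
  up <- kronecker(mask_low$labels, matrix(1L, factor, factor))
  labels <- matrix(1L, nrow(m), ncol(m))
  labels[seq_len(nrow(up)), seq_len(ncol(up))] <- up
  out <- structure(list(labels = labels, n_rois = mask_low$n_rois,
                        roi_areas = as.integer(tabulate(-labels[labels < 0],
                                                        mask_low$n_rois))),
                   class = "roi_mask")
  attr(out, "threshold") <- attr(mask_low, "threshold")
  attr(out, "k") <- params$k
  out
}

#' Export / import an ROI mask
#'
#' The mask is written as a 32-bit float TIFF of the signed label values
#' (background 1, ROI n = -n) plus a sidecar CSV with one row per ROI
#' (`roi_id`, `area_px`, `first_pixel_x`, `first_pixel_y`). A saved mask is
#' reusable with any stack of matching width and height.
#'
#' @param mask An `roi_mask`.
#' @param tif_path,csv_path Output paths (CSV optional on read).
#' @return `write_roi_mask()`: paths, invisibly. `read_roi_mask()`: the
#'   reconstructed `roi_mask`.
#' @export
write_roi_mask <- function(mask, tif_path, csv_path = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  write_float_tiff(array(mask$labels * 1.0, c(dim(mask$labels), 1L)), tif_path)
  if (!is.null(csv_path)) {
    nr <- nrow(mask$labels)
    info <- lapply(seq_len(mask$n_rois), function(n) {
      px <- roi_pixels(mask, n)
      rows <- ((px - 1L) %% nr) + 1L
      cols <- ((px - 1L) %/% nr) + 1L
      first <- order((rows - 1L) * ncol(mask$labels) + cols)[1]
      data.frame(roi_id = n, area_px = length(px),
                 first_pixel_x = cols[first], first_pixel_y = rows[first])
    })
    utils::write.csv(do.call(rbind, info) %||%
                       data.frame(roi_id = integer(), area_px = integer(),
                                  first_pixel_x = integer(),
                                  first_pixel_y = integer()),
                     csv_path, row.names = FALSE)
  }
  invisible(c(tif_path, csv_path))
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(tif_path) {
  m <- tiff::readTIFF(tif_path, all = TRUE)[[1]]
  labels <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  vals <- unique(as.vector(labels))
  bad <- setdiff(vals, c(1L, -seq_len(max(0L, -min(labels)))))
  if (length(bad)) stopf("'%s' is not a valid ROI mask", tif_path)
  n <- max(0L, -min(labels))
  structure(list(labels = labels, n_rois = n,
                 roi_areas = as.integer(tabulate(-labels[labels < 0], n))),
            class = "roi_mask")
}
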