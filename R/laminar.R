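#' Open polyline contour
#'
#' Layer borders (e.g. the two margins of the retinal inner plexiform
#' layer) are represented as open polylines of `(x, y)` pixel coordinates,
#' typically drawn by the user and stored as CSV point lists.
#'
#' @param x,y Numeric coordinate vectors (or `x` a two-column
#'   matrix/data frame).
#' @return A data frame with columns `x`, `y` and class `contour`.
#' @export
contour_points <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.data.frame(x)
    if (ncol(m) < 2) stopf("need x and y coordinates")
    x <- as.numeric(m[[1]]); y <- as.numeric(m[[2]])
  }
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("a contour needs at least 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("contour coordinates must be finite")
  dup <- which(diff(x) == 0 & diff(y) == 0)
  if (length(dup)) { x <- x[-(dup + 1)]; y <- y[-(dup + 1)] }
  if (length(x) < 2) stopf("contour is degenerate (all points coincide)")
  structure(data.frame(x = x, y = y), class = c("contour", "data.frame"))
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d points, length %.4g px\n", nrow(x),
              sum(sqrt(diff(x$x)^2 + diff(x$y)^2))))
  invisible(x)
}

#' Read / write contour CSV point lists
#' @param path CSV file with columns `x`, `y` (one file per border).
#' @param contour A [contour_points()] object.
#' @return `read_contour_csv()`: a contour; `write_contour_csv()`: `path`.
#' @export
read_contour_csv <- function(path) contour_points(utils::read.csv(path))

#' @rdname read_contour_csv
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(as.data.frame(unclass(contour))[c("x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

arc_lengths <- function(ct) c(0, cumsum(sqrt(diff(ct$x)^2 + diff(ct$y)^2)))

#' Resample a contour to m points uniform in arc length
#'
#' Point-wise correspondence between two borders (needed for isocontour
#' interpolation) requires both to carry the same number of points; m is
#' typically 8 times the image width in pixels, making vertex spacing much
#' finer than one pixel. Endpoints are preserved.
#'
#' @param contour A [contour_points()] polyline.
#' @param m Number of output points (>= 2).
#' @return A resampled contour.
#' @export
resample_contour <- function(contour, m) {
  stopifnot(inherits(contour, "contour"))
  if (!is_scalar_num(m) || m < 2) stopf("`m` must be >= 2")
  s <- arc_lengths(contour)
  L <- s[length(s)]
  if (L == 0) stopf("contour has zero length")
  target <- seq(0, L, length.out = as.integer(m))
  contour_points(stats::approx(s, contour$x, xout = target)$y,
                 stats::approx(s, contour$y, xout = target)$y)
}

#' Smooth a contour by locally weighted regression
#'
#' Each coordinate is smoothed as a function of arc length with Cleveland's
#' LOWESS (locally weighted linear fits, no robustness iterations). Hand-
#' drawn borders carry pixel-scale jitter which would otherwise imprint on
#' every interpolated isocontour. Straight lines are invariant; a span
#' covering fewer than 3 points returns the input with a warning.
#'
#' @param contour A [contour_points()] polyline.
#' @param span Smoother span as a fraction of the contour's points (0, 1].
#' @return A smoothed contour of the same length.
#' @export
smooth_contour <- function(contour, span = 0.1) {
  stopifnot(inherits(contour, "contour"))
  if (!is_scalar_num(span) || span <= 0 || span > 1)
    stopf("`span` must be in (0, 1]")
  n <- nrow(contour)
  if (floor(span * n) < 3) {
    warnf("span %.3g covers fewer than 3 of %d points; contour returned unsmoothed",
          span, n)
    return(contour)
  }
  s <- arc_lengths(contour)
  contour_points(stats::lowess(s, contour$x, f = span, iter = 0)$y,
                 stats::lowess(s, contour$y, f = span, iter = 0)$y)
}

#' Orient two border contours consistently
#'
#' Point-wise interpolation between borders presumes index-wise
#' correspondence; if the two polylines were drawn in opposite directions,
#' corresponding indices would cross. The second contour is reversed iff
#' that reduces the summed distance between endpoint pairs.
#'
#' @param c0,c100 Border contours resampled to equal point counts
#'   (`c0` = 0% side, e.g. facing the ganglion cells; `c100` = 100% side,
#'   e.g. facing the photoreceptors).
#' @return List with elements `c0`, `c100` (possibly reversed) and
#'   `reversed` (logical).
#' @export
orient_contours <- function(c0, c100) {
  stopifnot(inherits(c0, "contour"), inherits(c100, "contour"))
  if (nrow(c0) != nrow(c100))
    stopf("contours must be resampled to the same number of points")
  n <- nrow(c0)
  d <- function(i, j) sqrt((c0$x[i] - c100$x[j])^2 + (c0$y[i] - c100$y[j])^2)
  keep <- d(1, 1) + d(n, n)
  flip <- d(1, n) + d(n, 1)
  reversed <- flip < keep
  if (reversed)
    c100 <- contour_points(rev(c100$x), rev(c100$y))
  list(c0 = c0, c100 = c100, reversed = reversed)
}

#' Family of isocontours between two layer borders
#'
#' For each relative depth i the isocontour is interpolated point-wise
#' between the 0% border `C0` and the 100% border `C100`:
#' `Ci[j] = (i * C100[j] + (100 - i) * C0[j]) / 100`. The 99 isocontours
#' at i = 1..99 lie strictly between the borders; two more at i = -1 and
#' i = 101 are extrapolated by the same formula so that units just outside
#' the layer are still binned into the nearest marginal group. The family
#' therefore holds 103 ordered polylines sharing one point count.
#'
#' @param c0,c100 Border contours: resampled to equal point counts,
#'   smoothed and oriented (see [resample_contour()], [smooth_contour()],
#'   [orient_contours()]).
#' @return An object of class `isocontour_family`: list with `indices`
#'   (-1:101), `coords` (array `[point, xy, index]`) and `m` (points per
#'   contour).
#' @export
isocontour_family <- function(c0, c100) {
  stopifnot(inherits(c0, "contour"), inherits(c100, "contour"))
  if (nrow(c0) != nrow(c100))
    stopf("borders must carry the same number of points; resample first")
  m <- nrow(c0)
  indices <- -1:101
  coords <- array(NA_real_, c(m, 2L, length(indices)),
                  dimnames = list(NULL, c("x", "y"), indices))
  for (h in seq_along(indices)) {
    i <- indices[h]
    coords[, 1, h] <- (i * c100$x + (100 - i) * c0$x) / 100
    coords[, 2, h] <- (i * c100$y + (100 - i) * c0$y) / 100
  }
  structure(list(indices = indices, coords = coords, m = m),
            class = "isocontour_family")
}

#' @export
print.isocontour_family <- function(x, ...) {
  cat(sprintf("<isocontour_family> %d contours (indices %d..%d), %d points each\n",
              length(x$indices), min(x$indices), max(x$indices), x$m))
  invisible(x)
}

#' @rdname isocontour_family
#' @param family An `isocontour_family`.
#' @param i Depth index in -1..101.
#' @export
get_isocontour <- function(family, i) {
  stopifnot(inherits(family, "isocontour_family"))
  h <- match(i, family$indices)
  if (is.na(h)) stopf("index %s not in -1..101", format(i))
  contour_points(family$coords[, 1, h], family$coords[, 2, h])
}

#' Brightness-weighted centre of mass of ROIs
#'
#' Each ROI pixel's position vector is weighted by its brightness ("mass")
#' in the supplied weight image -- the same source image used to detect the
#' ROIs (average, SD or response image). Negative weights are clipped to
#' zero with a warning; if the total mass is not positive the unweighted
#' centroid is returned with a warning.
#'
#' @param mask An `roi_mask`.
#' @param weights A [fov_image()] or matrix of the mask's shape.
#' @param roi_id ROI number (1-based).
#' @return A list with `roi_id`, `x`, `y` (sub-pixel) and `total_mass`.
#' @export
centre_of_mass <- function(mask, weights, roi_id) {
  stopifnot(inherits(mask, "roi_mask"))
  w <- image_data(weights)
  if (!all(dim(w) == dim(mask$labels)))
    stopf("weight image shape does not match the mask")
  px <- roi_pixels(mask, roi_id)
  if (length(px) == 0) stopf("ROI %s does not exist in the mask", roi_id)
  nr <- nrow(mask$labels)
  ys <- ((px - 1L) %% nr) + 1L
  xs <- ((px - 1L) %/% nr) + 1L
  m <- w[px]
  if (any(m < 0)) {
    warnf("ROI %d has negative weights; clipped to 0", roi_id)
    m <- pmax(m, 0)
  }
  tot <- sum(m)
  if (tot <= 0) {
    warnf("ROI %d has zero total mass; using the unweighted centroid", roi_id)
    return(list(roi_id = as.integer(roi_id), x = mean(xs), y = mean(ys),
                total_mass = 0))
  }
  list(roi_id = as.integer(roi_id), x = sum(xs * m) / tot,
       y = sum(ys * m) / tot, total_mass = tot)
}

#' @rdname centre_of_mass
#' @return `centres_of_mass()`: data frame `roi_id`, `x`, `y`,
#'   `total_mass`, one row per ROI.
#' @export
centres_of_mass <- function(mask, weights) {
  rows <- lapply(seq_len(mask$n_rois), function(n)
    as.data.frame(centre_of_mass(mask, weights, n)))
  if (length(rows) == 0)
    return(data.frame(roi_id = integer(), x = numeric(), y = numeric(),
                      total_mass = numeric()))
  do.call(rbind, rows)
}

#' Assign relative laminar depth to centres of mass
#'
#' Each centre of mass receives the index of the isocontour with the
#' smallest Euclidean distance to it as its relative position (-1..101%);
#' distances are measured to polyline vertices, whose spacing is much
#' finer than a pixel at the default point density. Ties are broken toward
#' the lower index. Units beyond the extrapolated -1%/101% contours are
#' still binned into those marginal groups.
#'
#' @param family An [isocontour_family()].
#' @param centres Data frame with columns `x`, `y` (and optionally
#'   `roi_id`), e.g. from [centres_of_mass()].
#' @return A data frame (`position_table`) with one row per centre:
#'   `roi_id`, `depth_percent` (integer in -1..101) and
#'   `distance_px` (distance to the winning isocontour).
#' @export
assign_positions <- function(family, centres) {
  stopifnot(inherits(family, "isocontour_family"))
  centres <- as.data.frame(centres)
  if (nrow(centres) == 0) stopf("`centres` must be non-empty")
  if (!all(c("x", "y") %in% names(centres)))
    stopf("`centres` needs columns x and y")
  ids <- centres$roi_id %||% seq_len(nrow(centres))
  k <- length(family$indices)
  depth <- integer(nrow(centres)); dist_px <- numeric(nrow(centres))
  for (r in seq_len(nrow(centres))) {
    d2min <- vapply(seq_len(k), function(h) {
      min((family$coords[, 1, h] - centres$x[r])^2 +
            (family$coords[, 2, h] - centres$y[r])^2)
    }, numeric(1))
    h <- which.min(d2min)  # first minimum = lowest index on ties
    depth[r] <- family$indices[h]
    dist_px[r] <- sqrt(d2min[h])
  }
  structure(data.frame(roi_id = ids, depth_percent = depth,
                       distance_px = dist_px),
            class = c("position_table", "data.frame"))
}

#' Classify response polarity from a dF/F trace
#'
#' Scores are computed in units of the pre-stimulus standard deviation:
#' `stim_score = (mean(stim) - mean(pre)) / sd(pre)` and `post_score`
#' likewise for the post-stimulus window. A unit is ON if its calcium
#' signal rises during the light stimulus (`stim_score >= z`), OFF if it
#' falls during the stimulus (`stim_score <= -z`) or rebounds immediately
#' after it (`post_score >= z` while `stim_score < z`), and NONRESPONSIVE
#' otherwise. The z-score gate (default 3) makes the sign-based
#' classification deterministic on noisy traces.
#'
#' @param trace Numeric dF/F vector.
#' @param pre_window,stim_window,post_window Disjoint frame-index vectors
#'   within the trace; `pre_window` needs >= 3 frames.
#' @param z_threshold Positive score threshold (dimensionless).
#' @return A list (`polarity_call`) with `class` (`"ON"`, `"OFF"` or
#'   `"NONRESPONSIVE"`), `stim_score` and `post_score`.
#' @export
classify_polarity <- function(trace, pre_window, stim_window, post_window,
                              z_threshold = 3) {
  trace <- as.numeric(trace)
  n <- length(trace)
  wins <- list(pre = pre_window, stim = stim_window, post = post_window)
  for (nm in names(wins)) {
    w <- wins[[nm]]
    if (length(w) == 0 || any(w < 1 | w > n))
      stopf("%s_window must be non-empty and within the trace (1..%d)", nm, n)
  }
  if (length(pre_window) < 3) stopf("pre_window needs at least 3 frames")
  if (length(intersect(pre_window, stim_window)) ||
      length(intersect(pre_window, post_window)) ||
      length(intersect(stim_window, post_window)))
    stopf("windows must be disjoint")
  if (!is_scalar_num(z_threshold) || z_threshold <= 0)
    stopf("`z_threshold` must be > 0")
  s <- stats::sd(trace[pre_window])
  if (s == 0) {
    warnf("pre-stimulus window has zero variance; classified NONRESPONSIVE")
    return(structure(list(class = "NONRESPONSIVE", stim_score = NA_real_,
                          post_score = NA_real_), class = "polarity_call"))
  }
  stim_score <- (mean(trace[stim_window]) - mean(trace[pre_window])) / s
  post_score <- (mean(trace[post_window]) - mean(trace[pre_window])) / s
  cls <- if (stim_score >= z_threshold) "ON"
  else if (stim_score <= -z_threshold ||
           (post_score >= z_threshold && stim_score < z_threshold)) "OFF"
  else "NONRESPONSIVE"
  structure(list(class = cls, stim_score = stim_score,
                 post_score = post_score), class = "polarity_call")
}

#' @rdname classify_polarity
#' @param traces A dF/F `trace_matrix`.
#' @return `classify_polarities()`: data frame `roi_id`, `polarity`,
#'   `stim_score`, `post_score`.
#' @export
classify_polarities <- function(traces, pre_window, stim_window, post_window,
                                z_threshold = 3) {
  stopifnot(inherits(traces, "trace_matrix"))
  ids <- attr(traces, "roi_ids")
  rows <- lapply(seq_len(nrow(traces)), function(r) {
    p <- classify_polarity(traces[r, ], pre_window, stim_window, post_window,
                           z_threshold)
    data.frame(roi_id = ids[r], polarity = p$class,
               stim_score = p$stim_score, post_score = p$post_score)
  })
  do.call(rbind, rows)
}

#' Histogram of laminar positions by polarity
#'
#' Counts of units per depth bin (default width 5% of the layer), over all
#' units or restricted to one polarity class; with the `ALL` filter the
#' counts sum to the number of units in the table.
#'
#' @param table A position table from [assign_positions()].
#' @param calls Optional data frame with `roi_id` and `polarity` (from
#'   [classify_polarities()]); required for the ON/OFF filters.
#' @param filter `"ALL"`, `"ON"` or `"OFF"`.
#' @param bin_width Bin width in depth percent.
#' @return Data frame `bin_low`, `bin_high`, `count`.
#' @export
position_histogram <- function(table, calls = NULL, filter = c("ALL", "ON", "OFF"),
                               bin_width = 5) {
  filter <- match.arg(filter)
  depths <- table$depth_percent
  if (filter != "ALL") {
    if (is.null(calls)) stopf("`calls` is required for filter '%s'", filter)
    keep <- table$roi_id %in% calls$roi_id[calls$polarity == filter]
    depths <- depths[keep]
  }
  lo <- -bin_width / 2  # bins centred on multiples of bin_width; -1 falls in the first
  nb <- as.integer(ceiling((101 - lo) / bin_width))
  breaks <- lo + bin_width * (0:nb)
  counts <- if (length(depths))
    tabulate(findInterval(depths, breaks, rightmost.closed = TRUE), nb)
  else integer(nb)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             count = counts)
}
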