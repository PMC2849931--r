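#' Subtract per-frame background from a stack
#'
#' Fluorescence baselines include instrumentation offsets and non-specific
#' fluorescence. A user-specified background region, chosen to be devoid of
#' the reporter, is averaged in every frame and that scalar is subtracted
#' from all pixels of the frame. The region is never auto-detected.
#'
#' @param stack An [image_stack()].
#' @param bg_region Background region: a logical matrix of the frame shape,
#'   a two-column matrix/data frame of `(x, y)` pixel coordinates, or a
#'   rectangle `c(x0, x1, y0, y1)`.
#' @return The corrected [image_stack()] (`stage` becomes
#'   `"background_corrected"`) with the per-frame subtracted scalars in
#'   attribute `"background_levels"` for audit.
#' @export
subtract_background <- function(stack, bg_region) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  sel <- bg_region_indices(bg_region, d[1], d[2])
  if (length(sel) == 0) stopf("`bg_region` must contain at least one pixel")
  out <- stack
  levels <- numeric(d[3])
  for (t in seq_len(d[3])) {
    fr <- stack$data[, , t]
    levels[t] <- mean(fr[sel])
    out$data[, , t] <- fr - levels[t]
  }
  out$stage <- "background_corrected"
  attr(out, "background_levels") <- levels
  out
}

# Resolve the various background-region notations to linear pixel indices.
bg_region_indices <- function(bg_region, nr, nc) {
  if (is.logical(bg_region) && is.matrix(bg_region)) {
    if (!all(dim(bg_region) == c(nr, nc)))
      stopf("logical `bg_region` must match the frame shape (%d x %d)", nr, nc)
    return(which(bg_region))
  }
  if ((is.matrix(bg_region) || is.data.frame(bg_region)) &&
      ncol(bg_region) == 2) {
    bg_region <- as.matrix(bg_region)
    x <- as.integer(bg_region[, 1])
    y <- as.integer(bg_region[, 2])
    if (any(x < 1 | x > nc | y < 1 | y > nr))
      stopf("`bg_region` coordinates fall outside the frame")
    return(unique((x - 1L) * nr + y))
  }
  if (is.numeric(bg_region) && length(bg_region) == 4) {
    x0 <- bg_region[1]; x1 <- bg_region[2]
    y0 <- bg_region[3]; y1 <- bg_region[4]
    if (x0 < 1 || x1 > nc || y0 < 1 || y1 > nr || x0 > x1 || y0 > y1)
      stopf("`bg_region` rectangle c(x0, x1, y0, y1) is invalid for a %d x %d frame",
            nc, nr)
    idx <- expand.grid(y = y0:y1, x = x0:x1)
    return((idx$x - 1L) * nr + idx$y)
  }
  stopf("unrecognised `bg_region` specification")
}

#' Extract per-ROI time series
#'
#' The mean intensity over each ROI's pixels is measured in every frame,
#' giving one trace per ROI, stored row-wise in ROI-id order.
#'
#' @param stack An [image_stack()].
#' @param mask An `roi_mask` of matching width and height (masks are
#'   reusable across any stack of the same frame shape).
#' @return A `trace_matrix`: numeric matrix (ROI x time) with attributes
#'   `roi_ids`, `frame_interval` and `stage` (inherited from the stack:
#'   `"raw"` or `"background_corrected"`).
#' @export
extract_traces <- function(stack, mask) {
  stopifnot(inherits(stack, "image_stack"), inherits(mask, "roi_mask"))
  d <- dim(stack$data)
  if (!all(dim(mask$labels) == d[1:2]))
    stopf("mask shape (%d x %d) does not match frames (%d x %d)",
          nrow(mask$labels), ncol(mask$labels), d[1], d[2])
  n <- mask$n_rois
  vals <- matrix(0, n, d[3])
  if (n > 0) {
    flat <- matrix(stack$data, d[1] * d[2], d[3])
    for (r in seq_len(n)) {
      px <- roi_pixels(mask, r)
      vals[r, ] <- if (length(px) == 1) flat[px, ] else colMeans(flat[px, , drop = FALSE])
    }
  }
  trace_matrix(vals, roi_ids = seq_len(n),
               frame_interval = stack$frame_interval,
               stage = stack$stage)
}

#' Per-ROI time-series container
#'
#' @param values Numeric matrix, one row per ROI, one column per frame.
#' @param roi_ids Integer ROI identifiers (row order).
#' @param frame_interval Seconds per frame.
#' @param stage One of `"raw"`, `"background_corrected"`, `"dff"`.
#' @return A `trace_matrix` (numeric matrix with metadata attributes).
#' @export
trace_matrix <- function(values, roi_ids = seq_len(nrow(values)),
                         frame_interval = 1, stage = "raw") {
  stopifnot(is.matrix(values), is.numeric(values))
  stage <- match.arg(stage, c("raw", "background_corrected", "dff"))
  if (length(roi_ids) != nrow(values))
    stopf("`roi_ids` must have one entry per row")
  structure(values * 1.0, roi_ids = as.integer(roi_ids),
            frame_interval = frame_interval, stage = stage,
            class = c("trace_matrix", "matrix", "array"))
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d ROI(s) x %d frames, stage: %s, %.3g s/frame\n",
              nrow(x), ncol(x), attr(x, "stage"), attr(x, "frame_interval")))
  invisible(x)
}

#' @export
plot.trace_matrix <- function(x, offset = NULL, ...) {
  nt <- ncol(x); n <- nrow(x)
  tt <- (seq_len(nt) - 1) * attr(x, "frame_interval")
  offset <- offset %||% (if (n > 1) 1.2 * max(apply(x, 1, function(r) diff(range(r)))) else 0)
  graphics::matplot(tt, t(x + offset * (seq_len(n) - 1)), type = "l",
                    lty = 1, xlab = "time (s)",
                    ylab = sprintf("%s (offset)", attr(x, "stage")), ...)
  invisible(x)
}

#' Histogram-mode baseline of a fluorescence trace
#'
#' The resting fluorescence F0 is taken as the centre of the modal bin of a
#' histogram of all values in the trace, using `ceiling(1 + log2(N))` bins
#' spanning the trace's range. Because resting values dominate a trace even
#' in the presence of moderate spontaneous activity, the modal bin tracks
#' the baseline rather than the transients; with activity duty cycles above
#' 50% the mode moves into the response and F0 is overestimated. Ties
#' between equally tall bins are broken toward the lower-valued bin,
#' biasing toward baseline rather than response plateaus.
#'
#' @param trace Numeric vector, length >= 2.
#' @return An object of class `baseline_estimate`: list with `f0`,
#'   `n_bins` and `bin_width`.
#' @export
baseline_f0 <- function(trace) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (n < 2) stopf("trace must have at least 2 points")
  if (!all(is.finite(trace))) stopf("trace values must be finite")
  lo <- min(trace); hi <- max(trace)
  if (hi == lo)
    return(structure(list(f0 = lo, n_bins = 1L, bin_width = 0),
                     class = "baseline_estimate"))
  n_bins <- as.integer(ceiling(1 + log2(n)))
  w <- (hi - lo) / n_bins
  bin <- pmin(floor((trace - lo) / w) + 1L, n_bins)
  counts <- tabulate(bin, n_bins)
  modal <- which.max(counts)  # first maximum = lowest-valued bin on ties
  structure(list(f0 = lo + (modal - 0.5) * w, n_bins = n_bins, bin_width = w),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("<baseline_estimate> F0 = %.6g (%d bins, width %.4g)\n",
              x$f0, x$n_bins, x$bin_width))
  invisible(x)
}

#' Normalise traces to dF/F
#'
#' Each background-corrected trace F is expressed as the relative change
#' `(F - F0) / F0`, with F0 the per-trace histogram-mode baseline from
#' [baseline_f0()]. Rows whose F0 is zero cannot be normalised and are
#' returned as all-`NaN` with a warning; the other rows proceed.
#'
#' @param traces A `trace_matrix` at stage `"background_corrected"`.
#' @return A `trace_matrix` at stage `"dff"`, with per-ROI baselines in
#'   attribute `"f0"` (a data frame `roi_id`, `f0`, `n_bins`).
#' @export
dff <- function(traces) {
  stopifnot(inherits(traces, "trace_matrix"))
  stage <- attr(traces, "stage")
  if (stage != "background_corrected")
    stopf("dff() expects stage 'background_corrected' (got '%s'); run subtract_background() first",
          stage)
  n <- nrow(traces)
  f0s <- numeric(n); nb <- integer(n)
  out <- unclass(traces)
  for (r in seq_len(n)) {
    b <- baseline_f0(traces[r, ])
    f0s[r] <- b$f0; nb[r] <- b$n_bins
    if (b$f0 == 0) {
      warnf("ROI %d has F0 = 0; its dF/F trace is undefined (NaN)",
            attr(traces, "roi_ids")[r])
      out[r, ] <- NaN
    } else {
      out[r, ] <- (traces[r, ] - b$f0) / b$f0
    }
  }
  res <- trace_matrix(out, roi_ids = attr(traces, "roi_ids"),
                      frame_interval = attr(traces, "frame_interval"),
                      stage = "dff")
  attr(res, "f0") <- data.frame(roi_id = attr(traces, "roi_ids"),
                                f0 = f0s, n_bins = nb)
  res
}

#' Read / write trace matrices as CSV
#'
#' One file per processing stage, with a header row `time_s, roi_<id>, ...`
#' and one row per frame.
#'
#' @param traces A `trace_matrix`.
#' @param path CSV path.
#' @param stage Stage label to attach when reading.
#' @return `write_traces_csv()`: `path` invisibly; `read_traces_csv()`:
#'   a `trace_matrix`.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_matrix"))
  tt <- (seq_len(ncol(traces)) - 1) * attr(traces, "frame_interval")
  df <- data.frame(time_s = tt)
  vals <- t(unclass(traces))
  colnames(vals) <- sprintf("roi_%d", attr(traces, "roi_ids"))
  utils::write.csv(cbind(df, as.data.frame(vals)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path, stage = "raw") {
  df <- utils::read.csv(path, check.names = FALSE)
  roi_cols <- grep("^roi_", names(df))
  ids <- as.integer(sub("^roi_", "", names(df)[roi_cols]))
  fi <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else 1
  trace_matrix(t(as.matrix(df[roi_cols])), roi_ids = ids,
               frame_interval = fi, stage = stage)
}
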