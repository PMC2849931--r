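#' Specification of a synthetic blob scene
#'
#' Describes a field of diffraction-limited fluorescent terminals as
#' isotropic Gaussian blobs on a nonuniform background with additive noise.
#' The defaults emulate the regime the detector is designed for: ~20
#' terminals of sigma 1.5 px whose peak brightness spans a tenfold range
#' (30-300 intensity units), on a linear gradient background (0-60 units)
#' with Gaussian noise of sd 0.5 -- the noise level of a temporal-average
#' image (per-frame movie noise is set separately in [make_movie()]).
#' Everything is deterministic given `seed`.
#'
#' @param width,height Scene size in pixels (x and y).
#' @param n_blobs Number of terminals.
#' @param sigma Gaussian width of each terminal, pixels.
#' @param brightness Range `c(min, max)` of peak amplitudes above
#'   background; the default spans the tenfold variation typical of
#'   reporter-protein expression.
#' @param background `"gradient"` (linear along x) or `"constant"`.
#' @param background_range Intensity range `c(at x = 1, at x = width)`
#'   (for `"constant"`, the first value everywhere).
#' @param noise_sd Additive Gaussian noise sd, intensity units.
#' @param poisson If `TRUE`, replace each noiseless pixel by a Poisson
#'   draw of that mean before adding Gaussian noise (photon statistics;
#'   off by default so analytic checks stay exact).
#' @param centres Optional explicit blob centres (data frame/matrix with
#'   x, y); must lie within the frame with a 4-sigma margin.
#' @param min_separation Minimum distance between sampled centres.
#' @param seed RNG seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 256L, height = 256L, n_blobs = 20L,
                       sigma = 1.5, brightness = c(30, 300),
                       background = c("gradient", "constant"),
                       background_range = c(0, 60), noise_sd = 0.5,
                       poisson = FALSE, centres = NULL,
                       min_separation = 6 * sigma, seed = 1L) {
  background <- match.arg(background)
  stopifnot(width >= 8, height >= 8, n_blobs >= 0, sigma > 0,
            length(brightness) == 2, brightness[1] > 0,
            brightness[2] >= brightness[1], noise_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_blobs = as.integer(n_blobs), sigma = sigma,
                 brightness = brightness, background = background,
                 background_range = background_range, noise_sd = noise_sd,
                 poisson = isTRUE(poisson), centres = centres,
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "scene_spec")
}

scene_background <- function(spec) {
  bg_row <- if (spec$background == "gradient")
    seq(spec$background_range[1], spec$background_range[2],
        length.out = spec$width)
  else rep(spec$background_range[1], spec$width)
  matrix(bg_row, spec$height, spec$width, byrow = TRUE)
}

sample_centres <- function(spec) {
  margin <- 4 * spec$sigma + 1
  if (!is.null(spec$centres)) {
    ct <- as.data.frame(spec$centres)
    x <- as.numeric(ct[[1]]); y <- as.numeric(ct[[2]])
    if (length(x) != spec$n_blobs)
      stopf("explicit centres must match n_blobs = %d", spec$n_blobs)
    if (any(x < margin | x > spec$width - margin + 1 |
              y < margin | y > spec$height - margin + 1))
      stopf("blob centres fall outside the frame (margin %.3g px)", margin)
    return(data.frame(x = x, y = y))
  }
  xs <- numeric(0); ys <- numeric(0); tries <- 0L
  while (length(xs) < spec$n_blobs) {
    tries <- tries + 1L
    if (tries > 20000L)
      stopf("could not place %d blobs with min_separation %.3g",
            spec$n_blobs, spec$min_separation)
    # sampled terminals sit on pixel centres so the 1-sigma truth disc has a
    # consistent pixelisation; analytic placement via `centres` stays sub-pixel
    x <- round(stats::runif(1, margin, spec$width - margin + 1))
    y <- round(stats::runif(1, margin, spec$height - margin + 1))
    if (length(xs) == 0 ||
        all((xs - x)^2 + (ys - y)^2 >= spec$min_separation^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x = xs, y = ys)
}

# Sum of Gaussian blobs evaluated on the pixel grid.
blob_field <- function(spec, centres, amplitudes) {
  img <- matrix(0, spec$height, spec$width)
  if (nrow(centres) == 0) return(img)
  X <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  Y <- matrix(seq_len(spec$height), spec$height, spec$width)
  for (i in seq_len(nrow(centres))) {
    img <- img + amplitudes[i] *
      exp(-((X - centres$x[i])^2 + (Y - centres$y[i])^2) / (2 * spec$sigma^2))
  }
  img
}

# Ground-truth mask: pixels within 1 sigma of each blob centre.
truth_mask <- function(spec, centres) {
  labels <- matrix(1L, spec$height, spec$width)
  for (i in seq_len(nrow(centres))) {
    xr <- max(1, floor(centres$x[i] - spec$sigma)):
      min(spec$width, ceiling(centres$x[i] + spec$sigma))
    yr <- max(1, floor(centres$y[i] - spec$sigma)):
      min(spec$height, ceiling(centres$y[i] + spec$sigma))
    for (x in xr) for (y in yr)
      if ((x - centres$x[i])^2 + (y - centres$y[i])^2 <= spec$sigma^2)
        labels[y, x] <- -i
  }
  n <- nrow(centres)
  structure(list(labels = labels, n_rois = n,
                 roi_areas = as.integer(tabulate(-labels[labels < 0], n))),
            class = "roi_mask")
}

#' Generate a synthetic blob image with ground truth
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (a [fov_image()]) and `truth`: list holding
#'   `mask` (true `roi_mask`, pixels within 1 sigma of each centre),
#'   `centres` (data frame `roi_id`, `x`, `y`, `amplitude`) and `spec`.
#' @export
make_blob_image <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    centres <- sample_centres(spec)
    amps <- stats::runif(spec$n_blobs, spec$brightness[1], spec$brightness[2])
    img <- scene_background(spec) + blob_field(spec, centres, amps)
    if (spec$poisson) img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                                    nrow(img), ncol(img))
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    list(image = fov_image(img),
         truth = list(mask = truth_mask(spec, centres),
                      centres = cbind(data.frame(roi_id = seq_len(spec$n_blobs)),
                                      centres,
                                      data.frame(amplitude = amps)),
                      spec = spec))
  })
}

#' Specification of planted calcium responses
#'
#' Assigns each blob a phenomenological response class: `ON_sustained`
#' (step during the stimulus), `ON_transient` (jump at stimulus onset with
#' exponential decay), `OFF` (dip during the stimulus, rebound after it),
#' `spontaneous_spiker` (Poisson-timed spikes with exponential decay;
#' spike times are shared within a group so that synchronously spiking
#' terminals form a recoverable cluster), or `silent`. Amplitudes are in
#' dF/F units. Deterministic given `seed`.
#'
#' @param classes Character vector, one class per blob.
#' @param amplitudes dF/F amplitude per blob (recycled).
#' @param stim_window Frame indices of the stimulus.
#' @param tau_frames Decay time constant of transients, frames.
#' @param spike_rate_hz Spontaneous spike rate.
#' @param seed RNG seed for spontaneous spike times.
#' @return An object of class `response_spec`.
#' @export
response_spec <- function(classes, amplitudes = 0.8, stim_window,
                          tau_frames = 5, spike_rate_hz = 0.1, seed = 1L) {
  allowed <- c("ON_sustained", "ON_transient", "OFF", "spontaneous_spiker",
               "silent")
  if (!all(classes %in% allowed))
    stopf("classes must be among: %s", paste(allowed, collapse = ", "))
  structure(list(classes = classes,
                 amplitudes = rep_len(amplitudes, length(classes)),
                 stim_window = as.integer(stim_window),
                 tau_frames = tau_frames, spike_rate_hz = spike_rate_hz,
                 seed = as.integer(seed)),
            class = "response_spec")
}

# Noise-free dF/F template per blob (rows) given the response spec.
response_templates <- function(responses, n_frames, frame_interval) {
  sw <- responses$stim_window
  if (length(sw) && (min(sw) < 1 || max(sw) > n_frames))
    stopf("stimulus window lies outside the %d movie frames", n_frames)
  tau <- responses$tau_frames
  n <- length(responses$classes)
  tmpl <- matrix(0, n, n_frames)
  spont_trains <- list()  # one shared spike train per spontaneous group
  with_seed(responses$seed, {
    for (i in seq_len(n)) {
      cls <- responses$classes[i]
      r <- numeric(n_frames)
      if (cls == "ON_sustained") {
        r[sw] <- 1
      } else if (cls == "ON_transient") {
        on <- min(sw)
        tt <- seq_len(n_frames)
        r[tt >= on] <- exp(-(tt[tt >= on] - on) / tau)
      } else if (cls == "OFF") {
        r[sw] <- -0.5
        off <- max(sw)
        after <- seq_len(n_frames) > off
        r[after] <- exp(-(which(after) - off - 1) / tau)
      } else if (cls == "spontaneous_spiker") {
        key <- "spont_shared"
        if (is.null(spont_trains[[key]])) {
          p <- responses$spike_rate_hz * frame_interval
          spont_trains[[key]] <- which(stats::runif(n_frames) < p)
        }
        for (sp in spont_trains[[key]]) {
          tt <- seq_len(n_frames)
          r[tt >= sp] <- r[tt >= sp] + exp(-(tt[tt >= sp] - sp) / tau)
        }
      }
      tmpl[i, ] <- responses$amplitudes[i] * r
    }
  })
  tmpl
}

#' Generate a synthetic movie with planted responses and ground truth
#'
#' Builds a fluorescence time series in which blob i's brightness follows
#' `A_i * (1 + template_i(t))` on the scene background, with per-frame
#' Gaussian noise and, optionally, planted integer-jitter motion for
#' registration tests. Per-frame noise defaults to 4 intensity units so
#' that averaging a few hundred frames reproduces the scene-level noise of
#' [scene_spec()].
#'
#' @param scene A [scene_spec()].
#' @param responses A [response_spec()] with one class per blob.
#' @param n_frames Number of frames.
#' @param frame_interval Seconds per frame.
#' @param frame_noise_sd Per-frame Gaussian noise sd, intensity units.
#' @param jitter_px Integer: if > 0, every frame except the first is
#'   translated by shifts drawn uniformly from `-jitter_px..jitter_px`.
#' @return List with `stack` (an [image_stack()]) and `truth`: `mask`,
#'   `centres`, `dff` (noise-free planted dF/F templates, blob x frame),
#'   `classes`, `polarity` (`ON`/`OFF`/`NONRESPONSIVE` per blob),
#'   `cluster` (integer id of each blob's waveform group), `shifts`
#'   (planted per-frame `dx`, `dy`).
#' @export
make_movie <- function(scene = scene_spec(), responses, n_frames = 200L,
                       frame_interval = 0.2, frame_noise_sd = 4,
                       jitter_px = 0L) {
  stopifnot(inherits(scene, "scene_spec"), inherits(responses, "response_spec"))
  if (length(responses$classes) != scene$n_blobs)
    stopf("responses must specify one class per blob (%d)", scene$n_blobs)
  tmpl <- response_templates(responses, n_frames, frame_interval)
  with_seed(scene$seed, {
    centres <- sample_centres(scene)
    amps <- stats::runif(scene$n_blobs, scene$brightness[1],
                         scene$brightness[2])
    bg <- scene_background(scene)
    blobs <- lapply(seq_len(scene$n_blobs), function(i)
      blob_field(scene_spec_one(scene), centres[i, , drop = FALSE], amps[i]))
    shifts <- matrix(0L, n_frames, 2)
    if (jitter_px > 0)
      shifts[-1, ] <- matrix(sample(-jitter_px:jitter_px,
                                    2 * (n_frames - 1), replace = TRUE),
                             ncol = 2)
    data <- array(0, c(scene$height, scene$width, n_frames))
    for (t in seq_len(n_frames)) {
      fr <- bg
      for (i in seq_len(scene$n_blobs))
        fr <- fr + blobs[[i]] * (1 + tmpl[i, t])
      if (any(shifts[t, ] != 0))
        fr <- translate_matrix(fr, shifts[t, 1], shifts[t, 2],
                               stats::median(fr))
      if (frame_noise_sd > 0)
        fr <- fr + stats::rnorm(length(fr), 0, frame_noise_sd)
      data[, , t] <- fr
    }
    polarity <- c(ON_sustained = "ON", ON_transient = "ON", OFF = "OFF",
                  spontaneous_spiker = "NONRESPONSIVE",
                  silent = "NONRESPONSIVE")[responses$classes]
    # waveform group id: blobs sharing an identical template waveform
    key <- apply(tmpl, 1, function(r) paste(signif(r, 8), collapse = ","))
    cluster <- as.integer(factor(key, levels = unique(key)))
    stack <- image_stack(data, frame_interval = frame_interval)
    list(stack = stack,
         truth = list(mask = truth_mask(scene, centres),
                      centres = cbind(data.frame(roi_id = seq_len(scene$n_blobs)),
                                      centres,
                                      data.frame(amplitude = amps)),
                      dff = tmpl, classes = responses$classes,
                      polarity = unname(polarity), cluster = cluster,
                      shifts = data.frame(frame = seq_len(n_frames),
                                          dx = shifts[, 1], dy = shifts[, 2])))
  })
}

# A copy of `spec` describing a single blob (used to evaluate one blob's field).
scene_spec_one <- function(spec) {
  out <- spec; out$n_blobs <- 1L; out
}

#' Generate a layered scene with terminals at known relative depths
#'
#' Places blobs between two analytic border curves (concentric circular
#' arcs, emulating the roughly hemispheric curvature of the retina, or
#' parallel horizontal lines) at prescribed relative depths: depth d% lies
#' at the point-wise linear interpolation between the 0% and 100% borders.
#' The border polylines are returned exactly, so recovered depths can be
#' compared with the planted ones.
#'
#' @param borders List describing the geometry. For arcs:
#'   `list(type = "arc", centre = c(x, y), r0, r100, theta = c(from, to),
#'   n_points = 80)` (angles in radians; `r0` is the 0% border radius).
#'   For lines: `list(type = "line", y0, y100, x_range = c(from, to),
#'   n_points = 80)`.
#' @param depths Numeric vector of relative depths in -1..101 (percent),
#'   one terminal per entry.
#' @param spec A [scene_spec()]; its `n_blobs` is overridden by
#'   `length(depths)` and centres are placed analytically.
#' @return List with `image`, `c0`, `c100` (border [contour_points()]) and
#'   `truth` (`mask`, `centres` including `depth_percent`, `spec`).
#' @export
make_layered_scene <- function(borders, depths, spec = scene_spec()) {
  stopifnot(is.list(borders), !is.null(borders$type))
  if (any(depths < -1 | depths > 101)) stopf("depths must lie in -1..101")
  n <- length(depths)
  npts <- borders$n_points %||% 80L
  if (borders$type == "arc") {
    th <- seq(borders$theta[1], borders$theta[2], length.out = npts)
    c0 <- contour_points(borders$centre[1] + borders$r0 * cos(th),
                         borders$centre[2] + borders$r0 * sin(th))
    c100 <- contour_points(borders$centre[1] + borders$r100 * cos(th),
                           borders$centre[2] + borders$r100 * sin(th))
    span <- borders$theta[2] - borders$theta[1]
    th_b <- borders$theta[1] + span * (0.15 + 0.7 * (seq_len(n) - 0.5) / n)
    rr <- borders$r0 + depths / 100 * (borders$r100 - borders$r0)
    cx <- borders$centre[1] + rr * cos(th_b)
    cy <- borders$centre[2] + rr * sin(th_b)
  } else if (borders$type == "line") {
    xs <- seq(borders$x_range[1], borders$x_range[2], length.out = npts)
    c0 <- contour_points(xs, rep(borders$y0, npts))
    c100 <- contour_points(xs, rep(borders$y100, npts))
    xr <- borders$x_range
    cx <- xr[1] + (xr[2] - xr[1]) * (0.15 + 0.7 * (seq_len(n) - 0.5) / n)
    cy <- borders$y0 + depths / 100 * (borders$y100 - borders$y0)
  } else stopf("unknown border type '%s'", borders$type)
  spec$n_blobs <- n
  spec$centres <- data.frame(x = cx, y = cy)
  scene <- make_blob_image(spec)
  scene$truth$centres$depth_percent <- depths
  list(image = scene$image, c0 = c0, c100 = c100, truth = scene$truth)
}
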