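#' Pipeline configuration
#'
#' Builds and validates the declarative configuration consumed by
#' [run_pipeline_step()]. Defaults follow the method's standard settings:
#' detection threshold `k = -2.2` SD on the temporal-average image,
#' Pearson distance with a 25% cutoff, contour resampling to 8 points per
#' image-width pixel, and a polarity z-threshold of 3.
#'
#' @param ... Named settings overriding the defaults (or a single named
#'   list). Unknown keys are rejected. See Details.
#' @details Keys: `out_dir`, `experiment_id`, `movie` (TIFF path; the
#'   `simulate` step fills it in), `pixel_size_xy`, `frame_interval`,
#'   `register` (logical), `reference_frame`, `source`
#'   (`"average"|"sd"|"response"`), `k`, `min_size`, `connectivity`,
#'   `rest_frames`/`stim_frames` (for the response image),
#'   `bg_region` (rectangle `c(x0, x1, y0, y1)`),
#'   `metric`, `cutoff`, `c0_csv`/`c100_csv` (border contour files),
#'   `points_factor`, `lowess_span`, `z_threshold`,
#'   `pre_window`/`stim_window`/`post_window` (frame ranges for polarity),
#'   `bin_width`, `store` (results CSV), `seed`, plus `sim_*` knobs
#'   forwarded to the simulator (`sim_n_frames`, `sim_jitter_px`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) && is.list(args[[1]]))
    args <- args[[1]]
  defaults <- list(
    out_dir = "roiscope_out", experiment_id = "experiment",
    movie = NULL, pixel_size_xy = 1, frame_interval = 0.2,
    register = FALSE, reference_frame = 1L,
    source = "average", k = -2.2, min_size = 4L, connectivity = 8L,
    rest_frames = NULL, stim_frames = NULL, bg_region = NULL,
    metric = "pearson", cutoff = 25,
    c0_csv = NULL, c100_csv = NULL, points_factor = 8L, lowess_span = 0.1,
    z_threshold = 3, pre_window = NULL, stim_window = NULL,
    post_window = NULL, bin_width = 5,
    store = NULL, seed = 1L,
    sim_n_frames = 200L, sim_jitter_px = 0L)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, args, keep.null = TRUE)
  # validate before any stage runs
  detection_params(cfg$k, cfg$min_size, cfg$connectivity)
  if (!cfg$source %in% c("average", "sd", "response"))
    stopf("`source` must be one of average, sd, response")
  if (!cfg$metric %in% c("pearson", "euclidean", "normalized_euclidean",
                         "manhattan", "chebychev"))
    stopf("unknown metric '%s'", cfg$metric)
  if (cfg$cutoff <= 0 || cfg$cutoff >= 100)
    stopf("`cutoff` must be a percentage in (0, 100)")
  if (cfg$lowess_span <= 0 || cfg$lowess_span > 1)
    stopf("`lowess_span` must be in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file of config keys.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) pipeline_config(yaml::read_yaml(path))

artifact <- function(cfg, name) file.path(cfg$out_dir, name)

require_artifact <- function(cfg, name, producer) {
  p <- artifact(cfg, name)
  if (!file.exists(p))
    stopf("missing artifact '%s'; run the '%s' step first", p, producer)
  p
}

echo_config <- function(cfg, step) {
  keep <- !vapply(cfg, is.null, logical(1))
  yaml::write_yaml(unclass(cfg)[keep],
                   artifact(cfg, sprintf("config_used_%s.yaml", step)))
}

log_msg <- function(...) message(sprintf(...))

load_working_stack <- function(cfg) {
  reg <- artifact(cfg, "movie_registered.tif")
  src <- if (file.exists(reg)) reg
  else cfg$movie %||% require_artifact(cfg, "movie.tif", "simulate")
  load_stack(src, cfg$pixel_size_xy, cfg$frame_interval)
}

#' Run one pipeline stage
#'
#' File-based pipeline driver: each subcommand reads its upstream
#' artifacts from `out_dir`, runs the corresponding package functions, and
#' writes its outputs plus an echo of the fully resolved configuration
#' (`config_used_<step>.yaml`) beside them. Steps:
#'
#' * `simulate` -- generate a demo layered movie with planted responses
#'   (`movie.tif`, border CSVs, ground-truth tables).
#' * `detect` -- source image, Laplacian detection; writes `mask.tif` +
#'   `mask.csv`, `source_image.tif`, and the registered movie + shifts if
#'   `register` is enabled.
#' * `extract` -- background correction and per-ROI traces
#'   (`traces_raw.csv`, `traces_corrected.csv`, `background_levels.csv`).
#' * `dff` -- baseline estimation and normalisation (`traces_dff.csv`,
#'   `f0.csv`).
#' * `cluster` -- distance matrix, single-linkage clusters, means
#'   (`distance.csv`, `clusters.csv`, `cluster_means.csv`).
#' * `position` -- isocontour depth mapping and polarity
#'   (`positions.csv`, `histogram_*.csv`).
#' * `report` -- synopsis directory `report/`.
#' * `db` -- append terminal records to the `store` CSV.
#'
#' @param step One of `simulate`, `detect`, `extract`, `dff`, `cluster`,
#'   `position`, `report`, `db`.
#' @param config A [pipeline_config()].
#' @return Invisibly, the path(s) of the main artifacts written.
#' @export
run_pipeline_step <- function(step, config = pipeline_config()) {
  step <- match.arg(step, c("simulate", "detect", "extract", "dff",
                            "cluster", "position", "report", "db"))
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(step,
                simulate = step_simulate(config),
                detect = step_detect(config),
                extract = step_extract(config),
                dff = step_dff(config),
                cluster = step_cluster(config),
                position = step_position(config),
                report = step_report(config),
                db = step_db(config))
  echo_config(config, step)
  invisible(out)
}

#' @rdname run_pipeline_step
#' @param steps Character vector of steps to run in order.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         steps = c("simulate", "detect", "extract", "dff",
                                   "cluster", "position", "report", "db")) {
  for (s in steps) run_pipeline_step(s, config)
  invisible(config$out_dir)
}

# -- steps --------------------------------------------------------------

step_simulate <- function(cfg) {
  n_frames <- cfg$sim_n_frames
  depths <- c(15, 20, 25, 65, 70, 75, 40, 55, 85, 30, 60, 90)
  classes <- c("OFF", "OFF", "OFF", "ON_sustained", "ON_sustained",
               "ON_sustained", "ON_transient", "ON_transient",
               "ON_transient", "spontaneous_spiker", "spontaneous_spiker",
               "silent")
  stim <- seq(floor(n_frames * 0.4), floor(n_frames * 0.6))
  spec <- scene_spec(width = 128L, height = 128L, n_blobs = length(depths),
                     brightness = c(60, 300), background = "constant",
                     background_range = c(10, 10), seed = cfg$seed)
  borders <- list(type = "arc", centre = c(64, 210), r0 = 170, r100 = 120,
                  theta = c(-1.95, -1.19), n_points = 100)
  layered <- make_layered_scene(borders, depths, spec)
  spec$centres <- layered$truth$centres[c("x", "y")]
  responses <- response_spec(classes, amplitudes = 0.8, stim_window = stim,
                             spike_rate_hz = 0.15, seed = cfg$seed)
  movie <- make_movie(spec, responses, n_frames = n_frames,
                      frame_interval = cfg$frame_interval,
                      jitter_px = cfg$sim_jitter_px)
  save_stack(movie$stack, artifact(cfg, "movie.tif"),
             description = "synthetic demo movie")
  write_contour_csv(layered$c0, artifact(cfg, "c0.csv"))
  write_contour_csv(layered$c100, artifact(cfg, "c100.csv"))
  write_roi_mask(movie$truth$mask, artifact(cfg, "truth_mask.tif"),
                 artifact(cfg, "truth_mask.csv"))
  truth <- cbind(movie$truth$centres,
                 data.frame(depth_percent = depths,
                            class = movie$truth$classes,
                            polarity = movie$truth$polarity,
                            cluster = movie$truth$cluster))
  utils::write.csv(truth, artifact(cfg, "truth_terminals.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(stim_start = min(stim), stim_end = max(stim)),
                   artifact(cfg, "truth_stimulus.csv"), row.names = FALSE)
  log_msg("simulate: %d terminals, %d frames -> %s",
          length(depths), n_frames, artifact(cfg, "movie.tif"))
  artifact(cfg, "movie.tif")
}

# Frame windows for the demo stimulus, derived from the simulate artifacts
# (or from the config when analysing real data).
stimulus_windows <- function(cfg, n_frames) {
  if (!is.null(cfg$stim_window)) {
    stim <- cfg$stim_window
  } else {
    p <- artifact(cfg, "truth_stimulus.csv")
    if (!file.exists(p))
      stopf("no stimulus timing: set `stim_window` or run 'simulate'")
    tab <- utils::read.csv(p)
    stim <- seq(tab$stim_start, tab$stim_end)
  }
  pre <- cfg$pre_window %||% seq_len(min(stim) - 1)
  post_end <- min(n_frames, max(stim) + max(5L, length(stim)))
  post <- cfg$post_window %||% (if (max(stim) < post_end)
    seq(max(stim) + 1, post_end) else integer())
  list(pre = pre, stim = stim, post = post)
}

step_detect <- function(cfg) {
  src_path <- cfg$movie %||% require_artifact(cfg, "movie.tif", "simulate")
  stack <- load_stack(src_path, cfg$pixel_size_xy, cfg$frame_interval)
  if (isTRUE(cfg$register)) {
    stack <- register_stack(stack, cfg$reference_frame)
    save_stack(stack, artifact(cfg, "movie_registered.tif"))
    utils::write.csv(registration_shifts(stack), artifact(cfg, "shifts.csv"),
                     row.names = FALSE)
  }
  src <- switch(cfg$source,
                average = average_image(stack),
                sd = sd_image(stack),
                response = {
                  w <- stimulus_windows(cfg, n_frames(stack))
                  response_image(stack, cfg$rest_frames %||% w$pre, w$stim)
                })
  mask <- detect_rois(src, detection_params(cfg$k, cfg$min_size,
                                            cfg$connectivity))
  save_stack(src, artifact(cfg, "source_image.tif"))
  write_roi_mask(mask, artifact(cfg, "mask.tif"), artifact(cfg, "mask.csv"))
  log_msg("detect: %d ROI(s) at threshold %.4g (k = %.3g)",
          mask$n_rois, attr(mask, "threshold"), cfg$k)
  artifact(cfg, "mask.tif")
}

step_extract <- function(cfg) {
  mask <- read_roi_mask(require_artifact(cfg, "mask.tif", "detect"))
  stack <- load_working_stack(cfg)
  raw <- extract_traces(stack, mask)
  write_traces_csv(raw, artifact(cfg, "traces_raw.csv"))
  if (!is.null(cfg$bg_region)) {
    stack <- subtract_background(stack, cfg$bg_region)
    utils::write.csv(data.frame(frame = seq_len(n_frames(stack)),
                                background = attr(stack, "background_levels")),
                     artifact(cfg, "background_levels.csv"), row.names = FALSE)
  } else {
    stack$stage <- "background_corrected"  # explicit opt-out, no region given
    log_msg("extract: no bg_region configured; traces treated as background-free")
  }
  corrected <- extract_traces(stack, mask)
  write_traces_csv(corrected, artifact(cfg, "traces_corrected.csv"))
  log_msg("extract: %d trace(s) x %d frames", nrow(raw), ncol(raw))
  artifact(cfg, "traces_corrected.csv")
}

step_dff <- function(cfg) {
  tm <- read_traces_csv(require_artifact(cfg, "traces_corrected.csv",
                                         "extract"),
                        stage = "background_corrected")
  d <- dff(tm)
  write_traces_csv(d, artifact(cfg, "traces_dff.csv"))
  utils::write.csv(attr(d, "f0"), artifact(cfg, "f0.csv"), row.names = FALSE)
  log_msg("dff: %d trace(s) normalised", nrow(d))
  artifact(cfg, "traces_dff.csv")
}

step_cluster <- function(cfg) {
  d <- read_traces_csv(require_artifact(cfg, "traces_dff.csv", "dff"),
                       stage = "dff")
  dm <- pairwise_distance(d, cfg$metric)
  utils::write.csv(as.data.frame(unclass(dm)), artifact(cfg, "distance.csv"))
  cl <- cluster_traces(dm, cfg$cutoff)
  utils::write.csv(data.frame(roi_id = as.integer(names(cl$labels)),
                              cluster_id = ifelse(is.na(cl$labels),
                                                  "UNCLUSTERED", cl$labels)),
                   artifact(cfg, "clusters.csv"), row.names = FALSE)
  mns <- cluster_means(d, cl)
  utils::write.csv(as.data.frame(mns), artifact(cfg, "cluster_means.csv"))
  log_msg("cluster: %d cluster(s), %d unclustered", cl$n_clusters,
          sum(is.na(cl$labels)))
  artifact(cfg, "clusters.csv")
}

step_position <- function(cfg) {
  mask <- read_roi_mask(require_artifact(cfg, "mask.tif", "detect"))
  src <- load_stack(require_artifact(cfg, "source_image.tif", "detect"))
  weights <- src$data[, , 1]
  c0p <- cfg$c0_csv %||% require_artifact(cfg, "c0.csv", "simulate")
  c100p <- cfg$c100_csv %||% require_artifact(cfg, "c100.csv", "simulate")
  m <- cfg$points_factor * ncol(weights)
  c0 <- smooth_contour(resample_contour(read_contour_csv(c0p), m),
                       cfg$lowess_span)
  c100 <- smooth_contour(resample_contour(read_contour_csv(c100p), m),
                         cfg$lowess_span)
  ori <- orient_contours(c0, c100)
  fam <- isocontour_family(ori$c0, ori$c100)
  centres <- centres_of_mass(mask, weights)
  pos <- assign_positions(fam, centres)
  d <- read_traces_csv(require_artifact(cfg, "traces_dff.csv", "dff"),
                       stage = "dff")
  w <- stimulus_windows(cfg, ncol(d))
  pol <- classify_polarities(d, w$pre, w$stim, w$post, cfg$z_threshold)
  tab <- merge(merge(pos, pol, by = "roi_id"),
               centres[c("roi_id", "x", "y")], by = "roi_id")
  utils::write.csv(tab, artifact(cfg, "positions.csv"), row.names = FALSE)
  for (f in c("ALL", "ON", "OFF"))
    utils::write.csv(position_histogram(pos, pol, f, cfg$bin_width),
                     artifact(cfg, sprintf("histogram_%s.csv", tolower(f))),
                     row.names = FALSE)
  log_msg("position: %d centre(s) mapped to depth", nrow(tab))
  artifact(cfg, "positions.csv")
}

step_report <- function(cfg) {
  bundle <- list(experiment_id = cfg$experiment_id,
                 params = list(pixel_size_xy = cfg$pixel_size_xy,
                               frame_interval = cfg$frame_interval,
                               source = cfg$source, k = cfg$k,
                               min_size = cfg$min_size,
                               metric = cfg$metric, cutoff = cfg$cutoff,
                               seed = cfg$seed))
  src <- artifact(cfg, "source_image.tif")
  if (file.exists(src))
    bundle$average_image <- fov_image(load_stack(src)$data[, , 1])
  mk <- artifact(cfg, "mask.tif")
  if (file.exists(mk)) bundle$mask <- read_roi_mask(mk)
  tr <- artifact(cfg, "traces_corrected.csv")
  if (file.exists(tr))
    bundle$traces <- read_traces_csv(tr, "background_corrected")
  dv <- artifact(cfg, "traces_dff.csv")
  if (file.exists(dv)) bundle$dff <- read_traces_csv(dv, "dff")
  ps <- artifact(cfg, "positions.csv")
  if (file.exists(ps)) bundle$positions <- utils::read.csv(ps)
  synopsis(bundle, artifact(cfg, "report"))
  log_msg("report: written to %s", artifact(cfg, "report"))
  artifact(cfg, "report")
}

step_db <- function(cfg) {
  store <- cfg$store %||% artifact(cfg, "store.csv")
  mask <- read_roi_mask(require_artifact(cfg, "mask.tif", "detect"))
  d <- read_traces_csv(require_artifact(cfg, "traces_dff.csv", "dff"),
                       stage = "dff")
  f0p <- artifact(cfg, "f0.csv")
  if (file.exists(f0p)) attr(d, "f0") <- utils::read.csv(f0p)
  positions <- polarity <- centres <- NULL
  pp <- artifact(cfg, "positions.csv")
  if (file.exists(pp)) {
    tab <- utils::read.csv(pp)
    positions <- tab[c("roi_id", "depth_percent")]
    polarity <- tab[c("roi_id", "polarity")]
    centres <- tab[c("roi_id", "x", "y")]
  }
  clusters <- NULL
  cp <- artifact(cfg, "clusters.csv")
  if (file.exists(cp)) {
    ct <- utils::read.csv(cp)
    lab <- suppressWarnings(as.integer(ct$cluster_id))
    clusters <- structure(list(labels = stats::setNames(lab, ct$roi_id),
                               n_clusters = max(c(0L, lab), na.rm = TRUE),
                               cutoff_fraction = cfg$cutoff,
                               cutoff_value = NA, metric = cfg$metric),
                          class = "cluster_assignment")
  }
  rec <- terminal_records(cfg$experiment_id, mask, centres = centres,
                          positions = positions, polarity = polarity,
                          clusters = clusters, dff_traces = d,
                          pixel_size_xy = cfg$pixel_size_xy,
                          frame_interval = cfg$frame_interval)
  db_append(store, rec)
  log_msg("db: %d record(s) appended to %s", nrow(rec), store)
  store
}
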