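# Flat-file results store: one CSV, one header, one row per terminal.
# A plain-text table (rather than a binary database) keeps results easy to
# exchange between laboratories and to mine with any tool.

db_columns <- c("experiment_id", "roi_id", "com_x", "com_y", "depth_percent",
                "polarity", "cluster_id", "f0", "peak_dff", "area_px",
                "pixel_size_xy", "frame_interval", "date")

#' Assemble per-terminal records from analysis results
#'
#' Joins the per-ROI outputs of the pipeline stages into the store's row
#' format. Any stage may be omitted; its fields are then `NA`.
#'
#' @param experiment_id Experiment identifier (string).
#' @param mask `roi_mask` (areas).
#' @param centres Data frame from [centres_of_mass()].
#' @param positions Position table from [assign_positions()].
#' @param polarity Data frame from [classify_polarities()].
#' @param clusters A [cluster_traces()] assignment.
#' @param dff_traces A dF/F `trace_matrix` (supplies `f0` and `peak_dff`).
#' @param pixel_size_xy,frame_interval,date Acquisition metadata.
#' @return Data frame with the store's column dictionary, one row per ROI.
#' @export
terminal_records <- function(experiment_id, mask, centres = NULL,
                             positions = NULL, polarity = NULL,
                             clusters = NULL, dff_traces = NULL,
                             pixel_size_xy = NA, frame_interval = NA,
                             date = NA) {
  stopifnot(inherits(mask, "roi_mask"))
  n <- mask$n_rois
  rec <- data.frame(experiment_id = rep(as.character(experiment_id), n),
                    roi_id = seq_len(n), com_x = NA_real_, com_y = NA_real_,
                    depth_percent = NA_integer_, polarity = NA_character_,
                    cluster_id = NA_character_, f0 = NA_real_,
                    peak_dff = NA_real_, area_px = mask$roi_areas,
                    pixel_size_xy = pixel_size_xy,
                    frame_interval = frame_interval,
                    date = as.character(date))
  match_in <- function(df, col) df[[col]][match(rec$roi_id, df$roi_id)]
  if (!is.null(centres)) {
    rec$com_x <- match_in(centres, "x"); rec$com_y <- match_in(centres, "y")
  }
  if (!is.null(positions))
    rec$depth_percent <- match_in(positions, "depth_percent")
  if (!is.null(polarity)) rec$polarity <- match_in(polarity, "polarity")
  if (!is.null(clusters)) {
    lab <- clusters$labels[match(rec$roi_id, as.integer(names(clusters$labels)))]
    rec$cluster_id <- ifelse(is.na(lab), "UNCLUSTERED", as.character(lab))
  }
  if (!is.null(dff_traces)) {
    f0tab <- attr(dff_traces, "f0")
    if (!is.null(f0tab)) rec$f0 <- match_in(f0tab, "f0")
    ids <- attr(dff_traces, "roi_ids")
    pk <- apply(dff_traces, 1, max)
    rec$peak_dff <- pk[match(rec$roi_id, ids)]
  }
  rec
}

#' Append terminal records to a flat-file store
#'
#' The store is a line-delimited CSV table with a fixed column dictionary;
#' `(experiment_id, roi_id)` must be unique across the whole store, so
#' re-appending an experiment is rejected with a report of the offending
#' keys.
#'
#' @param store Path to the store CSV (created if absent).
#' @param records Data frame from [terminal_records()].
#' @return The store path, invisibly.
#' @export
db_append <- function(store, records) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(db_columns, names(records))
  if (length(missing_cols))
    stopf("records lack required column(s): %s",
          paste(missing_cols, collapse = ", "))
  records <- records[db_columns]
  if (nrow(records) == 0) return(invisible(store))
  keys <- paste(records$experiment_id, records$roi_id, sep = "\r")
  dup <- keys[duplicated(keys)]
  if (file.exists(store)) {
    old <- db_read(store)
    dup <- c(dup, intersect(keys, paste(old$experiment_id, old$roi_id,
                                        sep = "\r")))
  }
  if (length(dup))
    stopf("duplicate (experiment_id, roi_id) key(s): %s",
          paste(unique(gsub("\r", ":", dup)), collapse = ", "))
  if (file.exists(store))
    utils::write.table(records, store, append = TRUE, sep = ",",
                       row.names = FALSE, col.names = FALSE, qmethod = "double")
  else utils::write.csv(records, store, row.names = FALSE)
  invisible(store)
}

#' @rdname db_append
#' @export
db_read <- function(store) {
  if (!file.exists(store)) stopf("store '%s' does not exist", store)
  utils::read.csv(store, colClasses = c(experiment_id = "character",
                                        polarity = "character",
                                        cluster_id = "character",
                                        date = "character"))
}

#' Query the results store
#'
#' Returns all and only the records satisfying every predicate, in
#' insertion order. Each predicate is named after a store column and is
#' either a vector of allowed values (class membership / experiment sets)
#' or a function of the column returning a logical vector (ranges, e.g.
#' `depth_percent = function(d) d >= 50`). Predicates compose by
#' conjunction; with no predicates all records are returned.
#'
#' @param store Path to the store CSV.
#' @param ... Named predicates.
#' @return Data frame of matching records.
#' @examples
#' \dontrun{
#' # the "ectopic" screen: OFF terminals in the ON half of the layer
#' db_query("store.csv", polarity = "OFF",
#'          depth_percent = function(d) d >= 50)
#' }
#' @export
db_query <- function(store, ...) {
  df <- db_read(store)
  preds <- list(...)
  if (length(preds) && (is.null(names(preds)) || any(names(preds) == "")))
    stopf("all predicates must be named after store columns")
  keep <- rep(TRUE, nrow(df))
  for (field in names(preds)) {
    if (!field %in% names(df)) stopf("unknown field '%s' in query", field)
    p <- preds[[field]]
    hit <- if (is.function(p)) p(df[[field]]) else df[[field]] %in% p
    hit[is.na(hit)] <- FALSE
    keep <- keep & hit
  }
  df[keep, , drop = FALSE]
}

#' Write a per-experiment synopsis report
#'
#' Produces a directory holding a markdown summary plus image assets: the
#' imaging-parameters table, the averaged field of view, the numbered ROI
#' mask, a grey-scale raster of all traces (one image row per ROI, one
#' column per frame) and one numbered trace panel per ROI. Sections whose
#' inputs are missing from the bundle are omitted with a note. Output is
#' deterministic for fixed inputs.
#'
#' @param bundle Named list with any of: `experiment_id`, `params` (named
#'   list), `average_image` ([fov_image()]), `mask` (`roi_mask`), `traces`
#'   (`trace_matrix`, any stage), `dff` (`trace_matrix`), `positions`,
#'   `clusters`.
#' @param out_dir Output directory (created).
#' @return `out_dir`, invisibly.
#' @export
synopsis <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c(sprintf("# Experiment synopsis: %s",
                     bundle$experiment_id %||% "(unnamed)"), "")
  note_missing <- function(what)
    c(sprintf("*Section omitted: %s not available.*", what), "")

  lines <- c(lines, "## Imaging parameters", "")
  if (!is.null(bundle$params)) {
    p <- bundle$params
    lines <- c(lines, "| parameter | value |", "|---|---|",
               sprintf("| %s | %s |", names(p),
                       vapply(p, function(v) paste(format(v), collapse = " "),
                              character(1))), "")
  } else lines <- c(lines, note_missing("imaging parameters"))

  lines <- c(lines, "## Field of view", "")
  if (!is.null(bundle$average_image)) {
    png::writePNG(normalize01(image_data(bundle$average_image)),
                  file.path(out_dir, "average_image.png"))
    lines <- c(lines, "![averaged image](average_image.png)", "")
  } else lines <- c(lines, note_missing("averaged image"))

  lines <- c(lines, "## ROI mask", "")
  if (!is.null(bundle$mask)) {
    mk <- bundle$mask
    png::writePNG(normalize01(-pmin(mk$labels, 0)),
                  file.path(out_dir, "roi_mask.png"))
    lines <- c(lines, sprintf("%d ROIs (areas %s px).", mk$n_rois,
                              if (mk$n_rois) paste(range(mk$roi_areas),
                                                   collapse = "-") else "-"),
               "", "![ROI mask](roi_mask.png)", "")
  } else lines <- c(lines, note_missing("ROI mask"))

  tm <- bundle$dff %||% bundle$traces
  lines <- c(lines, "## Signal raster", "")
  if (!is.null(tm) && nrow(tm) > 0) {
    png::writePNG(normalize01(unclass(tm)), file.path(out_dir, "raster.png"))
    lines <- c(lines,
               sprintf("Grey-scale raster of all %d traces (%d frames).",
                       nrow(tm), ncol(tm)),
               "", "![raster](raster.png)", "")
  } else lines <- c(lines, note_missing("traces"))

  lines <- c(lines, "## Per-ROI traces", "")
  if (!is.null(tm) && nrow(tm) > 0) {
    ids <- attr(tm, "roi_ids")
    tt <- (seq_len(ncol(tm)) - 1) * attr(tm, "frame_interval")
    for (r in seq_len(nrow(tm))) {
      fn <- sprintf("trace_roi_%03d.png", ids[r])
      grDevices::png(file.path(out_dir, fn), width = 480, height = 160)
      graphics::par(mar = c(2.5, 3.5, 1.5, 0.5))
      graphics::plot(tt, tm[r, ], type = "l", xlab = "", ylab = "",
                     main = sprintf("ROI %d", ids[r]))
      grDevices::dev.off()
      lines <- c(lines, sprintf("![ROI %d](%s)", ids[r], fn))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, note_missing("traces"))

  if (!is.null(bundle$positions)) {
    lines <- c(lines, "## Laminar positions", "",
               "| roi_id | depth (%) |", "|---|---|",
               sprintf("| %d | %d |", bundle$positions$roi_id,
                       bundle$positions$depth_percent), "")
  }
  if (!is.null(bundle$clusters)) {
    cl <- bundle$clusters
    lines <- c(lines, "## Clusters", "",
               sprintf("%d cluster(s) at cutoff %.4g%% of the maximum distance.",
                       cl$n_clusters, cl$cutoff_fraction), "")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
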