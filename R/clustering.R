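#' Pairwise distance matrix between ROI traces
#'
#' Traces are compared pair-wise under one of five metrics commonly used
#' for expression-profile clustering: `pearson` (distance `1 - r`, so that
#' 0 means perfect correlation and 2 perfect anti-correlation),
#' `euclidean`, `normalized_euclidean` (Euclidean distance between traces
#' individually standardised to zero mean and unit variance), `manhattan`,
#' and `chebychev` (maximum coordinate difference).
#'
#' Constant traces have undefined correlation; under `pearson` (and
#' `normalized_euclidean`) their rows/columns are flagged `NA` with a
#' warning and such ROIs are excluded from clustering.
#'
#' @param traces A `trace_matrix` (>= 2 rows) or numeric matrix, one trace
#'   per row.
#' @param metric Distance metric name.
#' @return A symmetric numeric matrix with zero diagonal, of class
#'   `trace_distance`, with attributes `metric` and `roi_ids`.
#' @export
pairwise_distance <- function(traces,
                              metric = c("pearson", "euclidean",
                                         "normalized_euclidean", "manhattan",
                                         "chebychev")) {
  metric <- match.arg(metric)
  v <- unclass(traces)
  stopifnot(is.matrix(v), is.numeric(v))
  if (nrow(v) < 2) stopf("need at least 2 traces")
  ids <- attr(traces, "roi_ids") %||% seq_len(nrow(v))
  const <- apply(v, 1, function(r) stats::sd(r) == 0 || !all(is.finite(r)))
  d <- switch(metric,
    pearson = 1 - suppressWarnings(stats::cor(t(v))),
    euclidean = as.matrix(stats::dist(v, method = "euclidean")),
    manhattan = as.matrix(stats::dist(v, method = "manhattan")),
    chebychev = as.matrix(stats::dist(v, method = "maximum")),
    normalized_euclidean = {
      z <- v
      ok <- !const
      z[ok, ] <- t(scale(t(v[ok, , drop = FALSE])))
      as.matrix(stats::dist(z, method = "euclidean"))
    })
  if (metric %in% c("pearson", "normalized_euclidean") && any(const)) {
    warnf("%d constant/non-finite trace(s) have undefined %s distance; flagged NA",
          sum(const), metric)
    d[const, ] <- NA_real_
    d[, const] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(d, metric = metric, roi_ids = as.integer(ids),
            class = c("trace_distance", "matrix", "array"))
}

#' @export
print.trace_distance <- function(x, ...) {
  cat(sprintf("<trace_distance> %d x %d, metric: %s, max = %.4g\n",
              nrow(x), ncol(x), attr(x, "metric"), max(x, na.rm = TRUE)))
  invisible(x)
}

#' Single-linkage clustering of traces under a distance cutoff
#'
#' The absolute cutoff is a percentage of the highest pairwise distance
#' (typically 25-30%). Any two traces closer than the cutoff are grouped,
#' and further traces are added by single linkage (nearest-neighbour);
#' equivalently, clusters are the connected components of the graph whose
#' edges join pairs with distance strictly below the cutoff, which equals a
#' flat cut of the single-linkage dendrogram at that height. Components of
#' size 1 are not groupings and are reported as unclustered (`NA`).
#'
#' @param dist A [pairwise_distance()] matrix.
#' @param cutoff_fraction Cutoff as a percentage of the maximum distance,
#'   in (0, 100).
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (integer per ROI, `NA` = unclustered, ids 1..n_clusters contiguous in
#'   order of first member), `n_clusters`, `cutoff_fraction`,
#'   `cutoff_value` and `metric`.
#' @export
cluster_traces <- function(dist, cutoff_fraction = 25) {
  stopifnot(inherits(dist, "trace_distance") ||
              (is.matrix(dist) && isSymmetric(unname(unclass(dist)))))
  if (!is_scalar_num(cutoff_fraction) ||
      cutoff_fraction <= 0 || cutoff_fraction >= 100)
    stopf("`cutoff_fraction` must be a percentage in (0, 100)")
  d <- unclass(dist)
  n <- nrow(d)
  ids <- attr(dist, "roi_ids") %||% seq_len(n)
  off_diag_na <- is.na(d); diag(off_diag_na) <- TRUE
  valid <- !apply(off_diag_na, 1, all)  # rows flagged NA are excluded
  dmax <- max(d, na.rm = TRUE)
  labels <- rep(NA_integer_, n)
  if (dmax == 0) {
    # degenerate: all traces identical -> one cluster of all members
    labels[valid] <- 1L
    return(structure(list(labels = stats::setNames(labels, ids),
                          n_clusters = 1L,
                          cutoff_fraction = cutoff_fraction,
                          cutoff_value = 0,
                          metric = attr(dist, "metric")),
                     class = "cluster_assignment"))
  }
  cutoff <- dmax * cutoff_fraction / 100
  adj <- !is.na(d) & d < cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  comp <- igraph::components(g)$membership
  comp[!valid] <- NA_integer_
  sizes <- table(comp)
  big <- as.integer(names(sizes)[sizes >= 2])
  # contiguous cluster ids in order of first member
  big <- big[order(vapply(big, function(cmp) min(which(comp == cmp)), 1L))]
  for (j in seq_along(big)) labels[which(comp == big[j])] <- j
  structure(list(labels = stats::setNames(labels, ids),
                 n_clusters = length(big),
                 cutoff_fraction = cutoff_fraction,
                 cutoff_value = cutoff,
                 metric = attr(dist, "metric")),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cluster(s) at %.4g%% of max distance (cutoff %.4g)\n",
              x$n_clusters, x$cutoff_fraction, x$cutoff_value))
  if (x$n_clusters)
    for (k in seq_len(x$n_clusters))
      cat(sprintf("  cluster %d: ROIs %s\n", k,
                  paste(names(x$labels)[which(x$labels == k)], collapse = ", ")))
  cat(sprintf("  unclustered: %d\n", sum(is.na(x$labels))))
  invisible(x)
}

#' Mean trace per cluster
#'
#' @param traces The `trace_matrix` that was clustered.
#' @param assignment A [cluster_traces()] result.
#' @return A numeric matrix (cluster x time) with the per-cluster member
#'   ROI ids in attribute `"members"` (a list).
#' @export
cluster_means <- function(traces, assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  v <- unclass(traces)
  if (nrow(v) != length(assignment$labels))
    stopf("assignment does not match the trace matrix (%d vs %d rows)",
          length(assignment$labels), nrow(v))
  k <- assignment$n_clusters
  out <- matrix(0, k, ncol(v))
  members <- vector("list", k)
  ids <- attr(traces, "roi_ids") %||% seq_len(nrow(v))
  for (j in seq_len(k)) {
    rows <- which(assignment$labels == j)
    members[[j]] <- ids[rows]
    out[j, ] <- colMeans(v[rows, , drop = FALSE])
  }
  rownames(out) <- if (k) sprintf("cluster_%d", seq_len(k)) else NULL
  structure(out, members = members)
}
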