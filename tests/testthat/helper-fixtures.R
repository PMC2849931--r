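# Shared fixtures and independent oracles, all built in code at test time.

# Fraction of planted ROIs matched by a detected mask at a Jaccard-overlap
# criterion (default 0.5), plus whether any detected component merges >= 2
# planted ROIs.
match_planted <- function(detected, truth_mask, jaccard_min = 0.5) {
  n <- truth_mask$n_rois
  hit <- logical(n)
  for (i in seq_len(n)) {
    tp <- which(truth_mask$labels == -i)
    cand <- unique(detected$labels[tp])
    cand <- cand[cand < 0]
    best <- 0
    for (l in cand) {
      dp <- which(detected$labels == l)
      best <- max(best, length(intersect(tp, dp)) / length(union(tp, dp)))
    }
    hit[i] <- best >= jaccard_min
  }
  merged <- FALSE
  for (l in seq_len(detected$n_rois)) {
    dp <- which(detected$labels == -l)
    touched <- unique(truth_mask$labels[dp])
    if (sum(touched < 0) >= 2) merged <- TRUE
  }
  list(recall = mean(hit), hit = hit, merged = merged)
}

# Brute-force 4-neighbour Laplacian by explicit second differences with
# replicate padding (independent of the package's vectorised route).
bf_laplacian <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  at <- function(y, x) m[min(max(y, 1), nr), min(max(x, 1), nc)]
  for (y in seq_len(nr)) for (x in seq_len(nc))
    out[y, x] <- at(y - 1, x) + at(y + 1, x) + at(y, x - 1) + at(y, x + 1) -
      4 * m[y, x]
  out
}

# Explicit-sum distance formulas (independent of stats::dist / stats::cor).
bf_distance <- function(v, metric) {
  n <- nrow(v)
  d <- matrix(0, n, n)
  pear <- function(a, b) {
    am <- sum(a) / length(a); bm <- sum(b) / length(b)
    num <- sum((a - am) * (b - bm))
    num / sqrt(sum((a - am)^2) * sum((b - bm)^2))
  }
  zscore <- function(a) (a - mean(a)) / sqrt(sum((a - mean(a))^2) / (length(a) - 1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- v[i, ]; b <- v[j, ]
    d[i, j] <- switch(metric,
      pearson = 1 - pear(a, b),
      euclidean = sqrt(sum((a - b)^2)),
      manhattan = sum(abs(a - b)),
      chebychev = max(abs(a - b)),
      normalized_euclidean = sqrt(sum((zscore(a) - zscore(b))^2)))
  }
  diag(d) <- 0
  d
}

# Three distinct response waveforms (sustained ON, OFF with rebound,
# synchronous spontaneous spikes) with `members` noisy copies each.
planted_trace_groups <- function(seed, members = 4, n_frames = 120, snr = 5) {
  set.seed(seed)
  stim <- 40:80
  t_on <- numeric(n_frames); t_on[stim] <- 1
  t_off <- numeric(n_frames); t_off[stim] <- -0.5
  t_off[(max(stim) + 1):(max(stim) + 20)] <- exp(-(0:19) / 5)
  t_sp <- numeric(n_frames)
  for (s in c(10, 25, 95, 110)) {
    idx <- s:n_frames
    t_sp[idx] <- t_sp[idx] + exp(-(idx - s) / 5)
  }
  tmpl <- rbind(t_on, t_off, t_sp)
  v <- tmpl[rep(1:3, each = members), ]
  noise_sd <- max(abs(tmpl)) / snr
  v <- v + matrix(rnorm(length(v), 0, noise_sd), nrow(v), ncol(v))
  list(traces = trace_matrix(v), truth = rep(1:3, each = members),
       templates = tmpl)
}

# Do two label vectors describe the same partition (ignoring label names)?
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Small blobby reference frame for registration fixtures.
blobby_frame <- function(seed, size = 64, n = 6) {
  sc <- scene_spec(width = size, height = size, n_blobs = n,
                   brightness = c(60, 300), background = "constant",
                   background_range = c(10, 10), noise_sd = 0, seed = seed)
  make_blob_image(sc)$image$data
}

# Standard arc-border laminar fixture with planted depths.
arc_fixture <- function(depths, seed = 5) {
  borders <- list(type = "arc", centre = c(64, 230), r0 = 190, r100 = 140,
                  theta = c(-1.87, -1.27), n_points = 100)
  make_layered_scene(borders, depths,
                     scene_spec(width = 128, height = 128,
                                brightness = c(50, 200),
                                background = "constant",
                                background_range = c(0, 0),
                                noise_sd = 0.3, seed = seed))
}

# Depths recovered by the full laminar path for a layered-scene fixture.
recover_depths <- function(ls, span = 0.1, m = 8 * 128, swap = FALSE) {
  c0 <- smooth_contour(resample_contour(ls$c0, m), span)
  c100 <- smooth_contour(resample_contour(ls$c100, m), span)
  ori <- if (swap) orient_contours(c100, c0) else orient_contours(c0, c100)
  fam <- isocontour_family(ori$c0, ori$c100)
  com <- centres_of_mass(ls$truth$mask, ls$image)
  assign_positions(fam, com)
}
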