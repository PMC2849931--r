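test_that("background subtraction removes planted per-frame offsets", {
  base <- blobby_frame(31, size = 32, n = 3)
  nt <- 12
  offsets <- 5 * sin(seq_len(nt)) + 20          # time-varying offset c(t)
  a <- array(0, c(32, 32, nt))
  for (t in seq_len(nt)) a[, , t] <- base + offsets[t]
  bg <- c(1, 8, 1, 8)  # corner rectangle away from the blobs
  st <- subtract_background(image_stack(a), bg)
  lv <- attr(st, "background_levels")
  expect_equal(lv, offsets + mean(base[1:8, 1:8]))
  # residual background mean is 0 at every frame
  for (t in c(1, 6, 12))
    expect_equal(mean(st$data[1:8, 1:8, t]), 0, tolerance = 1e-12)
  expect_equal(st$stage, "background_corrected")
  # single-pixel region subtracts that pixel's value
  st1 <- subtract_background(image_stack(a), cbind(x = 2, y = 3))
  expect_equal(attr(st1, "background_levels"), a[3, 2, ])
  expect_error(subtract_background(image_stack(a), matrix(FALSE, 32, 32)),
               "at least one")
})

test_that("trace extraction averages ROI pixels per frame", {
  labels <- matrix(1L, 8, 8)
  labels[2:3, 2:3] <- -1L
  labels[6, 6] <- -2L
  mask <- structure(list(labels = labels, n_rois = 2L,
                         roi_areas = c(4L, 1L)), class = "roi_mask")
  a <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  tm <- extract_traces(image_stack(a, frame_interval = 0.5), mask)
  for (t in 1:5) {
    expect_equal(tm[1, t], mean(a[2:3, 2:3, t]))
    expect_equal(tm[2, t], a[6, 6, t])
  }
  expect_equal(attr(tm, "frame_interval"), 0.5)
  expect_equal(attr(tm, "stage"), "raw")
  # uniform ROI of constant value -> flat trace at that value
  b <- array(3, c(8, 8, 4))
  expect_equal(unclass(extract_traces(image_stack(b), mask))[1, ],
               rep(3, 4), ignore_attr = TRUE)
  # whole-frame ROI equals the spatial mean oracle
  whole <- structure(list(labels = matrix(-1L, 8, 8), n_rois = 1L,
                          roi_areas = 64L), class = "roi_mask")
  tmw <- extract_traces(image_stack(a), whole)
  expect_equal(as.vector(tmw[1, ]), apply(a, 3, mean))
  # degenerate: empty mask gives an empty matrix, no failure
  none <- structure(list(labels = matrix(1L, 8, 8), n_rois = 0L,
                         roi_areas = integer()), class = "roi_mask")
  expect_equal(nrow(extract_traces(image_stack(a), none)), 0L)
  expect_error(extract_traces(image_stack(a), whole2 <- structure(
    list(labels = matrix(1L, 4, 4), n_rois = 0L, roi_areas = integer()),
    class = "roi_mask")), "match")
})

test_that("histogram-mode baseline follows the 1 + log2 N bin rule", {
  set.seed(10)
  b <- baseline_f0(rnorm(1024))
  expect_equal(b$n_bins, 11L)           # 1 + log2(1024)
  expect_equal(baseline_f0(rnorm(500))$n_bins, 10L)  # ceiling(9.97)
  # constant trace degenerates to a single bin at that value
  bc <- baseline_f0(rep(7.3, 50))
  expect_equal(bc$f0, 7.3)
  expect_equal(bc$n_bins, 1L)
  expect_error(baseline_f0(5), "2 points")
})

test_that("baseline recovers a planted F0 under sparse transients", {
  ok <- 0
  for (s in 1:40) {
    set.seed(s)
    tr <- 100 + rnorm(500, 0, 2)
    act <- sample(500, 100)  # 20% duty cycle
    tr[act] <- tr[act] + 50 * runif(100, 0.5, 1)
    b <- baseline_f0(tr)
    ok <- ok + (abs(b$f0 - 100) <= b$bin_width)
  }
  expect_gte(ok, 38)
})

test_that("baseline overestimates F0 at high activity duty cycles", {
  set.seed(3)
  tr <- 100 + rnorm(500, 0, 2)
  act <- sample(500, 350)  # 70% duty
  tr[act] <- tr[act] + 50
  b <- baseline_f0(tr)
  expect_gt(b$f0, 110)  # mode sits in the response, not the baseline
})

test_that("modal ties break toward the lower-valued bin", {
  # two exactly equal peaks in bins 1 and 4 of a 4-bin histogram (N = 8)
  tr <- c(0, 0, 0, 4, 4, 4, 1.5, 2.5)
  b <- baseline_f0(tr)
  expect_equal(b$n_bins, 4L)
  expect_equal(b$f0, 0.5)  # centre of the lower bin [0, 1)
})

test_that("dF/F normalisation matches the element-wise formula", {
  set.seed(5)
  v <- matrix(rnorm(3 * 200, 100, 5), 3)
  tm <- trace_matrix(v, stage = "background_corrected")
  d <- dff(tm)
  f0 <- attr(d, "f0")
  for (r in 1:3)
    expect_equal(as.vector(d[r, ]), (v[r, ] - f0$f0[r]) / f0$f0[r])
  expect_equal(attr(d, "stage"), "dff")
  # flat trace at F0 -> all-zero; doubling step -> 0 -> 1
  flat <- trace_matrix(matrix(4, 1, 100), stage = "background_corrected")
  expect_true(all(dff(flat) == 0))
  step <- trace_matrix(matrix(c(rep(10, 80), rep(20, 20)), 1),
                       stage = "background_corrected")
  ds <- dff(step)
  f0s <- attr(ds, "f0")$f0[1]
  expect_lte(abs(f0s - 10), attr(ds, "f0")$f0[1] / 8)  # mode sits in the low bin
  expect_equal(ds[1, 100] - ds[1, 1], 10 / f0s)        # step of one baseline
  expect_equal(ds[1, 100] - ds[1, 1], 1, tolerance = 0.15)
  # stage discipline: raw traces must be corrected first
  expect_error(dff(trace_matrix(v, stage = "raw")), "background_corrected")
  expect_error(dff(d), "background_corrected")
})

test_that("zero baselines flag their row NaN and warn, others proceed", {
  v <- rbind(rep(0, 50), rnorm(50, 10))
  tm <- trace_matrix(v, stage = "background_corrected")
  expect_warning(d <- dff(tm), "F0 = 0")
  expect_true(all(is.nan(d[1, ])))
  expect_false(anyNA(d[2, ]))
})

test_that("dF/F is invariant to multiplicative gain", {
  set.seed(6)
  v <- matrix(rnorm(2 * 300, 50, 3), 2)
  d1 <- dff(trace_matrix(v, stage = "background_corrected"))
  d2 <- dff(trace_matrix(5 * v, stage = "background_corrected"))
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
})

test_that("trace CSVs round-trip values, ids and timing", {
  set.seed(9)
  tm <- trace_matrix(matrix(rnorm(12), 3), roi_ids = c(2L, 5L, 9L),
                     frame_interval = 0.25, stage = "dff")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(tm, csv)
  tm2 <- read_traces_csv(csv, stage = "dff")
  expect_equal(unclass(tm2), unclass(tm), ignore_attr = TRUE)
  expect_equal(attr(tm2, "roi_ids"), c(2L, 5L, 9L))
  expect_equal(attr(tm2, "frame_interval"), 0.25)
})
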