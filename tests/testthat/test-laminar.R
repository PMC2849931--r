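test_that("contours validate and deduplicate consecutive points", {
  expect_error(contour_points(1, 1), "at least 2")
  expect_error(contour_points(c(0, NA), c(0, 1)), "finite")
  ct <- contour_points(c(0, 0, 1), c(0, 0, 1))  # consecutive duplicate dropped
  expect_equal(nrow(ct), 2L)
  expect_error(contour_points(c(2, 2), c(3, 3)), "degenerate")
})

test_that("arc-length resampling spaces points uniformly", {
  seg <- contour_points(c(0, 10), c(0, 0))
  r <- resample_contour(seg, 11)
  expect_equal(r$x, 0:10)
  expect_equal(r$y, rep(0, 11))
  # L-shaped polyline vs cumulative-arc-length oracle
  L <- contour_points(c(0, 4, 4), c(0, 0, 3))  # total length 7
  r2 <- resample_contour(L, 8)                 # spacing 1
  s <- seq(0, 7, by = 1)
  oracle <- t(vapply(s, function(si)
    if (si <= 4) c(si, 0) else c(4, si - 4), numeric(2)))
  expect_equal(cbind(r2$x, r2$y), oracle, ignore_attr = TRUE)
  # endpoints preserved
  expect_equal(unlist(r2[8, ]), c(x = 4, y = 3))
  expect_error(resample_contour(seg, 1), ">= 2")
})

test_that("LOWESS smoothing attenuates zig-zag noise but keeps straight lines", {
  x <- seq(0, 100, length.out = 201)
  straight <- contour_points(x, 0.5 * x + 3)
  sm <- smooth_contour(straight, 0.2)
  expect_equal(sm$y, straight$y, tolerance = 1e-8)
  expect_equal(sm$x, straight$x, tolerance = 1e-8)
  zig <- contour_points(x, 0.5 * x + rep(c(1, -1), length.out = 201))
  smz <- smooth_contour(zig, 0.2)
  expect_lt(max(abs(smz$y - (0.5 * smz$x))), 0.3)
  # degenerate window: returned unchanged with a warning
  expect_warning(out <- smooth_contour(contour_points(0:9, rep(0, 10)), 0.05),
                 "fewer than 3")
  expect_equal(out$x, 0:9)
})

test_that("border orientation reverses an anti-parallel second contour", {
  c0 <- resample_contour(contour_points(c(0, 10), c(0, 0)), 20)
  c100 <- resample_contour(contour_points(c(0, 10), c(5, 5)), 20)
  ori <- orient_contours(c0, c100)
  expect_false(ori$reversed)
  expect_equal(ori$c100$x, c100$x)
  rev100 <- contour_points(rev(c100$x), rev(c100$y))
  ori2 <- orient_contours(c0, rev100)
  expect_true(ori2$reversed)
  expect_equal(ori2$c100$x, c100$x)
  # pairing segments of oriented smooth borders never cross
  set.seed(2)
  th <- seq(-1.8, -1.3, length.out = 40)
  a <- contour_points(50 + 90 * cos(th), 180 + 90 * sin(th))
  b <- contour_points(50 + 60 * cos(rev(th)), 180 + 60 * sin(rev(th)))
  o <- orient_contours(resample_contour(a, 50), resample_contour(b, 50))
  segs <- cbind(o$c0$x, o$c0$y, o$c100$x, o$c100$y)
  crosses <- function(p, q) {
    ccw <- function(ax, ay, bx, by, cx, cy)
      (cy - ay) * (bx - ax) > (by - ay) * (cx - ax)
    ccw(p[1], p[2], q[1], q[2], q[3], q[4]) !=
      ccw(p[3], p[4], q[1], q[2], q[3], q[4]) &&
      ccw(p[1], p[2], p[3], p[4], q[1], q[2]) !=
      ccw(p[1], p[2], p[3], p[4], q[3], q[4])
  }
  for (i in seq(1, 41, by = 8)) for (j in seq(5, 49, by = 8))
    if (i != j) expect_false(crosses(segs[i, ], segs[j, ]))
})

test_that("the isocontour family has 99 + 2 contours and exact endpoints", {
  c0 <- resample_contour(contour_points(c(0, 100), c(0, 0)), 101)
  c100 <- resample_contour(contour_points(c(0, 100), c(100, 100)), 101)
  fam <- isocontour_family(c0, c100)
  expect_equal(length(fam$indices), 103L)
  expect_equal(sum(fam$indices >= 1 & fam$indices <= 99), 99L)  # between borders
  expect_equal(sum(fam$indices %in% c(-1L, 101L)), 2L)          # extrapolated
  expect_equal(get_isocontour(fam, 0)$y, c0$y)
  expect_equal(get_isocontour(fam, 100)$y, c100$y)
  # straight borders at y = 0 and y = 100: Ci is the line y = i
  for (i in c(-1, 7, 50, 101))
    expect_equal(get_isocontour(fam, i)$y, rep(i, 101))
  expect_error(isocontour_family(c0, resample_contour(c100, 50)),
               "same number")
})

test_that("centre of mass implements brightness weighting", {
  labels <- matrix(1L, 8, 8)
  labels[1:4, 1:4] <- -1L
  labels[3, 7] <- -2L
  labels[5, 1:2] <- -3L
  mask <- structure(list(labels = labels, n_rois = 3L,
                         roi_areas = c(16L, 1L, 2L)), class = "roi_mask")
  w <- matrix(1, 8, 8)
  # uniform square ROI: geometric centroid
  cm <- centre_of_mass(mask, w, 1)
  expect_equal(c(cm$x, cm$y), c(2.5, 2.5))
  # single-pixel ROI: that pixel
  cm2 <- centre_of_mass(mask, w, 2)
  expect_equal(c(cm2$x, cm2$y), c(7, 5 - 2))
  # masses 1 and 3 at x = 1, 2: weighted x = (1*1 + 2*3) / 4 = 1.75
  w3 <- w; w3[5, 1] <- 1; w3[5, 2] <- 3
  cm3 <- centre_of_mass(mask, w3, 3)
  expect_equal(cm3$x, 1.75)
  expect_equal(cm3$y, 5)
  # zero total mass: unweighted centroid with a warning
  w0 <- w; w0[1:4, 1:4] <- 0
  expect_warning(cmz <- centre_of_mass(mask, w0, 1), "zero total mass")
  expect_equal(c(cmz$x, cmz$y), c(2.5, 2.5))
  expect_error(centre_of_mass(mask, w, 9), "does not exist")
})

test_that("positions snap to the nearest isocontour index", {
  c0 <- resample_contour(contour_points(c(0, 100), c(0, 0)), 801)
  c100 <- resample_contour(contour_points(c(0, 100), c(100, 100)), 801)
  fam <- isocontour_family(c0, c100)
  pos <- assign_positions(fam, data.frame(x = c(50, 50, 50, 50),
                                          y = c(0, 37.2, 101.4, 108)))
  expect_equal(pos$depth_percent, c(0L, 37L, 101L, 101L))
  expect_equal(pos$distance_px[1], 0)
})

test_that("planted depths are recovered within 2 points on curved layers", {
  ls <- arc_fixture(c(10, 30, 50, 70, 90))
  pos <- recover_depths(ls)
  expect_true(all(abs(pos$depth_percent -
                        ls$truth$centres$depth_percent) <= 2))
  # swapping the border roles maps every depth d to 100 - d exactly
  pos_sw <- recover_depths(ls, swap = TRUE)
  expect_identical(pos_sw$depth_percent, 100L - pos$depth_percent)
  # out-of-layer terminals bin to the extrapolated -1 / 101 contours
  ls2 <- arc_fixture(c(-1, 101), seed = 8)
  pos2 <- recover_depths(ls2)
  expect_identical(sort(pos2$depth_percent), c(-1L, 101L))
})

test_that("depth assignment is invariant under rigid scene rotation", {
  c0 <- resample_contour(contour_points(c(0, 60), c(0, 0)), 301)
  c100 <- resample_contour(contour_points(c(0, 60), c(40, 40)), 301)
  centres <- data.frame(x = c(10, 30, 50), y = c(8, 22, 35))
  pos <- assign_positions(isocontour_family(c0, c100), centres)
  th <- 0.7
  rot <- function(df) data.frame(
    x = cos(th) * df$x - sin(th) * df$y + 15,
    y = sin(th) * df$x + cos(th) * df$y - 4)
  rc <- function(ct) { r <- rot(ct); contour_points(r$x, r$y) }
  pos_rot <- assign_positions(isocontour_family(rc(c0), rc(c100)),
                              rot(centres))
  expect_identical(pos_rot$depth_percent, pos$depth_percent)
})

test_that("polarity classification follows the windowed z-score rule", {
  pre <- 1:20; stim <- 25:45; post <- 46:60
  base <- function() rnorm(60, 0, 0.02)
  set.seed(7)
  flat <- classify_polarity(base(), pre, stim, post)
  expect_equal(flat$class, "NONRESPONSIVE")
  on <- base(); on[stim] <- on[stim] + 1
  expect_equal(classify_polarity(on, pre, stim, post)$class, "ON")
  off <- base(); off[stim] <- off[stim] - 0.5
  expect_equal(classify_polarity(off, pre, stim, post)$class, "OFF")
  # rebound-only OFF: no dip but strong post-stimulus rise
  reb <- base(); reb[post] <- reb[post] + 1
  expect_equal(classify_polarity(reb, pre, stim, post)$class, "OFF")
  # zero pre-stimulus variance: NONRESPONSIVE with a warning
  const <- rep(1, 60); const[stim] <- 2
  expect_warning(pc <- classify_polarity(const, pre, stim, post),
                 "zero variance")
  expect_equal(pc$class, "NONRESPONSIVE")
  expect_error(classify_polarity(on, 1:2, stim, post), "at least 3")
  expect_error(classify_polarity(on, pre, 20:30, post), "disjoint")
})

test_that("position histograms conserve counts and locate planted layers", {
  set.seed(30)
  n_on <- 40; n_off <- 25
  tab <- data.frame(roi_id = 1:(n_on + n_off),
                    depth_percent = c(round(rnorm(n_on, 70, 2)),
                                      round(rnorm(n_off, 20, 2))),
                    distance_px = 0)
  calls <- data.frame(roi_id = 1:(n_on + n_off),
                      polarity = c(rep("ON", n_on), rep("OFF", n_off)))
  h_all <- position_histogram(tab, calls, "ALL")
  expect_equal(sum(h_all$count), n_on + n_off)
  h_on <- position_histogram(tab, calls, "ON")
  h_off <- position_histogram(tab, calls, "OFF")
  expect_equal(sum(h_on$count), n_on)
  expect_equal(sum(h_off$count), n_off)
  mode_centre <- function(h) mean(unlist(h[which.max(h$count), 1:2]))
  expect_lte(abs(mode_centre(h_on) - 70), 5)
  expect_lte(abs(mode_centre(h_off) - 20), 5)
  # empty class: all-zero histogram
  none <- position_histogram(tab, data.frame(roi_id = 1, polarity = "ON")[0, ],
                             "OFF")
  expect_true(all(none$count == 0))
})

test_that("contour CSVs round-trip", {
  ct <- contour_points(c(0, 3.5, 9), c(1, 2, 2.5))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_contour_csv(ct, csv)
  ct2 <- read_contour_csv(csv)
  expect_equal(ct2$x, ct$x)
  expect_equal(ct2$y, ct$y)
})
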