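test_that("Laplacian matches its kernel definition on simple inputs", {
  # constant image: all derivatives vanish
  lap <- laplacian(matrix(5, 8, 8))
  expect_equal(lap$data, matrix(0, 8, 8))
  expect_equal(lap$sd, 0)
  # single bright pixel: -4b at the pixel, +b at its 4 neighbours
  m <- matrix(0, 9, 9); m[5, 5] <- 3
  lap <- laplacian(m)
  expect_equal(lap$data[5, 5], -12)
  expect_equal(lap$data[4, 5], 3)
  expect_equal(lap$data[6, 5], 3)
  expect_equal(lap$data[5, 4], 3)
  expect_equal(lap$data[5, 6], 3)
  expect_equal(lap$data[4, 4], 0)
  expect_error(laplacian(matrix(0, 2, 5)), "3x3")
})

test_that("Laplacian equals brute-force second differences on random images", {
  for (s in 1:25) {
    set.seed(s)
    m <- matrix(rnorm(256, 50, 30), 16, 16)
    lap <- laplacian(m)
    expect_equal(lap$data, bf_laplacian(m), tolerance = 1e-12)
    expect_equal(lap$sd, sd(as.vector(bf_laplacian(m))))
  }
})

test_that("thresholding includes exactly the pixels at or below k * SD", {
  set.seed(2)
  lap <- laplacian(matrix(rnorm(400, 0, 10), 20, 20))
  b <- threshold_laplacian(lap, -2.2)
  expect_identical(matrix(b, nrow(b)), lap$data <= -2.2 * lap$sd)
  expect_equal(attr(b, "threshold"), -2.2 * lap$sd)
  # constant image: sd = 0 and nothing is strictly below 0
  expect_false(any(threshold_laplacian(laplacian(matrix(1, 5, 5)), -2)))
  expect_error(threshold_laplacian(lap, 0.5), "< 0")
  expect_error(detection_params(k = 1), "negative")
})

test_that("segmentation numbers components in raster order and filters size", {
  b <- matrix(FALSE, 10, 12)
  b[2:3, 2:3] <- TRUE        # first in raster order
  b[6:8, 7:9] <- TRUE        # second
  mk <- segment_rois(b, min_size = 0, connectivity = 8)
  expect_equal(mk$n_rois, 2L)
  expect_true(all(mk$labels[2:3, 2:3] == -1L))
  expect_true(all(mk$labels[6:8, 7:9] == -2L))
  expect_equal(mk$roi_areas, c(4L, 9L))
  # min-size filter drops the 3-px blob and renumbers from 1
  b2 <- matrix(FALSE, 8, 8)
  b2[1:3, 1] <- TRUE                   # 3 px
  b2[5:7, 5:7] <- TRUE                 # 9 px
  mk2 <- segment_rois(b2, min_size = 5, connectivity = 8)
  expect_equal(mk2$n_rois, 1L)
  expect_true(all(mk2$labels[5:7, 5:7] == -1L))
  # all-false input: background-only mask
  mk0 <- segment_rois(matrix(FALSE, 4, 4))
  expect_equal(mk0$n_rois, 0L)
  expect_true(all(mk0$labels == 1L))
})

test_that("4- and 8-connectivity differ exactly on diagonal touches", {
  b <- matrix(FALSE, 6, 6)
  b[2, 2] <- TRUE; b[3, 3] <- TRUE
  expect_equal(segment_rois(b, connectivity = 8)$n_rois, 1L)
  expect_equal(segment_rois(b, connectivity = 4)$n_rois, 2L)
})

test_that("mask encoding invariant holds on detected fixtures", {
  for (s in c(1, 7)) {
    sc <- make_blob_image(scene_spec(width = 96, height = 96, n_blobs = 6,
                                     seed = s))
    mk <- detect_rois(sc$image, detection_params(k = -2, min_size = 4))
    vals <- sort(unique(as.vector(mk$labels)))
    expect_identical(vals, sort(c(1L, -seq_len(mk$n_rois))))
    expect_true(all(mk$roi_areas >= 1L))
    expect_equal(mk$n_rois, length(mk$roi_areas))
  }
})

test_that("detection is invariant to affine intensity rescaling", {
  sc <- make_blob_image(scene_spec(width = 96, height = 96, n_blobs = 8,
                                   seed = 13))
  p <- detection_params(k = -2, min_size = 4)
  m1 <- detect_rois(sc$image, p)
  m2 <- detect_rois(3.7 * sc$image$data + 120, p)
  expect_identical(m1$labels, m2$labels)
})

test_that("threshold monotonicity: looser k includes every stricter pixel", {
  sc <- make_blob_image(scene_spec(width = 96, height = 96, n_blobs = 8,
                                   seed = 4))
  lap <- laplacian(sc$image)
  b_strict <- threshold_laplacian(lap, -3)
  b_loose <- threshold_laplacian(lap, -1.5)
  expect_true(all(b_loose[b_strict]))
})

test_that("Laplacian detection recovers blobs over a 10x brightness range", {
  sc <- make_blob_image(scene_spec(seed = 2))  # 20 blobs, gradient background
  mk <- detect_rois(sc$image, detection_params(k = -2, min_size = 4))
  res <- match_planted(mk, sc$truth$mask)
  expect_gte(res$recall, 0.95)
  expect_false(res$merged)
})

test_that("a blank noise scene yields at most one spurious ROI at k = -4", {
  sc <- make_blob_image(scene_spec(n_blobs = 0, noise_sd = 2, seed = 6))
  mk <- detect_rois(sc$image, detection_params(k = -4, min_size = 4))
  expect_lte(mk$n_rois, 1L)
})

test_that("high-res path recovers a plateau blob missed directly", {
  # flat-topped blob: top-hat of radius 6 on a 96x96 field, mild noise
  set.seed(8)
  m <- matrix(rnorm(96 * 96, 0, 0.5), 96, 96)
  X <- matrix(1:96, 96, 96, byrow = TRUE); Y <- t(X)
  plateau <- (X - 48)^2 + (Y - 48)^2 <= 36
  m[plateau] <- m[plateau] + 50
  p <- detection_params(k = -2, min_size = 4)
  direct <- detect_rois(m, p)
  covers_centre <- function(mk) mk$n_rois > 0 && mk$labels[48, 48] < 0
  expect_false(covers_centre(direct))  # only edges respond
  hi <- detect_rois_highres(m, sigma = 3, factor = 4, params = p)
  expect_true(covers_centre(hi))
  # shape contract and no-interpolation guarantee
  expect_identical(dim(hi$labels), dim(m))
  low <- detect_rois(block_down <- roiscope:::block_downsample(
    roiscope:::gaussian_blur(m, 3), 4), p)
  expect_true(all(unique(as.vector(hi$labels)) %in%
                    unique(as.vector(low$labels))))
  expect_error(detect_rois_highres(m, sigma = 3, factor = 1, params = p),
               "factor")
})

test_that("masks round-trip through TIFF + sidecar CSV export", {
  sc <- make_blob_image(scene_spec(width = 96, height = 96, n_blobs = 6,
                                   seed = 3))
  mk <- detect_rois(sc$image, detection_params(k = -2, min_size = 4))
  tif <- withr::local_tempfile(fileext = ".tif")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_roi_mask(mk, tif, csv)
  mk2 <- read_roi_mask(tif)
  expect_identical(mk2$labels, mk$labels)
  expect_identical(mk2$n_rois, mk$n_rois)
  side <- read.csv(csv)
  expect_equal(nrow(side), mk$n_rois)
  expect_equal(side$area_px, mk$roi_areas)
})
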