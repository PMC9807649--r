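test_that("gradient field matches hand-computed Sobel responses on ramps", {
  const <- gradient_field(matrix(0.5, 8, 8))
  expect_true(all(const$magnitude == 0))
  expect_true(all(const$orientation == 0))

  hram <- gradient_field(outer(1:10, 1:12, function(i, j) j))
  expect_true(all(hram$a == 8))
  expect_true(all(hram$b == 0))
  expect_true(all(hram$magnitude == 8))
  expect_true(all(hram$orientation == 0))

  vram <- gradient_field(outer(1:10, 1:12, function(i, j) i))
  expect_true(all(vram$a == 0))
  expect_true(all(abs(vram$b) == 8))
  expect_true(all(abs(vram$orientation) == pi / 2))

  expect_error(gradient_field(matrix(0, 2, 5)), "3x3")
})

test_that("gradient field agrees with the per-pixel loop oracle and scales with contrast", {
  set.seed(21)
  img <- matrix(runif(20 * 16), 20, 16)
  g <- gradient_field(img)
  o <- oracle_sobel(img)
  expect_equal(g$a, o$a, tolerance = 1e-12)
  expect_equal(g$b, o$b, tolerance = 1e-12)

  g2 <- gradient_field(3 * img)
  expect_equal(g2$magnitude, 3 * g$magnitude, tolerance = 1e-12)
})

test_that("HOG tiling, zero-image and ramp behavior follow the construction", {
  # (d*m) x (d*n) image -> m*n cells, here 3*4 = 12 cells of 8x8
  v <- hog_feature(matrix(runif(24 * 32), 24, 32))
  # blocks: (3-1)*(4-1) sliding 2x2-cell blocks, 4 cells * 9 bins each
  expect_equal(v$K, 6 * 4 * 9)

  zero <- hog_feature(matrix(0.7, 24, 32))
  expect_true(all(zero$values == 0))

  # horizontal ramp: all gradient mass at theta = 0 -> first bin of each cell
  ramp <- hog_feature(outer(1:16, 1:16, function(i, j) j / 16),
                      cell_size = 8, n_bins = 9, block_shape = c(1, 1))
  mass <- matrix(ramp$values, nrow = 9)
  expect_true(all(mass[1, ] > 0))
  expect_true(all(mass[-1, ] == 0))

  expect_error(hog_feature(matrix(0, 4, 4), cell_size = 8), "smaller")
})

test_that("Harris and Min-Eigen responses match the eigenvalue oracle exactly", {
  set.seed(31)
  img <- matrix(runif(24 * 24), 24, 24)
  oracle <- oracle_structure_responses(img)

  hk <- harris_keypoints(img, threshold = 0.5)
  ok <- oracle_nms(oracle$harris, 0.5, border = 3)
  expect_equal(unname(hk$points), unname(ok))

  mk <- min_eigen_keypoints(img, threshold = 0.5)
  om <- oracle_nms(oracle$mineigen, 0.5, border = 3)
  expect_equal(unname(mk$points), unname(om))
})

test_that("corner detectors find the corners of a bright square", {
  img <- matrix(0, 48, 48)
  img[15:34, 15:34] <- 1
  true_corners <- rbind(c(15, 15), c(15, 34), c(34, 15), c(34, 34))
  near_truth <- function(pts) {
    vapply(seq_len(nrow(true_corners)), function(k)
      any(abs(pts[, 1] - true_corners[k, 1]) <= 2 &
            abs(pts[, 2] - true_corners[k, 2]) <= 2), TRUE)
  }
  expect_true(all(near_truth(harris_keypoints(img)$points)))
  expect_true(all(near_truth(min_eigen_keypoints(img)$points)))
})

test_that("detector responses behave as the theory requires", {
  flat <- matrix(0.3, 32, 32)
  expect_equal(nrow(harris_keypoints(flat)$points), 0L)
  expect_equal(nrow(min_eigen_keypoints(flat)$points), 0L)
  expect_equal(nrow(fast_keypoints(flat)$points), 0L)
  expect_true(all(abs(hessian_response(flat)$response) < 1e-12))

  # min-eigen response never exceeds the larger eigenvalue
  set.seed(41)
  img <- matrix(runif(30 * 30), 30, 30)
  o <- oracle_structure_responses(img)
  expect_true(all(o$mineigen <= o$maxeigen + 1e-12))

  # raising the threshold never increases the number of detections
  n_lo <- nrow(harris_keypoints(img, threshold = 0.01)$points)
  n_hi <- nrow(harris_keypoints(img, threshold = 1)$points)
  expect_lte(n_hi, n_lo)
})

test_that("detectors are invariant to adding a constant intensity offset", {
  set.seed(51)
  img <- matrix(runif(32 * 32, 0, 0.6), 32, 32)
  shifted <- img + 0.3
  expect_equal(harris_keypoints(img)$points,
               harris_keypoints(shifted)$points)
  expect_equal(fast_keypoints(img, threshold = 0.15)$points,
               fast_keypoints(shifted, threshold = 0.15)$points)
  expect_equal(hessian_response(img)$response,
               hessian_response(shifted)$response, tolerance = 1e-10)
})

test_that("FAST agrees with the exhaustive circle-segment oracle", {
  # single bright pixel: the pixel itself sees an all-darker circle (corner),
  # but its 8 neighbours see a flat circle and are not corners
  spot <- matrix(0, 16, 16)
  spot[8, 8] <- 1
  det <- fast_keypoints(spot, threshold = 0.5, n_contig = 12)
  expect_true(any(det$points[, 1] == 8 & det$points[, 2] == 8))
  adjacent <- det$points[, 1] %in% 7:9 & det$points[, 2] %in% 7:9 &
    !(det$points[, 1] == 8 & det$points[, 2] == 8)
  expect_false(any(adjacent))

  set.seed(61)
  img <- matrix(runif(24 * 24), 24, 24)
  for (N in c(9L, 12L)) {
    det <- fast_keypoints(img, threshold = 0.12, n_contig = N)
    orc <- oracle_fast(img, 0.12, N)
    expect_equal(unname(det$points[order(det$points[, 1], det$points[, 2]), ,
                                   drop = FALSE]),
                 unname(orc[order(orc[, 1], orc[, 2]), , drop = FALSE]))
  }

  # stricter contiguity only removes detections
  d16 <- fast_keypoints(img, threshold = 0.05, n_contig = 16)
  d9 <- fast_keypoints(img, threshold = 0.05, n_contig = 9)
  key <- function(p) paste(p[, 1], p[, 2])
  expect_true(all(key(d16$points) %in% key(d9$points)))

  expect_error(fast_keypoints(img, n_contig = 17), "\\[1, 16\\]")
})

test_that("Hessian response is positive on blobs, negative on saddles, and matches its oracle", {
  xs <- outer(rep(1, 41), -20:20); ys <- t(xs)
  blob <- exp(-(xs^2 + ys^2) / (2 * 4^2))
  hr <- hessian_response(blob)
  expect_gt(hr$response[21, 21], 0)
  # blob center is among the detected maxima
  expect_true(any(hr$keypoints$points[, 1] == 21 &
                    hr$keypoints$points[, 2] == 21))

  saddle <- xs * ys / 400
  hs <- hessian_response(saddle)
  expect_lt(hs$response[21, 21], 0)

  set.seed(71)
  img <- matrix(runif(20 * 20), 20, 20)
  expect_equal(hessian_response(img, sigma = 1.2, w = 0.9)$response,
               oracle_hessian_response(img, l = 3, w_mix = 0.9),
               tolerance = 1e-10)
})

test_that("keypoint aggregation yields fixed-length conserved vectors", {
  empty <- keypoint_set(matrix(integer(0), ncol = 2), numeric(0),
                        detector_name = "x")
  v0 <- aggregate_keypoints(empty, c(64, 64), grid = c(4, 4))
  expect_equal(v0$K, 32L)
  expect_true(all(v0$values == 0))

  one <- keypoint_set(cbind(3, 5), 2.5, detector_name = "x")
  v1 <- aggregate_keypoints(one, c(64, 64), grid = c(4, 4))
  expect_equal(v1$values[1:2], c(1, 2.5))
  expect_true(all(v1$values[-(1:2)] == 0))

  set.seed(81)
  pts <- cbind(sample(1:64, 20, TRUE), sample(1:64, 20, TRUE))
  kp <- keypoint_set(pts, runif(20), detector_name = "x")
  v <- aggregate_keypoints(kp, c(64, 64), grid = c(4, 4))
  counts <- v$values[seq(1, length(v$values), by = 2)]
  expect_equal(sum(counts), 20)
})

test_that("extract_feature dispatches, keeps K fixed, and supports plug-ins", {
  set.seed(91)
  img1 <- matrix(runif(32 * 32), 32, 32)
  img2 <- matrix(runif(32 * 32), 32, 32)
  expect_equal(extract_feature(img1, "hog")$K, extract_feature(img2, "hog")$K)
  expect_equal(extract_feature(img1, "harris", list(grid = c(3, 3)))$K, 18L)
  expect_equal(extract_feature(img1, "fast")$K, 128L)

  stub <- deep_embedding("stub", function(arr) rep(0.5, 10), K = 10)
  v <- extract_feature(img1, "deep", list(embedding = stub))
  expect_equal(v$values, rep(0.5, 10))
  expect_equal(v$feature_name, "deep_stub")
  expect_error(extract_feature(img1, "deep"), "deep_embedding")

  register_feature_method("rowmeans_test", function(image, config)
    feature_vector(rowMeans(image)[1:4], "rowmeans_test"))
  expect_equal(extract_feature(img1, "rowmeans_test")$values,
               rowMeans(img1)[1:4])
  expect_true("rowmeans_test" %in% feature_methods())
  expect_error(register_feature_method("hog", identity), "built-in")
  expect_error(extract_feature(img1, "no_such_method"), "unknown feature method")
})
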