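# Per-scan feature extraction: image gradients, HOG, and keypoint detectors
# (Harris, minimum-eigenvalue, FAST segment test, determinant-of-Hessian),
# plus the aggregation step that turns keypoints into fixed-length vectors
# and the registry / deep-embedding plug-in surface.

# Sobel derivative kernels, applied as correlation (filter convention):
# a = response to G_x (horizontal derivative, + toward increasing column),
# b = response to G_y (vertical derivative, + toward decreasing row).
sobel_gx <- function() rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
sobel_gy <- function() rbind(c(1, 2, 1), c(0, 0, 0), c(-1, -2, -1))

#' Image gradient field
#'
#' Sobel gradient of a grayscale image: per interior pixel, `a` and `b` are
#' the horizontal/vertical derivative responses of the 3x3 neighbourhood,
#' `magnitude = sqrt(a^2 + b^2)` and `orientation = arctan(b / a)` in
#' `(-pi/2, pi/2]` (with `+/-pi/2` when `a = 0, b != 0`, and `0` when both
#' vanish). Computed on the valid interior only, so all arrays are
#' `(H-2) x (W-2)`.
#'
#' On a unit horizontal ramp `I(i,j) = j` the response is `a = 8, b = 0`
#' everywhere; on a unit vertical ramp `I(i,j) = i` it is `a = 0, b = -8`
#' (intensity increasing downward gives negative `b` under this kernel
#' orientation).
#'
#' @param image Numeric matrix, at least 3x3.
#' @param units `"radians"` (default) or `"degrees"` for the orientation.
#' @return An object of class `gradient_field`: list with `magnitude`,
#'   `orientation`, `a`, `b` (all `(H-2) x (W-2)` matrices) and `units`.
#' @export
gradient_field <- function(image, units = c("radians", "degrees")) {
  assert_image(image)
  units <- match.arg(units)
  if (nrow(image) < 3L || ncol(image) < 3L)
    stopf("image must be at least 3x3 for a Sobel gradient")
  a <- filter2_valid(image, sobel_gx())
  b <- filter2_valid(image, sobel_gy())
  # snap summation-order cancellation residue to an exact zero so flat
  # regions have magnitude 0 and a well-defined orientation
  tol <- 16 * .Machine$double.eps * max(abs(image), 1)
  a[abs(a) < tol] <- 0
  b[abs(b) < tol] <- 0
  theta <- matrix(0, nrow(a), ncol(a))
  nz_a <- a != 0
  theta[nz_a] <- atan(b[nz_a] / a[nz_a])
  vert <- !nz_a & b != 0
  theta[vert] <- sign(b[vert]) * pi / 2
  if (units == "degrees") theta <- theta * 180 / pi
  structure(list(magnitude = sqrt(a^2 + b^2), orientation = theta,
                 a = a, b = b, units = units),
            class = "gradient_field")
}

#' Keypoint set
#'
#' Detector output prior to aggregation: integer pixel coordinates, a scalar
#' response per point and (for scale-aware detectors) a per-point scale.
#'
#' @param points n x 2 integer matrix of (row, col) coordinates.
#' @param responses Numeric response per point.
#' @param scales Numeric scale per point (0 for single-scale detectors).
#' @param detector_name Identifier of the producing detector.
#' @return An object of class `keypoint_set`.
#' @export
keypoint_set <- function(points, responses, scales = NULL,
                         detector_name = "unknown") {
  points <- matrix(as.integer(points), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  n <- nrow(points)
  responses <- as.numeric(responses)
  if (length(responses) != n) stopf("one response per point required")
  if (any(!is.finite(responses))) stopf("responses must be finite")
  if (is.null(scales)) scales <- rep(0, n)
  structure(list(points = points, responses = responses,
                 scales = as.numeric(scales), detector_name = detector_name),
            class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set: %s, %d points>\n", x$detector_name,
              nrow(x$points)))
  invisible(x)
}

empty_keypoints <- function(name)
  keypoint_set(matrix(integer(0), ncol = 2L), numeric(0), numeric(0), name)

#' Histogram-of-oriented-gradients feature
#'
#' The image is tiled into `cell_size x cell_size` cells; each cell
#' accumulates a `n_bins`-bin histogram of gradient orientations weighted by
#' gradient magnitude (unsigned orientations over \[0, 180) degrees by
#' default, signed over \[0, 360) when `signed = TRUE`). Cells are grouped
#' into sliding blocks of `block_shape` cells; each block's concatenated
#' histogram is L2-normalized and the block vectors are concatenated into the
#' final feature, whose length depends only on the image size and
#' configuration.
#'
#' Gradients on the 1-pixel image border are treated as zero so an image of
#' size `(cell_size*m) x (cell_size*n)` yields exactly `m*n` cells.
#'
#' @param image Numeric matrix.
#' @param cell_size Cell side in pixels (default 8).
#' @param n_bins Orientation bins per cell (default 9).
#' @param block_shape Length-2 block size in cells (default `c(2, 2)`);
#'   shrunk to the cell-grid size when the grid is smaller.
#' @param signed Use signed \[0, 360) orientations instead of unsigned.
#' @return A [feature_vector()] named `"hog"`.
#' @export
hog_feature <- function(image, cell_size = 8L, n_bins = 9L,
                        block_shape = c(2L, 2L), signed = FALSE) {
  assert_image(image)
  if (!is_count(cell_size, 1) || !is_count(n_bins, 1))
    stopf("cell_size and n_bins must be positive integers")
  h <- nrow(image); w <- ncol(image)
  if (h < cell_size || w < cell_size)
    stopf("image (%dx%d) smaller than one %dx%d cell", h, w, cell_size, cell_size)
  g <- gradient_field(image)
  mag <- matrix(0, h, w); mag[2:(h - 1), 2:(w - 1)] <- g$magnitude
  if (signed) {
    ang <- matrix(0, h, w)
    ang[2:(h - 1), 2:(w - 1)] <- (atan2(g$b, g$a) * 180 / pi) %% 360
    span <- 360
  } else {
    ang <- matrix(0, h, w)
    ang[2:(h - 1), 2:(w - 1)] <- (g$orientation * 180 / pi) %% 180
    span <- 180
  }
  n_cr <- h %/% cell_size; n_cc <- w %/% cell_size
  bin <- floor(ang / (span / n_bins)) + 1L
  bin[bin > n_bins] <- n_bins
  hist_arr <- array(0, c(n_cr, n_cc, n_bins))
  rows_used <- n_cr * cell_size; cols_used <- n_cc * cell_size
  ci <- (seq_len(rows_used) - 1L) %/% cell_size + 1L
  cj <- (seq_len(cols_used) - 1L) %/% cell_size + 1L
  for (i in seq_len(rows_used)) {
    for (j in seq_len(cols_used)) {
      m <- mag[i, j]
      if (m > 0) {
        b <- bin[i, j]
        hist_arr[ci[i], cj[j], b] <- hist_arr[ci[i], cj[j], b] + m
      }
    }
  }
  bh <- min(block_shape[1], n_cr); bw <- min(block_shape[2], n_cc)
  blocks <- list()
  for (bi in seq_len(n_cr - bh + 1L)) {
    for (bj in seq_len(n_cc - bw + 1L)) {
      v <- as.numeric(hist_arr[bi:(bi + bh - 1L), bj:(bj + bw - 1L), , drop = FALSE])
      blocks[[length(blocks) + 1L]] <- v / sqrt(sum(v^2) + 1e-12)
    }
  }
  feature_vector(unlist(blocks), "hog")
}

# Gaussian window (normalized to sum 1), side `size`, std dev `sigma`.
gaussian_window <- function(size = 5L, sigma = 5 / 3) {
  r <- (size - 1) / 2
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Smoothed structure tensor components (Sxx, Syy, Sxy) at every pixel,
# with gradients zero on the 1-pixel border and zero-padded smoothing.
structure_tensor <- function(image, window_size = 5L, sigma = 5 / 3) {
  h <- nrow(image); w <- ncol(image)
  g <- gradient_field(image)
  ix <- matrix(0, h, w); iy <- matrix(0, h, w)
  ix[2:(h - 1), 2:(w - 1)] <- g$a
  iy[2:(h - 1), 2:(w - 1)] <- g$b
  win <- gaussian_window(window_size, sigma)
  list(Sxx = filter2_same(ix * ix, win),
       Syy = filter2_same(iy * iy, win),
       Sxy = filter2_same(ix * iy, win),
       border = (window_size - 1L) %/% 2L + 1L)
}

# Candidate mask excluding a border band where filter support is incomplete.
interior_mask <- function(h, w, border) {
  m <- matrix(FALSE, h, w)
  if (h > 2 * border && w > 2 * border)
    m[(border + 1L):(h - border), (border + 1L):(w - border)] <- TRUE
  m
}

#' Harris corner detector
#'
#' Smooths the outer product of Sobel gradients with a Gaussian window
#' (default 5x5, sigma = 5/3) into the structure tensor `M` and scores each
#' pixel with the Harris response `det(M) - k * trace(M)^2`. Pixels whose
#' response exceeds `threshold` and that are strict 3x3 local maxima (ties
#' broken toward the lexicographically smallest (row, col)) are returned.
#'
#' @param image Numeric matrix.
#' @param k Eigenvalue-combination constant (default 0.04).
#' @param threshold Response threshold (default 0.01).
#' @param window_size,sigma Gaussian smoothing window parameters.
#' @return A [keypoint_set()] named `"harris"`.
#' @export
harris_keypoints <- function(image, k = 0.04, threshold = 0.01,
                             window_size = 5L, sigma = 5 / 3) {
  assert_image(image)
  if (nrow(image) < window_size || ncol(image) < window_size)
    stopf("image smaller than the %dx%d smoothing window", window_size, window_size)
  st <- structure_tensor(image, window_size, sigma)
  resp <- (st$Sxx * st$Syy - st$Sxy^2) - k * (st$Sxx + st$Syy)^2
  pts <- nms3x3(resp, threshold,
                interior_mask(nrow(image), ncol(image), st$border))
  keypoint_set(pts, resp[pts], detector_name = "harris")
}

#' Minimum-eigenvalue (Shi-Tomasi) corner detector
#'
#' As [harris_keypoints()] but the response is the smaller eigenvalue of the
#' structure tensor rather than the Harris combination.
#'
#' @inheritParams harris_keypoints
#' @param threshold Response threshold on the minimum eigenvalue.
#' @return A [keypoint_set()] named `"mineigen"`.
#' @export
min_eigen_keypoints <- function(image, threshold = 0.01,
                                window_size = 5L, sigma = 5 / 3) {
  assert_image(image)
  if (nrow(image) < window_size || ncol(image) < window_size)
    stopf("image smaller than the %dx%d smoothing window", window_size, window_size)
  st <- structure_tensor(image, window_size, sigma)
  resp <- (st$Sxx + st$Syy) / 2 -
    sqrt(((st$Sxx - st$Syy) / 2)^2 + st$Sxy^2)
  pts <- nms3x3(resp, threshold,
                interior_mask(nrow(image), ncol(image), st$border))
  keypoint_set(pts, resp[pts], detector_name = "mineigen")
}

# The 16 (drow, dcol) offsets of the radius-3 Bresenham circle, clockwise
# from the top pixel (position 1 directly above the center).
fast_circle_offsets <- function() {
  cbind(drow = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3),
        dcol = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1))
}

# Longest circular run of TRUE per pixel across a list of 16 logical
# matrices (one per circle position), capped at 16.
circular_max_run <- function(flags) {
  run <- flags[[1]] * 0
  best <- run
  for (k in c(seq_along(flags), seq_along(flags))) {
    run <- (run + 1) * flags[[k]]
    best <- pmax(best, run)
  }
  pmin(best, length(flags))
}

#' FAST segment-test corner detector
#'
#' A pixel is a corner iff at least `n_contig` contiguous pixels on its
#' 16-pixel radius-3 Bresenham circle are all brighter than the center
#' intensity plus `threshold`, or all darker than the center minus
#' `threshold`. Circle pixels are enumerated clockwise from the top. The
#' response is the classic FAST score: the larger of the summed intensity
#' margins over the bright and dark circle pixels.
#'
#' @param image Numeric matrix (at least 7x7).
#' @param threshold Intensity threshold `t` (same units as the image).
#' @param n_contig Required contiguous arc length `N` in \[1, 16\]
#'   (default 12, the classic segment test).
#' @return A [keypoint_set()] named `"fast"`.
#' @export
fast_keypoints <- function(image, threshold = 0.1, n_contig = 12L) {
  assert_image(image)
  if (!is_count(n_contig, 1) || n_contig > 16L)
    stopf("n_contig must be an integer in [1, 16]")
  h <- nrow(image); w <- ncol(image)
  if (h < 7L || w < 7L) return(empty_keypoints("fast"))
  rows <- 4L:(h - 3L); cols <- 4L:(w - 3L)
  center <- image[rows, cols, drop = FALSE]
  off <- fast_circle_offsets()
  circ <- lapply(seq_len(16L), function(k)
    image[rows + off[k, 1L], cols + off[k, 2L], drop = FALSE])
  bright <- lapply(circ, function(m) m > center + threshold)
  dark <- lapply(circ, function(m) m < center - threshold)
  is_corner <- circular_max_run(bright) >= n_contig |
    circular_max_run(dark) >= n_contig
  idx <- which(is_corner, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_keypoints("fast"))
  score <- matrix(0, nrow(center), ncol(center))
  sb <- matrix(0, nrow(center), ncol(center)); sd <- sb
  for (k in seq_len(16L)) {
    sb <- sb + pmax(0, circ[[k]] - center - threshold)
    sd <- sd + pmax(0, center - threshold - circ[[k]])
  }
  score <- pmax(sb, sd)
  keypoint_set(cbind(idx[, 1L] + 3L, idx[, 2L] + 3L), score[idx],
               detector_name = "fast")
}

# SURF-style box-filter second-derivative kernels with lobe size l
# (l = 3 approximates a Gaussian at sigma = 1.2). Responses are normalized
# by the lobe area so scales are comparable.
hessian_kernels <- function(l) {
  dyy <- rbind(matrix(1, l, 2 * l - 1),
               matrix(-2, l, 2 * l - 1),
               matrix(1, l, 2 * l - 1)) / (l * (2 * l - 1))
  dxy <- matrix(0, 2 * l + 1, 2 * l + 1)
  dxy[1:l, 1:l] <- 1
  dxy[1:l, (l + 2):(2 * l + 1)] <- -1
  dxy[(l + 2):(2 * l + 1), 1:l] <- -1
  dxy[(l + 2):(2 * l + 1), (l + 2):(2 * l + 1)] <- 1
  dxy <- dxy / l^2
  list(dxx = t(dyy), dyy = dyy, dxy = dxy)
}

#' Determinant-of-Hessian blob response (SURF-style)
#'
#' Approximates the Gaussian second derivatives `D_xx`, `D_yy`, `D_xy` at
#' scale `sigma` with box filters (lobe size `3*sigma/1.2`, the SURF
#' convention) and scores each pixel with
#' `det(H) = D_xx * D_yy - (w * D_xy)^2`. Blob-like extrema give positive
#' responses, saddles negative ones. Local maxima above `threshold` are
#' returned as keypoints with scale `sigma`.
#'
#' @param image Numeric matrix.
#' @param sigma Detection scale in pixels (default 1.2, a 9x9 filter).
#' @param w Weight on the mixed derivative (default 0.9, the standard
#'   box-filter correction).
#' @param threshold Response threshold for keypoint extraction (default 0).
#' @return List with `response` (matrix, same size as `image`) and
#'   `keypoints` (a [keypoint_set()] named `"hessian"`).
#' @export
hessian_response <- function(image, sigma = 1.2, w = 0.9, threshold = 0) {
  assert_image(image)
  l <- max(1L, as.integer(round(3 * sigma / 1.2)))
  if (l %% 2L == 0L) l <- l + 1L   # box-filter lobes must be odd-sized
  if (nrow(image) < 3L * l || ncol(image) < 3L * l)
    stopf("image too small for scale sigma = %g (filter lobe %d)", sigma, l)
  ker <- hessian_kernels(l)
  dxx <- filter2_same(image, ker$dxx)
  dyy <- filter2_same(image, ker$dyy)
  dxy <- filter2_same(image, ker$dxy)
  resp <- dxx * dyy - (w * dxy)^2
  # The response is only defined where the filters have full support; the
  # border band (where zero padding leaks in) is set to 0.
  bsup <- max((3L * l - 1L) %/% 2L, l)
  resp <- resp * interior_mask(nrow(image), ncol(image), bsup)
  border <- bsup + 1L
  pts <- nms3x3(resp, threshold,
                interior_mask(nrow(image), ncol(image), border))
  list(response = resp,
       keypoints = keypoint_set(pts, resp[pts],
                                scales = rep(sigma, nrow(pts)),
                                detector_name = "hessian"))
}

#' Fixed-length feature vector
#'
#' The per-scan observation: a length-K numeric vector tagged with the name
#' of the producing method. K is constant across a dataset for a fixed
#' method and configuration.
#'
#' @param values Finite numeric vector.
#' @param feature_name Identifier of the producing method.
#' @return An object of class `feature_vector` with fields `values`,
#'   `feature_name`, `K`.
#' @export
feature_vector <- function(values, feature_name) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stopf("feature values must be finite")
  structure(list(values = values, feature_name = feature_name,
                 K = length(values)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector: %s, K = %d>\n", x$feature_name, x$K))
  invisible(x)
}

#' Aggregate keypoints into a fixed-length vector
#'
#' Overlays a `grid` of equal cells on the image and emits, per cell in
#' row-major order, the pair (keypoint count, sum of responses). The result
#' has length `K = 2 * prod(grid)` regardless of how many keypoints were
#' detected, making detector output usable as a classifier/HMM observation.
#'
#' @param kp A [keypoint_set()].
#' @param image_shape Length-2 `(rows, cols)` of the source image.
#' @param grid Length-2 `(rows, cols)` of aggregation cells (default 8x8).
#' @return A [feature_vector()] named after the detector.
#' @export
aggregate_keypoints <- function(kp, image_shape, grid = c(8L, 8L)) {
  if (!inherits(kp, "keypoint_set")) stopf("kp must be a keypoint_set")
  if (length(grid) != 2L || !all(vapply(grid, is_count, TRUE, min = 1)))
    stopf("grid must be two positive integers")
  gr <- as.integer(grid[1]); gc <- as.integer(grid[2])
  vals <- numeric(2L * gr * gc)
  if (nrow(kp$points) > 0L) {
    ri <- pmin(gr, ceiling(kp$points[, 1L] / (image_shape[1] / gr)))
    ci <- pmin(gc, ceiling(kp$points[, 2L] / (image_shape[2] / gc)))
    cell <- (ri - 1L) * gc + ci
    for (n in seq_along(cell)) {
      base <- (cell[n] - 1L) * 2L
      vals[base + 1L] <- vals[base + 1L] + 1
      vals[base + 2L] <- vals[base + 2L] + kp$responses[n]
    }
  }
  feature_vector(vals, paste0(kp$detector_name, "_grid"))
}

#' Deep-embedding plug-in contract
#'
#' Wraps an external embedding backend (e.g. a pretrained convolutional
#' network's fully connected layer) as a feature method: a deterministic
#' function from a 3-channel image array to a fixed-length numeric vector.
#' Pretrained weights are outside this package; any callable satisfying the
#' contract can be plugged in (a stub suffices for testing the pipeline).
#'
#' @param name Identifier.
#' @param embed Function taking an `h x w x 3` array and returning a numeric
#'   vector of length `K` (same image must give the same vector).
#' @param K Embedding length (e.g. 1000 for an FC-8 layer).
#' @return An object of class `deep_embedding`.
#' @export
deep_embedding <- function(name, embed, K) {
  if (!is.function(embed)) stopf("embed must be a function")
  if (!is_count(K, 1)) stopf("K must be a positive integer")
  structure(list(name = name, embed = embed, K = as.integer(K)),
            class = "deep_embedding")
}

.feature_registry <- new.env(parent = emptyenv())

#' Register a custom feature-extraction method
#'
#' Adds `fn(image, config)` (returning a [feature_vector()]) to the method
#' registry under `name`, making it available to [extract_feature()] and the
#' ranking harness. Built-in methods cannot be overwritten.
#'
#' @param name Method name.
#' @param fn Function `(image, config) -> feature_vector`.
#' @export
register_feature_method <- function(name, fn) {
  if (name %in% builtin_feature_methods())
    stopf("'%s' is a built-in method and cannot be replaced", name)
  if (!is.function(fn)) stopf("fn must be a function")
  assign(name, fn, envir = .feature_registry)
  invisible(name)
}

builtin_feature_methods <- function()
  c("hog", "harris", "mineigen", "fast", "hessian", "deep")

#' List available feature methods
#' @return Character vector of method names (built-ins plus registered
#'   plug-ins).
#' @export
feature_methods <- function()
  c(builtin_feature_methods(), ls(.feature_registry))

cfg <- function(config, name, default)
  if (!is.null(config[[name]])) config[[name]] else default

#' Extract a per-scan feature vector
#'
#' Dispatches over the registered methods. Detector methods (`harris`,
#' `mineigen`, `fast`, `hessian`) run the detector and aggregate keypoints on
#' a `config$grid` (default 8x8) via [aggregate_keypoints()]; `hog` computes
#' [hog_feature()]; `deep` applies [colorize_and_resize()] (size
#' `config$deep_size`, default 227x227) and the [deep_embedding()] supplied
#' as `config$embedding`. Unknown names fall through to plug-ins registered
#' with [register_feature_method()].
#'
#' @param image Numeric matrix in `[0, 1]` (required only by `deep`).
#' @param method Method name, see [feature_methods()].
#' @param config Named list of method options (detector thresholds, `grid`,
#'   `cell_size`, `embedding`, ...).
#' @return A [feature_vector()].
#' @export
extract_feature <- function(image, method, config = list()) {
  grid <- cfg(config, "grid", c(8L, 8L))
  shape <- dim(image)
  switch(method,
    hog = hog_feature(image,
                      cell_size = cfg(config, "cell_size", 8L),
                      n_bins = cfg(config, "n_bins", 9L),
                      block_shape = cfg(config, "block_shape", c(2L, 2L)),
                      signed = cfg(config, "signed", FALSE)),
    harris = aggregate_keypoints(
      harris_keypoints(image, k = cfg(config, "k", 0.04),
                       threshold = cfg(config, "threshold", 0.01)),
      shape, grid),
    mineigen = aggregate_keypoints(
      min_eigen_keypoints(image, threshold = cfg(config, "threshold", 0.01)),
      shape, grid),
    fast = aggregate_keypoints(
      fast_keypoints(image, threshold = cfg(config, "threshold", 0.1),
                     n_contig = cfg(config, "n_contig", 12L)),
      shape, grid),
    hessian = aggregate_keypoints(
      hessian_response(image, sigma = cfg(config, "sigma", 1.2),
                       w = cfg(config, "w", 0.9),
                       threshold = cfg(config, "threshold", 0))$keypoints,
      shape, grid),
    deep = {
      emb <- config$embedding
      if (!inherits(emb, "deep_embedding"))
        stopf("method 'deep' requires a deep_embedding as config$embedding")
      arr <- colorize_and_resize(image, cfg(config, "deep_size", c(227L, 227L)))
      v <- emb$embed(arr)
      if (length(v) != emb$K)
        stopf("embedding '%s' returned length %d, contract says K = %d",
              emb$name, length(v), emb$K)
      feature_vector(v, paste0("deep_", emb$name))
    },
    {
      if (!exists(method, envir = .feature_registry))
        stopf("unknown feature method '%s'; see feature_methods()", method)
      fn <- get(method, envir = .feature_registry)
      out <- fn(image, config)
      if (!inherits(out, "feature_vector"))
        stopf("registered method '%s' must return a feature_vector", method)
      out
    })
}
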