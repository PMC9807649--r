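#' Margin-crop specification
#'
#' Number of rows/columns stripped from each side of a B-scan. The defaults
#' follow the margins used for 512 x 496 SD-OCT scans: 20 top and 10 bottom
#' rows, 13 left and 3 right columns. Cropping removes uninformative border
#' pixels only; no resampling or denoising is applied.
#'
#' @param top_rows,bottom_rows,left_cols,right_cols Non-negative pixel counts.
#' @return An object of class `crop_spec`.
#' @export
crop_spec <- function(top_rows = 20L, bottom_rows = 10L,
                      left_cols = 13L, right_cols = 3L) {
  vals <- c(top_rows, bottom_rows, left_cols, right_cols)
  if (!all(vapply(vals, is_count, TRUE, min = 0)))
    stopf("crop margins must be non-negative integers")
  structure(list(top_rows = as.integer(top_rows),
                 bottom_rows = as.integer(bottom_rows),
                 left_cols = as.integer(left_cols),
                 right_cols = as.integer(right_cols)),
            class = "crop_spec")
}

#' Crop image margins
#'
#' Removes the stated number of rows/columns from each side, returning the
#' exact interior sub-block (no interpolation). A 496-row by 512-column scan
#' with the default margins becomes 466 x 496.
#'
#' @param image Numeric matrix (rows = height).
#' @param spec A [crop_spec()].
#' @return The cropped matrix of size
#'   `(H - top - bottom) x (W - left - right)`.
#' @export
crop_margins <- function(image, spec = crop_spec()) {
  assert_image(image)
  if (!inherits(spec, "crop_spec")) stopf("spec must be a crop_spec")
  h <- nrow(image); w <- ncol(image)
  if (spec$top_rows + spec$bottom_rows >= h)
    stopf("top + bottom margins (%d) must be < image height (%d)",
          spec$top_rows + spec$bottom_rows, h)
  if (spec$left_cols + spec$right_cols >= w)
    stopf("left + right margins (%d) must be < image width (%d)",
          spec$left_cols + spec$right_cols, w)
  image[(spec$top_rows + 1L):(h - spec$bottom_rows),
        (spec$left_cols + 1L):(w - spec$right_cols), drop = FALSE]
}

#' Monotone warm-cold colormap
#'
#' Maps intensities in `[0, 1]` to RGB so that low intensities are cold
#' (blue) and high intensities warm (red), passing through cyan/green/yellow.
#' Unlike the classic jet map, the red channel is non-decreasing and the blue
#' channel non-increasing in intensity, so channel ordering tracks intensity
#' ordering everywhere.
#'
#' @param x Numeric vector/array of intensities in `[0, 1]`.
#' @return A list with numeric components `r`, `g`, `b`, same shape as `x`.
#' @export
warmcold_map <- function(x) {
  list(r = clamp01(2 * (x - 0.25)),
       g = 1 - abs(2 * x - 1),
       b = clamp01(2 * (0.75 - x)))
}

# Separable area-average (box) resampling weights: output cell i covers the
# input interval [i-1, i) * n_in/n_out; weights are interval overlaps.
area_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale; hi <- i * scale
    j0 <- floor(lo) + 1L; j1 <- min(n_in, ceiling(hi))
    for (j in j0:j1)
      W[i, j] <- max(0, min(hi, j) - max(lo, j - 1))
  }
  W / rowSums(W)
}

# Area-average resize of a single-channel matrix to (h_out, w_out).
resize_area <- function(image, h_out, w_out) {
  L <- area_weights(nrow(image), h_out)
  R <- area_weights(ncol(image), w_out)
  L %*% image %*% t(R)
}

#' Colorize a grayscale scan and resize it for a deep-feature backend
#'
#' Applies a fixed monotone warm-cold colormap (warmer colors at higher
#' intensities), then downsamples each channel to `out_size` by area
#' averaging — a plain sampling-rate reduction that keeps the full field of
#' view, rather than cropping margins which could remove peripheral cysts.
#' The default output, 227 x 227 x 3, is the canonical AlexNet input size.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param out_size Length-2 integer `(rows, cols)` of the output.
#' @param colormap Function mapping intensities in `[0, 1]` to a list with
#'   `r`, `g`, `b` components (default [warmcold_map()]).
#' @return A `out_size[1] x out_size[2] x 3` array with values in `[0, 1]`.
#' @export
colorize_and_resize <- function(image, out_size = c(227L, 227L),
                                colormap = warmcold_map) {
  assert_image(image)
  if (any(image < 0) || any(image > 1))
    stopf("image intensities must lie in [0, 1]")
  if (length(out_size) != 2L || !all(vapply(out_size, is_count, TRUE, min = 1)))
    stopf("out_size must be two positive integers")
  rgb <- colormap(image)
  out <- array(0, c(out_size[1], out_size[2], 3L))
  chans <- list(rgb$r, rgb$g, rgb$b)
  for (c_i in 1:3) {
    ch <- matrix(chans[[c_i]], nrow(image), ncol(image))
    out[, , c_i] <- resize_area(ch, out_size[1], out_size[2])
  }
  out
}
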