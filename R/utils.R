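# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state after.
# seed = NULL leaves the RNG stream untouched.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# keep x first: pmin/pmax take attributes (dim!) from their first argument
clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_image <- function(image, what = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stopf("%s must be a numeric matrix (rows = height, cols = width)", what)
}

# Row-stochastic check with tolerance.
is_row_stochastic <- function(m, tol = 1e-9) {
  all(m >= -tol) && all(abs(rowSums(m) - 1) <= tol)
}

# Valid-region 2-D cross-correlation: out[i,j] = sum_k image[i+k-1, j+l-1] *
# kernel[k,l]. Kernels here are tiny (3x3 .. 9x9), so accumulating shifted
# sub-matrices is exact and fast.
filter2_valid <- function(image, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  oh <- nrow(image) - kh + 1L; ow <- ncol(image) - kw + 1L
  if (oh < 1L || ow < 1L) stopf("kernel larger than image")
  out <- matrix(0, oh, ow)
  for (k in seq_len(kh)) {
    for (l in seq_len(kw)) {
      if (kernel[k, l] != 0)
        out <- out + kernel[k, l] *
          image[k:(k + oh - 1L), l:(l + ow - 1L), drop = FALSE]
    }
  }
  out
}

# Zero-padded "same" cross-correlation with an odd-sized kernel.
filter2_same <- function(image, kernel) {
  ro <- (nrow(kernel) - 1L) %/% 2L
  co <- (ncol(kernel) - 1L) %/% 2L
  padded <- matrix(0, nrow(image) + 2L * ro, ncol(image) + 2L * co)
  padded[(ro + 1L):(ro + nrow(image)), (co + 1L):(co + ncol(image))] <- image
  filter2_valid(padded, kernel)
}

# Deterministic 3x3 non-maximum suppression on a response matrix.
# A pixel survives iff its response exceeds every 8-neighbour, where ties are
# broken toward the lexicographically smaller (row, col): on a tie the earlier
# raster-order pixel wins. `mask` optionally restricts candidate pixels.
nms3x3 <- function(response, threshold, mask = NULL) {
  h <- nrow(response); w <- ncol(response)
  keep <- response > threshold
  if (!is.null(mask)) keep <- keep & mask
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(idx)
  ok <- logical(nrow(idx))
  for (n in seq_len(nrow(idx))) {
    i <- idx[n, 1L]; j <- idx[n, 2L]
    r <- response[i, j]
    best <- TRUE
    for (dj in -1:1) {
      for (di in -1:1) {
        if (di == 0L && dj == 0L) next
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > h || jj < 1L || jj > w) next
        rn <- response[ii, jj]
        if (rn > r || (rn == r && (ii < i || (ii == i && jj < j)))) {
          best <- FALSE
          break
        }
      }
      if (!best) break
    }
    ok[n] <- best
  }
  idx <- idx[ok, , drop = FALSE]
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]   # raster order
}
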