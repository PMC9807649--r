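# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive each quantity with naive loops / exhaustive
# enumeration, sharing no code with the package internals they check.

# Random row-stochastic matrix (rows ~ normalized uniforms).
rand_stochastic <- function(nrow, ncol) {
  m <- matrix(stats::runif(nrow * ncol, 0.05, 1), nrow, ncol)
  m / rowSums(m)
}

rand_stochastic_seeded <- function(nrow, ncol, seed) {
  set.seed(seed)
  rand_stochastic(nrow, ncol)
}

is_row_stochastic_test <- function(m, tol = 1e-9)
  all(m >= -tol) && all(abs(rowSums(m) - 1) <= tol)

# Emission probability used by the oracles: dot of B_row with the
# normalized absolute observation (recomputed from scratch).
oracle_emission <- function(B_row, o) {
  ao <- abs(o)
  sum(B_row * ao / sum(ao))
}

# Exhaustive Viterbi: score all 2^T state paths in the linear domain and
# return the best path, ties resolved toward the lexicographically smallest
# path (state 1 first) to match the documented tie-break.
oracle_viterbi <- function(A, B, pi, obs) {
  T <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))[, T:1, drop = FALSE]
  # expand.grid varies the first factor fastest; after the column flip the
  # rows are in lexicographic order of (s1, ..., sT), so the first maximum
  # is the tie-broken winner.
  scores <- apply(paths, 1L, function(s) {
    p <- pi[s[1L]] * oracle_emission(B[s[1L], ], obs[1L, ])
    if (T > 1L) for (t in 2:T)
      p <- p * A[s[t - 1L], s[t]] * oracle_emission(B[s[t], ], obs[t, ])
    p
  })
  paths[which.max(scores), ]
}

# Exhaustive smoothing posterior P(s_t = 1 | o_1:T) by summing all paths.
oracle_posterior <- function(A, B, pi, obs) {
  T <- nrow(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))
  scores <- apply(paths, 1L, function(s) {
    p <- pi[s[1L]] * oracle_emission(B[s[1L], ], obs[1L, ])
    if (T > 1L) for (t in 2:T)
      p <- p * A[s[t - 1L], s[t]] * oracle_emission(B[s[t], ], obs[t, ])
    p
  })
  vapply(seq_len(T), function(t)
    sum(scores[paths[, t] == 1L]) / sum(scores), numeric(1))
}

# AUC as the pairwise rank statistic: P(score_pos > score_neg) + ties/2.
oracle_auc_paircount <- function(scores, truth) {
  pos <- scores[truth == 1L]; neg <- scores[truth == 2L]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Sobel gradients by explicit per-pixel loops (valid region).
oracle_sobel <- function(img) {
  gx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  gy <- rbind(c(1, 2, 1), c(0, 0, 0), c(-1, -2, -1))
  h <- nrow(img); w <- ncol(img)
  a <- matrix(0, h - 2, w - 2); b <- a
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    nb <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
    a[i - 1, j - 1] <- sum(gx * nb)
    b[i - 1, j - 1] <- sum(gy * nb)
  }
  list(a = a, b = b)
}

# Structure-tensor corner responses by explicit loops: gradients zeroed on
# the 1-pixel border, Gaussian window sums with zero padding, eigen() per
# pixel. Returns harris and min-eigen response matrices.
oracle_structure_responses <- function(img, k = 0.04, win = 5L,
                                       sigma = 5 / 3) {
  h <- nrow(img); w <- ncol(img)
  g <- oracle_sobel(img)
  ix <- matrix(0, h, w); iy <- matrix(0, h, w)
  ix[2:(h - 1), 2:(w - 1)] <- g$a
  iy[2:(h - 1), 2:(w - 1)] <- g$b
  r <- (win - 1) / 2
  gw <- exp(-((-r):r)^2 / (2 * sigma^2))
  gk <- outer(gw, gw); gk <- gk / sum(gk)
  harris <- matrix(0, h, w); mineig <- matrix(0, h, w)
  maxeig <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    sxx <- 0; syy <- 0; sxy <- 0
    for (di in (-r):r) for (dj in (-r):r) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
        wgt <- gk[di + r + 1, dj + r + 1]
        sxx <- sxx + wgt * ix[ii, jj]^2
        syy <- syy + wgt * iy[ii, jj]^2
        sxy <- sxy + wgt * ix[ii, jj] * iy[ii, jj]
      }
    }
    ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2), symmetric = TRUE)$values
    harris[i, j] <- prod(ev) - k * sum(ev)^2
    mineig[i, j] <- min(ev)
    maxeig[i, j] <- max(ev)
  }
  list(harris = harris, mineigen = mineig, maxeigen = maxeig)
}

# Independent 3x3 non-maximum suppression with the raster-order tie rule;
# returns a (row, col) matrix sorted in raster order.
oracle_nms <- function(resp, threshold, border) {
  h <- nrow(resp); w <- ncol(resp)
  pts <- NULL
  for (i in (border + 1):(h - border)) for (j in (border + 1):(w - border)) {
    if (resp[i, j] <= threshold) next
    best <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > h || jj < 1 || jj > w) next
      if (resp[ii, jj] > resp[i, j] ||
          (resp[ii, jj] == resp[i, j] &&
           (ii < i || (ii == i && jj < j)))) best <- FALSE
    }
    if (best) pts <- rbind(pts, c(i, j))
  }
  if (is.null(pts)) matrix(integer(0), ncol = 2) else pts
}

# Exhaustive FAST segment test: for every candidate pixel walk the 16-pixel
# circle (clockwise from the top) and look for a contiguous bright or dark
# arc of length >= n_contig, scanning all 16 start positions.
oracle_fast <- function(img, t, n_contig) {
  offs <- cbind(c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3),
                c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1))
  h <- nrow(img); w <- ncol(img)
  pts <- NULL
  for (i in 4:(h - 3)) for (j in 4:(w - 3)) {
    circ <- vapply(1:16, function(k) img[i + offs[k, 1], j + offs[k, 2]],
                   numeric(1))
    bright <- circ > img[i, j] + t
    dark <- circ < img[i, j] - t
    found <- FALSE
    for (start in 1:16) {
      okb <- TRUE; okd <- TRUE
      for (step in 0:(n_contig - 1)) {
        kk <- (start + step - 1) %% 16 + 1
        okb <- okb && bright[kk]
        okd <- okd && dark[kk]
      }
      if (okb || okd) { found <- TRUE; break }
    }
    if (found) pts <- rbind(pts, c(i, j))
  }
  if (is.null(pts)) matrix(integer(0), ncol = 2) else pts
}

# Determinant-of-Hessian response by direct window sums of the box-filter
# kernels from zero-padded image values.
oracle_hessian_response <- function(img, l, w_mix) {
  dyy <- rbind(matrix(1, l, 2 * l - 1), matrix(-2, l, 2 * l - 1),
               matrix(1, l, 2 * l - 1)) / (l * (2 * l - 1))
  dxy <- matrix(0, 2 * l + 1, 2 * l + 1)
  dxy[1:l, 1:l] <- 1; dxy[1:l, (l + 2):(2 * l + 1)] <- -1
  dxy[(l + 2):(2 * l + 1), 1:l] <- -1
  dxy[(l + 2):(2 * l + 1), (l + 2):(2 * l + 1)] <- 1
  dxy <- dxy / l^2
  dxx <- t(dyy)
  at <- function(ker, i, j) {
    kh <- nrow(ker); kw <- ncol(ker)
    ro <- (kh - 1) %/% 2; co <- (kw - 1) %/% 2
    s <- 0
    for (ki in 1:kh) for (kj in 1:kw) {
      ii <- i + ki - 1 - ro; jj <- j + kj - 1 - co
      if (ii >= 1 && ii <= nrow(img) && jj >= 1 && jj <= ncol(img))
        s <- s + ker[ki, kj] * img[ii, jj]
    }
    s
  }
  out <- matrix(0, nrow(img), ncol(img))
  b <- max((3 * l - 1) %/% 2, l)   # filters lack full support in this band
  for (i in (b + 1):(nrow(img) - b)) for (j in (b + 1):(ncol(img) - b))
    out[i, j] <- at(dxx, i, j) * at(dyy, i, j) - (w_mix * at(dxy, i, j))^2
  out
}

# Paired permutation reference for the difference of two AUCs: per case,
# randomly swap which method produced the score, and compare |dAUC|.
oracle_delong_permutation <- function(scores_a, scores_b, truth, reps,
                                      seed = 1L) {
  auc <- function(s) oracle_auc_paircount(s, truth)
  obs <- abs(auc(scores_a) - auc(scores_b))
  n <- length(truth)
  hits <- 0L
  set.seed(seed)
  for (r in seq_len(reps)) {
    swap <- stats::runif(n) < 0.5
    sa <- ifelse(swap, scores_b, scores_a)
    sb <- ifelse(swap, scores_a, scores_b)
    if (abs(auc(sa) - auc(sb)) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / reps
}

# Build a tiny labeled phantom dataset on disk; returns the manifest path.
make_phantom_manifest <- function(dir, n_patients = 4, T = 6, seed = 7) {
  cohort <- simulate_phantom_cohort(
    n_patients, T, phantom = phantom_spec(height = 64, width = 64,
                                          n_layers = 2,
                                          cyst_axes_range = c(3, 6),
                                          speckle_sigma = 0.03),
    seed = seed)
  write_phantom_dataset(cohort, dir)
  file.path(dir, "manifest.csv")
}
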