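#' Phantom B-scan specification
#'
#' Describes a synthetic OCT-like B-scan: a dark background crossed by bright
#' horizontal bands (retinal layers) into which dark elliptical cysts are
#' drawn, followed by multiplicative speckle noise. Phantoms only mimic the
#' coarse appearance of retinal OCT (bright layered tissue, dark fluid-filled
#' cysts, speckle); they are not anatomically realistic.
#'
#' @param height,width Image size in pixels (rows = height).
#' @param n_layers Number of bright horizontal bands.
#' @param n_cysts Number of dark elliptical cysts to draw (0 for a
#'   non-cystic scan).
#' @param cyst_axes_range Length-2 numeric `(min, max)` of cyst semi-axes in
#'   pixels; each cyst draws its column and row semi-axes uniformly from this
#'   range (the row semi-axis is clamped so the cyst fits inside its band).
#' @param speckle_sigma Scale of multiplicative speckle: the clean image is
#'   multiplied by `1 + speckle_sigma * N(0,1)` per pixel and clipped to
#'   `[0, 1]`. `0` disables noise.
#' @param seed Integer RNG seed; identical specs with identical seeds produce
#'   bit-identical phantoms. `NULL` uses (and advances) the current RNG stream.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom_bscan()]
#' @export
phantom_spec <- function(height = 96L, width = 128L, n_layers = 4L,
                         n_cysts = 1L, cyst_axes_range = c(3, 8),
                         speckle_sigma = 0.05, seed = NULL) {
  if (!is_count(height, 1) || !is_count(width, 1))
    stopf("height and width must be positive integers")
  if (!is_count(n_layers, 1))
    stopf("n_layers must be a positive integer")
  if (!is_count(n_cysts, 0))
    stopf("n_cysts must be a non-negative integer")
  if (length(cyst_axes_range) != 2L || any(cyst_axes_range < 1) ||
      cyst_axes_range[1] > cyst_axes_range[2])
    stopf("cyst_axes_range must be (min, max) with 1 <= min <= max")
  if (!is.numeric(speckle_sigma) || length(speckle_sigma) != 1L || speckle_sigma < 0)
    stopf("speckle_sigma must be a non-negative scalar")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_layers = as.integer(n_layers), n_cysts = as.integer(n_cysts),
                 cyst_axes_range = as.numeric(cyst_axes_range),
                 speckle_sigma = speckle_sigma, seed = seed),
            class = "phantom_spec")
}

#' Generate a phantom B-scan
#'
#' Draws the layered-band phantom described by a [phantom_spec()]: bands of
#' alternating brightness over a dark background, `n_cysts` dark axis-aligned
#' elliptical cysts confined to the bands, then multiplicative speckle.
#' Before noise, every cyst interior is strictly darker than the mean of its
#' enclosing band.
#'
#' @param spec A [phantom_spec()].
#' @return A list with components `image` (height x width matrix in `[0, 1]`),
#'   `cyst_mask` (logical matrix, `TRUE` inside cysts), and `label`
#'   (`"cystic"` iff the mask has at least one `TRUE` pixel, else
#'   `"non-cystic"`).
#' @examples
#' ph <- generate_phantom_bscan(phantom_spec(n_cysts = 2, seed = 1))
#' ph$label
#' @export
generate_phantom_bscan <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("spec must be a phantom_spec")
  local_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    img <- matrix(0.08, h, w)
    mask <- matrix(FALSE, h, w)

    # Retina occupies the central 60% of rows, split into n_layers bands.
    top <- max(1L, floor(0.2 * h)); bot <- min(h, ceiling(0.8 * h))
    edges <- round(seq(top, bot, length.out = spec$n_layers + 1L))
    band_rows <- lapply(seq_len(spec$n_layers), function(k)
      seq.int(edges[k], max(edges[k], edges[k + 1L] - 1L)))
    band_vals <- rep(c(0.75, 0.5), length.out = spec$n_layers) +
      stats::runif(spec$n_layers, -0.05, 0.05)
    for (k in seq_len(spec$n_layers)) img[band_rows[[k]], ] <- band_vals[k]

    if (spec$n_cysts > 0L) {
      # Cysts only fit in bands at least 3 rows thick.
      usable <- which(vapply(band_rows, length, 1L) >= 3L)
      if (length(usable) == 0L)
        stopf("no band is thick enough to contain a cyst; increase height or reduce n_layers")
      for (c_i in seq_len(spec$n_cysts)) {
        k <- usable[sample.int(length(usable), 1L)]
        rows <- band_rows[[k]]
        half <- (length(rows) - 1) / 2
        ax_c <- stats::runif(1, spec$cyst_axes_range[1], spec$cyst_axes_range[2])
        ax_r <- min(stats::runif(1, spec$cyst_axes_range[1], spec$cyst_axes_range[2]),
                    max(1, half - 0.5))
        cr <- stats::runif(1, min(rows) + ax_r, max(rows) - ax_r)
        ax_c <- min(ax_c, (w - 2) / 2)
        cc <- stats::runif(1, 1 + ax_c, w - ax_c)
        rr <- matrix(seq_len(h), h, w)
        cciD <- matrix(seq_len(w), h, w, byrow = TRUE)
        inside <- ((rr - cr) / ax_r)^2 + ((cciD - cc) / ax_c)^2 <= 1
        img[inside] <- band_vals[k] * 0.3
        mask <- mask | inside
      }
    }

    if (spec$speckle_sigma > 0)
      img <- clamp01(img * (1 + spec$speckle_sigma * stats::rnorm(h * w)))

    list(image = img, cyst_mask = mask,
         label = if (any(mask)) "cystic" else "non-cystic")
  })
}

#' Markov sequence simulation specification
#'
#' Parameters of the generative model behind simulated patients: a 2-state
#' Markov chain (`pi_true`, `A_true`) over the hidden cystic / non-cystic
#' status, and per-state emission profiles `B_true` from which each scan's
#' observation vector is sampled as multinomial counts with total mass
#' `obs_total`. This mirrors the statistical structure the HMM is trained on,
#' so supervised estimation applied to simulated cohorts is a consistent
#' estimator of (`A_true`, `B_true`, `pi_true`).
#'
#' @param A_true 2x2 row-stochastic transition matrix (state 1 = cystic).
#' @param pi_true Length-2 initial-state distribution.
#' @param B_true 2xK row-stochastic emission-profile matrix.
#' @param T Scans per patient (sequence length), `>= 1`.
#' @param n_patients Number of independent patient sequences.
#' @param obs_total Total count mass of each sampled observation vector.
#' @param sign_flip_prob Probability that an individual observation entry has
#'   its sign flipped, to exercise the absolute-value step of training.
#' @param seed Integer RNG seed (`NULL` = current stream).
#' @return An object of class `sequence_sim_spec`.
#' @export
sequence_sim_spec <- function(A_true, pi_true, B_true, T, n_patients,
                              obs_total = 100L, sign_flip_prob = 0,
                              seed = NULL) {
  A_true <- as.matrix(A_true); B_true <- as.matrix(B_true)
  pi_true <- as.numeric(pi_true)
  tol <- 1e-12
  if (!identical(dim(A_true), c(2L, 2L)) || !is_row_stochastic(A_true, tol))
    stopf("A_true must be a 2x2 row-stochastic matrix (rows sum to 1 within 1e-12)")
  if (length(pi_true) != 2L || any(pi_true < -tol) || abs(sum(pi_true) - 1) > tol)
    stopf("pi_true must be a 2-vector summing to 1 within 1e-12")
  if (nrow(B_true) != 2L || !is_row_stochastic(B_true, tol))
    stopf("B_true must be a 2xK row-stochastic matrix")
  if (!is_count(T, 1)) stopf("T must be a positive integer")
  if (!is_count(n_patients, 1)) stopf("n_patients must be a positive integer")
  if (!is_count(obs_total, 1)) stopf("obs_total must be a positive integer")
  if (sign_flip_prob < 0 || sign_flip_prob > 1)
    stopf("sign_flip_prob must lie in [0, 1]")
  structure(list(A_true = A_true, pi_true = pi_true, B_true = B_true,
                 T = as.integer(T), n_patients = as.integer(n_patients),
                 obs_total = as.integer(obs_total),
                 sign_flip_prob = sign_flip_prob, seed = seed),
            class = "sequence_sim_spec")
}

# One state path of length T from (pi, A); states coded 1/2.
sample_state_path <- function(pi, A, T) {
  s <- integer(T)
  s[1] <- sample.int(2L, 1L, prob = pi)
  if (T > 1L) for (t in 2:T) s[t] <- sample.int(2L, 1L, prob = A[s[t - 1L], ])
  s
}

#' Simulate patient observation sequences from a known HMM
#'
#' For each simulated patient, samples a hidden state path from the Markov
#' chain (`pi_true`, `A_true`) and, per scan, an observation vector of
#' multinomial counts with `obs_total` draws from the active state's row of
#' `B_true` (optionally sign-flipping entries with `sign_flip_prob`).
#'
#' @param spec A [sequence_sim_spec()].
#' @return A list of length `n_patients`; each element is a list with
#'   `states` (length-T integer vector over \{1, 2\}) and `observations`
#'   (T x K numeric matrix; each row sums to `obs_total` in absolute value).
#' @examples
#' spec <- sequence_sim_spec(A_true = matrix(c(.9, .2, .1, .8), 2),
#'                           pi_true = c(.5, .5),
#'                           B_true = rbind(c(.7, .3), c(.2, .8)),
#'                           T = 10, n_patients = 3, seed = 1)
#' sims <- generate_patient_sequences(spec)
#' sims[[1]]$states
#' @export
generate_patient_sequences <- function(spec) {
  if (!inherits(spec, "sequence_sim_spec")) stopf("spec must be a sequence_sim_spec")
  K <- ncol(spec$B_true)
  local_seed(spec$seed, {
    lapply(seq_len(spec$n_patients), function(p) {
      states <- sample_state_path(spec$pi_true, spec$A_true, spec$T)
      obs <- t(vapply(states, function(s)
        as.numeric(stats::rmultinom(1L, spec$obs_total, spec$B_true[s, ])),
        numeric(K)))
      if (spec$sign_flip_prob > 0) {
        flip <- matrix(stats::runif(length(obs)) < spec$sign_flip_prob,
                       nrow(obs), ncol(obs))
        obs[flip] <- -obs[flip]
      }
      list(states = states, observations = obs)
    })
  })
}

#' Simulate a phantom cohort with Markov-persistent cystic status
#'
#' Couples the two generators: per patient, a hidden cystic / non-cystic path
#' is drawn from (`pi_true`, `A_true`) and each scan is rendered as a phantom
#' B-scan whose cyst count is 0 in the non-cystic state and uniform on
#' `1:max_cysts` in the cystic state. This is the end-to-end test bed for the
#' full feature -> classifier -> HMM pipeline.
#'
#' @param n_patients Number of patients.
#' @param T Scans per patient.
#' @param A_true,pi_true Markov-chain parameters over \{cystic = 1,
#'   non-cystic = 2\}.
#' @param phantom A [phantom_spec()] used as template (its `n_cysts` and
#'   `seed` are overridden per scan).
#' @param max_cysts Maximum cysts in a cystic scan.
#' @param seed Integer RNG seed.
#' @return List of patients, each a list with `states`, `images` (list of
#'   matrices) and `masks`.
#' @export
simulate_phantom_cohort <- function(n_patients, T,
                                    A_true = matrix(c(0.9, 0.2, 0.1, 0.8), 2),
                                    pi_true = c(0.4, 0.6),
                                    phantom = phantom_spec(),
                                    max_cysts = 3L, seed = NULL) {
  local_seed(seed, {
    lapply(seq_len(n_patients), function(p) {
      states <- sample_state_path(pi_true, A_true, T)
      scans <- lapply(states, function(s) {
        sp <- phantom
        sp$n_cysts <- if (s == 1L) sample.int(max_cysts, 1L) else 0L
        sp$seed <- NULL
        generate_phantom_bscan(sp)
      })
      list(states = states,
           images = lapply(scans, `[[`, "image"),
           masks = lapply(scans, `[[`, "cyst_mask"))
    })
  })
}

#' Write a phantom cohort to disk as images plus a manifest
#'
#' Images are written as 8-bit grayscale PNG (or TIFF) files named
#' `p<patient>_s<scan>.<ext>`, and a `manifest.csv` with columns
#' `patient_id, scan_index, path, label` is written alongside (label encoded
#' 1 = cystic, 0 = non-cystic).
#'
#' @param cohort Output of [simulate_phantom_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return Invisibly, the manifest `data.frame` (paths are absolute).
#' @export
write_phantom_dataset <- function(cohort, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (p in seq_along(cohort)) {
    pat <- cohort[[p]]
    for (t in seq_along(pat$images)) {
      fn <- file.path(dir, sprintf("p%03d_s%03d.%s", p, t,
                                   if (format == "tiff") "tif" else "png"))
      if (format == "png") png::writePNG(pat$images[[t]], fn)
      else tiff::writeTIFF(pat$images[[t]], fn, bits.per.sample = 8L)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("p%03d", p), scan_index = t,
        path = normalizePath(fn),
        label = if (pat$states[t] == 1L) 1L else 0L)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write simulated sequences to disk
#'
#' One observation matrix CSV per patient (`patient<i>_obs.csv`, T x K, no
#' header) plus a single `states.csv` (`patient_id, scan_index, state`).
#'
#' @param sims Output of [generate_patient_sequences()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the states `data.frame`.
#' @export
write_patient_sequences <- function(sims, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- list()
  for (p in seq_along(sims)) {
    utils::write.table(sims[[p]]$observations,
                       file.path(dir, sprintf("patient%03d_obs.csv", p)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    st[[p]] <- data.frame(patient_id = sprintf("p%03d", p),
                          scan_index = seq_along(sims[[p]]$states),
                          state = sims[[p]]$states)
  }
  states <- do.call(rbind, st)
  utils::write.csv(states, file.path(dir, "states.csv"), row.names = FALSE)
  invisible(states)
}
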