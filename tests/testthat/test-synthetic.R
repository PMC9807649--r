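test_that("phantom label is consistent with the cyst mask and seeds are reproducible", {
  none <- generate_phantom_bscan(phantom_spec(n_cysts = 0, seed = 3))
  expect_false(any(none$cyst_mask))
  expect_identical(none$label, "non-cystic")

  sp <- phantom_spec(n_cysts = 3, seed = 11)
  a <- generate_phantom_bscan(sp)
  b <- generate_phantom_bscan(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$cyst_mask, b$cyst_mask)
  expect_identical(a$label, "cystic")
  expect_true(any(a$cyst_mask))
  expect_identical(dim(a$image), c(96L, 128L))
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("cyst interiors are darker than their enclosing band before noise", {
  ph <- generate_phantom_bscan(phantom_spec(n_cysts = 1, speckle_sigma = 0,
                                            seed = 5))
  mask <- ph$cyst_mask
  rows <- range(which(apply(mask, 1, any)))
  band <- ph$image[rows[1]:rows[2], ][!mask[rows[1]:rows[2], ]]
  expect_lt(mean(ph$image[mask]), mean(band))
})

test_that("invalid phantom and simulation specs are rejected", {
  expect_error(phantom_spec(height = 0), "positive")
  expect_error(phantom_spec(n_cysts = -1), "non-negative")
  expect_error(phantom_spec(cyst_axes_range = c(5, 2)), "min <= max")
  expect_error(
    sequence_sim_spec(matrix(c(.9, .2, .2, .8), 2), c(.5, .5),
                      rbind(c(.5, .5), c(.5, .5)), T = 3, n_patients = 1),
    "row-stochastic")
  expect_error(
    sequence_sim_spec(diag(2), c(.7, .7), rbind(c(.5, .5), c(.5, .5)),
                      T = 3, n_patients = 1),
    "summing to 1")
})

test_that("an absorbing start keeps every simulated sequence in state 1", {
  spec <- sequence_sim_spec(diag(2), c(1, 0),
                            rbind(c(.6, .4), c(.1, .9)),
                            T = 8, n_patients = 20, seed = 2)
  sims <- generate_patient_sequences(spec)
  for (p in sims) expect_true(all(p$states == 1L))
})

test_that("observation vectors conserve the count mass and respect the seed", {
  spec <- sequence_sim_spec(matrix(c(.9, .2, .1, .8), 2), c(.5, .5),
                            rand_stochastic(2, 6), T = 12, n_patients = 5,
                            obs_total = 40, sign_flip_prob = 0.2, seed = 9)
  sims1 <- generate_patient_sequences(spec)
  sims2 <- generate_patient_sequences(spec)
  expect_identical(sims1, sims2)
  for (p in sims1)
    expect_equal(rowSums(abs(p$observations)), rep(40, 12))
})

test_that("simulated state frequencies match the generating chain", {
  # T = 1: first-state distribution vs pi_true within 3 binomial s.e.
  pi_true <- c(0.3, 0.7)
  spec <- sequence_sim_spec(matrix(c(.9, .2, .1, .8), 2), pi_true,
                            rbind(c(.5, .5), c(.5, .5)),
                            T = 1, n_patients = 2000, seed = 4)
  sims <- generate_patient_sequences(spec)
  f1 <- mean(vapply(sims, function(p) p$states[1] == 1L, TRUE))
  se <- sqrt(pi_true[1] * (1 - pi_true[1]) / 2000)
  expect_lt(abs(f1 - pi_true[1]), 3 * se)

  # Long sequences: empirical transition frequencies vs A_true.
  A <- matrix(c(.85, .25, .15, .75), 2)
  spec2 <- sequence_sim_spec(A, c(.5, .5), rbind(c(.5, .5), c(.5, .5)),
                             T = 200, n_patients = 30, seed = 6)
  sims2 <- generate_patient_sequences(spec2)
  from <- unlist(lapply(sims2, function(p) p$states[-length(p$states)]))
  to <- unlist(lapply(sims2, function(p) p$states[-1]))
  for (i in 1:2) {
    n_i <- sum(from == i)
    phat <- sum(from == i & to == 1L) / n_i
    se_i <- sqrt(A[i, 1] * (1 - A[i, 1]) / n_i)
    expect_lt(abs(phat - A[i, 1]), 3 * se_i)
  }
})

test_that("phantom datasets round-trip through disk with an ordered manifest", {
  dir <- withr::local_tempdir()
  cohort <- simulate_phantom_cohort(3, 5,
                                    phantom = phantom_spec(height = 48,
                                                           width = 48,
                                                           n_layers = 2,
                                                           cyst_axes_range = c(3, 5)),
                                    seed = 8)
  manifest <- write_phantom_dataset(cohort, dir)
  expect_equal(nrow(manifest), 15L)
  man <- read_manifest(file.path(dir, "manifest.csv"), require_labels = TRUE)
  expect_equal(length(unique(man$patient_id)), 3L)
  # 0/1 on-disk labels are canonicalized to 1 = cystic, 2 = non-cystic.
  truth <- unlist(lapply(cohort, `[[`, "states"))
  expect_equal(man$label, as.integer(truth))
  img <- load_image(man$path[1])
  expect_equal(dim(img), c(48L, 48L))
  # 8-bit quantization on write
  expect_lt(max(abs(img - cohort[[1]]$images[[1]])), 1 / 255)
})
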