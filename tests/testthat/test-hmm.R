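test_that("per-patient estimates follow the counting and normalization rules", {
  est <- estimate_patient_params(c(2, 1, 2),
                                 rbind(c(1, 1), c(1, 3), c(2, 2)))
  expect_equal(est$A, rbind(c(0, 1), c(1, 0)))
  expect_equal(est$pi, c(0, 1))
  expect_false(any(est$A_fallback))

  # all-cystic patient: no transitions out of state 2, uniform fallback
  allc <- estimate_patient_params(c(1, 1, 1),
                                  matrix(1, 3, 4))
  expect_equal(allc$A[1, ], c(1, 0))
  expect_equal(allc$A[2, ], c(0.5, 0.5))
  expect_true(allc$A_fallback[2])
  expect_true(allc$B_fallback[2])
  expect_equal(allc$B[2, ], rep(0.25, 4))

  # absolute values precede summation and normalization
  neg <- estimate_patient_params(c(1, 1), rbind(c(1, 3), c(-3, 1)))
  expect_equal(neg$B[1, ], c(0.5, 0.5))

  expect_error(estimate_patient_params(integer(0), matrix(0, 0, 2)), "empty")
  expect_error(estimate_patient_params(c(1, 3), matrix(1, 2, 2)), "coded 1")
  expect_error(estimate_patient_params(c(1, 2), matrix(0, 2, 3)),
               "degenerate emissions")
})

test_that("training averages per-patient estimates element-wise", {
  p1 <- list(labels = c(1, 1, 2), observations = rbind(c(2, 0), c(2, 0), c(0, 2)))
  single <- hmm_train(list(p1))
  est <- estimate_patient_params(p1$labels, p1$observations)
  expect_equal(single$A, est$A)
  expect_equal(single$B, est$B)
  expect_equal(single$pi, est$pi)

  # hand-counted: pa (1,1,2,2) -> A1 = [(1/2,1/2), (0,1)];
  #               pb (2,1,2,1) -> A2 = [(0,1), (1,0)]
  pa <- list(labels = c(1, 1, 2, 2), observations = matrix(1, 4, 2))
  pb <- list(labels = c(2, 1, 2, 1), observations = matrix(1, 4, 2))
  m <- hmm_train(list(pa, pb))
  expect_equal(m$A, rbind(c(0.25, 0.75), c(0.5, 0.5)))

  # one cystic-first, one non-cystic-first patient -> pi = (0.5, 0.5)
  expect_equal(m$pi, c(0.5, 0.5))

  expect_error(hmm_train(list(p1, list(labels = c(1, 2), observations = matrix(1, 2, 3)))),
               "inconsistent")
})

test_that("fallback rows can be excluded from the averages", {
  pa <- list(labels = c(1, 1), observations = rbind(c(1, 0), c(1, 0)))  # state 2 absent
  pb <- list(labels = c(1, 2), observations = rbind(c(1, 0), c(0, 1)))
  inc <- hmm_train(list(pa, pb))
  exc <- hmm_train(list(pa, pb), exclude_flagged = TRUE)
  # included: state-2 rows average the uniform fallback with pb's estimate
  expect_equal(inc$B[2, ], c(0.25, 0.75))
  # excluded: only pb informs state 2
  expect_equal(exc$B[2, ], c(0, 1))
  expect_true(is_row_stochastic_test(inc$A) && is_row_stochastic_test(exc$A))
})

test_that("emission scores reduce observations as documented", {
  expect_equal(emission_score(rep(1 / 4, 4), c(3, -1, 2, 0)), 1 / 4)
  expect_equal(emission_score(c(0.1, 0.6, 0.3), c(0, 5, 0)), 0.6)

  set.seed(101)
  B_row <- as.numeric(rand_stochastic(1, 3))
  o <- rnorm(3)
  expect_equal(emission_score(B_row, o),
               sum(B_row * abs(o)) / sum(abs(o)))

  # multinomial alternative: counts times log-probabilities
  expect_equal(emission_score(c(0.5, 0.5), c(2, 2), mode = "multinomial"),
               4 * log(0.5))
  expect_error(emission_score(c(0.5, 0.5), c(0, 0)), "degenerate")
  expect_error(emission_score(c(0.5, 0.5), c(1, 2, 3)), "equal length")
})

test_that("Viterbi handles the single-scan and tie cases deterministically", {
  m <- hmm_params(matrix(c(.9, .2, .1, .8), 2), rbind(c(.8, .2), c(.3, .7)),
                  c(1, 0))
  vt <- hmm_viterbi(m, matrix(c(0, 5), 1))
  expect_equal(vt$qP, 1L)      # pi = (1, 0) decides regardless of o

  # identical emission rows, symmetric A, uniform pi: full tie -> all-1 path
  tie <- hmm_params(matrix(0.5, 2, 2), rbind(c(.5, .5), c(.5, .5)),
                    c(.5, .5))
  vt_tie <- hmm_viterbi(tie, matrix(runif(10), 5, 2))
  expect_equal(vt_tie$qP, rep(1L, 5))
  expect_equal(dim(vt_tie$delta), c(2L, 5L))
  expect_equal(vt_tie$phi[, 1], c(0L, 0L))
})

test_that("Viterbi equals exhaustive path maximization on 100 random instances", {
  set.seed(111)
  for (rep in 1:100) {
    T <- sample(2:10, 1)
    K <- sample(2:5, 1)
    A <- rand_stochastic(2, 2)
    B <- rand_stochastic(2, K)
    pi <- as.numeric(rand_stochastic(1, 2))
    obs <- matrix(rexp(T * K), T, K)
    m <- hmm_params(A, B, pi)
    expect_identical(hmm_viterbi(m, obs)$qP,
                     as.integer(oracle_viterbi(A, B, pi, obs)))
  }
})

test_that("log-domain trellis scores match linear-domain path scores", {
  set.seed(121)
  A <- rand_stochastic(2, 2); B <- rand_stochastic(2, 4)
  pi <- as.numeric(rand_stochastic(1, 2))
  obs <- matrix(rexp(8 * 4), 8, 4)
  m <- hmm_params(A, B, pi)
  vt <- hmm_viterbi(m, obs)
  s <- vt$qP
  lin <- pi[s[1]] * oracle_emission(B[s[1], ], obs[1, ])
  for (t in 2:8)
    lin <- lin * A[s[t - 1], s[t]] * oracle_emission(B[s[t], ], obs[t, ])
  expect_equal(vt$log_score, log(lin), tolerance = 1e-10)
})

test_that("posteriors match exhaustive marginalization and the absorbing case", {
  ab <- hmm_params(diag(2), rbind(c(.7, .3), c(.2, .8)), c(1, 0))
  post <- posterior_scores(ab, matrix(rexp(8), 4, 2))
  expect_equal(post, rep(1, 4))

  set.seed(131)
  A <- rand_stochastic(2, 2); B <- rand_stochastic(2, 3)
  pi <- as.numeric(rand_stochastic(1, 2))
  m <- hmm_params(A, B, pi)

  o1 <- matrix(rexp(3), 1, 3)
  p1 <- posterior_scores(m, o1)
  b1 <- c(oracle_emission(B[1, ], o1[1, ]), oracle_emission(B[2, ], o1[1, ]))
  expect_equal(p1, (pi * b1 / sum(pi * b1))[1], tolerance = 1e-12)

  obs <- matrix(rexp(4 * 3), 4, 3)
  expect_equal(posterior_scores(m, obs),
               oracle_posterior(A, B, pi, obs), tolerance = 1e-10)
  expect_true(all(posterior_scores(m, obs) >= 0 &
                    posterior_scores(m, obs) <= 1))
})

test_that("trained models recover the generating parameters from simulations", {
  A_true <- matrix(c(.8, .2, .2, .8), 2)
  B_true <- rand_stochastic_seeded(2, 10, seed = 141)
  spec <- sequence_sim_spec(A_true, c(.5, .5), B_true, T = 40,
                            n_patients = 250, obs_total = 200, seed = 151)
  fit <- hmm_train(generate_patient_sequences(spec))
  expect_lt(max(abs(fit$A - A_true)), 0.05)
  expect_lt(max(abs(fit$B - B_true)), 0.05)
  expect_true(abs(sum(fit$pi) - 1) < 1e-12)
})

test_that("model invariants are enforced at construction", {
  expect_error(hmm_params(matrix(c(.9, .2, .2, .8), 2),
                          rbind(c(.5, .5), c(.5, .5)), c(.5, .5)),
               "rows summing to 1")
  expect_error(hmm_params(matrix(c(.9, .2, .1, .8), 2),
                          rbind(c(.6, .5), c(.5, .5)), c(.5, .5)),
               "rows summing to 1")
  expect_error(hmm_params(matrix(c(.9, .2, .1, .8), 2),
                          rbind(c(.5, .5), c(.5, .5)), c(.6, .5)),
               "summing to 1")
})
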