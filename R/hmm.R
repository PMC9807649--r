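# Two-state hidden Markov model over a patient's ordered B-scans.
# State 1 = cystic, state 2 = non-cystic. Training is supervised: per-patient
# transition counting, one-hot initial state, emission rows built from
# normalized sums of absolute observation vectors, then element-wise
# averaging across patients. Decoding is Viterbi in the log domain.

#' Hidden-Markov-model parameters
#'
#' The trained model `lambda = (A, B, pi)`: a 2x2 row-stochastic transition
#' matrix, a 2xK row-stochastic emission-profile matrix (row 1 = cystic,
#' row 2 = non-cystic) and a length-2 initial-state distribution.
#'
#' @param A 2x2 transition matrix; `A[i, j]` is the probability that a scan
#'   in state `j` follows one in state `i`.
#' @param B 2xK emission matrix; row `i` is the normalized expected profile
#'   of absolute observation vectors in state `i`.
#' @param pi Length-2 initial-state distribution.
#' @param feature_name Optional name of the feature method the model was
#'   trained on (checked at decode time when present).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(A, B, pi, feature_name = NULL) {
  A <- as.matrix(A); B <- as.matrix(B); pi <- as.numeric(pi)
  tol <- 1e-9
  if (!identical(dim(A), c(2L, 2L)) || !is_row_stochastic(A, tol))
    stopf("A must be 2x2 with rows summing to 1 (within 1e-9)")
  if (nrow(B) != 2L || ncol(B) < 1L || !is_row_stochastic(B, tol))
    stopf("B must be 2xK with rows summing to 1 (within 1e-9)")
  if (length(pi) != 2L || any(pi < -tol) || abs(sum(pi) - 1) > tol)
    stopf("pi must be a 2-vector summing to 1 (within 1e-9)")
  structure(list(A = A, B = B, pi = pi, K = ncol(B),
                 feature_name = feature_name),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("<hmm_params: K = %d%s>\n", x$K,
              if (is.null(x$feature_name)) ""
              else paste0(", feature = ", x$feature_name)))
  cat("A:\n"); print(round(x$A, 4))
  cat("pi:", round(x$pi, 4), "\n")
  invisible(x)
}

check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stopf("empty label sequence")
  if (!all(labels %in% c(1L, 2L)))
    stopf("labels must be coded 1 (cystic) / 2 (non-cystic)")
  labels
}

as_obs_matrix <- function(observations, T) {
  if (is.vector(observations) && !is.list(observations))
    observations <- matrix(observations, nrow = T)
  observations <- as.matrix(observations)
  if (nrow(observations) != T)
    stopf("observations must have one row per scan (%d), got %d",
          T, nrow(observations))
  if (any(!is.finite(observations))) stopf("observations must be finite")
  observations
}

#' Per-patient supervised parameter estimates
#'
#' From one patient's labeled scan sequence: the initial distribution is the
#' one-hot vector of the first scan's label; each transition-matrix row is
#' the empirical fraction of transitions out of that state; each emission
#' row is the column-wise sum of the absolute observation vectors of the
#' scans in that state, normalized to sum 1 (absolute values first, since
#' feature entries may be negative while probabilities cannot be).
#'
#' States that produce no transitions (e.g. an all-cystic patient has no
#' transitions out of state 2) or no scans get uniform fallback rows, and
#' the affected rows are flagged so averaging can optionally exclude them.
#'
#' @param labels Length-T sequence over \{1, 2\}.
#' @param observations T x K numeric matrix, rows aligned with `labels`.
#' @return List with `A`, `B`, `pi`, and logical flags `A_fallback`,
#'   `B_fallback` (length 2 each, `TRUE` where the uniform fallback was
#'   used).
#' @examples
#' est <- estimate_patient_params(c(2, 1, 2), rbind(c(1, 3), c(-3, 1), c(2, 2)))
#' est$A   # one 2->1 and one 1->2 transition
#' @export
estimate_patient_params <- function(labels, observations) {
  labels <- check_labels(labels)
  T <- length(labels)
  observations <- as_obs_matrix(observations, T)
  K <- ncol(observations)

  pi_i <- if (labels[1] == 1L) c(1, 0) else c(0, 1)

  counts <- matrix(0, 2, 2)
  if (T > 1L) for (t in 2:T)
    counts[labels[t - 1L], labels[t]] <- counts[labels[t - 1L], labels[t]] + 1
  A_fallback <- rowSums(counts) == 0
  A_i <- counts / ifelse(rowSums(counts) == 0, 1, rowSums(counts))
  A_i[A_fallback, ] <- 0.5

  B_i <- matrix(0, 2, K)
  B_fallback <- c(FALSE, FALSE)
  for (s in 1:2) {
    rows <- which(labels == s)
    if (length(rows) == 0L) {
      B_i[s, ] <- 1 / K
      B_fallback[s] <- TRUE
    } else {
      sums <- colSums(abs(observations[rows, , drop = FALSE]))
      if (sum(sums) == 0)
        stopf("degenerate emissions: all-zero |observations| for state %d", s)
      B_i[s, ] <- sums / sum(sums)
    }
  }
  list(A = A_i, B = B_i, pi = pi_i,
       A_fallback = A_fallback, B_fallback = B_fallback)
}

# Accept either $labels or $states as the label field of a patient record.
patient_labels <- function(p) {
  lab <- if (!is.null(p$labels)) p$labels else p$states
  if (is.null(lab)) stopf("each patient needs a 'labels' (or 'states') field")
  lab
}

#' Train the HMM by averaging per-patient estimates
#'
#' Runs [estimate_patient_params()] on every patient and takes element-wise
#' means: `A_total = mean(A_i)`, `B_total = mean(B_i)`,
#' `pi_total = mean(pi_i)`. The mean of row-stochastic matrices is
#' row-stochastic, so the result is a valid model. With
#' `exclude_flagged = TRUE`, rows that fell back to uniform in a patient
#' (states absent from that patient's sequence) are left out of that row's
#' average instead of contributing the uniform value; a row flagged in every
#' patient stays uniform.
#'
#' @param patient_data List of patients, each with `labels` (or `states`)
#'   and `observations` — e.g. the output of
#'   [generate_patient_sequences()].
#' @param exclude_flagged Drop uniform-fallback rows from the averages.
#' @param feature_name Optional tag stored in the model.
#' @return An [hmm_params()] object.
#' @export
hmm_train <- function(patient_data, exclude_flagged = FALSE,
                      feature_name = NULL) {
  if (length(patient_data) == 0L) stopf("need at least one patient")
  ests <- lapply(patient_data, function(p)
    estimate_patient_params(patient_labels(p), p$observations))
  Ks <- vapply(ests, function(e) ncol(e$B), 1L)
  if (length(unique(Ks)) != 1L)
    stopf("inconsistent observation length K across patients: %s",
          paste(unique(Ks), collapse = ", "))
  N <- length(ests)
  A <- Reduce(`+`, lapply(ests, `[[`, "A")) / N
  B <- Reduce(`+`, lapply(ests, `[[`, "B")) / N
  pi <- Reduce(`+`, lapply(ests, `[[`, "pi")) / N
  if (exclude_flagged) {
    for (s in 1:2) {
      okA <- !vapply(ests, function(e) e$A_fallback[s], TRUE)
      if (any(okA))
        A[s, ] <- Reduce(`+`, lapply(ests[okA], function(e) e$A[s, ])) / sum(okA)
      okB <- !vapply(ests, function(e) e$B_fallback[s], TRUE)
      if (any(okB))
        B[s, ] <- Reduce(`+`, lapply(ests[okB], function(e) e$B[s, ])) / sum(okB)
    }
  }
  hmm_params(A, B, pi, feature_name = feature_name)
}

#' Emission score of an observation under one state's profile
#'
#' The model never defines a density over raw feature vectors; instead an
#' observation `o` is scored against an emission row by reducing it to its
#' normalized absolute profile. The default (`mode = "dot"`) is the inner
#' product `sum(B_row * |o| / sum(|o|))` — the expected emission probability
#' under the observation's weight profile, bounded in `(0, 1]` and symmetric
#' with how `B` is estimated. `mode = "multinomial"` instead returns the
#' multinomial log-likelihood `sum(|o| * log(B_row))`, with `eps` smoothing
#' added to zero profile entries before the log.
#'
#' @param B_row Length-K stochastic vector (one row of `B`).
#' @param o Length-K observation vector, not all zero.
#' @param mode `"dot"` (probability scale) or `"multinomial"` (log scale).
#' @param eps Smoothing for zero entries in multinomial mode.
#' @return A scalar score: in `(0, 1]` for `"dot"`, a log-likelihood
#'   (`<= 0` for count-type `o`) for `"multinomial"`.
#' @export
emission_score <- function(B_row, o, mode = c("dot", "multinomial"),
                           eps = 1e-10) {
  mode <- match.arg(mode)
  if (length(B_row) != length(o))
    stopf("B_row and o must have equal length")
  ao <- abs(o)
  s <- sum(ao)
  if (s == 0) stopf("degenerate observation: |o| sums to zero")
  if (mode == "dot") {
    sum(B_row * ao / s)
  } else {
    br <- ifelse(B_row <= 0, eps, B_row)
    sum(ao * log(br))
  }
}

# Log emission scores, 2 x T, for a whole observation matrix.
emission_log_matrix <- function(params, observations, mode, eps = 1e-10) {
  T <- nrow(observations)
  out <- matrix(NA_real_, 2L, T)
  for (t in seq_len(T)) {
    for (s in 1:2) {
      sc <- emission_score(params$B[s, ], observations[t, ], mode, eps)
      out[s, t] <- if (mode == "dot") log(sc) else sc
    }
  }
  out
}

#' Viterbi decoding of a patient's scan sequence
#'
#' Computes the most probable hidden-state path given the trained model and
#' the patient's ordered observation vectors. The trellis is built in the
#' log domain: `delta[i, 1] = log(pi[i]) + log(b_i(o_1))`, then
#' `delta[j, t] = max_i(delta[i, t-1] + log(a_ij)) + log(b_j(o_t))` with
#' backpointers `phi[j, t] = argmax_i(...)`. The terminal state is the
#' argmax of the last trellis column and the path is recovered by following
#' `phi` backwards. All ties (in the recursion and at the terminal) break
#' deterministically toward state 1, the lowest index.
#'
#' @param params An [hmm_params()] model.
#' @param observations T x K matrix, rows in scan order.
#' @param emission_mode Passed to [emission_score()].
#' @return An object of class `viterbi_trellis`: list with `delta` (2xT,
#'   log domain), `phi` (2xT backpointers, column 1 zero), `qP` (length-T
#'   decoded states over \{1, 2\}) and `log_score` (log score of the
#'   decoded path).
#' @export
hmm_viterbi <- function(params, observations, emission_mode = "dot") {
  if (!inherits(params, "hmm_params")) stopf("params must be hmm_params")
  observations <- as.matrix(observations)
  if (ncol(observations) != params$K)
    stopf("observation length %d does not match model K = %d",
          ncol(observations), params$K)
  T <- nrow(observations)
  if (T < 1L) stopf("need at least one observation")
  le <- emission_log_matrix(params, observations, emission_mode)
  lA <- log(params$A)
  delta <- matrix(-Inf, 2L, T)
  phi <- matrix(0L, 2L, T)
  delta[, 1L] <- log(params$pi) + le[, 1L]
  if (all(delta[, 1L] == -Inf))
    stopf("decoding failure: both states have zero probability at t = 1")
  if (T > 1L) {
    for (t in 2:T) {
      for (j in 1:2) {
        cand <- delta[, t - 1L] + lA[, j]
        i_star <- which.max(cand)     # ties -> state 1 (first index)
        phi[j, t] <- i_star
        delta[j, t] <- cand[i_star] + le[j, t]
      }
      if (all(delta[, t] == -Inf))
        stopf("decoding failure: both states have zero probability at t = %d", t)
    }
  }
  qP <- integer(T)
  qP[T] <- which.max(delta[, T])      # ties -> state 1
  if (T > 1L) for (t in (T - 1L):1L) qP[t] <- phi[qP[t + 1L], t + 1L]
  structure(list(delta = delta, phi = phi, qP = qP,
                 log_score = delta[qP[T], T]),
            class = "viterbi_trellis")
}

#' Posterior per-scan probability of the cystic state
#'
#' Forward-backward smoothing under the same emission reduction as
#' [hmm_viterbi()]: returns `P(state_t = 1 | o_1..o_T)` for every scan.
#' This continuous score complements the hard Viterbi path and is the input
#' used for ROC analysis of the HMM.
#'
#' @inheritParams hmm_viterbi
#' @return Numeric length-T vector in `[0, 1]`.
#' @export
posterior_scores <- function(params, observations, emission_mode = "dot") {
  if (!inherits(params, "hmm_params")) stopf("params must be hmm_params")
  observations <- as.matrix(observations)
  if (ncol(observations) != params$K)
    stopf("observation length %d does not match model K = %d",
          ncol(observations), params$K)
  T <- nrow(observations)
  le <- emission_log_matrix(params, observations, emission_mode)
  # Per-column shift keeps the scaled forward-backward in a safe range.
  e <- exp(sweep(le, 2L, apply(le, 2L, max)))
  if (any(colSums(e) == 0))
    stopf("decoding failure: both states have zero probability at some scan")
  A <- params$A
  alpha <- matrix(0, 2L, T)
  a1 <- params$pi * e[, 1L]
  alpha[, 1L] <- a1 / sum(a1)
  if (T > 1L) for (t in 2:T) {
    at <- as.numeric(t(A) %*% alpha[, t - 1L]) * e[, t]
    alpha[, t] <- at / sum(at)
  }
  beta <- matrix(1, 2L, T)
  if (T > 1L) for (t in (T - 1L):1L) {
    bt <- as.numeric(A %*% (e[, t + 1L] * beta[, t + 1L]))
    beta[, t] <- bt / sum(bt)
  }
  g <- alpha * beta
  g[1L, ] / colSums(g)
}
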