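---
title: "Cyst identification in retinal OCT with a two-state hidden Markov model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyst identification in retinal OCT with a two-state HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octhmm)
```

## The model and its assumptions

`octhmm` treats the cystic status of each B-scan in a patient's ordered OCT
volume as the hidden state of a two-state ergodic Markov chain. The key
anatomical assumption is spatial persistence: consecutive B-scans sample
adjacent retinal slices, so cysts extend across neighbouring scans and
`P(cystic | previous scan cystic)` is high. The observable per scan is a
fixed-length feature vector; the emission model does not assume a parametric
density over raw features but reduces each observation to its normalized
absolute profile (below).

Three further assumptions are worth making explicit:

* **Within-patient ordering is meaningful and contiguous.** The manifest
  reader enforces contiguous ascending `scan_index` per patient; decoding a
  shuffled or gappy sequence would silently change the problem.
* **Scan labels are available for training.** Estimation is supervised
  (counting and averaging); there is no Baum–Welch fallback, by design.
* **Two states suffice.** The package does not model cyst size, count, or
  position — only presence.

## Supervised estimation

Per patient: the initial distribution is the one-hot first-scan label; each
transition row is the empirical fraction of observed transitions out of that
state; emission row *i* is the column-wise sum of |o| over scans labeled
*i*, normalized to sum 1 (absolute values first, because feature entries may
be negative while probabilities cannot be). The final model averages the
per-patient estimates element-wise, which preserves row-stochasticity.

**Fallback rows.** A patient whose sequence never leaves (or never enters)
a state yields a 0/0 transition row or an empty emission row. These rows are
set to uniform and flagged. `hmm_train(exclude_flagged = TRUE)` instead
averages each row only over the patients that inform it. The default keeps
every patient (uniform rows included) for fidelity to the plain averaging
rule, but exclusion is strongly recommended for decoding work: in cohorts
where many patients lack one state, the uniform rows pull the averaged
emission profile toward 1/K exactly where the true profile is near zero,
which can invert log-likelihood scoring. We observed this concretely on
phantom cohorts: with fallback rows included the decoder classified nearly
every scan as cystic, while exclusion restored sensible behaviour.

**Small-sample bias of averaged ratios.** Averaging per-patient transition
MLEs is not the pooled MLE. For a sequence of length T, each patient
contributes a ratio estimate based on the (random) number of visits to each
state, and the mean of such ratios is biased by O(1/T), increasingly so as
one state becomes rare. Measured on simulated chains of length T = 31, the
mean per-patient estimate of a transition probability of 0.2 out of a state
occupied a third of the time is ≈ 0.27 — a bias no amount of patients
removes, because it is a property of the per-sequence estimator, not of the
sample size. The parameter-recovery experiment in the acceptance script
therefore uses a symmetric persistent chain, A = [[0.8, 0.2], [0.2, 0.8]]
with π = (0.5, 0.5), T = 31, 200 patients and K = 20, where both states are
well represented and the bias stays near 0.03; users estimating transition
structure from short sequences with a rare state should expect the rarer
state's row to be biased toward uniformity.

## Emission scoring

The emission matrix assigns probabilities to vector *components*, not to
whole vectors, so scoring a K-vector against a row needs a reduction. Two
modes are provided (`emission_score`):

* **`"dot"` (default):** the inner product of the row with |o| / sum(|o|) —
  the expected emission probability under the observation's weight profile.
  Bounded in (0, 1], smoothing-free, and symmetric with how B is built.
* **`"multinomial"`:** the multinomial log-likelihood Σ |oₖ| log Bᵢₖ, with
  ε = 1e-10 substituted for zero profile entries before the log.

The choice matters for decoding. Dot scores of both states live in a narrow
band around 1/K, so their log-ratio is small compared with the transition
log-odds (log(0.9/0.1) ≈ 2.2 for a strongly persistent chain); the Viterbi
prior then dominates and the decoded path can collapse into the more
persistent state. The multinomial reduction scales evidence with the count
mass of the observation and is the consistent likelihood for count-type
features (multinomial simulator output, keypoint-count aggregates,
magnitude-mass HOG vectors). Practical guidance: use `"dot"` when a bounded,
assumption-free score is wanted (e.g. as a ranking signal); use
`"multinomial"` when decoding sequences. The Markov-advantage experiment and
the phantom pipeline both use `"multinomial"` for the decoder *and* for the
memoryless baseline, so the comparison isolates the transition structure.

## Decoding

Viterbi runs in the log domain with −∞ for zero probabilities. Ties — in the
recursion maxima, and at the terminal state — break deterministically toward
state 1 (the cystic state). A full tie (identical emission rows, symmetric
transitions, uniform π) therefore decodes to the all-cystic path rather than
an arbitrary one; equal path scores are a theoretical failure mode of the
model, and determinism makes it testable. If both states receive zero
probability at some scan the decoder raises an error rather than guessing.
The trellis is 2×T for whatever T the patient has (volumes of 19–61 scans
are typical in SD-OCT). `posterior_scores` runs a scaled forward–backward
pass under the same emission reduction and supplies the continuous per-scan
P(cystic) used for ROC curves — the hard Viterbi path has no natural
threshold sweep, so ROC analysis of the HMM is defined on these posteriors.

## Features

* **Gradient field:** Sobel kernels applied as correlation; `a` responds to
  left-to-right intensity increase, `b` to bottom-to-top (a unit horizontal
  ramp gives a = 8 exactly). The vertical kernel is the standard Sobel
  [[1, 2, 1], [0, 0, 0], [−1, −2, −1]]; a sometimes-printed variant with +2
  in the bottom row is not a derivative operator (it responds on constant
  images) and is deliberately not used. Orientation is arctan(b/a) in
  (−π/2, π/2], with ±π/2 when a = 0 and 0 on flats; cancellation residue
  below 16·ε·max|image| is snapped to exact zero so flat regions have
  magnitude 0.
* **HOG:** d×d cells (default d = 8), 9 unsigned bins over [0°, 180°)
  (signed 0–360° optional), magnitude-weighted, no bin interpolation;
  sliding 2×2-cell blocks, each L2-normalized, concatenated. Border
  gradients are zero so a (dm)×(dn) image yields exactly m·n cells.
* **Harris / Min-Eigen:** structure tensor smoothed with a 5×5 Gaussian
  window of σ = 5/3; Harris response det − k·tr² with k = 0.04 and response
  threshold 0.01 (both exposed — the literature often conflates the two
  constants); Min-Eigen uses the smaller eigenvalue. Keypoints are strict
  3×3 local maxima with ties to the lexicographically smallest (row, col).
* **FAST:** 16-pixel radius-3 Bresenham circle, clockwise from the top;
  corner iff ≥ N contiguous circle pixels are all brighter than center + t
  or all darker than center − t. N defaults to 12 (the classic segment
  test); 9-of-16 is a config away.
* **Determinant of Hessian:** SURF-style box filters at scale σ (lobe
  3σ/1.2, forced odd), response Dxx·Dyy − (w·Dxy)² with w = 0.9, zero in
  the border band where the filters lack support. Blobs (cysts are dark
  blobs) score positive, saddles negative.
* **Aggregation:** detectors emit keypoint sets; a grid (default 8×8) turns
  them into fixed-length vectors of per-cell (count, response-sum) pairs, so
  K is independent of detections. How detector output becomes a classifier
  vector is genuinely open; counts-plus-mass is the simplest choice that
  keeps both density and strength information.
* **Deep embeddings** are a plug-in contract (`deep_embedding`): any
  deterministic function from a 3-channel image to a fixed-length vector,
  e.g. a pretrained network's FC layer. Weights are outside the package;
  `colorize_and_resize` prepares the 227×227×3 input with a monotone
  warm–cold colormap (red non-decreasing, blue non-increasing in intensity —
  unlike classic jet, channel order tracks intensity order) and
  area-average decimation, which preserves peripheral cysts that margin
  cropping would discard.

Preprocessing is margin removal only — 20/10 rows top/bottom, 13/3 columns
left/right by default for 512×496 scans (rows = height = 496 here; B-scans
are wider than tall) — no denoising, keeping the pipeline fast and the
features responsible for noise robustness.

## The synthetic generator

Phantoms emulate exactly the properties the method relies on: bright
horizontal bands (layered tissue), dark elliptical cysts confined to bands
and strictly darker than their band before noise, multiplicative speckle
(image·(1 + σN(0,1)), clipped), and — in `simulate_phantom_cohort` —
Markov-persistent cystic status across a patient's scans. Sequence
simulation (`generate_patient_sequences`) emits multinomial count vectors
from a known λ, which makes the normalize-summed-|o| training rule a
consistent estimator of the generating B and enables parameter-recovery
tests; a configurable fraction of entries can be sign-flipped to exercise
the absolute-value step.

What the phantoms do **not** model: real retinal anatomy and curvature,
vendor-specific speckle statistics, shadowing artifacts, intensity
inhomogeneity, or the feature statistics of clinical OCT. Green tests
demonstrate that the estimators, decoder and harness are correct and that
the Markov mechanism delivers its advantage when its assumptions hold; they
do not certify clinical accuracy figures, which require real labeled
volumes.

## Problem sizes and numerical choices

The test suite and acceptance script use deliberately modest sizes chosen as
adequate for each statistical claim: 100 random instances (T ≤ 10) for
Viterbi-vs-enumeration, 200 patients × 31 scans for recovery, 50 runs × 20
patients for the Markov advantage, 30 patients × 12 phantom scans (96×128)
for the end-to-end pipeline, 2·10⁴ permutation replicates against DeLong's
test at n = 20. Models serialize to JSON with 17 significant digits (exact
IEEE round trip); loading re-validates row-stochasticity, so tampered files
fail fast. All stochastic code paths take explicit seeds; all tie-breaks are
deterministic and documented.

## Known limitations

* The per-patient ratio averaging is biased for short sequences with a rare
  state (quantified above); pooled counting would remove it but is a
  different estimator by construction.
* The dot emission reduction compresses evidence; decoding with it under
  strong persistence can collapse to one state (use multinomial mode).
* DeLong's normal approximation is rough below ~30 cases per class; the
  permutation comparison in the tests quantifies the discrepancy.
* KNN tie behaviour depends on the RNG; the ranking harness derives
  per-method seeds from the split seed to stay reproducible.
* The classifiers in the ranking harness are intentionally plain (linear
  SVM, Euclidean KNN with k = 5, single batch fit — incremental fitting of a
  linear margin converges to the same decision function); no hyperparameter
  search is performed.
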