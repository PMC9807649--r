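# High-level wrappers tying the modules into the end-to-end workflow:
# manifest -> features -> trained HMM -> decoded state sequences.

#' Extract features for every scan in a manifest
#'
#' @param manifest An `oct_manifest` (see [read_manifest()]).
#' @param method Feature method name.
#' @param config Config list for [extract_feature()].
#' @param crop Optional [crop_spec()] applied before extraction.
#' @return Numeric matrix, one row per manifest row.
#' @export
manifest_features <- function(manifest, method, config = list(), crop = NULL) {
  images <- lapply(manifest$path, load_image)
  if (!is.null(crop)) images <- lapply(images, crop_margins, spec = crop)
  K <- extract_feature(images[[1L]], method, config)$K
  t(vapply(images, function(img)
    extract_feature(img, method, config)$values, numeric(K)))
}

split_by_patient <- function(manifest, features) {
  lapply(split(seq_len(nrow(manifest)), manifest$patient_id), function(ix) {
    ix <- ix[order(manifest$scan_index[ix])]
    list(patient_id = manifest$patient_id[ix[1L]],
         labels = manifest$label[ix],
         observations = features[ix, , drop = FALSE],
         scan_index = manifest$scan_index[ix])
  })
}

#' Train the HMM from a labeled manifest
#'
#' Extracts per-scan features, groups them into per-patient labeled
#' sequences and runs [hmm_train()].
#'
#' @inheritParams manifest_features
#' @param exclude_flagged See [hmm_train()].
#' @return An [hmm_params()] model tagged with the feature method.
#' @export
hmm_from_manifest <- function(manifest, method, config = list(), crop = NULL,
                              exclude_flagged = FALSE) {
  if (any(is.na(manifest$label)))
    stopf("training requires a fully labeled manifest")
  feats <- manifest_features(manifest, method, config, crop)
  hmm_train(split_by_patient(manifest, feats),
            exclude_flagged = exclude_flagged, feature_name = method)
}

#' Decode every patient in a manifest
#'
#' Runs Viterbi decoding and forward-backward posterior scoring patient by
#' patient, in scan order.
#'
#' @inheritParams manifest_features
#' @param params A trained [hmm_params()] model; its `feature_name`, when
#'   set, must match `method`.
#' @param emission_mode See [emission_score()].
#' @return A `data.frame` with columns `patient_id`, `scan_index`, `qP`
#'   (decoded state, 1 = cystic) and `posterior_state1`.
#' @export
decode_manifest <- function(params, manifest, method, config = list(),
                            crop = NULL, emission_mode = "dot") {
  if (!is.null(params$feature_name) && params$feature_name != method)
    stopf("model was trained on feature '%s', decoding requested '%s'",
          params$feature_name, method)
  feats <- manifest_features(manifest, method, config, crop)
  pats <- split_by_patient(manifest, feats)
  out <- lapply(pats, function(p) {
    vt <- hmm_viterbi(params, p$observations, emission_mode)
    post <- posterior_scores(params, p$observations, emission_mode)
    data.frame(patient_id = p$patient_id, scan_index = p$scan_index,
               qP = vt$qP, posterior_state1 = post)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-scan emission-only baseline
#'
#' Labels each observation independently by the larger emission score,
#' ignoring the Markov chain entirely. This is the memoryless comparator
#' that isolates the contribution of state persistence to decoding
#' accuracy.
#'
#' @param params An [hmm_params()] model (only `B` is used).
#' @param observations T x K matrix.
#' @param emission_mode See [emission_score()].
#' @return Integer vector over \{1, 2\}, one per row (ties toward state 1).
#' @export
emission_only_classify <- function(params, observations,
                                   emission_mode = "dot") {
  observations <- as.matrix(observations)
  le <- emission_log_matrix(params, observations, emission_mode)
  apply(le, 2L, which.max)
}
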