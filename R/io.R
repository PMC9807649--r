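# Manifest / image / model readers and writers.

#' Read and validate a scan manifest
#'
#' A manifest CSV lists one row per B-scan with columns `patient_id`,
#' `scan_index`, `path` and optionally `label`. Scan indices must be
#' contiguous ascending within each patient (the HMM needs each scan's
#' predecessor). Labels may be encoded 1 = cystic / 2 = non-cystic, or
#' 0/1 with 1 = cystic (detected by the presence of a 0); they are
#' canonicalized to \{1, 2\}.
#'
#' @param path CSV file path.
#' @param require_labels Fail when the `label` column is missing or
#'   incomplete (needed for training; decode-only manifests may be
#'   unlabeled).
#' @param check_paths Verify that every image file exists.
#' @return A `data.frame` (class `oct_manifest`) ordered by patient and
#'   scan index, with `label` canonicalized or `NA`.
#' @export
read_manifest <- function(path, require_labels = FALSE, check_paths = TRUE) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "scan_index", "path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("manifest is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$scan_index <- as.integer(df$scan_index)
  df <- df[order(df$patient_id, df$scan_index), , drop = FALSE]
  rownames(df) <- NULL
  for (pid in unique(df$patient_id)) {
    si <- df$scan_index[df$patient_id == pid]
    if (any(diff(si) != 1L))
      stopf("scan_index not contiguous ascending for patient '%s'", pid)
  }
  if ("label" %in% names(df) && !all(is.na(df$label))) {
    lab <- as.integer(df$label)
    if (any(is.na(lab))) stopf("non-numeric label values in manifest")
    if (any(lab == 0L)) {            # 0/1 encoding, 1 = cystic
      if (!all(lab %in% c(0L, 1L)))
        stopf("labels mix 0/1 and 1/2 encodings")
      lab <- ifelse(lab == 1L, 1L, 2L)
    } else if (!all(lab %in% c(1L, 2L))) {
      stopf("labels must be coded 0/1 or 1/2")
    }
    df$label <- lab
  } else {
    if (require_labels) stopf("manifest has no labels but labels are required")
    df$label <- NA_integer_
  }
  if (require_labels && any(is.na(df$label)))
    stopf("manifest labels are incomplete")
  if (check_paths) {
    gone <- !file.exists(df$path)
    if (any(gone))
      stopf("missing image file(s), e.g. %s", df$path[which(gone)[1L]])
  }
  class(df) <- c("oct_manifest", "data.frame")
  df
}

#' Load a grayscale image
#'
#' Reads a TIFF or PNG file into a numeric matrix in `[0, 1]` (8/16-bit
#' integer data are rescaled by the readers). Multi-channel inputs are
#' collapsed to a single channel by averaging the color channels (alpha
#' ignored).
#'
#' @param path Image file path (`.tif`, `.tiff`, `.png`).
#' @return Numeric matrix, rows = image height.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stopf("image not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stopf("unsupported image format '.%s' (use TIFF or PNG)", ext))
  if (length(dim(img)) == 3L) {
    nc <- min(dim(img)[3L], 3L)      # drop alpha if present
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
  }
  if (!is.matrix(img)) img <- as.matrix(img)
  img
}

#' Save an HMM model as JSON
#'
#' Serializes `A`, `B`, `pi`, `K` and the feature tag with full double
#' precision so that a save/load round trip reproduces the matrices exactly
#' at 15+ significant digits.
#'
#' @param params An [hmm_params()] model.
#' @param path Output JSON path.
#' @export
save_hmm_model <- function(params, path) {
  if (!inherits(params, "hmm_params")) stopf("params must be hmm_params")
  obj <- list(A = params$A, B = params$B, pi = params$pi, K = params$K,
              feature_name = params$feature_name,
              format = "octhmm-model-v1")
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load an HMM model from JSON
#'
#' Re-validates all stochasticity invariants on load, so a tampered file
#' (e.g. a transition row no longer summing to 1) is rejected.
#'
#' @param path JSON path written by [save_hmm_model()].
#' @return An [hmm_params()] model.
#' @export
load_hmm_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$A) || is.null(obj$B) || is.null(obj$pi))
    stopf("model file %s lacks A/B/pi fields", path)
  B <- matrix(as.numeric(obj$B), nrow = 2L, byrow = FALSE)
  if (!is.null(dim(obj$B))) B <- obj$B
  params <- hmm_params(obj$A, B, obj$pi,
                       feature_name = obj$feature_name)
  if (!is.null(obj$K) && params$K != obj$K)
    stopf("stored K (%s) disagrees with B's width (%d)", obj$K, params$K)
  params
}
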