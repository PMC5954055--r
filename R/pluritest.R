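# Align a named profile (or matrix) to the model's gene set; error when the
# overlap is too small.
align_to_model <- function(x, model, min_overlap = 0.95) {
  genes <- rownames(model$basis)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x), "x"))
  shared <- intersect(genes, rownames(x))
  if (!length(shared)) stopf("no genes overlap the model")
  if (length(shared) / length(genes) < min_overlap)
    stopf("only %.0f%% of model genes present (need %.0f%%)",
          100 * length(shared) / length(genes), 100 * min_overlap)
  x[match(genes, rownames(x)), , drop = FALSE]
}

#' Platform-shift vector from study H9 samples
#'
#' The correction for a platform change is the difference between the
#' row-wise means of the study's H9 replicate profiles and the H9 reference
#' profile the model was trained against. Subtracting it from every study
#' sample moves the study's H9 mean exactly onto the reference.
#'
#' @param study_h9 Genes x replicates matrix (or a single named profile) of
#'   H9 samples from the current dataset.
#' @param model A `projection_model` (see [gen_projection_model()] or
#'   [read_projection_model()]); at least 95% of its genes must be present.
#' @return Named gene-length shift vector.
#' @export
compute_shift_vector <- function(study_h9, model) {
  stopifnot(inherits(model, "projection_model"))
  h9 <- align_to_model(study_h9, model)
  if (anyNA(h9)) stopf("study H9 profiles do not cover the model gene set")
  setNames(rowMeans(h9) - model$h9_reference, rownames(model$basis))
}

#' Project a corrected sample onto the model basis
#'
#' After subtracting the platform shift, component weights are estimated by
#' unconstrained ordinary least squares, `h = argmin ||x' - B h||`,
#' replacing the non-negative multiplicative update of the original trained
#' model (the shift-corrected data are not restricted to positive values).
#' The reconstruction error is returned as the root-mean-square residual.
#'
#' @param sample Named gene-length expression profile.
#' @param model A `projection_model`.
#' @param shift Optional shift vector from [compute_shift_vector()]; zero
#'   when omitted.
#' @return List with `weights` (length-k) and `residual_rms`.
#' @export
project_sample <- function(sample, model, shift = NULL) {
  stopifnot(inherits(model, "projection_model"))
  x <- drop(align_to_model(sample, model))
  if (anyNA(x)) stopf("sample does not cover the model gene set")
  if (!is.null(shift)) x <- x - shift
  B <- model$basis
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) stopf("model basis is rank deficient")
  h <- qr.coef(qrB, x)
  resid <- x - drop(B %*% h)
  list(weights = setNames(as.numeric(h), colnames(B)),
       residual_rms = sqrt(mean(resid^2)))
}

#' Pluripotency / Novelty scores and threshold classification
#'
#' The Pluripotency Score is the dot product of the model's score weights
#' with the projection weights; the Novelty Score is the residual RMS mapped
#' through the model's monotone calibration (identity unless the model file
#' supplies an affine map). A sample passes when its Pluripotency Score is
#' at or above the pluripotency threshold and its Novelty Score is below the
#' novelty threshold; otherwise the failing criteria are flagged.
#'
#' @param weights Projection weights from [project_sample()].
#' @param residual_rms Residual RMS from [project_sample()].
#' @param model A `projection_model` carrying `thresholds` and
#'   `novelty_calibration`.
#' @return List with `pluripotency`, `novelty`, `classification` in
#'   `pass`, `flag-novelty`, `flag-pluripotency`, `flag-both`.
#' @export
score_and_classify <- function(weights, residual_rms, model) {
  stopifnot(inherits(model, "projection_model"))
  pluri <- sum(model$score_weights * weights)
  cal <- model$novelty_calibration %||% c(intercept = 0, slope = 1)
  novelty <- cal[["intercept"]] + cal[["slope"]] * residual_rms
  th <- model$thresholds
  low_pluri <- pluri < th[["pluripotency"]]
  high_nov <- novelty >= th[["novelty"]]
  cls <- if (low_pluri && high_nov) "flag-both"
  else if (high_nov) "flag-novelty"
  else if (low_pluri) "flag-pluripotency"
  else "pass"
  list(pluripotency = pluri, novelty = novelty, classification = cls)
}

#' Run the projection test on a sample matrix
#'
#' Computes the platform shift from the named H9 replicates (omitted when
#' `h9_samples` is `NULL`), projects every sample, and scores and
#' classifies it.
#'
#' @param matrix Genes x samples expression matrix.
#' @param model A `projection_model`.
#' @param h9_samples Column names of the study's H9 replicates.
#' @return A `pluritest_result` data frame: `sample`, `pluripotency`,
#'   `novelty`, `classification`.
#' @export
pluritest <- function(matrix, model, h9_samples = NULL) {
  shift <- if (!is.null(h9_samples))
    compute_shift_vector(matrix[, h9_samples, drop = FALSE], model)
  rows <- lapply(colnames(matrix), function(s) {
    pr <- project_sample(matrix[, s], model, shift)
    sc <- score_and_classify(pr$weights, pr$residual_rms, model)
    data.frame(sample = s, pluripotency = sc$pluripotency,
               novelty = sc$novelty, classification = sc$classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pluritest_result", "data.frame")
  out
}

#' Aggregate replicate-level results into cell-line calls
#'
#' A line passes when any replicate passes (one replicate below the novelty
#' threshold is considered sufficient); lines whose replicates are all
#' flagged are reported for further investigation. Replicate disagreement -
#' a novelty spread above `novelty_delta` - is annotated, since it may
#' reflect hybridisation failure or spontaneous differentiation in one
#' replicate.
#'
#' @param results A `pluritest_result` data frame.
#' @param lines Character vector mapping each result row to its cell line.
#' @param novelty_delta Spread (max - min novelty) above which replicate
#'   disagreement is annotated (default 0.5).
#' @return Data frame: `line`, `n_replicates`, `call`
#'   (`pass`/`investigate`), `novelty_spread`, `disagreement`.
#' @export
replicate_report <- function(results, lines, novelty_delta = 0.5) {
  stopifnot(nrow(results) == length(lines), nrow(results) >= 1L)
  rows <- lapply(unique(lines), function(ln) {
    r <- results[lines == ln, , drop = FALSE]
    spread <- if (nrow(r) > 1L) max(r$novelty) - min(r$novelty) else 0
    data.frame(line = ln, n_replicates = nrow(r),
               call = if (any(r$classification == "pass")) "pass" else "investigate",
               novelty_spread = spread,
               disagreement = spread > novelty_delta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
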