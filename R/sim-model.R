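#' Simulate a toy projection model for PluriTest-style scoring
#'
#' Builds a small stand-in for a trained transcriptome component model: a
#' non-negative genes x k basis with linearly independent columns, a score
#' weight vector whose first ("pluripotency") component dominates, and an H9
#' reference profile lying exactly in the basis span. The synthetic model is
#' labelled as such; it carries the published thresholds so that
#' classification logic can be exercised end to end.
#'
#' @param config A [sim_config()].
#' @param k Number of components (>= 2).
#' @param n_genes Number of genes.
#' @param thresholds Named vector `c(pluripotency =, novelty =)`.
#' @return A `projection_model`: list with `basis`, `score_weights`,
#'   `h9_reference`, `h9_weights` (the reference's true component weights),
#'   `thresholds` and `novelty_calibration` (affine `c(intercept, slope)`,
#'   identity by default).
#' @export
gen_projection_model <- function(config, k = 3L, n_genes = 200L,
                                 thresholds = c(pluripotency = 20, novelty = 1.67)) {
  stopifnot(inherits(config, "sim_config"))
  k <- as.integer(k)
  if (k < 2L) stopf("k must be at least 2")
  if (k > n_genes) stopf("k cannot exceed the gene count")
  with_seed(config$seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    basis <- matrix(runif(n_genes * k, 0.2, 2), nrow = n_genes,
                    dimnames = list(genes, sprintf("C%d", seq_len(k))))
    if (qr(basis)$rank < k) stopf("generated basis is rank deficient")  # a.s. never
    # component 1 carries the pluripotency signal
    score_weights <- c(25, runif(k - 1L, 1, 3))
    h9_weights <- c(1, runif(k - 1L, 0.05, 0.15))
    h9_reference <- drop(basis %*% h9_weights)
    structure(list(basis = basis,
                   score_weights = score_weights,
                   h9_reference = h9_reference,
                   h9_weights = h9_weights,
                   thresholds = thresholds,
                   novelty_calibration = c(intercept = 0, slope = 1)),
              class = "projection_model")
  })
}
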