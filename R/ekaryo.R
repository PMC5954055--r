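#' Preprocess a probe expression matrix for e-Karyotyping
#'
#' Applies, in order: (1) removal of probes without chromosome annotation;
#' (2) an expression floor at the boundary of the upper third of the pooled
#' log2 intensity distribution, with all lower values raised to it;
#' (3) removal of probes not expressed (pre-floor value below the floor) in
#' more than `presence_fraction` of samples; (4) per-probe median centering
#' across samples; (5) removal of the `variability_fraction` most variable
#' probes by the sum of squares of their relative values (ties broken by
#' probe label); (6) sorting by chromosome and position.
#'
#' @param x A `probe_matrix` (see [gen_probe_matrix()] or
#'   [read_probe_matrix()]).
#' @param presence_fraction Probes not expressed in more than this fraction
#'   of samples are removed (default 0.20).
#' @param variability_fraction Fraction of most-variable probes removed
#'   (default 0.10).
#' @return A `rel_expr` object: list with `values` (median-centred log2
#'   matrix, probes sorted by genome position), `annotation`, and
#'   `floor_threshold`.
#' @export
ekaryo_preprocess <- function(x, presence_fraction = 0.20,
                              variability_fraction = 0.10) {
  stopifnot(inherits(x, "probe_matrix") ||
              (is.list(x) && all(c("values", "annotation") %in% names(x))))
  values <- x$values
  ann <- x$annotation
  if (ncol(values) < 2L) stopf("at least 2 samples are required")

  keep <- !is.na(ann$chromosome)
  values <- values[keep, , drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  if (nrow(values) == 0L)
    stopf("no probes left after removing unannotated probes")

  floor_thr <- unname(quantile(values, probs = 2 / 3))
  not_expr <- values < floor_thr           # pre-floor expression calls
  values <- pmax(values, floor_thr)
  keep <- rowMeans(not_expr) <= presence_fraction
  values <- values[keep, , drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  if (nrow(values) == 0L)
    stopf("no probes left after the %.0f%% presence filter",
          100 * presence_fraction)

  med <- apply(values, 1L, median)
  rel <- values - med

  ss <- rowSums(rel^2)
  n_drop <- floor(variability_fraction * nrow(rel))
  if (n_drop > 0) {
    drop_idx <- order(-ss, rownames(rel))[seq_len(n_drop)]
    rel <- rel[-drop_idx, , drop = FALSE]
    ann <- ann[-drop_idx, , drop = FALSE]
  }
  if (nrow(rel) == 0L)
    stopf("no probes left after removing the %.0f%% most variable probes",
          100 * variability_fraction)

  ord <- order(chrom_factor(ann$chromosome), ann$position)
  structure(list(values = rel[ord, , drop = FALSE],
                 annotation = ann[ord, , drop = FALSE],
                 floor_threshold = floor_thr),
            class = "rel_expr")
}

#' Chromosome-wise moving average of relative expression
#'
#' Sliding-window (stride 1) arithmetic means of median-centred log2
#' expression over probes ordered by genomic position, computed per sample
#' and chromosome. Windows are anchored at probe ordinals; genomic distance
#' is ignored, matching the "window of n genes" convention of
#' expression-based CGH viewers. Chromosomes with fewer probes than the
#' window yield no windows (one warning per call).
#'
#' @param rel A `rel_expr` from [ekaryo_preprocess()].
#' @param window Window size in probes (default 300).
#' @return A `ma_track` data frame: `sample`, `chromosome`, `start`, `end`
#'   (probe ordinals within the chromosome), `center`, `mean`; the window
#'   size is kept in the `"window"` attribute.
#' @export
moving_average <- function(rel, window = 300L) {
  stopifnot(inherits(rel, "rel_expr"))
  window <- as.integer(window)
  if (window < 1L) stopf("window must be at least 1")
  ann <- rel$annotation
  chroms <- chrom_levels(ann$chromosome)
  short <- character(0)
  pieces <- list()
  for (ch in chroms) {
    idx <- which(ann$chromosome == ch)
    m <- length(idx)
    if (m < window) {
      short <- c(short, ch)
      next
    }
    nwin <- m - window + 1L
    for (s in colnames(rel$values)) {
      mu <- zoo::rollmean(rel$values[idx, s], k = window)
      pieces[[length(pieces) + 1L]] <- data.frame(
        sample = s, chromosome = ch,
        start = seq_len(nwin), end = seq_len(nwin) + window - 1L,
        center = seq_len(nwin) + (window - 1) / 2,
        mean = as.numeric(mu), stringsAsFactors = FALSE)
    }
  }
  if (length(short))
    warnf("chromosomes with fewer than %d probes yield no windows: %s",
          window, paste(short, collapse = ", "))
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(sample = character(0), chromosome = character(0),
               start = integer(0), end = integer(0),
               center = numeric(0), mean = numeric(0))
  attr(out, "window") <- window
  class(out) <- c("ma_track", "data.frame")
  out
}

# Per-probe weights such that crossprod(weights, x) equals the mean of all
# stride-1 window means of x (length m, window w).
window_mean_weights <- function(m, w) {
  nwin <- m - w + 1L
  cover <- pmin(seq_len(m), w, nwin, m - seq_len(m) + 1L)
  cover / (nwin * w)
}

#' Call chromosome-level aberrations from regional expression bias
#'
#' For each (sample, chromosome) the statistic is the mean of the moving-
#' average window means, equal to a coverage-weighted mean of the probe
#' values. The null distribution is built by permuting the probe-to-position
#' assignment within the sample and recomputing every chromosome's statistic;
#' a two-sided permutation tail probability is reported with per-sample
#' Bonferroni correction across chromosomes. This replaces the visual
#' inspection of moving-average plots with reproducible, assertable calls.
#'
#' The statistic is a weighted mean of hundreds of exchangeable probe
#' values, so its permutation null is very close to Gaussian; by default the
#' tail probability is taken from a normal fit to the permutation null
#' (mean and sd over the permutations), which gives p-values fine enough for
#' Bonferroni correction across 22 chromosomes without needing tens of
#' thousands of permutations. `tail = "empirical"` uses the raw permutation
#' rank instead (resolution `1 / (n_permutations + 1)`).
#'
#' @param rel A `rel_expr` from [ekaryo_preprocess()].
#' @param window Moving-average window in probes (default 300); chromosomes
#'   with fewer probes are not tested.
#' @param n_permutations Number of probe-assignment permutations (default
#'   1000; below 100 a warning is issued).
#' @param alpha Significance level applied to Bonferroni-adjusted p-values.
#' @param min_deviation Minimum absolute mean deviation (log2 units) for a
#'   call. Statistical significance alone is not sufficient: a sample
#'   carrying a strong genuine gain shifts its own permutation pool, so
#'   every other chromosome sits slightly left of the null and would be
#'   flagged as a minute "loss". The default 0.1 is well below the shift of
#'   a 25% mosaic trisomy (`aberration_shift(1.5, 0.25)` = 0.17) but above
#'   such contamination echoes.
#' @param seed Optional seed for the permutations.
#' @param tail `"normal"` (default) or `"empirical"`; see Details.
#' @param samples Optional subset of sample labels to test (all by default).
#' @return Data frame with one row per tested (sample, chromosome):
#'   `sample`, `chromosome`, `mean_deviation` (log2 units), `p_value`,
#'   `p_adjusted`, `direction` (`gain`/`loss`), `called`.
#' @export
call_aberrations <- function(rel, window = 300L, n_permutations = 1000L,
                             alpha = 0.01, min_deviation = 0.1, seed = NULL,
                             tail = c("normal", "empirical"),
                             samples = NULL) {
  stopifnot(inherits(rel, "rel_expr"))
  tail <- match.arg(tail)
  samples <- samples %||% colnames(rel$values)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 100L)
    warnf("n_permutations = %d is low; permutation p-values will be coarse",
          n_permutations)
  ann <- rel$annotation
  chroms <- chrom_levels(ann$chromosome)
  segs <- lapply(chroms, function(ch) which(ann$chromosome == ch))
  names(segs) <- chroms
  segs <- segs[vapply(segs, length, 0L) >= window]
  if (!length(segs)) stopf("no chromosome has at least %d probes", window)
  weights <- lapply(segs, function(idx) window_mean_weights(length(idx), window))

  run <- function() {
    out <- list()
    for (s in samples) {
      v <- rel$values[, s]
      obs <- vapply(names(segs), function(ch)
        sum(weights[[ch]] * v[segs[[ch]]]), 0)
      null <- matrix(0, nrow = n_permutations, ncol = length(segs),
                     dimnames = list(NULL, names(segs)))
      for (b in seq_len(n_permutations)) {
        p <- sample(v)
        null[b, ] <- vapply(names(segs), function(ch)
          sum(weights[[ch]] * p[segs[[ch]]]), 0)
      }
      pval <- if (tail == "empirical") {
        vapply(names(segs), function(ch)
          (1 + sum(abs(null[, ch]) >= abs(obs[ch]))) / (n_permutations + 1), 0)
      } else {
        vapply(names(segs), function(ch) {
          z <- (obs[ch] - mean(null[, ch])) / sd(null[, ch])
          2 * stats::pnorm(-abs(z))
        }, 0)
      }
      padj <- pmin(1, pval * length(segs))
      out[[s]] <- data.frame(
        sample = s, chromosome = names(segs),
        mean_deviation = unname(obs), p_value = unname(pval),
        p_adjusted = unname(padj),
        direction = ifelse(obs >= 0, "gain", "loss"),
        called = unname(padj <= alpha & abs(obs) >= min_deviation),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
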