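#' Simulate an HT-12-style probe expression matrix
#'
#' Generates log2 intensities for `n_samples` arrays over the configured
#' chromosomes. Each probe has its own baseline mean (uniform on 6-12 log2
#' units) and i.i.d. Gaussian noise across samples. Samples listed as
#' carriers of an aberration have every probe on the named chromosome
#' shifted by [aberration_shift()]. A configurable fraction of probes is
#' generated without chromosome annotation, to exercise the removal rule in
#' e-Karyotyping preprocessing.
#'
#' @param config A [sim_config()].
#' @param aberrations List of [aberration()] objects (may be empty).
#' @param n_samples Number of arrays; at least 2.
#' @param carriers List parallel to `aberrations`, each element an integer
#'   vector of carrier sample indices. Defaults to the last sample for every
#'   aberration.
#'
#' @return A `probe_matrix`: list with `values` (probes x samples log2
#'   matrix), `annotation` (data frame: `probe_id`, `chromosome`, `position`;
#'   `chromosome` is `NA` for unannotated probes) and `samples`.
#' @export
gen_probe_matrix <- function(config, aberrations = list(), n_samples = 4L,
                             carriers = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stopf("n_samples must be at least 2")
  if (inherits(aberrations, "aberration")) aberrations <- list(aberrations)
  for (ab in aberrations) {
    if (!ab$chromosome %in% config$chromosomes)
      stopf("aberration names unknown chromosome '%s'", ab$chromosome)
  }
  if (is.null(carriers)) carriers <- rep(list(n_samples), length(aberrations))
  if (length(carriers) != length(aberrations))
    stopf("carriers must be parallel to aberrations")

  with_seed(config$seed, {
    chroms <- rep(config$chromosomes, each = config$n_probes_per_chromosome)
    n <- length(chroms)
    pos <- unlist(lapply(config$chromosomes, function(ch) {
      sort(sample.int(2e8L, config$n_probes_per_chromosome))
    }), use.names = FALSE)
    probe_id <- sprintf("P%05d", seq_len(n))
    # unannotated probes keep a row in the matrix but lose their location
    n_unann <- round(config$unannotated_fraction * n)
    unann <- if (n_unann > 0) sample.int(n, n_unann) else integer(0)
    chrom_ann <- chroms
    pos_ann <- pos
    chrom_ann[unann] <- NA_character_
    pos_ann[unann] <- NA_integer_

    base <- runif(n, 6, 12)
    # per-probe noise sd is long-tailed across genes
    probe_sd <- config$noise_sd * rlnorm(n, 0, config$noise_sd_spread)
    values <- matrix(rnorm(n * n_samples, mean = base, sd = probe_sd),
                     nrow = n, ncol = n_samples)
    samples <- sprintf("S%02d", seq_len(n_samples))
    dimnames(values) <- list(probe_id, samples)
    for (i in seq_along(aberrations)) {
      ab <- aberrations[[i]]
      shift <- aberration_shift(ab$fold_change, ab$mosaic_fraction)
      rows <- which(chroms == ab$chromosome)
      values[rows, carriers[[i]]] <- values[rows, carriers[[i]]] + shift
    }
    structure(list(
      values = values,
      annotation = data.frame(probe_id = probe_id,
                              chromosome = chrom_ann,
                              position = pos_ann,
                              stringsAsFactors = FALSE),
      samples = samples
    ), class = "probe_matrix")
  })
}
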