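#' Simulation configuration for the synthetic-data generators
#'
#' Bundles the knobs shared by all generators. The defaults describe the
#' study conditions the package's analyses assume: an HT-12-style array with
#' several hundred expressed probes per chromosome, RNA-seq SNP coverage with
#' an overdispersed mean depth of 60 reads, Fluidigm-scale qPCR replicate
#' noise, and a 14-tissue reference panel.
#'
#' @param seed Integer seed; a fixed seed makes every generator byte-identical
#'   across calls.
#' @param chromosomes Chromosome labels used by the probe and SNP generators.
#'   Autosomes 1-22 by default (mixed-sex sample sets make Y uninformative;
#'   X is excluded for the same reason but can be added).
#' @param n_probes_per_chromosome Probes simulated per chromosome. Roughly
#'   the upper third survive e-Karyotyping preprocessing (the expression
#'   floor marks the rest unexpressed), so the default (matching the ~2000 probes per chromosome of an HT-12-class array) leaves about 650
#'   probes per chromosome, comfortably above the 300-gene window.
#' @param n_snps_per_chromosome Heterozygous SNPs simulated per chromosome.
#' @param read_depth_mean,read_depth_dispersion Negative-binomial per-SNP
#'   read depth: mean and size (dispersion) parameters.
#' @param noise_sd Typical (median) Gaussian noise sd on the log2 intensity
#'   scale (arrays).
#' @param noise_sd_spread Log-normal spread (sdlog) of the per-probe noise
#'   sd around `noise_sd`. Per-gene variability on expression arrays is
#'   long-tailed (a minority of genes vary strongly across cell lines);
#'   a spread of 0 makes every probe equally noisy, under which the
#'   most-variable-probe filter behaves pathologically (it singles out
#'   genuine copy-number signal rather than intrinsically variable genes).
#' @param ct_noise_sd Gaussian replicate noise sd on the Ct scale (qPCR).
#' @param fpkm_noise_sdlog Log-normal multiplicative noise sdlog on FPKM.
#' @param n_tissues Number of reference tissues in the synthetic body panel.
#' @param unannotated_fraction Fraction of array probes generated without
#'   chromosome annotation (exercises the removal rule in preprocessing).
#' @param hom_fraction Fraction of simulated SNPs that are homozygous
#'   (exercises the minor-allele filter).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = paste0("chr", 1:22),
                       n_probes_per_chromosome = 2000L,
                       n_snps_per_chromosome = 500L,
                       read_depth_mean = 60,
                       read_depth_dispersion = 5,
                       noise_sd = 0.25,
                       noise_sd_spread = 0.6,
                       ct_noise_sd = 0.5,
                       fpkm_noise_sdlog = 0.15,
                       n_tissues = 14L,
                       unannotated_fraction = 0.02,
                       hom_fraction = 0.1) {
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) stopf("seed must be a single integer")
  if (read_depth_mean <= 0) stopf("read_depth_mean must be positive")
  if (noise_sd < 0 || noise_sd_spread < 0 || ct_noise_sd < 0 ||
      fpkm_noise_sdlog < 0)
    stopf("noise parameters must be non-negative")
  if (unannotated_fraction < 0 || unannotated_fraction >= 1)
    stopf("unannotated_fraction must be in [0, 1)")
  if (hom_fraction < 0 || hom_fraction >= 1)
    stopf("hom_fraction must be in [0, 1)")
  structure(list(
    seed = seed,
    chromosomes = chromosomes,
    n_probes_per_chromosome = as.integer(n_probes_per_chromosome),
    n_snps_per_chromosome = as.integer(n_snps_per_chromosome),
    read_depth_mean = read_depth_mean,
    read_depth_dispersion = read_depth_dispersion,
    noise_sd = noise_sd,
    noise_sd_spread = noise_sd_spread,
    ct_noise_sd = ct_noise_sd,
    fpkm_noise_sdlog = fpkm_noise_sdlog,
    n_tissues = as.integer(n_tissues),
    unannotated_fraction = unannotated_fraction,
    hom_fraction = hom_fraction
  ), class = "sim_config")
}

#' Specify a chromosomal aberration for the array simulator
#'
#' Describes a (possibly mosaic) copy-number gain or loss. A culture in which
#' a fraction `f` of cells carries `fold_change` copies relative to diploid
#' shifts the bulk log2 expression of that chromosome by
#' `log2(((1 - f) * 2 + f * 2 * fold_change) / 2)`: a full trisomy
#' (`fold_change = 1.5`, `f = 1`) gives `log2(1.5) ~ 0.585`, a 50% mosaic
#' trisomy gives `log2(1.25) ~ 0.322`.
#'
#' @param chromosome Chromosome label (must exist in the generator's
#'   annotation).
#' @param fold_change Copy number relative to diploid in the variant cells
#'   (1.5 = trisomy, 0.5 = monosomy). Must be positive.
#' @param mosaic_fraction Fraction of cells carrying the change, in `[0, 1]`.
#'
#' @return An object of class `aberration`.
#' @seealso [aberration_shift()]
#' @export
aberration <- function(chromosome, fold_change, mosaic_fraction = 1) {
  if (fold_change <= 0) stopf("fold_change must be positive")
  if (mosaic_fraction < 0 || mosaic_fraction > 1)
    stopf("mosaic_fraction must be in [0, 1]")
  structure(list(chromosome = as.character(chromosome),
                 fold_change = fold_change,
                 mosaic_fraction = mosaic_fraction),
            class = "aberration")
}

#' Expected log2 expression shift implied by a mosaic copy-number change
#'
#' @param fold_change Copy number relative to diploid in the variant cells.
#' @param mosaic_fraction Fraction of cells carrying the change.
#' @return The bulk log2 shift
#'   `log2(((1 - f) * 2 + f * 2 * fold_change) / 2)`.
#' @export
aberration_shift <- function(fold_change, mosaic_fraction = 1) {
  f <- mosaic_fraction
  log2(((1 - f) * 2 + f * 2 * fold_change) / 2)
}
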