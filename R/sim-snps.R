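#' Simulate per-SNP allele-count tables from RNA-seq
#'
#' Generates transcribed-SNP allele counts for `n_samples` samples. Read
#' depth per SNP is negative-binomial (overdispersed RNA-seq coverage).
#' Heterozygous SNPs on diploid chromosomes draw the reference-allele count
#' from a symmetric binomial (p = 1/2); on trisomic chromosomes the
#' duplicated allele is chosen at random per SNP, so p is 2/3 or 1/3. A
#' configurable fraction of SNPs is homozygous (p = 0 or 1), which carries
#' no imbalance signal and is removed by [filter_snps()].
#'
#' @param config A [sim_config()].
#' @param trisomic_chromosomes Character vector of chromosome labels carrying
#'   a trisomy in every sample (applies to all samples; simulate samples
#'   separately for sample-specific aberrations).
#' @param n_samples Number of samples.
#'
#' @return A list of `snp_table` data frames (one per sample) with columns
#'   `chromosome`, `position`, `ref_count`, `alt_count`, `sample`. Positions
#'   are strictly increasing within each chromosome.
#' @export
gen_snp_table <- function(config, trisomic_chromosomes = character(0),
                          n_samples = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$read_depth_mean <= 0) stopf("depth model mean must be positive")
  bad <- setdiff(trisomic_chromosomes, config$chromosomes)
  if (length(bad)) stopf("unknown chromosome label: %s", bad[1])

  with_seed(config$seed, {
    chroms <- rep(config$chromosomes, each = config$n_snps_per_chromosome)
    n <- length(chroms)
    pos <- unlist(lapply(config$chromosomes, function(ch) {
      sort(sample.int(2e8L, config$n_snps_per_chromosome))
    }), use.names = FALSE)
    lapply(seq_len(n_samples), function(s) {
      depth <- rnbinom(n, mu = config$read_depth_mean,
                       size = config$read_depth_dispersion)
      hom <- runif(n) < config$hom_fraction
      p <- ifelse(chroms %in% trisomic_chromosomes,
                  ifelse(runif(n) < 0.5, 2 / 3, 1 / 3),
                  0.5)
      p[hom] <- ifelse(runif(sum(hom)) < 0.5, 0, 1)
      ref <- rbinom(n, depth, p)
      out <- data.frame(chromosome = chroms,
                        position = pos,
                        ref_count = ref,
                        alt_count = depth - ref,
                        sample = sprintf("S%02d", s),
                        stringsAsFactors = FALSE)
      class(out) <- c("snp_table", "data.frame")
      out
    })
  })
}
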