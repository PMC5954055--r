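#' Filter transcribed SNPs by depth and heterozygosity
#'
#' Retains SNPs with total read depth of at least `min_depth` (SNPs covered
#' by fewer transcripts are discarded) and a minor-allele count of at least
#' `min_minor_count`, a heterozygosity proxy: homozygous SNPs make the
#' major/minor ratio infinite and carry no imbalance signal. Retained rows
#' are sorted by chromosome and position.
#'
#' @param table A `snp_table` data frame (`chromosome`, `position`,
#'   `ref_count`, `alt_count`, `sample`).
#' @param min_depth Minimum total depth (default 20).
#' @param min_minor_count Minimum minor-allele count (default 3).
#' @return The filtered, sorted `snp_table`; a message is logged when the
#'   result is empty.
#' @export
filter_snps <- function(table, min_depth = 20L, min_minor_count = 3L) {
  stopifnot(all(c("chromosome", "position", "ref_count", "alt_count") %in%
                  names(table)))
  if (any(table$ref_count < 0 | table$alt_count < 0))
    stopf("allele counts must be non-negative")
  depth <- table$ref_count + table$alt_count
  minor <- pmin(table$ref_count, table$alt_count)
  out <- table[depth >= min_depth & minor >= min_minor_count, , drop = FALSE]
  out <- out[order(chrom_factor(out$chromosome), out$position), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) message("filter_snps: no SNPs survive the filters")
  class(out) <- c("snp_table", "data.frame")
  out
}

#' Major-to-minor allelic expression ratio
#'
#' @param count_a,count_b Allele read counts; both must be at least 1
#'   (guaranteed upstream by [filter_snps()]).
#' @return `max(count_a, count_b) / min(count_a, count_b)`, always >= 1.
#' @export
major_minor_ratio <- function(count_a, count_b) {
  if (any(pmin(count_a, count_b) < 1))
    stopf("zero minor-allele count: filter homozygous SNPs upstream")
  pmax(count_a, count_b) / pmin(count_a, count_b)
}

#' Moving-median track of allelic ratios along the genome
#'
#' Per chromosome, the stride-1 sliding median of the major/minor ratios is
#' paired with the sliding median of the SNP positions. Chromosomes with
#' fewer SNPs than the window yield no windows (one warning per call).
#'
#' @param table A filtered `snp_table` (see [filter_snps()]).
#' @param window Window size in SNPs; must be odd (default 151), so that the
#'   median is centred.
#' @return A `ratio_track` data frame: `sample`, `chromosome`,
#'   `median_position`, `median_ratio`; window size in the `"window"`
#'   attribute.
#' @export
moving_median_track <- function(table, window = 151L) {
  window <- as.integer(window)
  if (window < 1L) stopf("window must be at least 1")
  if (window %% 2L == 0L) stopf("window must be odd for a centred median")
  tab <- table[order(chrom_factor(table$chromosome), table$position), ,
               drop = FALSE]
  sample_lab <- if ("sample" %in% names(tab) && nrow(tab))
    tab$sample[1] else NA_character_
  pieces <- list()
  short <- character(0)
  for (ch in chrom_levels(tab$chromosome)) {
    rows <- tab[tab$chromosome == ch, , drop = FALSE]
    if (nrow(rows) < window) {
      short <- c(short, ch)
      next
    }
    ratio <- major_minor_ratio(rows$ref_count, rows$alt_count)
    pieces[[length(pieces) + 1L]] <- data.frame(
      sample = sample_lab, chromosome = ch,
      median_position = as.numeric(zoo::rollmedian(rows$position, k = window)),
      median_ratio = as.numeric(zoo::rollmedian(ratio, k = window)),
      stringsAsFactors = FALSE)
  }
  if (length(short))
    warnf("chromosomes with fewer than %d SNPs yield no windows: %s",
          window, paste(short, collapse = ", "))
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(sample = character(0), chromosome = character(0),
               median_position = numeric(0), median_ratio = numeric(0))
  attr(out, "window") <- window
  class(out) <- c("ratio_track", "data.frame")
  out
}

#' Call chromosomal allelic imbalance from a ratio track
#'
#' The statistic per (sample, chromosome) is the median of the windowed
#' major/minor medians. The null is built from the windowed medians of all
#' other chromosomes of the same sample: a circular block of the same number
#' of windows is drawn at a random offset and its median recorded,
#' `n_null` times. A chromosome is called when its statistic exceeds the
#' null's `1 - alpha` quantile. A permutation null (rather than a fixed
#' ratio cutoff) is used because the diploid ratio exceeds 1 in a
#' depth-dependent way.
#'
#' @param track A `ratio_track` from [moving_median_track()].
#' @param n_null Number of null draws (default 1000).
#' @param alpha Tail probability for calling (default 0.01).
#' @param seed Optional seed for the null draws.
#' @return Data frame: `sample`, `chromosome`, `median_ratio` (the
#'   statistic), `p_value`, `called`, `direction` (always `gain`: allelic
#'   imbalance raises the ratio regardless of which homologue is duplicated).
#'   An empty track yields an empty call list.
#' @export
call_imbalance <- function(track, n_null = 1000L, alpha = 0.01, seed = NULL) {
  stopifnot(inherits(track, "ratio_track") || is.data.frame(track))
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  empty <- data.frame(sample = character(0), chromosome = character(0),
                      median_ratio = numeric(0), p_value = numeric(0),
                      called = logical(0), direction = character(0))
  if (nrow(track) == 0L) return(empty)

  run <- function() {
    out <- list()
    for (s in unique(track$sample)) {
      tr <- track[track$sample == s, , drop = FALSE]
      chroms <- unique(tr$chromosome)
      if (length(chroms) < 2L)
        stopf("sample '%s': at least 2 chromosomes with windows are needed to build a null", s)
      for (ch in chroms) {
        own <- tr$median_ratio[tr$chromosome == ch]
        other <- tr$median_ratio[tr$chromosome != ch]
        obs <- median(own)
        len <- length(other)
        null <- vapply(seq_len(n_null), function(b) {
          start <- sample.int(len, 1L)
          idx <- ((start - 1L + seq_len(length(own)) - 1L) %% len) + 1L
          median(other[idx])
        }, 0)
        p <- (1 + sum(null >= obs)) / (n_null + 1)
        out[[length(out) + 1L]] <- data.frame(
          sample = s, chromosome = ch, median_ratio = obs,
          p_value = p, called = p <= alpha, direction = "gain",
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
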