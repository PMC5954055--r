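#' Remove low-quality qPCR samples
#'
#' Drops samples in which fewer than `min_detected_fraction` of the expected
#' panel genes were detected (strict less-than: a sample at exactly the
#' threshold is retained). Removals are logged with their detected fractions.
#'
#' @param ct A `ct_matrix` long data frame (see [gen_ct_timecourse()] or
#'   [read_ct_matrix()]); `NA` Ct marks a non-detect.
#' @param min_detected_fraction Minimum detected-gene fraction (default 0.33).
#' @return The filtered `ct_matrix`.
#' @export
qc_filter <- function(ct, min_detected_fraction = 0.33) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  n_expected <- length(unique(ct$gene))
  det <- tapply(!is.na(ct$ct), ct$sample, sum) / n_expected
  bad <- names(det)[det < min_detected_fraction]
  if (length(bad) == length(det))
    stopf("all samples fall below the %.0f%% detection threshold",
          100 * min_detected_fraction)
  if (length(bad))
    message(sprintf("qc_filter: removed %d sample(s): %s", length(bad),
                    paste(sprintf("%s (%.0f%%)", bad, 100 * det[bad]),
                          collapse = ", ")))
  out <- ct[!ct$sample %in% bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(ct)
  out
}

#' Normalise a Ct matrix into inverted expression values
#'
#' Applies, in order: (1) capping - Ct values above `cap` and non-detects are
#' set to `cap`; (2) control-gene scaling - per sample, the mean Ct of the
#' control genes is subtracted (delta-Ct); (3) quantile normalisation across
#' samples to the mean empirical distribution; (4) inversion - the
#' quantile-normalised values are mapped back onto `[0, cap]` by an affine
#' map (recorded in the provenance) and subtracted from `cap`, so that
#' larger values mean stronger expression.
#'
#' @param ct A (QC-filtered) `ct_matrix`.
#' @param cap Maximum Ct (default 35).
#' @param control_genes Control gene labels (default ACTB, GAPDH); every
#'   retained sample must measure both.
#' @return A `norm_expr` object: list with `values` (genes x samples,
#'   in `[0, cap]`), `meta` (sample metadata) and `provenance` (cap, affine
#'   map, step order).
#' @export
normalize_ct <- function(ct, cap = 35, control_genes = c("ACTB", "GAPDH")) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  genes <- sort(unique(ct$gene))
  samples <- unique(ct$sample)
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  mat[cbind(match(ct$gene, genes), match(ct$sample, samples))] <- ct$ct
  for (g in control_genes) {
    if (!g %in% genes) stopf("control gene %s absent from the panel", g)
    missing <- samples[is.na(mat[g, ]) &
                         !samples %in% ct$sample[ct$gene == g]]
    if (length(missing))
      stopf("control gene %s not measured in sample %s", g, missing[1])
  }
  # step 1: cap (non-detects included)
  mat[is.na(mat) | mat > cap] <- cap
  # step 2: delta-Ct against the control-gene mean
  ctrl <- colMeans(mat[control_genes, , drop = FALSE])
  dct <- sweep(mat, 2L, ctrl)
  # step 3: quantile normalisation to the mean empirical distribution
  qn <- limma::normalizeQuantiles(dct, ties = TRUE)
  # step 4: affine rescale onto [0, cap], then invert
  rng <- range(qn)
  slope <- if (diff(rng) > 0) cap / diff(rng) else 0
  intercept <- -slope * rng[1]
  expr <- cap - (intercept + slope * qn)

  meta_cols <- intersect(c("sample", "line", "condition", "day", "replicate"),
                         names(ct))
  meta <- unique(ct[meta_cols])
  meta <- meta[match(samples, meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = expr, meta = meta,
                 provenance = list(cap = cap, control_genes = control_genes,
                                   control_means = ctrl,
                                   affine = c(intercept = intercept,
                                              slope = slope))),
            class = "norm_expr")
}

# Per-(line, condition) gene ranks of the day-16 vs day-0 expression change;
# rank 1 = largest increase, ties broken by gene label.
rank_day16_change <- function(norm, genes) {
  meta <- norm$meta
  out <- list()
  for (line in unique(meta$line)) {
    for (cond in unique(meta$condition)) {
      s16 <- meta$sample[meta$line == line & meta$condition == cond &
                           meta$day == 16]
      s0 <- meta$sample[meta$line == line & meta$condition == cond &
                          meta$day == 0]
      if (!length(s16) || !length(s0)) next
      delta <- rowMeans(norm$values[genes, s16, drop = FALSE]) -
        rowMeans(norm$values[genes, s0, drop = FALSE])
      r <- integer(length(genes))
      r[order(-delta, genes)] <- seq_along(genes)
      out[[length(out) + 1L]] <- data.frame(line = line, condition = cond,
                                            gene = genes, rank = r,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Select lineage and undifferentiated marker sets by rank
#'
#' For every (cell line, condition) the genes are ranked by their day-16 vs
#' day-0 expression change (rank 1 = largest increase, ties broken by gene
#' label); the median rank across lines is taken per condition. The
#' `n_per_set` top-ranked genes per directed condition become that lineage's
#' markers; the `n_per_set` genes with the most extreme average rank in the
#' downregulated direction across all conditions become the markers of
#' undifferentiated cells. Control genes are excluded a priori. A gene
#' winning several sets is assigned to the set where its candidate position
#' is best; runner-up sets take their next-ranked gene, so the four sets are
#' pairwise disjoint.
#'
#' @param norm A `norm_expr` from [normalize_ct()] with day-0 and day-16
#'   samples for every (line, condition).
#' @param n_per_set Markers per set (default 15).
#' @param control_genes Genes excluded from selection.
#' @return A `marker_sets` object: named list `ectoderm`, `mesoderm`,
#'   `endoderm`, `undifferentiated`, each of `n_per_set` gene labels.
#' @export
select_markers <- function(norm, n_per_set = 15L,
                           control_genes = c("ACTB", "GAPDH")) {
  stopifnot(inherits(norm, "norm_expr"))
  genes <- setdiff(rownames(norm$values), control_genes)
  if (length(genes) < 4L * n_per_set)
    stopf("need at least %d eligible genes, have %d", 4L * n_per_set,
          length(genes))
  ranks <- rank_day16_change(norm, genes)
  med <- aggregate(rank ~ gene + condition, data = ranks, FUN = median)

  cand <- list()
  for (lin in c("ectoderm", "mesoderm", "endoderm")) {
    m <- med[med$condition == lin, ]
    if (!nrow(m)) stopf("no day-16 samples under the %s condition", lin)
    cand[[lin]] <- m$gene[order(m$rank, m$gene)]
  }
  avg <- aggregate(rank ~ gene, data = med, FUN = mean)
  # largest average rank = most consistently downregulated
  cand$undifferentiated <- avg$gene[order(-avg$rank, avg$gene)]

  sets <- lapply(cand, function(x) x[seq_len(n_per_set)])
  # resolve cross-set conflicts: the set where the gene sits earliest in its
  # candidate list keeps it; others move down their list
  repeat {
    all_genes <- unlist(sets, use.names = FALSE)
    dup <- unique(all_genes[duplicated(all_genes)])
    if (!length(dup)) break
    for (g in dup) {
      holders <- names(sets)[vapply(sets, function(s) g %in% s, TRUE)]
      pos <- vapply(holders, function(nm) match(g, cand[[nm]]), 0L)
      keep <- holders[which.min(pos)]
      for (nm in setdiff(holders, keep)) {
        taken <- unique(c(unlist(sets, use.names = FALSE)))
        nxt <- setdiff(cand[[nm]], taken)
        if (!length(nxt)) stopf("candidate list for %s exhausted", nm)
        sets[[nm]][match(g, sets[[nm]])] <- nxt[1L]
      }
    }
  }
  structure(sets, class = "marker_sets")
}

#' Moderated two-group t-statistics with empirical-Bayes variance shrinkage
#'
#' Per gene, the pooled two-sample variance `s_g^2` (on `d_g` degrees of
#' freedom) is shrunk toward a common prior value:
#' `s_tilde^2 = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, and
#' `t = (meanA - meanB) / (s_tilde * sqrt(1/nA + 1/nB))`. The prior
#' `(d0, s0^2)` is estimated by the method of moments on `log s_g^2` across
#' genes: under the scaled-F sampling model,
#' `var(log s^2) = trigamma(d/2) + trigamma(d0/2)`, inverted for `d0`, with
#' `s0^2` recovered from the mean of `log s^2`. `d0 = 0` reproduces the
#' ordinary pooled t; `d0 = Inf` uses the common prior variance for every
#' gene.
#'
#' @param values Genes x samples numeric matrix.
#' @param group_a,group_b Column names (or indices) of the two groups; each
#'   must contain at least 2 samples.
#' @param d0,s0_sq Optional prior df and variance overriding the
#'   method-of-moments estimate.
#' @return List with `t` (named vector), `mean_diff`, `s2` (per-gene pooled
#'   variances), `d0`, `s0_sq`, `df`.
#' @export
moderated_t <- function(values, group_a, group_b, d0 = NULL, s0_sq = NULL) {
  a <- values[, group_a, drop = FALSE]
  b <- values[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L) stopf("each group needs at least 2 samples")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
  df <- na + nb - 2L
  s2 <- ((na - 1) * va + (nb - 1) * vb) / df

  if (all(s2 == 0)) {
    warnf("zero within-group variance everywhere; falling back to ordinary t")
    d0 <- 0; s0_sq <- 0
  }
  if (is.null(d0)) {
    z <- log(s2[s2 > 0])
    evar <- var(z) - trigamma(df / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * limma::trigammaInverse(evar)
      if (is.null(s0_sq))
        s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                       digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      if (is.null(s0_sq))
        s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2))
    }
  }
  if (d0 == 0) {
    s2_tilde <- s2
  } else if (is.infinite(d0)) {
    if (is.null(s0_sq)) stopf("s0_sq must be supplied when d0 is infinite")
    s2_tilde <- rep(s0_sq, length(s2))
  } else {
    if (is.null(s0_sq)) stopf("s0_sq must be supplied with a finite d0")
    s2_tilde <- (d0 * s0_sq + df * s2) / (d0 + df)
  }
  tt <- (ma - mb) / sqrt(s2_tilde * (1 / na + 1 / nb))
  list(t = setNames(tt, rownames(values)), mean_diff = ma - mb, s2 = s2,
       d0 = d0, s0_sq = s0_sq, df = df)
}

#' Parametric gene-set lineage score (PAGE-style)
#'
#' Z-like enrichment of a marker set in the t-score ranking:
#' `score = (mean(t[markers]) - mean(t)) * sqrt(m) / sd(t)` with `m` the
#' marker-set size. The sign carries the direction of regulation.
#'
#' @param t_scores Named per-gene score vector (typically moderated t).
#' @param markers Marker gene labels; must be a subset of the scored genes.
#' @return The enrichment score (scalar).
#' @export
lineage_score <- function(t_scores, markers) {
  if (!length(markers)) stopf("marker set is empty")
  if (!all(markers %in% names(t_scores)))
    stopf("markers missing from the scored genes: %s",
          paste(setdiff(markers, names(t_scores)), collapse = ", "))
  (mean(t_scores[markers]) - mean(t_scores)) * sqrt(length(markers)) /
    sd(t_scores)
}

#' Map a lineage score to its categorical grade
#'
#' Bins: `+++` for scores above 3, `++` for scores in `[2, 3]`, `+` for
#' `[1, 2)`, `+/-` below 1 (the published 2-3 and 1-2 bins overlap at the
#' integers; the half-open convention here makes the map total and
#' non-overlapping). `NA` maps to `"nd"` (not analysed).
#'
#' @param score Numeric score(s).
#' @return Character grade(s).
#' @export
grade_score <- function(score) {
  vapply(score, function(s) {
    if (is.na(s)) "nd"
    else if (s > 3) "+++"
    else if (s >= 2) "++"
    else if (s >= 1) "+"
    else "+/-"
  }, "")
}

#' Build the lineage scorecard (differentiation potential and propensity)
#'
#' For every cell line and lineage, \emph{potential} is the lineage score of
#' that lineage's markers on the moderated t comparison of the line's
#' matched directed-condition day-16 replicates against all day-0 samples;
#' \emph{propensity} is the same computation under the neutral condition.
#' The undifferentiated marker set is scored alongside the three germ
#' layers. Scores are graded with [grade_score()]; a missing condition
#' yields an `nd` row.
#'
#' @param norm A `norm_expr` from [normalize_ct()].
#' @param markers A `marker_sets` object (see [select_markers()]).
#' @return A `lineage_scorecard` data frame: `line`, `lineage`, `potential`,
#'   `potential_grade`, `propensity`, `propensity_grade`.
#' @export
build_scorecard <- function(norm, markers) {
  stopifnot(inherits(norm, "norm_expr"), inherits(markers, "marker_sets"))
  meta <- norm$meta
  day0 <- meta$sample[meta$day == 0]
  if (length(day0) < 2L) stopf("need at least 2 day-0 baseline samples")
  score_for <- function(line, cond, set) {
    s16 <- meta$sample[meta$line == line & meta$condition == cond &
                         meta$day == 16]
    if (length(s16) < 2L) return(NA_real_)
    mt <- moderated_t(norm$values, s16, day0)
    lineage_score(mt$t, markers[[set]])
  }
  rows <- list()
  for (line in unique(meta$line)) {
    for (set in names(markers)) {
      directed <- if (set == "undifferentiated") "neutral" else set
      pot <- score_for(line, directed, set)
      pro <- score_for(line, "neutral", set)
      rows[[length(rows) + 1L]] <- data.frame(
        line = line, lineage = set,
        potential = pot, potential_grade = grade_score(pot),
        propensity = pro, propensity_grade = grade_score(pro),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lineage_scorecard", "data.frame")
  out
}
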