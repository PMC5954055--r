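#' Default tissue-group merges for signature derivation
#'
#' Central and peripheral nervous system, and small intestine and colon, are
#' merged into single tissue groups because their specific-gene expression
#' is similar.
#'
#' @return Named list: group label -> member tissue labels.
#' @export
default_merge_groups <- function() {
  list(cns_pns = c("cns", "pns"),
       intestine = c("small_intestine", "colon"))
}

# Map each tissue to its (possibly merged) group label.
tissue_group_of <- function(tissues, merge_groups) {
  grp <- setNames(tissues, tissues)
  for (g in names(merge_groups)) grp[merge_groups[[g]]] <- g
  grp
}

#' Derive a tissue-specific expression signature
#'
#' Candidate genes must pass two rules against the panels they are derived
#' from: (1) tissue specificity - mean FPKM in the gene's source tissue (the
#' tissue where it is highest) above `tissue_fold` times the mean of the
#' per-tissue means of all other tissues; (2) differentiation enrichment -
#' mean FPKM in the reference teratomas above `teratoma_fold` times the mean
#' in PSCs. Tissues listed in `merge_groups` are merged into single groups.
#' Candidates are ranked within each tissue group by their rule-1 fold and
#' taken round-robin across groups until `size` genes are collected, so that
#' every group stays represented; if fewer candidates exist than `size`, all
#' are returned with a logged shortfall.
#'
#' @param tissues [expression_panel()] of normal-tissue reference samples
#'   (meta columns `tissue` and `lineage` required).
#' @param teratomas [expression_panel()] (or matrix) of reference teratomas.
#' @param pscs [expression_panel()] (or matrix) of PSC reference samples.
#' @param tissue_fold Rule-1 fold threshold (default 8).
#' @param teratoma_fold Rule-2 fold threshold (default 4).
#' @param size Target signature size (default 100).
#' @param merge_groups Tissue merges (see [default_merge_groups()]).
#' @return A `terato_signature` data frame: `gene`, `tissue` (source),
#'   `tissue_group`, `lineage`, `reference_level` (mean FPKM in the source
#'   tissue) and `fold` (rule-1 fold).
#' @export
derive_signature <- function(tissues, teratomas, pscs,
                             tissue_fold = 8, teratoma_fold = 4,
                             size = 100L,
                             merge_groups = default_merge_groups()) {
  stopifnot(inherits(tissues, "expression_panel"))
  tvals <- tissues$values
  tmeta <- tissues$meta
  tlabs <- unique(tmeta$tissue)
  per_lin <- table(unique(tmeta[c("tissue", "lineage")])$lineage)
  if (any(per_lin < 2))
    warnf("lineages represented by fewer than 2 tissues: %s",
          paste(names(per_lin)[per_lin < 2], collapse = ", "))
  tmeans <- vapply(tlabs, function(t)
    rowMeans(tvals[, tmeta$sample[tmeta$tissue == t], drop = FALSE]),
    numeric(nrow(tvals)))
  ter_mean <- rowMeans(if (inherits(teratomas, "expression_panel"))
    teratomas$values else as.matrix(teratomas))
  psc_mean <- rowMeans(if (inherits(pscs, "expression_panel"))
    pscs$values else as.matrix(pscs))

  src_idx <- max.col(tmeans, ties.method = "first")
  src <- tlabs[src_idx]
  own <- tmeans[cbind(seq_len(nrow(tmeans)), src_idx)]
  others <- (rowSums(tmeans) - own) / (length(tlabs) - 1L)
  fold <- own / others
  rule1 <- is.finite(fold) & fold > tissue_fold
  rule2 <- ter_mean > teratoma_fold * psc_mean[rownames(tvals)]
  cand_idx <- which(rule1 & rule2)
  if (!length(cand_idx)) stopf("no genes pass the signature filters")

  lin_of <- setNames(tmeta$lineage[match(tlabs, tmeta$tissue)], tlabs)
  grp_of <- tissue_group_of(tlabs, merge_groups)
  cand <- data.frame(gene = rownames(tvals)[cand_idx],
                     tissue = src[cand_idx],
                     tissue_group = unname(grp_of[src[cand_idx]]),
                     lineage = unname(lin_of[src[cand_idx]]),
                     reference_level = unname(own[cand_idx]),
                     fold = unname(fold[cand_idx]),
                     stringsAsFactors = FALSE)
  groups <- unique(grp_of)
  missing_groups <- setdiff(groups, cand$tissue_group)
  if (length(missing_groups))
    warnf("no signature genes for tissue group(s): %s",
          paste(missing_groups, collapse = ", "))

  if (nrow(cand) <= size) {
    if (nrow(cand) < size)
      message(sprintf("derive_signature: only %d candidates for a %d-gene signature",
                      nrow(cand), size))
    out <- cand
  } else {
    # round-robin across groups, strongest rule-1 fold first within a group
    by_grp <- lapply(split(cand, cand$tissue_group), function(d)
      d[order(-d$fold, d$gene), , drop = FALSE])
    picked <- list()
    round <- 1L
    while (length(picked) < size) {
      advanced <- FALSE
      for (g in sort(names(by_grp))) {
        if (length(picked) >= size) break
        if (nrow(by_grp[[g]]) >= round) {
          picked[[length(picked) + 1L]] <- by_grp[[g]][round, ]
          advanced <- TRUE
        }
      }
      if (!advanced) break
      round <- round + 1L
    }
    out <- do.call(rbind, picked)
  }
  out <- out[order(out$lineage, out$tissue_group, -out$fold, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("terato_signature", "data.frame")
  out
}

#' Per-lineage and per-tissue-group expression percentages
#'
#' Each signature gene's expression in the sample is expressed as a
#' percentage of its reference level (its mean FPKM in the source tissue);
#' tissue-group and lineage values are arithmetic means of their member
#' genes' percentages. Genes with a zero reference level are dropped with a
#' warning; at least 80% of signature genes must be present in the sample.
#'
#' @param sample A named FPKM vector, or an [expression_panel()]/matrix with
#'   `sample_name` naming the column.
#' @param signature A `terato_signature` from [derive_signature()].
#' @param sample_name Column to extract when `sample` is a matrix or panel.
#' @return List with `per_gene`, `tissue_groups` and `lineages` (named
#'   percentage vectors); lineages absent from the signature get 0.
#' @export
lineage_expression <- function(sample, signature, sample_name = NULL) {
  stopifnot(inherits(signature, "terato_signature"))
  x <- as_profile(sample, sample_name)
  sig <- signature
  present <- sig$gene %in% names(x)
  if (mean(present) < 0.8)
    stopf("sample is missing %d signature genes: %s",
          sum(!present), paste(head(sig$gene[!present], 5), collapse = ", "))
  sig <- sig[present, , drop = FALSE]
  zero_ref <- sig$reference_level <= 0
  if (any(zero_ref)) {
    warnf("dropping %d signature gene(s) with zero reference level",
          sum(zero_ref))
    sig <- sig[!zero_ref, , drop = FALSE]
  }
  pct <- 100 * x[sig$gene] / sig$reference_level
  lineages <- c("ectoderm", "mesoderm", "endoderm", "extraembryonic")
  lin <- setNames(numeric(4), lineages)
  got <- tapply(pct, sig$lineage, mean)
  lin[names(got)] <- got
  grp <- tapply(pct, sig$tissue_group, mean)
  list(per_gene = setNames(unname(pct), sig$gene),
       tissue_groups = setNames(as.numeric(grp), names(grp)),
       lineages = lin)
}

#' TeratoScore unified grade
#'
#' @param lineage_means Numeric vector of the four per-lineage mean
#'   percentages (ectoderm, mesoderm, endoderm, extraembryonic), each >= 0.
#' @return `prod(lineage_means) / 100`.
#' @export
terato_grade <- function(lineage_means) {
  if (length(lineage_means) != 4L)
    stopf("exactly four lineage means are required")
  if (any(lineage_means < 0)) stopf("lineage means must be non-negative")
  prod(lineage_means) / 100
}

#' Classify a TeratoScore grade
#'
#' A grade strictly above the threshold indicates a tumour with a relatively
#' even representation of all lineages (balanced trilineage
#' differentiation); at or below it the tumour is graded deficient. The
#' dominant lineage and any lineage under `low_pct` percent (distinctly low
#' expression) are reported.
#'
#' @param grade_value Grade from [terato_grade()], >= 0.
#' @param lineage_means Optional named per-lineage means used for the
#'   dominant/deficient report.
#' @param threshold Grade threshold (default 10).
#' @param low_pct Percentage below which a lineage is flagged as distinctly
#'   low (default 4).
#' @return List with `classification` (`balanced-trilineage`/`deficient`),
#'   `dominant_lineage`, `low_lineages`.
#' @export
classify_grade <- function(grade_value, lineage_means = NULL, threshold = 10,
                           low_pct = 4) {
  if (grade_value < 0) stopf("grade must be non-negative")
  cls <- if (grade_value > threshold) "balanced-trilineage" else "deficient"
  dominant <- low <- NA_character_
  if (!is.null(lineage_means)) {
    dominant <- names(lineage_means)[which.max(lineage_means)]
    low <- names(lineage_means)[lineage_means < low_pct]
  }
  list(classification = cls, dominant_lineage = dominant, low_lineages = low)
}

#' Score teratoma samples against a tissue signature
#'
#' Convenience wrapper: per sample, computes lineage/tissue-group
#' percentages, the unified grade and its classification.
#'
#' @param samples [expression_panel()] or FPKM matrix of teratoma samples.
#' @param signature A `terato_signature`.
#' @param threshold Grade threshold (default 10).
#' @return A `teratoscore_result` data frame: one row per sample with the
#'   four lineage means, `grade`, `classification`, `dominant_lineage` and
#'   `low_lineages` (comma-separated); the per-tissue-group percentage
#'   matrix is attached as the `"tissue_groups"` attribute.
#' @export
teratoscore <- function(samples, signature, threshold = 10) {
  vals <- if (inherits(samples, "expression_panel")) samples$values else
    as.matrix(samples)
  rows <- lapply(colnames(vals), function(s) {
    le <- lineage_expression(vals[, s], signature)
    g <- terato_grade(le$lineages)
    cl <- classify_grade(g, le$lineages, threshold = threshold)
    cbind(data.frame(sample = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(le$lineages)),
          data.frame(grade = g, classification = cl$classification,
                     dominant_lineage = cl$dominant_lineage,
                     low_lineages = paste(cl$low_lineages, collapse = ","),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  groups <- t(vapply(colnames(vals), function(s)
    lineage_expression(vals[, s], signature)$tissue_groups,
    lineage_expression(vals[, 1], signature)$tissue_groups))
  attr(out, "tissue_groups") <- groups
  class(out) <- c("teratoscore_result", "data.frame")
  out
}

#' Screen teratomas for residual undifferentiated / yolk-sac marker expression
#'
#' Per teratoma, the mean over the marker panel of each gene's expression as
#' a percentage of its mean level in the PSC references. Samples whose
#' percentage strictly exceeds the cohort mean are flagged (the flag
#' threshold is a property of the cohort, not a fixed percentage).
#'
#' @param samples [expression_panel()] or FPKM matrix of teratomas.
#' @param pscs [expression_panel()] or FPKM matrix of PSC references.
#' @param panel Marker gene labels (typically 10 undifferentiated PSC /
#'   yolk-sac markers); must have a nonzero PSC mean.
#' @return Data frame: `sample`, `percent`, `flagged`; the cohort mean is in
#'   the `"cohort_mean"` attribute.
#' @export
undiff_marker_screen <- function(samples, pscs, panel) {
  vals <- if (inherits(samples, "expression_panel")) samples$values else
    as.matrix(samples)
  if (ncol(vals) == 0L) stopf("empty teratoma cohort")
  pvals <- if (inherits(pscs, "expression_panel")) pscs$values else
    as.matrix(pscs)
  if (!all(panel %in% rownames(pvals)) || !all(panel %in% rownames(vals)))
    stopf("marker panel genes missing from the expression data")
  ref <- rowMeans(pvals[panel, , drop = FALSE])
  if (any(ref <= 0)) stopf("marker panel has zero mean expression in PSCs")
  pct <- colMeans(100 * vals[panel, , drop = FALSE] / ref)
  out <- data.frame(sample = colnames(vals), percent = unname(pct),
                    flagged = unname(pct > mean(pct)),
                    stringsAsFactors = FALSE)
  attr(out, "cohort_mean") <- mean(pct)
  out
}
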