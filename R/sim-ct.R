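#' Default 190-gene qPCR panel
#'
#' Builds the gene label set used by the qPCR time-course simulator: the two
#' control genes (ACTB, GAPDH), 15 designated responder genes per germ layer,
#' 15 genes downregulated during differentiation (markers of the
#' undifferentiated state) and unresponsive filler genes up to `size`.
#'
#' @param size Total panel size (default 190).
#' @return Character vector of gene labels with a `"panel_roles"` attribute
#'   (named list: `controls`, `ectoderm`, `mesoderm`, `endoderm`,
#'   `undifferentiated`).
#' @export
default_panel <- function(size = 190L) {
  controls <- c("ACTB", "GAPDH")
  ecto <- sprintf("ECTO%02d", 1:15)
  meso <- sprintf("MESO%02d", 1:15)
  endo <- sprintf("ENDO%02d", 1:15)
  undf <- sprintf("UNDF%02d", 1:15)
  n_filler <- size - length(controls) - 60L
  if (n_filler < 0) stopf("size too small for the designated gene sets")
  filler <- sprintf("G%03d", seq_len(n_filler))
  panel <- c(controls, ecto, meso, endo, undf, filler)
  attr(panel, "panel_roles") <- list(controls = controls, ectoderm = ecto,
                                     mesoderm = meso, endoderm = endo,
                                     undifferentiated = undf)
  panel
}

#' Default planted differentiation effects for the qPCR simulator
#'
#' Day-16 log2-expression effects per (gene, condition). Responder genes get
#' `directed_effect` under their matched directed condition and
#' `neutral_effect` under neutral culture (spontaneous differentiation
#' produces all three lineages, more weakly). Undifferentiated-state genes
#' get `undiff_effect` (negative: expression falls) under every condition.
#'
#' @param panel A panel from [default_panel()] (roles attribute required).
#' @param directed_effect Effect size (log2 units / Ct units) under the
#'   matched directed condition.
#' @param neutral_effect Effect size under neutral conditions.
#' @param undiff_effect Effect for undifferentiated-state genes (negative).
#' @return Numeric matrix, genes x conditions
#'   (`neutral`, `ectoderm`, `mesoderm`, `endoderm`).
#' @export
default_lineage_effects <- function(panel, directed_effect = 6,
                                    neutral_effect = 2, undiff_effect = -4) {
  roles <- attr(panel, "panel_roles")
  if (is.null(roles)) stopf("panel lacks a panel_roles attribute")
  conds <- c("neutral", "ectoderm", "mesoderm", "endoderm")
  eff <- matrix(0, nrow = length(panel), ncol = length(conds),
                dimnames = list(panel, conds))
  for (lin in c("ectoderm", "mesoderm", "endoderm")) {
    eff[roles[[lin]], lin] <- directed_effect
    eff[roles[[lin]], "neutral"] <- neutral_effect
  }
  eff[roles$undifferentiated, ] <- undiff_effect
  eff
}

#' Simulate a qPCR Ct matrix for embryoid-body differentiation
#'
#' Emulates a Fluidigm-style time course: every (cell line, condition, day,
#' replicate) sample measures the full panel. Expression of gene g under
#' condition c at day d is `baseline - effect[g, c] * d / 16` on the Ct
#' scale (lower Ct = higher expression), plus a per-sample loading shift
#' (removed downstream by control-gene scaling) and Gaussian replicate
#' noise. Samples listed in `low_quality_samples` have `nondetect_fraction`
#' of their genes set to non-detect (`NA`), to exercise the QC filter;
#' non-detect is distinct from a capped Ct of 35.
#'
#' @param config A [sim_config()].
#' @param panel Gene labels (must contain ACTB and GAPDH and at least 60
#'   non-control genes); see [default_panel()].
#' @param lines Character vector of cell-line labels.
#' @param lineage_effects Genes x conditions effect matrix; see
#'   [default_lineage_effects()].
#' @param days Sampling days.
#' @param replicates Biological replicates per (line, condition, day).
#' @param low_quality_samples Sample labels to degrade (see Details for the
#'   label format `line_condition_dXX_rY`).
#' @param nondetect_fraction Fraction of genes set to non-detect in degraded
#'   samples.
#'
#' @return A `ct_matrix`: long data frame with columns `gene`, `sample`,
#'   `line`, `condition`, `day`, `replicate`, `ct` (`NA` = non-detect).
#' @export
gen_ct_timecourse <- function(config, panel = default_panel(),
                              lines = c("L1", "L2", "L3", "L4"),
                              lineage_effects = default_lineage_effects(panel),
                              days = c(0L, 4L, 10L, 16L),
                              replicates = 2L,
                              low_quality_samples = character(0),
                              nondetect_fraction = 0.7) {
  stopifnot(inherits(config, "sim_config"))
  controls <- c("ACTB", "GAPDH")
  if (!all(controls %in% panel))
    stopf("panel must contain the control genes ACTB and GAPDH")
  if (length(setdiff(panel, controls)) < 60L)
    stopf("panel must contain at least 60 non-control genes")
  if (!all(rownames(lineage_effects) == panel))
    stopf("lineage_effects rows must match the panel")
  conds <- colnames(lineage_effects)
  panel <- as.vector(panel)  # drop the roles attribute from the data columns

  with_seed(config$seed, {
    base <- setNames(runif(length(panel), 18, 28), panel)
    base["ACTB"] <- 16
    base["GAPDH"] <- 17
    design <- expand.grid(replicate = seq_len(replicates), day = days,
                          condition = conds, line = lines,
                          stringsAsFactors = FALSE)
    design$sample <- sprintf("%s_%s_d%02d_r%d", design$line, design$condition,
                             design$day, design$replicate)
    out <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      d <- design[i, ]
      shift <- rnorm(1, 0, 0.3)  # per-sample loading offset
      ct <- base - lineage_effects[, d$condition] * d$day / 16 + shift +
        rnorm(length(panel), 0, config$ct_noise_sd)
      if (d$sample %in% low_quality_samples) {
        drop <- sample(length(panel), round(nondetect_fraction * length(panel)))
        ct[drop] <- NA_real_
      }
      data.frame(gene = panel, sample = d$sample, line = d$line,
                 condition = d$condition, day = d$day,
                 replicate = d$replicate, ct = unname(ct),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    class(out) <- c("ct_matrix", "data.frame")
    out
  })
}
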