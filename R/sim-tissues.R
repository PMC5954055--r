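#' Default 14-tissue reference panel and lineage assignment
#'
#' Mirrors the size of a human body-tissue reference panel: three ectodermal,
#' six mesodermal, four endodermal tissues and placenta for the
#' extra-embryonic membranes. Central/peripheral nervous system and small
#' intestine/colon are kept as separate tissues here and merged into single
#' tissue groups during signature derivation (see [derive_signature()]).
#'
#' @return Named character vector: names are tissue labels, values lineages
#'   (`ectoderm`, `mesoderm`, `endoderm`, `extraembryonic`).
#' @export
default_tissue_lineages <- function() {
  c(cns = "ectoderm", pns = "ectoderm", skin = "ectoderm",
    heart = "mesoderm", skeletal_muscle = "mesoderm", kidney = "mesoderm",
    blood = "mesoderm", adipose = "mesoderm", bone = "mesoderm",
    liver = "endoderm", pancreas = "endoderm",
    small_intestine = "endoderm", colon = "endoderm",
    placenta = "extraembryonic")
}

#' Equal-weight mixture over a tissue panel
#'
#' @param lineage_map Named tissue-to-lineage vector
#'   (see [default_tissue_lineages()]).
#' @return Named weight vector, `1 / n_tissues` for every tissue.
#' @export
equal_mixture <- function(lineage_map = default_tissue_lineages()) {
  setNames(rep(1 / length(lineage_map), length(lineage_map)),
           names(lineage_map))
}

#' Construct an expression panel (FPKM matrix plus sample metadata)
#'
#' @param values Genes x samples FPKM matrix (dimnames required).
#' @param meta Data frame with columns `sample`, `role`
#'   (`tissue`/`psc`/`teratoma`), `tissue`, `lineage`; one row per column of
#'   `values`.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values, meta) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            identical(colnames(values), meta$sample))
  if (any(values < 0)) stopf("FPKM values must be non-negative")
  structure(list(values = values, meta = meta), class = "expression_panel")
}

#' Simulate a normal-tissue reference panel, PSC profiles and teratomas
#'
#' Each tissue owns a private set of genes expressed far above (>= 8-fold by
#' construction) their level in every other tissue; PSC profiles express a
#' designated 10-gene undifferentiated marker panel highly and tissue genes
#' near zero; housekeeping genes are expressed uniformly. A teratoma profile
#' is the weighted sum of the tissue mean signatures, plus an optional PSC
#' admixture, under multiplicative log-normal noise. Reference teratomas
#' (equal-weight mixtures, emulating the karyotypically normal pilot tumours
#' used to anchor signature derivation) are generated alongside.
#'
#' @param config A [sim_config()].
#' @param lineage_map Named tissue-to-lineage vector; every tissue must map
#'   to one of ectoderm/mesoderm/endoderm/extraembryonic.
#' @param mixtures Named list of per-tissue weight vectors (names matching
#'   `names(lineage_map)`), one teratoma per element. Weights must be
#'   non-negative and not all zero.
#' @param psc_fractions Numeric scalar or vector parallel to `mixtures`:
#'   fraction of residual undifferentiated PSC signal added to each teratoma.
#' @param n_genes_per_tissue Private genes per tissue.
#' @param n_housekeeping Uniformly expressed background genes.
#' @param n_per_tissue Samples per reference tissue.
#' @param n_psc PSC reference samples.
#' @param n_ref_teratomas Equal-weight reference teratomas.
#'
#' @return List with `tissues`, `pscs`, `reference_teratomas`, `teratomas`
#'   (all [expression_panel()]s), `tissue_genes` (gene/tissue/lineage map)
#'   and `undiff_panel` (the 10 marker gene labels).
#' @export
gen_tissue_panel_and_teratomas <- function(config,
                                           lineage_map = default_tissue_lineages(),
                                           mixtures = list(equal = equal_mixture(lineage_map)),
                                           psc_fractions = 0,
                                           n_genes_per_tissue = 12L,
                                           n_housekeeping = 30L,
                                           n_per_tissue = 3L,
                                           n_psc = 4L,
                                           n_ref_teratomas = 4L) {
  stopifnot(inherits(config, "sim_config"))
  lineages <- c("ectoderm", "mesoderm", "endoderm", "extraembryonic")
  if (!all(lineage_map %in% lineages))
    stopf("every tissue must map to one of: %s", paste(lineages, collapse = ", "))
  tissues <- names(lineage_map)
  psc_fractions <- rep_len(psc_fractions, length(mixtures))
  for (i in seq_along(mixtures)) {
    w <- mixtures[[i]]
    if (!all(names(w) %in% tissues)) stopf("mixture %d names unknown tissues", i)
    if (any(w < 0)) stopf("mixture weights must be non-negative")
    if (sum(w) + psc_fractions[i] <= 0)
      stopf("degenerate mixture: all weights zero")
  }

  with_seed(config$seed, {
    tissue_genes <- data.frame(
      gene = unlist(lapply(tissues, function(t)
        sprintf("%s_%02d", toupper(t), seq_len(n_genes_per_tissue)))),
      tissue = rep(tissues, each = n_genes_per_tissue),
      lineage = rep(unname(lineage_map), each = n_genes_per_tissue),
      stringsAsFactors = FALSE)
    undiff_panel <- sprintf("PSCM%02d", 1:10)
    hk <- sprintf("HK%02d", seq_len(n_housekeeping))
    genes <- c(tissue_genes$gene, undiff_panel, hk)
    n_genes <- length(genes)

    # mean signature per source (tissues + psc), before noise
    sig <- matrix(0, nrow = n_genes, ncol = length(tissues) + 1L,
                  dimnames = list(genes, c(tissues, ".psc")))
    sig[tissue_genes$gene, tissues] <- runif(nrow(tissue_genes) * length(tissues), 0.5, 1.5)
    for (t in tissues) {
      own <- tissue_genes$gene[tissue_genes$tissue == t]
      sig[own, t] <- runif(length(own), 80, 150)
    }
    sig[undiff_panel, tissues] <- 1
    sig[hk, tissues] <- 50
    sig[tissue_genes$gene, ".psc"] <- 0.5
    sig[undiff_panel, ".psc"] <- 200
    sig[hk, ".psc"] <- 50

    noisy <- function(mean_vec) {
      mean_vec * rlnorm(n_genes, meanlog = 0, sdlog = config$fpkm_noise_sdlog)
    }
    make_panel <- function(cols, meta) {
      values <- do.call(cbind, cols)
      dimnames(values) <- list(genes, meta$sample)
      expression_panel(values, meta)
    }

    tis_meta <- data.frame(
      sample = sprintf("%s_%d", rep(tissues, each = n_per_tissue),
                       rep(seq_len(n_per_tissue), length(tissues))),
      role = "tissue",
      tissue = rep(tissues, each = n_per_tissue),
      lineage = rep(unname(lineage_map), each = n_per_tissue),
      stringsAsFactors = FALSE)
    tis_panel <- make_panel(lapply(rep(tissues, each = n_per_tissue),
                                   function(t) noisy(sig[, t])), tis_meta)

    psc_meta <- data.frame(sample = sprintf("PSC_%d", seq_len(n_psc)),
                           role = "psc", tissue = NA, lineage = NA,
                           stringsAsFactors = FALSE)
    psc_panel <- make_panel(lapply(seq_len(n_psc),
                                   function(i) noisy(sig[, ".psc"])), psc_meta)

    mix_profile <- function(w, psc_f) {
      wfull <- setNames(numeric(length(tissues)), tissues)
      wfull[names(w)] <- w
      m <- drop(sig[, tissues, drop = FALSE] %*% wfull) + psc_f * sig[, ".psc"]
      noisy(m)
    }
    eq <- equal_mixture(lineage_map)
    ref_meta <- data.frame(sample = sprintf("RefTer_%d", seq_len(n_ref_teratomas)),
                           role = "teratoma", tissue = NA, lineage = NA,
                           stringsAsFactors = FALSE)
    ref_panel <- make_panel(lapply(seq_len(n_ref_teratomas),
                                   function(i) mix_profile(eq, 0)), ref_meta)

    ter_meta <- data.frame(sample = names(mixtures), role = "teratoma",
                           tissue = NA, lineage = NA, stringsAsFactors = FALSE)
    ter_panel <- make_panel(lapply(seq_along(mixtures), function(i)
      mix_profile(mixtures[[i]], psc_fractions[i])), ter_meta)

    list(tissues = tis_panel, pscs = psc_panel,
         reference_teratomas = ref_panel, teratomas = ter_panel,
         tissue_genes = tissue_genes, undiff_panel = undiff_panel)
  })
}
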