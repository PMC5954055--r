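# pscqc — computational assessment of human pluripotent stem cell lines

Human pluripotent stem cell (PSC) lines destined for research or clinical
use are characterised along two axes: are they genetically intact, and can
they actually differentiate into derivatives of all three embryonic germ
layers? `pscqc` implements, as one tested R package, the transcriptome-based
battery used to answer both questions, for stem-cell biologists and
facilities that bank or qualify PSC lines:

* **e-Karyotyping** — chromosomal gains/losses inferred from regional bias
  in expression-microarray profiles: a floor/presence/variability
  preprocessing chain, a 300-gene moving average along each chromosome, and
  a permutation test on the per-chromosome statistic. A culture in which a
  fraction *f* of cells carries *c* copies of a chromosome shifts its bulk
  log2 expression by `log2(((1-f)·2 + f·2c)/2)` (≈ 0.585 for a full
  trisomy).
* **eSNP-karyotyping** — aberrations inferred from allelic imbalance in
  RNA-seq SNP calls: depth ≥ 20 and heterozygosity filters, the
  major/minor ratio `max(a,b)/min(a,b)`, 151-SNP moving medians along the
  genome, and calls against a null built from the sample's other
  chromosomes (a trisomy pushes the expected ratio to ≈ 2).
* **EB lineage scorecard** — qPCR time courses of embryoid-body
  differentiation (190-gene panel): QC (< 33% detected genes removed), Ct
  capping at 35, ΔCt scaling to ACTB/GAPDH, quantile normalisation and
  inversion; rank-based selection of 15 markers per germ layer plus 15
  markers of the undifferentiated state; moderated t-statistics with
  empirical-Bayes variance shrinkage; and parametric gene-set scores
  `z = (t̄_markers − t̄)·√m / sd(t)`, graded `+++/++/+/+/-` and split into
  differentiation *potential* (directed conditions) and *propensity*
  (neutral conditions).
* **TeratoScore** — teratoma tissue composition from RNA-seq FPKM: a
  100-gene signature of tissue-specific genes (> 8-fold tissue specificity,
  > 4-fold teratoma/PSC enrichment), per-lineage expression percentages,
  and the unified grade `(ecto · meso · endo · extraembryonic)/100` with
  the > 10 balanced-trilineage threshold, plus a 10-gene screen for
  residual undifferentiated/yolk-sac cells.
* **Projection scoring** — a PluriTest-style classifier on a supplied
  component model: H9 shift-vector platform correction, unconstrained
  least-squares projection onto the model basis, Pluripotency
  (score-weight dot product, threshold ≥ 20) and Novelty (residual RMS,
  threshold 1.67) scores, and per-line replicate aggregation.
* **Synthetic data** — generators for all four input classes (arrays with
  mosaic chromosomal gains, allele-count tables with trisomic imbalance,
  differentiation time courses, teratomas as noisy mixtures of tissue
  signatures, and a toy projection model), deterministic under a fixed
  seed, with lossless TSV writers/readers.

See the methods vignette (`vignettes/pscqc-methods.Rmd`) for the models,
parameter choices and limitations in detail.

## Worked example

Simulate a 6-array study in which the last sample carries a full trisomy
of chromosome 12, and karyotype it from expression alone:

```r
library(pscqc)

cfg <- sim_config(seed = 42, chromosomes = paste0("chr", 1:12))
arrays <- gen_probe_matrix(cfg, list(aberration("chr12", 1.5, mosaic_fraction = 1)),
                           n_samples = 6, carriers = list(6))
rel <- ekaryo_preprocess(arrays)
calls <- call_aberrations(rel, window = 300, n_permutations = 300, seed = 1)
subset(calls, called)
#>    sample chromosome mean_deviation       p_value    p_adjusted direction called
#> 72    S06      chr12      0.4638025 9.013948e-242 1.081674e-240      gain   TRUE
```

The recovered deviation (0.46 log2 units) sits near the constructed
`log2(1.5) ≈ 0.585` (median centering across six samples absorbs part of
it), and only the planted (sample, chromosome) pair is called. The same
aberration seen through RNA-seq allele counts:

```r
snps <- gen_snp_table(cfg, trisomic_chromosomes = "chr12")[[1]]
track <- moving_median_track(filter_snps(snps), window = 151)
subset(call_imbalance(track, seed = 1), called)
#>    sample chromosome median_ratio     p_value called direction
#> 12    S01      chr12            2 0.000999001   TRUE      gain
```

The windowed major/minor ratio medians at 2.0 — the binomial expectation
for an allele transcribed from two of three copies. Scorecard and
TeratoScore on simulated differentiation data:

```r
ct <- gen_ct_timecourse(sim_config(seed = 7), lines = c("L1", "L2"))
norm <- normalize_ct(qc_filter(ct))
scorecard <- build_scorecard(norm, select_markers(norm))
head(scorecard, 4)
#>   line          lineage potential potential_grade propensity propensity_grade
#> 1   L1         ectoderm  8.584889             +++   4.490185              +++
#> 2   L1         mesoderm 10.177385             +++   4.832440              +++
#> 3   L1         endoderm 10.432699             +++   4.345228              +++
#> 4   L1 undifferentiated -9.616314             +/-  -9.616314              +/-

tp <- gen_tissue_panel_and_teratomas(sim_config(seed = 7),
        mixtures = list(teratoma_1 = equal_mixture()), psc_fractions = 0.05)
sig <- derive_signature(tp$tissues, tp$reference_teratomas, tp$pscs)
teratoscore(tp$teratomas, sig)
#>       sample ectoderm mesoderm endoderm extraembryonic    grade      classification
#> 1 teratoma_1 7.558277 7.381562 7.432379       7.235883 30.00479 balanced-trilineage

undiff_marker_screen(tp$teratomas, tp$pscs, tp$undiff_panel)
#>       sample  percent flagged
#> 1 teratoma_1 5.260576   FALSE
```

The cell line differentiates strongly into all three lineages (scores > 3
under directed conditions → `+++`) while its undifferentiated markers fall
(negative score). The balanced teratoma — an equal mixture of all 14
reference tissues — expresses each lineage's signature at ≈ 7% of pure
tissue levels (≈ 100/14), giving grade 30, above the > 10 threshold for
balanced trilineage differentiation; its 5% planted residual-PSC admixture
is recovered by the undifferentiated-marker screen (5.26%).

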