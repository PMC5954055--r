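# Synthetic-data generators: determinism, construction formulas, and
# round-trips through the writers and readers.

test_that("aberration shift follows the mosaic copy-number formula", {
  expect_equal(aberration_shift(1.5, 1), log2(1.5))
  expect_equal(aberration_shift(1.5, 0.5), log2(1.25))
  expect_equal(aberration_shift(1.5, 0), 0)
  expect_equal(aberration_shift(0.5, 1), -1)
  expect_error(aberration("chr1", -1), "positive")
  expect_error(aberration("chr1", 1.5, 1.2), "mosaic_fraction")
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 42, chromosomes = paste0("chr", 1:3),
                    n_probes_per_chromosome = 50, n_snps_per_chromosome = 40)
  expect_identical(gen_probe_matrix(cfg, n_samples = 3),
                   gen_probe_matrix(cfg, n_samples = 3))
  expect_identical(gen_snp_table(cfg, "chr2", 2), gen_snp_table(cfg, "chr2", 2))
  expect_identical(gen_ct_timecourse(cfg, lines = c("A", "B")),
                   gen_ct_timecourse(cfg, lines = c("A", "B")))
  expect_identical(gen_tissue_panel_and_teratomas(cfg),
                   gen_tissue_panel_and_teratomas(cfg))
  expect_identical(gen_projection_model(cfg), gen_projection_model(cfg))
})

test_that("probe generator plants the implied expression shift", {
  cfg <- sim_config(seed = 7, chromosomes = paste0("chr", 1:4),
                    n_probes_per_chromosome = 300, noise_sd = 0.1,
                    noise_sd_spread = 0, unannotated_fraction = 0)
  for (mosaic in c(1, 0.5)) {
    pm <- gen_probe_matrix(cfg, list(aberration("chr2", 1.5, mosaic)),
                           n_samples = 4, carriers = list(4))
    base <- gen_probe_matrix(cfg, n_samples = 4)
    on2 <- base$annotation$chromosome == "chr2"
    shift <- mean(pm$values[on2, 4] - base$values[on2, 4])
    expect_equal(shift, aberration_shift(1.5, mosaic), tolerance = 1e-8)
    # non-carriers and other chromosomes untouched
    expect_equal(pm$values[on2, 1:3], base$values[on2, 1:3])
    expect_equal(pm$values[!on2, ], base$values[!on2, ])
  }
})

test_that("probe generator validates inputs and annotates as configured", {
  cfg <- sim_config(seed = 1, chromosomes = c("chr1", "chr2"),
                    n_probes_per_chromosome = 100, unannotated_fraction = 0.1)
  expect_error(gen_probe_matrix(cfg, n_samples = 1), "at least 2")
  expect_error(gen_probe_matrix(cfg, list(aberration("chr9", 1.5)), 3),
               "unknown chromosome")
  pm <- gen_probe_matrix(cfg, n_samples = 3)
  expect_equal(sum(is.na(pm$annotation$chromosome)), 20)
  pos_ok <- tapply(pm$annotation$position, pm$annotation$chromosome,
                   function(p) all(diff(p) > 0))
  expect_true(all(pos_ok))
})

test_that("snp generator encodes diploid and trisomic allele fractions", {
  cfg <- sim_config(seed = 3, chromosomes = c("chr1", "chr2"),
                    n_snps_per_chromosome = 4000, read_depth_mean = 200,
                    read_depth_dispersion = 50, hom_fraction = 0)
  tab <- gen_snp_table(cfg, trisomic_chromosomes = "chr2", 1)[[1]]
  frac <- tab$ref_count / (tab$ref_count + tab$alt_count)
  dip <- frac[tab$chromosome == "chr1"]
  tri <- frac[tab$chromosome == "chr2"]
  expect_equal(mean(dip), 0.5, tolerance = 0.01)
  # duplicated allele random per SNP: fold the fraction about 1/2
  expect_equal(mean(pmax(tri, 1 - tri)), 2 / 3, tolerance = 0.01)
  expect_true(all(tapply(tab$position, tab$chromosome,
                         function(p) all(diff(p) > 0))))
})

test_that("a constant sub-filter depth leaves nothing after the depth-20 rule", {
  cfg <- sim_config(seed = 5, chromosomes = "chr1",
                    n_snps_per_chromosome = 200, read_depth_mean = 19)
  tab <- gen_snp_table(cfg, n_samples = 1)[[1]]
  tab <- tab[tab$ref_count + tab$alt_count > 0, ]
  # force every SNP to depth exactly 19, preserving the allele fractions
  scale <- 19 / (tab$ref_count + tab$alt_count)
  tab$ref_count <- round(tab$ref_count * scale)
  tab$alt_count <- 19L - tab$ref_count
  expect_true(all(tab$ref_count + tab$alt_count == 19L))
  expect_equal(nrow(suppressMessages(filter_snps(tab, 20, 0))), 0)
  # one read more crosses the boundary and is retained
  tab$alt_count <- tab$alt_count + 1L
  expect_gt(nrow(suppressMessages(filter_snps(tab, 20, 0))), 0)
})

test_that("ct generator plants time-course effects and non-detects", {
  cfg <- sim_config(seed = 11, ct_noise_sd = 0.2)
  panel <- default_panel()
  ct <- gen_ct_timecourse(cfg, panel, lines = "L1",
                          low_quality_samples = "L1_neutral_d04_r1")
  roles <- attr(panel, "panel_roles")
  ecto16 <- ct[ct$gene %in% roles$ectoderm & ct$condition == "ectoderm", ]
  m <- tapply(ecto16$ct, ecto16$day, mean)
  expect_true(all(diff(m[order(as.integer(names(m)))]) < 0))  # Ct falls
  undf <- ct[ct$gene %in% roles$undifferentiated & ct$condition == "mesoderm", ]
  mu <- tapply(undf$ct, undf$day, mean)
  expect_true(all(diff(mu[order(as.integer(names(mu)))]) > 0))  # Ct rises
  lowq <- ct[ct$sample == "L1_neutral_d04_r1", ]
  expect_equal(mean(is.na(lowq$ct)), 0.7, tolerance = 0.01)
  expect_error(gen_ct_timecourse(cfg, panel = c("ACTB", letters)),
               "control genes|60 non-control")
})

test_that("tissue generator builds mixtures that are linear in the weights", {
  map <- four_tissue_map()
  w <- c(skin = 0.4, heart = 0.3, liver = 0.2, placenta = 0.1)
  cfg <- sim_config(seed = 9, fpkm_noise_sdlog = 0)
  tp <- gen_tissue_panel_and_teratomas(cfg, lineage_map = map,
                                       mixtures = list(mix = w))
  tg <- tp$tissue_genes
  tmeans <- vapply(names(map), function(t)
    rowMeans(tp$tissues$values[, tp$tissues$meta$tissue == t, drop = FALSE]),
    numeric(nrow(tp$tissues$values)))
  skin_genes <- tg$gene[tg$tissue == "skin"]
  # noiseless mixture: skin genes at 40% of skin level plus tiny baseline
  ratio <- tp$teratomas$values[skin_genes, "mix"] / tmeans[skin_genes, "skin"]
  expect_equal(unname(ratio), rep(0.4, length(skin_genes)), tolerance = 0.05)
  expect_error(
    gen_tissue_panel_and_teratomas(cfg, lineage_map = map,
                                   mixtures = list(z = w * 0)),
    "degenerate")
})

test_that("projection model generator satisfies its contracts", {
  cfg <- sim_config(seed = 13)
  mod <- gen_projection_model(cfg, k = 3, n_genes = 120)
  expect_equal(qr(mod$basis)$rank, 3)
  expect_equal(drop(mod$basis %*% mod$h9_weights), mod$h9_reference)
  expect_error(gen_projection_model(cfg, k = 1), "at least 2")
  expect_error(gen_projection_model(cfg, k = 50, n_genes = 10), "gene count")
})

test_that("all four input classes and the model round-trip losslessly", {
  cfg <- sim_config(seed = 21, chromosomes = c("chr1", "chr2"),
                    n_probes_per_chromosome = 40, n_snps_per_chromosome = 30)
  dir <- withr::local_tempdir()

  pm <- gen_probe_matrix(cfg, n_samples = 3)
  write_probe_matrix(pm, file.path(dir, "m.tsv"), file.path(dir, "a.tsv"))
  pm2 <- read_probe_matrix(file.path(dir, "m.tsv"), file.path(dir, "a.tsv"))
  expect_equal(pm2$values, pm$values)
  expect_equal(pm2$annotation, pm$annotation)

  st <- gen_snp_table(cfg, "chr2", 2)
  write_snp_tables(st, file.path(dir, "snp.tsv"))
  st2 <- read_snp_tables(file.path(dir, "snp.tsv"))
  expect_equal(st2[["S01"]], st[[1]], ignore_attr = "row.names")
  expect_equal(st2[["S02"]], st[[2]], ignore_attr = "row.names")

  ct <- gen_ct_timecourse(cfg, lines = "L1",
                          low_quality_samples = "L1_neutral_d00_r1")
  write_ct_matrix(ct, file.path(dir, "ct.tsv"))
  expect_equal(read_ct_matrix(file.path(dir, "ct.tsv")), ct)

  tp <- gen_tissue_panel_and_teratomas(cfg, lineage_map = four_tissue_map())
  write_expression_panel(tp$tissues, file.path(dir, "f.tsv"),
                         file.path(dir, "meta.tsv"))
  tp2 <- read_expression_panel(file.path(dir, "f.tsv"), file.path(dir, "meta.tsv"))
  expect_equal(tp2$values, tp$tissues$values)
  expect_equal(tp2$meta$sample, tp$tissues$meta$sample)

  mod <- gen_projection_model(cfg, k = 3, n_genes = 50)
  write_projection_model(mod, file.path(dir, "model"))
  mod2 <- read_projection_model(file.path(dir, "model"))
  expect_equal(mod2$basis, mod$basis)
  expect_equal(unname(mod2$h9_reference), unname(mod$h9_reference))
  expect_equal(mod2$score_weights, mod$score_weights)
  expect_equal(mod2$thresholds, mod$thresholds)
})
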