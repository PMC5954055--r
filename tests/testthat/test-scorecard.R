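# Lineage scorecard: QC, normalisation (with a brute-force quantile
# normalisation oracle), marker selection, moderated t, PAGE scores, grades.

test_that("QC keeps samples at the detection boundary and drops below it", {
  genes <- sprintf("G%03d", 1:100)
  mat <- matrix(25, nrow = 100, ncol = 3,
                dimnames = list(genes, c("ok", "boundary", "bad")))
  ct <- make_ct_fixture(mat)
  ct$ct[ct$sample == "boundary"][1:67] <- NA  # 33/100 detected
  ct$ct[ct$sample == "bad"][1:70] <- NA       # 30/100 detected
  out <- suppressMessages(qc_filter(ct, 0.33))
  expect_setequal(unique(out$sample), c("ok", "boundary"))
  ct_all_bad <- ct
  ct_all_bad$ct <- NA_real_
  expect_error(qc_filter(ct_all_bad), "threshold")
})

test_that("normalisation caps, scales to controls, and inverts onto [0, cap]", {
  genes <- c("ACTB", "GAPDH", "X1", "X2")
  mat <- matrix(c(20, 22, 21, 37.2,
                  20, 22, 21, 30,
                  21, 23, 22, 28), nrow = 4,
                dimnames = list(genes, c("S1", "S2", "S3")))
  nm <- normalize_ct(make_ct_fixture(mat), cap = 35)
  expect_true(all(nm$values >= 0 & nm$values <= 35))
  # X1 sits exactly at the control mean in every sample: delta-Ct 0, which
  # quantile normalisation maps to the same value in every sample
  expect_equal(unname(nm$values["X1", "S1"]), unname(nm$values["X1", "S2"]))
  expect_equal(unname(nm$values["X1", "S1"]), unname(nm$values["X1", "S3"]))
  # after quantile normalisation each sample's sorted values are identical
  sorted <- apply(nm$values, 2, sort)
  expect_equal(sorted[, 2], sorted[, 1])
  expect_equal(sorted[, 3], sorted[, 1])
  # capping: a raw 37.2 behaves exactly like a raw 35
  mat2 <- mat
  mat2["X2", "S1"] <- 35
  nm2 <- normalize_ct(make_ct_fixture(mat2), cap = 35)
  expect_equal(nm2$values, nm$values)
  # non-detects are capped, not dropped
  mat3 <- mat
  mat3["X2", "S1"] <- NA
  nm3 <- normalize_ct(make_ct_fixture(mat3), cap = 35)
  expect_equal(nm3$values, nm$values)
  # missing control gene errors with the sample named
  ct_bad <- make_ct_fixture(mat)
  ct_bad <- ct_bad[!(ct_bad$gene == "GAPDH" & ct_bad$sample == "S2"), ]
  expect_error(normalize_ct(ct_bad), "GAPDH.*S2")
})

test_that("quantile normalisation matches the brute-force oracle", {
  m <- matrix(c(5, 2, 3,
                2, 4, 6,
                9, 1, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  expect_equal(limma::normalizeQuantiles(m, ties = TRUE),
               naive_quantile_normalize(m))
  set.seed(20)
  r <- matrix(rnorm(60), nrow = 12)
  expect_equal(limma::normalizeQuantiles(r, ties = TRUE),
               naive_quantile_normalize(r))
})

test_that("normalisation is invariant to row order of the long table", {
  cfg <- sim_config(seed = 30)
  ct <- gen_ct_timecourse(cfg, lines = c("L1", "L2"))
  nm1 <- normalize_ct(ct)
  set.seed(1)
  nm2 <- normalize_ct(ct[sample.int(nrow(ct)), ])
  expect_equal(nm2$values[rownames(nm1$values), colnames(nm1$values)],
               nm1$values)
})

test_that("marker selection recovers the planted responders exactly", {
  cfg <- sim_config(seed = 41)
  panel <- default_panel()
  roles <- attr(panel, "panel_roles")
  ct <- gen_ct_timecourse(cfg, panel, lines = c("L1", "L2", "L3", "L4"))
  nm <- normalize_ct(qc_filter(ct))
  mk <- select_markers(nm)
  expect_setequal(mk$ectoderm, roles$ectoderm)
  expect_setequal(mk$mesoderm, roles$mesoderm)
  expect_setequal(mk$endoderm, roles$endoderm)
  expect_setequal(mk$undifferentiated, roles$undifferentiated)
  # cardinality and disjointness
  expect_true(all(lengths(mk) == 15))
  expect_equal(anyDuplicated(unlist(mk)), 0)
  # control genes can never be selected
  expect_false(any(c("ACTB", "GAPDH") %in% unlist(mk)))
  expect_error(select_markers(nm, n_per_set = 100), "eligible")
})

test_that("independent top lists are made disjoint deterministically", {
  # brute-force check on a small planted overlap: a gene responding under
  # two conditions goes to the condition where it ranks best
  cfg <- sim_config(seed = 43, ct_noise_sd = 0.05)
  panel <- default_panel()
  eff <- default_lineage_effects(panel)
  # make ECTO01 the strongest mesoderm responder too
  eff["ECTO01", "mesoderm"] <- 12
  eff["ECTO01", "ectoderm"] <- 12
  ct <- gen_ct_timecourse(cfg, panel, lines = c("L1", "L2"),
                          lineage_effects = eff)
  mk <- select_markers(normalize_ct(ct))
  in_ecto <- "ECTO01" %in% mk$ectoderm
  in_meso <- "ECTO01" %in% mk$mesoderm
  expect_true(xor(in_ecto, in_meso))
  expect_true(all(lengths(mk) == 15))
  expect_equal(anyDuplicated(unlist(mk)), 0)
})

test_that("moderated t reduces to the ordinary t when shrinkage is off", {
  set.seed(50)
  m <- matrix(rnorm(5 * 6), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  a <- paste0("s", 1:3); b <- paste0("s", 4:6)
  mt <- moderated_t(m, a, b, d0 = 0)
  ord <- vapply(1:5, function(i) {
    unname(t.test(m[i, a], m[i, b], var.equal = TRUE)$statistic)
  }, 0)
  expect_equal(unname(mt$t), ord, tolerance = 1e-12)
  # full shrinkage: every gene uses the prior variance
  mt_inf <- moderated_t(m, a, b, d0 = Inf, s0_sq = 0.7)
  expect_equal(unname(mt_inf$t),
               unname((rowMeans(m[, a]) - rowMeans(m[, b])) /
                        sqrt(0.7 * (1 / 3 + 1 / 3))), tolerance = 1e-12)
  expect_error(moderated_t(m, a[1], b), "at least 2")
})

test_that("null moderated t is calibrated against its reference distribution", {
  set.seed(51)
  n <- 5000
  m <- matrix(rnorm(n * 6), nrow = n)
  rownames(m) <- paste0("g", seq_len(n))
  mt <- moderated_t(m, 1:3, 4:6)
  nu <- mt$d0 + mt$df
  sd_theory <- if (is.finite(nu)) sqrt(nu / (nu - 2)) else 1
  expect_lt(abs(sd(mt$t) / sd_theory - 1), 0.15)
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  set.seed(52)
  n <- 400
  # heteroskedastic genes so that shrinkage actually matters
  sds <- exp(rnorm(n, 0, 0.5))
  m <- matrix(rnorm(n * 8, sd = rep(sds, 8)), nrow = n,
              dimnames = list(paste0("g", 1:n), paste0("s", 1:8)))
  m[1:20, 1:4] <- m[1:20, 1:4] + 2
  mt <- moderated_t(m, 1:4, 5:8)
  design <- cbind(1, rep(c(1, 0), each = 4))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_gt(cor(mt$t, fit$t[, 2]), 0.99)
  expect_lt(abs(log(mt$d0 / fit$df.prior)), log(2.5))
})

test_that("lineage score follows the parametric enrichment formula", {
  set.seed(53)
  t_null <- rnorm(200)
  names(t_null) <- paste0("g", 1:200)
  # markers whose mean equals the global mean score zero
  tv <- t_null
  tv[1:16] <- mean(t_null[17:200])  # marker mean == non-marker mean != global?
  tv[1:16] <- mean(tv)              # iterate once: exact centring
  # construct exactly: set all markers to the global mean of the final vector
  f <- function(a) {
    x <- t_null; x[1:16] <- a
    a - mean(x)
  }
  a0 <- uniroot(f, c(-5, 5), tol = 1e-12)$root
  tv <- t_null; tv[1:16] <- a0
  expect_equal(lineage_score(tv, names(tv)[1:16]), 0, tolerance = 1e-6)
  # markers exceeding the global mean by one global sd score sqrt(m) = 4
  g <- function(a) {
    x <- t_null; x[1:16] <- a
    (a - mean(x)) / sd(x) - 1
  }
  a1 <- uniroot(g, c(0, 10), tol = 1e-12)$root
  tv1 <- t_null; tv1[1:16] <- a1
  expect_equal(lineage_score(tv1, names(tv1)[1:16]), 4, tolerance = 1e-6)
  expect_error(lineage_score(t_null, character(0)), "empty")
  expect_error(lineage_score(t_null, "nope"), "missing")
})

test_that("random marker sets on null scores are approximately standard normal", {
  set.seed(54)
  t_null <- rnorm(500)
  names(t_null) <- paste0("g", 1:500)
  draws <- vapply(1:1000, function(i)
    lineage_score(t_null, sample(names(t_null), 15)), 0)
  expect_lt(abs(mean(draws)), 0.15)
  expect_gt(sd(draws), 0.85)
  expect_lt(sd(draws), 1.15)
})

test_that("grades bin scores as published, with total boundary handling", {
  expect_equal(grade_score(c(3.4, 3, 2.5, 2, 1.99, 1, 0.2, -5, NA)),
               c("+++", "++", "++", "++", "+", "+", "+/-", "+/-", "nd"))
})

test_that("scorecard grades planted strong responders as +++ end to end", {
  cfg <- sim_config(seed = 61)
  ct <- gen_ct_timecourse(cfg, lines = c("L1", "L2"))
  nm <- normalize_ct(qc_filter(ct))
  mk <- select_markers(nm)
  sc <- build_scorecard(nm, mk)
  for (lin in c("ectoderm", "mesoderm", "endoderm")) {
    row <- sc[sc$line == "L1" & sc$lineage == lin, ]
    expect_equal(row$potential_grade, "+++")
    expect_equal(row$propensity_grade, "+++")
  }
  undiff <- sc[sc$lineage == "undifferentiated", ]
  expect_true(all(undiff$potential < 0))
  # a line without day-16 data in one condition is flagged nd
  ct2 <- ct[!(ct$line == "L2" & ct$condition == "endoderm" & ct$day == 16), ]
  sc2 <- build_scorecard(normalize_ct(ct2), mk)
  expect_equal(sc2$potential_grade[sc2$line == "L2" &
                                     sc2$lineage == "endoderm"], "nd")
})

test_that("potential scores increase with the planted effect size", {
  score_at <- function(effect) {
    mean(vapply(1:3, function(i) {
      cfg <- sim_config(seed = 700 + i)
      panel <- default_panel()
      eff <- default_lineage_effects(panel, directed_effect = effect,
                                     neutral_effect = effect / 3)
      ct <- gen_ct_timecourse(cfg, panel, lines = c("L1", "L2"),
                              lineage_effects = eff)
      nm <- normalize_ct(ct)
      roles <- attr(panel, "panel_roles")
      mk <- structure(roles[c("ectoderm", "mesoderm", "endoderm",
                              "undifferentiated")], class = "marker_sets")
      sc <- build_scorecard(nm, mk)
      mean(sc$potential[sc$lineage == "ectoderm"])
    }, 0))
  }
  scores <- vapply(c(0, 0.5, 1, 2), score_at, 0)
  expect_true(all(diff(scores) > 0))
  expect_lt(abs(scores[1]), 1)  # null effect scores near zero
})
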