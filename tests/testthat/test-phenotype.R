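# Growth statistics, relative reduction, leaf series, cells, epistasis.

test_that("relative reduction reproduces the worked ratios", {
  mk <- function(ctrl, stress) data.frame(
    treatment = rep(c("control", "mannitol"), each = 2),
    rosette_mm2 = c(ctrl, ctrl, stress, stress))
  wt <- mk(100, 70)                      # 30% reduction
  expect_equal(relative_reduction(mk(100, 40), wt), 2)     # 60% -> 2
  expect_equal(relative_reduction(mk(100, 70), wt), 1)     # identical -> 1
  expect_equal(relative_reduction(mk(100, 79), wt), 0.7)   # 21% -> 0.7
  # invariant to rescaling all areas of a genotype
  expect_equal(relative_reduction(mk(500, 200), wt), 2)
  # undefined when the wild type does not shrink
  expect_error(relative_reduction(mk(100, 40), mk(100, 100)),
               "undefined")
  expect_error(relative_reduction(mk(100, 40)[1:2, ], wt), "empty")
})

test_that("rosette model recovers planted effects and is calibrated", {
  cfg <- sim_config()
  # balanced noiseless data: line effect equals the ratio of means exactly
  d <- expand.grid(genotype = c("WT", "mut"),
                   treatment = c("control", "mannitol"),
                   rep = 1:2, plant = 1:3, stringsAsFactors = FALSE)
  d$rosette_mm2 <- 100 * ifelse(d$genotype == "mut", 1.12, 1) *
    ifelse(d$treatment == "mannitol", 0.7, 1)
  d[["repeat"]] <- d$rep
  # noiseless fixture: lm warns about a perfect fit, which is the point here
  fit <- suppressWarnings(rosette_growth_test(d, "mut"))
  expect_equal(fit$effects$control$percent, 12, tolerance = 1e-8)
  expect_equal(fit$effects$mannitol$percent, 12, tolerance = 1e-8)

  # +12% genotype effect detected in >= 95% of seeded runs (n = 10 x 3)
  hits <- vapply(1:60, function(s) {
    ge <- data.frame(genotype = c("WT", "mut"), control_mult = c(1, 1.12),
                     stress_mult = cfg$stress_area_multiplier)
    sim <- simulate_phenotypes(cfg, ge, seed = 400 + s)
    f <- rosette_growth_test(sim$plants, "mut")
    f$effects$control$log2_effect > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # null interaction: non-significant in >= 94% of runs at alpha 0.05
  null_p <- vapply(1:300, function(s) {
    sim <- simulate_phenotypes(
      cfg, data.frame(genotype = c("WT", "mut"), control_mult = 1,
                      stress_mult = cfg$stress_area_multiplier),
      seed = 9000 + s)
    rosette_growth_test(sim$plants, "mut")$interaction$p
  }, 0)
  expect_gte(mean(null_p >= 0.05), 0.94)

  # Tukey p-values lie in [0,1] and missing cells error
  expect_true(all(fit$tukey$p_tukey >= 0 & fit$tukey$p_tukey <= 1))
  expect_error(rosette_growth_test(d[d$treatment == "control", ], "mut"),
               "empty genotype x treatment cell")
})

test_that("leaf-series comparison flags planted leaves and controls FWE", {
  cfg <- sim_config(n_leaves = 8L)
  base <- simulate_phenotypes(cfg, data.frame(
    genotype = c("WT", "mut"), control_mult = 1,
    stress_mult = cfg$stress_area_multiplier), seed = 77)
  lv <- base$leaves[base$leaves$treatment == "control", ]
  # plant an effect on the youngest 3 leaves of the mutant
  young <- lv$leaf >= 6 & lv$genotype == "mut"
  lv$leaf_mm2[young] <- lv$leaf_mm2[young] * 0.55
  res <- leaf_series_compare(lv, "mut", n_mc = 2000)
  flagged <- res$leaf[res$p_adj < 0.05]
  expect_true(length(flagged) > 0)
  expect_true(all(flagged >= 6))           # flagged set within planted set
  # adjusted p never below raw p
  expect_true(all(res$p_adj >= res$p))

  # null calibration (scaled down: 120 runs, 4 leaves)
  cfg2 <- sim_config(n_leaves = 4L, n_plants = 6L)
  fwe <- vapply(1:120, function(s) {
    sim <- simulate_phenotypes(cfg2, data.frame(
      genotype = c("WT", "mut"), control_mult = 1,
      stress_mult = cfg2$stress_area_multiplier), seed = 3000 + s)
    l0 <- sim$leaves[sim$leaves$treatment == "control", ]
    r0 <- leaf_series_compare(l0, "mut", n_mc = 800)
    any(r0$p_adj < 0.05)
  }, logical(1))
  # per-leaf FWE 0.05; across 4 leaves expect < ~18% of runs with any flag
  expect_lte(mean(fwe), 0.05 * 4 + 2 * sqrt(0.2 * 0.8 / 120))

  # missing leaf in one genotype is skipped with a warning
  lv2 <- lv[!(lv$genotype == "mut" & lv$leaf == 2), ]
  expect_warning(leaf_series_compare(lv2, "mut", n_mc = 500),
                 "missing genotype")
})

test_that("cellular decomposition converts units and scales inversely", {
  # 40 mm^2 leaf with 1600 um^2 cells -> 25,000 cells
  d <- cellular_decomposition(40, rep(1600, 100))
  expect_equal(d$cell_number, 25000)
  # identical leaves -> ratio 1; halving cell area doubles the estimate
  d2 <- cellular_decomposition(40, rep(800, 100))
  expect_equal(d2$cell_number / d$cell_number, 2)
  expect_error(cellular_decomposition(40, rep(1600, 10)), ">= 30")
  expect_error(cellular_decomposition(40, rep(1600, 100),
                                      leaf_unit = "acres"), "unit")
  # genotype comparison on the log scale
  da <- lapply(1:5, function(i) cellular_decomposition(40, rep(1600, 100)))
  db <- lapply(1:5, function(i) cellular_decomposition(40, rep(800, 100)))
  cmp <- compare_cellular(da, db)
  expect_equal(cmp$log2_ratio[cmp$quantity == "cell_number"], -1)
  expect_equal(cmp$log2_ratio[cmp$quantity == "cell_area"], 1)
})

test_that("interaction test: contrast algebra, null calibration, recovery", {
  cfg <- sim_config()
  # constructed data with cell means exactly additive -> coefficient 0
  cells <- expand.grid(p1 = 0:1, p2 = 0:1, rep = 1:2, plant = 1:2)
  cells$rosette_mm2 <- 2^(8 - cells$p1 - 0.5 * cells$p2)
  cells[["repeat"]] <- cells$rep
  it0 <- suppressWarnings(interaction_test(cells))  # noiseless perfect fit
  expect_equal(it0$coefficient, 0, tolerance = 1e-10)
  expect_equal(it0$classification, "additive")

  # balanced designs: coefficient equals the cell-mean contrast
  cr <- simulate_cross(cfg, -1, -0.7, interaction_log2 = 0.3, seed = 21)
  it <- interaction_test(cr)
  mu <- tapply(log2(cr$rosette_mm2), cr$genotype, mean)
  expect_equal(it$coefficient,
               unname(mu["dc"] - mu["sc1"] - mu["sc2"] + mu["ref"]),
               tolerance = 1e-10)

  # additive null: false-positive rate <= alpha + 2 * MC error (500 runs)
  fp <- vapply(1:500, function(s) {
    cr0 <- simulate_cross(cfg, -1, -1, 0, seed = 5000 + s)
    interaction_test(cr0)$classification != "additive"
  }, logical(1))
  expect_lte(mean(fp), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))

  expect_error(interaction_test(cells[cells$p1 == 0, ]), "missing design")
})

test_that("expected double reduction is the multiplicative combination", {
  expect_equal(expected_double_reduction(0.5, 0.5), 0.75)
  expect_equal(expected_double_reduction(0, 0.4), 0.4)
  expect_equal(expected_double_reduction(0.3, 0.6), 0.72)
  # symmetric and monotone
  expect_equal(expected_double_reduction(0.2, 0.7),
               expected_double_reduction(0.7, 0.2))
  expect_gt(expected_double_reduction(0.4, 0.5),
            expected_double_reduction(0.3, 0.5))
  expect_error(expected_double_reduction(1, 0.5), "\\[0, 1\\)")
  expect_error(expected_double_reduction(-0.1, 0.5), "\\[0, 1\\)")
})
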