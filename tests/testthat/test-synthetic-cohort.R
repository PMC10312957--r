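test_that("identical seed and config give byte-identical datasets", {
  cfg <- small_cohort_config(seed = 42L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$cells, b$cells)
})

test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(n_pairs = 0), "n_pairs")
  expect_error(cohort_config(n_pairs = 1), "n_pairs")
  expect_error(cohort_config(cells_per_subject = 0), "cells_per_subject")
  expect_error(cohort_config(sz_effects = list(pv_intensity = -1)),
               "positive")
  expect_error(
    cohort_config(cell_level_correlations = list(cytoplasmic_nuclear = 1.2)),
    "correlations")
  # jointly infeasible correlations -> not positive definite
  expect_error(
    cohort_config(cell_level_correlations = list(cytoplasmic_nuclear = -0.95,
                                                 cytoplasmic_vamp1 = 0.95)),
    "positive definite")
  expect_error(generate_mixed_population(cohort_config(), pvi_fraction = 0),
               "pvi_fraction")
  expect_error(generate_mixed_population(cohort_config(), pvi_fraction = 1),
               "pvi_fraction")
})

test_that("null effects give a group ratio of 1 within Monte-Carlo error", {
  null_eff <- as.list(setNames(rep(1, 6), c(
    "cytoplasmic_rbfox1", "nuclear_rbfox1", "pv_intensity",
    "pv_grain_density", "cytoplasmic_rbfox1_frozen", "vamp1_grain_density")))
  ratios <- vapply(1:60, function(s) {
    coh <- generate_cohort(cohort_config(n_pairs = 10L, cells_per_subject = 8L,
                                         sz_effects = null_eff, seed = s))
    sm <- merge(subject_means(coh, "cytoplasmic_intensity"), coh$subjects)
    mean(sm$value[sm$diagnosis == "schizophrenia"]) /
      mean(sm$value[sm$diagnosis == "comparison"])
  }, numeric(1))
  # the ratio of arithmetic group means carries a small positive Jensen
  # bias of order Var(group mean)/mean^2 (~1%) on top of Monte-Carlo error
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("programmed group ratios are recovered at large n (2% tolerance)", {
  # low-noise configuration isolates the programmed moments from sampling
  # noise; the invariant is about the generator's expectations
  cfg <- cohort_config(
    n_pairs = 200L, cells_per_subject = 20L,
    noise = list(between_pair_cv = 0.05, between_subject_cv = 0.05,
                 within_subject_cv = 0.1),
    seed = 7L)
  coh <- generate_cohort(cfg)
  measure_map <- c(cytoplasmic_intensity = "cytoplasmic_rbfox1",
                   nuclear_intensity = "nuclear_rbfox1",
                   pv_intensity = "pv_intensity")
  for (i in seq_along(measure_map)) {
    sm <- merge(subject_means(coh, names(measure_map)[i]), coh$subjects)
    ratio <- mean(sm$value[sm$diagnosis == "schizophrenia"]) /
      mean(sm$value[sm$diagnosis == "comparison"])
    expect_equal(ratio, cfg$sz_effects[[measure_map[i]]], tolerance = 0.02,
                 label = paste("group ratio of", names(measure_map)[i]))
  }
  # frozen assay: grain-density deficits
  cfgf <- cohort_config(
    n_pairs = 200L, cells_per_subject = 20L, assay = "frozen",
    noise = list(between_pair_cv = 0.05, between_subject_cv = 0.05,
                 within_subject_cv = 0.1),
    seed = 8L)
  cohf <- generate_cohort(cfgf)
  for (m in c("pv_grain_density", "vamp1_grain_density")) {
    sm <- merge(subject_means(cohf, m), cohf$subjects)
    ratio <- mean(sm$value[sm$diagnosis == "schizophrenia"]) /
      mean(sm$value[sm$diagnosis == "comparison"])
    expect_equal(ratio, cfgf$sz_effects[[m]], tolerance = 0.02,
                 label = paste("group ratio of", m))
  }
})

test_that("cell-level correlation converges to the target", {
  cfg <- cohort_config(n_pairs = 2L, cells_per_subject = 1250L, seed = 11L)
  coh <- generate_cohort(cfg)
  r <- correlation(log(coh$cells$cytoplasmic_intensity),
                   log(coh$cells$nuclear_intensity), level = "cell")
  expect_equal(r$r, cfg$cell_level_correlations$cytoplasmic_nuclear,
               tolerance = 0.05)
})

test_that("emitted records satisfy the type invariants (property)", {
  set.seed(99)
  for (rep in 1:4) {
    cfg <- cohort_config(
      n_pairs = sample(2:6, 1), cells_per_subject = sample(3:10, 1),
      assay = sample(c("fixed", "frozen"), 1),
      sz_effects = list(cytoplasmic_rbfox1 = runif(1, 0.5, 1.5)),
      cell_level_correlations = list(cytoplasmic_nuclear = runif(1, -0.5, 0.9)),
      seed = sample.int(1e6, 1))
    coh <- generate_cohort(cfg, seed = NULL)
    su <- coh$subjects
    ce <- coh$cells
    # pairs share sex, exactly one schizophrenia member each
    for (p in unique(su$pair_id)) {
      mem <- su[su$pair_id == p, ]
      expect_equal(nrow(mem), 2L)
      expect_length(unique(mem$sex), 1L)
      expect_equal(sum(mem$diagnosis == "schizophrenia"), 1L)
    }
    expect_true(all(su$age > 0))
    expect_true(all(su$brain_pH >= 6.0 & su$brain_pH <= 7.2))
    expect_true(all(su$pmi > 0))
    expect_true(all(su$rin > 0 & su$rin <= 10))
    expect_true(all(su$storage > 0))
    # cell invariants
    expect_true(all(ce$body_intensity >= 0))
    expect_true(all(ce$nuclear_intensity >= 0))
    expect_true(all(ce$cytoplasmic_intensity >= 0))
    expect_true(all(ce$nucleus_area < ce$body_area))
    expect_equal(ce$cytoplasm_area, ce$body_area - ce$nucleus_area)
    if (cfg$assay == "frozen") {
      expect_true(all(ce$pv_grain_count >= 0))
      expect_true(all(ce$vamp1_grain_count >= 0))
    }
    expect_equal(nrow(ce), 2L * cfg$n_pairs * cfg$cells_per_subject)
  }
})

test_that("interneuron panel reproduces the enrichment folds in expectation", {
  cfg <- cohort_config(
    cells_per_subject = 150L,
    noise = list(between_pair_cv = 0.05, between_subject_cv = 0.1,
                 within_subject_cv = 0.2),
    seed = 5L)
  means <- Reduce(`+`, lapply(1:6, function(s) {
    pan <- generate_interneuron_panel(cfg, n_subjects = 3L, seed = s)
    as.matrix(stats::aggregate(
      cbind(cytoplasmic_intensity, nuclear_intensity, body_intensity) ~
        subtype, pan$cells, mean)[, -1])
  })) / 6
  rownames(means) <- c("CBI", "CRI", "PVI")  # aggregate sorts alphabetically
  expect_equal(means["PVI", "cytoplasmic_intensity"] /
                 means["CRI", "cytoplasmic_intensity"], 9.6, tolerance = 0.08)
  expect_equal(means["CBI", "cytoplasmic_intensity"] /
                 means["CRI", "cytoplasmic_intensity"], 5.0, tolerance = 0.08)
  expect_equal(means["PVI", "nuclear_intensity"] /
                 means["CRI", "nuclear_intensity"], 3.0, tolerance = 0.08)
  # total (cell-body) folds emerge from the compartment folds + areas
  expect_equal(means["PVI", "body_intensity"] /
                 means["CRI", "body_intensity"], 4.0, tolerance = 0.1)
  expect_equal(means["CBI", "body_intensity"] /
                 means["CRI", "body_intensity"], 3.0, tolerance = 0.1)
})

test_that("enrichment folds of 1 equalise subtype means", {
  cfg <- cohort_config(
    cells_per_subject = 200L,
    subtype_enrichment = list(
      cytoplasmic_rbfox1 = c(PVI = 1, CBI = 1, CRI = 1),
      nuclear_rbfox1 = c(PVI = 1, CBI = 1, CRI = 1)),
    seed = 6L)
  pan <- generate_interneuron_panel(cfg, n_subjects = 4L)
  m <- stats::aggregate(cytoplasmic_intensity ~ subtype, pan$cells, mean)
  expect_lt(max(m[[2]]) / min(m[[2]]), 1.1)
})

test_that("mixed population has the programmed composition and Vamp1 fold", {
  cfg <- cohort_config(seed = 12L)
  mix <- generate_mixed_population(cfg, n_cells = 252L,
                                   pvi_fraction = 64 / 252)
  expect_equal(sum(mix$true_subtype == "PVI"), 64L)
  big <- generate_mixed_population(cfg, n_cells = 6000L, pvi_fraction = 0.5,
                                   seed = 13L)
  vd <- big$vamp1_grain_count / big$cytoplasm_area
  fold <- mean(vd[big$true_subtype == "PVI"]) /
    mean(vd[big$true_subtype == "nonPV"])
  expect_equal(fold, cfg$pv_vs_nonpv_vamp1_fold, tolerance = 0.1)
})

test_that("cohort round-trips losslessly through CSV + JSON", {
  cfg <- small_cohort_config(assay = "frozen", seed = 21L)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects, coh$subjects)
  expect_equal(back$cells, coh$cells)
  expect_equal(unclass(back$config), unclass(coh$config))
})
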