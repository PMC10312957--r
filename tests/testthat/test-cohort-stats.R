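# a cohort_dataset whose subject means equal `values` exactly (one cell per
# subject), for closed-form checks
dataset_from_subject_values <- function(subjects, values) {
  cells <- data.frame(cell_id = paste0("c", seq_len(nrow(subjects))),
                      subject_id = subjects$subject_id,
                      cytoplasmic_intensity = values,
                      stringsAsFactors = FALSE)
  pvigamma:::new_cohort_dataset(subjects, cells, cohort_config())
}

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  # identical groups: no between-group variation
  r0 <- one_way_anova_tukey(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # SSB = 4, SSW = 1, df (1, 2) -> F = 8
  r <- one_way_anova_tukey(list(g1 = c(1, 2), g2 = c(3, 4)))
  expect_equal(r$F, 8)
  expect_equal(r$df_between, 1)
  expect_equal(r$df_within, 2)
  expect_error(one_way_anova_tukey(list(a = 1, b = c(1, 2))), "at least two")
})

test_that("Tukey adjusted p is never below the unadjusted pairwise p", {
  set.seed(41)
  for (rep in 1:8) {
    k <- sample(3:4, 1)
    n <- sample(4:7, 1)
    groups <- setNames(lapply(seq_len(k), function(i)
      rnorm(n, mean = runif(1, 0, 2))), paste0("g", seq_len(k)))
    res <- one_way_anova_tukey(groups)
    mse <- sum(vapply(groups, function(g)
      sum((g - mean(g))^2), numeric(1))) / res$df_within
    for (i in seq_len(nrow(res$tukey))) {
      pr <- strsplit(res$tukey$pair[i], "-", fixed = TRUE)[[1]]
      tstat <- (mean(groups[[pr[1]]]) - mean(groups[[pr[2]]])) /
        sqrt(mse * (1 / n + 1 / n))
      p_unadj <- 2 * stats::pt(-abs(tstat), res$df_within)
      expect_gte(res$tukey$adjusted_p[i], p_unadj - 1e-12)
    }
  }
})

test_that("subtype panel post hoc reproduces the enrichment ordering", {
  pan <- generate_interneuron_panel(cohort_config(cells_per_subject = 60L,
                                                  seed = 44L),
                                    n_subjects = 3L)
  per_subj <- stats::aggregate(
    body_intensity ~ subject_id + subtype, pan$cells, mean)
  groups <- split(per_subj$body_intensity, per_subj$subtype)[
    c("CRI", "CBI", "PVI")]
  res <- one_way_anova_tukey(groups)
  p_pvi_cri <- res$tukey$adjusted_p[res$tukey$pair == "PVI-CRI"]
  p_cbi_cri <- res$tukey$adjusted_p[res$tukey$pair == "CBI-CRI"]
  expect_lt(p_pvi_cri, p_cbi_cri)
  expect_lt(p_pvi_cri, 0.05)
})

test_that("ANCOVA F matches the normal-equations oracle to 1e-8", {
  set.seed(42)
  for (rep in 1:6) {
    np <- sample(5:8, 1)
    cfg <- cohort_config(n_pairs = np, cells_per_subject = 3L,
                         seed = sample.int(1e6, 1))
    coh <- generate_cohort(cfg, seed = NULL)
    for (model in c("paired", "unpaired")) {
      res <- ancova(coh, "cytoplasmic_intensity", model)
      d <- pvigamma:::build_ancova_data(coh, "cytoplasmic_intensity")
      covs <- pvigamma:::default_covariates(model, "cytoplasmic_intensity")
      block <- if (model == "paired") "pair" else NULL
      X_full <- stats::model.matrix(
        stats::reformulate(c("diagnosis", block, covs)), d)
      X_red <- stats::model.matrix(stats::reformulate(c(block, covs)), d)
      expect_equal(res$diagnosis_F,
                   oracle_partial_f(X_full, X_red, d$value),
                   tolerance = 1e-8)
    }
  }
})

test_that("percent difference matches the closed form on a hand-built design", {
  subjects <- data.frame(
    subject_id = sprintf("s%d", 1:8),
    pair_id = rep(1:4, each = 2),
    diagnosis = rep(c("comparison", "schizophrenia"), 4),
    sex = "M", age = 40, brain_pH = 6.7, pmi = 15, rin = 8, storage = 100,
    stringsAsFactors = FALSE)
  comp <- c(10, 12, 9, 11)
  sz <- comp - c(1, 3, 1, 3)          # group difference 2 on average
  values <- as.vector(rbind(comp, sz))
  ds <- dataset_from_subject_values(subjects, values)
  res <- ancova(ds, "cytoplasmic_intensity", "paired",
                covariates = character())
  expect_equal(res$percent_difference, 100 * 2 / mean(comp))
  expect_equal(unname(res$adjusted_means),
               c(mean(comp), mean(sz)))
  # F agrees with the oracle
  d <- pvigamma:::build_ancova_data(ds, "cytoplasmic_intensity")
  X_full <- stats::model.matrix(~ diagnosis + pair, d)
  X_red <- stats::model.matrix(~ pair, d)
  expect_equal(res$diagnosis_F, oracle_partial_f(X_full, X_red, d$value),
               tolerance = 1e-10)
})

test_that("paired model demands complete pairs; rank deficiency is named", {
  cfg <- small_cohort_config(seed = 51L)
  coh <- generate_cohort(cfg)
  coh$subjects <- coh$subjects[-1, ]
  coh$cells <- coh$cells[coh$cells$subject_id %in% coh$subjects$subject_id, ]
  expect_error(ancova(coh, "cytoplasmic_intensity", "paired"), "incomplete")
  # duplicated covariate column -> aliased term
  coh2 <- generate_cohort(cfg)
  coh2$subjects$storage <- coh2$subjects$pmi
  expect_error(ancova(coh2, "cytoplasmic_intensity", "unpaired"),
               "aliased")
})

test_that("null covariates are rarely retained; programmed ones always", {
  empties <- vapply(1:80, function(s) {
    coh <- generate_cohort(cohort_config(n_pairs = 10L,
                                         cells_per_subject = 4L, seed = s))
    length(retain_significant_covariates(coh, "cytoplasmic_intensity",
                                         "paired",
                                         covariates = "brain_pH")) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.9)

  kept <- vapply(1:15, function(s) {
    coh <- generate_cohort(cohort_config(
      n_pairs = 20L, cells_per_subject = 6L,
      covariate_effects = c(brain_pH = 0.8), seed = 100 + s))
    "brain_pH" %in% retain_significant_covariates(
      coh, "cytoplasmic_intensity", "paired", covariates = "brain_pH")
  }, logical(1))
  expect_true(all(kept))

  coh <- generate_cohort(small_cohort_config(seed = 52L))
  expect_identical(
    retain_significant_covariates(coh, "cytoplasmic_intensity", "paired",
                                  covariates = character()),
    character())
})

test_that("co-occurring factor scan is null under the null", {
  all_ns <- vapply(1:15, function(s) {
    coh <- generate_cohort(cohort_config(n_pairs = 20L,
                                         cells_per_subject = 4L, seed = s))
    tab <- suppressWarnings(
      cooccurring_factor_scan(coh, "cytoplasmic_intensity"))
    all(tab$p_adjusted > 0.05)
  }, logical(1))
  expect_gte(mean(all_ns), 0.8)
})

test_that("a factor tracking the dependent has the smallest adjusted p", {
  coh <- generate_cohort(cohort_config(n_pairs = 20L,
                                       cells_per_subject = 6L, seed = 61L))
  sm <- merge(subject_means(coh, "cytoplasmic_intensity"), coh$subjects)
  sz <- sm[sm$diagnosis == "schizophrenia", ]
  flag <- sz$subject_id[sz$value > stats::median(sz$value)]
  coh$subjects$suicide <- coh$subjects$subject_id %in% flag
  tab <- suppressWarnings(
    cooccurring_factor_scan(coh, "cytoplasmic_intensity"))
  expect_equal(tab$factor[which.min(tab$p_adjusted)], "suicide")
  # empty factor list -> empty table
  empty <- cooccurring_factor_scan(coh, "cytoplasmic_intensity",
                                   factors = character())
  expect_equal(nrow(empty), 0L)
})

test_that("correlation handles exact and degenerate cases", {
  x <- 1:10
  r <- correlation(x, 2 * x, level = "cell")
  expect_equal(r$r, 1)
  expect_error(correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(correlation(1:2, 2:3), "at least 3")
})

test_that("fold change is the ratio of group means", {
  expect_equal(fold_change(9.6, 1.0), 9.6)
  expect_equal(fold_change(3, 3), 1)
  a <- c(2, 4, 9); b <- c(1, 2, 3)
  expect_equal(fold_change(mean(a), mean(b)), mean(a) / mean(b))
  expect_error(fold_change(1, 0), "denominator")
})
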