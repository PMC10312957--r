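#' One-way ANOVA with Tukey's multiple comparison test
#'
#' Classical between/within sums-of-squares decomposition across groups,
#' followed by Tukey HSD adjusted pairwise comparisons and compact
#' significance letters (groups not sharing a letter differ at p < 0.05).
#'
#' @param groups named list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @return object of class \code{anova_result}: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p}, \code{group_means}, \code{tukey}
#'   (data.frame: pair, difference, adjusted_p, significant),
#'   \code{letters}.
#' @export
one_way_anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("every group needs at least two values", call. = FALSE)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk), difference = tk[, "diff"],
                      adjusted_p = tk[, "p adj"],
                      significant = tk[, "p adj"] < 0.05,
                      row.names = NULL, stringsAsFactors = FALSE)
  means <- vapply(groups, mean, numeric(1))
  structure(list(
    F = tab["group", "F value"], df_between = tab["group", "Df"],
    df_within = tab["Residuals", "Df"], p = tab["group", "Pr(>F)"],
    group_means = means, tukey = tukey,
    letters = significance_letters(names(groups), tukey)),
    class = "anova_result")
}

# compact letter display: groups not sharing a letter are significantly
# different (insert-and-absorb over the non-significant pairs)
significance_letters <- function(labels, tukey) {
  k <- length(labels)
  same <- diag(TRUE, k)
  dimnames(same) <- list(labels, labels)
  for (i in seq_len(nrow(tukey))) {
    pr <- strsplit(tukey$pair[i], "-", fixed = TRUE)[[1]]
    if (!tukey$significant[i])
      same[pr[1], pr[2]] <- same[pr[2], pr[1]] <- TRUE
  }
  groups_list <- list()
  for (g in labels) {
    members <- labels[same[g, ]]
    covered <- any(vapply(groups_list, function(s) all(members %in% s),
                          logical(1)))
    if (!covered) groups_list <- c(groups_list, list(members))
  }
  lett <- vapply(labels, function(g) paste(
    letters[which(vapply(groups_list, function(s) g %in% s, logical(1)))],
    collapse = ""), character(1))
  lett
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.3g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(data.frame(mean = x$group_means, letter = x$letters))
  invisible(x)
}

measure_is_mrna <- function(measure) {
  grepl("grain", measure, fixed = TRUE)
}

default_covariates <- function(model, measure) {
  covs <- c("brain_pH", "pmi", "storage")
  if (model == "unpaired") covs <- c("age", "sex", covs)
  if (measure_is_mrna(measure)) covs <- c(covs, "rin")
  covs
}

build_ancova_data <- function(dataset, measure) {
  sm <- subject_means(dataset, measure)
  d <- merge(dataset$subjects, sm, by = "subject_id")
  d$diagnosis <- factor(d$diagnosis, levels = c("comparison", "schizophrenia"))
  d$pair <- factor(d$pair_id)
  d
}

fit_lm_checked <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit
}

# partial (type-III) F test for one term: compare the full fit against the
# fit without that term
partial_f <- function(full, data, response, keep_terms, drop_term) {
  f_red <- stats::reformulate(setdiff(keep_terms, drop_term),
                              response = response)
  red <- stats::lm(f_red, data = data)
  a <- stats::anova(red, full)
  list(F = a$F[2], df = c(a$Df[2], a$Res.Df[2]), p = a$`Pr(>F)`[2])
}

#' Diagnosis-effect ANCOVA on subject-level means
#'
#' Fits the study's two covariance models on the subject means of a
#' measure. The paired model has diagnosis as the main effect, subject pair
#' as a fixed blocking factor, and tissue covariates (brain pH, PMI,
#' storage time, plus RIN for mRNA measures); the unpaired model replaces
#' the pair block with age and sex. The diagnosis effect is tested by a
#' partial (type-III) F test, and the percent difference is computed from
#' covariate-adjusted group means.
#'
#' @param dataset a \code{cohort_dataset}.
#' @param measure cell-level measure (see \code{\link{subject_means}}).
#' @param model \code{"paired"} or \code{"unpaired"}.
#' @param covariates candidate covariate names; defaults to the model's
#'   standard set (RIN included only for mRNA measures).
#' @param retain_covariates if TRUE, covariates are first screened in the
#'   full model and only those with partial-F p < 0.05 are kept (single
#'   pass), mirroring the study's final models.
#' @return object of class \code{ancova_result}: \code{model},
#'   \code{diagnosis_F}, \code{diagnosis_df}, \code{p},
#'   \code{percent_difference} (100 x (1 - adjusted schizophrenia mean /
#'   adjusted comparison mean)), \code{adjusted_means},
#'   \code{retained_covariates}, \code{coefficients}.
#' @export
ancova <- function(dataset, measure, model = c("paired", "unpaired"),
                   covariates = NULL, retain_covariates = FALSE) {
  model <- match.arg(model)
  if (is.null(covariates)) covariates <- default_covariates(model, measure)
  d <- build_ancova_data(dataset, measure)
  if (model == "paired") {
    counts <- table(d$pair_id)
    if (any(counts != 2))
      stop("paired model requires complete pairs; incomplete pair(s): ",
           paste(names(counts)[counts != 2], collapse = ", "), call. = FALSE)
  }
  if (retain_covariates && length(covariates))
    covariates <- retained_covariates_(d, model, covariates)
  block <- if (model == "paired") "pair" else NULL
  terms <- c("diagnosis", block, covariates)
  form <- stats::reformulate(terms, response = "value")
  fit <- fit_lm_checked(form, d)
  ft <- partial_f(fit, d, "value", terms, "diagnosis")

  adj <- adjusted_group_means(fit, d)
  if (adj["comparison"] <= 0)
    warning("adjusted comparison mean is not positive; ",
            "percent difference undefined")
  pct <- 100 * (1 - adj["schizophrenia"] / adj["comparison"])
  structure(list(
    model = model, measure = measure,
    diagnosis_F = ft$F, diagnosis_df = ft$df, p = ft$p,
    percent_difference = unname(pct), adjusted_means = adj,
    retained_covariates = covariates,
    coefficients = stats::coef(fit), fit = fit),
    class = "ancova_result")
}

# covariate-adjusted group means: predict every subject under each
# diagnosis (pair effects and covariates at their observed values) and
# average
adjusted_group_means <- function(fit, d) {
  p <- vapply(levels(d$diagnosis), function(lev) {
    dd <- d
    dd$diagnosis <- factor(lev, levels = levels(d$diagnosis))
    mean(stats::predict(fit, newdata = dd))
  }, numeric(1))
  p
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf(
    "%s ANCOVA on %s: diagnosis F(%d,%d) = %.3g, p = %.4g\n",
    x$model, x$measure, x$diagnosis_df[1], x$diagnosis_df[2],
    x$diagnosis_F, x$p))
  cat(sprintf("  adjusted means: comparison %.4g, schizophrenia %.4g (%.1f%% difference)\n",
              x$adjusted_means["comparison"],
              x$adjusted_means["schizophrenia"], x$percent_difference))
  if (length(x$retained_covariates))
    cat("  covariates:", paste(x$retained_covariates, collapse = ", "), "\n")
  invisible(x)
}

retained_covariates_ <- function(d, model, covariates) {
  block <- if (model == "paired") "pair" else NULL
  terms <- c("diagnosis", block, covariates)
  full <- fit_lm_checked(stats::reformulate(terms, "value"), d)
  keep <- vapply(covariates, function(cv)
    partial_f(full, d, "value", terms, cv)$p < 0.05, logical(1))
  covariates[keep]
}

#' Covariates retained by the initial-model screen
#'
#' Fits the full ANCOVA once and returns the covariates whose partial-F
#' p-value is below 0.05 (single pass, no iteration); the study's final
#' models included only these.
#'
#' @inheritParams ancova
#' @return character vector (possibly empty).
#' @export
retain_significant_covariates <- function(dataset, measure,
                                          model = c("paired", "unpaired"),
                                          covariates = NULL) {
  model <- match.arg(model)
  if (is.null(covariates)) covariates <- default_covariates(model, measure)
  if (!length(covariates)) return(character())
  d <- build_ancova_data(dataset, measure)
  retained_covariates_(d, model, covariates)
}

#' Scan schizophrenia-associated co-occurring factors
#'
#' Within the schizophrenia group only, fits one ANCOVA per binary factor
#' (factor as main effect; sex, age, brain pH, PMI, storage and RIN for
#' mRNA measures as covariates) and Bonferroni-adjusts the factor p-values
#' across the scan.  Factors with identical values in all subjects are
#' skipped with a warning.
#'
#' @param dataset a \code{cohort_dataset}.
#' @param measure cell-level measure.
#' @param factors factor column names (default: all seven study factors).
#' @return data.frame: factor, F, df1, df2, p, p_adjusted.
#' @export
cooccurring_factor_scan <- function(dataset, measure,
                                    factors = cooccurring_factors) {
  if (!length(factors))
    return(data.frame(factor = character(), F = numeric(),
                      df1 = integer(), df2 = integer(),
                      p = numeric(), p_adjusted = numeric()))
  d <- build_ancova_data(dataset, measure)
  d <- d[d$diagnosis == "schizophrenia", ]
  covs <- c("sex", "age", "brain_pH", "pmi", "storage")
  if (measure_is_mrna(measure)) covs <- c(covs, "rin")
  rows <- list()
  for (f in factors) {
    if (!f %in% names(d)) stop("unknown factor: ", f, call. = FALSE)
    if (length(unique(d[[f]])) < 2) {
      warning("factor ", f, " has identical values in all subjects; skipped")
      next
    }
    terms <- c(f, covs)
    fit <- fit_lm_checked(stats::reformulate(terms, "value"), d)
    ft <- partial_f(fit, d, "value", terms, f)
    rows[[f]] <- data.frame(factor = f, F = ft$F, df1 = ft$df[1],
                            df2 = ft$df[2], p = ft$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out))
    out$p_adjusted <- pmin(1, out$p * length(factors))  # Bonferroni
  out
}

#' Pearson correlation with two-sided test
#'
#' @param x,y numeric vectors (n >= 3, finite, non-degenerate).
#' @param level annotation only: \code{"subject"} or \code{"cell"}.
#' @return list with \code{r}, \code{p}, \code{n}, \code{level}.
#' @export
correlation <- function(x, y, level = c("subject", "cell")) {
  level <- match.arg(level)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), level = level)
}

#' Fold change of group means
#'
#' @param numerator_group_mean,denominator_group_mean group means; the
#'   denominator must be positive.
#' @return numeric fold.
#' @export
fold_change <- function(numerator_group_mean, denominator_group_mean) {
  if (any(denominator_group_mean <= 0))
    stop("fold change undefined: denominator must be positive",
         call. = FALSE)
  numerator_group_mean / denominator_group_mean
}
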