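#' Configuration for the synthetic matched-pair cohort generator
#'
#' Defines the statistical world the generator emulates: sex-matched
#' case/control subject pairs with tissue-quality covariates, and per-cell
#' measurements (compartment Rbfox1 immunofluorescence, PV immunofluorescence,
#' PV and Vamp1 mRNA grain counts) carrying programmed diagnosis effects,
#' interneuron-subtype enrichment and cell-level correlations.
#'
#' Intensities and grain densities are lognormal; variability is hierarchical
#' (pair effect, subject effect, cell noise, all on the log scale) so the
#' matched-pair structure is real.  Correlated measures are produced by a
#' Gaussian copula on the log scale, which preserves the lognormal marginals
#' while hitting the target Pearson correlations.  Grain counts are negative
#' binomial with the cytoplasmic area as offset.
#'
#' Default diagnosis effects are the study effect sizes: multiplicative
#' schizophrenia/comparison ratios of 0.71 for cytoplasmic and nuclear
#' Rbfox1 (29% deficits), 0.63 for PV immunofluorescence (37%), and for the
#' fresh-frozen assay 0.86 for cytoplasmic Rbfox1 and PV grain density (14%)
#' and 0.80 for Vamp1 grain density (20%).  Default subtype enrichment
#' (fold vs CRIs): cytoplasmic Rbfox1 9.6 (PVI) / 5.0 (CBI); nuclear Rbfox1
#' 3.0 (PVI) / 2.6 (CBI).  With the default compartment areas these imply
#' total-Rbfox1 folds of about 4.0 (PVI) and 3.0 (CBI), and a PVI/CRI C/N
#' fold of 3.2.
#'
#' @param n_pairs number of subject pairs (default 20; the fresh-frozen
#'   assay subset uses 10).
#' @param cells_per_subject sampled PVIs per subject (default 42,
#'   approximately the study's 847 cells / 20 subjects).
#' @param assay \code{"fixed"} (paraformaldehyde-fixed immunofluorescence:
#'   Rbfox1 compartment intensities + PV intensity) or \code{"frozen"}
#'   (fresh-frozen in situ hybridisation + immunohistochemistry: cytoplasmic
#'   and nuclear Rbfox1 intensity plus PV and Vamp1 grain counts).
#' @param baselines named list of lognormal medians: \code{cytoplasmic_rbfox1}
#'   and \code{nuclear_rbfox1} (CRI reference level, a.u.),
#'   \code{pv_intensity} (PVI, a.u.), \code{pv_grain_density} and
#'   \code{vamp1_grain_density} (PVI, grains/um^2), \code{pv_grain_density_nonpv}
#'   (non-PV neurons).
#' @param sz_effects named multiplicative schizophrenia/comparison factors
#'   (see Details); all must be positive.
#' @param subtype_enrichment list with per-measure fold vs CRI for
#'   \code{PVI} and \code{CBI}.
#' @param pv_vs_nonpv_vamp1_fold expected PVI / non-PV Vamp1 density fold.
#' @param cell_level_correlations named list of target cell-level Pearson
#'   correlations on the log scale:
#'   \code{cytoplasmic_nuclear}, \code{cytoplasmic_vamp1}.
#' @param noise list: \code{between_pair_cv}, \code{between_subject_cv},
#'   \code{within_subject_cv} (coefficients of variation of the lognormal
#'   components).
#' @param covariate_effects optional named numeric vector (names among
#'   \code{age}, \code{brain_pH}, \code{pmi}, \code{rin}, \code{storage});
#'   slope per covariate SD added to the log mean of every measure.  Zero
#'   (absent) by default: tissue covariates carry no effect, as the study
#'   found.
#' @param cooccurring_prevalence named probabilities of the co-occurring
#'   factors among schizophrenia subjects.  The factors are labels only
#'   (null effect), matching the study's negative factor scan.
#' @param areas list: \code{body_um2} (median cell-body area),
#'   \code{nucleus_fraction} (mean nuclear share of the body area),
#'   \code{area_cv}.
#' @param grain_size negative-binomial size (dispersion) of grain counts.
#' @param seed integer seed stored with the configuration and used by
#'   \code{\link{generate_cohort}}.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_pairs = 20L,
                          cells_per_subject = 42L,
                          assay = c("fixed", "frozen"),
                          baselines = list(),
                          sz_effects = list(),
                          subtype_enrichment = list(),
                          pv_vs_nonpv_vamp1_fold = 2,
                          cell_level_correlations = list(),
                          noise = list(),
                          covariate_effects = numeric(),
                          cooccurring_prevalence = list(),
                          areas = list(),
                          grain_size = 20,
                          seed = 1L) {
  assay <- match.arg(assay)
  base_def <- list(cytoplasmic_rbfox1 = 90, nuclear_rbfox1 = 500,
                   pv_intensity = 800,
                   pv_grain_density = 0.5, vamp1_grain_density = 0.30,
                   pv_grain_density_nonpv = 0.04)
  eff_def <- list(cytoplasmic_rbfox1 = 0.71, nuclear_rbfox1 = 0.71,
                  pv_intensity = 0.63, pv_grain_density = 0.86,
                  cytoplasmic_rbfox1_frozen = 0.86,
                  vamp1_grain_density = 0.80)
  enr_def <- list(cytoplasmic_rbfox1 = c(PVI = 9.6, CBI = 5.0, CRI = 1),
                  nuclear_rbfox1 = c(PVI = 3.0, CBI = 2.6, CRI = 1))
  cor_def <- list(cytoplasmic_nuclear = 0.6, cytoplasmic_vamp1 = 0.5)
  noise_def <- list(between_pair_cv = 0.15, between_subject_cv = 0.2,
                    within_subject_cv = 0.4)
  cooc_def <- list(schizoaffective = 0.25, substance_use = 0.40,
                   nicotine = 0.60, antidepressants = 0.35,
                   benzodiazepines = 0.25, valproic_acid = 0.15,
                   suicide = 0.30)
  areas_def <- list(body_um2 = 180, nucleus_fraction = 0.5, area_cv = 0.15)

  cfg <- list(
    n_pairs = as.integer(n_pairs),
    cells_per_subject = as.integer(cells_per_subject),
    assay = assay,
    baselines = utils::modifyList(base_def, as.list(baselines)),
    sz_effects = utils::modifyList(eff_def, as.list(sz_effects)),
    subtype_enrichment = utils::modifyList(enr_def,
                                           as.list(subtype_enrichment)),
    pv_vs_nonpv_vamp1_fold = pv_vs_nonpv_vamp1_fold,
    cell_level_correlations = utils::modifyList(cor_def,
                                                as.list(cell_level_correlations)),
    noise = utils::modifyList(noise_def, as.list(noise)),
    covariate_effects = covariate_effects,
    cooccurring_prevalence = utils::modifyList(cooc_def,
                                               as.list(cooccurring_prevalence)),
    areas = utils::modifyList(areas_def, as.list(areas)),
    grain_size = grain_size,
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.na(cfg$n_pairs) || cfg$n_pairs < 2L)
    stop("n_pairs must be at least 2", call. = FALSE)
  if (is.na(cfg$cells_per_subject) || cfg$cells_per_subject < 1L)
    stop("cells_per_subject must be positive", call. = FALSE)
  if (any(unlist(cfg$baselines) <= 0))
    stop("baselines must be positive", call. = FALSE)
  if (any(unlist(cfg$sz_effects) <= 0))
    stop("sz_effects must be positive multiplicative factors", call. = FALSE)
  if (any(unlist(cfg$subtype_enrichment) <= 0))
    stop("subtype enrichment folds must be positive", call. = FALSE)
  for (m in names(cfg$subtype_enrichment)) {
    f <- cfg$subtype_enrichment[[m]]
    if (!all(c("PVI", "CBI", "CRI") %in% names(f)))
      stop("subtype enrichment for ", m,
           " must name PVI, CBI and CRI", call. = FALSE)
  }
  if (cfg$pv_vs_nonpv_vamp1_fold <= 0)
    stop("pv_vs_nonpv_vamp1_fold must be positive", call. = FALSE)
  r <- unlist(cfg$cell_level_correlations)
  if (any(abs(r) >= 1))
    stop("cell-level correlations must lie in (-1, 1)", call. = FALSE)
  # copula correlation matrix must be positive definite
  ev <- eigen(copula_matrix(cfg), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("cell-level correlation matrix is not positive definite",
         call. = FALSE)
  if (any(unlist(cfg$noise) < 0))
    stop("noise CVs must be non-negative", call. = FALSE)
  pr <- unlist(cfg$cooccurring_prevalence)
  if (any(pr < 0 | pr > 1))
    stop("co-occurring prevalences must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

# measures carried through the log-scale Gaussian copula, in fixed order
copula_measures <- c("cytoplasmic_rbfox1", "nuclear_rbfox1", "pv_intensity",
                     "pv_grain_density", "vamp1_grain_density")

copula_matrix <- function(cfg) {
  r <- cfg$cell_level_correlations
  m <- diag(length(copula_measures))
  dimnames(m) <- list(copula_measures, copula_measures)
  m["cytoplasmic_rbfox1", "nuclear_rbfox1"] <-
    m["nuclear_rbfox1", "cytoplasmic_rbfox1"] <- r$cytoplasmic_nuclear
  m["cytoplasmic_rbfox1", "vamp1_grain_density"] <-
    m["vamp1_grain_density", "cytoplasmic_rbfox1"] <- r$cytoplasmic_vamp1
  m
}

# lognormal sigma for a target coefficient of variation
cv_to_sigma <- function(cv) sqrt(log(1 + cv^2))
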