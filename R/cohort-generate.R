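#' Generate a matched-pair cohort with per-cell measurements
#'
#' Draws \code{n_pairs} sex-matched case/control subject pairs with
#' tissue-quality covariates, then \code{cells_per_subject} sampled PVIs per
#' subject.  Measures are lognormal with a hierarchical log-scale
#' decomposition (pair + subject + cell) and a Gaussian copula across
#' measures, so that the expected schizophrenia/comparison ratio of subject
#' means equals \code{sz_effects[measure]} exactly and the matched-pair
#' ANCOVA has genuine blocking structure to exploit.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer; defaults to \code{config$seed}.  Pass \code{NULL} to
#'   draw from the current RNG state.
#' @return An object of class \code{cohort_dataset}: list with
#'   \code{subjects} (one row per subject), \code{cells} (one row per
#'   sampled neuron) and \code{config}.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  subjects <- draw_subjects(config)
  cells <- draw_cells(config, subjects)
  new_cohort_dataset(subjects, cells, config)
}

new_cohort_dataset <- function(subjects, cells, config) {
  structure(list(subjects = subjects, cells = cells, config = config),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Cohort dataset (", x$config$assay, " assay): ",
      nrow(x$subjects), " subjects, ", nrow(x$cells), " cells\n", sep = "")
  invisible(x)
}

cooccurring_factors <- c("schizoaffective", "substance_use", "nicotine",
                         "antidepressants", "benzodiazepines",
                         "valproic_acid", "suicide")

# Covariate distributions follow the cohort summary table: age matched
# within pair; brain pH slightly lower in schizophrenia; PMI, RIN and
# storage time similar between groups.
draw_subjects <- function(config) {
  np <- config$n_pairs
  pair_id <- rep(seq_len(np), each = 2)
  diagnosis <- rep(c("comparison", "schizophrenia"), np)
  sex <- rep(ifelse(runif(np) < 0.75, "M", "F"), each = 2)
  age_base <- pmax(18, rnorm(np, 46, 11.5))
  age <- pmax(18, rep(age_base, each = 2) + rnorm(2 * np, 0, 1.5))
  sz <- diagnosis == "schizophrenia"
  ph <- ifelse(sz, rnorm(2 * np, 6.5, 0.3), rnorm(2 * np, 6.7, 0.2))
  ph <- pmin(7.2, pmax(6.0, ph))
  pmi <- pmax(2, ifelse(sz, rnorm(2 * np, 15.4, 6.3), rnorm(2 * np, 16.4, 5.5)))
  rin <- pmin(10, pmax(5, rnorm(2 * np, 8.1, 0.5)))
  storage_base <- pmax(12, rnorm(np, 107, 30))
  storage <- pmax(12, rep(storage_base, each = 2) + rnorm(2 * np, 0, 12))
  out <- data.frame(
    subject_id = sprintf("S%02d%s", pair_id, ifelse(sz, "sz", "c")),
    pair_id = pair_id, diagnosis = diagnosis, sex = sex, age = age,
    brain_pH = ph, pmi = pmi, rin = rin, storage = storage,
    stringsAsFactors = FALSE)
  for (f in cooccurring_factors) {
    p <- config$cooccurring_prevalence[[f]]
    out[[f]] <- sz & (runif(2 * np) < p)
  }
  out
}

# per-subject log-scale offsets for every copula measure: pair effect +
# subject effect (both correlated across measures) + covariate effects
subject_log_offsets <- function(config, subjects) {
  nm <- length(copula_measures)
  ch <- chol(copula_matrix(config))
  s_pair <- cv_to_sigma(config$noise$between_pair_cv)
  s_subj <- cv_to_sigma(config$noise$between_subject_cv)
  np <- max(subjects$pair_id)
  u_pair <- (matrix(rnorm(np * nm), np) %*% ch) * s_pair
  u_subj <- (matrix(rnorm(nrow(subjects) * nm), nrow(subjects)) %*% ch) * s_subj
  off <- u_pair[subjects$pair_id, , drop = FALSE] + u_subj
  colnames(off) <- copula_measures
  ce <- config$covariate_effects
  if (length(ce)) {
    for (cv in names(ce)) {
      z <- scale(subjects[[cv]])[, 1]
      off <- off + ce[[cv]] * z
    }
  }
  off
}

draw_cell_areas <- function(config, n) {
  a <- config$areas
  body <- rlnorm(n, log(a$body_um2), cv_to_sigma(a$area_cv))
  # nuclear share of the body area, mildly variable around the mean
  frac <- stats::rbeta(n, a$nucleus_fraction * 40,
                       (1 - a$nucleus_fraction) * 40)
  nucleus <- body * frac
  data.frame(body_area = body, nucleus_area = nucleus,
             cytoplasm_area = body - nucleus)
}

# cell-level log medians for one subject given diagnosis and assay
measure_log_medians <- function(config, sz) {
  b <- config$baselines
  enr <- config$subtype_enrichment
  eff <- config$sz_effects
  med <- c(
    cytoplasmic_rbfox1 = b$cytoplasmic_rbfox1 * enr$cytoplasmic_rbfox1[["PVI"]],
    nuclear_rbfox1 = b$nuclear_rbfox1 * enr$nuclear_rbfox1[["PVI"]],
    pv_intensity = b$pv_intensity,
    pv_grain_density = b$pv_grain_density,
    vamp1_grain_density = b$vamp1_grain_density)
  if (sz) {
    cyto_eff <- if (config$assay == "frozen")
      eff$cytoplasmic_rbfox1_frozen else eff$cytoplasmic_rbfox1
    # the frozen assay reports the same co-regulated attenuation for both
    # Rbfox1 compartments
    nuc_eff <- if (config$assay == "frozen")
      eff$cytoplasmic_rbfox1_frozen else eff$nuclear_rbfox1
    med <- med * c(cyto_eff, nuc_eff, eff$pv_intensity,
                   eff$pv_grain_density, eff$vamp1_grain_density)
  }
  log(med)
}

draw_cells <- function(config, subjects) {
  n_cells <- config$cells_per_subject
  nm <- length(copula_measures)
  ch <- chol(copula_matrix(config))
  s_cell <- cv_to_sigma(config$noise$within_subject_cv)
  offsets <- subject_log_offsets(config, subjects)
  frozen <- config$assay == "frozen"

  res <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects[i, ]
    mu <- measure_log_medians(config, subj$diagnosis == "schizophrenia") +
      offsets[i, ]
    z <- (matrix(rnorm(n_cells * nm), n_cells) %*% ch) * s_cell
    logv <- sweep(z, 2, mu, `+`)
    colnames(logv) <- copula_measures
    areas <- draw_cell_areas(config, n_cells)

    nuclear <- exp(logv[, "nuclear_rbfox1"])
    cyto <- exp(logv[, "cytoplasmic_rbfox1"])
    body <- (nuclear * areas$nucleus_area + cyto * areas$cytoplasm_area) /
      areas$body_area
    layer <- if (frozen) rep("L4", n_cells)
             else sample(c("L2", "L4"), n_cells, replace = TRUE)
    cells <- data.frame(
      cell_id = sprintf("%s_c%03d", subj$subject_id, seq_len(n_cells)),
      subject_id = subj$subject_id, subtype = "PVI", layer = layer,
      body_intensity = body, nuclear_intensity = nuclear,
      cytoplasmic_intensity = cyto,
      body_area = areas$body_area, nucleus_area = areas$nucleus_area,
      cytoplasm_area = areas$cytoplasm_area,
      pv_intensity = if (frozen) NA_real_ else exp(logv[, "pv_intensity"]),
      pv_grain_count = NA_integer_, vamp1_grain_count = NA_integer_,
      stringsAsFactors = FALSE)
    if (frozen) {
      cells$pv_grain_count <- rnbinom(
        n_cells, size = config$grain_size,
        mu = exp(logv[, "pv_grain_density"]) * areas$cytoplasm_area)
      cells$vamp1_grain_count <- rnbinom(
        n_cells, size = config$grain_size,
        mu = exp(logv[, "vamp1_grain_density"]) * areas$cytoplasm_area)
    }
    res[[i]] <- cells
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Generate an interneuron subtype panel from unaffected subjects
#'
#' Emulates the subtype-comparison experiment: each unaffected subject
#' carries PVI, CBI and CRI cells whose expected compartment intensities
#' obey the configured enrichment folds relative to CRIs.  Total (cell-body)
#' intensity is the area-weighted combination of the nuclear and cytoplasmic
#' compartments, so its enrichment emerges from the compartment folds
#' (about 4.0-fold for PVIs and 3.0-fold for CBIs at the defaults).
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n_subjects number of unaffected subjects (the study used 3).
#' @param seed integer; defaults to \code{config$seed}.
#' @return a \code{cohort_dataset} whose cells span the three subtypes.
#' @export
generate_interneuron_panel <- function(config, n_subjects = 3L,
                                       seed = config$seed) {
  validate_cohort_config(config)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  enr <- config$subtype_enrichment
  subtypes <- c("PVI", "CBI", "CRI")

  subjects <- data.frame(
    subject_id = sprintf("U%02d", seq_len(n_subjects)),
    pair_id = seq_len(n_subjects), diagnosis = "comparison",
    sex = ifelse(runif(n_subjects) < 0.75, "M", "F"),
    age = pmax(18, rnorm(n_subjects, 46, 11.5)),
    brain_pH = pmin(7.2, pmax(6.0, rnorm(n_subjects, 6.7, 0.2))),
    pmi = pmax(2, rnorm(n_subjects, 16.4, 5.5)),
    rin = pmin(10, pmax(5, rnorm(n_subjects, 8.1, 0.5))),
    storage = pmax(12, rnorm(n_subjects, 107, 30)),
    stringsAsFactors = FALSE)

  nm <- 2L  # cytoplasmic, nuclear
  rho <- config$cell_level_correlations$cytoplasmic_nuclear
  ch <- chol(matrix(c(1, rho, rho, 1), 2))
  s_subj <- cv_to_sigma(config$noise$between_subject_cv)
  s_cell <- cv_to_sigma(config$noise$within_subject_cv)
  n_cells <- config$cells_per_subject
  b <- config$baselines

  res <- list()
  for (i in seq_len(n_subjects)) {
    u <- (rnorm(nm) %*% ch)[1, ] * s_subj
    for (st in subtypes) {
      mu <- c(log(b$cytoplasmic_rbfox1 * enr$cytoplasmic_rbfox1[[st]]),
              log(b$nuclear_rbfox1 * enr$nuclear_rbfox1[[st]])) + u
      z <- (matrix(rnorm(n_cells * nm), n_cells) %*% ch) * s_cell
      cyto <- exp(mu[1] + z[, 1])
      nuclear <- exp(mu[2] + z[, 2])
      areas <- draw_cell_areas(config, n_cells)
      body <- (nuclear * areas$nucleus_area + cyto * areas$cytoplasm_area) /
        areas$body_area
      res[[length(res) + 1L]] <- data.frame(
        cell_id = sprintf("%s_%s_c%03d", subjects$subject_id[i], st,
                          seq_len(n_cells)),
        subject_id = subjects$subject_id[i], subtype = st,
        layer = sample(c("L2", "L4"), n_cells, replace = TRUE),
        body_intensity = body, nuclear_intensity = nuclear,
        cytoplasmic_intensity = cyto,
        body_area = areas$body_area, nucleus_area = areas$nucleus_area,
        cytoplasm_area = areas$cytoplasm_area,
        pv_intensity = NA_real_, pv_grain_count = NA_integer_,
        vamp1_grain_count = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, res)
  rownames(cells) <- NULL
  new_cohort_dataset(subjects, cells, config)
}

#' Generate a mixed PVI / non-PV neuron population
#'
#' Emulates the layer-4 sample of Rbfox1-immunoreactive neurons used to
#' train and evaluate the PVI classifier: PV mRNA grain counts are drawn
#' from a high-density distribution for true PVIs and a low-density
#' distribution for non-PV neurons, and Vamp1 grain density carries the
#' configured PVI / non-PV fold.  True labels are retained in
#' \code{true_subtype}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n_cells total number of cells (the study sampled 252).
#' @param pvi_fraction fraction of true PVIs, in (0, 1) (study: 64/252).
#' @param seed integer; defaults to \code{config$seed}.
#' @return data.frame of cells with \code{true_subtype} labels.
#' @export
generate_mixed_population <- function(config, n_cells = 252L,
                                      pvi_fraction = 64 / 252,
                                      seed = config$seed) {
  validate_cohort_config(config)
  if (!(pvi_fraction > 0 && pvi_fraction < 1))
    stop("pvi_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_pvi <- round(n_cells * pvi_fraction)
  is_pvi <- rep(c(TRUE, FALSE), c(n_pvi, n_cells - n_pvi))
  b <- config$baselines
  s_cell <- cv_to_sigma(config$noise$within_subject_cv)

  pv_med <- ifelse(is_pvi, b$pv_grain_density, b$pv_grain_density_nonpv)
  vamp_med <- ifelse(is_pvi, b$vamp1_grain_density,
                     b$vamp1_grain_density / config$pv_vs_nonpv_vamp1_fold)
  areas <- draw_cell_areas(config, n_cells)
  pv_dens <- rlnorm(n_cells, log(pv_med), s_cell)
  vamp_dens <- rlnorm(n_cells, log(vamp_med), s_cell)
  out <- data.frame(
    cell_id = sprintf("M_c%03d", seq_len(n_cells)),
    subject_id = "pooled", subtype = "unknown",
    true_subtype = ifelse(is_pvi, "PVI", "nonPV"), layer = "L4",
    body_area = areas$body_area, nucleus_area = areas$nucleus_area,
    cytoplasm_area = areas$cytoplasm_area,
    pv_grain_count = rnbinom(n_cells, size = config$grain_size,
                             mu = pv_dens * areas$cytoplasm_area),
    vamp1_grain_count = rnbinom(n_cells, size = config$grain_size,
                                mu = vamp_dens * areas$cytoplasm_area),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
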