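#' Compartment masks for one cell
#'
#' Builds the cell-body / nucleus / cytoplasm mask triplet used for
#' compartment quantification.  The cytoplasmic mask is derived by
#' subtracting the nuclear mask from the cell-body mask.
#'
#' @param body_mask,nucleus_mask logical matrices of equal dimension; the
#'   nucleus must be contained in the body.
#' @return object of class \code{compartment_masks} with elements
#'   \code{body}, \code{nucleus}, \code{cytoplasm}.
#' @export
compartment_masks <- function(body_mask, nucleus_mask) {
  if (!identical(dim(body_mask), dim(nucleus_mask)))
    stop("body and nucleus masks must have identical dimensions",
         call. = FALSE)
  body_mask <- body_mask > 0
  nucleus_mask <- nucleus_mask > 0
  if (any(nucleus_mask & !body_mask))
    stop("nucleus mask must be contained in the body mask", call. = FALSE)
  structure(list(body = body_mask, nucleus = nucleus_mask,
                 cytoplasm = body_mask & !nucleus_mask),
            class = "compartment_masks")
}

#' Mean intensities within the cell body, nucleus and cytoplasm
#'
#' Arithmetic mean of the image over each compartment mask.  Cells whose
#' nucleus fills the cell body have no cytoplasmic compartment and are
#' flagged as quantification errors (such cells are excluded, not imputed).
#'
#' @param image numeric matrix of fluorescence intensities.
#' @param masks a \code{\link{compartment_masks}} object.
#' @return named numeric: \code{body_mean}, \code{nuclear_mean},
#'   \code{cytoplasmic_mean}.
#' @export
compartment_intensity <- function(image, masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  if (!identical(dim(image), dim(masks$body)))
    stop("image and masks must have identical dimensions", call. = FALSE)
  if (!any(masks$cytoplasm))
    stop("empty cytoplasm mask (nucleus fills the cell body); ",
         "cell must be excluded", call. = FALSE)
  if (!any(masks$nucleus))
    stop("empty nucleus mask", call. = FALSE)
  c(body_mean = mean(image[masks$body]),
    nuclear_mean = mean(image[masks$nucleus]),
    cytoplasmic_mean = mean(image[masks$cytoplasm]))
}

#' Cytoplasmic-to-nuclear ratio
#'
#' The C/N ratio of compartment mean intensities, the per-cell proxy for
#' the balance between cytoplasmic and nuclear Rbfox1 isoforms.
#'
#' @param cytoplasmic_mean,nuclear_mean compartment means;
#'   \code{nuclear_mean} must be positive.
#' @return numeric ratio.
#' @export
cn_ratio <- function(cytoplasmic_mean, nuclear_mean) {
  if (any(!is.finite(nuclear_mean)) || any(nuclear_mean <= 0))
    stop("C/N ratio undefined: nuclear mean must be positive", call. = FALSE)
  cytoplasmic_mean / nuclear_mean
}

#' Grain density within a compartment
#'
#' mRNA grains per square micrometre of (2-D projected) compartment area.
#'
#' @param count non-negative grain count.
#' @param area compartment area in um^2, positive.
#' @return list with \code{count}, \code{area}, \code{density}.
#' @export
grain_density <- function(count, area) {
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  if (any(count < 0)) stop("grain count must be non-negative", call. = FALSE)
  list(count = count, area = area, density = count / area)
}

#' Fit the two-component PVI classifier on grain densities
#'
#' An unsupervised stand-in for the study's naive Bayes classifier: a
#' two-component Gaussian mixture is fit on log(density + eps) by
#' expectation-maximisation, where eps is half the smallest non-zero
#' density (to admit zero-count cells).  The component with the larger
#' location is labelled PVI.  Because the single feature makes naive Bayes
#' and a Gaussian mixture classifier coincide, the posterior rule is the
#' naive Bayes rule with estimated class priors.
#'
#' @param densities non-negative grain densities (>= 20 cells).
#' @param tol stop when the log-likelihood increase falls below this
#'   (default 1e-8).
#' @param max_iter maximum EM iterations (default 500).
#' @return object of class \code{pvi_classifier}: priors, per-class
#'   location/scale on the log scale, \code{eps}, convergence info.
#' @export
fit_pvi_classifier <- function(densities, tol = 1e-8, max_iter = 500L) {
  if (length(densities) < 20)
    stop("need at least 20 cells to fit the classifier", call. = FALSE)
  if (any(densities < 0) || any(!is.finite(densities)))
    stop("densities must be finite and non-negative", call. = FALSE)
  nz <- densities[densities > 0]
  if (!length(nz) || stats::sd(densities) == 0)
    stop("cannot fit classifier: densities have zero variance", call. = FALSE)
  eps <- min(nz) / 2
  x <- log(densities + eps)
  if (stats::sd(x) < 1e-12)
    stop("cannot fit classifier: log densities have zero variance",
         call. = FALSE)

  # deterministic initialisation: split at the median
  lo <- x <= stats::median(x)
  mu <- c(mean(x[lo]), mean(x[!lo]))
  sg <- pmax(c(stats::sd(x[lo]), stats::sd(x[!lo])), 1e-3)
  pi1 <- 0.5
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(x, mu[1], sg[1])
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot)))
      stop("EM failure: zero mixture density (component collapse)",
           call. = FALSE)
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    n1 <- sum(g)
    pi1 <- n1 / length(x)
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / (length(x) - n1))
    sg <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                 sum((1 - g) * (x - mu[2])^2) / (length(x) - n1)))
    if (any(sg < 1e-8))
      stop("EM failure: a component collapsed to zero variance ",
           "(locations ", paste(signif(mu, 4), collapse = ", "), ")",
           call. = FALSE)
  }
  if (!converged)
    stop("EM did not converge in ", max_iter, " iterations ",
         "(last log-likelihood ", signif(ll, 8), ")", call. = FALSE)
  ord <- order(mu)  # component 2 = larger location = PVI
  structure(list(
    priors = c(nonPV = if (ord[1] == 1) pi1 else 1 - pi1,
               PVI = if (ord[2] == 1) pi1 else 1 - pi1),
    location = c(nonPV = mu[ord[1]], PVI = mu[ord[2]]),
    scale = c(nonPV = sg[ord[1]], PVI = sg[ord[2]]),
    eps = eps, log_likelihood = ll, iterations = it,
    threshold = 0.5), class = "pvi_classifier")
}

#' @export
print.pvi_classifier <- function(x, ...) {
  cat("PVI classifier (two-component Gaussian mixture on log grain density)\n")
  cat(sprintf("  priors: PVI %.3f / nonPV %.3f\n", x$priors["PVI"],
              x$priors["nonPV"]))
  cat(sprintf("  log-density locations: PVI %.3f / nonPV %.3f\n",
              x$location["PVI"], x$location["nonPV"]))
  invisible(x)
}

#' Classify cells as PVIs or non-PV neurons
#'
#' Posterior probability of the PVI component at each cell's PV grain
#' density; label = PVI when the posterior exceeds 0.5, with ties broken to
#' nonPV (conservative: avoids inflating PVI counts).
#'
#' @param classifier a fitted \code{\link{fit_pvi_classifier}}.
#' @param cells data.frame with \code{pv_grain_count} and
#'   \code{cytoplasm_area} columns, or a numeric vector of densities.
#' @return data.frame with \code{density}, \code{posterior_pvi},
#'   \code{label}.
#' @export
classify_cells <- function(classifier, cells) {
  stopifnot(inherits(classifier, "pvi_classifier"))
  dens <- if (is.numeric(cells)) cells
          else cells$pv_grain_count / cells$cytoplasm_area
  x <- log(dens + classifier$eps)
  d_pvi <- classifier$priors["PVI"] *
    stats::dnorm(x, classifier$location["PVI"], classifier$scale["PVI"])
  d_non <- classifier$priors["nonPV"] *
    stats::dnorm(x, classifier$location["nonPV"], classifier$scale["nonPV"])
  post <- as.numeric(d_pvi / (d_pvi + d_non))
  data.frame(density = dens, posterior_pvi = post,
             label = ifelse(post > classifier$threshold, "PVI", "nonPV"),
             stringsAsFactors = FALSE)
}

#' Select the pairs with the greatest within-pair differences
#'
#' Ranks subject pairs by the within-pair difference of subject-mean
#' values (comparison minus schizophrenia, descending) and returns the top
#' \code{k} pair ids.  Ties break deterministically by pair id.  This is
#' the rule used to carry the most-affected pairs into the fresh-frozen
#' assay.
#'
#' @param dataset a \code{cohort_dataset}.
#' @param measure a cell-level measure column, or one of
#'   \code{"pv_grain_density"}, \code{"vamp1_grain_density"}.
#' @param k number of pairs to keep.
#' @return integer vector of pair ids (length \code{k}).
#' @export
select_extreme_pairs <- function(dataset, measure = "cytoplasmic_intensity",
                                 k) {
  sm <- subject_means(dataset, measure)
  sm <- merge(sm, dataset$subjects[, c("subject_id", "pair_id", "diagnosis")],
              by = "subject_id")
  wide <- stats::reshape(sm[, c("pair_id", "diagnosis", "value")],
                         idvar = "pair_id", timevar = "diagnosis",
                         direction = "wide")
  if (k > nrow(wide)) stop("k exceeds the number of pairs", call. = FALSE)
  wide$diff <- wide$value.comparison - wide$value.schizophrenia
  ord <- order(-wide$diff, wide$pair_id)
  sort(wide$pair_id[ord][seq_len(k)])
}

#' Subject-level means of a cell measure
#'
#' Aggregates a per-cell measure to one value per subject (the mean over
#' that subject's sampled PVIs), the unit of analysis for the
#' diagnosis-effect models.  Grain-density measures are computed per cell
#' as count/area before averaging.
#'
#' @param dataset a \code{cohort_dataset}.
#' @param measure cell column name, or \code{"pv_grain_density"} /
#'   \code{"vamp1_grain_density"} / \code{"cn_ratio"}.
#' @return data.frame with \code{subject_id}, \code{value}.
#' @export
subject_means <- function(dataset, measure) {
  cells <- dataset$cells
  v <- switch(measure,
    pv_grain_density = cells$pv_grain_count / cells$cytoplasm_area,
    vamp1_grain_density = cells$vamp1_grain_count / cells$cytoplasm_area,
    cn_ratio = cn_ratio(cells$cytoplasmic_intensity,
                        cells$nuclear_intensity),
    {
      if (!measure %in% names(cells))
        stop("unknown measure: ", measure, call. = FALSE)
      cells[[measure]]
    })
  if (all(is.na(v)))
    stop("measure ", measure, " is not available in this assay",
         call. = FALSE)
  agg <- stats::aggregate(v, list(subject_id = cells$subject_id),
                          mean, na.rm = TRUE)
  names(agg)[2] <- "value"
  agg
}
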