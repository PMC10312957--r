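#' Trial-averaged metrics for one network configuration
#'
#' Runs \code{n_trials} independent trials and averages peak gamma power,
#' population firing rates and the interspike-interval coefficient of
#' variation (CV of the ISI) of pyramidal neurons.
#'
#' Trial \code{t} uses seed \code{trial_seed(master_seed, t)} regardless of
#' the parameter values under study, so metric curves across a sweep share
#' their trial noise (variance reduction for curve shape).
#'
#' @param cfg a \code{\link{network_config}}.
#' @param n_trials number of trials.
#' @param master_seed integer master seed.
#' @return one-row data.frame of trial means and SEMs.
#' @export
trial_average <- function(cfg, n_trials = 20L, master_seed = 1L) {
  m <- vapply(seq_len(n_trials), function(t) {
    sim <- simulate_trial(cfg, seed = trial_seed(master_seed, t))
    sp <- peak_gamma_power(sim)
    r <- firing_rates(sim)
    c(gamma_power = sp$peak_gamma_power, peak_frequency = sp$peak_frequency,
      rate_pyramidal = unname(r["rate_pyramidal"]),
      rate_pvi = unname(r["rate_pvi"]), cv_isi = cv_isi(sim)$cv_isi)
  }, numeric(5))
  mu <- rowMeans(m)
  sem <- apply(m, 1, stats::sd) / sqrt(n_trials)
  out <- as.data.frame(as.list(mu))
  names(sem) <- paste0(names(mu), "_sem")
  cbind(out, as.data.frame(as.list(sem)), n_trials = n_trials)
}

# deterministic per-trial seed below 2^31, independent of the swept parameter
trial_seed <- function(master_seed, t) {
  as.integer((as.numeric(master_seed) * 7919 + t * 104729) %% 2147483629)
}

#' Sweep the GABA release probability of PVI-to-pyramidal synapses
#'
#' For each release-probability value, averages peak gamma power, firing
#' rates and CV of the ISI over \code{n_trials} trials (same trial seeds at
#' every value).
#'
#' @param cfg base \code{\link{network_config}} (its \code{rp_ie} is
#'   overridden).
#' @param rp_values release probabilities to simulate, each in \[0, 1\].
#' @param n_trials trials per value.
#' @param master_seed integer master seed.
#' @return An object of class \code{sweep_result}: data.frame with one row
#'   per RP value (columns \code{rp}, \code{gamma_power}, \code{rate_*},
#'   \code{cv_isi} and their SEMs).
#' @export
rp_sweep <- function(cfg, rp_values = seq(0.5, 1, by = 0.05),
                     n_trials = 20L, master_seed = 1L) {
  if (length(rp_values) < 2) stop("need at least two RP values", call. = FALSE)
  if (any(rp_values < 0 | rp_values > 1))
    stop("rp values must lie in [0, 1]", call. = FALSE)
  rows <- lapply(rp_values, function(rp) {
    cfg_rp <- cfg
    cfg_rp$rp_ie <- rp
    cbind(rp = rp, trial_average(cfg_rp, n_trials, master_seed))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rp), ]
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "parameter") <- "rp_ie"
  attr(out, "master_seed") <- master_seed
  out
}

#' Plateau (nadir) onset of a sweep curve
#'
#' Finds the largest parameter value \code{v} such that every curve value at
#' parameters \code{<= v} lies within \code{tolerance * (max - min)} of the
#' curve minimum.  Used to locate the stable nadir of the gamma-power versus
#' release-probability curve.
#'
#' @param sweep a \code{\link{rp_sweep}} result, or a data.frame with the
#'   parameter in its first column and a \code{gamma_power} column.
#' @param tolerance fraction of the curve range (default 0.05).
#' @param value column to analyse (default \code{"gamma_power"}).
#' @return list with \code{onset} (parameter value), \code{tolerance},
#'   \code{degenerate} (TRUE when the curve is flat or monotone without a
#'   plateau, in which case the extreme grid value is returned, flagged).
#' @export
detect_nadir <- function(sweep, tolerance = 0.05, value = "gamma_power") {
  par <- sweep[[1]]
  y <- sweep[[value]]
  if (is.unsorted(par)) stop("sweep must be sorted by parameter", call. = FALSE)
  rng <- max(y) - min(y)
  if (rng == 0)
    return(list(onset = max(par), tolerance = tolerance, degenerate = TRUE))
  near_min <- y <= min(y) + tolerance * rng
  # largest v with all values at parameters <= v near the minimum
  ok <- cumprod(near_min) > 0
  if (!any(ok))
    return(list(onset = min(par), tolerance = tolerance, degenerate = TRUE))
  onset <- max(par[ok])
  # a plateau that never extends beyond the smallest swept value indicates a
  # monotone curve without a stable nadir
  list(onset = onset, tolerance = tolerance,
       degenerate = onset == min(par))
}

#' Joint versus additive effect of inhibitory strength and release
#' probability
#'
#' Scales the PVI-to-pyramidal conductance \code{G_IE} and release
#' probability \code{RP_IE} down from the baseline that maximises gamma
#' power (100% weight = \code{G_IE} of the base config, \code{rp_ie = 1}).
#' For each weight \code{w} it computes the gamma-power reduction from
#' lowering G alone, RP alone, their sum (the additive expectation), and
#' from lowering both together.  The crossover is the largest percentage
#' lowering up to which the joint reduction exceeds the additive
#' expectation at every sampled weight.
#'
#' @param cfg base \code{\link{network_config}}; its \code{G_IE} and
#'   \code{rp_ie = 1} define the 100% weights.
#' @param weights percentage grid, must include 100 (default 100 down to 70
#'   by 2.5).
#' @param n_trials trials per grid point.
#' @param master_seed integer master seed.
#' @return An object of class \code{synergy_result}: list with
#'   \code{curves} (data.frame: weight, reduction_g, reduction_rp,
#'   expected, joint), \code{baseline_power}, \code{crossover_pct} (largest
#'   lowering such that the joint reduction exceeds the expectation at
#'   every sampled weight up to that point) and
#'   \code{superadditive_max_pct} (largest lowering at which the joint
#'   reduction exceeds the expectation, ignoring earlier gaps; robust to
#'   trial noise near the baseline where both reductions are ~0).
#' @export
synergy_analysis <- function(cfg, weights = seq(100, 70, by = -2.5),
                             n_trials = 20L, master_seed = 1L) {
  if (!any(weights == 100))
    stop("weight grid must include the 100% baseline", call. = FALSE)
  if (any(weights <= 0 | weights > 100))
    stop("weights must lie in (0, 100]%", call. = FALSE)
  weights <- sort(unique(weights), decreasing = TRUE)
  g_base <- cfg$synapses$G_IE
  cfg$rp_ie <- 1

  power_at <- function(g, rp) {
    c2 <- cfg
    c2$synapses$G_IE <- g
    c2$rp_ie <- rp
    trial_average(c2, n_trials, master_seed)$gamma_power
  }
  p0 <- power_at(g_base, 1)
  rows <- lapply(weights, function(wpct) {
    w <- wpct / 100
    if (wpct == 100)
      return(data.frame(weight = 100, reduction_g = 0, reduction_rp = 0,
                        expected = 0, joint = 0))
    rg <- p0 - power_at(g_base * w, 1)
    rr <- p0 - power_at(g_base, w)
    rj <- p0 - power_at(g_base * w, w)
    data.frame(weight = wpct, reduction_g = rg, reduction_rp = rr,
               expected = rg + rr, joint = rj)
  })
  curves <- do.call(rbind, rows)
  cx <- synergy_crossover(curves)
  out <- list(curves = curves, baseline_power = p0,
              crossover_pct = cx$crossover_pct,
              superadditive_max_pct = cx$superadditive_max_pct,
              n_trials = n_trials, master_seed = master_seed)
  class(out) <- "synergy_result"
  out
}

#' Crossover statistics of synergy curves
#'
#' \code{crossover_pct} is the largest percentage lowering such that the
#' joint reduction strictly exceeds the additive expectation at every
#' sampled weight up to that point; \code{superadditive_max_pct} is the
#' largest lowering at which the joint reduction exceeds the expectation,
#' tolerant of gaps near the baseline where both reductions are within
#' trial noise of zero.
#'
#' @param curves data.frame with columns \code{weight} (percent, including
#'   100), \code{expected}, \code{joint}.
#' @return list with \code{crossover_pct} and \code{superadditive_max_pct}.
#' @export
synergy_crossover <- function(curves) {
  sub <- curves[curves$weight < 100, ]
  sub <- sub[order(sub$weight, decreasing = TRUE), ]
  super <- sub$joint > sub$expected
  run <- cumprod(super) > 0
  list(crossover_pct = if (any(run)) 100 - min(sub$weight[run]) else 0,
       superadditive_max_pct =
         if (any(super)) 100 - min(sub$weight[super]) else 0)
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("G_IE x RP_IE synergy: joint reduction exceeds the additive",
      "expectation up to", x$crossover_pct, "% lowering\n")
  print(x$curves, digits = 4)
  invisible(x)
}

#' Write sweep or synergy curves as CSV with a JSON summary
#'
#' @param x a \code{sweep_result} or \code{synergy_result}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_experiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "sweep_result")) {
    utils::write.csv(as.data.frame(x), file.path(dir, "sweep.csv"),
                     row.names = FALSE)
    nad <- detect_nadir(x)
    jsonlite::write_json(
      list(parameter = attr(x, "parameter"),
           argmax = x[[1]][which.max(x$gamma_power)],
           nadir_onset = nad$onset, nadir_degenerate = nad$degenerate),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "synergy_result")) {
    utils::write.csv(x$curves, file.path(dir, "synergy.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(baseline_power = x$baseline_power,
           crossover_pct = x$crossover_pct),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  } else stop("unsupported object", call. = FALSE)
  invisible(dir)
}
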