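#' Configuration for the pyramidal/PVI gamma network
#'
#' Builds the full parameter set for the quadratic integrate-and-fire (QIF)
#' network of regular-spiking pyramidal neurons and fast-spiking
#' parvalbumin-expressing interneurons (PVIs).  Connectivity is all-to-all
#' (self-connections excluded).  Excitatory synapses carry AMPA and NMDA
#' conductances, inhibitory synapses carry GABA conductance, and the
#' PVI-to-pyramidal synapses are subject to a Bernoulli release probability
#' \code{rp_ie}: each presynaptic PVI spike activates the GABA gate of each
#' pyramidal target independently with probability \code{rp_ie}.
#'
#' Conductances are in model units; \code{G_IE = 0.7} with \code{rp_ie = 1}
#' is the baseline (100% parameter weight) at which the default network
#' produces maximal gamma-band power.  Membrane dynamics follow
#' \deqn{dv/dt = (v - v_r)(v - v_t) / (\tau_m \Delta v) + I_{syn} + I_{appl}}
#' with a spike emitted when \eqn{v} reaches \code{v_peak} followed by reset
#' to \code{v_reset} and an absolute refractory period.
#'
#' @param n_pyramidal,n_pvi population sizes (defaults 80 and 20).
#' @param rp_ie release probability of PVI-to-pyramidal GABA synapses, in
#'   \[0, 1\].
#' @param synapses named list of synaptic parameters; see Details.  Partial
#'   lists override the defaults field-by-field.
#' @param pyr,pvi named lists of neuron parameters (\code{tau_m},
#'   \code{v_rest}, \code{v_thresh}, \code{v_peak}, \code{v_reset},
#'   \code{t_ref}, all ms or mV).  Partial lists override defaults.
#' @param drive named list: \code{i_appl_mean}, \code{i_appl_spread}
#'   (heterogeneity SD across pyramidal cells), \code{noise_sd_pyr},
#'   \code{noise_sd_pvi} (white-noise SD, mV/sqrt(ms)), \code{i_appl_pvi}.
#' @param dt integration step (ms).
#' @param duration trial length (ms).
#' @param transient_discard initial interval excluded from analysis (ms).
#' @param record_every record the summed excitatory current every this many
#'   integration steps.
#' @param release_mode \code{"per_target"} (independent Bernoulli draw per
#'   postsynaptic pyramidal cell, the default) or \code{"global"} (one draw
#'   per presynaptic spike shared by all targets).
#' @param psd_currents \code{"ampa_nmda"} (default) or \code{"ampa"}: which
#'   excitatory currents enter the summed trace used for spectral analysis.
#'
#' @return An object of class \code{network_config} (a named list).
#' @export
network_config <- function(n_pyramidal = 80L, n_pvi = 20L,
                           rp_ie = 1,
                           synapses = list(),
                           pyr = list(), pvi = list(),
                           drive = list(),
                           dt = 0.05, duration = 2000, transient_discard = 500,
                           record_every = 4L,
                           release_mode = c("per_target", "global"),
                           psd_currents = c("ampa_nmda", "ampa")) {
  release_mode <- match.arg(release_mode)
  psd_currents <- match.arg(psd_currents)

  syn_def <- list(
    G_EE = 0.2, G_NE = 0.01, G_EI = 1.5, G_NI = 0.01,
    G_IE = 0.7, G_II = 0.3, gain_ie = 1.15,
    tau_rise_ampa = 0.5, tau_decay_ampa = 2,
    tau_rise_nmda = 2, tau_decay_nmda = 100,
    tau_rise_gaba = 0.5, tau_decay_gaba = 8,
    E_exc = 0, E_inh = -70, mg_mM = 1)
  pyr_def <- list(tau_m = 10, v_rest = -65, v_thresh = -50,
                  v_peak = 25, v_reset = -65, t_ref = 3)
  pvi_def <- list(tau_m = 10, v_rest = -65, v_thresh = -50,
                  v_peak = 25, v_reset = -65, t_ref = 1)
  drive_def <- list(i_appl_mean = 3, i_appl_spread = 0.3,
                    noise_sd_pyr = 2.5, noise_sd_pvi = 0.5, i_appl_pvi = 0)

  cfg <- list(
    n_pyramidal = as.integer(n_pyramidal), n_pvi = as.integer(n_pvi),
    rp_ie = rp_ie,
    synapses = utils::modifyList(syn_def, as.list(synapses)),
    pyr = utils::modifyList(pyr_def, as.list(pyr)),
    pvi = utils::modifyList(pvi_def, as.list(pvi)),
    drive = utils::modifyList(drive_def, as.list(drive)),
    dt = dt, duration = duration, transient_discard = transient_discard,
    record_every = as.integer(record_every),
    release_mode = release_mode, psd_currents = psd_currents)
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

validate_network_config <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  if (cfg$n_pyramidal < 1L || cfg$n_pvi < 0L)
    stop("population sizes must be positive", call. = FALSE)
  if (!is.finite(cfg$rp_ie) || cfg$rp_ie < 0 || cfg$rp_ie > 1)
    stop("rp_ie must lie in [0, 1]", call. = FALSE)
  if (cfg$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (cfg$duration <= cfg$transient_discard)
    stop("duration must exceed transient_discard", call. = FALSE)
  s <- cfg$synapses
  gs <- unlist(s[c("G_EE", "G_NE", "G_EI", "G_NI", "G_IE", "G_II")])
  if (any(gs < 0)) stop("conductances must be non-negative", call. = FALSE)
  for (rec in c("ampa", "nmda", "gaba")) {
    r <- s[[paste0("tau_rise_", rec)]]
    d <- s[[paste0("tau_decay_", rec)]]
    if (!(d > r && r > 0))
      stop("synaptic time constants must satisfy decay > rise > 0 (",
           rec, ")", call. = FALSE)
  }
  for (pop in c("pyr", "pvi")) {
    p <- cfg[[pop]]
    if (!(p$v_reset < p$v_thresh && p$v_thresh < p$v_peak))
      stop("need v_reset < v_thresh < v_peak (", pop, ")", call. = FALSE)
    if (p$tau_m <= 0) stop("tau_m must be positive (", pop, ")", call. = FALSE)
  }
  invisible(cfg)
}

#' Read or write a network configuration as JSON
#'
#' Field names mirror \code{\link{network_config}}; conductances use the
#' conventional symbols (\code{G_EE}, \code{G_IE}, ...) and the release
#' probability is stored as \code{rp_ie}.
#'
#' @param cfg a \code{network_config}.
#' @param path file path.
#' @return \code{read_network_config} returns a \code{network_config}.
#' @export
write_network_config <- function(cfg, path) {
  validate_network_config(cfg)
  x <- unclass(cfg)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(network_config, x)
}
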