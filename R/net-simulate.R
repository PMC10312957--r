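#' Simulate one trial of the pyramidal/PVI network
#'
#' Integrates the QIF network with Euler-Maruyama at \code{cfg$dt} for
#' \code{cfg$duration} ms, discards the initial transient, and returns spike
#' trains together with the summed excitatory synaptic current into the
#' pyramidal population (the trace used for spectral analysis).
#'
#' Randomness is fully determined by \code{seed}: one master seed spawns
#' independent streams for initial conditions, drive noise and Bernoulli
#' release draws, so simulations at different \code{rp_ie} but the same seed
#' share their drive noise.
#'
#' @param cfg a \code{\link{network_config}}.
#' @param seed integer master seed for the trial.
#' @return An object of class \code{sim_result}: a list with
#'   \describe{
#'     \item{spikes}{data.frame with columns \code{neuron} (1..n, pyramidal
#'       first), \code{time} (ms, post-transient), \code{population}.}
#'     \item{i_exc}{summed excitatory synaptic current into pyramidal cells
#'       (AMPA+NMDA or AMPA-only per \code{cfg$psd_currents}).}
#'     \item{rec_time, rec_dt}{sample times (ms) and sampling step (ms).}
#'     \item{min_gate}{smallest synaptic gate value encountered (diagnostic;
#'       must be >= 0).}
#'     \item{config, seed}{echo of the inputs.}
#'   }
#' @export
simulate_trial <- function(cfg, seed = 1L) {
  validate_network_config(cfg)
  seed <- as.integer(seed)
  raw <- qif_network_cpp(unclass(cfg), seed)
  pop <- ifelse(raw$spike_neuron <= cfg$n_pyramidal, "pyramidal", "pvi")
  i_exc <- if (cfg$psd_currents == "ampa") raw$i_exc_ampa else raw$i_exc
  out <- list(
    spikes = data.frame(neuron = raw$spike_neuron, time = raw$spike_time,
                        population = pop, stringsAsFactors = FALSE),
    i_exc = as.numeric(i_exc),
    rec_time = as.numeric(raw$rec_time),
    rec_dt = raw$rec_dt,
    min_gate = raw$min_gate,
    config = cfg, seed = seed)
  class(out) <- "sim_result"
  out
}

#' Bernoulli thinning of presynaptic spike events
#'
#' Reference implementation of the stochastic-release rule applied inside
#' the simulator: each (presynaptic spike, postsynaptic target) pair is
#' transmitted independently with probability \code{rp}.  Exposed mainly so
#' the release rule can be tested in isolation.
#'
#' @param spike_times numeric vector of presynaptic spike times.
#' @param n_targets number of postsynaptic targets per spike.
#' @param rp release probability in \[0, 1\].
#' @return data.frame with columns \code{time} and \code{target} listing the
#'   transmitted events.
#' @export
bernoulli_release <- function(spike_times, n_targets, rp) {
  if (!is.finite(rp) || rp < 0 || rp > 1)
    stop("release probability must lie in [0, 1]", call. = FALSE)
  n_ev <- length(spike_times) * n_targets
  keep <- stats::runif(n_ev) < rp
  grid <- expand.grid(target = seq_len(n_targets), time = spike_times)
  out <- grid[keep, c("time", "target")]
  rownames(out) <- NULL
  out
}

#' Export spike trains as a two-column table
#'
#' @param sim a \code{sim_result}.
#' @param path CSV path.
#' @export
write_spikes <- function(sim, path) {
  utils::write.csv(sim$spikes[, c("neuron", "time")], path, row.names = FALSE)
  invisible(path)
}

#' @export
print.sim_result <- function(x, ...) {
  n_sp <- nrow(x$spikes)
  cat("QIF network trial: ", x$config$n_pyramidal, "E/", x$config$n_pvi,
      "I, rp_ie = ", x$config$rp_ie, ", ", n_sp, " spikes in (",
      x$config$transient_discard, ", ", x$config$duration, "] ms\n", sep = "")
  invisible(x)
}

#' Spike times of one population from a trial
#'
#' @param sim a \code{sim_result}.
#' @param population \code{"pyramidal"} or \code{"pvi"}.
#' @return list of numeric vectors of spike times, one per neuron (all
#'   neurons of the population, including silent ones).
#' @export
spike_trains <- function(sim, population = c("pyramidal", "pvi")) {
  population <- match.arg(population)
  cfg <- sim$config
  ids <- if (population == "pyramidal") seq_len(cfg$n_pyramidal)
         else cfg$n_pyramidal + seq_len(cfg$n_pvi)
  sp <- sim$spikes
  lapply(ids, function(i) sort(sp$time[sp$neuron == i]))
}
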