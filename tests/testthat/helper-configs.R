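# Small configurations used across tests to keep runtimes sensible.

# a fast network: fewer neurons, shorter trials; still a functioning E/I loop
tiny_net <- function(...) {
  network_config(n_pyramidal = 20L, n_pvi = 5L,
                 duration = 700, transient_discard = 200,
                 record_every = 8L, ...)
}

# a single deterministic QIF neuron with constant drive and no synapses
lone_qif <- function(i_appl, dt = 0.005, t_ref = 3, duration = 1000) {
  network_config(
    n_pyramidal = 1L, n_pvi = 0L, dt = dt,
    duration = duration, transient_discard = 0.5,
    pyr = list(tau_m = 10, t_ref = t_ref),
    synapses = list(G_EE = 0, G_NE = 0, G_EI = 0, G_NI = 0,
                    G_IE = 0, G_II = 0),
    drive = list(i_appl_mean = i_appl, i_appl_spread = 0,
                 noise_sd_pyr = 0, noise_sd_pvi = 0, i_appl_pvi = 0))
}

# quadrature oracle for the QIF interspike period (reset -> peak) plus the
# absolute refractory period
qif_period_oracle <- function(cfg) {
  p <- cfg$pyr
  i <- cfg$drive$i_appl_mean
  f <- function(v) 1 / ((v - p$v_rest) * (v - p$v_thresh) /
                          (p$tau_m * (p$v_thresh - p$v_rest)) + i)
  stats::integrate(f, p$v_reset, p$v_peak, rel.tol = 1e-10)$value + p$t_ref
}

# small cohort for fast statistical tests
small_cohort_config <- function(...) {
  cohort_config(n_pairs = 8L, cells_per_subject = 6L, ...)
}
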