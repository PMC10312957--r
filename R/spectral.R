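#' Welch power spectral density of a current trace
#'
#' Mean-subtracted, Hann-tapered, 50%-overlapping segments; one-sided
#' density scaled so that the integral of the PSD over frequency equals the
#' variance of the trace (Parseval).
#'
#' @param x numeric trace (model units).
#' @param dt sampling step in ms.
#' @param segment_ms segment length in ms (default 500).
#' @return list with \code{freq} (Hz) and \code{psd} (units^2/Hz).
#' @export
welch_psd <- function(x, dt, segment_ms = 500) {
  fs <- 1000 / dt                       # Hz
  nseg <- max(2L, as.integer(round(segment_ms / dt)))
  if (length(x) < nseg)
    stop("trace shorter than one Welch segment", call. = FALSE)
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / nseg))   # Hann
  u <- sum(w^2)
  nfreq <- nseg %/% 2L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / (fs * u)
    half <- sp[2:(nfreq + 1L)]
    # double the interior bins of the one-sided spectrum
    if (nseg %% 2L == 0L) half[-nfreq] <- 2 * half[-nfreq]
    else half <- 2 * half
    acc <- acc + half
  }
  list(freq = (1:nfreq) * fs / nseg, psd = acc / length(starts))
}

#' Peak gamma power of a summed excitatory current trace
#'
#' Computes the Welch PSD and extracts the maximum density (and its
#' frequency) within a band, by default the gamma band 30-80 Hz.  With
#' \code{mode = "integral"} the band-integrated power is reported instead of
#' the band maximum.
#'
#' @param x numeric trace, or a \code{sim_result} (its \code{i_exc} trace is
#'   used).
#' @param dt sampling step in ms (taken from the \code{sim_result} if one is
#'   supplied).
#' @param band numeric length-2, Hz.
#' @param segment_ms Welch segment length, ms.
#' @param mode \code{"peak"} (default) or \code{"integral"}.
#' @return An object of class \code{spectral_result}: list with
#'   \code{freq}, \code{psd}, \code{band}, \code{peak_gamma_power},
#'   \code{peak_frequency}.
#' @export
peak_gamma_power <- function(x, dt = NULL, band = c(30, 80),
                             segment_ms = 500, mode = c("peak", "integral")) {
  mode <- match.arg(mode)
  if (inherits(x, "sim_result")) {
    dt <- x$rec_dt
    x <- x$i_exc
  }
  if (is.null(dt)) stop("dt required for a bare trace", call. = FALSE)
  nyq <- 1000 / dt / 2
  if (band[2] > nyq || band[1] <= 0 || band[1] >= band[2])
    stop("band must lie within (0, Nyquist = ", nyq, " Hz)", call. = FALSE)
  ps <- welch_psd(x, dt, segment_ms)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  if (!any(sel)) stop("no frequency bins inside band", call. = FALSE)
  pk <- if (mode == "peak") max(ps$psd[sel])
        else sum(ps$psd[sel]) * (ps$freq[2] - ps$freq[1])
  out <- list(freq = ps$freq, psd = ps$psd, band = band,
              peak_gamma_power = pk,
              peak_frequency = ps$freq[sel][which.max(ps$psd[sel])],
              mode = mode)
  class(out) <- "spectral_result"
  out
}

#' Coefficient of variation of interspike intervals
#'
#' Per-neuron CV = sample SD of the ISIs (n-1 denominator) divided by the
#' mean ISI; the returned value is the mean over neurons with at least three
#' spikes.  Neurons with fewer spikes are excluded and counted.
#'
#' @param trains list of numeric spike-time vectors (one per neuron), or a
#'   \code{sim_result} (pyramidal population used).
#' @return list with \code{cv_isi} (NA if no neuron qualifies),
#'   \code{n_included}, \code{n_excluded}, \code{per_neuron}.
#' @export
cv_isi <- function(trains) {
  if (inherits(trains, "sim_result")) trains <- spike_trains(trains, "pyramidal")
  per <- vapply(trains, function(tt) {
    if (length(tt) < 3) return(NA_real_)
    isi <- diff(sort(tt))
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  ok <- !is.na(per)
  list(cv_isi = if (any(ok)) mean(per[ok]) else NA_real_,
       n_included = sum(ok), n_excluded = sum(!ok), per_neuron = per)
}

#' Population firing rates of a trial
#'
#' Mean spikes per second per neuron over the post-transient analysis
#' window, for the pyramidal and PVI populations.
#'
#' @param sim a \code{sim_result}.
#' @return named numeric: \code{rate_pyramidal}, \code{rate_pvi} (spikes/s).
#' @export
firing_rates <- function(sim) {
  cfg <- sim$config
  win_s <- (cfg$duration - cfg$transient_discard) / 1000
  sp <- sim$spikes
  c(rate_pyramidal = sum(sp$population == "pyramidal") /
      (cfg$n_pyramidal * win_s),
    rate_pvi = if (cfg$n_pvi > 0)
      sum(sp$population == "pvi") / (cfg$n_pvi * win_s) else NA_real_)
}

#' @export
print.spectral_result <- function(x, ...) {
  cat("Welch PSD: peak ", format(x$peak_gamma_power, digits = 4),
      " at ", x$peak_frequency, " Hz in band [", x$band[1], ", ",
      x$band[2], "] Hz (", x$mode, ")\n", sep = "")
  invisible(x)
}
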