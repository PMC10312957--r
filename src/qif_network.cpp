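// Quadratic integrate-and-fire network of pyramidal cells and fast-spiking
// PVIs with conductance-based AMPA/NMDA/GABA synapses, all-to-all coupling
// (self-connections excluded) and Bernoulli release probability on the
// PVI->pyramidal GABA synapses.  Euler-Maruyama integration.
//
// Three independent RNG streams (initial conditions, drive noise, release
// draws) are derived from one seed so that release-probability comparisons
// at a fixed seed share drive noise.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

inline double num(const List& cfg, const char* name) {
  return as<double>(cfg[name]);
}

// splitmix64 step, used to derive stream seeds from the master seed
inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct PopParams {
  double tau, vr, vt, vpeak, vreset, tref, dv;
};

PopParams pop_params(const List& p) {
  PopParams q;
  q.tau = as<double>(p["tau_m"]);
  q.vr = as<double>(p["v_rest"]);
  q.vt = as<double>(p["v_thresh"]);
  q.vpeak = as<double>(p["v_peak"]);
  q.vreset = as<double>(p["v_reset"]);
  q.tref = as<double>(p["t_ref"]);
  q.dv = q.vt - q.vr;
  return q;
}

}  // namespace

// [[Rcpp::export]]
List qif_network_cpp(List cfg, int seed) {
  const int n_e = as<int>(cfg["n_pyramidal"]);
  const int n_i = as<int>(cfg["n_pvi"]);
  const double dt = num(cfg, "dt");
  const double duration = num(cfg, "duration");
  const double transient = num(cfg, "transient_discard");
  const int record_every = as<int>(cfg["record_every"]);

  const PopParams pe = pop_params(cfg["pyr"]);
  const PopParams pi = pop_params(cfg["pvi"]);

  const List syn = cfg["synapses"];
  const double g_ee = num(syn, "G_EE"), g_ne = num(syn, "G_NE");
  const double g_ei = num(syn, "G_EI"), g_ni = num(syn, "G_NI");
  const double g_ie = num(syn, "G_IE") * num(syn, "gain_ie");
  const double g_ii = num(syn, "G_II");
  const double tr_a = num(syn, "tau_rise_ampa"), td_a = num(syn, "tau_decay_ampa");
  const double tr_n = num(syn, "tau_rise_nmda"), td_n = num(syn, "tau_decay_nmda");
  const double tr_g = num(syn, "tau_rise_gaba"), td_g = num(syn, "tau_decay_gaba");
  const double e_exc = num(syn, "E_exc"), e_inh = num(syn, "E_inh");
  const double mg = num(syn, "mg_mM");

  const double rp = num(cfg, "rp_ie");
  const bool per_target =
      as<std::string>(cfg["release_mode"]) == "per_target";

  const List drive = cfg["drive"];
  const double i_mean = num(drive, "i_appl_mean");
  const double i_spread = num(drive, "i_appl_spread");
  const double noise_e = num(drive, "noise_sd_pyr");
  const double noise_i = num(drive, "noise_sd_pvi");
  const double i_pvi = num(drive, "i_appl_pvi");

  if (rp < 0.0 || rp > 1.0) stop("rp_ie must lie in [0, 1]");
  if (dt <= 0.0) stop("dt must be positive");
  if (duration <= transient) stop("duration must exceed transient_discard");

  const int n_steps = static_cast<int>(std::round(duration / dt));
  const int step_trans = static_cast<int>(std::round(transient / dt));

  std::mt19937_64 rng_init(mix64(static_cast<uint64_t>(seed) * 3ULL + 1ULL));
  std::mt19937_64 rng_noise(mix64(static_cast<uint64_t>(seed) * 3ULL + 2ULL));
  std::mt19937_64 rng_rel(mix64(static_cast<uint64_t>(seed) * 3ULL + 3ULL));
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> v_e(n_e), v_i(n_i), iappl(n_e);
  std::vector<double> ref_e(n_e, -1.0), ref_i(n_i, -1.0);
  for (int i = 0; i < n_e; ++i) {
    v_e[i] = pe.vreset + unif(rng_init) * (pe.vt - pe.vreset);
    iappl[i] = i_mean + i_spread * gauss(rng_init);
  }
  for (int j = 0; j < n_i; ++j)
    v_i[j] = pi.vreset + unif(rng_init) * (pi.vt - pi.vreset);

  // Gate state.  Excitatory (AMPA, NMDA) gates are tracked as a population
  // total plus each pyramidal cell's own contribution so recurrent input to
  // cell i can exclude its own synapse; GABA onto PVIs likewise.  GABA onto
  // pyramidal cells is tracked per postsynaptic target because Bernoulli
  // release makes those gates target-specific.
  std::vector<double> xa(n_e, 0.0), sa(n_e, 0.0), xn(n_e, 0.0), sn(n_e, 0.0);
  double Xa = 0.0, Sa = 0.0, Xn = 0.0, Sn = 0.0;
  std::vector<double> xg(n_i, 0.0), sg(n_i, 0.0);
  double Xg = 0.0, Sg = 0.0;
  std::vector<double> xge(n_e, 0.0), sge(n_e, 0.0);

  const double dec_a = std::exp(-dt / tr_a), dec_n = std::exp(-dt / tr_n),
               dec_g = std::exp(-dt / tr_g);
  const double sqdt = std::sqrt(dt);
  const double mg_c = mg / 3.57;

  const int n_rec =
      (n_steps - step_trans + record_every - 1) / record_every;
  NumericVector rec_exc(n_rec), rec_exc_ampa(n_rec), rec_t(n_rec);
  int i_rec = 0;

  std::vector<int> sp_neuron;
  std::vector<double> sp_time;
  std::vector<int> fired_e, fired_i;
  fired_e.reserve(n_e);
  fired_i.reserve(n_i);

  double min_gate = 0.0;

  for (int step = 0; step < n_steps; ++step) {
    const double t = (step + 1) * dt;

    // synaptic gate integration (s driven by x, then x decays)
    Sa += dt * (Xa - Sa / td_a);
    Sn += dt * (Xn - Sn / td_n);
    Sg += dt * (Xg - Sg / td_g);
    Xa *= dec_a; Xn *= dec_n; Xg *= dec_g;
    for (int i = 0; i < n_e; ++i) {
      sa[i] += dt * (xa[i] - sa[i] / td_a); xa[i] *= dec_a;
      sn[i] += dt * (xn[i] - sn[i] / td_n); xn[i] *= dec_n;
      sge[i] += dt * (xge[i] - sge[i] / td_g); xge[i] *= dec_g;
    }
    for (int j = 0; j < n_i; ++j) {
      sg[j] += dt * (xg[j] - sg[j] / td_g); xg[j] *= dec_g;
    }

    fired_e.clear();
    fired_i.clear();

    double sum_exc = 0.0, sum_ampa = 0.0;
    const double ke = (n_e > 1) ? 1.0 / (n_e - 1) : 0.0;
    const double ki_on_e = (n_i > 0) ? 1.0 / n_i : 0.0;
    const double ke_on_i = (n_e > 0) ? 1.0 / n_e : 0.0;
    const double kii = (n_i > 1) ? 1.0 / (n_i - 1) : 0.0;

    for (int i = 0; i < n_e; ++i) {
      const double v = v_e[i];
      const double bmg = 1.0 / (1.0 + mg_c * std::exp(-0.062 * v));
      const double i_ampa = g_ee * ke * (Sa - sa[i]) * (e_exc - v);
      const double i_nmda = g_ne * ke * (Sn - sn[i]) * bmg * (e_exc - v);
      const double i_gaba = g_ie * ki_on_e * sge[i] * (e_inh - v);
      sum_ampa += i_ampa;
      sum_exc += i_ampa + i_nmda;
      if (t <= ref_e[i]) { v_e[i] = pe.vreset; continue; }
      double dv = dt * ((v - pe.vr) * (v - pe.vt) / (pe.tau * pe.dv) +
                        i_ampa + i_nmda + i_gaba + iappl[i]);
      if (noise_e > 0.0) dv += noise_e * sqdt * gauss(rng_noise);
      double vn = v + dv;
      if (!std::isfinite(vn) || vn < -1e4)
        stop("integration blow-up in pyramidal population; reduce dt (dt=%f)", dt);
      if (vn >= pe.vpeak) {
        fired_e.push_back(i);
        vn = pe.vreset;
        ref_e[i] = t + pe.tref;
        if (t > transient) { sp_neuron.push_back(i + 1); sp_time.push_back(t); }
      }
      v_e[i] = vn;
    }

    for (int j = 0; j < n_i; ++j) {
      const double v = v_i[j];
      const double bmg = 1.0 / (1.0 + mg_c * std::exp(-0.062 * v));
      const double i_ampa = g_ei * ke_on_i * Sa * (e_exc - v);
      const double i_nmda = g_ni * ke_on_i * Sn * bmg * (e_exc - v);
      const double i_gaba = g_ii * kii * (Sg - sg[j]) * (e_inh - v);
      if (t <= ref_i[j]) { v_i[j] = pi.vreset; continue; }
      double dv = dt * ((v - pi.vr) * (v - pi.vt) / (pi.tau * pi.dv) +
                        i_ampa + i_nmda + i_gaba + i_pvi);
      if (noise_i > 0.0) dv += noise_i * sqdt * gauss(rng_noise);
      double vn = v + dv;
      if (!std::isfinite(vn) || vn < -1e4)
        stop("integration blow-up in PVI population; reduce dt (dt=%f)", dt);
      if (vn >= pi.vpeak) {
        fired_i.push_back(j);
        vn = pi.vreset;
        ref_i[j] = t + pi.tref;
        if (t > transient) { sp_neuron.push_back(n_e + j + 1); sp_time.push_back(t); }
      }
      v_i[j] = vn;
    }

    // spike -> gate increments (take effect next step)
    for (int idx : fired_e) {
      Xa += 1.0; Xn += 1.0;
      xa[idx] += 1.0; xn[idx] += 1.0;
    }
    for (size_t jj = 0; jj < fired_i.size(); ++jj) {
      Xg += 1.0;
      xg[fired_i[jj]] += 1.0;
      if (per_target) {
        for (int i = 0; i < n_e; ++i)
          if (unif(rng_rel) < rp) xge[i] += 1.0;
      } else {
        if (unif(rng_rel) < rp)
          for (int i = 0; i < n_e; ++i) xge[i] += 1.0;
      }
    }

    if (step >= step_trans && (step - step_trans) % record_every == 0) {
      rec_exc[i_rec] = sum_exc;
      rec_exc_ampa[i_rec] = sum_ampa;
      rec_t[i_rec] = t;
      ++i_rec;
    }

    double mg_gate = 0.0;
    for (int i = 0; i < n_e; ++i)
      mg_gate = std::min(mg_gate, std::min(sge[i], std::min(sa[i], sn[i])));
    for (int j = 0; j < n_i; ++j) mg_gate = std::min(mg_gate, sg[j]);
    min_gate = std::min(min_gate, mg_gate);
  }

  return List::create(
      _["spike_neuron"] = wrap(sp_neuron), _["spike_time"] = wrap(sp_time),
      _["i_exc"] = rec_exc, _["i_exc_ampa"] = rec_exc_ampa,
      _["rec_time"] = rec_t, _["rec_dt"] = dt * record_every,
      _["min_gate"] = min_gate);
}
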