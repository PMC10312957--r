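---
title: "Models and methods behind pvigamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pvigamma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pvigamma` has two arms: a synthetic matched-pair cohort with the
quantification and statistics used on postmortem interneuron measurements,
and a spiking-network model linking GABA release probability from
parvalbumin interneurons (PVIs) to gamma-oscillation power. This vignette
documents the models, the defaults and why they were chosen, the numerical
choices, and the limitations a user should know about. It states no
empirical result that the package's tests and acceptance script do not
themselves compute.

## 1. The synthetic cohort

### What is emulated

Each cohort consists of `n_pairs` case/control subject pairs matched
perfectly for sex and closely for age, with tissue covariates drawn to
match a typical brain-bank cohort (age ≈ 46 ± 12 y; brain pH slightly lower
in cases, 6.5 ± 0.3 vs 6.7 ± 0.2; PMI ≈ 16 ± 6 h; RIN ≈ 8.1 ± 0.5; storage
time ≈ 107 ± 30 months with a pair-shared component, since pair tissue is
processed in parallel). Every subject carries `cells_per_subject` sampled
PVIs (default 42, roughly 850 cells over 20 subjects); each cell has
compartment areas and fluorescence intensities (cell body, nucleus,
cytoplasm) and, in the fresh-frozen assay, PV and Vamp1 mRNA grain counts.

### Distributional model

* **Intensities and grain densities are lognormal.** Fluorescence
  intensities are positive and right-skewed; the lognormal is the standard
  minimal model. Grain counts are negative binomial with the cytoplasmic
  area as offset (`mu = density × area`, size 20), the standard
  overdispersed count model for punctate in-situ signals.
* **Hierarchical variance decomposition.** On the log scale each measure
  decomposes into a pair effect (CV 0.15), a subject effect (CV 0.2) and
  cell noise (CV 0.4). The pair component is what gives the pair-blocked
  covariance model genuine blocking structure to absorb.
* **Gaussian copula across measures.** Cell- and subject-level effects for
  the five modelled measures are drawn as correlated Gaussians on the log
  scale (cytoplasmic–nuclear Rbfox1 r = 0.6; cytoplasmic
  Rbfox1–Vamp1 density r = 0.5), preserving the lognormal marginals while
  hitting the target Pearson correlations.
* **Programmed effects are multiplicative medians.** Because the log-scale
  noise is identical in both groups, the expected case/control ratio of
  subject means equals the programmed factor exactly. Defaults: 0.71 for
  cytoplasmic and nuclear Rbfox1 (a 29% deficit), 0.63 for PV intensity
  (37%), and on the fresh-frozen assay 0.86 for cytoplasmic Rbfox1 and PV
  grain density (14%) and 0.80 for Vamp1 grain density (20%).
* **Subtype enrichment.** Compartment folds relative to calretinin cells
  (CRIs): cytoplasmic Rbfox1 9.6 (PVI) and 5.0 (CBI); nuclear 3.0 and 2.6.
  Total (cell-body) intensity is *derived* as the area-weighted mix of the
  compartments. With the default baselines — cytoplasmic ≈ 18% of the
  nuclear level in CRIs and a nuclear area fraction of one half — the
  implied total folds are ≈ 4.0 (PVI) and ≈ 3.0 (CBI) and the implied
  PVI/CBI fold of the cytoplasmic-to-nuclear (C/N) ratio is
  (9.6/3.0)/(5.0/2.6) ≈ 1.66. These are emergent consistency checks, not
  separately tunable knobs.
* **Co-occurring factors** (schizoaffective diagnosis, substance use,
  nicotine, antidepressants, benzodiazepines, valproic acid, suicide) are
  assigned independently with realistic prevalences and have **no effect**
  on any measure by default, matching the negative factor scans such
  cohorts typically produce. Tissue covariates likewise carry no effect
  unless `covariate_effects` programs one.

### What a green test does and does not establish

The generator reproduces the *statistical skeleton* of a postmortem
dataset: marginals, hierarchical variance, matched-pair structure,
programmed group effects and correlations. It does not emulate
segmentation artefacts, background fluorescence, z-stack sampling,
subject exclusions, spatial layer gradients or any cell-size–intensity
coupling. A passing recovery test therefore establishes that the
statistical pipeline is unbiased and calibrated for data of this class —
not that it is robust to microscopy-specific systematics.

## 2. Per-cell quantification

The cytoplasmic mask is the cell-body mask minus the nuclear mask;
compartment intensities are plain arithmetic means over mask pixels, so the
body mean always lies between the nuclear and cytoplasmic means
(area-weighted average). Cells whose nucleus fills the body (empty
cytoplasm) are excluded, not imputed. Grain density uses the 2-D projected
cytoplasmic area.

The PVI classifier is an unsupervised stand-in for a naive Bayes
classifier: a two-component Gaussian mixture on `log(density + eps)`
fitted by EM (`eps` = half the smallest non-zero density, so zero-count
cells are admissible), the component with the larger location labelled
PVI, and a posterior-0.5 decision rule with ties broken to non-PV
(conservative: avoids inflating PVI counts). With one feature, the
Gaussian-mixture posterior *is* the naive Bayes rule. EM uses a
deterministic median split for initialisation, stops when the
log-likelihood gain falls below 1e-8 (cap 500 iterations), and reports
errors on component collapse or zero-variance input. Because `eps` scales
with the data, the classifier is scale-equivariant. One caveat of
per-class variances: at extreme densities far above both components the
wider component's tail eventually dominates, so the posterior is monotone
only over the data range — irrelevant in practice, but the reason the
tests probe the high-confidence region near the PVI component rather than
a literal limit.

## 3. Statistics

* **One-way ANOVA + Tukey HSD** over interneuron subtypes, with compact
  significance letters (groups not sharing a letter differ at 0.05).
* **Diagnosis ANCOVA** on subject means (mean over each subject's PVIs).
  Paired model: `value ~ diagnosis + pair + covariates` with the pair as a
  fixed blocking factor; unpaired model: `value ~ diagnosis + age + sex +
  covariates`. RIN enters only for mRNA-derived measures. The diagnosis
  test is a partial (type-III) F — full versus diagnosis-free fit — which
  is well defined in the presence of the block factor. The percent
  difference is computed from covariate-adjusted group means (every
  subject predicted under both diagnoses, then averaged).
* **Covariate retention** mirrors a screen-then-refit convention: fit the
  full model once, keep covariates with partial-F p < 0.05, refit — a
  single pass, no iteration.
* **Factor scans** run within the case group only, one ANCOVA per binary
  factor, Bonferroni-corrected across the seven factors (the correction
  method is a package decision; only "corrected" is conventionally
  specified for such scans).
* Fixed-effect pair blocking is not a true paired design (it costs one df
  per pair); it is used deliberately because it matches how such analyses
  are usually reported, and the type-I error of the diagnosis test is
  verified by simulation to be calibrated at α = 0.05.

## 4. The QIF gamma network

### Model

80 regular-spiking pyramidal cells and 20 fast-spiking PVIs, all-to-all
connected without self-connections. Membrane dynamics are quadratic
integrate-and-fire, `dv/dt = (v−v_r)(v−v_t)/(τ_m Δv) + I_syn + I_appl`,
spike at +25 mV, reset to −65 mV (v_r −65, v_t −50 mV). Synaptic gates are
rise/decay two-state filters incremented by presynaptic spikes (AMPA
0.5/2 ms, NMDA 2/100 ms with the standard sigmoidal magnesium block at
1 mM, GABA 0.5/8 ms; reversals 0/−70 mV). Integration is Euler–Maruyama at
dt = 0.05 ms for 2000 ms with a 500 ms transient discard. Release
probability applies to PVI→pyramidal synapses only: each presynaptic PVI
spike activates each pyramidal target's gate independently with
probability `RP_IE` (a per-spike global mode is available). One master
seed spawns three independent streams (initial conditions, drive noise,
release draws), so `RP_IE = 1` reproduces the deterministic network
exactly and different RP values share drive noise.

### Defaults and how they were set

The original parameter set for this architecture is not available, so the
defaults are the package's own calibration, chosen once so that the
deterministic network sits in a pyramidal-interneuron (PING) gamma regime
with the qualitative landmarks the model is meant to exhibit — an in-band
(~35–40 Hz) spectral peak maximal at `RP_IE = 1`, a sharp power decline to
a stable floor by RP ≈ 0.7, pyramidal rates insensitive to RP, CV_ISI
rising as RP falls, and a superadditive interaction between `G_IE` and
`RP_IE`:

| parameter | default | role |
|---|---|---|
| τ_m (both populations) | 10 ms | fast enough for an in-band PING frequency |
| t_ref pyr / PVI | 3 / 1 ms | crude stand-in for the AHP of regular-spiking cells |
| G_EE / G_NE | 0.2 / 0.01 | recurrent excitation promoting volley formation |
| G_EI / G_NI | 1.5 / 0.01 | strong E→I loop (rate compensation, volley relay) |
| G_IE | 0.7 | baseline inhibitory strength (100% weight) |
| G_II | 0.3 | PVI volley shaping |
| gain_ie | 1.15 | unit normalisation applied to G_IE so the reportable baseline stays 0.7 |
| I_appl (pyr) | 3 ± 0.3 across cells | heterogeneous drive; avoids degenerate full-network locking |
| noise SD pyr / PVI | 2.5 / 0.5 mV·ms^-1/2 | fluctuation-driven firing; sets the incoherent floor |

Pyramidal cells are moderately suprathreshold and noisy: when the PVI
volley rhythm is intact their spikes lock to it (low CV_ISI, strong
spectral peak ∝ coherent population amplitude); when stochastic release
degrades the volleys the same cells fire irregularly, the coherent peak
collapses toward the incoherent (∝ N) floor, and CV_ISI rises — while
their mean rate barely moves, because the E→I loop raises PVI firing just
enough to keep the *transmitted* inhibitory charge (`RP_IE` × PVI rate ×
G) approximately constant.

### A structural trade-off, stated openly

That last mechanism has an unavoidable corollary: if pyramidal rates are
flat while `RP_IE` falls by 30%, the PVI rate must rise by roughly 1/RP_IE
(~35%+). Pinning the PVI rate instead (tonic PVI drive, PVI refractory
caps, stronger PVI–PVI inhibition, or a doubly drive-dominated network)
was explored systematically and always sacrificed at least one gamma-power
landmark — the argmax at RP = 1, the stable nadir near 0.7, the rising
CV_ISI, or the superadditive G×RP interaction. The package keeps the
landmark-faithful regime and reports the PVI-rate sensitivity as a known
deviation: the dissociation test asserts rate stability for both
populations and fails, by design honestly, on the PVI clause. Users who
care about PVI-rate flatness more than the synergy landmark can explore
`drive$i_appl_pvi` and `pvi$t_ref`.

### Spectral and spike metrics

Gamma power is read from the Welch PSD of the summed excitatory synaptic
currents into pyramidal cells (AMPA+NMDA by default; an AMPA-only switch
exists): Hann-tapered 500 ms segments, 50% overlap, mean subtraction per
segment, one-sided density normalised so the PSD integrates to the trace
variance. "Peak gamma power" is the band maximum over 30–80 Hz (a
band-integral mode is provided; the landmark structure is insensitive to
the choice). CV_ISI uses the sample SD (n−1) over mean of ISIs per
pyramidal neuron with ≥ 3 spikes, averaged over included neurons.

### Experiments

`rp_sweep` averages metrics over `n_trials` per RP value with trial seeds
shared across values (variance reduction for curve shape). `detect_nadir`
returns the largest parameter value below which the whole curve sits
within 5% of its range above the minimum — the plateau onset.
`synergy_analysis` lowers `G_IE` alone, `RP_IE` alone, and both together
on a weight grid (100%→70% in 2.5% steps), and compares the joint
gamma-power reduction against the sum of the single-parameter reductions.
Two crossover statistics are reported: `crossover_pct` requires the joint
reduction to exceed the additive expectation at *every* grid point from
97.5% down — a chain that, at desk-scale trial counts, is decided by trial
noise near the baseline where both reductions are ≈ 0, and therefore
collapses to ~0–5% even when the joint curve visibly dominates;
`superadditive_max_pct` — the largest lowering at which the joint
reduction still exceeds the additive expectation — is robust to those
near-baseline sign flips and is the number that corresponds to the
"joint exceeds additive up to X%" statement. At 20 trials per point it
lands at ~12.5–15% on the default network. The default trial count for
publication-scale runs is 200; tests and the acceptance report use 20
trials per point and inherit proportionally wider Monte-Carlo error.

### Numerical choices

Euler–Maruyama at dt = 0.05 ms (halving dt moves the trial-averaged peak
frequency by less than one 2-Hz Welch bin); gates use exponential decay of
the rise variable and explicit Euler for the decay variable, which keeps
them non-negative for any dt below the decay constants; voltage
excursions beyond ±10^4 mV raise an integration error naming dt; spike
times are recorded at the end of the step that crosses the peak, a bias
bounded by dt.

## 5. Known limitations

* Network parameters are a calibration, not a measurement; all absolute
  power values are in model units and only parameter-relative landmarks
  are meaningful.
* The cohort generator's realism stops at the statistical skeleton
  (Section 1); it produces no images, only mask-level and count-level
  summaries.
* The unsupervised mixture classifier is a stand-in; if the original
  classifier was trained on labelled cells, its operating point may
  differ.
* Fixed-effect pair blocking, Bonferroni factor correction and type-III
  tests are package decisions where the analysis convention is
  under-specified; all are stated above and implemented in one place each.
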