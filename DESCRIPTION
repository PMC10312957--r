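Package: pvigamma
Title: Parvalbumin-Interneuron Cohort Statistics and Gamma-Oscillation
    Network Simulation
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the Rbfox1-Vamp1 pathway in prefrontal
    parvalbumin-expressing interneurons (PVIs) and its consequences for
    cortical gamma oscillations.  One arm generates synthetic matched-pair
    postmortem cohorts (compartment fluorescence intensities and mRNA grain
    counts per sampled neuron) and provides the per-cell quantification and
    matched-pair ANCOVA machinery used to estimate diagnosis effects.  The
    other arm simulates a quadratic integrate-and-fire network of pyramidal
    neurons and fast-spiking PVIs with conductance-based AMPA/NMDA/GABA
    synapses and Bernoulli release probability on inhibitory synapses, and
    measures peak gamma power, firing rates and spike-train regularity
    across release-probability and inhibitory-strength sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
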