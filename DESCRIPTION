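Package: spnsim
Title: Biophysical Simulation of Dendritic Integration in Striatal Spiny
    Projection Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multicompartment cable-equation simulator for direct-pathway
    striatal spiny projection neurons (dSPNs), built to study how
    depolarizing and shunting GABA-A receptor input interacts with
    clustered glutamatergic excitation of distal dendrites. Provides a
    calibrated synthetic morphology generator with dendritic spines,
    spatially distributed Hodgkin-Huxley-style ion channels, two-state
    kinetic AMPA/NMDA/GABA-A synapses with magnesium block, tonic GABA
    conductance, an implicit tree solver with passive characterization
    and sinusoidal impedance measurement, the stimulation protocols and
    plateau-potential metrics used to analyse on-site versus off-site
    inhibition, and reversal-potential estimation statistics for
    perforated-patch recordings (binned linear regression and the exact
    Wilcoxon signed-rank test).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
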