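Package: dbsnet
Title: Deep Brain Stimulation in Synchronized Bursting Neuron Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates pathologically synchronized populations of bursting
    neurons arranged on square lattices, as a computational model of basal
    ganglia activity in Parkinson's disease, and the desynchronizing action
    of high-frequency Deep Brain Stimulation (DBS). Two neuron backends are
    provided: a dimensionless Morris-Lecar neuron with a delayed slow
    feedback current, integrated with fixed-step RK4, and a reduced-order
    Izhikevich chattering neuron integrated with forward Euler. Networks use
    distance-weighted excitatory synapses, spatially incoherent
    exponentially correlated (Ornstein-Uhlenbeck) background noise, and
    charge-balanced biphasic 130 Hz pulse-train stimulation through one or
    four electrodes. Synchronization is quantified by a Kuramoto order
    parameter on burst-onset phases; macroscopic readouts include a
    simulated local field potential (1/r summation of ionic currents) and
    dB spectrograms. A two-population pacemaker/driven experiment and
    synthetic fixture generators for validating the metrics independently
    of the simulator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, signal, yaml, stats, graphics, grDevices, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
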