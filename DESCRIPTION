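Package: refret
Title: Simulation and Kinetic Analysis of Single-Molecule FRET Trajectories
    of RecA Filament Dynamics
Version: 0.1.0
Authors@R:
    person("refret", "developers", email = "refret@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse single-molecule FRET (smFRET)
    trajectories reporting on RecA nucleoprotein filament dynamics on
    single-stranded DNA. Includes a continuous-time Markov (Gillespie)
    simulator of filament nucleation and of monomer binding/dissociation at
    the 5' disassembly end with a realistic camera emission model (frame
    integration, shot noise, acceptor photobleaching); FRET efficiency
    computation, per-molecule histograms and Gaussian mixture fits; hidden
    Markov model trajectory idealization (Baum-Welch and Viterbi with
    Gaussian emissions); dwell-time, transition-density and kinetic-rate
    estimation including the filament growth-rate model and rate-ATPase
    correlation summaries; and a reproducible pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
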