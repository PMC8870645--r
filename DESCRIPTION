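Package: ringsim
Title: Hebbian Ring Models with Temporal-Difference Reward Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale simulator of rate-based Hebbian cognitive
    architectures built around a recurrent "Ring" of stimulus-selective
    neurons. Implements the Oja and BCM plasticity rules, a reduced
    one-step spike-timing-dependent plasticity (STDP) rule with a
    continuous-window quadrature oracle, a temporal-difference dopamine
    circuit (tapped delay lines, collector neuron, prediction-error
    unit), and a synthetic perception front end with name supervision.
    Two end-to-end assemblies (Ring Model A and Ring Model B) replicate a
    sensory-preconditioning experiment fully in silico: neutral stimulus
    pairs are associated, one member of each pair is conditioned with a
    delayed reward, and transitive reward inference is measured with
    learning-frozen probe trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
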