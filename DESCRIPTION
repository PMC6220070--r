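Package: mnsd
Title: Multi-Neuronal Spike-Sequence Detection with Latency-Based Spiking Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation of Leaky Integrate-and-Fire with Latency
    (LIFL) neurons and unsupervised learning of parallel spike sequences with
    the Multi-Neuronal spike-Sequence Detector (MNSD). Delay branches encode
    spike times through the state-dependent spike latency t_f = 1/(S - 1);
    heterosynaptic spike-timing-dependent plasticity between adjacent branches
    tunes the branch weights until a trained spatio-temporal pattern arrives
    synchronously at a coincidence-detecting target neuron. Includes the
    static-analysis relations for branch activation, target-weight bounds,
    simultaneity offsets and jitter tolerance; a synthetic generator of
    labelled Gaussian spike-time classes; a peak-time encoder for sampled
    time series; and confusion-matrix evaluation of the resulting detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
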