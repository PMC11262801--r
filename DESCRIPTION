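Package: larvaction
Title: Action Tagging and Latent Representations for Drosophila Larva
    Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying Drosophila larva behaviour from
    multi-animal tracking data. Reads and writes Choreography-style
    spine/outline files, FIMTrack-style tables and a WCON-like JSON label
    format; extracts normalized 2-s posture windows from midline tracks;
    learns a self-supervised latent representation of posture dynamics with
    an autoencoder that reconstructs past and future postures; fine-tunes a
    seven-class action classifier (crawl, bend, back, hunch, roll, stop,
    small action) on top of the encoder; and evaluates taggers with
    stimulus-aligned action-probability time series and per-action
    chi-squared tests with Bonferroni correction against a control line. A
    kinematic simulator of archetypal larval actions with ground-truth
    labels makes the whole pipeline testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
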