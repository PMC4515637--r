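Package: isica
Title: Inter-Spike-Interval Classification Analysis for Neural Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies extracellularly recorded neurons into subtypes from
    the statistics of their inter-spike intervals (ISIs). Per-unit features
    (gamma shape and scale by maximum likelihood, coefficient of variation,
    burst index, mean rate) are extracted per brain state, screened for
    departures from normality, clustered by cosine-distance k-means with
    many random restarts, and the number of clusters is selected by the
    jump method on the transformed distortion curve. Cluster quality is
    validated by Monte-Carlo comparison of the cluster index against a
    single multivariate-Gaussian null. Supporting tools detect slow-wave
    sleep from theta/delta band-power ratios of the local field potential,
    compute normalized power-density spectra, screen unit isolation quality
    (Isolation Distance, L-ratio), classify putative cell types, and analyze
    event-aligned responses (perievent Z-scores, response subcategories,
    first-spike latency). A synthetic spike-train generator with known
    ground truth makes the whole pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
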