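Package: netsi
Title: Stability Indicators for Inferred Networks with the HIM Distance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the stability of network reconstruction from
    high-throughput data. Implements the Hamming-Ipsen-Mikhailov (HIM)
    family of network distances combining a normalized edit (Hamming)
    component with a Lorentzian-smoothed Laplacian spectral
    (Ipsen-Mikhailov) component, a set of co-expression network inference
    methods (absolute Pearson correlation, soft-thresholded correlation,
    biweight midcorrelation, topological overlap, mutual information with
    ARACNE and CLR post-processing, the maximal information coefficient,
    and permutation-FDR filtered variants), and the NetSI resampling-based
    stability indicators: whole-network stability S, internal stability
    S_I, and per-edge and per-node variability rankings, with bootstrap
    confidence intervals. Includes generators for modular benchmark
    networks and block-correlated Gaussian expression surrogates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
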