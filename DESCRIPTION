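Package: wavemeg
Title: Wavelet Image Descriptors and Time-Resolved MEG Decoding with
    Representational Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links multilevel 2D Haar wavelet descriptors of visual stimuli
    to time-resolved magnetoencephalography (MEG) decoding. Provides a
    five-level Haar filter bank producing 25 descriptor vectors per
    stimulus, epoch-level preprocessing (baseline removal, peak-to-peak
    trial rejection, zero-phase low-pass filtering, PCA-based eyeblink
    removal), per-timepoint pairwise linear-SVM decoding into
    representational dissimilarity matrices (RDMs), Spearman
    representational similarity time-courses against 1-minus-Pearson
    descriptor RDMs, and nonparametric statistics: two-sided
    sign-permutation testing with cluster-size correction, bootstrap
    peak/onset latency estimates with SEM and percentile confidence
    intervals, outlier trimming, and significant-timepoint counts per
    wavelet orientation. Includes generators for synthetic stimuli with
    controlled oriented edge energy and synthetic MEG epochs with a known
    injected representational geometry and latency, so the full pipeline
    can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    png,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
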