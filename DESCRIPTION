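Package: hrvper
Title: Periodicity Measures for Heart Rate Variability Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Quantifies the periodicity of RR-interval time series, a
    characteristic of heart rate variability (HRV) that conventional time-
    and frequency-domain indices miss. Provides band-limited relative
    Lomb-Scargle spectra with the transformed Relative Shannon Entropy
    (tRSE) and spectral peak (maxPER); change-point piecewise-linear
    detrending with autocorrelation measures (maxACF, meanACF) and the
    sample entropy of the autocorrelation function (SE.ACF) using false
    nearest neighbour and mutual-information embedding selection; the
    conventional HRV battery (SDNN, RMSSD, triangular index, LF/HF,
    Poincare SD1/SD2, DFA, SampEn) as a comparator; ECG R-peak detection
    and epoching; a stochastically forced Van der Pol oscillator ensemble
    generator; and a rank-sum degree-of-monotonicity benchmark for
    comparing variability measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
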