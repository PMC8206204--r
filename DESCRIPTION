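Package: sevcor
Title: Spontaneous-Evoked Correlation Analysis for Electrophysiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates dynamic relationships between spontaneous pre-stimulus
    and stimulus-evoked electrophysiological activity (M/EEG) using two
    complementary estimators: the pseudotrial method (median split of trials
    by pre-stimulus amplitude with regression-to-the-mean correction from
    stimulus-free pseudotrials) and the trial-to-trial variability (TTV)
    method based on the law of total variance. Includes Morlet wavelet
    time-frequency decomposition with individualized frequency bands, IRASA
    separation of oscillatory and fractal (scale-free) spectral components,
    sensor-time cluster-based permutation inference with Wilcoxon signed-rank
    maps, and a generative simulation framework (1/f colored noise,
    amplitude-modulated alpha oscillations, additive or desynchronizing
    evoked responses, trial-varying signal-to-noise regimes) for validating
    both estimators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    jsonlite,
    arrow,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
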